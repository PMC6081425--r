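>miR-30c-5p-sensor-insert four perfect-complement repeats, XbaI..XmaI
TCTAGATAAGCTGAGAGTGTAGGATGTTTACACGATGCTGAGAGTGTAGGATGTTTACAACGCGTGTCGACGCTGAGAGT
GTAGGATGTTTACATCACGCTGAGAGTGTAGGATGTTTACACCCGGG
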