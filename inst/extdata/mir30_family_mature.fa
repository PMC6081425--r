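>miR-30a-5p
UGUAAACAUCCUCGACUGGAAG
>miR-30b-5p
UGUAAACAUCCUACACUCAGCU
>miR-30c-5p
UGUAAACAUCCUACACUCUCAGC
>miR-30d-5p
UGUAAACAUCCCCGACUGGAAG
>miR-30e-5p
UGUAAACAUCCUUGACUGGAAG
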