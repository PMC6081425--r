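name	oligo	description
sgRNA_1	caccgAAGCAAGCTGTGTCAAGGGA	minus-strand guide upstream of the miR-30 MRE
sgRNA_2	caccgTCTCCCAGTGGGGGGGCCCT	plus-strand guide downstream of the miR-30 MRE
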