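>MRE_WT Serpine1 miR-30 responsive element, MluI..SacI segment
AGAGTGTAGGTGACTTGTTTACA
>MRE_SEED 3prime-complementarity mutant, seed match intact
GATATTGTCCTGACTTGTTTACA
>MRE_MUT responsive element fully replaced
ACTCTGAAAGTGAAAAGCCAATG
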