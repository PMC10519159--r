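residue atom charge sigma_nm epsilon_kcal
BEA CA 0.10 0.3400 0.1094
BEA CB -0.25 0.3400 0.1094
SOL OW -0.834 0.3151 0.1521
CSL C1 0.15 0.3500 0.0660
CSL O -0.60 0.3066 0.2104
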