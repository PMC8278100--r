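cutoff=0.05
mirna_id	coefficient
miR-216a-5p	0.015
miR-194-3p	-0.035
miR-3677-3p	-0.124
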