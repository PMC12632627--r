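chr2L	0	700000	chr2L_arm	arm
chr2L	700000	1000000	chr2L_peri	pericentromeric
chr2R	0	300000	chr2R_peri	pericentromeric
chr2R	300000	1000000	chr2R_arm	arm
chr3L	0	560000	chr3L_arm	arm
chr3L	560000	800000	chr3L_peri	pericentromeric
chr3R	0	360000	chr3R_peri	pericentromeric
chr3R	360000	1200000	chr3R_arm	arm
chr4	0	300000	chr4	whole-chromosome
chrX	0	500000	chrX	whole-chromosome
chrY	0	200000	chrY	whole-chromosome
rDNA	0	8000	rDNA_unit	rDNA-unit
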