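id	equation	lb	ub	enzymatic	exchange	objective
R_glycolysis	glc -> 2 atp + 2 nadh + 2 pyr	0	1000	TRUE	FALSE	FALSE
R_acetate	pyr -> atp + nadh + ac + co2	0	1000	TRUE	FALSE	FALSE
R_lactate	nadh + pyr -> waste	0	1000	TRUE	FALSE	FALSE
R_tca	pyr -> atp + 5 nadh + 3 co2	0	1000	TRUE	FALSE	FALSE
R_oxphos	nadh + 0.5 o2 -> 2 atp	0	1000	TRUE	FALSE	FALSE
EX_glc	glc -> 	-10	0	FALSE	TRUE	FALSE
EX_o2	o2 -> 	-1000	0	FALSE	TRUE	FALSE
EX_ac	ac -> 	0	1000	FALSE	TRUE	FALSE
EX_waste	waste -> 	0	1000	FALSE	TRUE	FALSE
EX_co2	co2 -> 	0	1000	FALSE	TRUE	FALSE
DM_atp	atp -> 	0	1000	FALSE	TRUE	TRUE
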