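id	name	stoichiometry	lower_bound	upper_bound	gpr	rtype
EX_glc	glucose exchange	glc_e:-1	0	1000		exchange
EX_nh4	ammonium exchange	nh4_e:-1	0	1000		exchange
T_glc	glucose transport	glc_e:-1; glc_c:1	0	1000		transport
T_nh4	ammonium transport	nh4_e:-1; nh4_c:1	-1000	1000		transport
BIOMASS	biomass	glc_c:-1; nh4_c:-0.5; biomass:1	0	1000		biomass
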