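id	name	formula	charge	compartment	boundary
glc_e	D-glucose	C6H12O6	0	extracellular	FALSE
glc_c	D-glucose	C6H12O6	0	cytosol	FALSE
nh4_e	ammonium	H4N	1	extracellular	FALSE
nh4_c	ammonium	H4N	1	cytosol	FALSE
biomass	biomass		NA	cytosol	TRUE
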