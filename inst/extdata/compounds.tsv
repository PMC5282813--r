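name	formula	phase	charge	dGf0_kJ_mol	dHf0_kJ_mol	aliases	source
glucose	C6H12O6	aq	0	-917.22	-1264.22	C6H12O6	Thauer et al. 1977, aqueous, 1 M
ethanol	C2H6O	aq	0	-181.75	-288.30	CH3CH2OH|C2H5OH	Thauer et al. 1977, aqueous, 1 M
acetate	C2H3O2	aq	-1	-369.41	-486.01	CH3COO-|C2H3O2-	Thauer et al. 1977, anion, 1 M
propionate	C3H5O2	aq	-1	-361.08	-510.75	CH3CH2COO-|C2H5COO-	Thauer et al. 1977, anion, 1 M
butyrate	C4H7O2	aq	-1	-352.63	-535.55	CH3(CH2)2COO-|C3H7COO-	Thauer et al. 1977, anion, 1 M
water	H2O	l	0	-237.18	-285.83	H2O	Thauer et al. 1977, liquid
carbon_dioxide	CO2	g	0	-394.36	-393.51	CO2	Thauer et al. 1977, gas, 1 atm
hydrogen	H2	g	0	0	0	H2	element reference state, gas, 1 atm
methane	CH4	g	0	-50.75	-74.81	CH4	Thauer et al. 1977, gas, 1 atm
proton	H	aq	1	0	0	H+	convention: dGf0(H+) = 0 at 1 M
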