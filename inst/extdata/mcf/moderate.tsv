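rule_id	pattern	description
MCF01	[$([NX3](=O)=O),$([NX3+](=O)[O-])]	nitro group
MCF02	N=[N+]=[N-]	azide
MCF03	[CX3H1](=O)[#6]	aldehyde
MCF04	[CX3](=O)[F,Cl,Br,I]	acyl halide
MCF05	[CX4][Br,I]	alkyl bromide/iodide
MCF06	[OX2][OX2]	peroxide
MCF07	[NX3][NX2]=O	N-nitroso
MCF08	[SX2H]	thiol
MCF09	[NX3][NX3]	hydrazine
MCF10	N=C=[O,S]	iso(thio)cyanate
MCF11	C=CC(=O)[#6]	vinyl ketone (Michael acceptor)
MCF12	O=C1C=CC(=O)C=C1	quinone
MCF13	C(=O)OC(=O)	anhydride
MCF14	[CX3;!R]=[NX2;!R][#6]	acyclic imine
MCF15	[C;r3]1[O,N;r3][C;r3]1	epoxide/aziridine
MCF16	S(=O)(=O)[F,Cl,Br,I]	sulfonyl halide
MCF17	[#6]N=N[#6]	azo compound
MCF18	[CH2][CH2][CH2][CH2][CH2][CH2][CH2]	long aliphatic chain
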