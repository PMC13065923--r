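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
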