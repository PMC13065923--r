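rule_id	pattern	description
COV01	[CX3]=[CX3][CX3](=O)[NX3]	acrylamide (Michael-acceptor warhead)
COV02	C=CS(=O)(=O)	vinyl sulfone
COV03	ClCC(=O)N	chloroacetamide
COV04	C1OC1	epoxide
COV05	[CX3H1](=O)[#6]	aldehyde warhead
COV06	B(O)O	boronic acid
COV07	C=CC#N	acrylonitrile
COV08	[F,Cl,Br,I]CC(=O)[#6]	alpha-haloketone
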