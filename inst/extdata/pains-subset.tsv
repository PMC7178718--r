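# Small curated substructure-alert catalog written for this package.
# It illustrates PAINS-style screening with the supported SMARTS subset;
# it is NOT the full published PAINS catalog.
# name<TAB>smarts
anil_di_alk_para_methoxy	[CX4][OX2]c1ccc(cc1)[NX3]([CX4])[CX4]
azo_aromatic	c[NX2]=[NX2]c
para_quinone	O=C1C=CC(=O)C=C1
catechol	[OX2H]c1ccccc1[OX2H]
rhodanine_core	S=C1NC(=O)CS1
ene_one_michael	[CX3]=[CX3][CX3]=[OX1]
hydrazone_aryl	c[CX3]=[NX2][NX3]
thiol	[SX2H]
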