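# Compact SMARTS fingerprint library for fragment-enrichment analysis.
# One feature per line: name<TAB>SMARTS. The module accepts any library in
# this format (e.g. a full chemotype set); this bundled set covers the
# fragment families most often implicated in classification disagreement.
benzene_ring	c1ccccc1
fused_aromatic	[aR2]
heteroaromatic_n	[n]
heteroaromatic_o	[o]
heteroaromatic_s	[s]
furan_ring	c1ccoc1
pyrazine_ring	c1cnccn1
non_aromatic_heterocycle	[!#6;!#1;R;!a]
dioxolane	[OX2;r5][CX4;r5][OX2;r5]
lactone	[#6;R](=[OX1])[#8;R]
ester	[#6][CX3](=[OX1])[OX2][#6]
carboxylic_acid	[CX3](=[OX1])[OX2H1]
aldehyde	[CX3H1](=[OX1])[#6]
ketone	[#6][CX3](=[OX1])[#6]
vicinal_diketone	[CX3](=[OX1])[CX3](=[OX1])
ab_unsaturated_carbonyl	[CX3](=[OX1])[CX3]=[CX3]
allyl_ester	[CH2]=[CH][CH2][OX2][CX3]=[OX1]
allyl_alcohol	[CH2]=[CH][CH2][OX2H]
primary_alcohol	[CX4H2][OX2H]
secondary_alcohol	[CX4H1]([#6])([#6])[OX2H]
tertiary_alcohol	[CX4]([#6])([#6])([#6])[OX2H]
ether_aliphatic	[OX2;!$([OX2H]);!$([OX2][CX3]=[OX1])]([CX4])[CX4]
ether_aromatic	[c][OX2][#6]
thiol	[SX2H]
thioether	[#16X2;!$([#16][#16]);!$([#16H])]([#6])[#6]
disulphide	[#16X2][#16X2]
isothiocyanate	[NX2]=C=[SX1]
primary_amine	[NX3H2][#6]
aromatic_amine	[NX3][c]
amide	[NX3][CX3]=[OX1]
sulfonate	[#16](=[OX1])(=[OX1])[#8]
phosphorus	[#15]
halogen	[F,Cl,Br,I]
quaternary_carbon	[CX4]([#6])([#6])([#6])[#6]
isoprene_unit	CC(C)=C
amino_acid_backbone	[NX3][CX4][CX3](=[OX1])[OX2H1,OX1-]
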