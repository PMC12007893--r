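#matching: stereo_agnostic
# Common terpenes (rule R.16). The list ships the alcohols documented as
# expert-recognised terpenes plus a handful of ubiquitous terpene
# hydrocarbons; it is user-replaceable. Entries: SMILES<TAB>name.
CC(C)=CCCC(C)(O)C=C	linalool
CC(C)=CCCC(C)=CCCC(C)(O)C=C	nerolidol
CC1=CCC(CC1)C(C)(C)O	alpha-terpineol
CC1=CCC(O)(C(C)C)CC1	terpinen-4-ol
CC(C)C1CCC2(C)CCC3(C)C(CCC3C(C)(C)O)C12	cubebol (sesquiterpene alcohol)
OCC1=CCC2C(C)(C)C3CCC12CC3	vetiverol (sesquiterpene alcohol)
CC1=CCC(CC1)C(C)=C	limonene
CC(C)=CCCC(=C)C=C	myrcene
CC1=CCC2CC1C2(C)C	alpha-pinene
CC(C)=CCCC(C)=CCO	geraniol
CC(CCC=C(C)C)CCO	citronellol
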