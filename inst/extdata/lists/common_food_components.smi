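#matching: stereo_agnostic
# Common components of food (rule R.22). Deliberately compact, mirroring the
# reference tables shipped with the in silico tools; intended to be
# maintained as a distinct, evolving document. Entries: SMILES<TAB>name.
Cc1cnccn1	2-methylpyrazine
Cc1cnc(C)cn1	2,5-dimethylpyrazine
OC(=O)c1cccnc1	nicotinic acid
CC1=C(O)C(=O)C=CO1	maltol
CCC1=C(O)C(=O)C=CO1	ethyl maltol
COc1cc(C=O)ccc1O	vanillin
O=Cc1ccccc1	benzaldehyde
CC(C)=CCCC(C)=CC=O	citral
CC(C)C1CCC(C)CC1O	menthol
Cn1cnc2c1c(=O)n(C)c(=O)n2C	caffeine
CCCCCC(O)=O	hexanoic acid
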