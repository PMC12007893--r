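#matching: stereo_agnostic
# Normal constituents of the body (rule R.1). Membership is stereo-agnostic:
# the rule wording admits optical isomers. Entries: SMILES<TAB>name<TAB>ref.
NCC(O)=O	glycine	proteinogenic amino acid
N[C@@H](C)C(O)=O	L-alanine	proteinogenic amino acid
N[C@@H](C(C)C)C(O)=O	L-valine	proteinogenic amino acid
N[C@@H](CC(C)C)C(O)=O	L-leucine	proteinogenic amino acid
N[C@@H]([C@@H](C)CC)C(O)=O	L-isoleucine	proteinogenic amino acid
OC(=O)[C@@H]1CCCN1	L-proline	proteinogenic amino acid
N[C@@H](Cc1ccccc1)C(O)=O	L-phenylalanine	proteinogenic amino acid
N[C@@H](Cc1ccc(O)cc1)C(O)=O	L-tyrosine	proteinogenic amino acid
N[C@@H](Cc1c[nH]c2ccccc12)C(O)=O	L-tryptophan	proteinogenic amino acid
N[C@@H](CO)C(O)=O	L-serine	proteinogenic amino acid
N[C@@H]([C@H](O)C)C(O)=O	L-threonine	proteinogenic amino acid
N[C@@H](CS)C(O)=O	L-cysteine	proteinogenic amino acid
N[C@@H](CCSC)C(O)=O	L-methionine	proteinogenic amino acid
N[C@@H](CC(N)=O)C(O)=O	L-asparagine	proteinogenic amino acid
N[C@@H](CCC(N)=O)C(O)=O	L-glutamine	proteinogenic amino acid
N[C@@H](CC(O)=O)C(O)=O	L-aspartic acid	proteinogenic amino acid
N[C@@H](CCC(O)=O)C(O)=O	L-glutamic acid	proteinogenic amino acid
N[C@@H](CCCCN)C(O)=O	L-lysine	proteinogenic amino acid
N[C@@H](CCCNC(N)=N)C(O)=O	L-arginine	proteinogenic amino acid
N[C@@H](Cc1c[nH]cn1)C(O)=O	L-histidine	proteinogenic amino acid
CC(O)C(O)=O	lactic acid	glycolysis metabolite
CC(=O)C(O)=O	pyruvic acid	glycolysis metabolite
CC(O)=O	acetic acid	metabolic intermediate
CCO	ethanol	endogenous at trace levels
OC(=O)CCC(O)=O	succinic acid	citric acid cycle
OC(=O)/C=C/C(O)=O	fumaric acid	citric acid cycle
OC(=O)CC(O)C(O)=O	malic acid	citric acid cycle
OC(=O)CC(O)(CC(O)=O)C(O)=O	citric acid	citric acid cycle
OCC(O)CO	glycerol	lipid backbone
NC(N)=O	urea	nitrogen excretion
C[N+](C)(C)CCO	choline	phospholipid constituent
OC[C@H]1OC(O)[C@H](O)[C@@H](O)[C@@H]1O	D-glucose	blood sugar
OC[C@H]1OC(O)(CO)[C@@H](O)[C@@H]1O	D-fructose	monosaccharide
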