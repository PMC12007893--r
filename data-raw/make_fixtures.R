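# Generates inst/extdata/fixtures.json: the packaged corpus of named
# compounds with their documented expected classes per scheme. Expectations
# are recorded only for the schemes whose handling of the compound is pinned
# down; expert judgments, where documented, are stored separately (the two
# may legitimately disagree - that disagreement is the subject matter).
# `citation` keys the entry to a paragraph of inst/extdata/fixture_notes.md.

suppressMessages(library(jsonlite))

fx <- function(name, smiles, group, citation, expert = NA, original = NA,
               extended = NA, revised = NA)
  list(name = name, smiles = smiles, group = group, citation = citation,
       expert_class = expert,
       expectations = Filter(Negate(is.na),
                             list(original = original, extended = extended,
                                  revised = revised)))

entries <- list(
  fx("hex-5-en-2-one", "C=CCCC(C)=O", "aliphatic ketones", "ketones",
     expert = "II", original = "II", revised = "I"),
  fx("3-methylpentan-2-one", "CCC(C)C(C)=O", "aliphatic ketones", "ketones",
     expert = "II", original = "II"),
  fx("hexan-2-one", "CCCCC(C)=O", "aliphatic ketones", "ketones",
     expert = "II", original = "II", revised = "I"),
  fx("cis-5-octen-2-one", "CC/C=C\\CCC(C)=O", "aliphatic ketones",
     "ketones", revised = "I"),
  fx("6-methylheptan-3-one", "CCC(=O)CCC(C)C", "aliphatic ketones",
     "ketones", revised = "I"),
  fx("propane-1-thiol", "CCCS", "thiols", "sulphur",
     expert = "I", original = "I", revised = "III"),
  fx("methyl propyl sulphide", "CSCCC", "thioethers", "sulphur",
     expert = "I", original = "I", extended = "III", revised = "I"),
  fx("propane-1,3-dithiol", "SCCCS", "thiols", "sulphur",
     expert = "I", original = "III"),
  fx("2,4-dithiapentane", "CSCSC", "thioethers", "sulphur",
     expert = "I", original = "III"),
  fx("1,2,4-trithiolane", "C1SSCS1", "cyclic polysulphides",
     "polysulphides", expert = "II", original = "III", revised = "III"),
  fx("3,6-dimethyl-1,2,4,5-tetrathiane", "CC1SSC(C)SS1",
     "cyclic polysulphides", "polysulphides",
     expert = "II", original = "III", revised = "III"),
  fx("diethyl disulphide", "CCSSCC", "acyclic polysulphides",
     "polysulphides", expert = "I", original = "I", revised = "III"),
  fx("pentano-1,4-lactone", "CC1CCC(=O)O1", "lactones", "lactones",
     expert = "I", original = "I", revised = "I"),
  fx("4-butyloctano-1,4-lactone", "CCCCC1(CCCC)CCC(=O)O1", "lactones",
     "lactones", expert = "I", original = "I", revised = "I"),
  fx("butyro-1,4-lactone", "O=C1CCCO1", "lactones", "lactones",
     expert = "I", original = "I", revised = "I"),
  fx("coumarin", "O=C1C=Cc2ccccc2O1", "lactones", "lactones",
     original = "III", revised = "III"),
  fx("phthalide", "O=C1OCc2ccccc12", "lactones", "lactones",
     revised = "III"),
  fx("L-cysteine", "N[C@@H](CS)C(O)=O", "amino acids", "amino-acids",
     expert = "III", original = "I"),
  fx("L-phenylalanine", "N[C@@H](Cc1ccccc1)C(O)=O", "amino acids",
     "amino-acids", expert = "III", original = "I"),
  fx("L-arginine", "N[C@@H](CCCNC(N)=N)C(O)=O", "amino acids",
     "amino-acids", expert = "III", original = "I"),
  fx("L-alanine", "N[C@@H](C)C(O)=O", "amino acids", "amino-acids",
     original = "I", revised = "I"),
  fx("calcium lactate", "[Ca+2].CC(O)C([O-])=O.CC(O)C([O-])=O", "salts",
     "salts"),
  fx("sodium dodecyl sulphate", "[Na+].CCCCCCCCCCCCOS([O-])(=O)=O",
     "salts", "salts"),
  fx("taurine", "NCCS(O)(=O)=O", "salts", "salts", original = "III"),
  fx("1,4-benzenediamine", "Nc1ccc(N)cc1", "complex aromatics",
     "complex-aromatics", expert = "III", original = "III"),
  fx("benzyl octyl ether", "CCCCCCCCOCc1ccccc1", "ethers",
     "complex-aromatics", expert = "III", original = "III",
     revised = "III"),
  fx("benzyl methyl ether", "COCc1ccccc1", "ethers", "ethers"),
  fx("prenyl ethyl ether", "CCOCC=C(C)C", "ethers", "ethers",
     revised = "I"),
  fx("linalool", "CC(C)=CCCC(C)(O)C=C", "terpenes", "terpenes",
     expert = "I", original = "I"),
  fx("nerolidol", "CC(C)=CCCC(C)=CCCC(C)(O)C=C", "terpenes", "terpenes",
     expert = "I", original = "I"),
  fx("limonene", "CC1=CCC(CC1)C(C)=C", "terpenes", "terpenes",
     original = "I"),
  fx("2,3,4-trimethyl-3-pentanol", "CC(C)C(C)(O)C(C)C",
     "tertiary alcohols", "alcohols", expert = "I", original = "I"),
  fx("hexan-3-ol", "CCCC(O)CC", "secondary alcohols", "alcohols",
     expert = "I", original = "I"),
  fx("1-phenylpropan-1-ol", "CCC(O)c1ccccc1", "secondary alcohols",
     "alcohols", expert = "I", original = "I"),
  fx("3,3,5-trimethylcyclohexan-1-ol", "CC1(C)CC(O)CC(C)C1",
     "secondary alcohols", "alcohols", original = "I"),
  fx("oct-3-en-2-ol", "CC(O)C=CCCCC", "secondary alcohols", "alcohols",
     original = "I"),
  fx("2-methylpyrazine", "Cc1cnccn1", "simple heterocycles",
     "heterocycles", expert = "II", original = "II"),
  fx("2,5-dimethylpyrazine", "Cc1cnc(C)cn1", "simple heterocycles",
     "heterocycles", original = "II"),
  fx("nicotinic acid", "OC(=O)c1cccnc1", "simple heterocycles",
     "heterocycles", original = "II"),
  fx("maltol", "CC1=C(O)C(=O)C=CO1", "simple heterocycles",
     "heterocycles", original = "II"),
  fx("ethyl maltol", "CCC1=C(O)C(=O)C=CO1", "simple heterocycles",
     "heterocycles", original = "II"),
  fx("2-methyltetrahydrofuran", "CC1CCCO1", "simple heterocycles",
     "heterocycles", original = "III", revised = "II"),
  fx("furfural", "O=Cc1ccco1", "simple heterocycles", "heterocycles",
     expert = "II", original = "III"),
  fx("allyl isothiocyanate", "C=CCN=C=S", "isothiocyanates",
     "isothiocyanates", expert = "II", original = "III", revised = "III"),
  fx("diacetyl", "CC(=O)C(C)=O", "vicinal diketones", "diketones",
     expert = "II", original = "III", revised = "III"),
  fx("cinnamaldehyde", "O=C/C=C/c1ccccc1",
     "alpha,beta-unsaturated carbonyls", "ab-unsaturated",
     original = "I", revised = "II"),
  fx("beta-ionone", "CC(=O)/C=C/C1=C(C)CCCC1(C)C",
     "alpha,beta-unsaturated carbonyls", "ab-unsaturated",
     original = "I", revised = "II"),
  fx("acrolein", "C=CC=O", "alpha,beta-unsaturated carbonyls",
     "ab-unsaturated", original = "II", revised = "II"),
  fx("allyl acetate", "CC(=O)OCC=C", "allyl esters", "allyl",
     original = "II", revised = "III"),
  fx("D-glucose", "OC[C@H]1OC(O)[C@H](O)[C@@H](O)[C@@H]1O",
     "carbohydrates", "carbohydrates", expert = "I", original = "I"),
  fx("4-methyl-1,3-dioxolane", "CC1COCO1", "1,3-dioxolanes", "dioxolanes",
     original = "III", revised = "I"),
  fx("4,5-dimethyl-1,3-dioxolane", "CC1OCOC1C", "1,3-dioxolanes",
     "dioxolanes", original = "III", revised = "III"),
  fx("4,5,5-trimethyl-1,3-dioxolane", "CC1OCOC1(C)C", "1,3-dioxolanes",
     "dioxolanes", revised = "I")
)

write_json(entries, "inst/extdata/fixtures.json", auto_unbox = TRUE,
           pretty = TRUE, null = "null")
cat("wrote", length(entries), "fixture entries\n")
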