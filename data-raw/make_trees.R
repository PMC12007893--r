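# Generates the shipped decision-tree JSON definitions under
# inst/extdata/trees/. Run from the repository root:
#   Rscript data-raw/make_trees.R
#
# The original 33-question topology follows the 1978 scheme as commonly
# reproduced; rule ids and the behaviour of every rule discussed in the
# concordance literature (R.1 body list, R.4 salts, R.5 carbohydrates,
# R.7 heterocycles, R.9 lactones, R.12/R.14 heterocycle routing, R.16/R.17
# terpenes, R.18 list question, R.20 acyclic list question, R.22 food
# components, R.23/R.24/R.26 alicyclics, R.30 complex aromatics) are encoded
# as written. Connective nodes whose wording is not pinned down are marked
# provenance = "reconstructed"; revised-tree nodes borrowed from the original
# topology are marked provenance = "fallback".

suppressMessages(library(jsonlite))

node <- function(text, kind, expression, yes, no, yes_transform = NULL,
                 no_transform = NULL, provenance = "as_written") {
  out <- list(text = text,
              predicate = list(kind = kind, expression = expression),
              yes = yes, no = no)
  if (!is.null(yes_transform)) out$yes_transform <- yes_transform
  if (!is.null(no_transform)) out$no_transform <- no_transform
  out$provenance <- provenance
  out
}

# ---- shared SMARTS pattern dictionary --------------------------------------

patterns <- list(
  alert_small_ring_het = "[O,N;r3]",
  alert_n_nitroso = "[NX3][NX2]=[OX1]",
  alert_azo = "[#6][NX2]=[NX2][#6]",
  alert_hydrazine = "[NX3][NX3]",
  alert_sec_amine =
    "[NX3H1;!R;!$([NX3H1][CX3]=[OX1]);!$([NX3H1]c)]([CX4])[CX4]",
  alert_quat_n = "[NX4+;H0]",
  ring = "[R]",
  heterocyclic = "[!#6;!#1;R]",
  lactone = "[#6;R](=[OX1])[#8;R]",
  lactone_ab_unsat = "[#8;R][#6;R](=[OX1])[#6]=,:[#6]",
  lactone_fused_o = "[#8;R2][#6;R](=[OX1])",
  lactone_fused_c = "[#6;R2][#6;R](=[OX1])[#8;R]",
  lactone_fused_n = "[#8;R]([#6;R]=[OX1])[#6;R2]",
  aromatic = "[a]",
  small_ring_het = "[!#6;!#1;r3,r4]",
  fused_aromatic = "[aR2]",
  biphenyl = "c1ccc(cc1)-c1ccccc1",
  ring_enone = "[CX3;R](=[OX1])[#6;R]=,:[#6;R]",
  phthalide = "[#8;R]1[#6;R](=[OX1])c2ccccc2[#6;R]1",
  coumarin = "O=[#6;R]1~[#6;R]~[#6;R]~[#6;R]2~[#6;R]~[#6;R]~[#6;R]~[#6;R]~[#6;R]2[#8;R]1",
  allyl_alcohol = "[CH2]=[CH][CH2][OX2H]",
  allyl_ester = "[CH2]=[CH][CH2][OX2][CX3]=[OX1]",
  allyl_acetal = "[CH2]=[CH][CH2][OX2][CX4]",
  acrolein = "[CX3H1](=[OX1])[CX3]=[CX3H2]",
  methacrolein = "[CX3H1](=[OX1])[CX3]([CX4H3])=[CX3H2]",
  acrylic_acid = "[OX2H][CX3](=[OX1])[CX3]=[CX3H2]",
  methacrylic_acid = "[OX2H][CX3](=[OX1])[CX3]([CX4H3])=[CX3H2]",
  vinyl_ketone = "[#6][CX3](=[OX1])[CX3]=[CX3H2]",
  vicinal_diketone = "[CX3](=[OX1])[CX3](=[OX1])",
  vicinal_sec_diol = "[CX4H1]([#6])([OX2H])[CX4H1]([#6])[OX2H]",
  ab_unsat_aldehyde = "[CX3H1](=[OX1])[CX3]=[CX3;H1,H2]",
  ab_unsat_ketone = "[#6][CX3](=[OX1])[CX3]=[CX3;H1,H2]",
  thioether_s = "[#16X2;!$([#16][#16]);!$([#16H])]([#6])[#6]",
  polysulphide_ss = "[#16X2][#16X2]",
  enol_ether = "[OX2;!$([OX2H])]([CX4])[CX3]=[CX3]"
)

ALERTS <- paste("alert_small_ring_het | alert_n_nitroso | alert_azo",
                "| alert_hydrazine | alert_sec_amine | alert_quat_n")

# ---- original scheme -------------------------------------------------------

original_nodes <- list(

  R.1 = node("Is the substance a normal constituent of the body or an optical isomer of such?",
             "lookup_membership", "body_constituents", "I", "R.2"),

  R.2 = node("Does the substance contain functional groups associated with enhanced toxicity (epoxide/aziridine, N-nitroso, azo, hydrazine, aliphatic secondary amine, quaternary nitrogen)?",
             "smarts_boolean_expr", ALERTS, "III", "R.3"),

  R.3 = node("Does the substance contain elements other than carbon, hydrogen, oxygen, nitrogen or divalent sulphur?",
             "element_set", "C,H,O,N,S2", "R.4", "R.5"),

  R.4 = node("Are those elements present only as a sodium, potassium, calcium, magnesium or ammonium salt of a carboxylic, sulphonic, sulphamic or sulphuric acid, or as an amine hydrochloride?",
             "computed", "common_salt", "R.5", "III",
             yes_transform = "counterion_removal"),

  R.5 = node("Is the substance a simply branched acyclic aliphatic hydrocarbon or a common carbohydrate?",
             "computed", "acyclic_hydrocarbon_or_carbohydrate", "I", "R.6"),

  R.6 = node("Does the substance contain a ring of any kind?",
             "smarts", "[R]", "R.7", "R.16",
             provenance = "reconstructed"),

  R.7 = node("Is the substance heterocyclic?",
             "smarts", "[!#6;!#1;R]", "R.8", "R.16"),

  R.8 = node("Is the substance a lactone or cyclic diester?",
             "smarts", "[#6;R](=[OX1])[#8;R]", "R.9", "R.10",
             provenance = "reconstructed"),

  R.9 = node("Is the lactone alpha,beta-unsaturated or fused to another ring?",
             "smarts_boolean_expr",
             "lactone_ab_unsat | lactone_fused_o | lactone_fused_c | lactone_fused_n",
             "III", "R.20", no_transform = "lactone_hydrolysis"),

  R.10 = node("Is the heterocyclic ring aromatic?",
              "smarts", "[a]", "R.13", "R.11",
              provenance = "reconstructed"),

  R.11 = node("Does the substance contain a strained three- or four-membered heterocyclic ring?",
              "smarts", "[!#6;!#1;r3,r4]", "III", "R.12",
              provenance = "reconstructed"),

  R.12 = node("Is the non-aromatic heterocycle a polyhydroxylated, sugar-like ring?",
              "computed", "sugar_like_polyol", "R.18", "R.22",
              provenance = "reconstructed"),

  R.13 = node("Is the aromatic heterocycle fused to a further ring?",
              "smarts", "[aR2]", "III", "R.14",
              provenance = "reconstructed"),

  R.14 = node("Is the aromatic heterocycle a monocyclic azine (pyridine- or pyrazine-type nitrogen ring)?",
              "computed", "bare_azine_ring", "R.15", "R.22",
              provenance = "reconstructed"),

  R.15 = node("Is the heterocycle, or an obvious metabolite of it, a common component of food?",
              "lookup_membership", "common_food_components", "II", "III",
              provenance = "reconstructed"),

  R.16 = node("Is the substance a common terpene (hydrocarbon, alcohol, aldehyde or ester thereof)?",
              "computed", "common_terpene", "R.17", "R.19"),

  R.17 = node("Does the terpene bear functional groups other than those typical of common terpenes (hydroxyl, carbonyl, ester)?",
              "computed", "terpene_unusual_functionality", "II", "I"),

  R.18 = node("Does the substance bear any of: allyl alcohol or its acetal, ketal or ester derivative; acrolein or methacrolein; acrylic or methacrylic acid; a ketone adjacent to a terminal vinyl unit; or a ketone with a chain of four or more carbon atoms on a carbonyl wing?",
              "computed", "q18_features", "II", "I"),

  R.19 = node("Is the substance open chain (acyclic)?",
              "smarts_boolean_expr", "!ring", "R.20", "R.23"),

  R.20 = node("Does the substance possess no more than one each of one or more of: hydroxyl, aldehyde, ketone, carboxylic acid, ester, thiol, thioether or polysulphide, and no other functional groups?",
              "computed", "one_each_functional_groups", "R.21", "R.22"),

  R.21 = node("Is the carbon skeleton simply branched, free of quaternary carbon centres?",
              "computed", "no_quaternary_carbon", "R.18", "R.22",
              provenance = "reconstructed"),

  R.22 = node("Is the substance a common component of food?",
              "lookup_membership", "common_food_components", "II", "III"),

  R.23 = node("Is the substance aromatic?",
              "smarts", "[c]", "R.27", "R.24"),

  R.24 = node("Does the alicyclic substance possess no more than one each of one or more of the functional groups listed at R.20?",
              "computed", "one_each_functional_groups", "R.25", "R.26"),

  R.25 = node("Does the ring system contain an alpha,beta-unsaturated (conjugated) ring ketone?",
              "smarts", "[CX3;R](=[OX1])[#6;R]=,:[#6;R]", "R.26", "R.18",
              provenance = "reconstructed"),

  R.26 = node("Are the multiple functional groups exclusively hydroxyls (a simple polyol)?",
              "computed", "hydroxyls_only_functionality", "R.18", "R.22",
              provenance = "reconstructed"),

  R.27 = node("Does the substance contain more than one aromatic ring (fused or directly linked)?",
              "smarts_boolean_expr", "fused_aromatic | biphenyl",
              "R.28", "R.30", provenance = "reconstructed"),

  R.28 = node("Do the multiple aromatic rings bear complex substituents?",
              "computed", "complex_aromatic_substituents", "III", "R.29",
              provenance = "reconstructed"),

  R.29 = node("Do the multiple aromatic rings bear any substituent at all?",
              "smarts", "[c][!c;!#1]", "R.30", "III",
              provenance = "reconstructed"),

  R.30 = node("Is the benzene ring substituted with complex substituents (incorporating nitrogen or sulphur in any form, or carbon chains in excess of five carbons not readily hydrolysed to shorter ring substituents)?",
              "computed", "complex_aromatic_substituents", "R.31", "R.18"),

  R.31 = node("Are the complex substituents free of nitrogen and sulphur and reducible, by ester hydrolysis, to ring substituents of five or fewer carbons?",
              "computed", "complex_substituents_reducible", "R.32", "III",
              provenance = "reconstructed"),

  R.32 = node("Are the anticipated hydrolysis products free of the structural alerts listed at R.2?",
              "computed", "hydrolysis_products_clear_alerts", "R.33", "III",
              provenance = "reconstructed"),

  R.33 = node("Does the ring bear more than two substituted positions?",
              "computed", "ring_multi_substituted", "III", "II",
              provenance = "reconstructed")
)

# ---- five extension rules --------------------------------------------------

extension_nodes <- list(
  R.40 = node("Does the substance contain phosphorus (organophosphates and related)?",
              "smarts", "[#15]", "III", "R.41"),
  R.41 = node("Does the substance contain an unsaturated heteroatom moiety of the imine or azomethine type?",
              "smarts", "[CX3]=[NX2]", "III", "R.42"),
  R.42 = node("Is the substance benzene or a benzene-like simple aromatic hydrocarbon?",
              "computed", "benzene_like_hydrocarbon", "III", "R.43"),
  R.43 = node("Does the substance contain potentially harmful divalent sulphur as a thioether or polysulphide?",
              "smarts_boolean_expr", "thioether_s | polysulphide_ss",
              "III", "R.44"),
  R.44 = node("Does the substance contain an unsaturated heteroatom moiety of the enol ether or vinyl ester type?",
              "smarts", "[OX2;!$([OX2H])]([#6])[CX3]=[CX3]", "III", "R.3")
)

lookup_lists <- list(
  body_constituents = list(file = "body_constituents.smi",
                           matching = "stereo_agnostic"),
  common_carbohydrates = list(file = "common_carbohydrates.smi",
                              matching = "stereo_agnostic"),
  common_terpenes = list(file = "common_terpenes.smi",
                         matching = "stereo_agnostic"),
  common_food_components = list(file = "common_food_components.smi",
                                matching = "stereo_agnostic")
)

original <- list(
  scheme_name = "original",
  variant = "base",
  root = "R.1",
  product_combination = "worst_case",
  preprocessors = list(),
  config = list(ketone_chain_reading = "either_side",
                terpene_smarts = FALSE),
  patterns = patterns,
  lookup_lists = lookup_lists,
  nodes = original_nodes
)

extended <- original
extended$variant <- "extended"
extended$nodes <- c(original_nodes, extension_nodes)
extended$nodes$R.2$no <- "R.40"

# ---- revised scheme --------------------------------------------------------

revised_nodes <- list(

  R.2 = node("Is the substance an L-amino acid, or a simple linear alkyl alcohol, carboxylic acid or aldehyde?",
             "computed", "l_amino_acid_or_simple_linear", "I", "R.3"),

  R.3 = node("Does the substance contain functional groups associated with enhanced toxicity (epoxide/aziridine, N-nitroso, azo, hydrazine, aliphatic secondary amine, quaternary nitrogen)?",
             "smarts_boolean_expr", ALERTS, "III", "R.4",
             provenance = "fallback"),

  R.4 = node("Does the substance contain elements other than carbon, hydrogen, oxygen, nitrogen or divalent sulphur?",
             "element_set", "C,H,O,N,S2", "R.5", "R.6",
             provenance = "fallback"),

  R.5 = node("Is the substance a metallic (sodium, potassium, calcium, magnesium, ammonium) salt of a carboxylic or sulphonic acid, or an amine hydrochloride?",
             "computed", "common_salt", "R.6", "III",
             yes_transform = "counterion_removal"),

  R.6 = node("Is the substance a common carbohydrate, or a monocyclic or bicyclic terpene (10 or 15 carbon terpene hydrocarbons)?",
             "computed", "carbohydrate_or_terpene_hydrocarbon", "I", "R.7"),

  R.7 = node("Is the substance heterocyclic?",
             "smarts", "[!#6;!#1;R]", "R.8", "R.23",
             provenance = "fallback"),

  R.8 = node("Is the substance a lactone or cyclic diester?",
             "smarts", "[#6;R](=[OX1])[#8;R]", "R.9", "R.10",
             provenance = "fallback"),

  R.9 = node("Is the lactone a phthalide or a coumarin?",
             "smarts_boolean_expr", "phthalide | coumarin",
             "III", "R.16", no_transform = "lactone_hydrolysis"),

  R.10 = node("Is the heterocyclic ring aromatic?",
              "smarts", "[a]", "R.13", "R.11",
              provenance = "fallback"),

  R.11 = node("Does the substance contain a strained three- or four-membered heterocyclic ring?",
              "smarts", "[!#6;!#1;r3,r4]", "III", "R.12",
              provenance = "fallback"),

  R.12 = node("Is the substance a simple non-aromatic heterocycle bearing only innocuous substituents?",
              "computed", "simple_heterocycle", "II", "III"),

  R.13 = node("Is the aromatic heterocycle fused to a further ring?",
              "smarts", "[aR2]", "III", "R.14",
              provenance = "fallback"),

  R.14 = node("Is the substance a simple monocyclic aromatic heterocycle bearing only innocuous substituents?",
              "computed", "simple_heterocycle", "II", "III"),

  R.16 = node("Does the substance possess no more than one each of one or more of: hydroxyl, aldehyde, ketone, carboxylic acid, ester, methoxy or ethoxy ether, or thioether - thiols and polysulphides qualifying only alongside other functionality - and no other functional groups?",
              "computed", "revised_16_condition", "R.17", "R.18c"),

  R.17 = node("Is the substance allyl alcohol or an ester of allyl alcohol?",
              "smarts_boolean_expr", "allyl_alcohol | allyl_ester",
              "III", "R.18"),

  R.18 = node("Does the substance bear vicinal diacetyl groups, or a vicinal diol in which both hydroxyls are secondary (oxidisable to a vicinal dione)?",
              "smarts_boolean_expr", "vicinal_diketone | vicinal_sec_diol",
              "III", "R.18b"),

  R.18b = node("Is the substance an alpha,beta-unsaturated aldehyde or ketone with no or one beta-carbon substituent?",
               "smarts_boolean_expr", "ab_unsat_aldehyde | ab_unsat_ketone",
               "II", "I"),

  R.18c = node("Does the substance bear vicinal diacetyl groups, or a vicinal diol in which both hydroxyls are secondary (oxidisable to a vicinal dione)?",
               "smarts_boolean_expr", "vicinal_diketone | vicinal_sec_diol",
               "III", "R.18d"),

  R.18d = node("Is the substance an alpha,beta-unsaturated aldehyde or ketone with no or one beta-carbon substituent?",
               "smarts_boolean_expr", "ab_unsat_aldehyde | ab_unsat_ketone",
               "II", "R.18e"),

  R.18e = node("Are the functional groups in excess exclusively hydroxyls or carboxylic acids (a simple polyol or polyacid)?",
               "computed", "hydroxyls_or_acids_only", "I", "III",
               provenance = "reconstructed"),

  R.23 = node("Is the substance aromatic?",
              "smarts", "[c]", "R.25", "R.16",
              provenance = "fallback"),

  R.25 = node("Do the aromatic ring substituents incorporate nitrogen or sulphur in any form?",
              "computed", "aromatic_substituent_with_ns", "III", "R.26"),

  R.26 = node("Do the aromatic ring substituents incorporate an ether linkage or a carbon chain in excess of five carbons?",
              "computed", "aromatic_ether_or_long_chain", "III", "R.27"),

  R.27 = node("Are the aromatic ring substituents otherwise complex?",
              "computed", "complex_aromatic_substituents", "III", "R.17")
)

revised <- list(
  scheme_name = "revised",
  variant = "base",
  root = "R.2",
  product_combination = "worst_case",
  preprocessors = list("ester_hydrolysis", "acetal_hydrolysis",
                       "disulphide_reduction"),
  config = list(follow_intent_over_behavior = TRUE),
  patterns = patterns,
  lookup_lists = setNames(list(), character(0)),
  nodes = revised_nodes
)

dir.create("inst/extdata/trees", recursive = TRUE, showWarnings = FALSE)
write_json(original, "inst/extdata/trees/cramer_original.json",
           auto_unbox = TRUE, pretty = TRUE)
write_json(extended, "inst/extdata/trees/cramer_extended.json",
           auto_unbox = TRUE, pretty = TRUE)
write_json(revised, "inst/extdata/trees/cramer_revised.json",
           auto_unbox = TRUE, pretty = TRUE)
cat("wrote 3 tree definitions\n")
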