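test_that("the base tree has 33 question nodes and the extended tree 38", {
  expect_length(treeNodes(cachedTree("original")), 33L)
  expect_length(treeNodes(cachedTree("extended")), 38L)
})

test_that("tree construction is deterministic", {
  t1 <- buildOriginalTree()
  t2 <- buildOriginalTree()
  expect_identical(t1@nodes, t2@nodes)
  expect_identical(t1@patterns, t2@patterns)
  expect_identical(lapply(lookupLists(t1), function(l) l@members),
                   lapply(lookupLists(t2), function(l) l@members))
})

test_that("look-up membership honours the stereo policy of each list", {
  tree <- cachedTree("original")
  body <- lookupLists(tree)$body_constituents
  # optical isomers of listed body constituents qualify
  expect_true(lookupMembership("N[C@@H](C)C(O)=O", body))  # L-alanine
  expect_true(lookupMembership("N[C@H](C)C(O)=O", body))   # D-alanine
  expect_true(lookupMembership("NC(C)C(O)=O", body))       # undefined stereo
  expect_false(lookupMembership("c1ccccc1", body))
  food <- lookupLists(tree)$common_food_components
  expect_true(lookupMembership("Cc1cnccn1", food))         # 2-methylpyrazine
  expect_false(lookupMembership("CCO", food))
  empty <- new("LookupList", name = "x", members = character(0),
               matching = "stereo_agnostic")
  expect_error(lookupMembership("CCO", empty), "empty")
})

test_that("rule-level answers match the documented as-written readings", {
  tree <- cachedTree("original")
  # salt rule: recognises metallic carboxylate/sulphate salts ...
  expect_true(evaluateOriginalRule(
    "R.4", "[Ca+2].CC(O)C([O-])=O.CC(O)C([O-])=O", tree))
  expect_true(evaluateOriginalRule(
    "R.4", "[Na+].CCCCCCCCCCCCOS([O-])(=O)=O", tree))
  # ... but answers no for an un-ionised sulphonic acid
  expect_false(evaluateOriginalRule("R.4", "NCCS(O)(=O)=O", tree))
  # complex-aromatic rule flags nitrogen-bearing substituents
  expect_true(evaluateOriginalRule("R.30", "Nc1ccc(N)cc1", tree))
  expect_false(evaluateOriginalRule("R.30", "Cc1ccccc1", tree))
  # R.18 does not fire on a mere secondary alcohol
  expect_false(evaluateOriginalRule("R.18", "CCCC(O)CC", tree))
  expect_error(evaluateOriginalRule("R.99", "CCO", tree), "unknown rule")
})

test_that("the ketone chain rule depends on the configured reading", {
  tree <- cachedTree("original")
  both <- cachedTree("original_both_sides")
  # hex-5-en-2-one: one wing of four carbons
  expect_true(evaluateOriginalRule("R.18", "C=CCCC(C)=O", tree))
  expect_false(evaluateOriginalRule("R.18", "C=CCCC(C)=O", both))
  # nonan-5-one: four carbons on both wings
  expect_true(evaluateOriginalRule("R.18", "CCCCC(=O)CCCC", both))
})

test_that("documented original-scheme classifications are reproduced", {
  tree <- cachedTree("original")
  cls <- function(smi) as.character(finalClass(evaluateTree(tree, smi)))
  expect_identical(cls("CCCCC(C)=O"), "II")    # hexan-2-one
  expect_identical(cls("N[C@@H](CS)C(O)=O"), "I")  # L-cysteine via body list
  expect_identical(cls("CSCSC"), "III")        # 2,4-dithiapentane
  expect_identical(cls("CCCC(O)CC"), "I")      # hexan-3-ol
  expect_identical(cls("O=C1CCCO1"), "I")      # butyro-1,4-lactone
})

test_that("classification is invariant across enantiomers entering at the body-constituent rule", {
  tree <- cachedTree("original")
  pairs <- list(c("N[C@@H](C)C(O)=O", "N[C@H](C)C(O)=O"),
                c("N[C@@H](CS)C(O)=O", "N[C@H](CS)C(O)=O"),
                c("N[C@@H](Cc1ccccc1)C(O)=O", "N[C@H](Cc1ccccc1)C(O)=O"))
  for (p in pairs) {
    ta <- evaluateTree(tree, p[1])
    tb <- evaluateTree(tree, p[2])
    expect_identical(ta@final, tb@final)
    expect_identical(unname(traceFragments(ta)[[1]]$steps[1, ]),
                     c("R.1", "yes"))
  }
})

test_that("base and extended variants differ only on compounds matching the extension predicates", {
  base <- cachedTree("original")
  ext <- cachedTree("extended")
  fx <- loadFixtures()
  ext_patterns <- function(smi) {
    matchesSmarts(smi, "[#15]") || matchesSmarts(smi, "[CX3]=[NX2]") ||
      matchesSmarts(smi, "[#16X2;!$([#16][#16]);!$([#16H])]([#6])[#6]") ||
      matchesSmarts(smi, "[#16X2][#16X2]") ||
      matchesSmarts(smi, "[OX2;!$([OX2H])]([#6])[CX3]=[CX3]") ||
      (matchesSmarts(smi, "c1ccccc1") &&
         countSmarts(smi, "[!#6;!#1]") == 0L)
  }
  for (i in seq_len(nrow(fx))) {
    tb <- evaluateTree(base, fx$smiles[i])
    te <- evaluateTree(ext, fx$smiles[i])
    if (!ext_patterns(fx$smiles[i])) {
      expect_identical(tb@final, te@final)
      # identical rule sequences once the pass-through extension steps are
      # dropped from the extended trace
      drop_ext <- function(tr) lapply(traceFragments(tr), function(f)
        f$steps[!grepl("^R\\.4[0-4]$", f$steps[, 1]), , drop = FALSE])
      expect_identical(drop_ext(tb), drop_ext(te))
    }
  }
  # a thioether the extension reassigns
  expect_identical(evaluateTree(base, "CSCCC")@final, "I")
  expect_identical(evaluateTree(ext, "CSCCC")@final, "III")
})

test_that("linear ketone class changes at most once along the homologous series", {
  tree <- cachedTree("original")
  cls <- vapply(generateSeries("linear_ketones", 8), function(s)
    evaluateTree(tree, s)@final, character(1))
  expect_true(all(cls %in% c("I", "II")))
  changes <- sum(cls[-1] != cls[-length(cls)])
  expect_lte(changes, 1L)
  # boundary at a four-carbon wing: hexan-2-one first to reach II
  expect_identical(unname(cls), c("I", "I", "I", rep("II", 5)))
})
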