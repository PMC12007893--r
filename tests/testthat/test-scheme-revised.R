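test_that("the revised tree consults no look-up list anywhere", {
  tree <- cachedTree("revised")
  kinds <- vapply(treeNodes(tree), function(nd) nd$predicate$kind,
                  character(1))
  expect_false(any(kinds == "lookup_membership"))
  expect_length(lookupLists(tree), 0L)
  expect_true("disulphide_reduction" %in% preprocessors(tree))
  expect_true("ester_hydrolysis" %in% preprocessors(tree))
  expect_true("acetal_hydrolysis" %in% preprocessors(tree))
})

test_that("revised builds are deterministic and reject behaviour-faithful mode", {
  t1 <- buildRevisedTree()
  t2 <- buildRevisedTree()
  expect_identical(t1@nodes, t2@nodes)
  expect_error(revisedSchemeConfig(followIntentOverBehavior = FALSE),
               "intent")
})

test_that("documented revised-scheme classifications are reproduced", {
  tree <- cachedTree("revised")
  cls <- function(smi) as.character(finalClass(
    classifyRevised(smi, tree = tree)))
  expect_identical(cls("CC(=O)OCC=C"), "III")   # allyl ester
  expect_identical(cls("O=C/C=C/c1ccccc1"), "II")  # cinnamaldehyde
  expect_identical(cls("CCCCC(C)=O"), "I")      # hexan-2-one
  expect_identical(cls("O=C1CCCO1"), "I")       # butyro-1,4-lactone
  expect_identical(cls("CC(=O)C(C)=O"), "III")  # diacetyl
  expect_identical(cls("O=C1C=Cc2ccccc2O1"), "III")  # coumarin
  expect_identical(cls("CC1CCCO1"), "II")       # 2-methyltetrahydrofuran
})

test_that("revised rule-level answers follow documented intent", {
  tree <- cachedTree("revised")
  expect_true(evaluateRevisedRule("R.2", "N[C@@H](C)C(O)=O", tree))
  expect_true(evaluateRevisedRule("R.2", "CCCO", tree))     # linear alcohol
  expect_false(evaluateRevisedRule("R.2", "CCC(C)O", tree)) # branched
  # acrolein: alpha,beta-unsaturated aldehyde with zero beta substituents
  expect_true(evaluateRevisedRule("R.18b", "C=CC=O", tree))
  # beta,beta-disubstituted enone falls outside the condition
  expect_false(evaluateRevisedRule("R.18b", "CC(C)=CC(C)=O", tree))
  # the reduced form of 1,2,4-trithiolane carries two thiols: 16(c) says no
  reduced <- applyTransforms("C1SSCS1", "disulphide_reduction")
  expect_false(evaluateRevisedRule("R.16", reduced, tree))
})

test_that("divergence log records documented intent/behaviour conflicts", {
  tr <- classifyRevised("N[C@@H](C)C(O)=O", tree = cachedTree("revised"),
                        substance = "L-alanine")
  div <- revisedDivergences(tr)
  expect_true("R.2" %in% div$rule)
  tr2 <- classifyRevised("C1SSCS1", tree = cachedTree("revised"),
                         substance = "1,2,4-trithiolane")
  expect_true("R.16" %in% revisedDivergences(tr2)$rule)
})

test_that("dioxolane hydrolysis products decide the class in both directions", {
  tree <- cachedTree("revised")
  # 4,5-disubstituted: both product hydroxyls secondary -> III
  di <- vapply(c("CC1OCOC1C", "CCC1OCOC1C"), function(s)
    evaluateTree(tree, s)@final, character(1))
  expect_true(all(di == "III"))
  # 4-substituted (primary alcohol) and 4,5,5-trisubstituted (tertiary) -> I
  mono <- vapply(c("CC1COCO1", "CCC1COCO1", "C1COCO1"), function(s)
    evaluateTree(tree, s)@final, character(1))
  expect_true(all(mono == "I"))
  tri <- evaluateTree(tree, "CC1OCOC1(C)C")@final
  expect_identical(tri, "I")
})

test_that("revised and original disagree on alpha,beta-unsaturated carbonyls in the II-vs-I direction", {
  tor <- cachedTree("original")
  trv <- cachedTree("revised")
  fx <- loadFixtures()
  ab <- fx[fx$group == "alpha,beta-unsaturated carbonyls" &
             !is.na(fx$original) & fx$original == "I", ]
  expect_gte(nrow(ab), 2L)
  for (i in seq_len(nrow(ab))) {
    expect_identical(evaluateTree(tor, ab$smiles[i])@final, "I")
    expect_identical(evaluateTree(trv, ab$smiles[i])@final, "II")
  }
})

test_that("no trace through the revised tree ever consults a look-up list", {
  tree <- cachedTree("revised")
  fx <- loadFixtures()
  for (smi in fx$smiles) {
    tr <- evaluateTree(tree, smi)
    rules <- unlist(lapply(traceFragments(tr), function(f) f$steps[, 1]))
    kinds <- vapply(rules, function(r)
      treeNodes(tree)[[r]]$predicate$kind, character(1))
    expect_false(any(kinds == "lookup_membership"))
  }
})
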