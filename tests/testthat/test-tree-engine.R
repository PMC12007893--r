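test_that("a one-question tree classifies by its predicate", {
  tree <- toyTree()
  tr <- evaluateTree(tree, "CCN")
  expect_identical(as.character(finalClass(tr)), "I")
  expect_identical(unname(traceFragments(tr)[[1]]$steps[1, ]),
                   c("Q1", "yes"))
  expect_identical(as.character(finalClass(evaluateTree(tree, "CCC"))),
                   "III")
})

test_that("validateTree reports dangling targets, cycles and clean trees", {
  dangling <- toyTree(yes = "Qmissing")
  rep <- validateTree(dangling)
  expect_true("dangling_target" %in% rep$type)

  cyc <- toyTree()
  cyc@nodes <- list(
    Q1 = list(text = "a", predicate = list(kind = "smarts",
                                           expression = "[#7]"),
              yes = "Q2", no = "III"),
    Q2 = list(text = "b", predicate = list(kind = "smarts",
                                           expression = "[#8]"),
              yes = "Q1", no = "I"))
  expect_true("cycle" %in% validateTree(cyc)$type)

  expect_identical(nrow(validateTree(toyTree())), 0L)

  badp <- toyTree(predicate = list(kind = "computed",
                                   expression = "no_such_predicate"))
  expect_true("unknown_computed" %in% validateTree(badp)$type)
})

test_that("combineProductClasses takes the severity maximum", {
  expect_identical(combineProductClasses(c("I", "I")), "I")
  expect_identical(combineProductClasses(c("I", "III")), "III")
  expect_identical(combineProductClasses("II"), "II")
  expect_error(combineProductClasses(character(0)), "no classes")
})

test_that("boolean-expression predicates honour negation and pattern names", {
  tree <- toyTree(predicate = list(kind = "smarts_boolean_expr",
                                   expression = "!ring"))
  expect_identical(as.character(finalClass(evaluateTree(tree, "CCN"))), "I")
  expect_identical(as.character(finalClass(evaluateTree(tree, "C1CC1"))),
                   "III")
  bad <- toyTree(predicate = list(kind = "smarts_boolean_expr",
                                  expression = "nonexistent_pattern"))
  expect_error(evaluateTree(bad, "CC"), "pattern")
})

test_that("locateDivergence distinguishes none, answer and structural divergence", {
  a <- classifyOriginal("CCCCC(C)=O", tree = cachedTree("original"),
                        substance = "hexan-2-one")
  b <- classifyOriginal("CCCCC(C)=O", tree = cachedTree("original"),
                        substance = "hexan-2-one")
  expect_identical(locateDivergence(a, b)$type, "none")

  c1 <- classifyOriginal("CCCCC(C)=O",
                         tree = cachedTree("original_both_sides"),
                         substance = "hexan-2-one")
  d <- locateDivergence(a, c1)
  expect_identical(d$type, "answer")
  expect_identical(d$rule, "R.18")

  r <- classifyRevised("CCCCC(C)=O", tree = cachedTree("revised"),
                       substance = "hexan-2-one")
  expect_identical(locateDivergence(a, r)$type, "structural")

  other <- classifyOriginal("CCO", tree = cachedTree("original"),
                            substance = "ethanol")
  expect_error(locateDivergence(a, other), "different substances")
})

test_that("traces replay through their trees and serialise to JSON lines", {
  tree <- cachedTree("original")
  for (smi in c("CCCCC(C)=O", "O=C1CCCO1", "Cc1cnccn1",
                "[Ca+2].CC(O)C([O-])=O.CC(O)C([O-])=O")) {
    tr <- evaluateTree(tree, smi)
    expect_true(replayTrace(tree, tr))
  }
  tr <- evaluateTree(tree, "O=C1CCCO1", substance = "butyrolactone")
  line <- tracesToJsonl(tr)
  parsed <- jsonlite::fromJSON(line, simplifyVector = FALSE)
  expect_identical(parsed$id, "butyrolactone")
  expect_identical(parsed$final, "I")
  expect_true(length(parsed$fragments) >= 1)
})

test_that("evaluation is total over generated series", {
  tor <- cachedTree("original")
  trv <- cachedTree("revised")
  series <- c(generateSeries("linear_ketones", 6),
              generateSeries("alkyl_thiols", 4),
              generateSeries("dioxolanes", 4),
              generateSeries("allyl_esters", 3),
              generateSeries("amino_acids", 5))
  for (smi in series) {
    for (tree in list(tor, trv)) {
      tr <- evaluateTree(tree, smi)
      expect_true(tr@final %in% c("I", "II", "III"))
      expect_true(replayTrace(tree, tr))
    }
  }
})
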