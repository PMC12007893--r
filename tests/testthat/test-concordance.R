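table3A <- function() cramerConfusion(matrix(
  c(1570, 154, 164, 154, 40, 40, 208, 313, 612), 3, 3, byrow = TRUE),
  "toxtree_original", "toxtree_revised")

test_that("confusion matrices count only substances with both assignments", {
  tab <- substanceTable(
    data.frame(identifier = paste0("S", 1:4),
               smiles = rep("CCO", 4),
               A = c("I", "I", "I", "II"),
               B = c("I", "I", "I", NA)),
    sources = c("A", "B"))
  cm <- buildConfusion(tab, "A", "B")
  expect_identical(sum(confusionCounts(cm)), 3L)
  expect_identical(confusionCounts(cm)["I", "I"], 3L)
  expect_error(buildConfusion(tab, "A", "nope"), "unknown source")
})

test_that("hand-entered grid sums to the documented total", {
  expect_identical(sum(confusionCounts(table3A())), 3255L)
})

test_that("overall concordance edge cases", {
  expect_equal(overallConcordance(cramerConfusion(diag(3) * 5)), 100)
  zero_diag <- matrix(1, 3, 3) - diag(3)
  expect_equal(overallConcordance(cramerConfusion(zero_diag)), 0)
})

test_that("kappa matches the from-pairs oracle on random small matrices", {
  set.seed(42)
  for (rep_i in 1:12) {
    cm <- cramerConfusion(matrix(rpois(9, 4) + 1, 3, 3))
    for (wt in c("none", "linear")) {
      expect_equal(kappaEstimate(cohenKappa(cm, wt)), kappaOracle(
        confusionCounts(cm), wt), tolerance = 1e-12)
    }
  }
})

test_that("kappa is invariant under transposition and degenerate weights equal unweighted", {
  set.seed(7)
  for (rep_i in 1:8) {
    m <- matrix(rpois(9, 6) + 1, 3, 3)
    k1 <- kappaEstimate(cohenKappa(cramerConfusion(m), "linear"))
    k2 <- kappaEstimate(cohenKappa(cramerConfusion(t(m)), "linear"))
    expect_equal(k1, k2, tolerance = 1e-12)
  }
  # perfect agreement scores 1 under both weightings
  perfect <- cramerConfusion(diag(3) * 7)
  expect_equal(kappaEstimate(cohenKappa(perfect, "none")), 1)
  expect_equal(kappaEstimate(cohenKappa(perfect, "linear")), 1)
})

test_that("counts proportional to the product of margins give kappa zero", {
  r <- c(10, 20, 30); s <- c(6, 3, 1)
  cm <- cramerConfusion(outer(r, s))
  expect_equal(kappaEstimate(cohenKappa(cm, "none")), 0, tolerance = 1e-12)
  expect_equal(kappaEstimate(cohenKappa(cm, "linear")), 0,
               tolerance = 1e-12)
})

test_that("degenerate marginals are rejected", {
  one_class <- matrix(0, 3, 3); one_class[1, 1] <- 10
  expect_error(cohenKappa(cramerConfusion(one_class)), "degenerate")
})

test_that("intra-class concordance equals the intersection-over-union oracle", {
  set.seed(11)
  for (rep_i in 1:8) {
    m <- matrix(rpois(9, 5) + 1, 3, 3)
    cm <- cramerConfusion(m)
    r <- ratingsFromMatrix(m)
    for (cl in c("I", "II", "III")) {
      inter <- sum(r$a == cl & r$b == cl)
      uni <- sum(r$a == cl | r$b == cl)
      expect_equal(unname(intraClassConcordance(cm, cl)),
                   100 * inter / uni, tolerance = 1e-12)
    }
  }
  disjoint <- matrix(0, 3, 3); disjoint[1, 2] <- 5
  expect_equal(unname(intraClassConcordance(cramerConfusion(disjoint),
                                            "I")), 0)
  expect_error(intraClassConcordance(cramerConfusion(disjoint), "III"),
               "absent")
})

test_that("per-class metrics match a brute-force one-vs-rest oracle", {
  set.seed(23)
  for (rep_i in 1:6) {
    m <- matrix(rpois(9, 5) + 1, 3, 3)
    cm <- cramerConfusion(m)
    r <- ratingsFromMatrix(m)
    got <- perClassMetrics(cm, "a")
    for (cl in c("I", "II", "III")) {
      truth <- r$a == cl; call <- r$b == cl
      row <- got[got$class == cl, ]
      expect_equal(row$tpr, sum(truth & call) / sum(truth))
      expect_equal(row$tnr, sum(!truth & !call) / sum(!truth))
      expect_equal(row$ppv, sum(truth & call) / sum(call))
    }
  }
  ident <- perClassMetrics(cramerConfusion(diag(3) * 4), "a")
  expect_true(all(ident$tpr == 1 & ident$tnr == 1 & ident$ppv == 1))
})

test_that("an all-III caller has ppv equal to the prevalence of III in the reference", {
  m <- matrix(0, 3, 3)
  m[, 3] <- c(5, 3, 2)   # every call from source B is III
  got <- perClassMetrics(cramerConfusion(m), "a")
  expect_equal(got$ppv[got$class == "III"], 2 / 10)
  expect_true(is.na(got$ppv[got$class == "I"]))
})

test_that("compareSources assembles the full panel", {
  tab <- substanceTable(
    data.frame(identifier = paste0("S", 1:6),
               smiles = rep("CCO", 6),
               A = c("I", "I", "II", "II", "III", "III"),
               B = c("I", "II", "II", "III", "III", "I")),
    sources = c("A", "B"))
  rep <- compareSources(tab, "A", "B")
  expect_identical(rep$n, 6L)
  expect_equal(rep$concordance, 50)
  expect_s4_class(rep$kappa_weighted, "KappaResult")
  expect_length(rep$intra_class, 3)
  f <- withr::local_tempfile(fileext = ".json")
  writeComparison(rep, f)
  back <- jsonlite::read_json(f)
  expect_equal(back$concordance_percent, 50)
  expect_identical(back$n_shared, 6L)
})
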