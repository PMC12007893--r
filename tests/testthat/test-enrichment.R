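miniLibrary <- function() data.frame(
  feature = c("benzene", "hydroxyl", "thiol"),
  smarts = c("c1ccccc1", "[OX2H]", "[SX2H]"),
  stringsAsFactors = FALSE)

poolTable <- function() {
  # 6 concordant + 2 discordant (I->III carries the benzene feature)
  substanceTable(
    data.frame(identifier = paste0("S", 1:8),
               smiles = c(rep("CCO", 6), "c1ccccc1CO", "c1ccccc1CCO"),
               A = c(rep("I", 6), "I", "I"),
               B = c(rep("I", 6), "III", "III")),
    sources = c("A", "B"))
}

test_that("fingerprints set bit i iff SMARTS i matches", {
  fp <- computeFingerprints(c(tol = "Cc1ccccc1", eth = "CCO"),
                            miniLibrary())
  expect_identical(dim(fp), c(2L, 3L))
  expect_true(fp["tol", "benzene"])
  expect_false(fp["tol", "hydroxyl"])
  expect_true(fp["eth", "hydroxyl"])
  empty <- computeFingerprints("CCO", miniLibrary()[0, ])
  expect_identical(ncol(empty), 0L)
})

test_that("malformed SMARTS are reported with the feature name", {
  bad <- data.frame(feature = "broken", smarts = "[[[",
                    stringsAsFactors = FALSE)
  expect_error(computeFingerprints("CCO", bad), "broken")
})

test_that("pool partition is exhaustive, disjoint and direction-sensitive", {
  tab <- poolTable()
  pools <- partitionPools(tab, "A", "B")
  expect_length(pools, 7L)
  expect_setequal(names(pools),
                  c("concordant", "I->II", "I->III", "II->I", "II->III",
                    "III->I", "III->II"))
  expect_identical(sum(lengths(pools)), 8L)     # conservation
  expect_identical(anyDuplicated(unlist(pools)), 0L)
  expect_length(pools[["I->III"]], 2L)
  # direction sensitivity: swapping the sources mirrors the pool labels
  rev <- partitionPools(tab, "B", "A")
  expect_identical(sort(rev[["III->I"]]), sort(pools[["I->III"]]))
  expect_identical(rev[["I->III"]], character(0))
})

test_that("all-concordant input leaves the six discordant pools empty", {
  tab <- substanceTable(data.frame(identifier = c("a", "b"),
                                   smiles = c("CCO", "CCC"),
                                   A = c("I", "II"), B = c("I", "II")),
                        sources = c("A", "B"))
  pools <- partitionPools(tab, "A", "B")
  expect_identical(lengths(pools)[["concordant"]], 2L)
  expect_true(all(lengths(pools)[-1] == 0L))
  fps <- computeFingerprints(stats::setNames(c("CCO", "CCC"),
                                             c("a", "b")), miniLibrary())
  expect_warning(out <- chi2Enrichment(pools, fps), "no enrichment rows")
  expect_identical(nrow(out), 0L)
})

test_that("chi-square statistics match the four-cell oracle and equal rates give zero", {
  # build pools/fingerprints directly
  pools <- list(concordant = paste0("c", 1:500), `I->II` = character(0),
                `I->III` = paste0("d", 1:100), `II->I` = character(0),
                `II->III` = character(0), `III->I` = character(0),
                `III->II` = character(0))
  ids <- c(pools$concordant, pools$`I->III`)
  fps <- matrix(FALSE, length(ids), 2,
                dimnames = list(ids, c("equal_rates", "enriched")))
  # equal rates: 10% in both pools
  fps[c(paste0("d", 1:10), paste0("c", 1:50)), "equal_rates"] <- TRUE
  # enriched: 50/100 in pool vs 50/500 concordant
  fps[c(paste0("d", 1:50), paste0("c", 1:50)), "enriched"] <- TRUE
  out <- chi2Enrichment(pools, fps)
  eq <- out[out$feature == "equal_rates", ]
  expect_equal(eq$statistic, 0, tolerance = 1e-12)
  en <- out[out$feature == "enriched", ]
  # independent oracle: direct sum of (O-E)^2/E over the four cells
  o <- matrix(c(50, 50, 50, 450), 2, 2)
  e <- outer(rowSums(o), colSums(o)) / sum(o)
  expect_equal(en$statistic, sum((o - e)^2 / e), tolerance = 1e-9)
  # statistic invariant under swapping rows/columns of the 2x2 table
  o_swap <- o[2:1, 2:1]
  e_swap <- outer(rowSums(o_swap), colSums(o_swap)) / sum(o_swap)
  expect_equal(sum((o_swap - e_swap)^2 / e_swap), en$statistic,
               tolerance = 1e-9)
  # enriched feature ranks first
  expect_identical(out$feature[1], "enriched")
})

test_that("end-to-end enrichment ranks the planted fragment first", {
  tab <- poolTable()
  out <- enrichDiscordant(tab, "A", "B", smartsLibrary = miniLibrary())
  expect_identical(out$pool[1], "I->III")
  expect_identical(out$feature[1], "benzene")
  expect_true(all(out$p_adjusted >= out$p - 1e-15))
  # features absent everywhere are skipped
  expect_false("thiol" %in% out$feature)
})
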