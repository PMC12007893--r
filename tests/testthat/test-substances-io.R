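writeFixtureCsv <- function(df, path) {
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = TRUE,
                     na = "")
  path
}

test_that("reading a substance table keeps valid rows and derives structure status", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeFixtureCsv(data.frame(identifier = c("S1", "S2"),
                             cas = c("64-17-5", "71-23-8"),
                             name = c("ethanol", "propanol"),
                             smiles = c("CCO", "CCCO"),
                             FEMA = c("I", "ii")), f)
  tab <- readSubstanceTable(f)
  rec <- substanceRecords(tab)
  expect_identical(nrow(rec), 2L)
  expect_identical(rec$structure_status, c("defined", "defined"))
  expect_identical(rec$FEMA, c("I", "II"))   # case-tolerant
  expect_identical(assignmentSources(tab), "FEMA")
})

test_that("rows with empty or wildcard SMILES are retained as undefined", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeFixtureCsv(data.frame(identifier = c("S1", "S2", "S3"),
                             smiles = c("CCO", "", "C* polymer"),
                             expert = c("I", "III", "II")), f)
  tab <- readSubstanceTable(f, columnMap = c(identifier = "identifier",
                                             smiles = "smiles"))
  rec <- substanceRecords(tab)
  expect_identical(rec$structure_status,
                   c("defined", "undefined", "undefined"))
  expect_identical(rec$expert, c("I", "III", "II"))  # judgments retained
})

test_that("malformed class tokens are rejected with a row-level report", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeFixtureCsv(data.frame(identifier = c("S1", "S2"),
                             smiles = c("CCO", "CCC"),
                             expert = c("I", "IV")), f)
  expect_error(readSubstanceTable(f, columnMap = c(identifier = "identifier",
                                                   smiles = "smiles")),
               "malformed class token.*row 2")
})

test_that("write/read round-trip preserves every field", {
  tab <- substanceTable(data.frame(identifier = c("A", "B", "C"),
                                   cas = c("x", NA, "z"),
                                   name = c("one", "two", "three"),
                                   smiles = c("CCO", NA, "c1ccccc1"),
                                   src1 = c("I", "II", NA),
                                   src2 = c(NA, "III", "II")),
                        sources = c("src1", "src2"))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeSubstanceTable(tab, f)
  back <- readSubstanceTable(f, columnMap = c(identifier = "identifier",
                                              cas = "cas", name = "name",
                                              smiles = "smiles"),
                             sourceColumns = c("src1", "src2"))
  rec0 <- substanceRecords(tab)
  rec1 <- substanceRecords(back)
  rec1$cas[rec1$cas == ""] <- NA
  expect_identical(rec1$identifier, rec0$identifier)
  expect_identical(rec1$structure_status, rec0$structure_status)
  expect_identical(rec1$src1, rec0$src1)
  expect_identical(rec1$src2, rec0$src2)
})

mkTab <- function(ids, source, classes, smiles = NULL) {
  substanceTable(
    data.frame(identifier = ids,
               smiles = smiles %||% rep("CCO", length(ids)),
               cls = classes,
               stringsAsFactors = FALSE) |>
      (\(d) { names(d)[names(d) == "cls"] <- source; d })(),
    sources = source)
}

test_that("merge unions assignments across tables", {
  t1 <- mkTab(c("X", "Y"), "A", c("I", "II"))
  t2 <- mkTab(c("X", "Z"), "B", c("III", "I"))
  m <- mergeInventories(list(t1, t2))
  rec <- substanceRecords(m)
  expect_identical(nrow(rec), 3L)
  x <- rec[rec$identifier == "X", ]
  expect_identical(x$A, "I")
  expect_identical(x$B, "III")
  mem <- attr(m, "membership")
  expect_identical(mem$shared[1, 2], 1L)
  expect_identical(mem$unique, c(1L, 1L))
})

test_that("disjoint merges sum record counts and merge is idempotent", {
  t1 <- mkTab(c("A1", "A2"), "A", c("I", "I"))
  t2 <- mkTab(c("B1", "B2", "B3"), "B", c("II", "II", "III"))
  m <- mergeInventories(list(t1, t2))
  expect_identical(nrow(substanceRecords(m)), 5L)
  m2 <- mergeInventories(list(m))
  expect_identical(substanceRecords(m2), substanceRecords(m))
  # order-insensitive record membership
  m_rev <- mergeInventories(list(t2, t1))
  expect_setequal(substanceRecords(m_rev)$identifier,
                  substanceRecords(m)$identifier)
})

test_that("merge flags SMILES conflicts and rejects intra-source class conflicts", {
  t1 <- mkTab("X", "A", "I", smiles = "CCO")
  t2 <- mkTab("X", "B", "II", smiles = "CCC")
  expect_warning(m <- mergeInventories(list(t1, t2)), "conflicting SMILES")
  expect_identical(substanceRecords(m)$smiles, "CCO")  # first seen retained

  t3 <- mkTab("X", "A", "III")
  expect_error(suppressWarnings(mergeInventories(list(t1, t3))),
               "assigns both")
})
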