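test_that("the fixture corpus is complete and well-formed", {
  fx <- loadFixtures()
  expect_gte(nrow(fx), 25L)
  expect_gte(length(unique(fx$group)), 15L)
  expect_true(all(nzchar(fx$citation)))
  required <- c("hexan-2-one", "hex-5-en-2-one", "3-methylpentan-2-one",
                "cis-5-octen-2-one", "6-methylheptan-3-one",
                "propane-1-thiol", "methyl propyl sulphide",
                "propane-1,3-dithiol", "2,4-dithiapentane",
                "1,2,4-trithiolane", "3,6-dimethyl-1,2,4,5-tetrathiane",
                "pentano-1,4-lactone", "4-butyloctano-1,4-lactone",
                "butyro-1,4-lactone", "L-cysteine", "L-phenylalanine",
                "L-arginine", "calcium lactate", "sodium dodecyl sulphate",
                "taurine", "1,4-benzenediamine", "benzyl octyl ether",
                "linalool", "nerolidol", "hexan-3-ol",
                "2,3,4-trimethyl-3-pentanol", "2-methylpyrazine",
                "diacetyl", "cinnamaldehyde", "coumarin", "allyl acetate",
                "prenyl ethyl ether")
  expect_true(all(required %in% fx$name))
  # every SMILES parses
  expect_false(any(is.na(canonicalSmiles(fx$smiles))))
  # expectation values are legal classes
  for (col in c("expert_class", "original", "extended", "revised"))
    expect_true(all(is.na(fx[[col]]) | fx[[col]] %in% c("I", "II", "III")))
})

test_that("every citation key resolves to the packaged fixture notes", {
  fx <- loadFixtures()
  notes <- readLines(system.file("extdata", "fixture_notes.md",
                                 package = "cramertree"), warn = FALSE)
  headings <- sub("^## ", "", grep("^## ", notes, value = TRUE))
  expect_true(all(unique(fx$citation) %in% headings))
})

test_that("the suite passes for every documented expectation on correctly built schemes", {
  rep <- runFixtureSuite(list(original = cachedTree("original"),
                              extended = cachedTree("extended"),
                              revised = cachedTree("revised")))
  expect_gte(nrow(rep), 25L)
  if (!all(rep$pass)) print(rep[!rep$pass, ])
  expect_true(all(rep$pass))
  by_group <- attr(rep, "by_group")
  expect_true(all(by_group$pass == 1))
})

test_that("corrupting the ketone reading makes the ketone fixtures fail", {
  rep <- runFixtureSuite(list(original = cachedTree("original_both_sides")))
  ket <- rep[rep$name %in% c("hexan-2-one", "hex-5-en-2-one",
                             "3-methylpentan-2-one"), ]
  expect_true(all(!ket$pass))
  expect_true(all(ket$observed == "I"))
})

test_that("an empty scheme list yields an empty report", {
  rep <- runFixtureSuite(list())
  expect_identical(nrow(rep), 0L)
})

test_that("generated series are deterministic, parseable and unique", {
  expect_identical(generateSeries("linear_ketones", 3),
                   c("CC(C)=O", "CCC(C)=O", "CCCC(C)=O"))
  expect_identical(generateSeries("amino_acids", 2),
                   c("NCC(O)=O", "N[C@@H](C)C(O)=O"))
  for (tmpl in c("linear_ketones", "alkyl_thiols", "dioxolanes",
                 "allyl_esters", "amino_acids")) {
    s <- generateSeries(tmpl, 5)
    expect_length(s, 5L)
    expect_identical(anyDuplicated(s), 0L)
    expect_false(any(is.na(canonicalSmiles(s))))
    expect_identical(s, generateSeries(tmpl, 5))
  }
  expect_error(generateSeries("linear_ketones", 0))
})

test_that("the corpus exports to a substance table", {
  tab <- fixturesAsSubstanceTable()
  expect_s4_class(tab, "SubstanceTable")
  rec <- substanceRecords(tab)
  expect_identical(nrow(rec), nrow(loadFixtures()))
  expect_true(all(rec$structure_status == "defined"))
  expect_true("expert" %in% assignmentSources(tab))
})
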