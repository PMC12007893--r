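# The packaged test corpus: named compounds with documented expected
# classes, plus deterministic homologous-series generators for
# property-style testing.

#' Load the packaged fixture corpus
#'
#' Each entry carries a compound name, SMILES, chemical-group label, a
#' citation key into the packaged fixture notes
#' (`inst/extdata/fixture_notes.md`), the documented expert class where one
#' exists, and per-scheme expected classes for the schemes whose handling
#' of the compound is pinned down. Expert judgment and scheme expectation
#' may disagree; both are kept.
#'
#' @return data.frame with columns `name`, `smiles`, `group`, `citation`,
#'   `expert_class`, `original`, `extended`, `revised` (NA where no
#'   expectation is documented).
#' @export
loadFixtures <- function() {
  path <- system.file("extdata", "fixtures.json", package = "cramertree",
                      mustWork = TRUE)
  raw <- jsonlite::read_json(path)
  rows <- lapply(raw, function(e) {
    exp <- e$expectations
    data.frame(name = e$name, smiles = e$smiles, group = e$group,
               citation = e$citation,
               expert_class = e$expert_class %||% NA_character_,
               original = exp$original %||% NA_character_,
               extended = exp$extended %||% NA_character_,
               revised = exp$revised %||% NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export the fixture corpus as a substance table
#'
#' @return A [SubstanceTable-class] with the documented expert class and
#'   per-scheme expectations as assignment sources.
#' @export
fixturesAsSubstanceTable <- function() {
  fx <- loadFixtures()
  rec <- data.frame(identifier = fx$name, cas = NA_character_,
                    name = fx$name, smiles = fx$smiles,
                    expert = fx$expert_class, original = fx$original,
                    extended = fx$extended, revised = fx$revised,
                    stringsAsFactors = FALSE)
  substanceTable(rec, sources = c("expert", "original", "extended",
                                  "revised"))
}

#' Run the fixture suite against built schemes
#'
#' An entry passes iff, for every supplied scheme with a documented
#' expectation, the classifier agrees with it.
#'
#' @param schemes Named list of validated [CramerTree-class] objects; names
#'   must match fixture expectation columns (`original`, `extended`,
#'   `revised`).
#' @param fixtures Fixture data.frame (defaults to [loadFixtures()]).
#' @return data.frame with one row per (entry, scheme-with-expectation):
#'   `name`, `group`, `scheme`, `expected`, `observed`, `pass`; summary by
#'   group attached as attribute `"by_group"`.
#' @export
runFixtureSuite <- function(schemes, fixtures = loadFixtures()) {
  if (!length(schemes))
    return(data.frame(name = character(0), group = character(0),
                      scheme = character(0), expected = character(0),
                      observed = character(0), pass = logical(0)))
  stopifnot(!is.null(names(schemes)),
            all(names(schemes) %in% c("original", "extended", "revised")))
  rows <- list()
  for (sc in names(schemes)) {
    tree <- schemes[[sc]]
    has <- which(!is.na(fixtures[[sc]]))
    for (i in has) {
      trace <- evaluateTree(tree, fixtures$smiles[i],
                            substance = fixtures$name[i])
      obs <- trace@final
      rows[[length(rows) + 1L]] <- data.frame(
        name = fixtures$name[i], group = fixtures$group[i], scheme = sc,
        expected = fixtures[[sc]][i], observed = obs,
        pass = identical(obs, fixtures[[sc]][i]), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "by_group") <- stats::aggregate(pass ~ group, data = out,
                                            FUN = function(x)
                                              sum(x) / length(x))
  out
}

#' Generate deterministic homologous series
#'
#' Synthetic structure series for property-style tests (for example, the
#' class of linear methyl ketones as a function of chain length must change
#' at most once at the chain-length boundary). No randomness is involved.
#'
#' @param template One of `"linear_ketones"` (propan-2-one upward),
#'   `"alkyl_thiols"`, `"dioxolanes"` (4-alkyl-1,3-dioxolanes, starting at
#'   the unsubstituted ring), `"allyl_esters"` (allyl alkanoates) or
#'   `"amino_acids"` (glycine, then L-2-aminoalkanoic acids).
#' @param n Number of members (>= 1).
#' @return Character vector of SMILES.
#' @export
generateSeries <- function(template = c("linear_ketones", "alkyl_thiols",
                                        "dioxolanes", "allyl_esters",
                                        "amino_acids"), n) {
  template <- match.arg(template)
  stopifnot(is.numeric(n), n >= 1)
  n <- as.integer(n)
  k <- seq_len(n)
  switch(template,
    linear_ketones = paste0(strrep("C", k), "C(C)=O"),
    alkyl_thiols = paste0(strrep("C", k), "S"),
    dioxolanes = c("C1COCO1", paste0(strrep("C", k[-n]), "C1COCO1")),
    allyl_esters = paste0(strrep("C", k), "C(=O)OCC=C"),
    amino_acids = c("NCC(O)=O",
                    if (n > 1) paste0("N[C@@H](", strrep("C", k[-n]),
                                      ")C(O)=O"))
  )
}
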