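# High-level workflow functions: classify a substance table under a scheme,
# compare two assignment sources, and run fragment enrichment. These are the
# workhorses behind the command-line interface.

.build_scheme <- function(scheme = c("original", "extended", "revised"),
                          lookupDir = NULL, treeOverride = NULL,
                          config = list()) {
  scheme <- match.arg(scheme)
  if (scheme == "revised" && !is.null(lookupDir))
    stop("the revised scheme uses no look-up lists; lookupDir must not be ",
         "set", call. = FALSE)
  if (!is.null(treeOverride)) {
    tree <- treeFromJson(treeOverride, lookupDir = lookupDir,
                         config = config)
    rep <- validateTree(tree)
    if (nrow(rep))
      stop("tree override failed validation: ",
           paste(rep$type, rep$node, collapse = "; "), call. = FALSE)
    return(tree)
  }
  if (scheme == "revised") buildRevisedTree()
  else buildOriginalTree(originalSchemeConfig(
    variant = if (scheme == "extended") "extended" else "base",
    lookupDir = lookupDir))
}

#' Classify every substance in a table
#'
#' Adds a `<scheme>_class` column. Records without a defined structure are
#' assigned `NA` (with the reason noted) and processing continues; they are
#' retained for expert-concordance analysis only.
#'
#' @param table A [SubstanceTable-class].
#' @param scheme `"original"`, `"extended"` or `"revised"`.
#' @param lookupDir Optional look-up list directory (original/extended
#'   only; the revised scheme rejects it).
#' @param treeOverride Optional path to a tree-definition JSON replacing the
#'   shipped scheme.
#' @param trace Logical; collect full decision traces.
#' @return The table with the new class column appended as a source; when
#'   `trace = TRUE` the traces are attached as attribute `"traces"` (a list
#'   of [DecisionTrace-class]), and skipped records as attribute
#'   `"skipped"`.
#' @export
classifySubstances <- function(table, scheme = c("original", "extended",
                                                 "revised"),
                               lookupDir = NULL, treeOverride = NULL,
                               trace = FALSE) {
  stopifnot(methods::is(table, "SubstanceTable"))
  scheme <- match.arg(scheme)
  tree <- .build_scheme(scheme, lookupDir, treeOverride)
  rec <- table@records
  col <- paste0(scheme, "_class")
  out <- rep(NA_character_, nrow(rec))
  traces <- list()
  skipped <- character(0)
  for (i in seq_len(nrow(rec))) {
    if (rec$structure_status[i] != "defined") {
      skipped <- c(skipped, rec$identifier[i])
      next
    }
    tr <- if (scheme == "revised")
      classifyRevised(rec$smiles[i], tree = tree,
                      substance = rec$identifier[i])
    else evaluateTree(tree, rec$smiles[i], substance = rec$identifier[i])
    out[i] <- tr@final
    if (trace) traces[[rec$identifier[i]]] <- tr
  }
  rec[[col]] <- out
  res <- methods::new("SubstanceTable", records = rec,
                      sources = unique(c(table@sources, col)))
  if (trace) attr(res, "traces") <- traces
  attr(res, "skipped") <- skipped
  res
}

#' Serialise an agreement report
#'
#' @param report List from [compareSources()].
#' @param path Output path; `.json` selects JSON, anything else CSV (the
#'   pairwise statistics table).
#' @return The path, invisibly.
#' @export
writeComparison <- function(report, path) {
  kappas <- function(k) list(
    estimate = roundHalfUp(k@estimate, 3), se = k@se,
    ci_low = roundHalfUp(k@ciLow, 3), ci_high = roundHalfUp(k@ciHigh, 3),
    level = k@level)
  obj <- list(
    source_a = report$confusion@sourceA,
    source_b = report$confusion@sourceB,
    n_shared = report$n,
    confusion = as.data.frame.matrix(report$confusion@counts),
    concordance_percent = roundHalfUp(report$concordance, 1),
    kappa_unweighted = kappas(report$kappa_unweighted),
    kappa_weighted = kappas(report$kappa_weighted),
    intra_class_percent = as.list(roundHalfUp(report$intra_class,
                                              c(1, 2, 1))),
    per_class_reference_a = report$metrics_ref_a,
    per_class_reference_b = report$metrics_ref_b)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  } else {
    flat <- data.frame(
      statistic = c("n_shared", "concordance_percent",
                    "kappa_unweighted", "kappa_unweighted_ci_low",
                    "kappa_unweighted_ci_high", "kappa_weighted",
                    "kappa_weighted_ci_low", "kappa_weighted_ci_high",
                    paste0("intra_class_", names(report$intra_class))),
      value = c(report$n, roundHalfUp(report$concordance, 1),
                roundHalfUp(report$kappa_unweighted@estimate, 3),
                roundHalfUp(report$kappa_unweighted@ciLow, 3),
                roundHalfUp(report$kappa_unweighted@ciHigh, 3),
                roundHalfUp(report$kappa_weighted@estimate, 3),
                roundHalfUp(report$kappa_weighted@ciLow, 3),
                roundHalfUp(report$kappa_weighted@ciHigh, 3),
                roundHalfUp(report$intra_class, 1)),
      stringsAsFactors = FALSE)
    utils::write.table(flat, path, sep = ",", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}

#' Fragment enrichment between two sources of a table
#'
#' Partitions the shared substances into the seven discordance pools,
#' fingerprints every defined structure against a SMARTS library and runs
#' the pool-by-pool chi-square enrichment.
#'
#' @param table A [SubstanceTable-class].
#' @param sourceA,sourceB Source column names.
#' @param smartsLibrary Path to (or data.frame of) the SMARTS library;
#'   defaults to the compact library shipped with the package.
#' @param against See [chi2Enrichment()].
#' @return Enrichment data.frame (see [chi2Enrichment()]).
#' @export
enrichDiscordant <- function(table, sourceA, sourceB,
                             smartsLibrary = NULL,
                             against = "concordant") {
  if (is.null(smartsLibrary))
    smartsLibrary <- system.file("extdata", "toxprint_mini.tsv",
                                 package = "cramertree", mustWork = TRUE)
  pools <- partitionPools(table, sourceA, sourceB)
  ids <- unlist(pools, use.names = FALSE)
  rec <- table@records[match(ids, table@records$identifier), ]
  ok <- rec$structure_status == "defined"
  pools <- lapply(pools, function(p) intersect(p, rec$identifier[ok]))
  structures <- stats::setNames(rec$smiles[ok], rec$identifier[ok])
  fps <- computeFingerprints(structures, smartsLibrary)
  chi2Enrichment(pools, fps, against = against)
}
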