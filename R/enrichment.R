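# Fragment-enrichment analysis: shared substances are divided into seven
# pools (one concordant, six directional discordance pools); SMARTS
# fingerprint features are then tested pool-by-pool against the concordant
# pool with a Pearson chi-square on the implied 2x2 table, ranking the
# fragments overrepresented among discordantly classified substances.

.POOL_LABELS <- c("concordant", "I->II", "I->III", "II->I", "II->III",
                  "III->I", "III->II")

#' Read a SMARTS fingerprint library
#'
#' Format: one `name<TAB>SMARTS` per line; `#` starts a comment.
#'
#' @param path Library file.
#' @return data.frame with columns `feature` and `smarts`.
#' @export
readSmartsLibrary <- function(path) {
  if (!file.exists(path)) stop("SMARTS library not found: ", path,
                               call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2)
  if (length(bad)) stop("malformed library line(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  data.frame(feature = vapply(parts, `[[`, "", 1),
             smarts = vapply(parts, `[[`, "", 2),
             stringsAsFactors = FALSE)
}

#' Compute SMARTS fingerprints
#'
#' Bit i of a substance is set iff SMARTS i matches its structure.
#'
#' @param structures Character vector of SMILES (names used as row names).
#' @param library data.frame from [readSmartsLibrary()], or a path to a
#'   library file.
#' @return Logical matrix, substances x features.
#' @export
computeFingerprints <- function(structures, library) {
  if (is.character(library) && length(library) == 1)
    library <- readSmartsLibrary(library)
  stopifnot(all(c("feature", "smarts") %in% names(library)))
  if (anyDuplicated(library$feature))
    stop("duplicate feature names in library", call. = FALSE)
  fp <- matrix(FALSE, nrow = length(structures),
               ncol = nrow(library),
               dimnames = list(names(structures) %||% structures,
                               library$feature))
  for (j in seq_len(nrow(library))) {
    for (i in seq_along(structures)) {
      hit <- tryCatch(matchesSmarts(structures[[i]], library$smarts[j]),
                      error = function(e)
                        stop("feature '", library$feature[j],
                             "': ", conditionMessage(e), call. = FALSE))
      fp[i, j] <- hit
    }
  }
  fp
}

#' Partition shared substances into discordance pools
#'
#' Substances carrying both assignments are divided into seven pools: one
#' whose classifications align, and six direction-sensitive discordance
#' pools labelled `"X->Y"` (class X from source A, class Y from source B).
#'
#' @param table A [SubstanceTable-class].
#' @param sourceA,sourceB Source column names.
#' @return Named list of identifier vectors, one per pool label (always all
#'   seven labels, possibly empty).
#' @export
partitionPools <- function(table, sourceA, sourceB) {
  stopifnot(methods::is(table, "SubstanceTable"))
  for (s in c(sourceA, sourceB))
    if (!s %in% table@sources) stop("unknown source: ", s, call. = FALSE)
  a <- table@records[[sourceA]]
  b <- table@records[[sourceB]]
  id <- table@records$identifier
  keep <- !is.na(a) & !is.na(b)
  if (!any(keep)) stop("no substances shared by ", sourceA, " and ", sourceB,
                       call. = FALSE)
  lab <- ifelse(a[keep] == b[keep], "concordant",
                paste0(a[keep], "->", b[keep]))
  pools <- lapply(.POOL_LABELS, function(p) id[keep][lab == p])
  names(pools) <- .POOL_LABELS
  pools
}

#' Chi-square fragment enrichment over discordance pools
#'
#' For each (feature, discordant pool) the 2x2 table {feature present,
#' absent} x {pool, concordant} is tested with a Pearson chi-square
#' (1 d.f., no continuity correction). Rows are sorted by statistic
#' descending; Benjamini-Hochberg adjusted p-values are reported alongside
#' the raw ones. Features occurring nowhere are skipped, empty pools are
#' omitted (with a note), and cells with small expected counts are flagged
#' rather than silently switched to another test.
#'
#' @param pools Pool partition from [partitionPools()].
#' @param fps Fingerprint matrix from [computeFingerprints()] whose row
#'   names cover all pooled substances.
#' @param against `"concordant"` (default: each pool vs the concordant
#'   pool) or `"rest"` (each pool vs all other shared substances).
#' @return data.frame of enrichment rows (feature, pool, counts, statistic,
#'   p, p_adjusted, low_expected flag).
#' @export
chi2Enrichment <- function(pools, fps, against = c("concordant", "rest")) {
  against <- match.arg(against)
  stopifnot(identical(sort(names(pools)), sort(.POOL_LABELS)))
  all_ids <- unlist(pools, use.names = FALSE)
  missing <- setdiff(all_ids, rownames(fps))
  if (length(missing))
    stop("fingerprints missing for: ", paste(utils::head(missing, 5),
                                             collapse = ", "), call. = FALSE)
  rows <- list()
  skipped <- character(0)
  for (pool in setdiff(.POOL_LABELS, "concordant")) {
    ids <- pools[[pool]]
    if (!length(ids)) { skipped <- c(skipped, pool); next }
    ref_ids <- if (against == "concordant") pools[["concordant"]] else
      setdiff(all_ids, ids)
    if (!length(ref_ids)) { skipped <- c(skipped, pool); next }
    for (feat in colnames(fps)) {
      x1 <- sum(fps[ids, feat])
      x0 <- sum(fps[ref_ids, feat])
      if (x1 + x0 == 0) next
      tab <- matrix(c(x1, length(ids) - x1, x0, length(ref_ids) - x0), 2, 2)
      exp_counts <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      stat <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      rows[[length(rows) + 1L]] <- data.frame(
        feature = feat, pool = pool,
        count_in_pool = x1, pool_size = length(ids),
        count_in_reference = x0, reference_size = length(ref_ids),
        statistic = unname(stat$statistic), p = unname(stat$p.value),
        low_expected = any(exp_counts < 5), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    warning("no enrichment rows (all pools concordant or empty)",
            call. = FALSE)
    out <- data.frame(feature = character(0), pool = character(0),
                      count_in_pool = integer(0), pool_size = integer(0),
                      count_in_reference = integer(0),
                      reference_size = integer(0), statistic = numeric(0),
                      p = numeric(0), low_expected = logical(0),
                      p_adjusted = numeric(0))
    attr(out, "skipped_pools") <- skipped
    return(out)
  }
  out <- do.call(rbind, rows)
  out$p[is.na(out$p)] <- 1
  out$statistic[is.na(out$statistic)] <- 0
  out$p_adjusted <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(-out$statistic), ]
  rownames(out) <- NULL
  attr(out, "skipped_pools") <- skipped
  out
}
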