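# Reading, curating, merging and writing substance tables with Cramer class
# assignments. Substances lacking a defined structure (mixtures, polymers,
# unparseable SMILES) are retained - they still carry expert judgments and
# enter concordance analysis - but are never classified in silico.

.REQ_COLS <- c("identifier", "cas", "name", "smiles", "structure_status")

.norm_class <- function(x) {
  x <- toupper(trimws(as.character(x)))
  x[x == ""] <- NA_character_
  x
}

# defined structure: SMILES parses and carries no wildcard/polymer markers;
# multi-component SMILES (salts) are defined - they are the subject of the
# salt rule, not curation casualties
.structure_status <- function(smiles) {
  vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(s)) return("undefined")
    if (grepl("\\*", s)) return("undefined")
    if (is.na(canonicalSmiles(s))) return("undefined")
    "defined"
  }, character(1), USE.NAMES = FALSE)
}

#' Construct a substance table
#'
#' @param records data.frame with at least an `identifier` column; `cas`,
#'   `name`, `smiles` are completed with `NA` when absent and
#'   `structure_status` is derived from the SMILES.
#' @param sources Character vector naming the class-assignment columns.
#' @return A [SubstanceTable-class].
#' @export
substanceTable <- function(records, sources = character(0)) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  for (cc in c("cas", "name", "smiles"))
    if (is.null(records[[cc]])) records[[cc]] <- NA_character_
  records$identifier <- as.character(records$identifier)
  records$smiles <- as.character(records$smiles)
  if (is.null(records$structure_status))
    records$structure_status <- .structure_status(records$smiles)
  for (s in sources) records[[s]] <- .norm_class(records[[s]])
  records <- records[c(.REQ_COLS, setdiff(names(records), .REQ_COLS))]
  rownames(records) <- NULL
  methods::new("SubstanceTable", records = records,
               sources = as.character(sources))
}

#' Read a substance table from CSV/TSV
#'
#' One record per row. Rows whose SMILES cell is empty or unparseable are
#' retained with `structure_status = "undefined"`; class cells outside
#' I/II/III (case- and whitespace-tolerant) are collected into a row-level
#' error report and rejected.
#'
#' @param path CSV or TSV file with a header row.
#' @param columnMap Named character vector mapping the semantic columns
#'   (`identifier`, and optionally `cas`, `name`, `smiles`) to file headers.
#' @param sourceColumns Headers holding class assignments; by default every
#'   column not claimed by `columnMap`.
#' @param sep Field separator; inferred from the extension when `NULL`.
#' @return A [SubstanceTable-class].
#' @export
readSubstanceTable <- function(path,
                               columnMap = c(identifier = "identifier",
                                             cas = "cas", name = "name",
                                             smiles = "smiles"),
                               sourceColumns = NULL, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep))
    sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          quote = "\"", comment.char = "")
  if (!"identifier" %in% names(columnMap))
    stop("columnMap must map 'identifier'", call. = FALSE)
  missing_cols <- setdiff(unname(columnMap), names(df))
  if (length(missing_cols))
    stop("mapped column(s) absent from file: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  rec <- data.frame(identifier = as.character(df[[columnMap[["identifier"]]]]),
                    stringsAsFactors = FALSE)
  for (cc in c("cas", "name", "smiles"))
    rec[[cc]] <- if (cc %in% names(columnMap))
      as.character(df[[columnMap[[cc]]]]) else NA_character_
  if ("structure_status" %in% names(df) &&
      all(df$structure_status %in% c("defined", "undefined")))
    rec$structure_status <- df$structure_status
  if (is.null(sourceColumns))
    sourceColumns <- setdiff(names(df),
                             c(unname(columnMap), "structure_status"))
  sourceColumns <- setdiff(sourceColumns, "structure_status")
  bad <- list()
  for (s in sourceColumns) {
    v <- .norm_class(df[[s]])
    invalid <- which(!is.na(v) & !v %in% c("I", "II", "III"))
    if (length(invalid))
      bad[[s]] <- data.frame(source = s, row = invalid,
                             value = df[[s]][invalid],
                             stringsAsFactors = FALSE)
    rec[[s]] <- v
  }
  if (length(bad)) {
    rep <- do.call(rbind, bad)
    stop("malformed class token(s): ",
         paste(sprintf("%s[row %d]='%s'", rep$source, rep$row, rep$value),
               collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(rec$identifier))
    stop("duplicate identifiers in ", path, call. = FALSE)
  substanceTable(rec, sources = sourceColumns)
}

#' Write a substance table to CSV/TSV
#'
#' The output carries the identifier/cas/name/smiles columns, the derived
#' `structure_status`, and one column per classification source, and
#' round-trips through [readSubstanceTable()] unchanged.
#'
#' @param table A [SubstanceTable-class].
#' @param path Output path (`.tsv` extension selects tab separation).
#' @export
writeSubstanceTable <- function(table, path) {
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(table@records, path, sep = sep, row.names = FALSE,
                     quote = TRUE, na = "")
  invisible(path)
}

#' Merge substance inventories
#'
#' One record per unique identifier; assignments from all sources are
#' unioned onto it. Conflicting SMILES for one identifier are flagged with a
#' warning and the first-seen structure retained; one source assigning two
#' different classes to one identifier is an error. Membership counts
#' (per-table totals, pairwise shared, per-table unique) are attached as
#' attribute `"membership"`.
#'
#' @param tables List of [SubstanceTable-class] objects.
#' @return A merged [SubstanceTable-class].
#' @export
mergeInventories <- function(tables) {
  stopifnot(length(tables) >= 1,
            all(vapply(tables, function(t) methods::is(t, "SubstanceTable"),
                       logical(1))))
  sources <- unique(unlist(lapply(tables, function(t) t@sources)))
  recs <- list()
  for (ti in seq_along(tables)) {
    tab <- tables[[ti]]
    for (i in seq_len(nrow(tab@records))) {
      row <- tab@records[i, , drop = FALSE]
      id <- row$identifier
      if (is.null(recs[[id]])) {
        base <- row[.REQ_COLS]
        for (s in sources) base[[s]] <- NA_character_
        recs[[id]] <- base
      } else {
        old <- recs[[id]]
        if (!is.na(row$smiles) && !is.na(old$smiles) &&
            !identical(canonicalSmiles(row$smiles),
                       canonicalSmiles(old$smiles)))
          warning("conflicting SMILES for ", id,
                  "; first-seen structure retained", call. = FALSE)
      }
      for (s in tab@sources) {
        v <- row[[s]]
        if (is.na(v)) next
        old <- recs[[id]][[s]]
        if (!is.na(old) && !identical(old, v))
          stop("source '", s, "' assigns both ", old, " and ", v,
               " to ", id, call. = FALSE)
        recs[[id]][[s]] <- v
      }
    }
  }
  merged <- do.call(rbind, recs)
  rownames(merged) <- NULL
  out <- methods::new("SubstanceTable", records = merged, sources = sources)
  ids <- lapply(tables, function(t) t@records$identifier)
  k <- length(tables)
  shared <- matrix(0L, k, k)
  for (i in seq_len(k)) for (j in seq_len(k))
    shared[i, j] <- length(intersect(ids[[i]], ids[[j]]))
  uniq <- vapply(seq_len(k), function(i)
    length(setdiff(ids[[i]], unlist(ids[-i]))), integer(1))
  attr(out, "membership") <- list(
    n_tables = k, totals = lengths(ids), shared = shared, unique = uniq,
    n_merged = nrow(merged),
    n_defined = sum(merged$structure_status == "defined"))
  out
}
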