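# Look-up lists: plain-text, referenced, user-replaceable files answering the
# subjective rules (body constituents, common carbohydrates, common terpenes,
# common components of food).
#
# File format: UTF-8 text; first line `#matching: stereo_agnostic|stereo_aware`;
# then one SMILES (or InChIKey) per line, optionally followed by
# <TAB>name<TAB>reference. Lines starting with '#' are comments.

.is_inchikey <- function(x) grepl("^[A-Z]{14}-[A-Z]{10}-[A-Z]$", x)

.inchikey <- function(smiles) {
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SMI", "INCHIKEY", smiles)),
    error = function(e) "")
  out <- .first_token(out)
  if (!nzchar(out)) NA_character_ else out
}

#' Read a look-up list file
#'
#' @param path Path to the list file.
#' @param name Optional list name; defaults to the file name without
#'   extension.
#' @return A [LookupList-class] object. Members are stored as canonical
#'   structure keys (stereo handled per the file's matching declaration).
#' @export
readLookupList <- function(path, name = NULL) {
  if (!file.exists(path)) stop("look-up list not found: ", path,
                               call. = FALSE)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  matching <- "stereo_agnostic"
  m <- grep("^#matching:", lines, value = TRUE)
  if (length(m)) matching <- trimws(sub("^#matching:", "", m[1]))
  if (!matching %in% c("stereo_aware", "stereo_agnostic"))
    stop("invalid matching declaration in ", path, call. = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  keys <- vapply(lines, function(ln) {
    entry <- strsplit(ln, "\t", fixed = TRUE)[[1]][1]
    entry <- trimws(entry)
    if (.is_inchikey(entry)) {
      if (matching == "stereo_agnostic") substr(entry, 1, 14) else entry
    } else {
      stereo <- if (matching == "stereo_agnostic") "agnostic" else "aware"
      k <- canonicalKey(entry, stereo)
      if (is.na(k)) stop("unparseable list entry in ", basename(path), ": ",
                         entry, call. = FALSE)
      k
    }
  }, character(1), USE.NAMES = FALSE)
  methods::new("LookupList", name = name, members = unique(keys),
               matching = matching)
}

#' Membership of a structure in a look-up list
#'
#' Membership is decided by canonical structure key under the list's matching
#' policy: `stereo_agnostic` lists (such as the body-constituents list, whose
#' rule explicitly admits optical isomers) ignore stereo descriptors, so the
#' D- and L-forms of a listed substance both match.
#'
#' @param structure A SMILES string.
#' @param list A [LookupList-class] object.
#' @return Logical.
#' @export
lookupMembership <- function(structure, list) {
  stopifnot(methods::is(list, "LookupList"))
  if (!length(list@members)) stop("look-up list '", list@name, "' is empty",
                                  call. = FALSE)
  mol <- asMol(structure)
  stereo <- if (list@matching == "stereo_agnostic") "agnostic" else "aware"
  key <- canonicalKey(mol$canonical, stereo)
  if (key %in% list@members) return(TRUE)
  # lists may also carry InChIKey entries
  ik <- list@members[.is_inchikey(list@members) |
                       grepl("^[A-Z]{14}$", list@members)]
  if (length(ik)) {
    mk <- .inchikey(mol$canonical)
    if (!is.na(mk)) {
      if (list@matching == "stereo_agnostic") mk <- substr(mk, 1, 14)
      return(mk %in% ik)
    }
  }
  FALSE
}

#' Write a look-up list file
#'
#' @param list A [LookupList-class] object.
#' @param path Output path.
#' @export
writeLookupList <- function(list, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("#matching: ", list@matching), con)
  writeLines(list@members, con)
  invisible(path)
}
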