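# Chemistry backend: SMILES parsing, canonicalisation and SMARTS matching via
# OpenBabel (ChemmineOB), with a light molecular-graph view (ChemmineR atom and
# bond blocks) used by the transform engine.

.chem_cache <- new.env(parent = emptyenv())

.cache_get <- function(key) {
  if (exists(key, envir = .chem_cache, inherits = FALSE)) {
    get(key, envir = .chem_cache, inherits = FALSE)
  } else NULL
}

.cache_set <- function(key, value) {
  assign(key, value, envir = .chem_cache)
  value
}

.first_token <- function(x) {
  # OpenBabel SMILES output carries a trailing title/tab/newline
  sub("^([^ \t\n]*).*$", "\\1", x)
}

#' Canonicalise a SMILES string
#'
#' Returns the OpenBabel canonical SMILES, or `NA_character_` when the input
#' does not parse. Canonical SMILES are used internally as join keys only;
#' they are self-consistent but not comparable across toolkits.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of canonical SMILES (`NA` where unparseable).
#' @export
canonicalSmiles <- function(smiles) {
  vapply(as.character(smiles), function(s) {
    if (is.na(s) || !nzchar(s) || grepl("[ \t\n]", s)) return(NA_character_)
    key <- paste0("can\r", s)
    hit <- .cache_get(key)
    if (!is.null(hit)) return(hit)
    out <- tryCatch(ChemmineOB::convertFormat("SMI", "CAN", s),
                    error = function(e) "")
    out <- .first_token(out)
    if (!nzchar(out)) out <- NA_character_
    .cache_set(key, out)
  }, character(1), USE.NAMES = FALSE)
}

.strip_stereo <- function(smiles) {
  # remove tetrahedral (@) and cis/trans (/ \) descriptors; the remainder is
  # still a valid SMILES of the same constitution
  gsub("[/\\\\]", "", gsub("@", "", smiles))
}

#' Structure key for look-up and merge operations
#'
#' Two SMILES of the same structure map to the same key. With
#' `stereo = "agnostic"` stereo descriptors are removed before keying, so
#' enantiomers (e.g. L- and D-alanine) share a key.
#'
#' @param smiles Character vector of SMILES.
#' @param stereo `"aware"` (default) or `"agnostic"`.
#' @return Character vector of keys; `NA` where the SMILES does not parse.
#' @examples
#' canonicalKey("OCC") == canonicalKey("CCO")
#' @export
canonicalKey <- function(smiles, stereo = c("aware", "agnostic")) {
  stereo <- match.arg(stereo)
  if (stereo == "agnostic") smiles <- .strip_stereo(as.character(smiles))
  canonicalSmiles(smiles)
}

# ---- molecular graph -------------------------------------------------------

# Old-style ctab charge codes (field 6 of the atom line)
.CHG_CODE <- c(`1` = 3L, `2` = 2L, `3` = 1L, `5` = -1L, `6` = -2L, `7` = -3L)

.decode_charge <- function(code) {
  out <- .CHG_CODE[as.character(code)]
  out[is.na(out)] <- 0L
  unname(out)
}

#' @keywords internal
#' @noRd
parseSmiles <- function(smiles) {
  if (is.list(smiles) && inherits(smiles, "cramer_mol")) return(smiles)
  smiles <- as.character(smiles)
  can <- canonicalSmiles(smiles)
  if (is.na(can)) return(NULL)
  key <- paste0("mol\r", can)
  hit <- .cache_get(key)
  if (!is.null(hit)) return(hit)
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(can))[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elem <- sub("_.*$", "", rownames(ab))
  charge <- if ("C6" %in% colnames(ab)) .decode_charge(ab[, "C6"]) else
    integer(length(elem))
  bonds <- if (is.matrix(bb) && nrow(bb) > 0) {
    data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
               order = as.integer(bb[, 3]))
  } else data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))
  mol <- structure(list(smiles = smiles, canonical = can,
                        atoms = data.frame(elem = elem, charge = charge,
                                           stringsAsFactors = FALSE),
                        bonds = bonds),
                   class = "cramer_mol")
  .cache_set(key, mol)
}

asMol <- function(x) {
  if (inherits(x, "cramer_mol")) return(x)
  m <- parseSmiles(x)
  if (is.null(m)) stop("SMILES does not parse: ", x, call. = FALSE)
  m
}

molSmiles <- function(x) if (inherits(x, "cramer_mol")) x$canonical else
  as.character(x)

#' Count SMARTS matches in a structure
#'
#' @param structure SMILES string or internal molecule object.
#' @param smarts A SMARTS pattern.
#' @return Integer count of unique matches.
#' @export
countSmarts <- function(structure, smarts) {
  mol <- asMol(structure)
  key <- paste0("sma\r", mol$canonical, "\r", smarts)
  hit <- .cache_get(key)
  if (!is.null(hit)) return(hit)
  n <- ChemmineOB::forEachMol("SMILES", mol$canonical, function(m)
    ChemmineOB::smartsSearch_OB(list(m), smarts, uniqueMatches = TRUE))[[1]]
  .cache_set(key, as.integer(n))
}

#' @rdname countSmarts
#' @export
matchesSmarts <- function(structure, smarts) countSmarts(structure, smarts) > 0

# total bond order of each atom (implicit hydrogens excluded)
.atom_bond_order <- function(mol) {
  n <- nrow(mol$atoms)
  deg <- integer(n)
  if (nrow(mol$bonds)) {
    for (i in seq_len(nrow(mol$bonds))) {
      o <- mol$bonds$order[i]
      if (o == 4L) o <- 1.5  # aromatic
      deg[mol$bonds$a1[i]] <- deg[mol$bonds$a1[i]] + o
      deg[mol$bonds$a2[i]] <- deg[mol$bonds$a2[i]] + o
    }
  }
  deg
}

# neighbours of atom i as integer indices
.neighbours <- function(mol, i) {
  b <- mol$bonds
  c(b$a2[b$a1 == i], b$a1[b$a2 == i])
}

.bond_between <- function(mol, i, j) {
  b <- mol$bonds
  which((b$a1 == i & b$a2 == j) | (b$a1 == j & b$a2 == i))
}

heavyAtomCount <- function(structure) {
  mol <- asMol(structure)
  sum(mol$atoms$elem != "H")
}

elementCounts <- function(structure) {
  mol <- asMol(structure)
  table(mol$atoms$elem)
}

# TRUE when every sulphur atom is divalent (total bond order <= 2, no charge)
.sulfur_all_divalent <- function(mol) {
  s <- which(mol$atoms$elem == "S")
  if (!length(s)) return(TRUE)
  deg <- .atom_bond_order(mol)
  all(deg[s] <= 2 & mol$atoms$charge[s] == 0)
}

# ring-bond flags: a bond is in a ring iff it is not a bridge of the graph
.ring_bonds <- function(mol) {
  if (!nrow(mol$bonds)) return(logical(0))
  g <- igraph::graph_from_edgelist(
    cbind(mol$bonds$a1, mol$bonds$a2), directed = FALSE)
  if (igraph::vcount(g) < nrow(mol$atoms))
    g <- igraph::add_vertices(g, nrow(mol$atoms) - igraph::vcount(g))
  br <- igraph::bridges(g)
  res <- rep(TRUE, nrow(mol$bonds))
  res[as.integer(br)] <- FALSE
  res
}

.components <- function(mol) {
  g <- igraph::make_empty_graph(n = nrow(mol$atoms), directed = FALSE)
  if (nrow(mol$bonds))
    g <- igraph::add_edges(g, rbind(mol$bonds$a1, mol$bonds$a2))
  igraph::components(g)$membership
}

# serialise the graph as a V2000 molblock with M CHG lines
.mol_to_molblock <- function(atoms, bonds) {
  natom <- nrow(atoms)
  nbond <- nrow(bonds)
  hdr <- sprintf("mol\n cramertree\n\n%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                 natom, nbond)
  atom_lines <- sprintf(
    "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
    seq_len(natom) * 0.1, 0, 0, atoms$elem)
  bond_lines <- if (nbond) sprintf("%3d%3d%3d  0  0  0  0",
                                   bonds$a1, bonds$a2, bonds$order) else
    character(0)
  chg <- which(atoms$charge != 0)
  chg_lines <- if (length(chg)) {
    vapply(split(chg, ceiling(seq_along(chg) / 8)), function(idx) {
      paste0("M  CHG", sprintf("%3d", length(idx)),
             paste0(sprintf("%4d%4d", idx, atoms$charge[idx]), collapse = ""))
    }, character(1))
  } else character(0)
  paste(c(hdr, atom_lines, bond_lines, chg_lines, "M  END", "$$$$", ""),
        collapse = "\n")
}

# canonical SMILES of an edited graph (single component expected)
.graph_to_smiles <- function(atoms, bonds) {
  blk <- .mol_to_molblock(atoms, bonds)
  out <- tryCatch(ChemmineOB::convertFormat("SDF", "CAN", blk),
                  error = function(e) "")
  out <- .first_token(out)
  if (!nzchar(out)) stop("transform produced an invalid structure",
                         call. = FALSE)
  out
}

# split an edited graph into connected components, returning SMILES per
# component
.graph_components_smiles <- function(atoms, bonds) {
  mol <- list(atoms = atoms, bonds = bonds)
  memb <- .components(mol)
  vapply(sort(unique(memb)), function(k) {
    keep <- which(memb == k)
    remap <- match(seq_len(nrow(atoms)), keep)
    bsub <- bonds[bonds$a1 %in% keep & bonds$a2 %in% keep, , drop = FALSE]
    bsub$a1 <- remap[bsub$a1]; bsub$a2 <- remap[bsub$a2]
    .graph_to_smiles(atoms[keep, , drop = FALSE], bsub)
  }, character(1))
}
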