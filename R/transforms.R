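# In silico hydrolysis / reduction transforms.
#
# The revised Cramer tree screens susceptible substances not as parents but as
# their breakdown products: esters and acetals are hydrolysed, disulphides
# reduced. Transforms are implemented as graph edits on the atom/bond matrices
# (bond deletions plus, for hydrolyses, one added oxygen per cleaved linkage),
# after which connected components become the product structures.

# locate ester linkages C(=O)-O-C; returns list of c(o = ester O, calk = the
# carbon losing the O). `ring` selects in-ring (lactone) or acyclic linkages.
.find_esters <- function(mol, ring = c("acyclic", "ring", "any")) {
  ring <- match.arg(ring)
  rb <- .ring_bonds(mol)
  deg <- .atom_bond_order(mol)
  hits <- list()
  for (o in which(mol$atoms$elem == "O" & mol$atoms$charge == 0)) {
    nb <- .neighbours(mol, o)
    if (length(nb) != 2 || any(mol$atoms$elem[nb] != "C")) next
    is_carbonyl <- vapply(nb, function(c1) {
      any(vapply(.neighbours(mol, c1), function(k) {
        k != o && mol$atoms$elem[k] == "O" &&
          mol$bonds$order[.bond_between(mol, c1, k)][1] == 2L
      }, logical(1)))
    }, logical(1))
    if (sum(is_carbonyl) != 1) next       # skip anhydrides and plain ethers
    calk <- nb[!is_carbonyl]
    bidx <- .bond_between(mol, o, calk)
    if (mol$bonds$order[bidx[1]] != 1L) next
    in_ring <- rb[bidx[1]]
    if (ring == "acyclic" && in_ring) next
    if (ring == "ring" && !in_ring) next
    hits[[length(hits) + 1L]] <- c(o = o, calk = calk)
  }
  hits
}

# locate acetal/ketal carbons: sp3 C bearing two ether oxygens
.find_acetals <- function(mol) {
  deg <- .atom_bond_order(mol)
  hits <- list()
  for (c0 in which(mol$atoms$elem == "C" & mol$atoms$charge == 0)) {
    nb <- .neighbours(mol, c0)
    bords <- vapply(nb, function(k)
      mol$bonds$order[.bond_between(mol, c0, k)][1], integer(1))
    if (any(bords != 1L)) next            # sp3 centre only
    ethers <- nb[vapply(seq_along(nb), function(i) {
      k <- nb[i]
      if (mol$atoms$elem[k] != "O" || mol$atoms$charge[k] != 0) return(FALSE)
      onb <- .neighbours(mol, k)
      if (length(onb) != 2) return(FALSE)              # hydroxyl excluded
      other <- setdiff(onb, c0)
      if (mol$atoms$elem[other] != "C") return(FALSE)
      # exclude ester oxygens (acyl on the far side)
      !any(vapply(.neighbours(mol, other), function(m2)
        mol$atoms$elem[m2] == "O" &&
          mol$bonds$order[.bond_between(mol, other, m2)][1] == 2L,
        logical(1)))
    }, logical(1))]
    if (length(ethers) >= 2) hits[[length(hits) + 1L]] <-
        c(c0 = c0, o1 = ethers[1], o2 = ethers[2])
  }
  hits
}

.find_disulphides <- function(mol) {
  deg <- .atom_bond_order(mol)
  b <- mol$bonds
  idx <- which(b$order == 1L &
                 mol$atoms$elem[b$a1] == "S" & mol$atoms$elem[b$a2] == "S" &
                 deg[b$a1] <= 2 & deg[b$a2] <= 2)
  lapply(idx, function(i) c(a1 = b$a1[i], a2 = b$a2[i]))
}

.drop_bond <- function(bonds, i, j) {
  keep <- !((bonds$a1 == i & bonds$a2 == j) | (bonds$a1 == j & bonds$a2 == i))
  bonds[keep, , drop = FALSE]
}

# apply one round of a named transform; returns NULL when nothing matched,
# otherwise list(atoms, bonds)
.apply_transform_once <- function(mol, name) {
  atoms <- mol$atoms; bonds <- mol$bonds
  if (name %in% c("ester_hydrolysis", "lactone_hydrolysis")) {
    ring <- if (name == "lactone_hydrolysis") "ring" else "acyclic"
    hit <- .find_esters(mol, ring)
    if (!length(hit)) return(NULL)
    h <- hit[[1]]
    bonds <- .drop_bond(bonds, h["o"], h["calk"])
    atoms <- rbind(atoms, data.frame(elem = "O", charge = 0L))
    bonds <- rbind(bonds, data.frame(a1 = unname(h["calk"]),
                                     a2 = nrow(atoms), order = 1L))
    return(list(atoms = atoms, bonds = bonds))
  }
  if (name == "acetal_hydrolysis") {
    hit <- .find_acetals(mol)
    if (!length(hit)) return(NULL)
    h <- hit[[1]]
    bonds <- .drop_bond(bonds, h["c0"], h["o1"])
    bonds <- .drop_bond(bonds, h["c0"], h["o2"])
    atoms <- rbind(atoms, data.frame(elem = "O", charge = 0L))
    bonds <- rbind(bonds, data.frame(a1 = unname(h["c0"]),
                                     a2 = nrow(atoms), order = 2L))
    return(list(atoms = atoms, bonds = bonds))
  }
  if (name == "disulphide_reduction") {
    hit <- .find_disulphides(mol)
    if (!length(hit)) return(NULL)
    h <- hit[[1]]
    bonds <- .drop_bond(bonds, h["a1"], h["a2"])
    return(list(atoms = atoms, bonds = bonds))
  }
  stop("unknown transform rule: ", name, call. = FALSE)
}

#' Transform rules available to the schemes
#'
#' @return Character vector of transform rule names.
#' @export
transformRules <- function() c("ester_hydrolysis", "lactone_hydrolysis",
                               "acetal_hydrolysis", "disulphide_reduction")

#' Apply hydrolysis/reduction transforms to a structure
#'
#' Each named rule is applied exhaustively (to fixpoint). A structure with no
#' susceptible group is returned unchanged as a singleton list. Products are
#' the connected components of the edited structure; every product is a valid
#' structure.
#'
#' @param structure A SMILES string.
#' @param rules Character vector of rule names (see [transformRules()]).
#' @return Character vector of product SMILES (canonical).
#' @examples
#' applyTransforms("CCOC(=O)CC", "ester_hydrolysis")  # ethanol + propanoic acid
#' @export
applyTransforms <- function(structure, rules) {
  stopifnot(all(rules %in% transformRules()))
  mol <- asMol(structure)
  atoms <- mol$atoms; bonds <- mol$bonds
  changed <- TRUE
  guard <- 0L
  while (changed) {
    changed <- FALSE
    guard <- guard + 1L
    if (guard > 200L) stop("transform did not reach fixpoint", call. = FALSE)
    cur <- list(atoms = atoms, bonds = bonds)
    for (r in rules) {
      res <- .apply_transform_once(cur, r)
      if (!is.null(res)) {
        atoms <- res$atoms; bonds <- res$bonds
        changed <- TRUE
        break
      }
    }
  }
  if (identical(atoms, mol$atoms) && identical(bonds, mol$bonds))
    return(mol$canonical)
  .graph_components_smiles(atoms, bonds)
}
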