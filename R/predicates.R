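# Structural predicates behind the question nodes.
#
# Four predicate kinds are data-driven (smarts, smarts_boolean_expr,
# lookup_membership, element_set); `computed` predicates are registered here.
# Every predicate is a pure function of the structure (plus, for look-ups,
# the attached list), so traversal is deterministic.

# ---- functional group census ----------------------------------------------

.FG_PATTERNS <- list(
  acid      = c("[CX3](=[OX1])[OX2H1]", "[CX3](=[OX1])[OX1-]"),
  ester     = c("[#6][CX3](=[OX1])[OX2][#6]"),
  aldehyde  = c("[CX3H1,CX3H2](=[OX1])"),
  ketone    = c("[#6][CX3](=[OX1])[#6]"),
  hydroxyl  = c("[OX2H][#6;!$([CX3]=[OX1])]"),
  ether     = c("[OX2;!$([OX2H]);!$([OX2][CX3]=[OX1])]([#6])[#6]"),
  acetal    = c("[CX4]([OX2][#6])([OX2][#6])"),
  thiol     = c("[SX2H]"),
  thioether = c("[#16X2;!$([#16][#16]);!$([#16H])]([#6])[#6]"),
  polysulphide = c("[#16X2][#16X2]")
)

.fg_count <- function(mol, group) {
  sum(vapply(.FG_PATTERNS[[group]], function(p) countSmarts(mol, p),
             integer(1)))
}

# Census of the functional groups named in the acyclic/alicyclic list
# questions, plus a flag for any feature outside that vocabulary
# (nitrogen-bearing groups, higher-valence sulphur, unaccounted oxygen,
# foreign elements).
.fg_census <- function(mol) {
  counts <- vapply(names(.FG_PATTERNS), function(g) .fg_count(mol, g),
                   integer(1))
  # an acetal centre consumes two of the matched ether oxygens
  counts["ether"] <- max(0L, counts["ether"] - 2L * counts["acetal"])
  # an S-S chain counts as a single polysulphide unit
  ss_bonds <- counts["polysulphide"]
  counts["polysulphide"] <- as.integer(ss_bonds > 0)

  elems <- mol$atoms$elem
  other <- any(!elems %in% c("C", "H", "O", "N", "S"))
  if (any(elems == "N")) other <- TRUE
  # sulphur accounting: thiol + thioether + S-S sulphurs must cover all S
  n_s <- sum(elems == "S")
  s_used <- counts["thiol"] + counts["thioether"] +
    countSmarts(mol, "[#16X2;$([#16X2][#16X2])]")
  if (n_s > s_used) other <- TRUE
  # oxygen accounting
  n_o <- sum(elems == "O")
  o_used <- counts["hydroxyl"] + 2L * counts["acid"] + 2L * counts["ester"] +
    counts["aldehyde"] + counts["ketone"] + counts["ether"] +
    2L * counts["acetal"]
  if (n_o > o_used) other <- TRUE
  list(counts = counts, other = other)
}

# "no more than one each of one or more of" the listed groups, and nothing
# outside the list; ethers and acetals are not in the original R.20 list
# (Toxtree's acceptance of them is a documented fault, not reproduced here)
.one_each_condition <- function(mol) {
  cs <- .fg_census(mol)
  !cs$other && all(cs$counts <= 1L) &&
    cs$counts["ether"] == 0L && cs$counts["acetal"] == 0L
}

# the revised scheme's stricter variant: thiols (and polysulphides, normally
# already reduced) trigger only in the presence of other functionality, and
# ether linkages are admitted only as methoxy/ethoxy units
.revised16_condition <- function(mol) {
  cs <- .fg_census(mol)
  if (cs$other || any(cs$counts > 1L)) return(FALSE)
  counts <- cs$counts
  if (counts["ether"] > 0) {
    short <- countSmarts(mol, "[OX2]([CX4H3])[#6]") +
      countSmarts(mol, "[OX2]([CX4H2][CX4H3])[#6;!$([CX4H3])]")
    if (counts["ether"] > short) return(FALSE)
  }
  strict <- counts["thiol"] + counts["polysulphide"]
  if (strict > 0 && sum(counts) == strict) return(FALSE)
  TRUE
}

# ---- ketone chain-length rule (original 18(h)) -----------------------------

# carbon count on each wing of every ketone carbonyl; reading = either_side
# requires >= 4 carbons on at least one wing, both_sides on both
.ketone_wing_condition <- function(mol, reading = c("either_side",
                                                    "both_sides")) {
  reading <- match.arg(reading)
  b <- mol$bonds
  carbonyl <- integer(0)
  for (i in seq_len(nrow(b))) {
    if (b$order[i] == 2L) {
      p <- c(b$a1[i], b$a2[i])
      cc <- p[mol$atoms$elem[p] == "C"]
      oo <- p[mol$atoms$elem[p] == "O"]
      if (length(cc) == 1 && length(oo) == 1) {
        nb <- setdiff(.neighbours(mol, cc), oo)
        if (length(nb) == 2 && all(mol$atoms$elem[nb] == "C"))
          carbonyl <- c(carbonyl, cc)
      }
    }
  }
  if (!length(carbonyl)) return(FALSE)
  rb <- .ring_bonds(mol)
  ring_atoms <- unique(c(mol$bonds$a1[rb], mol$bonds$a2[rb]))
  for (c0 in carbonyl) {
    nb <- setdiff(.neighbours(mol, c0), which(mol$atoms$elem == "O"))
    # a wing qualifies only when it is a purely acyclic carbon chain
    # ("open-chained alkyl" reading) of the required length
    wings <- lapply(nb, function(w) {
      g <- igraph::make_empty_graph(n = nrow(mol$atoms), directed = FALSE)
      if (nrow(mol$bonds))
        g <- igraph::add_edges(g, rbind(mol$bonds$a1, mol$bonds$a2))
      g <- igraph::delete_vertices(g, c0)
      idx <- seq_len(nrow(mol$atoms))[-c0]
      comp <- igraph::components(g)$membership
      reach <- idx[comp == comp[match(w, idx)]]
      list(n = sum(mol$atoms$elem[reach] == "C"),
           pure = all(mol$atoms$elem[reach] == "C") &&
             !any(reach %in% ring_atoms))
    })
    ok <- vapply(wings, function(w) w$pure && w$n >= 4, logical(1))
    hit <- if (reading == "either_side") any(ok) else all(ok)
    if (hit) return(TRUE)
  }
  FALSE
}

# ---- aromatic substituent complexity (original R.30 family) ----------------

# decompose a benzene-bearing structure into ring core and substituents;
# a substituent is complex when it carries N or S in any form, or more than
# five carbons not reducible (by ester hydrolysis) to a five-or-fewer-carbon
# ring substituent
.aromatic_substituents <- function(mol) {
  rb <- .ring_bonds(mol)
  ring_atoms <- unique(c(mol$bonds$a1[rb], mol$bonds$a2[rb]))
  non_ring <- setdiff(seq_len(nrow(mol$atoms)), ring_atoms)
  if (!length(non_ring)) return(list())
  g <- igraph::make_empty_graph(n = nrow(mol$atoms), directed = FALSE)
  if (nrow(mol$bonds))
    g <- igraph::add_edges(g, rbind(mol$bonds$a1, mol$bonds$a2))
  sub <- igraph::induced_subgraph(g, non_ring)
  comp <- igraph::components(sub)$membership
  out <- list()
  for (k in unique(comp)) {
    atoms_k <- non_ring[comp == k]
    attach <- atoms_k[vapply(atoms_k, function(a)
      any(.neighbours(mol, a) %in% ring_atoms), logical(1))]
    if (!length(attach)) next
    out[[length(out) + 1L]] <- list(atoms = atoms_k, attach = attach[1])
  }
  out
}

.substituent_is_complex <- function(mol, subst) {
  el <- mol$atoms$elem[subst$atoms]
  if (any(el %in% c("N", "S"))) return(TRUE)
  n_c <- sum(el == "C")
  if (n_c <= 5) return(FALSE)
  !.substituent_reducible(mol, subst)
}

# TRUE when hydrolysing the substituent's ester linkages leaves <= 5 carbons
# attached to the ring (and no N/S on the ring side)
.substituent_reducible <- function(mol, subst) {
  esters <- .find_esters(mol, "acyclic")
  esters <- Filter(function(h) h["o"] %in% subst$atoms, esters)
  if (!length(esters)) return(FALSE)
  g <- igraph::make_empty_graph(n = nrow(mol$atoms), directed = FALSE)
  keep <- !apply(mol$bonds, 1, function(bd) any(vapply(esters, function(h)
    setequal(c(bd[["a1"]], bd[["a2"]]), c(h[["o"]], h[["calk"]])),
    logical(1))))
  bsub <- mol$bonds[keep, , drop = FALSE]
  if (nrow(bsub)) g <- igraph::add_edges(g, rbind(bsub$a1, bsub$a2))
  comp <- igraph::components(g)$membership
  ring_side <- which(comp == comp[subst$attach])
  ring_side <- intersect(ring_side, subst$atoms)
  el <- mol$atoms$elem[ring_side]
  sum(el == "C") <= 5 && !any(el %in% c("N", "S"))
}

# ---- simple linear alkyl series (revised R.2) ------------------------------

# unbranched acyclic all-carbon skeleton terminated by exactly one alcohol,
# aldehyde or carboxylic acid
.simple_linear_alkyl <- function(mol) {
  el <- mol$atoms$elem
  if (any(!el %in% c("C", "O"))) return(FALSE)
  if (any(mol$atoms$charge != 0)) return(FALSE)
  if (length(.ring_bonds(mol)) && any(.ring_bonds(mol))) return(FALSE)
  n_o <- sum(el == "O")
  grp <- c(alcohol = countSmarts(mol, "[OX2H][CX4H2,CX4H3]"),
           aldehyde = countSmarts(mol, "[CX3H1](=[OX1])[#6]"),
           acid = countSmarts(mol, "[CX3](=[OX1])[OX2H1]"))
  o_used <- grp[["alcohol"]] + grp[["aldehyde"]] + 2L * grp[["acid"]]
  if (sum(grp) != 1L || o_used != n_o) return(FALSE)
  # unbranched: every carbon bonded to at most two other carbons, all single
  carbons <- which(el == "C")
  for (c0 in carbons) {
    nb <- .neighbours(mol, c0)
    cn <- nb[mol$atoms$elem[nb] == "C"]
    if (length(cn) > 2) return(FALSE)
    for (k in cn)
      if (mol$bonds$order[.bond_between(mol, c0, k)][1] != 1L) return(FALSE)
  }
  TRUE
}

.L_AA_PATTERNS <- c(
  "[NX3H2][C@@H]([#6])[CX3](=[OX1])[OX2H1,OX1-]",   # standard L-alpha centre
  "[NX3H2][CX4H2][CX3](=[OX1])[OX2H1,OX1-]",        # glycine (achiral)
  "[NX3H1;R][C@@H]([#6;R])[CX3](=[OX1])[OX2H1,OX1-]" # proline-type
)

.is_l_amino_acid <- function(mol) {
  el <- mol$atoms$elem
  if (any(!el %in% c("C", "H", "O", "N", "S"))) return(FALSE)
  any(vapply(.L_AA_PATTERNS, function(p) countSmarts(mol, p) > 0, logical(1)))
}

# ---- salt recognition (original R.4 / revised R.5) -------------------------

.METAL_CATIONS <- c("Na", "K", "Ca", "Mg")

.is_common_salt <- function(mol) {
  memb <- .components(mol)
  if (max(memb) < 2) return(FALSE)
  el <- mol$atoms$elem
  chg <- mol$atoms$charge
  metal <- any(el %in% .METAL_CATIONS & chg > 0) ||
    countSmarts(mol, "[NX4+]") > 0
  anion <- countSmarts(mol, "[CX3](=[OX1])[OX1-]") > 0 ||      # carboxylate
    countSmarts(mol, "[#16](=[OX1])(=[OX1])[OX1-]") > 0 ||     # sulphonate/-ate
    countSmarts(mol, "[NX3][#16](=[OX1])(=[OX1])[OX1-]") > 0   # sulphamate
  if (metal && anion) return(TRUE)
  # amine hydrochloride / amine sulphate pairs
  halide <- any(el %in% c("Cl", "Br") & chg < 0)
  ammonium <- countSmarts(mol, "[NX4+;!$([NX4+]([CX4])([CX4])([CX4])[CX4])]") >
    0 || countSmarts(mol, "[NX3;!$([NX3][CX3]=[OX1])]") > 0
  halide && ammonium
}

# counterion removal: drop carbon-free components, neutralise charges; used
# on the yes edge of the salt rules so the organic parent is evaluated
.apply_counterion_removal <- function(mol) {
  memb <- .components(mol)
  has_c <- vapply(seq_len(max(memb)), function(k)
    any(mol$atoms$elem[memb == k] == "C"), logical(1))
  if (all(has_c) && all(mol$atoms$charge == 0)) return(NULL)
  keep <- which(has_c[memb])
  if (!length(keep)) return(NULL)
  remap <- match(seq_len(nrow(mol$atoms)), keep)
  atoms <- mol$atoms[keep, , drop = FALSE]
  atoms$charge <- 0L
  bonds <- mol$bonds[mol$bonds$a1 %in% keep & mol$bonds$a2 %in% keep, ,
                     drop = FALSE]
  bonds$a1 <- remap[bonds$a1]; bonds$a2 <- remap[bonds$a2]
  list(atoms = atoms, bonds = bonds)
}

# ---- registry --------------------------------------------------------------

.COMPUTED_PREDICATES <- list(
  acyclic_hydrocarbon_or_carbohydrate = function(mol, tree, config) {
    hydro <- all(mol$atoms$elem %in% c("C", "H")) &&
      !any(.ring_bonds(mol))
    if (hydro) return(TRUE)
    lst <- tree@lookupLists[["common_carbohydrates"]]
    !is.null(lst) && lookupMembership(mol, lst)
  },
  pure_hydrocarbon = function(mol, tree, config)
    all(mol$atoms$elem %in% c("C", "H")),
  common_salt = function(mol, tree, config) .is_common_salt(mol),
  one_each_functional_groups = function(mol, tree, config)
    .one_each_condition(mol),
  revised_16_condition = function(mol, tree, config)
    .revised16_condition(mol),
  no_quaternary_carbon = function(mol, tree, config) {
    !matchesSmarts(mol, "[CX4]([#6])([#6])([#6])[#6]")
  },
  ketone_wing = function(mol, tree, config) {
    reading <- config$ketone_chain_reading %||% "either_side"
    .ketone_wing_condition(mol, reading)
  },
  complex_aromatic_substituents = function(mol, tree, config) {
    subst <- .aromatic_substituents(mol)
    any(vapply(subst, function(s) .substituent_is_complex(mol, s),
               logical(1)))
  },
  complex_substituents_reducible = function(mol, tree, config) {
    subst <- .aromatic_substituents(mol)
    cx <- Filter(function(s) .substituent_is_complex(mol, s), subst)
    if (!length(cx)) return(FALSE)
    all(vapply(cx, function(s) {
      el <- mol$atoms$elem[s$atoms]
      !any(el %in% c("N", "S")) && .substituent_reducible(mol, s)
    }, logical(1)))
  },
  hydrolysis_products_clear_alerts = function(mol, tree, config) {
    prods <- applyTransforms(mol$canonical, "ester_hydrolysis")
    alerts <- tree@patterns[grepl("^alert_", names(tree@patterns))]
    all(vapply(prods, function(p) {
      pm <- parseSmiles(p)
      !is.null(pm) && !any(vapply(alerts, function(a)
        countSmarts(pm, a) > 0, logical(1)))
    }, logical(1)))
  },
  l_amino_acid_or_simple_linear = function(mol, tree, config)
    .is_l_amino_acid(mol) || .simple_linear_alkyl(mol),
  terpene_hydrocarbon_c10_c15 = function(mol, tree, config) {
    if (!all(mol$atoms$elem %in% c("C", "H"))) return(FALSE)
    n_c <- sum(mol$atoms$elem == "C")
    rb <- .ring_bonds(mol)
    n_ring_bonds <- sum(rb)
    n_rings <- nrow(mol$bonds) - (nrow(mol$atoms) - max(.components(mol)))
    n_c %in% c(10L, 15L) && n_rings >= 1 && n_rings <= 2 &&
      matchesSmarts(mol, "[CX4H3]")   # methyl-bearing, terpene-like
  },
  sugar_like_polyol = function(mol, tree, config) {
    countSmarts(mol, "[C][OX2H]") >= 4 &&
      sum(mol$atoms$elem == "O") * 2 >= sum(mol$atoms$elem == "C")
  },
  terpene_smarts_conditions = function(mol, tree, config) {
    if (!isTRUE(config$terpene_smarts)) return(FALSE)
    n_c <- sum(mol$atoms$elem == "C")
    n_o <- sum(mol$atoms$elem == "O")
    n_c %in% c(10L, 15L) && n_o <= 1 &&
      all(mol$atoms$elem %in% c("C", "H", "O")) &&
      (matchesSmarts(mol, "CC(C)=C") || matchesSmarts(mol, "[CX4]([CX4H3])([CX4H3])"))
  },
  bare_azine_ring = function(mol, tree, config) {
    matchesSmarts(mol, "[nX2;r6]") && !matchesSmarts(mol, "[o,s;R]") &&
      !matchesSmarts(mol, "[OX2,SX2;R]")
  },
  common_terpene = function(mol, tree, config) {
    lst <- tree@lookupLists[["common_terpenes"]]
    if (!is.null(lst) && lookupMembership(mol$canonical, lst)) return(TRUE)
    .COMPUTED_PREDICATES$terpene_smarts_conditions(mol, tree, config)
  },
  terpene_unusual_functionality = function(mol, tree, config) {
    cs <- .fg_census(mol)
    usual <- c("hydroxyl", "aldehyde", "ketone", "ester", "acid")
    cs$other || any(cs$counts[setdiff(names(cs$counts), usual)] > 0)
  },
  q18_features = function(mol, tree, config) {
    pats <- c("allyl_alcohol", "allyl_ester", "allyl_acetal", "acrolein",
              "methacrolein", "acrylic_acid", "methacrylic_acid",
              "vinyl_ketone")
    hit <- any(vapply(pats, function(nm)
      countSmarts(mol, tree@patterns[[nm]]) > 0, logical(1)))
    hit || .ketone_wing_condition(
      mol, config$ketone_chain_reading %||% "either_side")
  },
  hydroxyls_only_functionality = function(mol, tree, config) {
    cs <- .fg_census(mol)
    !cs$other && cs$counts["hydroxyl"] >= 1L &&
      sum(cs$counts) == cs$counts["hydroxyl"]
  },
  hydroxyls_or_acids_only = function(mol, tree, config) {
    cs <- .fg_census(mol)
    keep <- cs$counts["hydroxyl"] + cs$counts["acid"]
    !cs$other && keep >= 1L && sum(cs$counts) == keep
  },
  ring_multi_substituted = function(mol, tree, config)
    countSmarts(mol, "[c][!c;!#1]") > 2,
  benzene_like_hydrocarbon = function(mol, tree, config) {
    all(mol$atoms$elem %in% c("C", "H")) &&
      matchesSmarts(mol, "c1ccccc1") && !matchesSmarts(mol, "[R2]") &&
      sum(mol$atoms$elem == "C") <= 10
  },
  carbohydrate_or_terpene_hydrocarbon = function(mol, tree, config) {
    .COMPUTED_PREDICATES$sugar_like_polyol(mol, tree, config) ||
      .COMPUTED_PREDICATES$terpene_hydrocarbon_c10_c15(mol, tree, config)
  },
  simple_heterocycle = function(mol, tree, config) {
    all(mol$atoms$elem %in% c("C", "H", "O", "N", "S")) &&
      sum(mol$atoms$elem != "H") <= 12
  },
  aromatic_substituent_with_ns = function(mol, tree, config) {
    subst <- .aromatic_substituents(mol)
    any(vapply(subst, function(s)
      any(mol$atoms$elem[s$atoms] %in% c("N", "S")), logical(1)))
  },
  aromatic_ether_or_long_chain = function(mol, tree, config) {
    subst <- .aromatic_substituents(mol)
    any(vapply(subst, function(s) {
      el <- mol$atoms$elem[s$atoms]
      has_ether <- any(vapply(s$atoms, function(a) {
        mol$atoms$elem[a] == "O" && length(.neighbours(mol, a)) == 2 &&
          all(mol$atoms$elem[.neighbours(mol, a)] == "C")
      }, logical(1)))
      has_ether || sum(el == "C") > 5
    }, logical(1)))
  }
)

`%||%` <- function(a, b) if (is.null(a)) b else a
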