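# Scheme-agnostic decision-tree machinery: predicate evaluation, traversal
# with full audit trace, validation, replay and trace comparison.

.TERMINALS <- c("I", "II", "III")

.is_terminal <- function(x) x %in% .TERMINALS

# ---- predicate evaluation --------------------------------------------------

.bool_expr_tokens <- function(expr)
  regmatches(expr, gregexpr("[A-Za-z_][A-Za-z0-9_]*", expr))[[1]]

.eval_bool_expr <- function(expr, values) {
  e <- expr
  for (nm in names(values))
    e <- gsub(paste0("\\b", nm, "\\b"), as.character(values[[nm]]), e)
  if (grepl("[A-Za-z_]", gsub("TRUE|FALSE", "", e)))
    stop("unresolved name in boolean expression: ", expr, call. = FALSE)
  if (grepl("[^TRUEFALSE!&|() ]", e))
    stop("invalid boolean expression: ", expr, call. = FALSE)
  eval(parse(text = e)[[1]], envir = baseenv())
}

.eval_predicate <- function(pred, mol, tree) {
  kind <- pred$kind
  expr <- pred$expression
  config <- tree@config
  switch(kind,
    smarts = countSmarts(mol, expr) > 0,
    smarts_boolean_expr = {
      nms <- .bool_expr_tokens(expr)
      vals <- lapply(nms, function(nm) {
        if (!nm %in% names(tree@patterns))
          stop("pattern '", nm, "' not defined for tree", call. = FALSE)
        countSmarts(mol, tree@patterns[[nm]]) > 0
      })
      names(vals) <- nms
      .eval_bool_expr(expr, vals)
    },
    lookup_membership = {
      lst <- tree@lookupLists[[expr]]
      if (is.null(lst))
        stop("look-up list '", expr, "' not attached", call. = FALSE)
      lookupMembership(mol$canonical, lst)
    },
    element_set = {
      allowed <- trimws(strsplit(expr, ",")[[1]])
      s_divalent_ok <- "S2" %in% allowed
      allowed <- setdiff(allowed, "S2")
      el <- unique(mol$atoms$elem)
      extra <- setdiff(el, c(allowed, "H", if (s_divalent_ok) "S"))
      length(extra) > 0 ||
        (s_divalent_ok && !.sulfur_all_divalent(mol))
    },
    computed = {
      f <- .COMPUTED_PREDICATES[[expr]]
      if (is.null(f)) stop("unknown computed predicate: ", expr,
                           call. = FALSE)
      isTRUE(f(mol, tree, config))
    },
    stop("unknown predicate kind: ", kind, call. = FALSE)
  )
}

# ---- validation ------------------------------------------------------------

#' Validate a decision tree
#'
#' Checks the rule graph for dangling targets, cycles, nodes unreachable from
#' the root, unresolvable predicates and unreferenced look-up lists. A tree
#' should only be used when the report is empty.
#'
#' @param tree A [CramerTree-class].
#' @return A data.frame with columns `type`, `node`, `detail` (zero rows when
#'   the tree is clean).
#' @export
validateTree <- function(tree) {
  findings <- list()
  add <- function(type, node, detail)
    findings[[length(findings) + 1L]] <<- data.frame(
      type = type, node = node, detail = detail, stringsAsFactors = FALSE)
  ids <- names(tree@nodes)
  edges <- NULL
  for (id in ids) {
    nd <- tree@nodes[[id]]
    for (side in c("yes", "no")) {
      tgt <- nd[[side]]
      if (is.null(tgt)) { add("missing_target", id, side); next }
      if (.is_terminal(tgt)) next
      if (!tgt %in% ids) add("dangling_target", id,
                             paste0(side, " -> ", tgt))
      else edges <- rbind(edges, c(id, tgt))
      if (identical(tgt, id)) add("self_reference", id, side)
    }
    # predicate resolvability
    pr <- nd$predicate
    if (is.null(pr$kind) || is.null(pr$expression)) {
      add("bad_predicate", id, "missing kind or expression")
    } else if (pr$kind == "smarts") {
      ok <- tryCatch({countSmarts("CCO", pr$expression); TRUE},
                     error = function(e) FALSE)
      if (!ok) add("bad_smarts", id, pr$expression)
    } else if (pr$kind == "smarts_boolean_expr") {
      for (nm in .bool_expr_tokens(pr$expression))
        if (!nm %in% names(tree@patterns))
          add("unknown_pattern", id, nm)
    } else if (pr$kind == "lookup_membership") {
      lst <- tree@lookupLists[[pr$expression]]
      if (is.null(lst)) add("missing_list", id, pr$expression)
      else if (!length(lst@members)) add("empty_list", id, pr$expression)
    } else if (pr$kind == "computed") {
      if (!pr$expression %in% names(.COMPUTED_PREDICATES))
        add("unknown_computed", id, pr$expression)
    } else if (pr$kind != "element_set") {
      add("unknown_kind", id, pr$kind)
    }
    for (side in c("yes_transform", "no_transform")) {
      tr <- nd[[side]]
      if (!is.null(tr) &&
          !all(tr %in% c(transformRules(), "counterion_removal")))
        add("unknown_transform", id, paste(tr, collapse = ","))
    }
  }
  # cycles
  if (!is.null(edges)) {
    g <- igraph::graph_from_edgelist(edges, directed = TRUE)
    if (!igraph::is_dag(g)) {
      add("cycle", NA_character_, "rule graph contains a cycle")
    } else {
      reach <- igraph::subcomponent(g, tree@root, mode = "out")
      unreachable <- setdiff(ids, names(reach))
      for (u in unreachable) add("unreachable_node", u, "")
    }
  }
  # lists consulted by computed predicates
  computed_list_use <- list(
    acyclic_hydrocarbon_or_carbohydrate = "common_carbohydrates",
    common_terpene = "common_terpenes")
  referenced <- unlist(lapply(tree@nodes, function(nd) {
    if (identical(nd$predicate$kind, "lookup_membership"))
      nd$predicate$expression
    else if (identical(nd$predicate$kind, "computed"))
      computed_list_use[[nd$predicate$expression]]
    else NULL
  }))
  for (nm in setdiff(names(tree@lookupLists), referenced))
    add("unreferenced_list", NA_character_, nm)
  if (!length(findings))
    return(data.frame(type = character(0), node = character(0),
                      detail = character(0), stringsAsFactors = FALSE))
  do.call(rbind, findings)
}

# ---- product class combination ---------------------------------------------

#' Combine breakdown-product classes
#'
#' The revised scheme classifies breakdown products rather than parents; this
#' combines per-product terminal classes into one verdict. `worst_case`
#' returns the maximum by severity (I < II < III).
#'
#' @param classes Non-empty character/factor vector of classes.
#' @param policy Combination policy; only `"worst_case"` combines.
#' @return A single class (character).
#' @export
combineProductClasses <- function(classes, policy = "worst_case") {
  cl <- cramerClass(classes)
  cl <- cl[!is.na(cl)]
  if (!length(cl)) stop("no classes to combine", call. = FALSE)
  if (policy == "worst_case") as.character(max(cl))
  else as.character(cl[1])
}

# ---- traversal -------------------------------------------------------------

.edge_products <- function(smiles, transforms) {
  notes <- character(0)
  cur <- smiles
  for (tr in transforms) {
    out <- unlist(lapply(cur, function(s) {
      if (tr == "counterion_removal") {
        res <- .apply_counterion_removal(asMol(s))
        if (is.null(res)) s else .graph_components_smiles(res$atoms,
                                                          res$bonds)
      } else applyTransforms(s, tr)
    }))
    cur <- out
  }
  keep <- vapply(cur, function(s) {
    m <- parseSmiles(s)
    !is.null(m) && any(m$atoms$elem == "C")
  }, logical(1))
  if (any(!keep))
    notes <- paste0("inorganic product skipped: ",
                    paste(cur[!keep], collapse = " "))
  if (!any(keep)) keep[] <- TRUE   # wholly inorganic input: keep as-is
  list(products = unique(cur[keep]), notes = notes)
}

#' Evaluate a structure through a decision tree
#'
#' Preprocessing transforms are applied first; each resulting product is
#' traversed from the root, recording every (rule, answer) step. Edges may
#' carry their own transforms (e.g. mid-tree lactone hydrolysis at the cyclic
#' ester rule), which split the traversal into per-product continuations.
#' Fragment terminal classes combine under the tree's product-combination
#' policy.
#'
#' @param tree A validated [CramerTree-class].
#' @param structure SMILES string.
#' @param substance Optional identifier recorded in the trace.
#' @return A [DecisionTrace-class].
#' @export
evaluateTree <- function(tree, structure, substance = NULL) {
  mol <- asMol(structure)
  if (is.null(substance)) substance <- molSmiles(mol)
  notes <- character(0)
  start <- if (length(tree@preprocessors)) {
    ep <- .edge_products(mol$canonical, tree@preprocessors)
    notes <- c(notes, ep$notes)
    ep$products
  } else mol$canonical
  work <- lapply(start, function(s)
    list(smiles = s, node = tree@root, steps = list(), hops = 0L))
  fragments <- list()
  guard <- 0L
  while (length(work)) {
    guard <- guard + 1L
    if (guard > 10000L) stop("traversal did not terminate", call. = FALSE)
    item <- work[[1]]; work <- work[-1]
    fmol <- asMol(item$smiles)
    cur <- item$node
    steps <- item$steps
    repeat {
      nd <- tree@nodes[[cur]]
      if (is.null(nd)) stop("undefined node reached: ", cur, call. = FALSE)
      ans <- tryCatch(.eval_predicate(nd$predicate, fmol, tree),
                      error = function(e)
                        stop("predicate failure at ", cur, ": ",
                             conditionMessage(e), call. = FALSE))
      side <- if (isTRUE(ans)) "yes" else "no"
      steps[[length(steps) + 1L]] <- c(cur, side)
      tgt <- nd[[side]]
      tr <- nd[[paste0(side, "_transform")]]
      if (!is.null(tr) && item$hops < 6L) {
        ep <- .edge_products(fmol$canonical, tr)
        notes <- c(notes, ep$notes)
        if (!(length(ep$products) == 1 &&
              ep$products[1] == fmol$canonical)) {
          for (p in ep$products)
            work[[length(work) + 1L]] <- list(smiles = p, node = tgt,
                                              steps = steps,
                                              hops = item$hops + 1L)
          break
        }
      }
      if (.is_terminal(tgt)) {
        fragments[[length(fragments) + 1L]] <- list(
          smiles = fmol$canonical,
          steps = do.call(rbind, steps),
          terminal = tgt)
        break
      }
      cur <- tgt
    }
  }
  final <- combineProductClasses(
    vapply(fragments, function(f) f$terminal, character(1)),
    tree@productCombination)
  methods::new("DecisionTrace", substance = as.character(substance),
               scheme = tree@schemeName, fragments = fragments,
               final = final, notes = unique(notes))
}

#' Replay a trace's recorded answers through a tree
#'
#' Feeds the recorded yes/no answers back through the node graph and checks
#' that each fragment reproduces its recorded terminal class.
#'
#' @param tree The [CramerTree-class] the trace came from.
#' @param trace A [DecisionTrace-class].
#' @return Logical: `TRUE` when every fragment replays to its terminal.
#' @export
replayTrace <- function(tree, trace) {
  for (fr in trace@fragments) {
    steps <- fr$steps
    n <- nrow(steps)
    cur <- tree@root
    tgt <- NULL
    for (i in seq_len(n)) {
      if (!identical(unname(steps[i, 1]), cur)) return(FALSE)
      nd <- tree@nodes[[cur]]
      if (is.null(nd)) return(FALSE)
      tgt <- nd[[unname(steps[i, 2])]]
      if (is.null(tgt)) return(FALSE)
      if (i < n) {
        if (.is_terminal(tgt)) return(FALSE)
        cur <- tgt
      }
    }
    if (!identical(tgt, fr$terminal)) return(FALSE)
  }
  TRUE
}

#' Locate the divergence between two decision traces
#'
#' Identifies the rule at which two classifications of the same substance
#' part ways: if the traces share a rule-id prefix and then answer a shared
#' rule differently, that rule is the primary origin of disagreement; if the
#' paths share no comparable node (e.g. traces from structurally different
#' schemes), a structural marker is returned; identical traces diverge
#' nowhere.
#'
#' @param a,b [DecisionTrace-class] objects for the same substance.
#' @return A list with elements `type` ("none", "answer" or "structural")
#'   and `rule` (the diverging rule id, or `NA`).
#' @export
locateDivergence <- function(a, b) {
  stopifnot(methods::is(a, "DecisionTrace"), methods::is(b, "DecisionTrace"))
  if (!identical(a@substance, b@substance))
    stop("traces concern different substances", call. = FALSE)
  pa <- a@fragments[[1]]$steps
  pb <- b@fragments[[1]]$steps
  same <- identical(lapply(a@fragments, function(f) f[c("steps", "terminal")]),
                    lapply(b@fragments, function(f) f[c("steps", "terminal")]))
  if (same && identical(a@final, b@final))
    return(list(type = "none", rule = NA_character_))
  n <- min(nrow(pa), nrow(pb))
  for (i in seq_len(n)) {
    if (!identical(pa[i, 1], pb[i, 1]))
      return(list(type = "structural", rule = NA_character_))
    if (!identical(pa[i, 2], pb[i, 2]))
      return(list(type = "answer", rule = pa[i, 1]))
  }
  list(type = "structural", rule = NA_character_)
}

#' Serialise decision traces to JSON lines
#'
#' One JSON object per trace: `{id, scheme, final, fragments: [{smiles,
#' steps: [[rule, answer], ...], terminal}]}`.
#'
#' @param traces A list of [DecisionTrace-class] objects (or one).
#' @param path Optional output file; when `NULL` the lines are returned.
#' @return Character vector of JSON lines (invisibly when written to file).
#' @export
tracesToJsonl <- function(traces, path = NULL) {
  if (methods::is(traces, "DecisionTrace")) traces <- list(traces)
  lines <- vapply(traces, function(tr) {
    obj <- list(
      id = tr@substance, scheme = tr@scheme, final = tr@final,
      fragments = lapply(tr@fragments, function(f) list(
        smiles = f$smiles,
        steps = apply(f$steps, 1, function(r) as.list(unname(r)),
                      simplify = FALSE),
        terminal = f$terminal)))
    jsonlite::toJSON(obj, auto_unbox = TRUE)
  }, character(1))
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
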