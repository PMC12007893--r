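# Trees are data, not code: every scheme ships as an editable JSON rule graph
# (nodes keyed by rule id with verbatim wording, predicate, yes/no targets and
# provenance tags), so users can audit or amend individual rules.

#' Read a decision-tree definition from JSON
#'
#' @param path Path to the tree JSON file.
#' @param lookupDir Directory holding the look-up list files referenced by
#'   the tree (required when the tree declares any).
#' @param config Named list of scheme options merged over the file defaults.
#' @return A [CramerTree-class] (not yet validated; see [validateTree()]).
#' @export
treeFromJson <- function(path, lookupDir = NULL, config = list()) {
  if (!file.exists(path)) stop("tree definition not found: ", path,
                               call. = FALSE)
  def <- jsonlite::read_json(path)
  nodes <- lapply(def$nodes, function(nd) {
    nd$predicate <- lapply(nd$predicate, identity)
    nd
  })
  lists <- list()
  if (length(def$lookup_lists)) {
    if (is.null(lookupDir))
      stop("tree references look-up lists; lookupDir is required",
           call. = FALSE)
    for (nm in names(def$lookup_lists)) {
      f <- file.path(lookupDir, def$lookup_lists[[nm]]$file)
      lists[[nm]] <- readLookupList(f, name = nm)
      if (!is.null(def$lookup_lists[[nm]]$matching) &&
          lists[[nm]]@matching != def$lookup_lists[[nm]]$matching)
        stop("matching policy of list '", nm,
             "' disagrees with the tree definition", call. = FALSE)
    }
  }
  cfg <- def$config %||% list()
  cfg[names(config)] <- config
  methods::new("CramerTree",
               schemeName = def$scheme_name,
               variant = def$variant %||% "base",
               root = def$root,
               nodes = nodes,
               patterns = unlist(def$patterns) %||% character(0),
               preprocessors = unlist(def$preprocessors) %||% character(0),
               lookupLists = lists,
               productCombination = def$product_combination %||% "worst_case",
               config = cfg)
}

#' Write a decision-tree definition to JSON
#'
#' Look-up lists are referenced by file name, not embedded; [writeLookupList()]
#' serialises the lists themselves.
#'
#' @param tree A [CramerTree-class].
#' @param path Output path.
#' @export
treeToJson <- function(tree, path) {
  def <- list(
    scheme_name = tree@schemeName,
    variant = tree@variant,
    root = tree@root,
    product_combination = tree@productCombination,
    preprocessors = as.list(tree@preprocessors),
    patterns = as.list(tree@patterns),
    config = tree@config,
    lookup_lists = lapply(tree@lookupLists, function(l)
      list(file = paste0(l@name, ".smi"), matching = l@matching)),
    nodes = tree@nodes)
  jsonlite::write_json(def, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}
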