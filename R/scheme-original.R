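# The original 33-question Cramer tree (as written, with the documented
# clarified interpretations) and its five-rule extension.

.tree_file <- function(name)
  system.file("extdata", "trees", name, package = "cramertree",
              mustWork = TRUE)

.default_lookup_dir <- function()
  system.file("extdata", "lists", package = "cramertree", mustWork = TRUE)

#' Configuration for the original Cramer scheme
#'
#' @param variant `"base"` (33 questions) or `"extended"` (the five
#'   additional rules covering phosphates, benzene-like substances, divalent
#'   sulphur and unsaturated heteroatom moieties).
#' @param lookupDir Directory containing the four look-up list files
#'   (`body_constituents.smi`, `common_carbohydrates.smi`,
#'   `common_terpenes.smi`, `common_food_components.smi`); defaults to the
#'   lists shipped with the package.
#' @param ketoneChainReading How the ketone chain-length condition of the
#'   R.18 list is read: `"either_side"` (default; one carbonyl wing of four
#'   or more carbons suffices) or `"both_sides"` (both wings must qualify).
#' @param terpeneSmarts Logical; additionally admit structural (SMARTS-style)
#'   terpene conditions at R.16 beside the look-up list. The list always
#'   wins; the structural conditions only extend it.
#' @return A named list of options.
#' @export
originalSchemeConfig <- function(variant = c("base", "extended"),
                                 lookupDir = NULL,
                                 ketoneChainReading = c("either_side",
                                                        "both_sides"),
                                 terpeneSmarts = FALSE) {
  list(variant = match.arg(variant),
       lookup_dir = lookupDir %||% .default_lookup_dir(),
       ketone_chain_reading = match.arg(ketoneChainReading),
       terpene_smarts = isTRUE(terpeneSmarts))
}

#' Build the original (or extended) Cramer decision tree
#'
#' Loads the shipped JSON rule graph, attaches the four look-up lists and
#' validates the tree; an unclean validation report is an error.
#'
#' @param config See [originalSchemeConfig()].
#' @return A validated [CramerTree-class].
#' @examples
#' \donttest{
#' tree <- buildOriginalTree()
#' length(treeNodes(tree))  # 33
#' }
#' @export
buildOriginalTree <- function(config = originalSchemeConfig()) {
  f <- if (config$variant == "extended") "cramer_extended.json" else
    "cramer_original.json"
  tree <- treeFromJson(.tree_file(f), lookupDir = config$lookup_dir,
                       config = config[c("ketone_chain_reading",
                                         "terpene_smarts")])
  rep <- validateTree(tree)
  if (nrow(rep))
    stop("original tree failed validation: ",
         paste(rep$type, rep$node, collapse = "; "), call. = FALSE)
  tree
}

#' Evaluate a single original-scheme rule on a structure
#'
#' Returns the as-written answer of one question node, independent of tree
#' position - the audit entry point for rule-level comparisons (e.g. the
#' salt rule R.4 answering yes for calcium lactate but no for un-ionised
#' taurine).
#'
#' @param ruleId Rule label, e.g. `"R.18"`.
#' @param structure SMILES string.
#' @param tree A built tree (see [buildOriginalTree()]), or `NULL` to build
#'   the default.
#' @return Logical answer.
#' @export
evaluateOriginalRule <- function(ruleId, structure, tree = NULL) {
  if (is.null(tree)) tree <- buildOriginalTree()
  nd <- tree@nodes[[ruleId]]
  if (is.null(nd)) stop("unknown rule id: ", ruleId, call. = FALSE)
  .eval_predicate(nd$predicate, asMol(structure), tree)
}

#' Classify a structure under the original Cramer scheme
#'
#' @param structure SMILES string.
#' @param config See [originalSchemeConfig()]; ignored when `tree` is given.
#' @param tree Optionally a pre-built tree, to amortise construction over
#'   many substances.
#' @param substance Optional identifier recorded in the trace.
#' @return A [DecisionTrace-class]; the class itself via [finalClass()].
#' @export
classifyOriginal <- function(structure, config = originalSchemeConfig(),
                             tree = NULL, substance = NULL) {
  if (is.null(tree)) tree <- buildOriginalTree(config)
  evaluateTree(tree, structure, substance = substance)
}
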