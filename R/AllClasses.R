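#' @import methods
NULL

#' Ordered Cramer class factor
#'
#' The Cramer scheme assigns substances to one of three ordinal hazard tiers:
#' I (lowest concern) < II (intermediate) < III (highest concern).
#'
#' @param x Character or factor with values among "I", "II", "III" (NA kept).
#' @return An ordered factor with levels I < II < III.
#' @export
cramerClass <- function(x) {
  x <- as.character(x)
  bad <- !is.na(x) & !x %in% c("I", "II", "III")
  if (any(bad))
    stop("invalid Cramer class value(s): ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  factor(x, levels = c("I", "II", "III"), ordered = TRUE)
}

#' @title Look-up list of substances
#'
#' @description Expert-curated substance lists (normal body constituents,
#' common carbohydrates, common terpenes, common components of food) answer
#' the subjective rules of the original Cramer scheme by membership. Members
#' are stored as structure keys; `matching` states whether membership honours
#' stereochemistry (`"stereo_aware"`) or ignores it (`"stereo_agnostic"`,
#' so that optical isomers qualify).
#'
#' @slot name Character, list identifier used by predicates.
#' @slot members Character vector of canonical structure keys.
#' @slot matching `"stereo_aware"` or `"stereo_agnostic"`.
#' @exportClass LookupList
setClass("LookupList",
         representation(name = "character", members = "character",
                        matching = "character"),
         validity = function(object) {
           if (!object@matching %in% c("stereo_aware", "stereo_agnostic"))
             return("matching must be 'stereo_aware' or 'stereo_agnostic'")
           TRUE
         })

#' @title Cramer decision tree
#'
#' @description A scheme is a rooted binary rule graph: each question node
#' carries a structural predicate and yes/no targets that are either further
#' node ids or terminal classes ("I", "II", "III"). Trees optionally carry
#' preprocessing transforms (hydrolysis/reduction applied before traversal),
#' a SMARTS pattern dictionary for boolean-expression predicates, and
#' attached look-up lists.
#'
#' @slot schemeName Character scheme label (e.g. "original", "revised").
#' @slot variant Character sub-variant (e.g. "base", "extended").
#' @slot root Id of the entry node.
#' @slot nodes Named list of question nodes.
#' @slot patterns Named character vector of SMARTS used by boolean predicates.
#' @slot preprocessors Character vector of transform rule names.
#' @slot lookupLists Named list of [LookupList-class] objects.
#' @slot productCombination How breakdown-product classes combine
#'   ("worst_case").
#' @slot config Named list of scheme options.
#' @exportClass CramerTree
setClass("CramerTree",
         representation(schemeName = "character", variant = "character",
                        root = "character", nodes = "list",
                        patterns = "character", preprocessors = "character",
                        lookupLists = "list", productCombination = "character",
                        config = "list"),
         prototype(variant = "base", patterns = character(0),
                   preprocessors = character(0), lookupLists = list(),
                   productCombination = "worst_case", config = list()))

setValidity("CramerTree", function(object) {
  if (!length(object@nodes)) return("tree has no nodes")
  if (!object@root %in% names(object@nodes))
    return("root does not name a node")
  if (!object@productCombination %in% c("worst_case", "per_product_report"))
    return("unknown product combination policy")
  TRUE
})

#' @title Decision trace
#'
#' @description The audit object behind rule-level disagreement analysis: for
#' each fragment considered (the parent structure, or a breakdown product
#' produced by a transform), the ordered sequence of (rule id, yes/no answer)
#' steps plus the terminal class; `final` combines fragment terminals under
#' the tree's product-combination policy.
#'
#' @slot substance Substance identifier (or the input SMILES).
#' @slot scheme Scheme name the trace belongs to.
#' @slot fragments List of lists with elements `smiles`, `steps`
#'   (two-column matrix: rule, answer) and `terminal`.
#' @slot final Character, the combined class.
#' @slot notes Character vector of engine notes (e.g. skipped inorganic
#'   products).
#' @exportClass DecisionTrace
setClass("DecisionTrace",
         representation(substance = "character", scheme = "character",
                        fragments = "list", final = "character",
                        notes = "character"),
         prototype(notes = character(0)))

#' @title Substance table with class assignments
#'
#' @description One row per substance: identifier (unique key), optional CAS
#' and name, SMILES, structure status, and one column per classification
#' source holding Cramer classes. Substances lacking a defined structure
#' (mixtures, polymers, unparseable SMILES) are retained for concordance
#' analysis but excluded from classification.
#'
#' @slot records A data.frame with columns `identifier`, `cas`, `name`,
#'   `smiles`, `structure_status`, plus one column per source.
#' @slot sources Character vector of classification source names.
#' @exportClass SubstanceTable
setClass("SubstanceTable",
         representation(records = "data.frame", sources = "character"))

setValidity("SubstanceTable", function(object) {
  req <- c("identifier", "cas", "name", "smiles", "structure_status")
  if (!all(req %in% names(object@records)))
    return(paste("records must contain columns:", paste(req, collapse = ", ")))
  if (anyDuplicated(object@records$identifier))
    return("duplicate identifiers in records")
  if (any(!nzchar(object@records$identifier)))
    return("empty identifier")
  if (!all(object@sources %in% names(object@records)))
    return("every source must have a records column")
  for (s in object@sources) {
    v <- object@records[[s]]
    if (!all(is.na(v) | v %in% c("I", "II", "III")))
      return(paste0("assignments in '", s, "' outside {I, II, III}"))
  }
  if (!all(object@records$structure_status %in% c("defined", "undefined")))
    return("structure_status must be 'defined' or 'undefined'")
  TRUE
})

#' @title Confusion matrix of two classification sources
#'
#' @description 3x3 cross-tabulation of the Cramer classes assigned by two
#' sources to their shared substances (rows: source A, columns: source B).
#'
#' @slot counts 3x3 integer matrix, dimnames I/II/III.
#' @slot sourceA,sourceB Source names.
#' @exportClass CramerConfusion
setClass("CramerConfusion",
         representation(counts = "matrix", sourceA = "character",
                        sourceB = "character"))

setValidity("CramerConfusion", function(object) {
  cm <- object@counts
  if (!all(dim(cm) == c(3, 3))) return("counts must be 3x3")
  if (any(cm < 0) || any(cm != round(cm))) return("counts must be counts")
  if (!identical(rownames(cm), c("I", "II", "III")) ||
      !identical(colnames(cm), c("I", "II", "III")))
    return("dimnames must be I, II, III")
  TRUE
})

#' @title Cohen kappa agreement result
#'
#' @description Chance-corrected agreement between two sources, unweighted or
#' with linear weights on the ordinal class scale, with the asymptotic
#' standard error and confidence interval.
#'
#' @slot estimate Kappa estimate in [-1, 1].
#' @slot weighting "none" or "linear".
#' @slot observedAgreement,expectedAgreement Weighted observed/expected
#'   agreement proportions.
#' @slot se Asymptotic standard error.
#' @slot ciLow,ciHigh Confidence bounds.
#' @slot level Confidence level (default 0.95).
#' @slot n Number of paired assignments.
#' @exportClass KappaResult
setClass("KappaResult",
         representation(estimate = "numeric", weighting = "character",
                        observedAgreement = "numeric",
                        expectedAgreement = "numeric", se = "numeric",
                        ciLow = "numeric", ciHigh = "numeric",
                        level = "numeric", n = "numeric"))
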