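#' @name cramertree-accessors
#' @title Accessors for cramertree classes
#' @description Slot accessors for the S4 containers.
#' @param object An object of the documented class.
NULL

#' @rdname cramertree-accessors
#' @export
setGeneric("schemeName", function(object) standardGeneric("schemeName"))
#' @rdname cramertree-accessors
#' @export
setGeneric("treeNodes", function(object) standardGeneric("treeNodes"))
#' @rdname cramertree-accessors
#' @export
setGeneric("lookupLists", function(object) standardGeneric("lookupLists"))
#' @rdname cramertree-accessors
#' @export
setGeneric("preprocessors", function(object) standardGeneric("preprocessors"))
#' @rdname cramertree-accessors
#' @export
setGeneric("finalClass", function(object) standardGeneric("finalClass"))
#' @rdname cramertree-accessors
#' @export
setGeneric("traceFragments", function(object)
  standardGeneric("traceFragments"))
#' @rdname cramertree-accessors
#' @export
setGeneric("substanceRecords", function(object)
  standardGeneric("substanceRecords"))
#' @rdname cramertree-accessors
#' @export
setGeneric("assignmentSources", function(object)
  standardGeneric("assignmentSources"))
#' @rdname cramertree-accessors
#' @export
setGeneric("confusionCounts", function(object)
  standardGeneric("confusionCounts"))
#' @rdname cramertree-accessors
#' @export
setGeneric("kappaEstimate", function(object) standardGeneric("kappaEstimate"))

setMethod("schemeName", "CramerTree", function(object) object@schemeName)
setMethod("treeNodes", "CramerTree", function(object) object@nodes)
setMethod("lookupLists", "CramerTree", function(object) object@lookupLists)
setMethod("preprocessors", "CramerTree", function(object)
  object@preprocessors)
setMethod("finalClass", "DecisionTrace", function(object)
  cramerClass(object@final))
setMethod("traceFragments", "DecisionTrace", function(object)
  object@fragments)
setMethod("substanceRecords", "SubstanceTable", function(object)
  object@records)
setMethod("assignmentSources", "SubstanceTable", function(object)
  object@sources)
setMethod("confusionCounts", "CramerConfusion", function(object)
  object@counts)
setMethod("kappaEstimate", "KappaResult", function(object) object@estimate)

setMethod("show", "CramerTree", function(object) {
  cat("CramerTree scheme:", object@schemeName,
      sprintf("(variant: %s)\n", object@variant))
  cat(" ", length(object@nodes), "question nodes, root", object@root, "\n")
  if (length(object@preprocessors))
    cat("  preprocessors:", paste(object@preprocessors, collapse = ", "),
        "\n")
  if (length(object@lookupLists))
    cat("  look-up lists:",
        paste(vapply(object@lookupLists, function(l)
          sprintf("%s (%d)", l@name, length(l@members)), character(1)),
          collapse = ", "), "\n")
  cat("  product combination:", object@productCombination, "\n")
})

setMethod("show", "DecisionTrace", function(object) {
  cat(sprintf("DecisionTrace [%s] %s -> Class %s\n", object@scheme,
              object@substance, object@final))
  for (fr in object@fragments) {
    path <- paste(sprintf("%s:%s", fr$steps[, 1], fr$steps[, 2]),
                  collapse = " ")
    cat(sprintf("  %s  [%s] -> %s\n", fr$smiles, path, fr$terminal))
  }
  if (length(object@notes)) cat("  notes:", paste(object@notes,
                                                  collapse = "; "), "\n")
})

setMethod("show", "SubstanceTable", function(object) {
  cat("SubstanceTable:", nrow(object@records), "substances,",
      sum(object@records$structure_status == "defined"),
      "with defined structure\n")
  if (length(object@sources))
    cat("  sources:", paste(object@sources, collapse = ", "), "\n")
})

setMethod("show", "CramerConfusion", function(object) {
  cat(sprintf("CramerConfusion %s (rows) vs %s (columns), n = %d\n",
              object@sourceA, object@sourceB, sum(object@counts)))
  print(object@counts)
})

setMethod("show", "KappaResult", function(object) {
  cat(sprintf(
    "Cohen kappa (%s weights): %.3f  [%.3f, %.3f] (%d%% CI), n = %d\n",
    object@weighting, object@estimate, object@ciLow, object@ciHigh,
    round(object@level * 100), as.integer(object@n)))
  cat(sprintf("  observed agreement %.4f, expected %.4f, se %.4f\n",
              object@observedAgreement, object@expectedAgreement, object@se))
})
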