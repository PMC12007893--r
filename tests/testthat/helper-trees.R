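# Shared scheme builds (trees are deterministic; build once per test run)

`%||%` <- function(a, b) if (is.null(a)) b else a

.tree_cache <- new.env()

cachedTree <- function(which = c("original", "extended", "revised",
                                 "original_both_sides")) {
  which <- match.arg(which)
  if (is.null(.tree_cache[[which]])) {
    .tree_cache[[which]] <- switch(which,
      original = buildOriginalTree(),
      extended = buildOriginalTree(originalSchemeConfig(variant =
                                                          "extended")),
      revised = buildRevisedTree(),
      original_both_sides = buildOriginalTree(
        originalSchemeConfig(ketoneChainReading = "both_sides")))
  }
  .tree_cache[[which]]
}

# a tiny one-question tree used by the engine tests
toyTree <- function(yes = "I", no = "III",
                    predicate = list(kind = "smarts", expression = "[#7]")) {
  new("CramerTree", schemeName = "toy", variant = "base", root = "Q1",
      nodes = list(Q1 = list(text = "contains nitrogen?",
                             predicate = predicate, yes = yes, no = no)),
      patterns = c(ring = "[R]"), preprocessors = character(0),
      lookupLists = list(), productCombination = "worst_case",
      config = list())
}

# expand a confusion matrix into the two aligned rating vectors
ratingsFromMatrix <- function(cm) {
  classes <- c("I", "II", "III")
  ra <- rb <- character(0)
  for (i in 1:3) for (j in 1:3) {
    k <- cm[i, j]
    if (k > 0) {
      ra <- c(ra, rep(classes[i], k))
      rb <- c(rb, rep(classes[j], k))
    }
  }
  list(a = ra, b = rb)
}

# independent from-pairs kappa oracle: observed agreement from the n aligned
# pairs, expected agreement from the full n x n pairing grid
kappaOracle <- function(cm, weighting = "none") {
  w <- if (weighting == "linear")
    outer(1:3, 1:3, function(i, j) 1 - abs(i - j) / 2) else diag(3)
  r <- ratingsFromMatrix(cm)
  ia <- match(r$a, c("I", "II", "III"))
  ib <- match(r$b, c("I", "II", "III"))
  po <- mean(w[cbind(ia, ib)])
  pe <- mean(w[as.matrix(expand.grid(ia, ib))])
  (po - pe) / (1 - pe)
}
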