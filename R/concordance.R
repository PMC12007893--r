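# Agreement statistics between two classification sources over shared
# substances: classification concordance (general accuracy), Cohen kappa in
# unweighted and linearly weighted forms with asymptotic confidence
# intervals, per-class one-vs-rest metrics, and intra-class concordance
# (intersection over union of each class's assignments).

.CLASSES <- c("I", "II", "III")

#' Cross-tabulate two classification sources
#'
#' Counts only substances carrying BOTH assignments; all others are ignored.
#'
#' @param table A [SubstanceTable-class].
#' @param sourceA,sourceB Source column names (rows / columns).
#' @return A [CramerConfusion-class].
#' @export
buildConfusion <- function(table, sourceA, sourceB) {
  stopifnot(methods::is(table, "SubstanceTable"))
  for (s in c(sourceA, sourceB))
    if (!s %in% table@sources) stop("unknown source: ", s, call. = FALSE)
  a <- table@records[[sourceA]]
  b <- table@records[[sourceB]]
  keep <- !is.na(a) & !is.na(b)
  if (!any(keep)) stop("no substances shared by ", sourceA, " and ", sourceB,
                       call. = FALSE)
  cm <- table(factor(a[keep], levels = .CLASSES),
              factor(b[keep], levels = .CLASSES))
  cramerConfusion(unclass(cm), sourceA, sourceB)
}

#' Construct a confusion matrix from counts
#'
#' @param counts 3x3 matrix of counts (rows: source A, columns: source B,
#'   classes in the order I, II, III).
#' @param sourceA,sourceB Source labels.
#' @return A [CramerConfusion-class].
#' @export
cramerConfusion <- function(counts, sourceA = "A", sourceB = "B") {
  counts <- matrix(as.integer(counts), 3, 3,
                   dimnames = list(.CLASSES, .CLASSES))
  methods::new("CramerConfusion", counts = counts, sourceA = sourceA,
               sourceB = sourceB)
}

#' Overall classification concordance
#'
#' @param cm A [CramerConfusion-class].
#' @return Percentage of shared substances with identical assignments.
#' @export
overallConcordance <- function(cm) {
  n <- sum(cm@counts)
  if (n < 1) stop("empty confusion matrix", call. = FALSE)
  100 * sum(diag(cm@counts)) / n
}

.kappa_weights <- function(weighting) {
  k <- length(.CLASSES)
  i <- matrix(seq_len(k), k, k)
  switch(weighting,
         none = diag(k),
         linear = 1 - abs(i - t(i)) / (k - 1),
         quadratic = 1 - (i - t(i))^2 / (k - 1)^2,
         stop("unknown weighting: ", weighting, call. = FALSE))
}

#' Cohen kappa for two classification sources
#'
#' Unweighted kappa scores only exact agreement; linear weights on the
#' ordinal scale I < II < III give partial credit proportional to class
#' distance (`w_ij = 1 - |i-j|/2`). The standard error is the asymptotic
#' (large-sample, non-null) weighted-kappa variance, and the confidence
#' interval is `estimate +/- z * se`. Quadratic weights are available for
#' sensitivity analysis.
#'
#' @param cm A [CramerConfusion-class].
#' @param weighting `"none"`, `"linear"`, or `"quadratic"`.
#' @param level Confidence level (default 0.95).
#' @return A [KappaResult-class].
#' @export
cohenKappa <- function(cm, weighting = c("none", "linear", "quadratic"),
                       level = 0.95) {
  weighting <- match.arg(weighting)
  n <- sum(cm@counts)
  if (n < 1) stop("empty confusion matrix", call. = FALSE)
  w <- .kappa_weights(weighting)
  p <- cm@counts / n
  pr <- rowSums(p)
  pc <- colSums(p)
  po <- sum(w * p)
  pe <- sum(w * outer(pr, pc))
  if (abs(1 - pe) < .Machine$double.eps^0.5)
    stop("degenerate marginals: expected agreement is 1", call. = FALSE)
  est <- (po - pe) / (1 - pe)
  # asymptotic variance (Fleiss/Cohen/Everitt large-sample form)
  wbar_r <- as.vector(w %*% pc)       # row-wise expected weight
  wbar_c <- as.vector(t(w) %*% pr)    # column-wise expected weight
  wsum <- outer(wbar_r, rep(1, 3)) + outer(rep(1, 3), wbar_c)
  term <- sum(p * (w * (1 - pe) - wsum * (1 - po))^2)
  var_k <- (term - (po * pe - 2 * pe + po)^2) / (n * (1 - pe)^4)
  se <- sqrt(max(0, var_k))
  z <- stats::qnorm(1 - (1 - level) / 2)
  methods::new("KappaResult", estimate = est, weighting = weighting,
               observedAgreement = po, expectedAgreement = pe, se = se,
               ciLow = est - z * se, ciHigh = est + z * se, level = level,
               n = as.numeric(n))
}

#' Intra-class concordance (intersection over union)
#'
#' From all assignments of one class issued by the two sources, the
#' percentage common to both: `diag / (row_total + col_total - diag)`.
#'
#' @param cm A [CramerConfusion-class].
#' @param class `"I"`, `"II"` or `"III"`; all three when missing.
#' @return Named numeric percentage(s).
#' @export
intraClassConcordance <- function(cm, class = .CLASSES) {
  class <- match.arg(class, .CLASSES, several.ok = TRUE)
  out <- vapply(class, function(cl) {
    i <- match(cl, .CLASSES)
    d <- cm@counts[i, i]
    tot <- sum(cm@counts[i, ]) + sum(cm@counts[, i]) - d
    if (tot == 0) stop("class ", cl, " absent from both sources",
                       call. = FALSE)
    100 * d / tot
  }, numeric(1))
  names(out) <- class
  out
}

#' Per-class one-vs-rest agreement metrics
#'
#' Treats one source as reference and reports, per class, the true positive
#' rate, true negative rate and positive predictive value of the other.
#'
#' @param cm A [CramerConfusion-class].
#' @param reference `"a"` (rows are truth) or `"b"` (columns are truth).
#' @return data.frame with columns `class`, `tpr`, `tnr`, `ppv` (NA where
#'   undefined).
#' @export
perClassMetrics <- function(cm, reference = c("a", "b")) {
  reference <- match.arg(reference)
  counts <- if (reference == "a") cm@counts else t(cm@counts)
  n <- sum(counts)
  out <- lapply(seq_along(.CLASSES), function(i) {
    tp <- counts[i, i]
    fn <- sum(counts[i, ]) - tp
    fp <- sum(counts[, i]) - tp
    tn <- n - tp - fn - fp
    data.frame(class = .CLASSES[i],
               tpr = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
               tnr = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
               ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Round half up (report rounding)
#'
#' Report tables round half up: 0.05 at one decimal becomes 0.1.
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Numeric.
#' @export
roundHalfUp <- function(x, digits = 1)
  floor(x * 10^digits + 0.5) / 10^digits

#' Full agreement report for two sources
#'
#' The complete statistics panel for one source pair: confusion matrix,
#' overall concordance, kappa under both weightings with confidence
#' intervals, intra-class concordances and per-class one-vs-rest metrics.
#'
#' @param table A [SubstanceTable-class].
#' @param sourceA,sourceB Source column names.
#' @param level Confidence level for the kappa intervals.
#' @return A list with elements `confusion`, `n`, `concordance`,
#'   `kappa_unweighted`, `kappa_weighted`, `intra_class`, `metrics_ref_a`,
#'   `metrics_ref_b`.
#' @export
compareSources <- function(table, sourceA, sourceB, level = 0.95) {
  cm <- buildConfusion(table, sourceA, sourceB)
  intra <- vapply(.CLASSES, function(cl)
    tryCatch(unname(intraClassConcordance(cm, cl)),
             error = function(e) NA_real_), numeric(1))
  list(confusion = cm,
       n = sum(cm@counts),
       concordance = overallConcordance(cm),
       kappa_unweighted = cohenKappa(cm, "none", level),
       kappa_weighted = cohenKappa(cm, "linear", level),
       intra_class = intra,
       metrics_ref_a = perClassMetrics(cm, "a"),
       metrics_ref_b = perClassMetrics(cm, "b"))
}
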