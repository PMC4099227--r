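# Group-level statistics: descriptives, two-sample mean comparison, and
# nonparametric ROC analysis of diagnostic ability.

#' Descriptive summary of a feature sample
#'
#' @param values Non-empty numeric vector (one feature value per case).
#' @return A `DescriptiveStats` list: `mean`, `st_dev` (sample `n - 1`
#'   denominator; 0 by convention for `n = 1`), `min`, `max`, `n`.
#' @export
descriptiveStats <- function(values) {
  if (length(values) == 0 || anyNA(values))
    lgStop("values must be non-empty and finite", "lg_empty_input_error")
  structure(list(mean = mean(values),
                 st_dev = if (length(values) == 1) 0 else stats::sd(values),
                 min = min(values), max = max(values),
                 n = length(values)),
            class = "DescriptiveStats")
}

#' @export
print.DescriptiveStats <- function(x, ...) {
  cat(sprintf("n=%d mean=%.4g sd=%.4g min=%.4g max=%.4g\n",
              x$n, x$mean, x$st_dev, x$min, x$max))
  invisible(x)
}

#' Two-sample comparison of group means
#'
#' Unpaired two-sample t-test between two feature samples. The study groups
#' have unequal sizes, so an unpaired comparison is the only coherent
#' reading; the pooled-variance Student form (df = `n_a + n_b - 2`) is the
#' default, with Welch-Satterthwaite available.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @param pooled Logical; `TRUE` (default) for the equal-variance Student
#'   form, `FALSE` for Welch.
#' @return A `TTestResult` list: `t_stat`, `df`, `p_value` (two-sided).
#' @examples
#' twoSampleT(c(1, 2, 3), c(3, 4, 5))
#' @export
twoSampleT <- function(a, b, pooled = TRUE) {
  if (length(a) < 2 || length(b) < 2)
    lgStop("each group needs at least 2 observations", "lg_empty_input_error")
  ht <- tryCatch(stats::t.test(a, b, var.equal = isTRUE(pooled)),
                 error = function(e) NULL)
  if (is.null(ht)) {
    # both groups (essentially) constant: the statistic degenerates
    delta <- mean(a) - mean(b)
    df <- if (isTRUE(pooled)) length(a) + length(b) - 2 else NA_real_
    return(structure(list(
      t_stat = if (delta == 0) 0 else sign(delta) * Inf, df = df,
      p_value = if (delta == 0) 1 else 0), class = "TTestResult"))
  }
  structure(list(t_stat = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = ht$p.value),
            class = "TTestResult")
}

#' @export
print.TTestResult <- function(x, ...) {
  cat(sprintf("t = %.4g, df = %.4g, p = %.4g\n", x$t_stat, x$df, x$p_value))
  invisible(x)
}

# Midrank-based Mann-Whitney AUC: ties count half. Equivalent to explicit
# enumeration of all (pos, neg) pairs.
mannWhitneyAUC <- function(pos, neg) {
  r <- rank(c(pos, neg))  # midranks
  np <- length(pos); nn <- length(neg)
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' Nonparametric (Mann-Whitney) area under the ROC curve
#'
#' Estimates the probability that a positive-class score exceeds a
#' negative-class score, counting ties as one half — the tie-corrected
#' Mann-Whitney estimator, identical to the trapezoidal area under the
#' empirical ROC curve. The standard error uses the Hanley-McNeil formula;
#' the p-value tests the null of no diagnostic value (AUC = 0.5) with a
#' two-sided normal test using the Hanley-McNeil variance evaluated under
#' that null. `method = "delong"` substitutes the DeLong variance estimate
#' for both the SE and the test.
#'
#' @param pos Scores of the positive class (here: osteolytic metastases).
#' @param neg Scores of the negative class (here: multiple myeloma).
#' @param method `"hanley"` (default) or `"delong"`.
#' @return An `ROCResult` list: `auc`, `se`, `p_value`, `n_pos`, `n_neg`,
#'   `method`.
#' @examples
#' empiricalAUC(pos = c(2, 3, 4), neg = c(1, 2, 3))  # 7/9
#' @seealso [rocCurvePoints()], [binormalAUC()]
#' @export
empiricalAUC <- function(pos, neg, method = c("hanley", "delong")) {
  method <- match.arg(method)
  if (length(pos) < 1 || length(neg) < 1)
    lgStop("both groups must be non-empty", "lg_empty_input_error")
  np <- length(pos); nn <- length(neg)
  auc <- mannWhitneyAUC(pos, neg)
  hanleyVar <- function(A) {
    q1 <- A / (2 - A); q2 <- 2 * A^2 / (1 + A)
    (A * (1 - A) + (np - 1) * (q1 - A^2) + (nn - 1) * (q2 - A^2)) / (np * nn)
  }
  if (method == "hanley") {
    se <- sqrt(max(hanleyVar(auc), 0))
    se0 <- sqrt(hanleyVar(0.5))
  } else {
    # DeLong: placement values
    v10 <- vapply(pos, function(p)
      mean((p > neg) + 0.5 * (p == neg)), numeric(1))
    v01 <- vapply(neg, function(q)
      mean((pos > q) + 0.5 * (pos == q)), numeric(1))
    se <- sqrt(stats::var(v10) / np + stats::var(v01) / nn)
    se0 <- se
  }
  z <- if (se0 > 0) (auc - 0.5) / se0 else 0
  p <- if (se0 > 0) 2 * stats::pnorm(-abs(z)) else 1
  structure(list(auc = auc, se = se, p_value = min(p, 1),
                 n_pos = np, n_neg = nn, method = method),
            class = "ROCResult")
}

#' @export
print.ROCResult <- function(x, ...) {
  cat(sprintf("AUC = %.3f (SE %.3f, %s), p[AUC=0.5] = %.4g  (n+ = %d, n- = %d)\n",
              x$auc, x$se, x$method, x$p_value, x$n_pos, x$n_neg))
  invisible(x)
}

#' Empirical ROC curve points
#'
#' One `(fpr, tpr)` point per distinct score threshold (classify positive
#' when score >= threshold), from `(0, 0)` at threshold `+Inf` to `(1, 1)`.
#' The trapezoidal area under these points equals [empiricalAUC()] exactly,
#' including under ties.
#'
#' @param pos,neg Score vectors as in [empiricalAUC()].
#' @return A `data.frame` with columns `threshold`, `fpr`, `tpr`, ordered
#'   by increasing `fpr`.
#' @export
rocCurvePoints <- function(pos, neg) {
  if (length(pos) < 1 || length(neg) < 1)
    lgStop("both groups must be non-empty", "lg_empty_input_error")
  thr <- c(Inf, sort(unique(c(pos, neg)), decreasing = TRUE))
  data.frame(threshold = thr,
             fpr = vapply(thr, function(t) mean(neg >= t), numeric(1)),
             tpr = vapply(thr, function(t) mean(pos >= t), numeric(1)))
}

#' Trapezoidal area under ROC points
#'
#' @param points A `data.frame` from [rocCurvePoints()].
#' @return The trapezoidal area (a number in `[0, 1]`).
#' @export
trapezoidalAUC <- function(points) {
  o <- order(points$fpr, points$tpr)
  x <- points$fpr[o]; y <- points$tpr[o]
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Closed-form AUC for two normal score distributions
#'
#' `AUC = pnorm((muPos - muNeg) / sqrt(sdPos^2 + sdNeg^2))`, the
#' probability that a draw from the positive-class normal exceeds an
#' independent draw from the negative-class normal. Serves as the
#' analytical companion against which the synthetic generator's empirical
#' AUCs are validated.
#'
#' @param muPos,sdPos Positive-class mean and SD.
#' @param muNeg,sdNeg Negative-class mean and SD.
#' @return The binormal AUC.
#' @examples
#' binormalAUC(270.66, 16.80, 248.12, 9.51)  # flat-bone SDGL, about 0.88
#' @export
binormalAUC <- function(muPos, sdPos, muNeg, sdNeg) {
  if (sdPos < 0 || sdNeg < 0)
    lgStop("standard deviations must be >= 0", "lg_param_error")
  s <- sqrt(sdPos^2 + sdNeg^2)
  if (s == 0) {
    if (muPos == muNeg)
      lgStop("AUC undefined: both SDs zero with equal means",
             "lg_degenerate_error")
    return(as.numeric(muPos > muNeg))
  }
  stats::pnorm((muPos - muNeg) / s)
}
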