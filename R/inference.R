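#' Percentile bootstrap confidence interval of the mean
#'
#' Resamples the values with replacement \code{n} times (default 1000)
#' and reports the percentile interval of the resampled means.
#'
#' @param values numeric sample.
#' @param n number of resamples (default 1000).
#' @param level confidence level (default 0.95).
#' @param seed optional seed; when given, the caller's RNG state is left
#'   untouched.
#' @return a [BootstrapCI-class].
#' @export
bootstrapCi <- function(values, n = 1000, level = 0.95, seed = NULL) {
  if (!length(values)) stop("empty sample")
  values <- sort(values)   # endpoints independent of input ordering
  draw <- function() {
    m <- matrix(sample(values, n * length(values), replace = TRUE),
                nrow = n)
    rowMeans(m)
  }
  means <- if (is.null(seed)) draw() else withLocalSeed(seed, draw())
  qs <- stats::quantile(means, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE)
  pt <- mean(values)
  new("BootstrapCI", point = pt, lo = min(qs[1], pt), hi = max(qs[2], pt),
      nResamples = n)
}

#' Benjamini-Hochberg false discovery rate correction
#'
#' Step-up procedure at level \code{q}. Also reports the pFDR threshold
#' in the style used for figure annotations ("p < pFDR = ..."): the
#' largest rejected p-value, or 0 when nothing is rejected.
#'
#' @param pvalues numeric vector of p-values.
#' @param q FDR level (default 0.05).
#' @return list with \code{rejected} (logical vector) and
#'   \code{threshold} (pFDR).
#' @export
bhFdr <- function(pvalues, q = 0.05) {
  if (!length(pvalues)) return(list(rejected = logical(0), threshold = 0))
  rejected <- stats::p.adjust(pvalues, method = "BH") <= q
  threshold <- if (any(rejected)) max(pvalues[rejected]) else 0
  list(rejected = rejected, threshold = threshold)
}

#' Normality-gated two-sample post-hoc test
#'
#' Applies an Anderson-Darling normality test to each sample at level
#' \code{alpha}; if both samples are consistent with normality, compares
#' them with a two-sample t-test, otherwise with the two-sided Wilcoxon
#' rank-sum test ([ranksumPvalue()]). Samples too small for the
#' Anderson-Darling test (n < 8) or degenerate (zero variance) are
#' treated as non-normal.
#'
#' @param x,y numeric samples.
#' @param alpha level for the normality gate (default 0.05).
#' @return list with \code{test} ("t_test" or "ranksum") and \code{p}.
#' @export
selectPosthocTest <- function(x, y, alpha = 0.05) {
  isNormal <- function(v) {
    if (length(v) < 8 || stats::sd(v) == 0) return(FALSE)
    nortest::ad.test(v)$p.value > alpha
  }
  if (isNormal(x) && isNormal(y)) {
    list(test = "t_test", p = stats::t.test(x, y, var.equal = TRUE)$p.value)
  } else {
    list(test = "ranksum", p = ranksumPvalue(x, y))
  }
}
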