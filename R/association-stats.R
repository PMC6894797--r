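#' Binomial sampling-bias probability of haplotype absence
#'
#' The probability that a haplotype present at population frequency \code{f}
#' is observed at most \code{atMost} times in a random sample of \code{n}
#' accessions drawn with replacement. The default \code{atMost = 0} is the
#' absence probability \eqn{(1-f)^n}, evaluated in log space so that
#' vanishingly small values (the haplotype-3 case: f = 51/172, n = 200 gives
#' about 2.8e-31) do not underflow; general tails use the binomial CDF.
#'
#' @param f haplotype frequency, in [0, 1].
#' @param n sample size (non-negative integer).
#' @param atMost count threshold k; returns P(X <= k) for X ~ Binomial(n, f).
#' @return A probability.
#' @examples
#' absenceProbability(51 / 172, 200)
#' @export
absenceProbability <- function(f, n, atMost = 0L) {
  if (!is.numeric(f) || f < 0 || f > 1)
    stop("domain error: f must lie in [0, 1]")
  if (n < 0) stop("domain error: n must be non-negative")
  if (atMost < 0) stop("domain error: atMost must be non-negative")
  if (atMost == 0L) {
    if (f == 1 && n > 0) return(0)
    return(exp(n * log1p(-f)))
  }
  pbinom(atMost, n, f)
}

#' Pearson chi-squared test of haplotype-by-phenotype independence
#'
#' Computes the Pearson statistic \eqn{\sum (O-E)^2/E} with expected counts
#' from the table margins, \code{(r-1)(c-1)} degrees of freedom and the
#' asymptotic upper-tail p-value, optionally adding a seeded Monte-Carlo
#' p-value from multinomial resampling under fixed margins. No continuity
#' correction is applied by default.
#'
#' @param x contingency table: a matrix of non-negative integer counts with
#'   at least two rows and two columns.
#' @param correct apply the Yates continuity correction (2x2 tables only).
#' @param B number of Monte-Carlo resamples (0 disables the Monte-Carlo p).
#' @param seed integer seed for the Monte-Carlo draw.
#' @return A list: \code{statistic}, \code{df}, \code{p.value},
#'   \code{expected}, and \code{p.mc} when \code{B > 0}.
#' @examples
#' chiSquareIndependence(matrix(c(20, 5, 5, 20), 2))
#' @export
chiSquareIndependence <- function(x, correct = FALSE, B = 0L, seed = NULL) {
  x <- as.matrix(x)
  if (nrow(x) < 2L || ncol(x) < 2L)
    stop("degenerate-table error: at least 2 rows and 2 columns required")
  if (any(x < 0)) stop("counts must be non-negative")
  if (any(rowSums(x) == 0) || any(colSums(x) == 0))
    stop("degenerate-table error: zero margin")
  res <- suppressWarnings(stats::chisq.test(x, correct = correct))
  out <- list(statistic = unname(res$statistic),
              df = unname(res$parameter),
              p.value = unname(res$p.value),
              expected = res$expected)
  if (B > 0L) {
    mc <- withSeed(seed, suppressWarnings(
      stats::chisq.test(x, simulate.p.value = TRUE, B = as.integer(B))))
    out$p.mc <- unname(mc$p.value)
  }
  out
}
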