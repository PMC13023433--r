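# Paired comparison statistics for subject-wise accuracy distributions.

#' Paired t-test on per-subject scores
#'
#' Two-sided paired t-test: t = mean(d) / (sd(d)/sqrt(n)) for d = a - b,
#' with p from the t distribution on n - 1 degrees of freedom. Identical
#' vectors give t = 0, p = 1 by convention.
#'
#' @param a,b Numeric vectors of equal length (paired by subject).
#' @return List with \code{t}, \code{p}, \code{df}, \code{mean_diff}.
#' @export
paired_ttest <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  n <- length(d)
  s <- stats::sd(d)
  if (s == 0) {
    if (mean(d) == 0) return(list(t = 0, p = 1, df = n - 1, mean_diff = 0))
    t <- sign(mean(d)) * Inf
    return(list(t = t, p = 0, df = n - 1, mean_diff = mean(d)))
  }
  t <- mean(d) / (s / sqrt(n))
  list(t = t, p = 2 * stats::pt(-abs(t), df = n - 1), df = n - 1,
       mean_diff = mean(d))
}

#' Wilcoxon signed-rank test on per-subject scores
#'
#' Two-sided test with zero differences dropped. Ranks |d| (ties get average
#' ranks), sums positive- and negative-sign ranks, and reports
#' W = min(W+, W-). The p-value is exact by enumeration of all 2^n sign
#' patterns for n <= 12 and uses the normal approximation (with continuity
#' correction) above. All differences zero is an error.
#'
#' @param a,b Numeric vectors of equal length (paired).
#' @return List with \code{W}, \code{W_plus}, \code{W_minus}, \code{p},
#'   \code{n} (non-zero differences used).
#' @export
wilcoxon_signed_rank <- function(a, b) {
  stopifnot(length(a) == length(b))
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("all paired differences are zero; test undefined")
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  w_minus <- sum(r[d < 0])
  W <- min(w_plus, w_minus)
  total <- n * (n + 1) / 2
  if (n <= 12L) {
    # exact: distribution of W+ over all sign assignments of the observed ranks
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    wp <- as.vector(signs %*% r)
    p <- mean(pmin(wp, total - wp) <= W)
  } else {
    mu <- total / 2
    sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24)
    z <- (W - mu + 0.5) / sigma
    p <- min(1, 2 * stats::pnorm(z))
  }
  list(W = W, W_plus = w_plus, W_minus = w_minus, p = p, n = n)
}

#' Cohen's d effect size (pooled SD)
#'
#' d = (mean(a) - mean(b)) / s_pooled with the two-sample pooled standard
#' deviation. Identical vectors give 0.
#'
#' @param a,b Numeric vectors (need not be equal length).
#' @return The effect size d.
#' @export
cohens_d <- function(a, b) {
  na <- length(a); nb <- length(b)
  stopifnot(na >= 2, nb >= 2)
  sp <- sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
               (na + nb - 2))
  if (sp == 0) return(0)
  (mean(a) - mean(b)) / sp
}
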