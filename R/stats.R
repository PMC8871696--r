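#' Paired Wilcoxon signed-rank test on a vector of differences
#'
#' Zero differences are dropped before ranking; tied absolute differences
#' receive average ranks. When, after dropping zeros, n <= 25, the two-sided
#' p-value is exact: the null distribution of the signed-rank statistic is
#' enumerated over all 2^n sign assignments conditional on the observed
#' (possibly tied) ranks, by dynamic programming. For larger n a normal
#' approximation with tie correction and continuity correction is used. If
#' every difference is zero the test carries no signal and p = 1.
#'
#' @param d Numeric vector of paired differences (length >= 1).
#' @return List with `statistic` (signed-rank W, sum of ranks of positive
#'   differences), `p`, `n_used` (non-zero differences), `method`
#'   ("exact" or "approx").
#' @export
paired_wilcoxon <- function(d) {
  if (length(d) == 0L) stop("empty difference vector")
  if (anyNA(d)) stop("NA differences are not allowed")
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(list(statistic = 0, p = 1, n_used = 0L, method = "exact"))
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= 25L) {
    # doubled ranks are integers even with average-rank ties; convolve the
    # sign-flip distribution of the doubled statistic
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    dist <- numeric(total + 1L)  # dist[s + 1] = P(2W = s) * 2^n
    dist[1L] <- 1
    for (rk in r2) {
      shifted <- c(numeric(rk), dist[seq_len(total + 1L - rk)])
      dist <- dist + shifted
    }
    dev <- abs(seq(0L, total) - total / 2)
    p <- sum(dist[dev >= abs(2 * w - total / 2) - 1e-9]) / 2^n
    return(list(statistic = w, p = min(p, 1), n_used = n, method = "exact"))
  }
  mu <- n * (n + 1) / 4
  tie_n <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_n^3 - tie_n) / 48
  z <- w - mu
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)
  p <- 2 * min(pnorm(z), pnorm(z, lower.tail = FALSE))
  list(statistic = w, p = min(p, 1), n_used = n, method = "approx")
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment; the output is order-aligned with the input and
#' clipped to at most 1. Zero p-values are accepted: degenerate but
#' legitimate cases (a perfect rank correlation under the t approximation, a
#' zero background proportion in an enrichment test) produce them.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Two-sided exact binomial skew test
#'
#' Tests whether significantly up- and down-spliced intron counts deviate from
#' a 50/50 split, with the minimum-likelihood two-sided convention (for
#' pi = 0.5 this equals twice the smaller tail, capped at 1).
#'
#' @param n_up,n_down Non-negative counts; `n_up + n_down >= 1`.
#' @return Two-sided p-value.
#' @export
binomial_skew_test <- function(n_up, n_down) {
  stopifnot(n_up >= 0, n_down >= 0)
  n <- n_up + n_down
  if (n < 1) stop("n_up + n_down must be >= 1")
  binom.test(n_up, n, p = 0.5)$p.value
}

#' One-sided exact binomial enrichment test
#'
#' P(X >= n_up) for X ~ Binomial(n_tested, prop): are more successes observed
#' than the background proportion predicts?
#'
#' @param n_up Observed successes.
#' @param n_tested Trials (> 0).
#' @param prop Background success probability in \[0, 1\].
#' @return One-sided (upper tail) p-value.
#' @export
binomial_enrichment_test <- function(n_up, n_tested, prop) {
  if (n_tested <= 0) stop("n_tested must be > 0")
  stopifnot(n_up >= 0, n_up <= n_tested, prop >= 0, prop <= 1)
  pbinom(n_up - 1, n_tested, prop, lower.tail = FALSE)
}

# all permutations of 1..n as an n! x n matrix; used only for small n
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow = nrow(sub)))
  }))
}

#' Spearman rank correlation with small-sample exact p-value
#'
#' rho is the Pearson correlation of average ranks. The two-sided p-value is
#' exact by enumeration of all n! permutations for n <= 7 (proportion of
#' permutations with |rho| at least as large as observed) and uses the
#' t approximation on n - 2 degrees of freedom otherwise. Zero variance in
#' either vector leaves rho undefined.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return List with `n`, `rho`, `p` (both `NA` if degenerate).
#' @export
spearman_test <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) stop("NA values are not allowed")
  if (sd(x) == 0 || sd(y) == 0) {
    return(list(n = n, rho = NA_real_, p = NA_real_))
  }
  rx <- rank(x)
  ry <- rank(y)
  rho <- cor(rx, ry)
  if (n <= 7) {
    perm <- all_permutations(n)
    rhos <- apply(perm, 1L, function(idx) cor(rx, ry[idx]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
  } else {
    if (1 - rho^2 < .Machine$double.eps) {
      p <- 0
    } else {
      tval <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * pt(-abs(tval), df = n - 2)
    }
  }
  list(n = n, rho = rho, p = p)
}
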