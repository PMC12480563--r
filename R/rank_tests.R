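## Nonparametric rank-test primitives: Mann-Whitney U with exact
## enumeration, Vargha-Delaney A, Wilcoxon signed-rank with exact sign-flip
## distribution, and Benjamini-Hochberg adjustment.

.new_rank_test <- function(statistic, value, n1, n2, p_value, alternative, method) {
  structure(list(statistic = statistic, value = value, n1 = n1, n2 = n2,
                 p_value = p_value, alternative = alternative, method = method),
            class = "rank_test")
}

#' @export
print.rank_test <- function(x, ...) {
  cat(sprintf("%s = %g (n1 = %d, n2 = %d), p = %.6g [%s, %s]\n",
              x$statistic, x$value, x$n1, x$n2, x$p_value, x$alternative, x$method))
  invisible(x)
}

## U statistic via midranks: U = sum(rank(x)) - n1(n1+1)/2, counts pairs
## xi > yj plus half-ties.
.u_statistic <- function(x, y) {
  n1 <- length(x)
  r <- rank(c(x, y))
  sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
}

#' Mann-Whitney U test
#'
#' U counts pairs `(i, j)` with `x[i] > y[j]`, ties counting one half. For
#' small samples (`n1 + n2 <= exact_limit`) the p-value is computed by exact
#' enumeration of all `choose(n1 + n2, n1)` group assignments of the pooled
#' observations (valid under ties); otherwise by normal approximation with
#' tie-corrected variance and continuity correction. Two-sided p-values are
#' twice the smaller tail, capped at 1.
#'
#' @param x,y Numeric vectors, both non-empty.
#' @param alternative `"two_sided"`, `"greater"` (x tends larger) or
#'   `"less"`.
#' @param exact Force exact enumeration on/off; default `NULL` decides by
#'   `exact_limit`.
#' @param exact_limit Largest `n1 + n2` for automatic exact enumeration.
#' @return A `rank_test` with statistic `"U"`.
#' @export
mann_whitney_u <- function(x, y, alternative = c("two_sided", "greater", "less"),
                           exact = NULL, exact_limit = 20L) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("x and y must be non-empty")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  u <- .u_statistic(x, y)
  if (is.null(exact)) exact <- n <= exact_limit

  if (exact) {
    ## count subsets of size n1 by doubled-midrank sum (handles ties exactly)
    r2 <- as.integer(round(2 * rank(c(x, y))))
    u2 <- as.integer(round(2 * u)) + n1 * (n1 + 1L)  # 2*rank-sum of x group
    total <- sum(r2)
    f <- matrix(0, n1 + 1L, total + 1L)  # f[k+1, s+1] = #size-k subsets with sum s
    f[1L, 1L] <- 1
    for (i in seq_len(n)) {
      ri <- r2[i]
      for (k in rev(seq_len(min(i, n1)))) {
        idx <- (ri + 1L):(total + 1L)
        f[k + 1L, idx] <- f[k + 1L, idx] + f[k, idx - ri]
      }
    }
    dist <- f[n1 + 1L, ]
    n_sets <- sum(dist)
    p_ge <- sum(dist[(u2 + 1L):(total + 1L)]) / n_sets
    p_le <- sum(dist[seq_len(u2 + 1L)]) / n_sets
    method <- "exact enumeration"
  } else {
    mu <- n1 * n2 / 2
    ties <- table(c(x, y))
    tie_term <- sum(ties^3 - ties)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
    if (sigma2 <= 0) {
      p_ge <- p_le <- 1
    } else {
      sd <- sqrt(sigma2)
      p_ge <- pnorm((u - mu - 0.5) / sd, lower.tail = FALSE)
      p_le <- pnorm((u - mu + 0.5) / sd)
    }
    method <- "normal approximation with tie correction"
  }
  p <- switch(alternative,
              greater = p_ge, less = p_le,
              two_sided = min(1, 2 * min(p_ge, p_le)))
  .new_rank_test("U", u, n1, n2, p, alternative, method)
}

#' Vargha-Delaney A effect size
#'
#' The probability that a random draw from `x` exceeds a random draw from
#' `y`, ties counting one half: `A = U / (n1 * n2)`. `A = 0.5` is stochastic
#' equality; `A(x, y) + A(y, x) = 1`.
#'
#' @param x,y Numeric vectors, both non-empty.
#' @return A scalar in `[0, 1]`.
#' @export
vargha_delaney_a <- function(x, y) {
  if (!length(x) || !length(y)) stop("x and y must be non-empty")
  .u_statistic(x, y) / (length(x) * length(y))
}

#' Wilcoxon signed-rank test
#'
#' Zero differences are dropped (Wilcoxon's original treatment); absolute
#' differences get average ranks under ties; `W` is the rank sum over
#' positive differences. For `m <= exact_limit` non-zero differences the
#' p-value is exact over all `2^m` sign assignments (computed by dynamic
#' programming over the rank-sum distribution); otherwise a normal
#' approximation with the exact permutation variance `sum(r^2) / 4` and
#' continuity correction is used.
#'
#' @param d Numeric vector of paired differences with at least one non-zero
#'   entry.
#' @param alternative `"greater"` (positive shift), `"less"` or
#'   `"two_sided"`.
#' @inheritParams mann_whitney_u
#' @return A `rank_test` with statistic `"W"`; `n1` is the number of
#'   non-zero differences, `n2` the number of dropped zeros.
#' @export
wilcoxon_signed_rank <- function(d, alternative = c("greater", "less", "two_sided"),
                                 exact = NULL, exact_limit = 20L) {
  alternative <- match.arg(alternative)
  d <- as.numeric(d)
  if (!length(d)) stop("d must be non-empty")
  if (anyNA(d)) stop("missing values not allowed")
  zeros <- sum(d == 0)
  d <- d[d != 0]
  m <- length(d)
  if (!m) stop("all differences are zero; signed-rank test undefined")
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (is.null(exact)) exact <- m <= exact_limit

  if (exact) {
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    f <- numeric(total + 1L)  # f[s+1] = #sign assignments with doubled W = s
    f[1L] <- 1
    for (ri in r2) {
      g <- numeric(total + 1L)
      g[(ri + 1L):(total + 1L)] <- f[seq_len(total + 1L - ri)]
      f <- f + g
    }
    w2 <- as.integer(round(2 * w))
    p_ge <- sum(f[(w2 + 1L):(total + 1L)]) / 2^m
    p_le <- sum(f[seq_len(w2 + 1L)]) / 2^m
    method <- "exact enumeration"
  } else {
    mu <- sum(r) / 2
    sigma <- sqrt(sum(r^2) / 4)
    p_ge <- pnorm((w - mu - 0.5) / sigma, lower.tail = FALSE)
    p_le <- pnorm((w - mu + 0.5) / sigma)
    method <- "normal approximation with tie correction"
  }
  p <- switch(alternative,
              greater = p_ge, less = p_le,
              two_sided = min(1, 2 * min(p_ge, p_le)))
  .new_rank_test("W", w, m, zeros, p, alternative, method)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted values: with p sorted ascending,
#' `q(i) = min over j >= i of (m / j) * p(j)`, capped at 1, returned in the
#' input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values, component-wise `>= p` and `<= 1`.
#' @export
bh_adjust <- function(p) {
  p <- as.numeric(p)
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1] with no missing values")
  p.adjust(p, method = "BH")
}
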