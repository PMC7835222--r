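## stats_core: self-contained implementations of the statistical procedures
## the downstream analyses report (Fisher's exact 2x2, Wilcoxon rank-sum,
## two-sample t, Benjamini-Hochberg), with stated sidedness and exactness
## conventions. Base R's fisher.test/wilcox.test/t.test/p.adjust are used as
## independent cross-checks in the test suite, never as the implementation.

new_test_result <- function(statistic, p_value, method, n) {
  structure(list(statistic = statistic, p_value = p_value,
                 method = method, n = n),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> statistic = %.6g, p = %.6g (%s, n = %s)\n",
              x$statistic, x$p_value, x$method, paste(x$n, collapse = "+")))
  invisible(x)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by the probability rule: the sum of hypergeometric
#' probabilities, over all tables with the observed margins, of tables whose
#' probability does not exceed the observed table's (with a relative slack
#' of 1e-7 to absorb floating-point noise). Probabilities are computed in
#' log space.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return `test_result` with `statistic` = odds-ratio estimate
#'   (ad/bc, Inf/NaN-safe as computed) and the two-sided p-value.
#' @export
#' @examples
#' fisher_exact_2x2(matrix(c(2, 0, 0, 2), 2))$p_value  # 1/3
fisher_exact_2x2 <- function(table) {
  tb <- as.matrix(table)
  if (!all(dim(tb) == c(2L, 2L))) abort("table must be 2x2")
  if (any(tb < 0) || any(tb != round(tb))) {
    abort("table cells must be non-negative integers")
  }
  a <- tb[1, 1]; b <- tb[1, 2]; cc <- tb[2, 1]; d <- tb[2, 2]
  r1 <- a + b; c1 <- a + cc; n <- a + b + cc + d
  if (n == 0) return(new_test_result(NaN, 1, "exact", 0))
  support <- max(0, r1 + c1 - n):min(r1, c1)
  logp <- lchoose(c1, support) + lchoose(n - c1, r1 - support) -
    lchoose(n, r1)
  logp_obs <- logp[support == a]
  keep <- logp <= logp_obs + log(1 + 1e-7)
  p <- sum(exp(logp[keep]))
  new_test_result(statistic = (a * d) / (b * cc), p_value = min(p, 1),
                  method = "exact", n = n)
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided. When the combined sample size is at most `exact_max` (default
#' 20) and the data are tie-free, the exact null distribution of the
#' Mann-Whitney U statistic is used (p = 2 * min of the two tails, capped at
#' 1); otherwise a normal approximation with midranks, tie-corrected
#' variance and a 0.5 continuity correction.
#'
#' @param x,y numeric samples (non-empty).
#' @param exact_max largest combined sample size for the exact branch.
#' @return `test_result`; `statistic` is U for sample `x`.
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max = 20L) {
  nx <- length(x); ny <- length(y)
  if (nx == 0L || ny == 0L) abort("both samples must be non-empty")
  pooled <- c(x, y)
  r <- rank(pooled)
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- any(duplicated(pooled))
  if (!ties && nx + ny <= exact_max) {
    p <- 2 * min(stats::pwilcox(u, nx, ny),
                 stats::pwilcox(u - 1, nx, ny, lower.tail = FALSE))
    return(new_test_result(u, min(p, 1), "exact", c(nx, ny)))
  }
  mu <- nx * ny / 2
  N <- nx + ny
  tie_tab <- table(pooled)
  sigma2 <- (nx * ny / 12) * ((N + 1) - sum(tie_tab^3 - tie_tab) /
                                (N * (N - 1)))
  if (sigma2 <= 0) return(new_test_result(u, 1, "degenerate", c(nx, ny)))
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
  new_test_result(u, min(2 * stats::pnorm(-abs(z)), 1), "approximate",
                  c(nx, ny))
}

#' Two-sample t test
#'
#' Two-tailed. Student's pooled-variance test by default (the convention
#' when a legend says only "t test"); Welch's unequal-variance form behind
#' `welch = TRUE`. Zero-variance inputs degrade gracefully: equal means give
#' t = 0, p = 1; unequal means give p = 0.
#'
#' @param x,y numeric samples with at least 2 values each.
#' @param welch use the Welch-Satterthwaite form.
#' @return `test_result` with the t statistic and two-tailed p-value.
#' @export
two_sample_t <- function(x, y, welch = FALSE) {
  check_flag(welch, "welch")
  nx <- length(x); ny <- length(y)
  if (nx < 2L || ny < 2L) abort("each sample needs at least 2 values")
  vx <- stats::var(x); vy <- stats::var(y)
  diff <- mean(x) - mean(y)
  if (welch) {
    se2 <- vx / nx + vy / ny
    df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  } else {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    se2 <- sp2 * (1 / nx + 1 / ny)
    df <- nx + ny - 2
  }
  if (se2 <= 0 || !is.finite(df)) {
    if (diff == 0) return(new_test_result(0, 1, "degenerate", c(nx, ny)))
    return(new_test_result(sign(diff) * Inf, 0, "degenerate", c(nx, ny)))
  }
  t_stat <- diff / sqrt(se2)
  p <- 2 * stats::pt(-abs(t_stat), df)
  new_test_result(t_stat, min(p, 1),
                  if (welch) "welch" else "student", c(nx, ny))
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up q-values: q_(i) = min over j >= i of m * p_(j) / j, clipped at 1,
#' returned in the input order.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return q-values in the original order.
#' @export
benjamini_hochberg <- function(p_values) {
  if (any(!is.finite(p_values) | p_values < 0 | p_values > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  m <- length(p_values)
  if (m == 0L) return(numeric(0))
  o <- order(p_values)
  q_sorted <- rev(cummin(rev(p_values[o] * m / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}
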