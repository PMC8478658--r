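# Shared statistical primitives: exact and Monte Carlo Fisher tests,
# two-sample KS distance, multiplicity corrections, Welch t and rank tests.
# All return a common "aml_test" result record.

test_result <- function(statistic, p_value, method, n_resamples = 0L,
                        adjusted_p = NULL, extra = list()) {
  stopifnot(p_value >= -1e-12, p_value <= 1 + 1e-12)
  out <- c(list(statistic = unname(statistic),
                p_value = min(max(p_value, 0), 1),
                method = method,
                n_resamples = as.integer(n_resamples),
                adjusted_p = adjusted_p), extra)
  class(out) <- "aml_test"
  out
}

#' @export
print.aml_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.6g, p = %.4g", x$method, x$statistic,
              x$p_value))
  if (x$n_resamples > 0) cat(sprintf(" (B = %d)", x$n_resamples))
  cat("\n")
  invisible(x)
}

check_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop2("expected a 2x2 table")
  if (any(table < 0) || any(table != round(table)))
    stop2("counts must be nonnegative integers")
  if (sum(table) == 0) stop2("all-zero table")
  table
}

#' Exact two-sided Fisher test for a 2x2 table
#'
#' Enumerates all tables with the observed margins and sums the
#' hypergeometric probabilities of tables no more probable than the observed
#' one (probability-mass rule, with a relative tolerance of 1e-7 on the
#' comparison, the convention also used by standard implementations).
#'
#' @param table 2x2 matrix of nonnegative integer counts; rows are groups,
#'   columns trait present/absent.
#' @return An `aml_test` record with the odds-ratio-free probability-mass
#'   statistic (the observed table probability) and the exact two-sided p.
#' @examples
#' exact_fisher_2x2(matrix(c(6, 4, 1, 10), 2, byrow = TRUE))
#' @export
exact_fisher_2x2 <- function(table) {
  tab <- check_2x2(table)
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  lo <- max(0L, k - n); hi <- min(k, m)
  support <- lo:hi
  logp <- stats::dhyper(support, m, n, k, log = TRUE)
  obs <- stats::dhyper(tab[1, 1], m, n, k, log = TRUE)
  p <- sum(exp(logp[logp <= obs + log(1 + 1e-7)]))
  test_result(exp(obs), p, "fisher_exact_2x2")
}

# log probability of an r x c table under fixed-margin (multivariate
# hypergeometric) sampling.
log_table_prob <- function(tab) {
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  sum(lfactorial(rs)) + sum(lfactorial(cs)) - lfactorial(n) -
    sum(lfactorial(tab))
}

#' Monte Carlo Fisher exact test for an r x c table
#'
#' Resamples `B` tables with the observed margins held fixed (Patefield's
#' algorithm via [r2dtable()]; a hypergeometric shortcut for 2x2 tables) and
#' estimates the two-sided p as `(1 + #{prob(resample) <= prob(observed)}) /
#' (B + 1)`, the add-one estimator that never returns exactly zero.
#'
#' @param table r x c matrix of nonnegative integer counts.
#' @param B number of resamples (default 1e6, the conventional desk-scale
#'   choice for contingency-table association screens).
#' @param seed integer seed controlling the resampling stream.
#' @return An `aml_test` record; `statistic` is the observed table's
#'   fixed-margin log probability.
#' @export
monte_carlo_fisher <- function(table, B = 1e6, seed = 1L) {
  tab <- as.matrix(table)
  if (any(tab < 0) || any(tab != round(tab)))
    stop2("counts must be nonnegative integers")
  if (B < 1) stop2("B must be >= 1")
  rs <- rowSums(tab); cs <- colSums(tab)
  if (sum(rs > 0) < 2 || sum(cs > 0) < 2)
    stop2("degenerate margins: need at least two nonzero rows and columns")
  tab <- tab[rs > 0, cs > 0, drop = FALSE]
  rs <- rowSums(tab); cs <- colSums(tab)
  obs <- log_table_prob(tab)
  cutoff <- obs + log(1 + 1e-7)
  B <- as.integer(B)
  hits <- with_seed(derive_seed(seed, "mcfisher"), {
    if (all(dim(tab) == c(2L, 2L))) {
      # 2x2 with fixed margins is determined by one cell ~ hypergeometric
      a <- stats::rhyper(B, rs[1], rs[2], cs[1])
      lp <- stats::dhyper(a, rs[1], rs[2], cs[1], log = TRUE)
      sum(lp <= stats::dhyper(tab[1, 1], rs[1], rs[2], cs[1], log = TRUE) +
            log(1 + 1e-7))
    } else {
      const <- sum(lfactorial(rs)) + sum(lfactorial(cs)) -
        lfactorial(sum(tab))
      total <- 0L
      done <- 0L
      while (done < B) {
        nb <- min(50000L, B - done)
        sims <- stats::r2dtable(nb, rs, cs)
        lp <- vapply(sims, function(s) const - sum(lfactorial(s)),
                     numeric(1))
        total <- total + sum(lp <= cutoff)
        done <- done + nb
      }
      total
    }
  })
  test_result(obs, (1 + hits) / (B + 1), "monte_carlo_fisher",
              n_resamples = B, extra = list(seed = seed))
}

#' Two-sample Kolmogorov-Smirnov distance
#'
#' D_KS is the largest absolute difference between the two empirical
#' cumulative distribution functions; the p-value uses the asymptotic
#' two-sample Kolmogorov distribution.
#'
#' @param x,y numeric samples (nonempty).
#' @return An `aml_test` record with `statistic` = D_KS.
#' @export
ks_distance <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) == 0 || length(y) == 0) stop2("empty sample")
  n_x <- length(x); n_y <- length(y)
  pooled <- sort(unique(c(x, y)))
  ecdf_x <- stats::ecdf(x)(pooled)
  ecdf_y <- stats::ecdf(y)(pooled)
  d <- max(abs(ecdf_x - ecdf_y))
  n_eff <- n_x * n_y / (n_x + n_y)
  lambda <- (sqrt(n_eff) + 0.12 + 0.11 / sqrt(n_eff)) * d
  j <- 1:100
  p <- 2 * sum((-1)^(j - 1) * exp(-2 * lambda^2 * j^2))
  test_result(d, min(max(p, 0), 1), "ks_two_sample")
}

#' Multiple-testing correction
#'
#' Bonferroni (`min(1, m p)`), Benjamini-Hochberg step-up with monotone
#' enforcement, or Holm's step-down Sidak: sorted `p_(i)` mapped to
#' `1 - (1 - p_(i))^(m - i + 1)` and monotonized by a cumulative maximum.
#' Input order is restored in the output.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @param method one of `"bonferroni"`, `"bh"`, `"holm_sidak"`.
#' @return numeric vector of adjusted p-values, same length and order as `p`.
#' @export
adjust_pvalues <- function(p, method = c("bh", "bonferroni", "holm_sidak")) {
  method <- match.arg(method)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop2("p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0) return(numeric(0))
  ord <- order(p)
  ps <- p[ord]
  adj <- switch(method,
    bonferroni = pmin(1, ps * m),
    bh = {
      q <- ps * m / seq_len(m)
      rev(cummin(rev(pmin(1, q))))
    },
    holm_sidak = {
      a <- 1 - (1 - ps)^(m - seq_len(m) + 1)
      pmin(1, cummax(a))
    })
  out <- numeric(m)
  out[ord] <- adj
  out
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom and a
#' two-sided p-value.
#'
#' @param x,y numeric samples with n >= 2 each; at least one must have
#'   nonzero variance.
#' @return An `aml_test` record with fields `statistic` (t) and `df`.
#' @export
welch_t_test <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2 || length(y) < 2) stop2("each sample needs n >= 2")
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0) stop2("both samples have zero variance")
  se2 <- vx / length(x) + vy / length(y)
  t_stat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / (vx^2 / (length(x)^2 * (length(x) - 1)) +
                   vy^2 / (length(y)^2 * (length(y) - 1)))
  p <- 2 * stats::pt(-abs(t_stat), df)
  test_result(t_stat, p, "welch_t", extra = list(df = df))
}

#' Rank-based group comparisons
#'
#' Mann-Whitney U (exactly two groups) or Kruskal-Wallis H (two or more),
#' both with midrank tie handling and the standard tie-corrected variance,
#' and asymptotic p-values (normal for U, chi-square for H).
#'
#' @param samples list of numeric vectors, one per group.
#' @param mode `"mann_whitney"` or `"kruskal_wallis"`.
#' @return An `aml_test` record (`statistic` is U or H).
#' @export
rank_tests <- function(samples, mode = c("mann_whitney", "kruskal_wallis")) {
  mode <- match.arg(mode)
  if (!is.list(samples) || any(!vapply(samples, is.numeric, logical(1))))
    stop2("samples must be a list of numeric vectors")
  sizes <- lengths(samples)
  if (any(sizes == 0)) stop2("empty group")
  if (mode == "mann_whitney" && length(samples) != 2L)
    stop2("mann_whitney needs exactly 2 groups")
  if (mode == "kruskal_wallis" && length(samples) < 2L)
    stop2("kruskal_wallis needs >= 2 groups")
  pooled <- unlist(samples, use.names = FALSE)
  n <- length(pooled)
  r <- rank(pooled)  # midranks
  grp <- rep(seq_along(samples), sizes)
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties)
  if (mode == "mann_whitney") {
    n1 <- sizes[1]; n2 <- sizes[2]
    r1 <- sum(r[grp == 1])
    u <- r1 - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
    if (sigma2 <= 0) return(test_result(u, 1, "mann_whitney_u"))
    z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    test_result(u, min(p, 1), "mann_whitney_u", extra = list(z = z))
  } else {
    rbar <- tapply(r, grp, mean)
    h <- 12 / (n * (n + 1)) * sum(sizes * (rbar - (n + 1) / 2)^2)
    correction <- 1 - tie_term / (n^3 - n)
    if (correction > 0) h <- h / correction
    df <- length(samples) - 1
    p <- stats::pchisq(h, df, lower.tail = FALSE)
    test_result(h, p, "kruskal_wallis_h", extra = list(df = df))
  }
}
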