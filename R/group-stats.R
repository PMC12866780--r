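# Nonparametric group inference: Scheirer-Ray-Hare two-factor rank test,
# Kruskal-Wallis wrapper, and Dunn's post-hoc test with Bonferroni
# correction. Midranks are used for ties throughout.

.tie_sum <- function(r) {
  t <- table(r)
  sum(t^3 - t)
}

#' Scheirer-Ray-Hare two-factor rank test
#'
#' Nonparametric analogue of two-way ANOVA: all values are ranked together
#' (midranks for ties), sums of squares for the two main effects and the
#' interaction are computed from the rank two-way layout (Type II model
#' comparisons, so unbalanced designs are handled), and each effect's
#' statistic `H = SS_effect / MS_total` is referred to a chi-square
#' distribution with the effect's degrees of freedom. `MS_total =
#' SS_total / (N - 1)` computed from the midranks is the tie-corrected
#' denominator (default); the uncorrected variant uses `N (N + 1) / 12`.
#'
#' @param values Numeric responses.
#' @param a,b Factor levels (coerced to factor) for the two factors.
#' @param tie_correction Use the tie-corrected denominator (default
#'   `TRUE`).
#' @return An object of class `srh_test`: data frame with one row per
#'   effect (`A`, `B`, `A:B`) giving `SS`, `df`, `H`, `p`.
#' @export
scheirer_ray_hare <- function(values, a, b, tie_correction = TRUE) {
  a <- factor(a); b <- factor(b)
  stopifnot(length(values) == length(a), length(values) == length(b))
  if (nlevels(a) < 2) {
    stop_mechisto("factor A needs >= 2 levels", "mechisto_format_error")
  }
  if (any(table(a, b) == 0)) {
    stop_mechisto("empty factor-combination cell", "mechisto_format_error")
  }
  N <- length(values)
  r <- rank(values)
  ss_total <- sum((r - mean(r))^2)
  rss <- function(fml) sum(resid(lm(fml, data = data.frame(r = r, a = a, b = b)))^2)
  if (nlevels(b) < 2) {
    # degenerate second factor: the design collapses to one-way and the
    # factor-A statistic reduces to (tie-corrected) Kruskal-Wallis H
    ss <- c(A = sum((r - mean(r))^2) - rss(r ~ a), B = 0, `A:B` = 0)
  } else {
    rss_ab <- rss(r ~ a + b)
    ss <- c(A = rss(r ~ b) - rss_ab,
            B = rss(r ~ a) - rss_ab,
            `A:B` = rss_ab - rss(r ~ a * b))
  }
  df <- c(nlevels(a) - 1, max(nlevels(b) - 1, 0),
          (nlevels(a) - 1) * (nlevels(b) - 1))
  ms_total <- if (tie_correction) {
    ss_total / (N - 1)
  } else {
    N * (N + 1) / 12
  }
  H <- if (ms_total > 0) ss / ms_total else ss * 0
  out <- data.frame(effect = names(ss), SS = unname(ss), df = df,
                    H = unname(H),
                    p = pchisq(unname(H), df, lower.tail = FALSE))
  out$p[out$df == 0] <- NA_real_
  structure(out, class = c("srh_test", "data.frame"),
            tie_correction = tie_correction, n = N)
}

#' Kruskal-Wallis rank-sum test (tie-corrected)
#'
#' Thin wrapper over [stats::kruskal.test()] returning the same result
#' structure as the other tests in this package.
#'
#' @param groups List of numeric vectors, one per group (each non-empty).
#' @return List with `H` (tie-corrected statistic), `df`, `p`, `n`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2) {
    stop_mechisto("need >= 2 groups", "mechisto_format_error")
  }
  if (any(!lengths(groups))) {
    stop_mechisto("empty group", "mechisto_format_error")
  }
  kt <- stats::kruskal.test(groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value, n = sum(lengths(groups)))
}

#' Dunn's post-hoc test with Bonferroni correction
#'
#' Pairwise z statistics from the joint rank sums with tie correction:
#' `z = (rbar_i - rbar_j) / sqrt((N(N+1)/12 - T/(12(N-1))) (1/n_i +
#' 1/n_j))` where `T = sum(t^3 - t)` over tie groups. Two-sided normal p
#' values; `p_adj = min(1, p * m)` for `m = k(k-1)/2` comparisons.
#'
#' @param groups Named list of numeric vectors (each non-empty).
#' @return Data frame with `group1`, `group2`, `z`, `p`, `p_adj`.
#' @export
dunn_bonferroni <- function(groups) {
  if (length(groups) < 2) {
    stop_mechisto("need >= 2 groups", "mechisto_format_error")
  }
  if (any(!lengths(groups))) {
    stop_mechisto("empty group", "mechisto_format_error")
  }
  k <- length(groups)
  nm <- names(groups) %||% as.character(seq_len(k))
  if (is.null(names(groups))) names(groups) <- nm
  x <- unlist(groups, use.names = FALSE)
  g <- rep(nm, lengths(groups))
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, factor(g, levels = nm), mean)
  n_i <- lengths(groups)
  var_term <- N * (N + 1) / 12 - .tie_sum(r) / (12 * (N - 1))
  pairs <- utils::combn(seq_len(k), 2)
  m <- ncol(pairs)
  out <- data.frame(group1 = nm[pairs[1, ]], group2 = nm[pairs[2, ]],
                    z = NA_real_, p = NA_real_, p_adj = NA_real_)
  for (j in seq_len(m)) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    se <- sqrt(var_term * (1 / n_i[i1] + 1 / n_i[i2]))
    z <- if (se > 0) (rbar[i1] - rbar[i2]) / se else 0
    out$z[j] <- unname(z)
    out$p[j] <- 2 * pnorm(-abs(unname(z)))
    out$p_adj[j] <- min(1, out$p[j] * m)
  }
  out
}
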