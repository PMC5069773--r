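#' Dunn's post hoc pairwise rank test
#'
#' Pairwise z-tests on mean ranks following a Kruskal-Wallis omnibus test,
#' with tie correction (Dunn 1964). The standard error of the difference in
#' mean ranks between groups i and j is
#' `sqrt((N(N+1)/12 - sum(t^3 - t)/(12(N-1))) * (1/n_i + 1/n_j))` where `t`
#' runs over tie-group sizes.
#'
#' @param x Numeric vector of values.
#' @param g Group labels, coerced to factor.
#' @param p_adjust Multiplicity adjustment method passed to
#'   [stats::p.adjust()] (default `"BH"`).
#' @return Tibble with one row per pair: `group1`, `group2`, `z`, `p.value`,
#'   `p.adjusted`.
#' @export
dunn_test <- function(x, g, p_adjust = "BH") {
  g <- as.factor(g)
  if (nlevels(g) < 2) abort("need at least 2 groups")
  N <- length(x)
  r <- rank(x)
  tie_sizes <- table(x)
  tie_term <- sum(tie_sizes^3 - tie_sizes) / (12 * (N - 1))
  v <- N * (N + 1) / 12 - tie_term
  mean_ranks <- tapply(r, g, mean)
  ns <- tapply(r, g, length)
  pairs <- utils::combn(levels(g), 2)
  z <- p <- numeric(ncol(pairs))
  for (i in seq_len(ncol(pairs))) {
    g1 <- pairs[1, i]; g2 <- pairs[2, i]
    se <- sqrt(v * (1 / ns[[g1]] + 1 / ns[[g2]]))
    z[i] <- if (se > 0) (mean_ranks[[g1]] - mean_ranks[[g2]]) / se else 0
    p[i] <- min(1, 2 * pnorm(-abs(z[i])))
  }
  tibble::tibble(
    group1 = pairs[1, ], group2 = pairs[2, ],
    z = z, p.value = p,
    p.adjusted = p.adjust(p, method = p_adjust)
  )
}

#' Welch's two-sample t test, tidied
#'
#' @param data Data frame of measurements.
#' @param value Column of values.
#' @param group Column of group labels (exactly two levels).
#' @return One-row tibble: group means, difference estimate, 95% CI,
#'   `statistic`, `df`, `p.value`.
#' @export
welch_test <- function(data, value, group) {
  x <- dplyr::pull(data, {{ value }})
  g <- as.factor(dplyr::pull(data, {{ group }}))
  if (nlevels(g) != 2) abort("`group` must have exactly 2 levels")
  ht <- t.test(x[g == levels(g)[1]], x[g == levels(g)[2]])
  tibble::tibble(
    group1 = levels(g)[1], group2 = levels(g)[2],
    mean1 = unname(ht$estimate[1]), mean2 = unname(ht$estimate[2]),
    estimate = unname(ht$estimate[1] - ht$estimate[2]),
    conf.low = ht$conf.int[1], conf.high = ht$conf.int[2],
    statistic = unname(ht$statistic), df = unname(ht$parameter),
    p.value = ht$p.value
  )
}

# Row-wise two-sided Mann-Whitney U test (normal approximation with tie and
# continuity corrections; matches wilcox.test(exact = FALSE, correct = TRUE)).
# Rows with zero rank variance (all values tied) get p = 1. Used for per-clade
# and per-KO tests where thousands of rows make wilcox.test calls wasteful.
row_mann_whitney <- function(m, idx_a, idx_b) {
  n1 <- length(idx_a); n2 <- length(idx_b); N <- n1 + n2
  unname(apply(m, 1, function(v) {
    vv <- v[c(idx_a, idx_b)]
    r <- rank(vv)
    U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    ties <- table(vv)
    s2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (s2 <= 0) return(1)
    z <- U - n1 * n2 / 2
    z <- z - sign(z) * 0.5
    min(1, 2 * pnorm(-abs(z) / sqrt(s2)))
  }))
}
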