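#' Wilcoxon rank-sum (Mann-Whitney) test with effect size
#'
#' A/B comparison of two samples (e.g. interface size distributions, which
#' are right-skewed and left-bounded by the minimum-area cutoff, hence the
#' nonparametric choice). Exact enumeration when the pooled size is at most
#' 12 and there are no ties, otherwise the tie-corrected normal
#' approximation with continuity correction. The effect size is
#' r = |Z| / sqrt(n), with Z recovered from the p value.
#'
#' @param a,b Numeric samples.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @param effect_n Sample size used in the effect-size denominator
#'   (default `length(a) + length(b)`; exposed because conventions differ).
#' @return One-row tibble: `statistic` (U), `p_value`, `effect_size`,
#'   `n_a`, `n_b`, `tails`, `method`.
#' @export
wilcoxon_rank_sum <- function(a, b, alternative = "two.sided",
                              effect_n = length(a) + length(b)) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  n <- length(a) + length(b)
  if (length(unique(c(a, b))) == 1) {
    p <- 1
    stat <- length(a) * length(b) / 2
    method <- "degenerate"
  } else {
    exact <- n <= 12 && !any(duplicated(c(a, b)))
    ht <- suppressWarnings(
      wilcox.test(a, b, alternative = alternative, exact = exact,
                  correct = TRUE)
    )
    p <- ht$p.value
    stat <- unname(ht$statistic)
    method <- if (exact) "exact" else "normal_approx"
  }
  tails <- if (alternative == "two.sided") "two" else "one"
  tibble(
    statistic = stat, p_value = p,
    effect_size = effect_size_r(p, n = effect_n, tails = tails),
    n_a = length(a), n_b = length(b), tails = tails,
    method = paste0("wilcoxon_rank_sum_", method)
  )
}

#' Wilcoxon signed-rank test with effect size
#'
#' One-sample/paired test on differences (default one-tailed for a positive
#' location, the direction of "first interface larger"). Zero differences
#' are dropped before ranking. Exact when at most 20 nonzero differences
#' and no tied magnitudes, else the tie-corrected normal approximation with
#' continuity correction.
#'
#' @param d Paired differences.
#' @param alternative `"greater"` (default), `"less"` or `"two.sided"`.
#' @param effect_n Effect-size denominator sample size (default: nonzero n).
#' @return One-row tibble as in [wilcoxon_rank_sum()] with `n` the number of
#'   nonzero differences.
#' @export
wilcoxon_signed_rank <- function(d, alternative = "greater",
                                 effect_n = NULL) {
  d <- d[d != 0]
  if (length(d) == 0) stop("all differences are zero: test undefined")
  n <- length(d)
  effect_n <- effect_n %||% n
  exact <- n <= 20 && !any(duplicated(abs(d)))
  ht <- suppressWarnings(
    wilcox.test(d, alternative = alternative, exact = exact, correct = TRUE)
  )
  tails <- if (alternative == "two.sided") "two" else "one"
  tibble(
    statistic = unname(ht$statistic), p_value = ht$p.value,
    effect_size = effect_size_r(ht$p.value, n = effect_n, tails = tails),
    n = n, tails = tails,
    method = paste0("wilcoxon_signed_rank_",
                    if (exact) "exact" else "normal_approx")
  )
}

#' Effect size r from a p value
#'
#' r = |Z| / sqrt(n), where Z is the standard-normal score corresponding to
#' the p value for the stated number of tails.
#'
#' @param p_value p value in (0, 1\].
#' @param n Sample size (>= 1).
#' @param tails `"two"` (default) or `"one"`.
#' @return Nonnegative effect size(s).
#' @export
effect_size_r <- function(p_value, n, tails = c("two", "one")) {
  tails <- match.arg(tails)
  if (any(p_value <= 0)) {
    stop("p value underflow: p = 0 has no finite Z score")
  }
  stopifnot(all(p_value <= 1), all(n >= 1))
  z <- qnorm(if (tails == "two") p_value / 2 else p_value,
             lower.tail = FALSE)
  abs(pmax(z, 0)) / sqrt(n)
}

#' Dunn's test of multiple comparisons with Holm-Bonferroni correction
#'
#' Pairwise post-hoc comparisons between k groups on pooled ranks, with the
#' standard tie correction, two-sided z p values and Holm step-down
#' adjustment of the family-wise error rate. Effect size is |z| / sqrt of
#' the pair's pooled size.
#'
#' @param data A data frame.
#' @param value Column of values (bare name).
#' @param group Column of group labels (bare name).
#' @return Tibble, one row per group pair: `group_a`, `group_b`, `z`,
#'   `p_value`, `p_adj`, `effect_size`, `n_a`, `n_b`.
#' @export
dunn_holm <- function(data, value, group) {
  v <- dplyr::pull(data, {{ value }})
  g <- as.character(dplyr::pull(data, {{ group }}))
  groups <- sort(unique(g))
  if (length(groups) < 3) stop("Dunn's test needs at least 3 groups")
  if (any(table(g) == 0)) stop("empty group")
  N <- length(v)
  r <- rank(v)
  mean_rank <- tapply(r, g, mean)
  n_g <- tapply(r, g, length)
  ties <- table(v)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  var_base <- N * (N + 1) / 12 - tie_term
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  out <- purrr::map_dfr(pairs, function(pr) {
    i <- pr[1]; j <- pr[2]
    se <- sqrt(max(var_base, 0) * (1 / n_g[[i]] + 1 / n_g[[j]]))
    z <- if (se == 0) 0 else (mean_rank[[i]] - mean_rank[[j]]) / se
    tibble(group_a = i, group_b = j, z = z,
           p_value = 2 * pnorm(-abs(z)),
           n_a = n_g[[i]], n_b = n_g[[j]])
  })
  out$p_adj <- p.adjust(out$p_value, method = "holm")
  out$effect_size <- abs(out$z) / sqrt(out$n_a + out$n_b)
  dplyr::select(out, "group_a", "group_b", "z", "p_value", "p_adj",
                "effect_size", "n_a", "n_b")
}

#' Fisher's exact test with sample odds ratio and relative risk
#'
#' For a 2x2 table of counts (rows: groups, columns: outcome/no outcome),
#' reports the sample odds ratio ad/bc, Fisher's exact p value (two-sided
#' by default: the sum over tables with probability at most the observed),
#' and the relative risk. A zero cell yields an infinite or zero odds
#' ratio, flagged in `degenerate`.
#'
#' @param x 2x2 matrix, or a length-4 count vector `c(a, b, c, d)` read
#'   row-wise.
#' @param alternative Passed to [fisher.test()] (default `"two.sided"`).
#' @return One-row tibble: `odds_ratio`, `p_value`, `relative_risk`,
#'   `prop_a`, `prop_b`, `degenerate`.
#' @export
fisher_exact_or <- function(x, alternative = "two.sided") {
  m <- if (is.matrix(x)) x else matrix(as.numeric(x), 2, 2, byrow = TRUE)
  stopifnot(all(m >= 0), all(m == round(m)))
  a <- m[1, 1]; b <- m[1, 2]; cc <- m[2, 1]; d <- m[2, 2]
  or <- (a * d) / (b * cc)
  p <- fisher.test(m, alternative = alternative)$p.value
  tibble(
    odds_ratio = or, p_value = p,
    relative_risk = (a / (a + b)) / (cc / (cc + d)),
    prop_a = a / (a + b), prop_b = cc / (cc + d),
    degenerate = any(m == 0)
  )
}

#' Jeffreys binomial confidence interval
#'
#' Equal-tailed interval from the Jeffreys posterior
#' Beta(x + 1/2, n - x + 1/2), at 68% coverage by default (one-sigma error
#' bars for proportions). Boundary rule: the lower limit is 0 when x = 0
#' and the upper limit is 1 when x = n.
#'
#' @param x Successes (vectorised).
#' @param n Trials.
#' @param level Coverage in (0, 1), default 0.68.
#' @return Tibble: `x`, `n`, `estimate`, `lower`, `upper`, `level`.
#' @export
jeffreys_ci <- function(x, n, level = 0.68) {
  stopifnot(all(x >= 0), all(x <= n), all(n >= 1), level > 0, level < 1)
  alpha <- (1 - level) / 2
  lower <- ifelse(x == 0, 0, qbeta(alpha, x + 0.5, n - x + 0.5))
  upper <- ifelse(x == n, 1, qbeta(1 - alpha, x + 0.5, n - x + 0.5))
  tibble(x = x, n = n, estimate = x / n, lower = lower, upper = upper,
         level = level)
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties and the t-distribution
#' approximation for the p value.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return One-row tibble: `rho`, `p_value`, `n`.
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    stop("constant input: correlation undefined")
  }
  ht <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  tibble(rho = unname(ht$estimate), p_value = ht$p.value, n = length(x))
}
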