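#' Stratified bootstrap of a mean difference
#'
#' Bootstraps the mean of per-subunit differences (e.g. first-minus-last
#' interface area) within strata such as protein age class or operon
#' membership: each resample draws, within every stratum independently,
#' with replacement at the stratum's own size, and the point estimate is
#' the stratum mean. The one-sided probability that the difference is not
#' positive uses the finite-sampling correction
#' p = (1 + #\{estimates <= 0\}) / (B + 1), so p is never reported as 0 and
#' is bounded below by 1/(B+1).
#'
#' @param data A data frame.
#' @param value Column of differences (bare name).
#' @param strata Optional column of stratum labels (bare name); omitted,
#'   all rows form one stratum.
#' @param B Number of resamples (default 10^4).
#' @param seed Integer seed; required so results are exactly reproducible.
#' @return Object of class `strat_boot`: list with `estimates` (tibble
#'   `stratum`, `replicate`, `estimate`), `summary` (per-stratum tibble
#'   with observed mean and corrected p), `B`, `seed`. Methods: [tidy()],
#'   [glance()], [autoplot()].
#' @export
stratified_bootstrap <- function(data, value, strata = NULL, B = 10000,
                                 seed = 20220728) {
  if (B < 1) stop("B must be at least 1")
  v <- dplyr::pull(data, {{ value }})
  s <- tryCatch(as.character(dplyr::pull(data, {{ strata }})),
                error = function(e) NULL)
  if (is.null(s)) s <- rep("all", length(v))
  if (any(tapply(v, s, length) == 0)) stop("empty stratum")
  strata_levels <- sort(unique(s))
  est <- withr::with_seed(as.integer(seed), {
    purrr::map(strata_levels, function(st) {
      x <- v[s == st]
      n <- length(x)
      draws <- matrix(sample(x, n * B, replace = TRUE), nrow = B)
      rowMeans(draws)
    })
  })
  estimates <- purrr::map2_dfr(strata_levels, est, function(st, e) {
    tibble(stratum = st, replicate = seq_len(B), estimate = e)
  })
  summary <- purrr::map2_dfr(strata_levels, est, function(st, e) {
    tibble(
      stratum = st, n = sum(s == st), B = B,
      observed_mean = mean(v[s == st]),
      boot_mean = mean(e),
      p_value = (1 + sum(e <= 0)) / (B + 1)
    )
  })
  structure(list(estimates = estimates, summary = summary, B = B,
                 seed = seed),
            class = "strat_boot")
}

#' @export
print.strat_boot <- function(x, ...) {
  cat("Stratified bootstrap,", x$B, "resamples (seed", x$seed, ")\n")
  print(x$summary)
  invisible(x)
}

#' @describeIn stratified_bootstrap Per-stratum summary tibble.
#' @param x A `strat_boot` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.strat_boot <- function(x, ...) as_tibble(x$summary)

#' @describeIn stratified_bootstrap One-row summary (`B`, `n_strata`, `n`).
#' @exportS3Method generics::glance
glance.strat_boot <- function(x, ...) {
  tibble(B = x$B, n_strata = nrow(x$summary), n = sum(x$summary$n))
}

#' @describeIn stratified_bootstrap Boxplots of the bootstrap distribution
#'   of the mean difference per stratum, with the zero line.
#' @param object A `strat_boot` object.
#' @exportS3Method ggplot2::autoplot
autoplot.strat_boot <- function(object, ...) {
  ggplot2::ggplot(object$estimates,
                  ggplot2::aes(x = .data$stratum, y = .data$estimate)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_boxplot(outlier.size = 0.4, fill = "steelblue",
                          alpha = 0.6) +
    ggplot2::labs(
      x = NULL,
      y = expression("Bootstrap mean difference (" * ring(A)^2 * ")"),
      title = "Stratified bootstrap of first - last interface area"
    ) +
    ggplot2::theme_minimal()
}
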