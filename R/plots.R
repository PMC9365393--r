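#' Translational build-up of a subunit's interfaces
#'
#' For one chain, plots the cumulative buried area of each of its
#' interfaces as the chain is synthesised N to C, with each interface's
#' midpoint (the residue where half the eventual area is exposed) marked.
#'
#' @param ifaces [pairwise_interfaces()] output with the `residues`
#'   list-column.
#' @param chain Chain id to plot.
#' @return A ggplot object.
#' @export
plot_interface_buildup <- function(ifaces, chain) {
  rows <- ifaces[ifaces$chain_a == chain | ifaces$chain_b == chain, ,
                 drop = FALSE]
  if (nrow(rows) == 0) stop("chain has no interfaces: ", chain)
  if (!"residues" %in% names(rows)) {
    stop("per-residue detail needed: rerun pairwise_interfaces() with ",
         "keep_residues = TRUE")
  }
  build <- purrr::pmap_dfr(
    list(rows$chain_a, rows$chain_b, rows$residues,
         rows$midpoint_a, rows$midpoint_b),
    function(a, b, res, mid_a, mid_b) {
      partner <- if (a == chain) b else a
      r <- res[res$chain == chain, , drop = FALSE]
      r <- r[order(r$seq_pos), ]
      tibble(partner = partner, seq_pos = r$seq_pos,
             cumulative_bsa = cumsum(r$bsa),
             midpoint = if (a == chain) mid_a else mid_b)
    }
  )
  mids <- build |>
    dplyr::group_by(.data$partner) |>
    dplyr::summarise(
      seq_pos = dplyr::first(.data$midpoint),
      cumulative_bsa = .data$cumulative_bsa[
        which.min(abs(.data$seq_pos - dplyr::first(.data$midpoint)))],
      .groups = "drop"
    )
  ggplot2::ggplot(build, ggplot2::aes(x = .data$seq_pos,
                                      y = .data$cumulative_bsa,
                                      colour = .data$partner)) +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::geom_point(data = mids, size = 2.5) +
    ggplot2::labs(
      x = "Residue (translation order, N to C)",
      y = expression("Cumulative buried area (" * ring(A)^2 * ")"),
      colour = "Interface with",
      title = paste0("Interface build-up during translation of chain ",
                     chain)
    ) +
    ggplot2::theme_minimal()
}

#' Proportion plot with Jeffreys error bars
#'
#' Convenience plot of binomial proportions (e.g. cotranslational assembly
#' frequency per protein age group) with 68% Jeffreys intervals.
#'
#' @param ci A [jeffreys_ci()] tibble with an added grouping column
#'   `group`.
#' @return A ggplot object.
#' @export
plot_proportions <- function(ci) {
  stopifnot("group" %in% names(ci))
  ggplot2::ggplot(ci, ggplot2::aes(x = .data$group,
                                   y = 100 * .data$estimate)) +
    ggplot2::geom_col(fill = "steelblue", alpha = 0.7) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = 100 * .data$lower,
                                        ymax = 100 * .data$upper),
                           width = 0.2) +
    ggplot2::labs(x = NULL, y = "Frequency (%)") +
    ggplot2::theme_minimal()
}
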