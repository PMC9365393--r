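#' Per-subunit interface profiles
#'
#' Unrolls a pairwise interface table into one row per interface *side*:
#' each chain's view of each of its interfaces, with its buried area,
#' midpoint, first/last interface residue, sequence length and the relative
#' location of the midpoint.
#'
#' @param ifaces Output of [pairwise_interfaces()].
#' @param chains Per-chain summary from [chain_summary()] (supplies `L` and
#'   `protein_id`); optional, in which case `L` is the largest interface
#'   residue seen and relative metrics are omitted.
#' @return Tibble: `complex_id`, `chain`, `protein_id`, `partner`,
#'   `partner_protein`, `homomeric`, `bsa`, `apolar`, `midpoint`,
#'   `first_res`, `last_res`, `L`, `rel_location`, `half`.
#' @export
subunit_profiles <- function(ifaces, chains = NULL) {
  if (nrow(ifaces) == 0) {
    return(tibble(
      complex_id = character(), chain = character(), protein_id = character(),
      partner = character(), partner_protein = character(),
      homomeric = logical(), bsa = numeric(), apolar = numeric(),
      midpoint = integer(), first_res = integer(), last_res = integer(),
      L = integer(), rel_location = numeric(), half = character()
    ))
  }
  side_view <- function(df, side) {
    other <- if (side == "a") "b" else "a"
    tibble(
      complex_id = df$complex_id,
      chain = df[[paste0("chain_", side)]],
      partner = df[[paste0("chain_", other)]],
      homomeric = df$homomeric,
      bsa = df[[paste0("bsa_", side)]],
      apolar = df[[paste0("apolar_", side)]],
      midpoint = df[[paste0("midpoint_", side)]],
      first_res = df[[paste0("first_res_", side)]],
      last_res = df[[paste0("last_res_", side)]]
    )
  }
  out <- dplyr::bind_rows(side_view(ifaces, "a"), side_view(ifaces, "b"))
  if (!is.null(chains)) {
    key <- chains[, c("chain", "protein_id", "L")]
    out <- out |>
      dplyr::left_join(key, by = "chain") |>
      dplyr::left_join(
        dplyr::rename(key[, c("chain", "protein_id")],
                      partner = "chain", partner_protein = "protein_id"),
        by = "partner"
      ) |>
      dplyr::mutate(
        rel_location = relative_interface_location(.data$midpoint, .data$L),
        half = terminal_half(.data$midpoint, .data$L)
      )
  } else {
    out <- dplyr::mutate(out, protein_id = .data$chain,
                         partner_protein = .data$partner,
                         L = NA_integer_, rel_location = NA_real_,
                         half = NA_character_)
  }
  dplyr::arrange(
    dplyr::select(out, "complex_id", "chain", "protein_id", "partner",
                  "partner_protein", "homomeric", "bsa", "apolar",
                  "midpoint", "first_res", "last_res", "L",
                  "rel_location", "half"),
    .data$chain, .data$partner
  )
}

#' First and last translated interfaces of multi-interface subunits
#'
#' Per subunit, among interfaces burying more than `min_area`, the first
#' interface is the one exposing the most N-terminal interface residue and,
#' treating the termini symmetrically, the last interface is the one
#' exposing the most C-terminal interface residue. Ties on the extreme
#' residue go to the larger-area interface. Subunits with fewer than two
#' retained interfaces are not multi-interface subunits and are dropped;
#' fully nested interface sets (first and last coincide) are kept but
#' flagged `nested` and should be excluded from first/last comparisons.
#'
#' @param profiles Output of [subunit_profiles()].
#' @param min_area Per-side area cutoff in Angstrom^2 (default 400).
#' @return Tibble per multi-interface subunit: `complex_id`, `chain`,
#'   `protein_id`, `L`, `n_ifaces`, `first_partner`, `last_partner`,
#'   `f_first`, `f_last`, `bsa_first`, `bsa_last`, `rel_distance`,
#'   `rel_size_diff`, `first_larger`, `nested`.
#' @export
first_last_interfaces <- function(profiles, min_area = 400) {
  kept <- dplyr::filter(profiles, .data$bsa > min_area)
  empty <- tibble(
    L = integer(), n_ifaces = integer(), first_partner = character(),
    last_partner = character(), f_first = integer(), f_last = integer(),
    bsa_first = numeric(), bsa_last = numeric(), rel_distance = numeric(),
    rel_size_diff = numeric(), first_larger = logical(), nested = logical()
  )
  kept |>
    dplyr::group_by(.data$complex_id, .data$chain, .data$protein_id) |>
    dplyr::group_modify(function(g, key) {
      if (nrow(g) < 2) return(empty)
      first_i <- g[order(g$first_res, -g$bsa), ][1, ]
      last_i <- g[order(-g$last_res, -g$bsa), ][1, ]
      nested <- identical(first_i$partner, last_i$partner)
      L <- first_i$L
      tibble(
        L = L, n_ifaces = nrow(g),
        first_partner = first_i$partner, last_partner = last_i$partner,
        f_first = first_i$first_res, f_last = last_i$first_res,
        bsa_first = first_i$bsa, bsa_last = last_i$bsa,
        rel_distance = if (nested || is.na(L)) NA_real_ else
          relative_translational_distance(first_i$first_res,
                                          last_i$first_res, L),
        rel_size_diff = if (nested) NA_real_ else
          relative_size_difference(first_i$bsa, last_i$bsa),
        first_larger = if (nested) NA else first_i$bsa > last_i$bsa,
        nested = nested
      )
    }) |>
    dplyr::ungroup()
}
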