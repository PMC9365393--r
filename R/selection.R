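#' Select a representative chain per protein
#'
#' When a protein maps to several candidate chains across structures, keep
#' the maximum under the lexicographic ordering (sequence identity, number
#' of unique subunits in the complex, number of atoms in the chain), all
#' descending, with a deterministic final tie-break by ascending complex
#' id. Permuting the candidate rows never changes the result.
#'
#' @param candidates Tibble with columns `protein_id`, `complex_id`,
#'   `chain`, `seq_identity` (fraction in \[0, 1\]), `n_unique_subunits`,
#'   `n_atoms`.
#' @return One row per protein: the selected candidate.
#' @export
select_representative_chain <- function(candidates) {
  if (nrow(candidates) == 0) stop("empty candidate list")
  stopifnot(all(candidates$seq_identity >= 0),
            all(candidates$seq_identity <= 1))
  candidates |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::arrange(dplyr::desc(.data$seq_identity),
                   dplyr::desc(.data$n_unique_subunits),
                   dplyr::desc(.data$n_atoms),
                   .data$complex_id, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
}

#' Structure-selection filter configuration
#'
#' Thresholds of the multi-interface subunit inclusion rules: minimum
#' chain completeness 0.70, large-interface cutoff 800 Angstrom^2 (a chain
#' must bury that much with at least two different subunits), heteromeric
#' complexes with 10 or more subunits excluded, chains of 50 or fewer
#' observed residues excluded.
#'
#' @param min_completeness Observed/L completeness threshold.
#' @param large_iface Per-partner buried-area threshold (Angstrom^2).
#' @param max_subunits Complexes with at least this many subunits fail.
#' @param min_chain_len Minimum chain length in residues (chains shorter
#'   than this fail as `short_chain`).
#' @return Named list of thresholds.
#' @export
filter_config <- function(min_completeness = 0.70, large_iface = 800,
                          max_subunits = 10, min_chain_len = 51) {
  list(min_completeness = min_completeness, large_iface = large_iface,
       max_subunits = max_subunits, min_chain_len = min_chain_len)
}

#' Apply the structure-selection filters to a complex
#'
#' Evaluates, per chain, the inclusion rules for multi-interface analyses:
#' the complex must have fewer than `max_subunits` subunits
#' (`too_many_subunits`), the chain must be at least 70% complete relative
#' to its full-length sequence (`chain_incomplete`), it must bury more
#' than `large_iface` Angstrom^2 with at least two different partner
#' subunits (`too_few_large_interfaces`), and it must be longer than 50
#' observed residues (`short_chain`). A chain passes exactly when no
#' reason applies.
#'
#' @param ifaces [pairwise_interfaces()] output for the complex (computed
#'   with `min_area = 0` so the 800 cutoff is applied here).
#' @param chains [chain_summary()] output (supplies `observed_count`, `L`).
#' @param config Thresholds from [filter_config()].
#' @return Tibble, one row per chain: `chain`, `passed`, `reasons`
#'   (list-column of rule ids, empty iff passed).
#' @export
filter_complex <- function(ifaces, chains, config = filter_config()) {
  n_subunits <- nrow(chains)
  profiles <- subunit_profiles(ifaces, chains = chains)
  purrr::pmap_dfr(
    chains[, c("chain", "observed_count", "L")],
    function(chain, observed_count, L) {
      reasons <- character()
      if (n_subunits >= config$max_subunits) {
        reasons <- c(reasons, "too_many_subunits")
      }
      if (observed_count / L < config$min_completeness) {
        reasons <- c(reasons, "chain_incomplete")
      }
      p <- profiles[profiles$chain == chain, , drop = FALSE]
      n_large <- length(unique(p$partner[p$bsa > config$large_iface]))
      if (n_large < 2) {
        reasons <- c(reasons, "too_few_large_interfaces")
      }
      if (observed_count < config$min_chain_len) {
        reasons <- c(reasons, "short_chain")
      }
      tibble(chain = chain, passed = length(reasons) == 0,
             reasons = list(reasons))
    }
  )
}
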