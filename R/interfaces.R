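#' Pairwise buried interfaces of a complex
#'
#' For every pair of chains, per-residue buried surface area (BSA) is the
#' difference between a residue's solvent-accessible area with its chain in
#' isolation and in the presence of the partner chain only (pure pairwise
#' context, the additivity assumption of interface-size based assembly
#' prediction). Each side of a retained interface carries its total and
#' apolar buried area, its translational midpoint (the residue at which half
#' of the side's buried area is reached during N-to-C synthesis) and its
#' most N- and C-terminal interface residues.
#'
#' @param atoms A `cotasm_structure` with at least two chains.
#' @param probe Probe radius in Angstrom (default 1.4).
#' @param min_area Pair retention cutoff in Angstrom^2: interfaces where
#'   neither side buries more than `min_area` are dropped (default 400,
#'   the cutoff excluding crystallographic contacts; set 0 to keep all).
#' @param n_points Surface points per atom for the SASA lattice.
#' @param keep_residues Keep the per-residue BSA detail as a nested
#'   `residues` list-column (default TRUE).
#' @return Tibble with one row per retained chain pair: `complex_id`,
#'   `chain_a`, `chain_b`, `homomeric`, `bsa_a`, `bsa_b`, `bsa_total`,
#'   `apolar_a`, `apolar_b`, `midpoint_a`, `midpoint_b`, `first_res_a`,
#'   `last_res_a`, `first_res_b`, `last_res_b`, and optionally `residues`
#'   (tibbles of `side`, `chain`, `seq_pos`, `aa`, `bsa`).
#' @export
pairwise_interfaces <- function(atoms, probe = 1.4, min_area = 400,
                                n_points = 960L, keep_residues = TRUE) {
  cid <- complex_id(atoms)
  chains <- unique(atoms$chain)
  if (length(chains) < 2) {
    return(empty_interface_table(keep_residues))
  }
  prot <- atoms |>
    dplyr::distinct(.data$chain, .data$protein_id) |>
    tibble::deframe()
  by_chain <- split(as_tibble(atoms), atoms$chain)
  iso <- purrr::map(by_chain, compute_sasa, probe = probe,
                    n_points = n_points)

  pairs <- utils::combn(sort(chains), 2, simplify = FALSE)
  rows <- purrr::map(pairs, function(pr) {
    a <- pr[1]; b <- pr[2]
    joint <- dplyr::bind_rows(by_chain[[a]], by_chain[[b]])
    ctx <- compute_sasa(joint, probe = probe, n_points = n_points)
    per_res <- purrr::map2_dfr(c(a, b), c("a", "b"), function(ch, side) {
      i <- iso[[ch]]
      x <- dplyr::left_join(i, ctx[ctx$chain == ch, c("chain", "seq_pos", "asa")],
                            by = c("chain", "seq_pos"),
                            suffix = c("_iso", "_ctx"))
      tibble(side = side, chain = ch, seq_pos = x$seq_pos, aa = x$aa,
             bsa = x$asa_iso - x$asa_ctx)
    })
    side_stats <- function(side) {
      r <- per_res[per_res$side == side & per_res$bsa > 0, , drop = FALSE]
      if (nrow(r) == 0) {
        return(list(bsa = 0, apolar = 0, midpoint = NA_integer_,
                    first_res = NA_integer_, last_res = NA_integer_))
      }
      list(
        bsa = sum(r$bsa),
        apolar = apolar_area(r),
        midpoint = interface_midpoint(r$seq_pos, r$bsa),
        first_res = min(r$seq_pos),
        last_res = max(r$seq_pos)
      )
    }
    sa <- side_stats("a"); sb <- side_stats("b")
    out <- tibble(
      complex_id = cid, chain_a = a, chain_b = b,
      homomeric = identical(prot[[a]], prot[[b]]),
      bsa_a = sa$bsa, bsa_b = sb$bsa, bsa_total = sa$bsa + sb$bsa,
      apolar_a = sa$apolar, apolar_b = sb$apolar,
      midpoint_a = sa$midpoint, midpoint_b = sb$midpoint,
      first_res_a = sa$first_res, last_res_a = sa$last_res,
      first_res_b = sb$first_res, last_res_b = sb$last_res
    )
    if (keep_residues) out$residues <- list(per_res[per_res$bsa > 0, ])
    out
  })
  out <- dplyr::bind_rows(rows)
  out <- out[pmax(out$bsa_a, out$bsa_b) > min_area, , drop = FALSE]
  if (nrow(out) == 0) empty_interface_table(keep_residues) else out
}

empty_interface_table <- function(keep_residues) {
  out <- tibble(
    complex_id = character(), chain_a = character(), chain_b = character(),
    homomeric = logical(), bsa_a = numeric(), bsa_b = numeric(),
    bsa_total = numeric(), apolar_a = numeric(), apolar_b = numeric(),
    midpoint_a = integer(), midpoint_b = integer(),
    first_res_a = integer(), last_res_a = integer(),
    first_res_b = integer(), last_res_b = integer()
  )
  if (keep_residues) out$residues <- list()
  out
}

#' Per-chain buried area against the full complex
#'
#' Alternative to the pure pairwise context of [pairwise_interfaces()]:
#' each chain's total buried area is its isolated ASA minus its ASA in the
#' context of all other chains together. Pair attribution is not defined in
#' this context, so the result is per chain.
#'
#' @inheritParams pairwise_interfaces
#' @return Tibble: `chain`, `bsa`.
#' @export
chain_buried_area <- function(atoms, probe = 1.4, n_points = 960L) {
  ctx <- compute_sasa(atoms, probe = probe, n_points = n_points)
  by_chain <- split(as_tibble(atoms), atoms$chain)
  purrr::imap_dfr(by_chain, function(ch_atoms, ch) {
    iso <- compute_sasa(ch_atoms, probe = probe, n_points = n_points)
    tibble(chain = ch,
           bsa = sum(iso$asa) - sum(ctx$asa[ctx$chain == ch]))
  })
}

#' Apolar buried area of an interface side
#'
#' Sum of per-residue buried area over the apolar amino acids
#' (A, F, G, I, L, V, M, P, Y).
#'
#' @param residues Tibble with columns `aa` and `bsa`.
#' @return Apolar area in Angstrom^2.
#' @export
apolar_area <- function(residues) {
  sum(residues$bsa[residues$aa %in% apolar_residues()], na.rm = TRUE)
}

#' Interface midpoint
#'
#' The residue at which half of an interface side's buried area is reached:
#' the smallest sequence position whose N-to-C cumulative per-residue BSA is
#' at least half the side total (so a single-residue interface is its own
#' midpoint). Invariant to uniform scaling of the areas.
#'
#' @param seq_pos Residue positions (1-based).
#' @param bsa Per-residue buried areas, same length.
#' @return The midpoint position (integer).
#' @export
interface_midpoint <- function(seq_pos, bsa) {
  stopifnot(length(seq_pos) == length(bsa), length(bsa) > 0)
  o <- order(seq_pos)
  cum <- cumsum(bsa[o])
  seq_pos[o][which(cum >= sum(bsa) / 2)[1]]
}

#' Relative interface location
#'
#' `(i - 1) / (L - 1)` for a midpoint at position `i` of a protein of
#' length `L`; 0 at the N terminus, 1 at the C terminus. Values below 0.5
#' classify the interface as N-terminal-half (the boundary itself is
#' assigned to the N half, the earlier-synthesised side).
#'
#' @param i Midpoint position(s), 1-based.
#' @param L Sequence length(s), >= 2.
#' @return Fraction(s) in \[0, 1\].
#' @export
relative_interface_location <- function(i, L) {
  if (any(L < 2)) stop("sequence length must be >= 2")
  stopifnot(all(i >= 1), all(i <= L))
  (i - 1) / (L - 1)
}

#' N- or C-terminal half classification of a midpoint
#' @inheritParams relative_interface_location
#' @return `"N"` or `"C"` per element (boundary 0.5 goes to `"N"`).
#' @export
terminal_half <- function(i, L) {
  ifelse(relative_interface_location(i, L) <= 0.5, "N", "C")
}

#' Relative translational distance between two interfaces
#'
#' `(f_last - f_first) / L`, where `f` is the first (most N-terminal)
#' residue of each interface: the separation of the translational start
#' points of the first and last interface as a fraction of sequence length.
#'
#' @param f_first,f_last First residues of the first and last interface.
#' @param L Sequence length.
#' @return Fraction(s) in \[0, 1).
#' @export
relative_translational_distance <- function(f_first, f_last, L) {
  if (any(f_first > f_last) || any(f_last > L)) {
    stop("require f_first <= f_last <= L")
  }
  (f_last - f_first) / L
}

#' Relative size difference between first and last interfaces
#'
#' `(BSA_first - BSA_last) / (BSA_first + BSA_last)`; positive when the
#' first-translated interface is the larger one, antisymmetric in its
#' arguments, in \[-1, 1\].
#'
#' @param bsa_first,bsa_last Buried areas of the first and last translated
#'   interfaces (Angstrom^2; their sum must be positive).
#' @return Dimensionless value(s) in \[-1, 1\].
#' @export
relative_size_difference <- function(bsa_first, bsa_last) {
  if (any(bsa_first + bsa_last <= 0)) {
    stop("bsa_first + bsa_last must be positive")
  }
  (bsa_first - bsa_last) / (bsa_first + bsa_last)
}
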