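#' Specification of a synthetic bead-model complex
#'
#' Describes a coarse-grained complex: one pseudo-atom per residue (a
#' "bead" of fixed radius at a Calpha-like position), with a plan of which
#' sequence windows of which chain pairs are in contact. Window length
#' controls the realized interface area, so the plan's rank order of window
#' lengths becomes the rank order of buried areas; non-planned chain pairs
#' never touch. Geometry is deterministic: each planned interface occupies
#' its own site far (>= 1000 Angstrom) from every other site and from the
#' chains' home segments, so interfaces are strictly pairwise and additive.
#'
#' @param chains Named integer vector: residues per chain (names are chain
#'   ids).
#' @param interfaces Tibble with columns `chain_a`, `chain_b`, `start_a`,
#'   `end_a`, `start_b`, `end_b`: the contact windows on each side.
#' @param bead_radius Bead radius in Angstrom (default 3.0).
#' @param sequences Optional named list/vector of one-letter sequences per
#'   chain (default: poly-alanine).
#' @return A `complex_spec` list, validated (windows inside their chains
#'   and non-overlapping within a chain; overlapping windows are an
#'   infeasible plan and raise an error naming the chain).
#' @export
complex_spec <- function(chains, interfaces, bead_radius = 3.0,
                         sequences = NULL) {
  stopifnot(!is.null(names(chains)), all(chains >= 1))
  ifc <- as_tibble(interfaces)
  need <- c("chain_a", "chain_b", "start_a", "end_a", "start_b", "end_b")
  stopifnot(all(need %in% names(ifc)))
  for (k in seq_len(nrow(ifc))) {
    for (side in c("a", "b")) {
      ch <- ifc[[paste0("chain_", side)]][k]
      s <- ifc[[paste0("start_", side)]][k]
      e <- ifc[[paste0("end_", side)]][k]
      if (!ch %in% names(chains)) stop("unknown chain in plan: ", ch)
      if (s < 1 || e > chains[[ch]] || s > e) {
        stop("window [", s, ",", e, "] outside chain ", ch)
      }
    }
  }
  ## windows on the same chain must not collide (a residue has one position)
  for (ch in names(chains)) {
    win <- list()
    for (k in seq_len(nrow(ifc))) {
      for (side in c("a", "b")) {
        if (ifc[[paste0("chain_", side)]][k] == ch) {
          win[[length(win) + 1]] <- seq(ifc[[paste0("start_", side)]][k],
                                        ifc[[paste0("end_", side)]][k])
        }
      }
    }
    all_pos <- unlist(win)
    if (anyDuplicated(all_pos)) {
      stop("infeasible plan: contact windows collide on chain ", ch,
           " (residue ", all_pos[duplicated(all_pos)][1], ")")
    }
  }
  seqs <- purrr::imap(as.list(chains), function(n, ch) {
    s <- sequences[[ch]] %||% strrep("A", n)
    aa <- strsplit(s, "")[[1]]
    if (length(aa) != n) stop("sequence length mismatch for chain ", ch)
    aa
  })
  structure(list(chains = chains, interfaces = ifc,
                 bead_radius = bead_radius, sequences = seqs),
            class = "complex_spec")
}

#' Generate a synthetic bead-model complex
#'
#' Realises a [complex_spec()] as a `cotasm_structure` (and optionally a
#' PDB file): each chain's non-contact beads lie on its own home segment,
#' and each planned interface's windows interdigitate at a dedicated site
#' (4 Angstrom bead spacing, 3.5 Angstrom inter-chain offset), well within
#' mutual occlusion range for 3 Angstrom beads and a 1.4 Angstrom probe.
#'
#' @param spec A `complex_spec`.
#' @param path Optional path: write the structure as PDB.
#' @param complex_id Identifier (default `"synthetic"`).
#' @return A `cotasm_structure` tibble.
#' @export
generate_complex <- function(spec, path = NULL, complex_id = "synthetic") {
  stopifnot(inherits(spec, "complex_spec"))
  chains <- spec$chains
  ifc <- spec$interfaces
  site_spacing <- 2000
  rows <- purrr::imap(as.list(chains), function(n, ch) {
    home_y <- site_spacing * match(ch, names(chains))
    tibble(
      chain = ch, protein_id = ch, seq_pos = seq_len(n),
      aa = spec$sequences[[ch]],
      x = 8 * seq_len(n), y = home_y, z = 0
    )
  })
  atoms <- dplyr::bind_rows(rows)
  for (k in seq_len(nrow(ifc))) {
    site <- c(site_spacing * k, -site_spacing, 0)
    wa <- seq(ifc$start_a[k], ifc$end_a[k])
    wb <- seq(ifc$start_b[k], ifc$end_b[k])
    ia <- atoms$chain == ifc$chain_a[k] & atoms$seq_pos %in% wa
    ib <- atoms$chain == ifc$chain_b[k] & atoms$seq_pos %in% wb
    atoms$x[ia] <- site[1] + 4 * seq_along(wa)
    atoms$y[ia] <- site[2]
    atoms$z[ia] <- 0
    atoms$x[ib] <- site[1] + 4 * seq_along(wb) + 2
    atoms$y[ib] <- site[2] + 3.5
    atoms$z[ib] <- 0
  }
  atoms$resid <- setNames(names(.aa3to1), unname(.aa3to1))[atoms$aa]
  atoms$elety <- "CA"
  atoms$element <- "C"
  atoms$radius <- spec$bead_radius
  atoms$nonstandard <- FALSE
  st <- new_structure(atoms, complex_id)
  if (!is.null(path)) write_structure(st, path)
  st
}

#' Generate a synthetic cohort of multi-interface subunits
#'
#' Draws a tabular cohort with the statistical structure the analysis
#' assumes: per subunit, the first- and last-translated interface areas are
#' log-normal with log-sd `sigma_log` and a mean ratio `delta` favouring
#' the first interface; a cotranslational flag follows a logistic link on
#' log interface size; assembly-onset positions sit at a designated
#' interface's midpoint plus the ribosome tunnel offset plus Gaussian
#' noise; age-class and operon labels are assigned at the stated
#' fractions. A fixed seed gives identical output.
#'
#' The defaults emulate the magnitudes reported for real proteomes:
#' `delta = 1.15` (first interface ~15% larger on average) together with
#' `sigma_log = 0.35` puts the first interface above the last in ~60% of
#' subunits (61% exactly), while keeping the paired excess reliably
#' detectable at cohort sizes around 150; `meanlog = log(1300)` matches a
#' ~205 Angstrom^2 mean difference at that ratio.
#'
#' @param n Number of subunits.
#' @param delta Mean first/last area ratio (> 0; 1 = null).
#' @param sigma_log Log-scale standard deviation of areas.
#' @param meanlog Log-scale mean of the last-interface area.
#' @param cotrans_rate Baseline cotranslational fraction.
#' @param cotrans_slope Logistic slope of the cotranslational flag on
#'   centred log area (0 = independent).
#' @param p_designate_first Probability that the designated (onset-bearing)
#'   interface is the first one.
#' @param age_ancient Fraction of subunits labelled `ancient`.
#' @param operon_fraction Fraction labelled operon-encoded.
#' @param onset_noise SD (residues) of Gaussian noise on onset positions.
#' @param midpoint_gap Distance (residues) between the first and last
#'   interface midpoints.
#' @param homomeric_fraction Fraction of subunits carrying an additional
#'   homomeric decoy interface (C-terminal of the last midpoint).
#' @param tunnel_offset Ribosome tunnel length added to onsets.
#' @param delta_operon,delta_ancient Optional stratum-specific `delta`
#'   overrides for operon-encoded / ancient subunits.
#' @param seed Integer seed (required for reproducibility).
#' @return Tibble, one row per subunit: `protein_id`, `L`, `bsa_first`,
#'   `bsa_last`, `midpoint_first`, `midpoint_last`, `midpoint_homo`,
#'   `f_first`, `f_last`, `designated`, `cotranslational`, `age_class`,
#'   `operon`, `onset` (NA for non-cotranslational subunits).
#' @export
generate_cohort <- function(n = 150, delta = 1.15, sigma_log = 0.35,
                            meanlog = log(1300), cotrans_rate = 0.3,
                            cotrans_slope = 1, p_designate_first = 0.5,
                            age_ancient = 0.5, operon_fraction = 0.45,
                            onset_noise = 5, midpoint_gap = 120,
                            homomeric_fraction = 0.15, tunnel_offset = 30,
                            delta_operon = NULL, delta_ancient = NULL,
                            seed = 20220728) {
  stopifnot(delta > 0, n >= 1)
  withr::with_seed(as.integer(seed), {
    operon <- stats::runif(n) < operon_fraction
    age_class <- ifelse(stats::runif(n) < age_ancient, "ancient", "recent")
    d <- rep(delta, n)
    if (!is.null(delta_operon)) d[operon] <- delta_operon
    if (!is.null(delta_ancient)) d[age_class == "ancient"] <- delta_ancient
    bsa_last <- stats::rlnorm(n, meanlog, sigma_log)
    bsa_first <- stats::rlnorm(n, meanlog + log(d), sigma_log)
    midpoint_first <- sample(40:120, n, replace = TRUE)
    midpoint_last <- midpoint_first + midpoint_gap
    has_homo <- stats::runif(n) < homomeric_fraction
    midpoint_homo <- ifelse(has_homo, midpoint_last + 80L, NA_integer_)
    L <- midpoint_last + 120L
    bigger <- pmax(bsa_first, bsa_last)
    p_cot <- stats::plogis(stats::qlogis(cotrans_rate) +
                             cotrans_slope * (log(bigger) - meanlog))
    cotranslational <- stats::runif(n) < p_cot
    designated <- ifelse(stats::runif(n) < p_designate_first,
                         "first", "last")
    mid_des <- ifelse(designated == "first", midpoint_first, midpoint_last)
    onset <- mid_des + tunnel_offset +
      round(stats::rnorm(n, 0, onset_noise))
    onset <- pmin(pmax(onset, 1L), L)
    onset[!cotranslational] <- NA_integer_
    tibble(
      protein_id = sprintf("P%04d", seq_len(n)), L = L,
      bsa_first = bsa_first, bsa_last = bsa_last,
      midpoint_first = midpoint_first, midpoint_last = midpoint_last,
      midpoint_homo = midpoint_homo,
      f_first = pmax(1L, midpoint_first - 15L),
      f_last = pmax(1L, midpoint_last - 15L),
      designated = designated, cotranslational = cotranslational,
      age_class = age_class, operon = operon, onset = as.integer(onset)
    )
  })
}

#' Interface-midpoint table of a synthetic cohort
#'
#' Reshapes a [generate_cohort()] table into the per-interface profile
#' format consumed by [map_onsets()] (one row per interface with
#' `protein_id`, `partner`, `midpoint`, `homomeric`, `bsa`).
#'
#' @param cohort A [generate_cohort()] tibble.
#' @return Interface-midpoint tibble.
#' @export
cohort_interfaces <- function(cohort) {
  first <- tibble(protein_id = cohort$protein_id, partner = "first",
                  midpoint = cohort$midpoint_first, homomeric = FALSE,
                  bsa = cohort$bsa_first)
  last <- tibble(protein_id = cohort$protein_id, partner = "last",
                 midpoint = cohort$midpoint_last, homomeric = FALSE,
                 bsa = cohort$bsa_last)
  homo <- cohort[!is.na(cohort$midpoint_homo), , drop = FALSE]
  homo <- tibble(protein_id = homo$protein_id, partner = "homo",
                 midpoint = homo$midpoint_homo, homomeric = TRUE,
                 bsa = NA_real_)
  dplyr::arrange(dplyr::bind_rows(first, last, homo), .data$protein_id)
}

#' Synthetic pH ~ charge titration curve
#'
#' Henderson-Hasselbalch net charge of a sequence on a pH grid, using the
#' shipped standard pKa set ([pka_reference()]) including free termini.
#' The curve is monotone non-increasing in pH, so a unique isoelectric
#' point can be interpolated with [interpolate_pi()].
#'
#' @param sequence One-letter sequence (single string or vector).
#' @param pka Named pKa vector (default [pka_reference()]).
#' @param pH_grid pH grid (default 0 to 14 by 0.1).
#' @return Tibble: `pH`, `charge`.
#' @export
generate_titration_curve <- function(sequence, pka = pka_reference(),
                                     pH_grid = seq(0, 14, by = 0.1)) {
  aa <- if (length(sequence) == 1) {
    strsplit(sequence, "")[[1]]
  } else {
    as.character(sequence)
  }
  if (length(aa) == 0) stop("empty sequence")
  pos_groups <- c(K = sum(aa == "K"), R = sum(aa == "R"),
                  H = sum(aa == "H"), nterm = 1)
  neg_groups <- c(D = sum(aa == "D"), E = sum(aa == "E"),
                  C = sum(aa == "C"), Y = sum(aa == "Y"), cterm = 1)
  charge <- vapply(pH_grid, function(ph) {
    plus <- sum(pos_groups * 1 / (1 + 10^(ph - pka[names(pos_groups)])))
    minus <- sum(neg_groups * 1 / (1 + 10^(pka[names(neg_groups)] - ph)))
    plus - minus
  }, numeric(1))
  tibble(pH = pH_grid, charge = charge)
}
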