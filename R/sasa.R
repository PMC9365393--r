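## Solvent-accessible surface area by the Shrake-Rupley sphere-point method
## with a deterministic golden-section lattice.

golden_points <- function(n) {
  k <- seq_len(n) - 1
  z <- 1 - (2 * k + 1) / n
  phi <- k * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

## core: per-atom accessible area for spheres (xyz matrix, radii vector)
sr_sasa_atoms <- function(xyz, radii, probe = 1.4, n_points = 960L) {
  n <- nrow(xyz)
  if (n == 0) stop("empty atom list")
  pts <- golden_points(n_points)
  R <- radii + probe
  asa <- numeric(n)
  d2 <- as.matrix(dist(xyz))^2
  for (i in seq_len(n)) {
    lim <- (R[i] + R)^2
    nb <- which(d2[i, ] < lim)
    nb <- nb[nb != i]
    if (length(nb) == 0) {
      asa[i] <- 4 * pi * R[i]^2
      next
    }
    sp <- pts * R[i]
    sp[, 1] <- sp[, 1] + xyz[i, 1]
    sp[, 2] <- sp[, 2] + xyz[i, 2]
    sp[, 3] <- sp[, 3] + xyz[i, 3]
    acc <- rep(TRUE, n_points)
    ## nearest occluders first so the accessible set shrinks fast
    nb <- nb[order(d2[i, nb])]
    for (j in nb) {
      dj2 <- (sp[, 1] - xyz[j, 1])^2 + (sp[, 2] - xyz[j, 2])^2 +
        (sp[, 3] - xyz[j, 3])^2
      acc <- acc & (dj2 > R[j]^2)
      if (!any(acc)) break
    }
    asa[i] <- 4 * pi * R[i]^2 * mean(acc)
  }
  asa
}

#' Solvent-accessible surface area
#'
#' Computes per-atom and per-residue SASA of a set of atoms with a 1.4
#' Angstrom probe by the Shrake-Rupley method on a deterministic
#' golden-section point lattice (default 960 points per atom). Per-residue
#' ASA is the sum over member atoms. Results are exactly reproducible for a
#' fixed `n_points`.
#'
#' @param atoms Atom tibble (`chain`, `seq_pos`, `aa`, `x`, `y`, `z`,
#'   `radius`), e.g. a [read_structure()] result, possibly subset to the
#'   context of interest (a chain in isolation, a chain pair, the full
#'   complex).
#' @param probe Probe radius in Angstrom (default 1.4, water).
#' @param n_points Surface points per atom (>= 60; default 960).
#' @param by `"residue"` (default) or `"atom"`.
#' @return Tibble of ASA in Angstrom^2: per residue (`chain`, `seq_pos`,
#'   `aa`, `asa`) or per atom (input columns plus `asa`).
#' @export
compute_sasa <- function(atoms, probe = 1.4, n_points = 960L,
                         by = c("residue", "atom")) {
  by <- match.arg(by)
  stopifnot(probe >= 0, n_points >= 60)
  if (nrow(atoms) == 0) stop("empty atom list")
  asa <- sr_sasa_atoms(as.matrix(atoms[, c("x", "y", "z")]),
                       atoms$radius, probe, as.integer(n_points))
  out <- dplyr::mutate(as_tibble(atoms), asa = asa)
  if (by == "atom") return(out)
  out |>
    dplyr::group_by(.data$chain, .data$seq_pos) |>
    dplyr::summarise(aa = dplyr::first(.data$aa), asa = sum(.data$asa),
                     .groups = "drop")
}

#' Relative accessible surface area and surface classification
#'
#' Divides per-residue ASA by a per-amino-acid maximal reference area and
#' flags residues with relative accessibility strictly greater than the
#' threshold as surface residues (default 0.25, i.e. "more than 25%").
#' Residues with unknown amino acid are dropped with a warning.
#'
#' @param res_asa Per-residue ASA tibble from [compute_sasa()] (needs
#'   `aa`, `asa`).
#' @param max_table Named reference vector (default [max_asa_reference()]).
#' @param threshold Surface cutoff on rASA (strict inequality).
#' @return Input tibble plus `rasa` and `surface` columns.
#' @export
relative_asa <- function(res_asa, max_table = max_asa_reference(),
                         threshold = 0.25) {
  unknown <- !(res_asa$aa %in% names(max_table))
  if (any(unknown)) {
    warning(sum(unknown), " residue(s) with unknown amino acid excluded ",
            "from relative accessibility")
    res_asa <- res_asa[!unknown, , drop = FALSE]
  }
  dplyr::mutate(
    as_tibble(res_asa),
    rasa = .data$asa / unname(max_table[.data$aa]),
    surface = .data$rasa > threshold
  )
}
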