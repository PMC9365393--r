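#' Read a multi-chain structure from a PDB file
#'
#' Parses ATOM records of a Brookhaven-format PDB file into an atom-level
#' tibble, the geometric substrate of all interface computations. HETATM
#' records and hydrogens are excluded, only the first model of multi-model
#' files is used, and where an atom carries multiple alternate locations the
#' first is kept. Nonstandard residue names are mapped to their canonical
#' one-letter equivalents where a mapping is known (e.g. MSE to M); unmapped
#' residues are kept for geometry but flagged, and are excluded from
#' chemical-class based metrics.
#'
#' @param path Path to a PDB file.
#' @param radii Named vector of element van der Waals radii in Angstrom
#'   (default [vdw_radii()]). Elements absent from the table get 1.80.
#' @param chain_proteins Optional named character vector mapping chain id to
#'   protein id (used to flag homomeric interfaces). Defaults to the chain id
#'   itself.
#' @param complex_id Identifier for the complex; defaults to the file name
#'   without extension.
#'
#' @return A tibble of class `cotasm_structure` with one row per heavy atom:
#'   `chain`, `protein_id`, `seq_pos` (1-based position in the full-length
#'   sequence), `aa` (one-letter, NA when unmapped), `resid`, `elety`,
#'   `element`, `x`, `y`, `z`, `radius`, `nonstandard`.
#' @export
read_structure <- function(path, radii = vdw_radii(), chain_proteins = NULL,
                           complex_id = NULL) {
  if (!file.exists(path)) {
    stop("cannot read structure: file not found: ", path)
  }
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("parse error reading '", path, "': ",
                             conditionMessage(e))
  )
  at <- tibble::as_tibble(pdb$atom)
  at <- dplyr::filter(at, .data$type == "ATOM")
  if (nrow(at) == 0) stop("structural error: no ATOM records in ", path)
  at$element <- toupper(ifelse(is.na(at$elesy) | at$elesy == "",
                               substr(trimws(at$elety), 1, 1), at$elesy))
  at <- dplyr::filter(at, !.data$element %in% c("H", "D"))
  ## first altloc only: first record per atom identity in file order
  at <- dplyr::distinct(at, .data$chain, .data$resno, .data$insert,
                        .data$elety, .keep_all = TRUE)

  res3 <- toupper(at$resid)
  aa <- unname(.aa3to1[res3])
  nonstd <- is.na(aa) & !is.na(unname(.aa_nonstandard[res3]))
  aa[nonstd] <- unname(.aa_nonstandard[res3[nonstd]])
  nonstandard <- !(res3 %in% names(.aa3to1))

  chain <- ifelse(is.na(at$chain), "A", at$chain)
  if (is.null(chain_proteins)) {
    protein_id <- chain
  } else {
    protein_id <- unname(chain_proteins[chain])
    protein_id[is.na(protein_id)] <- chain[is.na(protein_id)]
  }
  radius <- unname(radii[at$element])
  radius[is.na(radius)] <- .default_radius

  out <- tibble(
    chain = chain, protein_id = protein_id,
    seq_pos = as.integer(at$resno), aa = aa, resid = res3,
    elety = trimws(at$elety), element = at$element,
    x = at$x, y = at$y, z = at$z, radius = radius,
    nonstandard = nonstandard
  )
  out <- dplyr::arrange(out, .data$chain, .data$seq_pos)
  if (any(table(out$chain) == 0)) stop("structural error: empty chain")
  new_structure(out, complex_id %||%
                  sub("\\.[^.]*$", "", basename(path)))
}

new_structure <- function(df, complex_id) {
  df <- as_tibble(df)
  attr(df, "complex_id") <- complex_id
  class(df) <- c("cotasm_structure", class(df))
  df
}

#' Complex identifier of a structure
#' @param x A `cotasm_structure`.
#' @return The complex id string.
#' @export
complex_id <- function(x) attr(x, "complex_id") %||% "complex"

#' Write a structure to a PDB file
#'
#' Inverse of [read_structure()] for package-generated structures: emits
#' ATOM/TER/END records only, one record per atom, coordinates to three
#' decimals.
#'
#' @param atoms A `cotasm_structure` (or compatible tibble).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(atoms, path) {
  atoms <- dplyr::arrange(as_tibble(atoms), .data$chain, .data$seq_pos)
  aa1to3 <- setNames(names(.aa3to1), unname(.aa3to1))
  resid <- if ("resid" %in% names(atoms)) atoms$resid else aa1to3[atoms$aa]
  resid[is.na(resid)] <- "UNK"
  elety <- if ("elety" %in% names(atoms)) atoms$elety else "CA"
  element <- if ("element" %in% names(atoms)) atoms$element else "C"
  suppressWarnings(bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(atoms[, c("x", "y", "z")]))),
    type = rep("ATOM", nrow(atoms)),
    resno = atoms$seq_pos, resid = resid, chain = atoms$chain,
    eleno = seq_len(nrow(atoms)), elety = elety, elesy = element,
    o = rep(1, nrow(atoms)), b = rep(0, nrow(atoms))
  ))
  invisible(path)
}

#' Per-chain residue summary
#'
#' Observed residue counts and full sequence length per chain. `L` comes from
#' `lengths` (a tibble `protein_id`, `L`, typically from a full-length
#' sequence table) when supplied, else from the maximum observed position;
#' the source is recorded per chain.
#'
#' @param atoms A `cotasm_structure`.
#' @param lengths Optional tibble with columns `protein_id`, `L`.
#' @return Tibble: `chain`, `protein_id`, `observed_count`, `L`, `L_source`.
#' @export
chain_summary <- function(atoms, lengths = NULL) {
  out <- atoms |>
    dplyr::group_by(.data$chain, .data$protein_id) |>
    dplyr::summarise(
      observed_count = dplyr::n_distinct(.data$seq_pos),
      L_obs = max(.data$seq_pos),
      .groups = "drop"
    )
  if (!is.null(lengths)) {
    out <- dplyr::left_join(out, lengths, by = "protein_id")
    out$L_source <- ifelse(is.na(out$L), "observed", "sequence_table")
    out$L <- ifelse(is.na(out$L), out$L_obs, out$L)
  } else {
    out$L <- out$L_obs
    out$L_source <- "observed"
  }
  dplyr::select(out, "chain", "protein_id", "observed_count", "L", "L_source")
}
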