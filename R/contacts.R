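contact_classes <- c("apolar-apolar", "apolar-charged", "apolar-polar",
                     "charged-charged", "charged-polar", "polar-polar")

#' Interfacial residue-residue contacts
#'
#' A residue of one chain contacts a residue of the other when their minimum
#' heavy-atom distance is at most `cutoff` (default 5.5 Angstrom). Each
#' contact is typed by the chemical-class pair of the two residues:
#' charged (D, E, K, R), apolar (A, F, G, I, L, V, M, P, Y), polar
#' (the remainder; histidine is polar).
#'
#' @param atoms A `cotasm_structure`.
#' @param chain_a,chain_b The two chain ids.
#' @param cutoff Heavy-atom distance cutoff in Angstrom (> 0).
#' @return Tibble of contacts: `seq_pos_a`, `aa_a`, `seq_pos_b`, `aa_b`,
#'   `dist` (minimum heavy-atom distance), `class_pair`.
#' @export
residue_contacts <- function(atoms, chain_a, chain_b, cutoff = 5.5) {
  stopifnot(cutoff > 0)
  a <- as_tibble(atoms)[atoms$chain == chain_a, , drop = FALSE]
  b <- as_tibble(atoms)[atoms$chain == chain_b, , drop = FALSE]
  if (nrow(a) == 0 || nrow(b) == 0) stop("unknown chain id")
  ma <- as.matrix(a[, c("x", "y", "z")])
  mb <- as.matrix(b[, c("x", "y", "z")])
  d2 <- outer(rowSums(ma^2), rep(1, nrow(mb))) +
    outer(rep(1, nrow(ma)), rowSums(mb^2)) - 2 * ma %*% t(mb)
  d <- sqrt(pmax(d2, 0))
  hit <- which(d <= cutoff, arr.ind = TRUE)
  if (nrow(hit) == 0) {
    return(tibble(seq_pos_a = integer(), aa_a = character(),
                  seq_pos_b = integer(), aa_b = character(),
                  dist = numeric(), class_pair = character()))
  }
  out <- tibble(
    seq_pos_a = a$seq_pos[hit[, 1]], aa_a = a$aa[hit[, 1]],
    seq_pos_b = b$seq_pos[hit[, 2]], aa_b = b$aa[hit[, 2]],
    dist = d[hit]
  ) |>
    dplyr::group_by(.data$seq_pos_a, .data$seq_pos_b) |>
    dplyr::summarise(aa_a = dplyr::first(.data$aa_a),
                     aa_b = dplyr::first(.data$aa_b),
                     dist = min(.data$dist), .groups = "drop")
  cls <- cbind(residue_class(out$aa_a), residue_class(out$aa_b))
  out$class_pair <- apply(cls, 1, function(p) {
    if (anyNA(p)) NA_character_ else paste(sort(p), collapse = "-")
  })
  dplyr::arrange(out, .data$seq_pos_a, .data$seq_pos_b)
}

#' Contact counts by chemical-class pair
#'
#' @param contacts Output of [residue_contacts()].
#' @return Tibble with one row per class pair (all six always present):
#'   `class_pair`, `n`. Contacts involving unclassifiable residues are not
#'   counted.
#' @export
contact_class_counts <- function(contacts) {
  tallied <- table(factor(contacts$class_pair, levels = contact_classes))
  tibble(class_pair = contact_classes, n = as.integer(tallied))
}

#' Non-interfacial surface composition of a subunit in complex
#'
#' NIS_a and NIS_c: the percentages of apolar and charged residues among
#' the surface residues of a chain in the context of its complex (surface =
#' relative accessibility above `threshold`).
#'
#' @param rasa Per-residue tibble with `aa` and `surface` columns, e.g.
#'   [relative_asa()] applied to in-complex SASA of one chain.
#' @param threshold Unused when a `surface` column is present; otherwise
#'   applied to a `rasa` column (default 0.25).
#' @return Tibble: `nis_a`, `nis_c` (per cent), `n_surface`.
#' @export
nis_parameters <- function(rasa, threshold = 0.25) {
  if (!"surface" %in% names(rasa)) {
    rasa$surface <- rasa$rasa > threshold
  }
  surf <- rasa$aa[rasa$surface & !is.na(rasa$aa)]
  if (length(surf) == 0) stop("no surface residues")
  tibble(
    nis_a = 100 * mean(surf %in% apolar_residues()),
    nis_c = 100 * mean(surf %in% charged_residues()),
    n_surface = length(surf)
  )
}

#' Fraction of charged residues in a sequence
#'
#' Fractional content of positively (Arg + Lys) and negatively (Asp + Glu)
#' charged amino acids in a full-length protein sequence.
#'
#' @param sequence One-letter sequence as a single string or a character
#'   vector of residues.
#' @return Tibble: `frac_pos`, `frac_neg`, `length`.
#' @export
charged_fractions <- function(sequence) {
  aa <- if (length(sequence) == 1) {
    strsplit(sequence, "")[[1]]
  } else {
    as.character(sequence)
  }
  if (length(aa) == 0) stop("empty sequence")
  tibble(
    frac_pos = mean(aa %in% c("R", "K")),
    frac_neg = mean(aa %in% c("D", "E")),
    length = length(aa)
  )
}

#' Contact-based binding affinity
#'
#' Linear contact model of binding free energy: an intercept, one weight
#' per residue-contact chemical-class count, and weights for the
#' non-interfacial surface terms NIS_a and NIS_c. Coefficients are
#' user-supplied (the package ships no trained values).
#'
#' @param counts Tibble from [contact_class_counts()] or a named vector of
#'   counts keyed by class pair.
#' @param nis_a,nis_c Non-interfacial surface percentages
#'   (see [nis_parameters()]).
#' @param coefficients Named numeric vector containing `intercept`, one
#'   entry per contact class pair (`apolar-apolar`, ..., `polar-polar`),
#'   `nis_a` and `nis_c`.
#' @return Predicted Delta-G in kcal/mol (numeric scalar).
#' @export
predict_affinity <- function(counts, nis_a, nis_c, coefficients) {
  if (is.data.frame(counts)) {
    counts <- setNames(counts$n, counts$class_pair)
  }
  needed <- c("intercept", contact_classes, "nis_a", "nis_c")
  missing <- setdiff(needed, names(coefficients))
  if (length(missing) > 0) {
    stop("missing affinity coefficient(s): ", paste(missing, collapse = ", "))
  }
  counts_full <- setNames(numeric(length(contact_classes)), contact_classes)
  counts_full[names(counts)] <- counts
  unname(coefficients["intercept"] +
           sum(coefficients[contact_classes] * counts_full) +
           coefficients["nis_a"] * nis_a + coefficients["nis_c"] * nis_c)
}

#' Isoelectric point from a titration curve
#'
#' Linearly interpolates the pH at which net charge crosses zero from a
#' pH ~ charge titration curve. For proteins split into fragments, take the
#' arithmetic mean of the fragment pI values ([mean_fragment_pi()]).
#'
#' @param curve Tibble or data frame with ascending `pH` and `charge`
#'   columns, bracketing zero charge.
#' @return The interpolated pI (pH units).
#' @export
interpolate_pi <- function(curve) {
  stopifnot(all(c("pH", "charge") %in% names(curve)), nrow(curve) >= 2)
  if (is.unsorted(curve$pH, strictly = FALSE)) stop("pH must be ascending")
  ch <- curve$charge
  if (any(ch == 0)) return(curve$pH[which(ch == 0)[1]])
  cross <- which(ch[-length(ch)] > 0 & ch[-1] < 0)
  if (length(cross) == 0) {
    stop("no zero crossing in titration curve: charge is ",
         if (all(ch > 0)) "positive" else if (all(ch < 0)) "negative"
         else "non-monotone without a +/- crossing", " over the pH range")
  }
  i <- cross[1]
  curve$pH[i] + ch[i] * (curve$pH[i + 1] - curve$pH[i]) / (ch[i] - ch[i + 1])
}

#' Mean pI across protein fragments
#' @param pis Numeric vector of per-fragment isoelectric points.
#' @return Their arithmetic mean.
#' @export
mean_fragment_pi <- function(pis) mean(pis)
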