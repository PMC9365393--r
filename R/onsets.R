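#' Adjust assembly-onset positions for the ribosome exit tunnel
#'
#' An assembly-onset is the sequence position being decoded at the moment
#' cotranslational binding is detected; the residue actually emerging from
#' the ribosome is ~30 residues behind, so the tunnel length is subtracted.
#' Results are clamped at position 1.
#'
#' @param raw Raw onset position(s), 1-based.
#' @param tunnel_offset Tunnel length in residues (default 30).
#' @return Adjusted position(s), `max(1, raw - tunnel_offset)`.
#' @export
adjust_onset <- function(raw, tunnel_offset = 30) {
  stopifnot(all(raw >= 1))
  pmax(1, raw - tunnel_offset)
}

#' Map assembly onsets to interface midpoints
#'
#' Each (tunnel-adjusted) onset is mapped to the closest interface midpoint
#' in the linear sequence of its protein. Compressing every interface to a
#' single midpoint residue avoids the bias whereby large interfaces, having
#' many residues, would soak up onsets. Onsets whose nearest midpoint
#' belongs to a homomeric interface are discarded (the homomeric interface
#' is assumed to assemble in cis); equidistant midpoints resolve to the more
#' N-terminal (earlier-translated) interface.
#'
#' @param profiles Interface-side table with columns `protein_id`,
#'   `partner`, `midpoint`, `homomeric` (e.g. [subunit_profiles()]).
#' @param onsets Tibble with `protein_id` and `onset` (raw positions).
#' @param tunnel_offset Residues subtracted from raw onsets (default 30).
#' @param max_pos Optional named vector of sequence lengths by protein;
#'   onsets beyond the length are skipped with status `out_of_range`.
#' @return Tibble, one row per onset: `protein_id`, `raw_onset`,
#'   `adjusted_onset`, `interface` (partner chain id, NA when discarded),
#'   `midpoint`, `status` (`mapped`, `discarded_homomeric`, `no_interface`,
#'   `out_of_range`).
#' @export
map_onsets <- function(profiles, onsets, tunnel_offset = 30,
                       max_pos = NULL) {
  purrr::pmap_dfr(
    onsets[, c("protein_id", "onset")],
    function(protein_id, onset) {
      adj <- adjust_onset(onset, tunnel_offset)
      base <- tibble(protein_id = protein_id, raw_onset = onset,
                     adjusted_onset = adj, interface = NA_character_,
                     midpoint = NA_integer_, status = NA_character_)
      if (!is.null(max_pos) && protein_id %in% names(max_pos) &&
          onset > max_pos[[protein_id]]) {
        base$status <- "out_of_range"
        return(base)
      }
      p <- profiles[profiles$protein_id == protein_id &
                      !is.na(profiles$midpoint), , drop = FALSE]
      if (nrow(p) == 0) {
        base$status <- "no_interface"
        return(base)
      }
      ## nearest midpoint; ties resolved to the more N-terminal midpoint
      p <- p[order(abs(p$midpoint - adj), p$midpoint), , drop = FALSE]
      hit <- p[1, ]
      base$midpoint <- as.integer(hit$midpoint)
      if (hit$homomeric) {
        base$status <- "discarded_homomeric"
      } else {
        base$interface <- hit$partner
        base$status <- "mapped"
      }
      base
    }
  )
}

#' Annotate multi-interface subunits with cotranslational interfaces
#'
#' Joins onset mappings onto per-subunit interface profiles to produce the
#' paired-comparison table: for each multi-interface heteromeric subunit
#' whose onset mapped to one of its heteromeric interfaces, the mapped
#' interface's buried area and assembly order are paired with the mean over
#' all its *other* heteromeric interfaces. Subunits with a single
#' heteromeric interface cannot enter a paired comparison and are dropped;
#' onsets that were discarded or for proteins absent from the profiles are
#' skipped.
#'
#' @param profiles [subunit_profiles()] output.
#' @param mapped [map_onsets()] output.
#' @param orders Optional tidy assembly-order table(s) with `chain_a`,
#'   `chain_b`, `normalized_order` (e.g. `tidy(predict_assembly_pathway(...))`,
#'   rows concatenated across complexes) used to add order columns.
#' @return Tibble, one row per annotatable subunit: `protein_id`, `chain`,
#'   `cotrans_interface`, `bsa_cotrans`, `bsa_other_mean`, `n_other`, and,
#'   when `orders` is given, `order_cotrans`, `order_other_mean`.
#' @export
annotate_cohort <- function(profiles, mapped, orders = NULL) {
  hits <- mapped[mapped$status == "mapped", , drop = FALSE]
  rows <- purrr::pmap_dfr(
    hits[, c("protein_id", "interface")],
    function(protein_id, interface) {
      p <- profiles[profiles$protein_id == protein_id &
                      !profiles$homomeric, , drop = FALSE]
      self <- p$partner == interface
      if (!any(self) || sum(!self) == 0) return(tibble())
      out <- tibble(
        protein_id = protein_id,
        chain = p$chain[self][1],
        cotrans_interface = interface,
        bsa_cotrans = p$bsa[self][1],
        bsa_other_mean = mean(p$bsa[!self]),
        n_other = sum(!self)
      )
      if (!is.null(orders)) {
        ch <- p$chain[self][1]
        key <- function(x, y) paste(pmin(x, y), pmax(x, y))
        ok <- setNames(orders$normalized_order,
                       key(orders$chain_a, orders$chain_b))
        out$order_cotrans <- unname(ok[key(ch, interface)])
        out$order_other_mean <- mean(ok[key(ch, p$partner[!self])],
                                     na.rm = TRUE)
      }
      out
    }
  )
  rows
}
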