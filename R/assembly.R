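#' Predict a complex assembly pathway by interface-size additivity
#'
#' Greedy agglomeration under the additivity assumption: starting from
#' single subunits, each step merges the two current components whose union
#' gains the largest summed pairwise buried area. An interface "forms" at
#' the step where its two chains first co-occur in one component, so a step
#' can gain several interfaces at once, all sharing that step's order. Ties
#' in gained area are broken deterministically by the lexicographically
#' smallest pair of component representative chain ids. The largest pairwise
#' interface of a complex is always gained at step 1, and the pathway is
#' invariant to positive rescaling of all areas.
#'
#' @param ifaces Interface table with columns `chain_a`, `chain_b` and an
#'   area column (default `bsa_total`), e.g. from [pairwise_interfaces()]
#'   called with `min_area = 0`.
#' @param area_col Name of the area column used for gains.
#' @param min_area Interfaces at or below this area still contribute gained
#'   area but are not emitted as ordered interfaces (default 0: emit all).
#' @param chains Optional character vector of all chain ids (defaults to
#'   those appearing in `ifaces`); chains without interfaces form their own
#'   connected components.
#' @return An object of class `assembly_pathway`: list with `steps` (tibble
#'   of `step`, `component_a`, `component_b`, `gained_bsa`), `order` (tibble
#'   of `chain_a`, `chain_b`, `bsa`, `step`, `normalized_order`, `label`),
#'   `S` (total step count) and `n_subunits`. Use [tidy()] for the
#'   per-interface order table.
#' @export
predict_assembly_pathway <- function(ifaces, area_col = "bsa_total",
                                     min_area = 0, chains = NULL) {
  if (nrow(ifaces) == 0) stop("no interfaces: cannot predict a pathway")
  ed <- tibble(
    a = as.character(ifaces$chain_a), b = as.character(ifaces$chain_b),
    bsa = ifaces[[area_col]]
  )
  stopifnot(all(ed$bsa > 0))
  chains <- sort(unique(c(chains, ed$a, ed$b)))
  comp <- as.list(chains)        # current components (sets of chain ids)
  steps <- list()
  formed <- integer(nrow(ed))    # step at which each interface forms
  s <- 0L
  repeat {
    if (length(comp) == 1) break
    ## gain for every component pair
    best <- NULL
    for (i in seq_along(comp)) {
      for (j in seq_len(i - 1L)) {
        cross <- (ed$a %in% comp[[i]] & ed$b %in% comp[[j]]) |
          (ed$a %in% comp[[j]] & ed$b %in% comp[[i]])
        gain <- sum(ed$bsa[cross])
        if (gain <= 0) next
        key <- sort(c(min(comp[[i]]), min(comp[[j]])))
        if (is.null(best) || gain > best$gain + 1e-9 ||
            (abs(gain - best$gain) <= 1e-9 &&
             paste(key, collapse = " ") < paste(best$key, collapse = " "))) {
          best <- list(i = i, j = j, gain = gain, key = key, cross = cross)
        }
      }
    }
    if (is.null(best)) break     # remaining components are disconnected
    s <- s + 1L
    steps[[s]] <- tibble(
      step = s,
      component_a = paste(sort(comp[[best$i]]), collapse = "+"),
      component_b = paste(sort(comp[[best$j]]), collapse = "+"),
      gained_bsa = best$gain
    )
    formed[best$cross & formed == 0L] <- s
    comp[[best$i]] <- sort(c(comp[[best$i]], comp[[best$j]]))
    comp[[best$j]] <- NULL
  }
  S <- s
  ord <- tibble(
    chain_a = ed$a, chain_b = ed$b, bsa = ed$bsa, step = formed,
    normalized_order = if (S <= 1) rep(0, nrow(ed)) else
      (formed - 1) / (S - 1)
  )
  ord$label <- classify_step(ord$normalized_order)
  emit <- ord$bsa > min_area
  structure(
    list(steps = dplyr::bind_rows(steps), order = ord[emit, , drop = FALSE],
         S = S, n_subunits = length(chains)),
    class = "assembly_pathway"
  )
}

#' Early/late classification of normalised assembly order
#'
#' The normalised assembly order places an interface's formation step on a
#' 0-to-1 scale from the first to the last step of the predicted pathway;
#' steps at or below 0.5 are "early".
#'
#' @param normalized_order Values in \[0, 1\].
#' @return Character vector, `"early"` or `"late"`.
#' @export
classify_step <- function(normalized_order) {
  stopifnot(all(normalized_order >= 0 & normalized_order <= 1))
  ifelse(normalized_order <= 0.5, "early", "late")
}

#' @export
print.assembly_pathway <- function(x, ...) {
  cat("Assembly pathway:", x$n_subunits, "subunits,", x$S, "steps\n")
  print(x$steps)
  invisible(x)
}

#' @describeIn predict_assembly_pathway Per-interface order table: `chain_a`,
#'   `chain_b`, `bsa`, `step`, `normalized_order`, `label`.
#' @param x An `assembly_pathway`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.assembly_pathway <- function(x, ...) as_tibble(x$order)

#' @describeIn predict_assembly_pathway One-row summary: `n_subunits`, `S`,
#'   `n_interfaces`, `total_bsa`.
#' @exportS3Method generics::glance
glance.assembly_pathway <- function(x, ...) {
  tibble(n_subunits = x$n_subunits, S = x$S,
         n_interfaces = nrow(x$order), total_bsa = sum(x$order$bsa))
}
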