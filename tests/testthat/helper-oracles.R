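## Independent oracles and fixture builders. Everything here is kept
## code-path-independent of the package implementation it checks.

## Minimal atom tibble for bead fixtures.
bead_atoms <- function(xyz, radius = 3.0, aa = "A", chain = "A",
                       seq_pos = NULL) {
  xyz <- matrix(xyz, ncol = 3)
  n <- nrow(xyz)
  tibble::tibble(
    chain = rep_len(chain, n), protein_id = rep_len(chain, n),
    seq_pos = seq_pos %||% seq_len(n),
    aa = rep_len(aa, n),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    radius = radius
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Closed-form accessible areas of two intersecting probe-expanded spheres
## (spherical-cap formula).
two_sphere_asa <- function(r1, r2, d, probe = 1.4) {
  R1 <- r1 + probe; R2 <- r2 + probe
  stopifnot(d < R1 + R2, d > abs(R1 - R2))
  x <- (d^2 + R1^2 - R2^2) / (2 * d)
  h1 <- R1 - x
  h2 <- R2 - (d - x)
  c(4 * pi * R1^2 - 2 * pi * R1 * h1,
    4 * pi * R2^2 - 2 * pi * R2 * h2)
}

## Monte-Carlo SASA: uniform random directions (Marsaglia normal trick),
## a different point set and code path from the deterministic lattice.
mc_sasa_oracle <- function(xyz, radii, probe = 1.4, n_mc = 20000,
                           seed = 42) {
  xyz <- as.matrix(xyz)
  withr::with_seed(seed, {
    n <- nrow(xyz)
    R <- radii + probe
    vapply(seq_len(n), function(i) {
      dirs <- matrix(stats::rnorm(3 * n_mc), ncol = 3)
      dirs <- dirs / sqrt(rowSums(dirs^2))
      px <- dirs[, 1] * R[i] + xyz[i, 1]
      py <- dirs[, 2] * R[i] + xyz[i, 2]
      pz <- dirs[, 3] * R[i] + xyz[i, 3]
      acc <- rep(TRUE, n_mc)
      for (j in seq_len(n)[-i]) {
        acc <- acc & ((px - xyz[j, 1])^2 + (py - xyz[j, 2])^2 +
                        (pz - xyz[j, 3])^2 > R[j]^2)
      }
      4 * pi * R[i]^2 * mean(acc)
    }, numeric(1))
  })
}

## Random bead heterotrimer plan: non-overlapping 15-residue blocks per
## chain host one contact window per planned pair.
random_trimer_spec <- function(seed) {
  withr::with_seed(seed, {
    lens <- c(A = 45, B = 45, C = 45)
    prs <- list(c("A", "B"), c("B", "C"), c("A", "C"))
    use <- c(TRUE, TRUE, stats::runif(1) < 0.5)
    nxt <- c(A = 1, B = 1, C = 1)
    rows <- list()
    for (k in seq_along(prs)) {
      if (!use[k]) next
      a <- prs[[k]][1]; b <- prs[[k]][2]
      wl <- sample(6:12, 2, replace = TRUE)
      sa <- (nxt[[a]] - 1) * 15 + 1
      sb <- (nxt[[b]] - 1) * 15 + 1
      nxt[[a]] <- nxt[[a]] + 1; nxt[[b]] <- nxt[[b]] + 1
      rows[[length(rows) + 1]] <- tibble::tibble(
        chain_a = a, chain_b = b,
        start_a = sa, end_a = sa + wl[1] - 1,
        start_b = sb, end_b = sb + wl[2] - 1
      )
    }
    cotasm::complex_spec(chains = lens,
                         interfaces = dplyr::bind_rows(rows))
  })
}

## Exhaustive enumeration of merge sequences; the optimal pathway is the
## one whose stepwise-gain sequence is lexicographically maximal.
enumerate_merge_orders <- function(edges, chains) {
  rec <- function(comp, formed, gains, step) {
    if (length(comp) == 1) return(list(list(gains = gains, formed = formed)))
    out <- list()
    for (i in seq_along(comp)) {
      for (j in seq_len(i - 1)) {
        cross <- (edges$a %in% comp[[i]] & edges$b %in% comp[[j]]) |
          (edges$a %in% comp[[j]] & edges$b %in% comp[[i]])
        g <- sum(edges$bsa[cross])
        if (g <= 0) next
        comp2 <- comp
        comp2[[i]] <- c(comp[[i]], comp[[j]])
        comp2[[j]] <- NULL
        f2 <- formed
        f2[cross & f2 == 0] <- step
        out <- c(out, rec(comp2, f2, c(gains, g), step + 1L))
      }
    }
    out
  }
  rec(as.list(chains), integer(nrow(edges)), numeric(0), 1L)
}

oracle_assembly_steps <- function(edges, chains) {
  all_paths <- enumerate_merge_orders(edges, chains)
  best <- NULL
  for (p in all_paths) {
    if (is.null(best)) { best <- p; next }
    k <- which(p$gains != best$gains)[1]
    if (!is.na(k) && p$gains[k] > best$gains[k]) best <- p
  }
  best
}

## Fixed-width PDB ATOM line (Brookhaven columns).
pdb_line <- function(serial, name, alt, resname, chain, resno, x, y, z,
                     element = "C") {
  sprintf("ATOM  %5d  %-3s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, alt, resname, chain, resno, x, y, z, 1, 0, element)
}
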