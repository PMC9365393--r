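test_that("distant chains form no interface and no contacts", {
  atoms <- dplyr::bind_rows(
    bead_atoms(cbind(8 * (1:10), 0, 0), chain = "A"),
    bead_atoms(cbind(8 * (1:10), 100, 0), chain = "B")
  )
  st <- cotasm:::new_structure(atoms, "far")
  expect_equal(nrow(pairwise_interfaces(st)), 0)
  ## even with the cutoff off, separation > 2*(r + 2*probe) buries nothing
  expect_equal(nrow(pairwise_interfaces(st, min_area = 0)), 0)
  expect_equal(nrow(residue_contacts(st, "A", "B", cutoff = 5.5)), 0)
})

test_that("a mirror-symmetric homodimer buries equal areas on both sides", {
  xyz_a <- cbind(4 * (1:12), 0, 0)
  xyz_b <- cbind(4 * (1:12), 4.2, 0)
  atoms <- dplyr::bind_rows(
    bead_atoms(xyz_a, chain = "A"),
    bead_atoms(xyz_b, chain = "B")
  )
  atoms$protein_id <- "same"
  st <- cotasm:::new_structure(atoms, "dimer")
  i <- pairwise_interfaces(st, min_area = 0)
  expect_equal(nrow(i), 1)
  expect_true(i$homomeric)
  expect_equal(i$bsa_a, i$bsa_b, tolerance = 0.02)
})

test_that("pair BSA equals the brute-force per-residue ASA-difference sum", {
  st <- generate_complex(random_trimer_spec(101))
  ifc <- pairwise_interfaces(st, min_area = 0)
  for (k in seq_len(nrow(ifc))) {
    a <- ifc$chain_a[k]; b <- ifc$chain_b[k]
    ## independent route: raw per-residue ASA in isolation vs in the pair
    for (side in c(a, b)) {
      iso <- compute_sasa(st[st$chain == side, ])
      ctx <- compute_sasa(st[st$chain %in% c(a, b), ])
      ctx <- ctx[ctx$chain == side, ]
      brute <- sum(pmax(iso$asa - ctx$asa[match(iso$seq_pos, ctx$seq_pos)], 0))
      got <- if (side == a) ifc$bsa_a[k] else ifc$bsa_b[k]
      expect_equal(got, brute, tolerance = 1e-6)
    }
  }
  ## conservation: nested per-residue detail sums back to the side totals
  res <- ifc$residues[[1]]
  expect_equal(sum(res$bsa[res$side == "a"]), ifc$bsa_a[1],
               tolerance = 1e-6)
  expect_equal(sum(res$bsa[res$side == "b"]), ifc$bsa_b[1],
               tolerance = 1e-6)
})

test_that("interface midpoint follows the cumulative half-area rule", {
  expect_equal(interface_midpoint(42L, 100), 42L)
  expect_equal(interface_midpoint(5:8, c(10, 10, 10, 10)), 6L)
  expect_equal(interface_midpoint(c(1L, 9L), c(30, 10)), 1L)
  ## invariant to uniform scaling and to input order
  pos <- c(3L, 10L, 20L, 31L); bsa <- c(5, 40, 10, 20)
  m <- interface_midpoint(pos, bsa)
  expect_equal(interface_midpoint(pos, 1000 * bsa), m)
  o <- c(4, 2, 1, 3)
  expect_equal(interface_midpoint(pos[o], bsa[o]), m)
})

test_that("relative location, translational distance and size difference", {
  expect_equal(relative_interface_location(1, 100), 0)
  expect_equal(relative_interface_location(100, 100), 1)
  expect_equal(relative_interface_location(51, 101), 0.5)
  expect_error(relative_interface_location(1, 1), ">= 2")
  expect_equal(terminal_half(c(50, 52), 101), c("N", "C"))

  expect_equal(relative_translational_distance(10, 110, 200), 0.5)
  expect_equal(relative_translational_distance(7, 7, 50), 0)
  expect_equal(relative_translational_distance(1, 400, 400), 0.9975)
  expect_error(relative_translational_distance(10, 5, 50))

  expect_equal(relative_size_difference(4226, 484), 3742 / 4710,
               tolerance = 1e-9)
  expect_equal(relative_size_difference(500, 500), 0)
  expect_equal(relative_size_difference(0, 123), -1)
  expect_error(relative_size_difference(0, 0))
  ## antisymmetry
  withr::with_seed(5, {
    x <- stats::runif(20, 1, 5000); y <- stats::runif(20, 1, 5000)
  })
  expect_equal(relative_size_difference(x, y),
               -relative_size_difference(y, x))
})

test_that("apolar area sums buried area over the apolar residue set", {
  all_leu <- tibble::tibble(aa = c("L", "L"), bsa = c(60, 40))
  expect_equal(apolar_area(all_leu), 100)
  charged <- tibble::tibble(aa = c("D", "E", "K"), bsa = c(50, 20, 30))
  expect_equal(apolar_area(charged), 0)
  mixed <- tibble::tibble(aa = c("L", "D"), bsa = c(100, 50))
  expect_equal(apolar_area(mixed), 100)
})

make_profile <- function(partner, first_res, last_res, bsa,
                         homomeric = FALSE) {
  tibble::tibble(
    complex_id = "cx", chain = "A", protein_id = "pA", partner = partner,
    partner_protein = partner, homomeric = homomeric, bsa = bsa,
    apolar = 0, midpoint = as.integer((first_res + last_res) / 2),
    first_res = as.integer(first_res), last_res = as.integer(last_res),
    L = 400L, rel_location = NA_real_, half = NA_character_
  )
}

test_that("first and last translated interfaces follow the extreme residues", {
  prof <- make_profile(c("X", "Y"), c(10, 150), c(200, 300), c(2000, 1500))
  fl <- first_last_interfaces(prof)
  expect_equal(fl$first_partner, "X")
  expect_equal(fl$last_partner, "Y")
  expect_equal(fl$f_first, 10L)
  expect_equal(fl$f_last, 150L)
  expect_false(fl$nested)
  expect_equal(fl$rel_size_diff,
               relative_size_difference(2000, 1500))

  ## fully nested interfaces: first and last coincide, flagged for exclusion
  nested <- make_profile(c("X", "Y"), c(10, 150), c(300, 200), c(2000, 1500))
  fl2 <- first_last_interfaces(nested)
  expect_true(fl2$nested)
  expect_true(is.na(fl2$rel_size_diff))

  ## tie on the extreme residue goes to the larger interface
  tied <- make_profile(c("X", "Y"), c(10, 10), c(200, 300), c(500, 2500))
  fl3 <- first_last_interfaces(tied)
  expect_equal(fl3$first_partner, "Y")

  ## single retained interface: not a multi-interface subunit
  single <- make_profile(c("X", "Y"), c(10, 150), c(200, 300), c(2000, 300))
  expect_equal(nrow(first_last_interfaces(single)), 0)
})

test_that("chain buried area against the full complex is attribution-free", {
  st <- generate_complex(random_trimer_spec(7))
  full <- chain_buried_area(st)
  pairs <- pairwise_interfaces(st, min_area = 0)
  ## with site-separated pairwise contacts the full-complex context is the
  ## sum of pair contexts
  for (ch in unique(st$chain)) {
    pair_sum <- sum(pairs$bsa_a[pairs$chain_a == ch]) +
      sum(pairs$bsa_b[pairs$chain_b == ch])
    expect_equal(full$bsa[full$chain == ch], pair_sum, tolerance = 1e-6)
  }
})
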