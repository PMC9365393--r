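test_that("synthetic structures survive a write/read round trip", {
  spec <- complex_spec(
    chains = c(A = 10, B = 10),
    interfaces = tibble::tibble(chain_a = "A", chain_b = "B",
                                start_a = 1, end_a = 8,
                                start_b = 1, end_b = 8)
  )
  st <- generate_complex(spec)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(st, path)
  back <- read_structure(path, radii = c(C = 3.0))

  expect_equal(length(unique(back$chain)), 2)
  expect_equal(nrow(back), 20)
  expect_equal(back$seq_pos, st$seq_pos)
  expect_equal(back$chain, st$chain)
  expect_equal(back$aa, st$aa)
  expect_equal(back$x, st$x, tolerance = 1e-3)
  expect_equal(back$y, st$y, tolerance = 1e-3)
  expect_equal(back$z, st$z, tolerance = 1e-3)
  expect_equal(unique(back$radius), 3.0)
})

test_that("altloc duplicates, heteroatoms and hydrogens are excluded", {
  lines <- c(
    pdb_line(1, "CA", " ", "ALA", "A", 1, 0, 0, 0),
    pdb_line(2, "CA", "A", "ALA", "A", 2, 4, 0, 0),
    pdb_line(3, "CA", "B", "ALA", "A", 2, 4.5, 0, 0),  # second altloc
    pdb_line(4, "CA", " ", "MSE", "A", 3, 8, 0, 0),
    pdb_line(5, "H", " ", "ALA", "A", 1, 0, 1, 0, element = "H"),
    sub("^ATOM  ", "HETATM", pdb_line(6, "O", " ", "HOH", "A", 90, 9, 9, 9,
                                      element = "O")),
    "TER", "END"
  )
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, path)
  st <- read_structure(path)

  expect_equal(nrow(st), 3)                      # altloc B, H, HOH dropped
  expect_equal(sum(st$seq_pos == 2), 1)          # first altloc kept
  expect_equal(st$x[st$seq_pos == 2], 4, tolerance = 1e-6)
  ## selenomethionine maps to canonical M but stays flagged nonstandard
  expect_equal(st$aa[st$seq_pos == 3], "M")
  expect_true(st$nonstandard[st$seq_pos == 3])
  expect_error(read_structure(withr::local_tempfile(fileext = ".pdb")),
               "not found")
})

test_that("representative chain selection follows the lexicographic keys", {
  base <- tibble::tibble(
    protein_id = "P1",
    complex_id = c("1abc", "2xyz"),
    chain = c("A", "B")
  )
  pick <- function(k1, k2, k3) {
    cand <- dplyr::mutate(base, seq_identity = k1, n_unique_subunits = k2,
                          n_atoms = k3)
    select_representative_chain(cand)$chain
  }
  expect_equal(pick(c(0.95, 0.99), c(2, 1), c(800, 500)), "B")  # identity wins
  expect_equal(pick(c(0.95, 0.95), c(2, 3), c(800, 100)), "B")  # subunits next
  expect_equal(pick(c(0.95, 0.95), c(2, 2), c(800, 900)), "B")  # atoms last
  expect_equal(pick(c(0.95, 0.95), c(2, 2), c(800, 800)), "A")  # complex id tie

  ## permutation invariance
  cand <- tibble::tibble(
    protein_id = "P1", complex_id = c("3q", "1a", "2b"),
    chain = c("X", "Y", "Z"),
    seq_identity = c(0.9, 0.95, 0.95),
    n_unique_subunits = c(5, 3, 3), n_atoms = c(900, 700, 400)
  )
  for (perm in list(1:3, 3:1, c(2, 3, 1))) {
    expect_equal(select_representative_chain(cand[perm, ])$chain, "Y")
  }
  expect_error(select_representative_chain(cand[0, ]), "empty")
})

make_ifaces <- function(chain, partners, bsa) {
  tibble::tibble(
    complex_id = "cx", chain_a = chain, chain_b = partners,
    homomeric = FALSE, bsa_a = bsa, bsa_b = bsa, bsa_total = 2 * bsa,
    apolar_a = 0, apolar_b = 0, midpoint_a = 10L, midpoint_b = 10L,
    first_res_a = 5L, last_res_a = 20L, first_res_b = 5L, last_res_b = 20L
  )
}

test_that("complex filters fire on the documented rules", {
  chains <- tibble::tibble(chain = c("A", "B", "C"),
                           protein_id = c("pA", "pB", "pC"),
                           observed_count = c(100L, 100L, 100L),
                           L = c(100L, 100L, 100L), L_source = "observed")
  ifaces <- make_ifaces("A", c("B", "C"), c(900, 850))

  rep <- filter_complex(ifaces, chains)
  expect_true(rep$passed[rep$chain == "A"])
  expect_equal(rep$reasons[rep$chain == "A"][[1]], character(0))

  ## 65% complete chain
  chains2 <- chains
  chains2$observed_count[1] <- 65L
  rep2 <- filter_complex(ifaces, chains2)
  expect_false(rep2$passed[rep2$chain == "A"])
  expect_true("chain_incomplete" %in% rep2$reasons[rep2$chain == "A"][[1]])

  ## ten-subunit complex
  chains10 <- tibble::tibble(chain = LETTERS[1:10], protein_id = LETTERS[1:10],
                             observed_count = 100L, L = 100L,
                             L_source = "observed")
  rep10 <- filter_complex(make_ifaces("A", c("B", "C"), c(900, 850)), chains10)
  expect_true(all(!rep10$passed))
  expect_true(all(purrr::map_lgl(rep10$reasons,
                                 ~ "too_many_subunits" %in% .x)))

  ## only one partner above 800, and a short chain
  rep3 <- filter_complex(make_ifaces("A", c("B", "C"), c(900, 700)), chains)
  expect_true("too_few_large_interfaces" %in%
                rep3$reasons[rep3$chain == "A"][[1]])
  chains_short <- dplyr::mutate(chains,
                                observed_count = c(50L, 100L, 100L),
                                L = c(50L, 100L, 100L))
  rep4 <- filter_complex(ifaces, chains_short)
  expect_true("short_chain" %in% rep4$reasons[rep4$chain == "A"][[1]])
})

test_that("relaxing a filter threshold never adds a reason", {
  chains <- tibble::tibble(chain = c("A", "B", "C"),
                           protein_id = c("pA", "pB", "pC"),
                           observed_count = c(60L, 100L, 100L),
                           L = c(100L, 100L, 100L), L_source = "observed")
  ifaces <- make_ifaces("A", c("B", "C"), c(900, 700))
  strict <- filter_complex(ifaces, chains, filter_config())
  relaxed <- filter_complex(ifaces, chains,
                            filter_config(min_completeness = 0.5,
                                          large_iface = 600,
                                          max_subunits = 20,
                                          min_chain_len = 20))
  for (ch in chains$chain) {
    expect_true(all(relaxed$reasons[relaxed$chain == ch][[1]] %in%
                      strict$reasons[strict$chain == ch][[1]]))
  }
})
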