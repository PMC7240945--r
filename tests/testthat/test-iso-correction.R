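test_that("formula parsing handles Hill notation and rejects unknowns", {
  expect_equal(parse_formula("C2H5NO2"),
               c(C = 2L, H = 5L, N = 1L, O = 2L, S = 0L))
  expect_equal(parse_formula("C4H9NO3S")[["S"]], 1L)
  expect_error(parse_formula("C2XeO2"), "unknown element")
  expect_error(metabolite_spec("x", "C2H5NO2", n_tracer = 2), "must equal")
})

test_that("zero natural abundance and purity 1 give the identity matrix", {
  ab0 <- natural_abundance()
  for (el in names(ab0)) ab0[[el]] <- c(1, rep(0, length(ab0[[el]]) - 1L))
  sp <- metabolite_spec("Gln", "C5H10N2O3")
  m <- build_correction_matrix(sp, purity = 1, mode = "full", abundances = ab0)
  expect_equal(m$entries, diag(3), tolerance = 1e-15)
})

test_that("1-N tracer_only matrix matches the hand binomial convolution", {
  sp <- metabolite_spec("Gly", "C2H5NO2")
  m <- build_correction_matrix(sp, purity = 0.98, mode = "tracer_only")
  expect_equal(m$entries[, 1], c(0.99636, 0.00364), tolerance = 1e-12)
  expect_equal(m$entries[, 2], c(0.02, 0.98), tolerance = 1e-12)
})

test_that("full-mode columns match brute-force isotopic enumeration", {
  ab <- natural_abundance()
  # glycine column 0 row 1: probability of exactly one heavy atom
  sp <- metabolite_spec("Gly", "C2H5NO2")
  m <- build_correction_matrix(sp, purity = 1, mode = "full", abundances = ab)
  oracle <- enumerate_envelope(
    molecule_atom_dists(sp$counts, 0L, 1, ab, "full"), sp$n_tracer)
  expect_equal(m$entries[, 1], oracle, tolerance = 1e-12)
  # random small formulas, every column, <= 10 atoms (enumeration oracle)
  set.seed(11)
  for (rep_i in 1:5) {
    f <- random_formula()
    sp <- metabolite_spec(paste0("m", rep_i), f)
    purity <- stats::runif(1, 0.9, 1)
    m <- build_correction_matrix(sp, purity = purity, mode = "full",
                                 abundances = ab)
    for (j in 0:sp$n_tracer) {
      oracle <- enumerate_envelope(
        molecule_atom_dists(sp$counts, j, purity, ab, "full"), sp$n_tracer)
      expect_equal(m$entries[, j + 1], oracle, tolerance = 1e-12)
    }
  }
})

test_that("column sums: tracer_only stochastic, full mode <= 1", {
  sp <- metabolite_spec("Gln", "C5H10N2O3")
  m1 <- build_correction_matrix(sp, purity = 0.98, mode = "tracer_only")
  expect_equal(colSums(m1$entries), rep(1, 3), tolerance = 1e-12)
  m2 <- build_correction_matrix(sp, purity = 0.98, mode = "full")
  expect_true(all(colSums(m2$entries) <= 1 + 1e-12))
  expect_true(all(m2$entries >= 0))
})

test_that("degenerate purity and bad abundances are rejected", {
  sp <- metabolite_spec("Gly", "C2H5NO2")
  expect_error(build_correction_matrix(sp, purity = 0), "purity")
  ab <- natural_abundance()
  ab$N <- c(0.5, 0.4) # does not sum to 1
  expect_error(build_correction_matrix(sp, abundances = ab), "sum to 1")
})

test_that("correct_vector round-trips constructed raw vectors", {
  sp <- metabolite_spec("Gly", "C2H5NO2")
  m <- build_correction_matrix(sp, purity = 0.98)
  raw <- as.numeric(m$entries %*% c(0.3, 0.7))
  expect_equal(correct_vector(raw, m), c(0.3, 0.7), tolerance = 1e-10)
  # property: random formulas and random distributions, both modes
  set.seed(42)
  ab <- natural_abundance()
  for (rep_i in 1:25) {
    sp <- metabolite_spec(paste0("m", rep_i), random_formula())
    mode <- sample(c("tracer_only", "full"), 1)
    m <- build_correction_matrix(sp, purity = stats::runif(1, 0.9, 1),
                                 mode = mode, abundances = ab)
    x <- random_simplex(sp$n_tracer + 1L)
    raw <- as.numeric(m$entries %*% x)
    expect_equal(correct_vector(raw, m), x, tolerance = 1e-8)
  }
})

test_that("correct_vector enforces nonnegativity and normalization", {
  sp <- metabolite_spec("Gly", "C2H5NO2")
  m <- build_correction_matrix(sp, purity = 0.98)
  # identity-like behaviour
  m_id <- m
  m_id$entries <- diag(2)
  expect_equal(correct_vector(c(0.5, 0.5), m_id), c(0.5, 0.5))
  # small negative noise floor is clipped upstream of the solve
  raw <- as.numeric(m$entries %*% c(0.999, 0.001)) + c(0, -1e-4)
  out <- correct_vector(raw, m)
  expect_true(all(out >= 0))
  expect_equal(sum(out), 1, tolerance = 1e-12)
  expect_error(correct_vector(c(0, 0), m), "empty measurement")
  expect_error(correct_vector(c(0.2, 0.3, 0.5), m), "does not match")
})

test_that("mean_enrichment follows its definition and contract", {
  expect_equal(mean_enrichment(c(0.2, 0.8)), 0.8)
  expect_equal(mean_enrichment(c(0.25, 0.5, 0.25)), 0.5)
  expect_error(mean_enrichment(c(0.5, 0.2)), "summing to 1")
  # fully labeled 1-N substrate, purity-corrected, recovers 1.0
  sp <- metabolite_spec("Gly", "C2H5NO2")
  m <- build_correction_matrix(sp, purity = 0.98)
  raw <- as.numeric(m$entries %*% c(0, 1))
  expect_equal(mean_enrichment(correct_vector(raw, m)), 1.0,
               tolerance = 1e-10)
})

test_that("raising the heaviest raw fraction never lowers corrected enrichment", {
  set.seed(7)
  sp <- metabolite_spec("Gln", "C5H10N2O3")
  m <- build_correction_matrix(sp, purity = 0.98)
  for (rep_i in 1:20) {
    raw <- random_simplex(3)
    bumped <- raw
    bumped[3] <- bumped[3] + 0.2
    bumped <- bumped / sum(bumped)
    e1 <- mean_enrichment(correct_vector(raw, m))
    e2 <- mean_enrichment(correct_vector(bumped, m))
    expect_gte(e2, e1 - 1e-10)
  }
})

test_that("correct_isotopologues handles a long table and flags problems", {
  reg <- default_registry()
  raw_tbl <- tibble::tibble(
    sample_id = "s1", leaf_rank = "L15", replicate = 1L, time_min = 30,
    metabolite = "Gly", isotopologue_index = 0:1,
    mass_fraction = c(0.4, 0.6), status = "raw"
  )
  out <- correct_isotopologues(raw_tbl, reg)
  expect_equal(nrow(out), 2L)
  expect_equal(sum(out$mass_fraction), 1, tolerance = 1e-12)
  expect_equal(unique(out$status), "corrected")
  expect_equal(out$enrichment[1],
               mean_enrichment(out$mass_fraction), tolerance = 1e-12)
  bad <- dplyr::mutate(raw_tbl, metabolite = "Unknown")
  expect_error(correct_isotopologues(bad, reg), "absent from registry")
  expect_error(
    correct_isotopologues(dplyr::mutate(raw_tbl, status = "corrected"), reg),
    "raw")
})
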