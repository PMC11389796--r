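test_that("fingerprints are deterministic with well-formed environments", {
  cfg <- fingerprint_config(n_bits = 512, radius = 2)
  # methane: one heavy atom -> only radius-0, single-atom environments
  fp <- fingerprint("C", cfg)
  expect_true(all(vapply(fp$environments, `[[`, integer(1), "radius") == 0L))
  expect_true(all(lengths(lapply(fp$environments, `[[`, "atoms")) == 1L))
  expect_equal(sum(fp$bits), length(fp$on_bits))

  # determinism
  expect_identical(fingerprint("c1ccccc1Cl", cfg), fingerprint("c1ccccc1Cl", cfg))

  # CCO: all environments inside the 3 atoms, radius bounded by cfg
  fp <- fingerprint("CCO", cfg)
  expect_equal(fp$n_atoms, 3L)
  for (e in fp$environments) {
    expect_true(all(e$atoms %in% 1:3))
    expect_lte(e$radius, 2L)
    expect_true(e$center %in% e$atoms)
    expect_true(e$bit %in% fp$on_bits)
  }
  expect_error(fingerprint("C1CC", cfg), "ring closure")
})

test_that("fingerprint_matrix stacks per-molecule bit vectors", {
  cfg <- fingerprint_config(n_bits = 64)
  X <- fingerprint_matrix(c("CCO", "CCN"), cfg)
  expect_equal(dim(X), c(2L, 64L))
  expect_equal(unname(X[1, ]), fingerprint("CCO", cfg)$bits)
  expect_true(all(X %in% c(0L, 1L)))
})

test_that("weight attribution divides evenly and conserves the bit total", {
  # bit 7 carries +0.4 on a single-atom environment; bit 12 carries -0.9
  # on a three-atom environment -> atoms (0.1, -0.3, -0.3), total -0.5
  w <- numeric(16); w[7] <- 0.4; w[12] <- -0.9
  fp <- list(environments = list(list(bit = 7L, center = 1L, radius = 0L, atoms = 1L),
                                 list(bit = 12L, center = 2L, radius = 1L, atoms = 1:3)),
             n_atoms = 3L)
  at <- attribute_weights_to_atoms(w, fp)
  expect_equal(at$atom_attribution, c(0.1, -0.3, -0.3))
  expect_equal(at$total, -0.5)
  expect_lt(abs(at$conservation_residual), 1e-12)

  # single bit, single atom: full weight lands on that atom
  fp1 <- list(environments = list(list(bit = 3L, center = 1L, radius = 0L, atoms = 1L)),
              n_atoms = 1L)
  expect_equal(attribute_weights_to_atoms(c(0, 0, 0.4), fp1)$atom_attribution, 0.4)

  # collision: two environments on one bit share its weight equally
  fpc <- list(environments = list(list(bit = 5L, center = 1L, radius = 0L, atoms = 1L),
                                  list(bit = 5L, center = 2L, radius = 0L, atoms = 2L)),
              n_atoms = 2L)
  atc <- attribute_weights_to_atoms(c(0, 0, 0, 0, 1), fpc)
  expect_equal(atc$atom_attribution, c(0.5, 0.5))
  expect_equal(atc$total, 1)

  bad <- list(environments = list(list(bit = 1L, center = 1L, radius = 0L, atoms = 4L)),
              n_atoms = 2L)
  expect_error(attribute_weights_to_atoms(1, bad), "nonexistent atom")
})

test_that("conservation holds on real molecules with random weights", {
  cfg <- fingerprint_config(n_bits = 32)     # small n_bits forces collisions
  set.seed(7)
  recs <- generate_molecules(25, seed = 31)
  saw_collision <- FALSE
  for (sm in recs$smiles) {
    fp <- fingerprint(sm, cfg)
    bit_of <- vapply(fp$environments, `[[`, integer(1), "bit")
    if (anyDuplicated(bit_of)) saw_collision <- TRUE
    w <- rnorm(cfg$n_bits)
    at <- attribute_weights_to_atoms(w, fp)
    expect_lt(abs(at$conservation_residual), 1e-10)
    expect_equal(at$total, sum(w[fp$on_bits]), tolerance = 1e-10)
  }
  expect_true(saw_collision)

  # all-negative weights imply all atom attributions <= 0
  fp <- fingerprint("OCC(C)N", cfg)
  at <- attribute_weights_to_atoms(-abs(rnorm(cfg$n_bits)), fp)
  expect_true(all(at$atom_attribution <= 0))
})

test_that("robust scaling centers by the median and spans p10-p90", {
  s <- robust_scale(0:10)
  expect_equal(s$center, 5)
  expect_equal(s$scale, 8)          # p90 = 9, p10 = 1 by linear interpolation
  expect_equal(s$scaled[10], 0.5)   # y = 9
  expect_equal(robust_unscale(s$scaled, s), as.numeric(0:10), tolerance = 1e-12)

  expect_error(robust_scale(rep(2, 5)), "distinct")
  # distinct values but coincident percentiles: scale undefined
  expect_error(robust_scale(c(0, rep(5, 30), 10)), "percentiles")
})
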