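test_that("classification follows the gate precedence on constructed ions", {
  gates <- population_gates(empty_mass_window = 0.02)
  full <- 4.9105e6
  empty <- 3.8605e6
  meas <- data.frame(
    mass_da = c(4.91e6, 3.86e6, 9.82e6, 5.4e6, 2.0e6, 2.0e6),
    charge_e = c(165, 160, 250, 170, 100, 30))
  # fragment at 2 MDa: Rayleigh limit ~111 e, so 100 e is in band, 30 e is not
  labels <- classify_ions(meas, full, empty_mass_da = empty, gates = gates)
  expect_identical(labels, c("INTACT_FULL", "EMPTY", "DIMER", "AGGREGATE",
                             "FRAGMENT", "UNASSIGNED"))
  # without an empty species the EMPTY gate is off
  l2 <- classify_ions(meas[2, ], full, gates = gates)
  expect_false(identical(l2, "EMPTY"))
  expect_identical(classify_ions(meas[0, ], full), character(0))
})

test_that("classification is deterministic and permutation-invariant", {
  sc <- build_scenario("freeze_thaw")
  ens <- sample_ion_ensemble(sc, 800, seed = 12)
  meas <- measurements_from_truth(ens, seed = 13)
  l1 <- classify_ions(meas, sc$full_mass_da)
  perm <- sample(nrow(meas))
  l2 <- classify_ions(meas[perm, ], sc$full_mass_da)
  expect_identical(l2, l1[perm])
  expect_identical(l1, classify_ions(meas, sc$full_mass_da))
})

test_that("classified fragments satisfy the sub-Rayleigh charge gate", {
  sc <- build_scenario("aa_ph4_37c")
  meas <- measurements_from_truth(sample_ion_ensemble(sc, 3000, seed = 14),
                                  seed = 15)
  labels <- classify_ions(meas, sc$full_mass_da)
  fr <- meas[labels == "FRAGMENT", ]
  expect_gt(nrow(fr), 100)
  expect_true(all(fr$charge_e <= 1.02 * rayleigh_charge_for_mass(fr$mass_da)))
})

test_that("population fractions sum to one", {
  expect_error(population_fractions(character(0)), "non-empty")
  expect_identical(population_fractions(rep("INTACT_FULL", 5)),
                   c(INTACT_FULL = 1))
  set.seed(16)
  labs <- sample(c("A", "B", "C"), 200, TRUE)
  expect_equal(sum(population_fractions(labs)), 1)
})

test_that("bound-ligand counting is exact on noiseless masses", {
  expect_identical(estimate_bound_count(5.10e6, 4.60e6, 3.4e4), 15L)
  expect_identical(estimate_bound_count(4.94e6, 4.60e6, 3.4e4), 10L)
  expect_identical(estimate_bound_count(4.6e6, 4.6e6, 3.4e4), 0L)
  n <- 0:50
  expect_identical(estimate_bound_count(4.6e6 + n * 3.4e4, 4.6e6, 3.4e4), n)
  clamped <- estimate_bound_count(4.5e6, 4.6e6, 3.4e4)
  expect_identical(as.integer(clamped), 0L)
  expect_true(attr(clamped, "clamped"))
  expect_error(estimate_bound_count(5e6, 4.6e6, 0), "outside")
})

test_that("charge-versus-bound trend recovers the configured slope", {
  # noiseless two-point line: exact -8/3
  two <- data.frame(mass_da = 4.6e6 + c(0, 15) * 3.4e4,
                    charge_e = c(160, 120))
  sl <- charge_vs_bound_slope(two, 4.6e6, 3.4e4)
  expect_equal(sl$slope_e_per_ligand, -8 / 3, tolerance = 1e-12)
  expect_equal(sl$intercept_e, 160, tolerance = 1e-9)

  const <- data.frame(mass_da = 4.6e6 + (0:10) * 3.4e4,
                      charge_e = rep(150, 11))
  expect_equal(charge_vs_bound_slope(const, 4.6e6, 3.4e4)$slope_e_per_ligand,
               0, tolerance = 1e-12)
  one <- data.frame(mass_da = rep(4.6e6, 5), charge_e = rnorm(5, 160))
  expect_error(charge_vs_bound_slope(one, 4.6e6, 3.4e4), "distinct")
})
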