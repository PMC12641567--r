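test_that("presets resolve and overrides are validated", {
  sc <- build_scenario("aa_neutral")
  expect_s3_class(sc, "scenario_config")
  expect_equal(sc$components$intact$mass$mean, 4.93e6)
  expect_equal(sc$components$intact$charge$centroids, c(165, 150))

  sc7 <- build_scenario("pbs_neutral")
  expect_equal(sc7$components$intact$charge$centroids,
               c(171, 159, 147, 137, 128, 117, 102))

  err <- tryCatch(build_scenario("nope"), error = conditionMessage)
  expect_match(err, "valid presets")
  expect_match(err, "freeze_thaw")

  sc2 <- build_scenario("aa_ph4_37c",
                        list(`components.intact.charge.centroids` = c(160, 150)))
  expect_equal(sc2$components$intact$charge$centroids, c(160, 150))
  expect_error(build_scenario("aa_neutral", list(`components.bogus.weight` = 1)),
               "unknown override key")
})

test_that("freeze_thaw degraded weight is tunable down to intact-only", {
  sc <- build_scenario("freeze_thaw", list(degraded_weight = 0))
  expect_named(sc$components, "intact")
  expect_equal(sc$components$intact$weight, 1)
  sc16 <- build_scenario("freeze_thaw")
  w <- vapply(sc16$components, `[[`, numeric(1), "weight")
  expect_equal(sum(w[c("fragment", "aggregate")]), 0.16, tolerance = 1e-12)
})

test_that("ensembles reproduce the configured mixture", {
  sc <- build_scenario("aa_neutral")
  ens <- sample_ion_ensemble(sc, 10000, seed = 5)
  # conformer mixture expectation: 0.85 * 165 + 0.15 * 150 = 162.75
  expect_equal(mean(ens$charge_e), 162.75, tolerance = 0.2 / 162.75)
  expect_equal(nrow(sample_ion_ensemble(sc, 1, seed = 1)), 1L)

  # degradation continuum spans 1-12 MDa
  scd <- build_scenario("aa_ph4_37c")
  ensd <- sample_ion_ensemble(scd, 4000, seed = 2)
  deg <- ensd[ensd$population != "INTACT_FULL", ]
  expect_true(all(deg$mass_da >= 1e6 & deg$mass_da <= 1.2e7))
  # fragment charges sit on the Rayleigh band by construction
  fr <- ensd[ensd$population == "FRAGMENT", ]
  ratio <- fr$charge_e / rayleigh_charge_for_mass(fr$mass_da)
  expect_true(all(ratio >= 0.85 - 1e-9 & ratio <= 1.00 + 1e-9))
})

test_that("ensembles are byte-identical under a fixed seed", {
  sc <- build_scenario("pbs_ph4_37c")
  a <- sample_ion_ensemble(sc, 500, seed = 123)
  b <- sample_ion_ensemble(sc, 500, seed = 123)
  expect_identical(a, b)
  expect_false(identical(a, sample_ion_ensemble(sc, 500, seed = 124)))
})

test_that("empirical component weights converge to configured weights", {
  sc <- build_scenario("aa_ph4_37c")
  w <- vapply(sc$components, `[[`, numeric(1), "weight")
  labels <- vapply(sc$components, `[[`, character(1), "label")
  rejected <- 0L
  n_seeds <- 20L
  for (s in seq_len(n_seeds)) {
    ens <- sample_ion_ensemble(sc, 2000, seed = 100 + s)
    obs <- table(factor(ens$population, levels = unique(labels)))
    exp_w <- tapply(w, labels, sum)[names(obs)]
    p <- suppressWarnings(stats::chisq.test(obs, p = exp_w)$p.value)
    if (p < 0.01) rejected <- rejected + 1L
  }
  expect_lte(rejected, 1L)
})
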