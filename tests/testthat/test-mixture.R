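sim_hist <- function(centroids, n, sigma = 4, seed = 1, weights = NULL) {
  set.seed(seed)
  if (is.null(weights)) weights <- rep(1 / length(centroids), length(centroids))
  comp <- sample(seq_along(centroids), n, TRUE, prob = weights)
  histogram1d(rnorm(n, centroids[comp], sigma), axis = "charge")
}

test_that("a single Gaussian fit matches the moment estimate", {
  set.seed(10)
  v <- rnorm(5000, 165, 4)
  f <- fit_gaussian_mixture(histogram1d(v, axis = "charge"), k = 1)
  expect_true(f$converged)
  expect_equal(f$components$centroid, mean(v), tolerance = 0.2 / 165)
  expect_equal(f$components$sigma, 4, tolerance = 0.15)
})

test_that("mixture fits are scale-equivariant in the counts", {
  h <- sim_hist(c(160, 130), 4000, seed = 2)
  f1 <- fit_gaussian_mixture(h, k = 2)
  h10 <- h
  h10$counts <- h$counts * 10L
  f10 <- fit_gaussian_mixture(h10, k = 2)
  expect_equal(f10$components$centroid, f1$components$centroid,
               tolerance = 1e-4)
  expect_equal(f10$components$sigma, f1$components$sigma, tolerance = 1e-3)
  expect_equal(f10$components$area, 10 * f1$components$area,
               tolerance = 1e-3)
})

test_that("components come back sorted by descending centroid", {
  f <- fit_gaussian_mixture(sim_hist(c(120, 170, 145), 6000, seed = 3), k = 3)
  expect_true(all(diff(f$components$centroid) < 0))
})

test_that("BIC selects the generating component count for separated mixtures", {
  correct <- 0L
  cases <- expand.grid(k0 = 1:3, seed = 1:6)
  for (i in seq_len(nrow(cases))) {
    k0 <- cases$k0[i]
    centroids <- seq(110, by = 22, length.out = k0)  # > 5 sigma apart
    f <- fit_gaussian_mixture(sim_hist(centroids, 4000, seed = 40 + i),
                              k = "auto")
    if (f$k == k0) correct <- correct + 1L
  }
  expect_gte(correct, 0.9 * nrow(cases))
})

test_that("centroids are stable under halving the bin width", {
  set.seed(5)
  v <- rnorm(8000, sample(c(150, 165), 8000, TRUE), 4)
  f1 <- fit_gaussian_mixture(histogram1d(v, 1, axis = "charge"), k = 2)
  f2 <- fit_gaussian_mixture(histogram1d(v, 0.5, axis = "charge"), k = 2)
  expect_equal(f1$components$centroid, f2$components$centroid,
               tolerance = 0.1 / 150)
})

test_that("excess components are quantile-seeded, degenerate input errors", {
  f <- fit_gaussian_mixture(sim_hist(165, 3000, seed = 6), k = 3)
  expect_equal(nrow(f$components), 3)
  one_bin <- histogram1d(rep(165, 50), axis = "charge",
                         range = c(164.5, 165.5))
  expect_error(fit_gaussian_mixture(one_bin, k = 1), "degenerate")
})

test_that("gm_fit methods are self-consistent", {
  h <- sim_hist(c(160, 130), 4000, seed = 7)
  f <- fit_gaussian_mixture(h, k = 2)
  expect_equal(nrow(coef(f)), 2)
  expect_equal(predict(f) + residuals(f), h$counts, tolerance = 1e-12)
  expect_length(predict(f, c(130, 160)), 2)
  expect_output(print(f), "Gaussian component")
})

test_that("centroid() fits a Gaussian and falls back on pathological shapes", {
  # symmetric histogram: centroid at the axis of symmetry
  set.seed(8)
  v <- 165 + c(rnorm(4000, -6, 2), rnorm(4000, 6, 2))
  ctr <- centroid(histogram1d(v, axis = "charge"))
  expect_equal(as.numeric(ctr), 165, tolerance = 0.3 / 165)

  # well-resolved skewed bimodal: the single-Gaussian model is rejected
  vb <- c(rnorm(6000, 100, 2), rnorm(2000, 160, 2))
  cb <- centroid(histogram1d(vb, axis = "charge"))
  expect_true(attr(cb, "flagged"))
  expect_identical(attr(cb, "method"), "weighted_mean")

  # recovered mass centroid of a simulated intact ensemble
  ens <- sample_ion_ensemble(build_scenario("aa_neutral"), 2000, seed = 9)
  meas <- measurements_from_truth(ens, seed = 10)
  cm <- centroid(histogram1d(meas$mass_da, axis = "mass"))
  expect_equal(as.numeric(cm), 4.93e6, tolerance = 0.003)
  expect_error(centroid(histogram1d(numeric(0), axis = "mass")), "empty")
})
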