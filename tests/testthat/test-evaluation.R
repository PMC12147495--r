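test_that("measured Gaussians use the sample SD at n >= 3 and the fallback below", {
  g <- fit_gaussian_measured(c(10, 20, 30))
  expect_equal(g$mean, 20)
  expect_equal(g$sd, 10)
  expect_false(g$sd_substituted)

  g1 <- fit_gaussian_measured(15, fallback_sd = 4)
  expect_equal(c(g1$mean, g1$sd), c(15, 4))
  expect_true(g1$sd_substituted)

  g2 <- fit_gaussian_measured(c(7, 9), fallback_sd = 4)
  expect_equal(c(g2$mean, g2$sd), c(8, 4))
  expect_true(g2$sd_substituted)

  expect_error(fit_gaussian_measured(numeric(0)), class = "bonevar_input_error")
  expect_error(fit_gaussian_measured(c(1, 2), fallback_sd = NULL),
               class = "bonevar_input_error")
  expect_error(fit_gaussian_measured(c(5, 5, 5)),
               class = "bonevar_degenerate_distribution_error")
})

test_that("fallback SD averages the sample SDs of well-measured materials", {
  mk <- function(id, y) list(material_id = id, base_features = c(f = 1),
                             measurements = y)
  # SDs 2 and 4 for the two materials with >= 3 measurements
  ds <- material_dataset(list(
    mk("p", c(10, 12, 14)),
    mk("q", c(20, 24, 28)),
    mk("r", c(1, 2)),
    mk("s", 5)))
  expect_equal(compute_fallback_sd(ds), 3)
  ds1 <- material_dataset(list(mk("p", c(10, 15, 20)), mk("s", 5)))
  expect_equal(compute_fallback_sd(ds1), 5)
  ds_none <- material_dataset(list(mk("r", c(1, 2)), mk("s", 5)))
  expect_error(compute_fallback_sd(ds_none),
               class = "bonevar_fallback_undefined_error")
})

test_that("predicted Gaussians summarise the estimate vector", {
  g <- fit_gaussian_predicted(1:100)
  expect_equal(g$mean, 50.5)
  expect_equal(g$sd, sqrt(sum((1:100 - 50.5)^2) / 99))
  expect_false(g$sd_substituted)
  gf <- fit_gaussian_predicted(rep(3, 100))
  expect_equal(gf$sd, 1e-6)
  expect_true(gf$sd_substituted)
  expect_error(fit_gaussian_predicted(5), class = "bonevar_input_error")
})

test_that("numerical KL matches the closed-form Gaussian KL", {
  expect_lt(kl_divergence(gaussian_summary(0, 1, 5), gaussian_summary(0, 1, 5)),
            1e-8)
  expect_equal(kl_divergence(gaussian_summary(0, 1, 5), gaussian_summary(1, 1, 5)),
               0.5, tolerance = 1e-6)
  expect_equal(kl_divergence(gaussian_summary(0, 2, 5), gaussian_summary(0, 1, 5)),
               log(1 / 2) + (4 + 0) / 2 - 1 / 2, tolerance = 1e-6)
  for (mu in c(-1.5, 0, 0.7)) {
    for (s1 in c(0.1, 1, 10)) {
      for (s2 in c(0.3, 2, 7)) {
        expect_equal(
          kl_divergence(gaussian_summary(mu, s1, 5), gaussian_summary(0, s2, 5)),
          kl_gaussian_closed(mu, s1, 0, s2),
          tolerance = 1e-6,
          label = sprintf("KL(N(%g,%g) || N(0,%g))", mu, s1, s2))
      }
    }
  }
  expect_error(kl_divergence(gaussian_summary(0, 1, 5), list(mean = 0, sd = -1)))
})

test_that("JS divergence is symmetric, bounded, zero at identity, ln 2 at separation", {
  p <- gaussian_summary(0, 1, 5)
  expect_lt(js_divergence(p, p), 1e-8)
  expect_equal(js_divergence(p, gaussian_summary(100, 1, 5)), log(2),
               tolerance = 1e-4)
  withr::with_seed(21, {
    for (i in 1:25) {
      a <- gaussian_summary(runif(1, -5, 5), runif(1, 0.1, 10), 5)
      b <- gaussian_summary(runif(1, -5, 5), runif(1, 0.1, 10), 5)
      ab <- js_divergence(a, b)
      expect_lt(abs(ab - js_divergence(b, a)), 1e-10)
      expect_gte(ab, 0)
      expect_lte(ab, log(2) + 1e-6)
    }
  })
  # bits switch rescales by log 2
  q <- gaussian_summary(2, 3, 5)
  expect_equal(js_divergence(p, q, base = "bits"),
               js_divergence(p, q) / log(2), tolerance = 1e-12)
})

test_that("JS increases with mean separation and is stable under grid refinement", {
  vals <- vapply(c(0, 0.5, 1, 2, 4), function(d) {
    js_divergence(gaussian_summary(0, 1, 5), gaussian_summary(d, 1, 5))
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
  p <- gaussian_summary(0.3, 1.7, 5); q <- gaussian_summary(2, 0.4, 5)
  expect_lt(abs(js_divergence(p, q, grid = divergence_grid(40001L)) -
                js_divergence(p, q)), 1e-7)
})

test_that("r-squared of means follows the coefficient-of-determination form", {
  m <- c(10, 20, 30, 40)
  expect_equal(r_squared_of_means(m, m), 1)
  expect_equal(r_squared_of_means(m, rep(mean(m), 4)), 0)
  expect_equal(r_squared_of_means(c(0, 10), c(10, 0)), -3)
  # invariant under adding a constant to both vectors
  p <- c(12, 18, 33, 38)
  expect_equal(r_squared_of_means(m + 7, p + 7), r_squared_of_means(m, p))
  expect_error(r_squared_of_means(c(5, 5), c(1, 2)),
               class = "bonevar_undefined_variance_error")
})

test_that("an oracle predictor scores near-zero divergence; a constant predictor has r2 <= 0", {
  gen <- generate_synthetic_dataset(small_config(seed = 13))
  ds <- gen$dataset
  fb <- compute_fallback_sd(ds)
  ids <- names(summarize_measurements(ds))
  oracle <- withr::with_seed(31, {
    t(vapply(ds$samples, function(s) {
      g <- fit_gaussian_measured(s$measurements, fallback_sd = fb)
      rnorm(100, g$mean, g$sd)
    }, numeric(100)))
  })
  rownames(oracle) <- ids
  pred <- structure(list(estimates = oracle, combo_label = "A"),
                    class = "ensemble_prediction")
  ev <- evaluate_method(ds, pred, method_combo("A"))
  expect_lt(ev$aggregate_d_js, 0.05)
  expect_equal(ev$aggregate_d_js, mean(ev$per_material$d_js))

  flat <- pred
  flat$estimates <- withr::with_seed(32,
    matrix(rnorm(length(ids) * 100, 30, 1), length(ids), 100,
           dimnames = list(ids, NULL)))
  ev_flat <- evaluate_method(ds, flat, method_combo("A"))
  expect_lte(ev_flat$r_squared, 0)
})

test_that("dispersion rectangles report the predicted/measured spread ratio", {
  gen <- generate_synthetic_dataset(small_config(seed = 17))
  ds <- gen$dataset
  fb <- compute_fallback_sd(ds)
  ids <- names(summarize_measurements(ds))
  sds <- vapply(ds$samples, function(s) {
    fit_gaussian_measured(s$measurements, fallback_sd = fb)$sd
  }, numeric(1))
  # build estimates whose SD is exactly twice the measured SD
  est <- withr::with_seed(33, t(vapply(seq_along(ids), function(i) {
    v <- scale(rnorm(100))[, 1]  # mean 0, sd 1 exactly
    30 + 2 * sds[i] * v
  }, numeric(100))))
  rownames(est) <- ids
  pred <- structure(list(estimates = est, combo_label = "A"),
                    class = "ensemble_prediction")
  rect <- rectangle_summary(ds, pred, multiplier = 2)
  expect_equal(rect$aspect, rep(2, length(ids)), tolerance = 1e-8)
  expect_equal(rect$width, 2 * sds, tolerance = 1e-8)
  expect_equal(rect$height, 2 * 2 * sds, tolerance = 1e-8)
})
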