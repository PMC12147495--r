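test_that("sub-dataset draws respect measurement sets and the seed", {
  ds <- tiny_dataset()
  subs <- generate_subdatasets(ds, 50, seed = 8)
  expect_length(subs, 50L)
  for (s in subs[c(1, 25, 50)]) {
    for (i in seq_along(ds$samples)) {
      smp <- ds$samples[[i]]
      expect_equal(s$responses[[smp$material_id]],
                   smp$measurements[s$chosen_index[[smp$material_id]]])
    }
  }
  # single-measurement material keeps the same response everywhere
  e_vals <- vapply(subs, function(s) s$responses[["e"]], numeric(1))
  expect_equal(unique(e_vals), 50)
  # determinism
  expect_identical(generate_subdatasets(ds, 10, seed = 8)[[3]],
                   subs[[3]])
  expect_error(generate_subdatasets(material_dataset(list()), 5, seed = 1),
               class = "bonevar_input_error")
})

test_that("each measurement of a two-value material is drawn about half the time", {
  ds <- material_dataset(list(
    list(material_id = "m", base_features = c(f = 1), measurements = c(10, 20)),
    list(material_id = "n", base_features = c(f = 2), measurements = 5)))
  subs <- generate_subdatasets(ds, 10000, seed = 99)
  n10 <- sum(vapply(subs, function(s) s$responses[["m"]], numeric(1)) == 10)
  # binomial(10000, 0.5): 4 sigma band is 5000 +/- 200
  expect_gt(n10, 4800)
  expect_lt(n10, 5200)
})

test_that("a single-method zoo is always chosen; a clean linear signal favours ols over a tree", {
  sub <- linear_sub()
  only <- select_and_fit(sub, model_zoo("tree"), seed = 2)
  expect_equal(only$method, "tree")
  both <- select_and_fit(sub, model_zoo(c("ols", "tree")), seed = 2)
  expect_equal(both$method, "ols")
  expect_gt(both$inner_score, 0.99)
  # the refitted model predicts the training rows near-exactly
  pred <- predict(both, sub$feature_table$matrix)
  expect_equal(unname(pred), unname(sub$responses), tolerance = 1e-6)
})

test_that("select_and_fit validates folds and degenerate targets", {
  sub <- linear_sub(n = 4)
  expect_error(select_and_fit(sub, model_zoo("ols"), inner_folds = 5),
               class = "bonevar_fold_error")
  sub10 <- linear_sub(n = 10)
  sub10$responses[] <- 7
  expect_error(select_and_fit(sub10, model_zoo("ols")),
               class = "bonevar_degenerate_target_error")
})

test_that("double cross-validation predicts every material exactly once, reproducibly", {
  sub <- linear_sub()
  d1 <- double_cross_validate(sub, model_zoo("ridge"), seed = 5)
  expect_length(d1$estimates, 38L)
  expect_false(anyNA(d1$estimates))
  expect_length(d1$chosen_methods, 10L)
  d2 <- double_cross_validate(sub, model_zoo("ridge"), seed = 5)
  expect_identical(d1, d2)
  # noiseless linear response: out-of-fold r2 essentially 1
  r2 <- 1 - sum((sub$responses - d1$estimates)^2) /
    sum((sub$responses - mean(sub$responses))^2)
  expect_gt(r2, 0.99)
  expect_error(double_cross_validate(linear_sub(n = 6), model_zoo("ridge"),
                                     outer_folds = 10),
               class = "bonevar_fold_error")
})

test_that("ensemble prediction has one estimate per sub-dataset per material", {
  gen <- generate_synthetic_dataset(small_config(seed = 2))
  pred <- predict_ensemble(gen$dataset, method_combo("A"), fast_zoo(),
                           n_subdatasets = 6, outer_folds = 5, seed = 3)
  expect_equal(dim(pred$estimates), c(14L, 6L))
  expect_false(anyNA(pred$estimates))
  expect_equal(dim(pred$chosen_methods), c(6L, 5L))
  expect_equal(pred$n_models, 30L)
  expect_true(all(pred$chosen_methods %in% c("ridge", "tree")))
  # bit-for-bit reproducible under the same root seed
  pred2 <- predict_ensemble(gen$dataset, method_combo("A"), fast_zoo(),
                            n_subdatasets = 6, outer_folds = 5, seed = 3)
  expect_identical(pred$estimates, pred2$estimates)
})

test_that("a missing image block is imputed before modelling", {
  cfg <- small_config(seed = 6)
  cfg$image_missing_fraction <- 0.2
  gen <- generate_synthetic_dataset(cfg)
  expect_lt(length(gen$dataset$images), 14L)
  pred <- predict_ensemble(gen$dataset, method_combo("D"), model_zoo("ridge"),
                           n_subdatasets = 2, outer_folds = 5, seed = 4)
  expect_false(anyNA(pred$feature_table$matrix))
  expect_false(anyNA(pred$estimates))
})
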