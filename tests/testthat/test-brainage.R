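test_that("MAE and R^2 follow their definitions and degenerate cases", {
  y <- c(60, 65, 70, 75)
  expect_equal(mae(y, y), 0)
  expect_equal(r_squared(y, y), 1)
  expect_equal(mae(y + 5, y), 5)
  expect_equal(r_squared(rep(mean(y), 4), y), 0)
  expect_warning(r2 <- r_squared(c(1, 2), c(3, 3)), "zero variance")
  expect_true(is.nan(r2))
})

test_that("stratified folds partition subjects evenly and stay seeded", {
  ages <- runif(103, 18, 92)
  f1 <- csvdbag:::make_age_folds(ages, 5, seed = 4)
  f2 <- csvdbag:::make_age_folds(ages, 5, seed = 4)
  expect_identical(f1, f2)
  expect_setequal(unique(f1), 1:5)
  expect_lte(diff(range(table(f1))), 1)
  expect_error(csvdbag:::make_age_folds(ages[1:3], 5), "folds")
})

test_that("scaling uses training statistics and guards constant columns", {
  x <- cbind(a = rnorm(20), b = rnorm(20, 10, 5))
  sc <- csvdbag:::fit_scaler(x)
  manual <- sweep(sweep(x, 2, colMeans(x)), 2, apply(x, 2, sd), "/")
  expect_equal(csvdbag:::apply_scaler(x, sc), manual)
  # held-out rows are standardized with the training statistics
  xnew <- cbind(a = rnorm(5), b = rnorm(5))
  expect_equal(csvdbag:::apply_scaler(xnew, sc)[, "a"],
               (xnew[, "a"] - mean(x[, "a"])) / sd(x[, "a"]))
  xc <- cbind(a = rnorm(10), b = rep(2, 10))
  expect_warning(sc2 <- csvdbag:::fit_scaler(xc), "constant")
  expect_equal(unname(sc2$scale[["b"]]), 1)
})

test_that("a noiseless affine age signal is learned to within epsilon", {
  set.seed(2)
  n <- 120
  age <- runif(n, 18, 92)
  x <- cbind(f1 = 500 - 1.2 * age, f2 = 700 - 0.9 * age)
  spec <- model_spec(cost_grid = c(1, 10, 100), gamma_grid = c(0.05, 0.5),
                     epsilon = 0.1, seed = 5)
  fit <- nested_cv_fit(x, age, spec)
  expect_lte(fit$cv$pooled_mae, spec$epsilon + 0.5)
  expect_gte(fit$cv$pooled_r2, 0.8)
  # out-of-fold bookkeeping: every subject predicted exactly once
  expect_setequal(fit$cv$oof$index, seq_len(n))
  expect_setequal(unique(fit$cv$oof$fold), 1:5)
})

test_that("inner grid search equals exhaustive enumeration over all pairs", {
  set.seed(7)
  n <- 60
  age <- runif(n, 20, 90)
  x <- cbind(f1 = 600 - age + rnorm(n, 0, 6),
             f2 = 450 - 0.7 * age + rnorm(n, 0, 6))
  spec <- model_spec(seed = 13)                    # full 7 x 7 grid
  sel <- csvdbag:::svr_cv_select(x, age, spec, k = 5, seed = 13)
  expect_equal(nrow(sel$grid), 49)

  # independent brute-force loop over the same folds and all 49 pairs
  fold <- csvdbag:::make_age_folds(age, 5, seed = 13)
  brute <- expand.grid(gamma = spec$gamma_grid, cost = spec$cost_grid)
  brute <- brute[order(brute$cost, brute$gamma), ]
  brute$cv_mae <- NA_real_
  for (g in seq_len(nrow(brute))) {
    err <- numeric(0)
    for (f in 1:5) {
      tr <- fold != f
      ctr <- colMeans(x[tr, ]); sdv <- apply(x[tr, ], 2, sd)
      xs <- sweep(sweep(x[tr, ], 2, ctr), 2, sdv, "/")
      xt <- sweep(sweep(x[!tr, , drop = FALSE], 2, ctr), 2, sdv, "/")
      m <- e1071::svm(x = xs, y = age[tr], type = "eps-regression",
                      kernel = "radial", cost = brute$cost[g],
                      gamma = brute$gamma[g], epsilon = 0.1, scale = FALSE)
      err <- c(err, abs(predict(m, xt) - age[!tr]))
    }
    brute$cv_mae[g] <- mean(err)
  }
  expect_equal(sel$grid$cv_mae, brute$cv_mae, tolerance = 1e-10)
  best <- which.min(brute$cv_mae)
  expect_equal(sel$cost, brute$cost[best])
  expect_equal(sel$gamma, brute$gamma[best])
})

test_that("constant ages yield constant predictions and undefined R^2", {
  x <- cbind(f = rnorm(30))
  age <- rep(70, 30)
  expect_warning(fit <- nested_cv_fit(x, age, model_spec(
    cost_grid = 1, gamma_grid = 0.1, seed = 2)), "constant|undefined")
  expect_lt(mae(fit$cv$oof$predicted, age), 1e-6)
  expect_true(is.nan(fit$cv$pooled_r2))
})

test_that("regional models are independent and deterministic per region", {
  atlas <- tiny_atlas(nc = 2, ns = 0, nb = 0, v = 3)
  tr <- generate_training_cohort(tiny_cfg(), atlas)
  # make region 2's voxel block an exact copy of region 1's
  vox <- tr$features$voxels
  vox[, 4:6] <- vox[, 1:3]
  fs <- feature_set(vox, atlas, tr$features$subject_ids)
  spec <- model_spec(cost_grid = c(1, 10), gamma_grid = 0.1, seed = 6)
  models <- fit_regional_models(fs, tr$subjects$age, atlas, spec,
                                nested = FALSE)
  expect_named(models, atlas$regions$region_id)
  p1 <- predict(models$ctx_001, region_features(fs, "ctx_001"))
  p2 <- predict(models$ctx_002, region_features(fs, "ctx_002"))
  expect_equal(unname(p1), unname(p2), tolerance = 1e-10)
})

test_that("a pure-noise region predicts age no better than the mean", {
  set.seed(10)
  r2 <- replicate(3, {
    n <- 80
    age <- runif(n, 20, 90)
    x <- matrix(rnorm(n * 5), n, dimnames = list(NULL, paste0("v", 1:5)))
    fit <- nested_cv_fit(x, age, model_spec(cost_grid = c(1, 10),
                                            gamma_grid = c(0.1, 1),
                                            seed = sample.int(1000, 1)))
    fit$cv$pooled_r2
  })
  expect_lt(mean(r2), 0.15)
})

test_that("BAG is predicted minus chronological age, with schema checks", {
  atlas <- tiny_atlas(nc = 2, ns = 0, nb = 0, v = 3)
  cfg <- tiny_cfg(sigma_g = 1)
  tr <- generate_training_cohort(cfg, atlas)
  ap <- generate_application_cohort(cfg, atlas)
  spec <- model_spec(cost_grid = c(1, 10), gamma_grid = 0.1, seed = 8)
  gm <- fit_global_model(tr$features, tr$subjects$age, spec, nested = FALSE)
  models <- list(global = gm, regional = list())
  bag <- predict_and_bag(models, ap$features, ap$subjects$age)
  expect_equal(bag$bag, bag$predicted_age - ap$subjects$age)
  expect_true(all((bag$bag > 0) == (bag$predicted_age > ap$subjects$age)))
  # applying the model to its own training set reproduces the residuals
  bag_tr <- predict_and_bag(models, tr$features, tr$subjects$age)
  expect_equal(bag_tr$bag,
               predict(gm, region_means(tr$features)) - tr$subjects$age)
  # schema mismatch names the offending columns
  wrong <- region_means(ap$features)
  colnames(wrong)[1] <- "bogus"
  expect_error(predict(gm, wrong), "missing.*ctx_001.*extra.*bogus")
})

test_that("an RBF kernel expansion oracle reproduces SVR predictions", {
  set.seed(3)
  n <- 60
  age <- runif(n, 20, 90)
  x <- cbind(f1 = 600 - age + rnorm(n, 0, 2),
             f2 = 480 - 0.5 * age + rnorm(n, 0, 2))
  spec <- model_spec(cost_grid = 10, gamma_grid = 0.5, seed = 4)
  fit <- nested_cv_fit(x, age, spec, nested = FALSE)
  # manual kernel expansion: f(z) = sum_i alpha_i K(x_i, z) + b
  sv <- fit$fit$SV
  coefs <- fit$fit$coefs
  rho <- fit$fit$rho
  z <- csvdbag:::apply_scaler(x[1:5, ], fit$scaler)
  kern <- function(u, v) exp(-0.5 * sum((u - v)^2))
  manual <- vapply(seq_len(nrow(z)), function(i) {
    sum(coefs * apply(sv, 1, kern, v = z[i, ])) - rho
  }, numeric(1))
  expect_equal(unname(predict(fit, x[1:5, ])), manual, tolerance = 1e-8)
})
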