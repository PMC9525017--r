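test_that("ANCOVA matches a normal-equations and F-distribution oracle", {
  set.seed(31)
  n <- 40
  covs <- random_covs(n, seed = 31, vascular = TRUE)
  group <- rbinom(n, 1, 0.5)
  y <- 2 + 1.5 * group + 0.1 * covs$age - 0.2 * covs$education + rnorm(n)
  res <- ancova_group_effect(y, group, covs)

  X_full <- cbind(1, group, as.matrix(covs))
  X_red <- cbind(1, as.matrix(covs))
  full <- ols_oracle(X_full, y)
  red <- ols_oracle(X_red, y)
  ss_group <- red$sse - full$sse
  f_stat <- ss_group / (full$sse / full$df)
  expect_equal(res$estimate, unname(full$beta[2]), tolerance = 1e-10)
  expect_equal(res$ss_group, ss_group, tolerance = 1e-8)
  expect_equal(res$p, pf(f_stat, 1, full$df, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_equal(res$eta2, ss_group / (ss_group + full$sse), tolerance = 1e-10)
})

test_that("partial eta^2 equals t^2/(t^2 + df) for the single-df effect", {
  set.seed(32)
  for (i in 1:5) {
    n <- 60
    covs <- random_covs(n, seed = 32 + i, vascular = TRUE)
    group <- rbinom(n, 1, 0.4)
    y <- rnorm(n) + 0.5 * group + 0.05 * covs$age
    res <- ancova_group_effect(y, group, covs)
    expect_equal(res$eta2, res$t^2 / (res$t^2 + res$df), tolerance = 1e-10)
  }
})

test_that("a response fully explained by a covariate has a null group effect", {
  set.seed(33)
  covs <- random_covs(50, seed = 33, vascular = TRUE)
  group <- rbinom(50, 1, 0.5)
  y <- covs$education          # exactly a covariate
  # lm warns about the (intentionally) perfect fit
  res <- suppressWarnings(ancova_group_effect(y, group, covs))
  expect_lt(abs(res$estimate), 1e-10)
  expect_lt(res$eta2, 1e-10)
})

test_that("group inference is invariant to shifting all responses", {
  set.seed(34)
  covs <- random_covs(45, seed = 34, vascular = TRUE)
  group <- rbinom(45, 1, 0.5)
  y <- rnorm(45) + group
  r1 <- ancova_group_effect(y, group, covs)
  r2 <- ancova_group_effect(y + 100, group, covs)
  expect_equal(r1$p, r2$p, tolerance = 1e-9)
  expect_equal(r1$eta2, r2$eta2, tolerance = 1e-9)
  expect_equal(r1$estimate, r2$estimate, tolerance = 1e-9)
})

test_that("collinear and degenerate designs are rejected with names", {
  covs <- random_covs(30, seed = 35, vascular = FALSE)
  covs$dup <- covs$education * 2
  group <- rep(c(0, 1), 15)
  y <- rnorm(30)
  expect_error(ancova_group_effect(y, group, covs), "dup|collinear")
  covs$dup <- NULL
  expect_error(ancova_group_effect(rep(1, 30), group, covs), "constant")
  expect_error(ancova_group_effect(y, rep(1, 30), covs), "group")
})

test_that("permuting group labels yields uniform p-values under the null", {
  set.seed(36)
  n <- 60
  covs <- random_covs(n, seed = 36, vascular = TRUE)
  y <- rnorm(n) + 0.04 * covs$age
  group <- rep(c(0, 1), n / 2)
  p <- replicate(200, ancova_group_effect(y, sample(group), covs)$p)
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.001)
  expect_gt(mean(p), 0.35)
  expect_lt(mean(p), 0.65)
})

test_that("Bonferroni threshold is alpha over the number of comparisons", {
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.01, 4), 0.0025)
  expect_error(bonferroni_threshold(0.05, 0), "k")
  expect_error(bonferroni_threshold(1.2, 10), "alpha")
})

test_that("regional screen tallies significant regions by compartment", {
  atlas <- tiny_atlas(nc = 4, ns = 2, nb = 2, v = 2)
  n <- 80
  set.seed(37)
  subjects <- cbind(
    data.frame(subject_id = sprintf("s%03d", 1:n)),
    random_covs(n, seed = 37, vascular = TRUE)[
      c("age", "sex", "education", "efc", "tiv", "hypertension",
        "diabetes", "dyslipidemia", "smoking")]
  )
  group <- rbinom(n, 1, 0.4)
  # strong planted effect in two regions, pure noise elsewhere
  planted <- c("ctx_002", "sub_001")
  bag <- do.call(rbind, lapply(atlas$regions$region_id, function(r) {
    eff <- if (r %in% planted) 8 else 0
    data.frame(subject_id = subjects$subject_id, scope = r,
               predicted_age = NA_real_,
               bag = rnorm(n, 0, 1.5) + eff * group)
  }))
  class(bag) <- c("bag_result", "data.frame")
  res <- regional_bag_comparison(bag, subjects, group, atlas)
  sig <- res$table$region_id[res$table$significant]
  expect_setequal(sig, planted)
  expect_equal(res$threshold, 0.05 / 8)
  expect_equal(sum(res$by_compartment), length(sig))
  expect_equal(as.integer(res$by_compartment[c("cortical", "subcortical")]),
               c(1L, 1L))
  # missing region column is an error naming the region
  bag2 <- bag[bag$scope != "cbl_001", ]
  class(bag2) <- c("bag_result", "data.frame")
  expect_error(regional_bag_comparison(bag2, subjects, group, atlas),
               "cbl_001")
})
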