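test_that("default atlas matches the 400/14/28 parcellation layout", {
  atlas <- atlas_spec()
  expect_equal(atlas$n_regions, 442)
  expect_equal(as.integer(table(atlas$regions$compartment)[c(
    "cortical", "subcortical", "cerebellar")]), c(400L, 14L, 28L))
  expect_setequal(unique(atlas$regions$network[
    atlas$regions$compartment == "cortical"]), CANONICAL_NETWORKS)
  expect_false(anyDuplicated(atlas$regions$region_id) > 0)
  # JSON round trip preserves the region table
  path <- withr::local_tempfile(fileext = ".json")
  write_atlas_json(atlas, path)
  expect_equal(read_atlas_json(path)$regions, atlas$regions)
})

test_that("noise-free GMV is an exact affine function of age", {
  atlas <- tiny_atlas()
  cfg <- tiny_cfg(sigma_g = 0, quad = 0)
  tr <- generate_training_cohort(cfg, atlas)
  rm <- region_means(tr$features)
  for (r in atlas$regions$region_id) {
    expect_equal(cor(rm[, r], tr$subjects$age), -1, tolerance = 1e-12)
  }
  # residual of the affine fit is numerically zero
  fit <- lm(rm[, 1] ~ tr$subjects$age)
  expect_lt(max(abs(residuals(fit))), 1e-9)
})

test_that("generation is bit-identical under the same config and seed", {
  atlas <- tiny_atlas()
  cfg <- tiny_cfg(affected_regions = "ctx_001", delta_years = 4)
  a1 <- generate_application_cohort(cfg, atlas)
  a2 <- generate_application_cohort(cfg, atlas)
  expect_identical(a1$subjects, a2$subjects)
  expect_identical(a1$features$voxels, a2$features$voxels)
  expect_identical(a1$truth, a2$truth)
  t1 <- generate_training_cohort(cfg, atlas)
  t2 <- generate_training_cohort(cfg, atlas)
  expect_identical(t1$features$voxels, t2$features$voxels)
})

test_that("training cohort honours the full-scale size and age range", {
  atlas <- tiny_atlas(2, 1, 1, v = 2)
  cfg <- sim_config(n_train = 1482, n_app = 10,
                    train_age_range = c(18, 92), seed = 3)
  tr <- generate_training_cohort(cfg, atlas)
  expect_equal(nrow(tr$subjects), 1482)
  expect_true(all(tr$subjects$age >= 18 & tr$subjects$age <= 92))
  ap <- generate_application_cohort(cfg, atlas)
  expect_true(all(ap$subjects$age >= 50))
})

test_that("invalid configs are rejected naming the offending field", {
  expect_error(sim_config(n_train = 0), "n_train")
  expect_error(sim_config(train_age_range = c(50, 50)), "train_age_range")
  expect_error(sim_config(delta_years = -1), "delta_years")
  expect_error(sim_config(markers = list(wmh_sdlog = 0)), "wmh_sdlog")
  atlas <- tiny_atlas()
  cfg <- tiny_cfg(affected_regions = "ctx_999", delta_years = 2)
  expect_error(generate_application_cohort(cfg, atlas), "ctx_999")
})

test_that("null extra-aging leaves features identical in law to no effect", {
  atlas <- tiny_atlas()
  cfg0 <- tiny_cfg(affected_regions = "ctx_002", delta_years = 0)
  cfg_none <- tiny_cfg()
  a0 <- generate_application_cohort(cfg0, atlas)
  a_none <- generate_application_cohort(cfg_none, atlas)
  expect_true(all(a0$truth$extra_aging == 0))
  expect_identical(a0$features$voxels, a_none$features$voxels)
})

test_that("null cognitive model gives scores independent of CSVD", {
  atlas <- tiny_atlas()
  cfg <- tiny_cfg(seed = 9)          # defaults: b_m empty, c_prime = 0
  ap <- generate_application_cohort(cfg, atlas)
  fit <- lm(ap$subjects$mmse ~ ap$truth$csvd + ap$subjects$age +
              ap$subjects$education)
  t_csvd <- summary(fit)$coefficients["ap$truth$csvdTRUE", "t value"]
  expect_lt(abs(t_csvd), 3)
})

test_that("the median split puts half the cohort at or above the threshold", {
  atlas <- tiny_atlas()
  for (seed in c(5, 6, 7)) {
    ap <- generate_application_cohort(tiny_cfg(seed = seed), atlas)
    ratio <- wmh_ratio(ap$subjects$wmh_volume, ap$subjects$tiv_ml)
    frac <- mean(ratio >= ap$truth$wmh_threshold)
    n <- nrow(ap$subjects)
    expect_lte(abs(frac - 0.5), 1 / n + 1e-12)
  }
})

test_that("planted-effect monotonicity: larger delta, larger downstream BAG gap", {
  atlas <- tiny_atlas(2, 1, 1, v = 5)
  spec <- model_spec(cost_grid = c(1, 10), gamma_grid = c(0.05, 0.2),
                     seed = 11)
  gap <- vapply(c(0, 4, 8), function(delta) {
    cfg <- sim_config(n_train = 150, n_app = 120, sigma_g = 2,
                      affected_regions = "ctx_001", delta_years = delta,
                      seed = 100)
    tr <- generate_training_cohort(cfg, atlas)
    ap <- generate_application_cohort(cfg, atlas)
    mdl <- nested_cv_fit(region_features(tr$features, "ctx_001"),
                         tr$subjects$age, spec, nested = FALSE)
    bag <- predict(mdl, region_features(ap$features, "ctx_001")) -
      ap$subjects$age
    mean(bag[ap$truth$csvd]) - mean(bag[!ap$truth$csvd])
  }, numeric(1))
  expect_true(all(diff(gap) > 0))
  expect_lt(abs(gap[1]), 2)          # null configuration: gap near zero
})
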