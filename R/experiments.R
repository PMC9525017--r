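#' Type-I error of the bootstrap indirect-effect test
#'
#' Monte-Carlo study of the a*b BCa bootstrap test under a planted null in
#' which the exposure moves the mediator (a != 0) but the mediator does not
#' move the outcome (b = 0), so the indirect effect is exactly zero while
#' both marginal paths stay realistic. Reports the rejection rate at
#' `alpha`, which should sit near the nominal level.
#'
#' @param n_reps Number of simulated datasets.
#' @param n Subjects per dataset.
#' @param B Bootstrap resamples per dataset.
#' @param alpha Test level.
#' @param seed Base seed; replicate i uses `seed + i`.
#' @return A list: `rate` (rejection proportion), `rejections`, `n_reps`,
#'   and the per-replicate p-values.
#' @export
experiment_type1_error <- function(n_reps = 500, n = 200, B = 1000,
                                   alpha = 0.05, seed = 1L) {
  pvals <- vapply(seq_len(n_reps), function(i) {
    set.seed(seed + i)
    age <- stats::runif(n, 50, 90)
    covs <- data.frame(age = age, age2 = age^2,
                       sex = stats::rbinom(n, 1, 0.5))
    x <- stats::rbinom(n, 1, 0.5)
    while (stats::var(x) == 0) x <- stats::rbinom(n, 1, 0.5)
    m <- 0.5 + 1.0 * x + 0.05 * age + stats::rnorm(n)
    y <- 2 - 0.03 * age + 0.3 * x + stats::rnorm(n)   # b = 0: no mediation
    res <- bootstrap_mediation(x, m, y, covs, B = B, seed = seed + i,
                               alpha = alpha)
    res$boot$p[res$boot$stat == "ab"]
  }, numeric(1))
  list(rate = mean(pvals < alpha), rejections = sum(pvals < alpha),
       n_reps = n_reps, pvals = pvals)
}

#' Family-wise error of the regional screen under the null
#'
#' Simulates cohorts in which no region carries any group effect (regional
#' BAG is pure noise) and counts the replicates in which the
#' Bonferroni-controlled regional comparison flags at least one region.
#' The synthetic null BAG is fed directly into the screening stage: the
#' property under test is the screen's error control, not the brain-age
#' models.
#'
#' @param n_reps Number of null cohorts.
#' @param n Subjects per cohort.
#' @param n_regions Regions per atlas (split across compartments).
#' @param alpha Family-wise level.
#' @param seed Base seed.
#' @return A list: `fwe` (proportion of replicates with any flag),
#'   `n_flagged` per replicate, `n_reps`.
#' @export
experiment_null_fwe <- function(n_reps = 200, n = 150, n_regions = 40,
                                alpha = 0.05, seed = 1L) {
  nc <- n_regions - 10
  atlas <- atlas_spec(nc, 5, 5, voxels_per_region = 1)
  n_flagged <- vapply(seq_len(n_reps), function(i) {
    set.seed(seed + i)
    subjects <- data.frame(
      subject_id = sprintf("s%04d", seq_len(n)),
      age = stats::runif(n, 50, 90), sex = stats::rbinom(n, 1, 0.5),
      education = stats::runif(n, 0, 16),
      efc = stats::rnorm(n, 0.45, 0.04),
      tiv = stats::rnorm(n, 1.45, 0.13),
      hypertension = stats::rbinom(n, 1, 0.4),
      diabetes = stats::rbinom(n, 1, 0.2),
      dyslipidemia = stats::rbinom(n, 1, 0.3),
      smoking = stats::rbinom(n, 1, 0.3)
    )
    group <- stats::rbinom(n, 1, 0.35)
    while (stats::var(group) == 0) group <- stats::rbinom(n, 1, 0.35)
    bag <- do.call(rbind, lapply(atlas$regions$region_id, function(r) {
      data.frame(subject_id = subjects$subject_id, scope = r,
                 predicted_age = NA_real_,
                 bag = stats::rnorm(n, 0, 8), stringsAsFactors = FALSE)
    }))
    class(bag) <- c("bag_result", "data.frame")
    res <- regional_bag_comparison(bag, subjects, group, atlas,
                                   alpha = alpha)
    sum(res$table$significant)
  }, numeric(1))
  list(fwe = mean(n_flagged > 0), n_flagged = n_flagged, n_reps = n_reps)
}

#' Default study conditions of the planted-effect recovery experiment
#'
#' Forty regions with ten voxel features each; an 8-year mean extra-aging
#' offset planted in five regions spanning all three compartments, with
#' subject-level severity heterogeneity (`delta_cv = 0.5`) so the mediator
#' carries identifying variation beyond group membership. One planted
#' region (a thalamus-like subcortical region) additionally mediates a
#' global-cognition deficit with b = -0.5 points per extra-aging year and
#' a direct effect c' = -1, so the true proportion mediated is
#' 100 * (-0.5 * 8) / (-0.5 * 8 - 1) = 80%.
#'
#' @param seed Master seed for the replicate.
#' @return A list with `atlas`, `sim` (a [sim_config()]), `model`
#'   (a [model_spec()]), `planted` region ids, `mediator` region,
#'   `outcome`, and `prop_true`.
#' @export
recovery_conditions <- function(seed = 1L) {
  atlas <- atlas_spec(28, 6, 6, voxels_per_region = 10)
  planted <- c("ctx_003", "ctx_010", "ctx_017", "sub_002", "cbl_004")
  sim <- sim_config(
    n_train = 200, n_app = 250, sigma_g = 1,
    app_age_range = c(50, 75),         # keeps effective ages inside the
    affected_regions = planted,        # training support (<= 92 y)
    delta_years = 8, delta_cv = 0.5,
    cognitive = list(
      mmse = list(intercept = 27, age_coef = -0.06, edu_coef = 0.15,
                  sex_coef = 0, b_m = c(sub_002 = -0.5), c_prime = -1,
                  sigma_y = 2),
      cvvlt = list(intercept = 7, age_coef = -0.05, edu_coef = 0.10,
                   sex_coef = 0, b_m = numeric(0), c_prime = 0,
                   sigma_y = 2),
      vft = list(intercept = 14, age_coef = -0.08, edu_coef = 0.20,
                 sex_coef = 0, b_m = numeric(0), c_prime = 0,
                 sigma_y = 3)),
    seed = seed)
  model <- model_spec(cost_grid = c(1, 10, 100), gamma_grid = c(0.01, 0.1),
                      seed = seed)
  list(atlas = atlas, sim = sim, model = model, planted = planted,
       mediator = "sub_002", outcome = "mmse",
       prop_true = 100 * (-0.5 * 8) / (-0.5 * 8 - 1))
}

#' Demo-scale study conditions for the worked analysis
#'
#' Same planted structure as [recovery_conditions()] but with the larger
#' demo cohorts (400 training, 300 application subjects) used by the
#' numbered analysis scripts, where a single end-to-end run is the point
#' rather than a replicate study.
#'
#' @param seed Master seed.
#' @return Same structure as [recovery_conditions()].
#' @export
demo_conditions <- function(seed = 1L) {
  cond <- recovery_conditions(seed = seed)
  cond$sim$n_train <- 400L
  cond$sim$n_app <- 300L
  cond
}

#' Planted-effect recovery experiment
#'
#' For each replicate: simulate a training and an application cohort under
#' [recovery_conditions()], fit all 40 regional brain-age models, compute
#' BAG in the application cohort, classify CSVD from the generated markers,
#' run the Bonferroni-controlled regional comparison, and check (i) that
#' exactly the five planted regions are flagged, and (ii) that the true
#' proportion mediated of the planted mediator lies inside its 95% BCa
#' bootstrap interval.
#'
#' @param n_reps Number of seeded replicates.
#' @param B Bootstrap resamples for the mediation model.
#' @param seed Base seed; replicate i uses `seed + 1000 * i`.
#' @return Data frame, one row per replicate: `exact_set`, `n_flagged`,
#'   `n_planted_flagged`, `prop_hat`, `prop_lo`, `prop_hi`, `covered`.
#' @export
experiment_recovery <- function(n_reps = 20, B = 1000, seed = 1L) {
  rows <- lapply(seq_len(n_reps), function(i) {
    cond <- recovery_conditions(seed = seed + 1000L * i)
    tr <- generate_training_cohort(cond$sim, cond$atlas)
    ap <- generate_application_cohort(cond$sim, cond$atlas)
    models <- fit_regional_models(tr$features, tr$subjects$age,
                                  cond$atlas, cond$model, nested = FALSE)
    bag <- predict_and_bag(list(global = NULL, regional = models),
                           ap$features, ap$subjects$age)
    markers <- ap$subjects[c("subject_id", "wmh_volume", "tiv_ml",
                             "lacune_count", "cmb_count")]
    names(markers)[names(markers) == "tiv_ml"] <- "tiv"
    group <- as.integer(classify_csvd(markers)$flags$csvd)
    cmp <- regional_bag_comparison(bag, ap$subjects, group, cond$atlas)
    flagged <- cmp$table$region_id[cmp$table$significant]

    covs <- build_covariates(ap$subjects, vascular = FALSE)
    wide <- bag_wide(bag)[ap$subjects$subject_id, , drop = FALSE]
    med <- bootstrap_mediation(group, wide[, cond$mediator],
                               ap$subjects[[cond$outcome]], covs,
                               B = B, seed = seed + 1000L * i)
    pr <- med$boot[med$boot$stat == "prop", ]
    data.frame(
      rep = i,
      exact_set = setequal(flagged, cond$planted),
      n_flagged = length(flagged),
      n_planted_flagged = length(intersect(flagged, cond$planted)),
      prop_hat = pr$estimate, prop_lo = pr$ci_lower, prop_hi = pr$ci_upper,
      covered = pr$ci_lower <= cond$prop_true &
        cond$prop_true <= pr$ci_upper
    )
  })
  do.call(rbind, rows)
}
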