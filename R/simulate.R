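#' Simulation configuration for synthetic cohorts
#'
#' Collects every parameter of the synthetic-cohort generator: cohort sizes
#' and age ranges, the per-region GMV aging model, the CSVD extra-aging
#' offsets, the MRI marker model, the cognitive-outcome model, and the
#' master seed. The generator plants known effects so downstream recovery
#' can be checked against ground truth.
#'
#' The GMV model for subject i, region r, voxel j is
#' `g = mu_{r,j} - beta_r * age_eff - quad * age_eff^2 + N(0, sigma_g^2)`
#' where `age_eff = age + delta_r` in affected regions of CSVD subjects and
#' `age_eff = age` otherwise. Region slopes `beta_r` (GMV units per year)
#' are drawn once from `slope_range` under the master seed unless `beta`
#' is supplied explicitly.
#'
#' @param n_train,n_app Training and application cohort sizes.
#' @param train_age_range,app_age_range Age ranges in years; ages are drawn
#'   uniformly (the healthy training range spans 18-92 y, the application
#'   cohort is 50+ y).
#' @param beta Optional per-region aging slope(s) (GMV units/year); recycled
#'   over regions. When `NULL`, slopes are drawn uniformly from
#'   `slope_range`.
#' @param slope_range Range for randomly drawn region slopes.
#' @param quad Quadratic aging coefficient (GMV units/year^2), default 0.
#' @param sigma_g Voxel noise SD (GMV units); `0` gives the noise-free limit.
#' @param baseline_gmv,voxel_sd Mean voxel GMV at age 0 and the spread of
#'   voxel baselines within a region.
#' @param affected_regions Character vector of region_ids receiving the CSVD
#'   extra-aging offset.
#' @param delta_years Extra-aging offset(s) Delta_r in years, >= 0; scalar or
#'   one value per affected region.
#' @param delta_cv Subject-level heterogeneity of the extra aging: each CSVD
#'   subject's offsets are scaled by a multiplier drawn from N(1, delta_cv^2)
#'   truncated to \[0, 2\] (symmetric truncation, so the mean offset stays
#'   Delta_r). `0` (default) gives every CSVD subject the identical offset;
#'   note that in that degenerate case the true mediator is collinear with
#'   CSVD status, so a planted mediation path b is not identifiable.
#' @param markers List of marker-model parameters: WMH volume is lognormal
#'   with `wmh_meanlog` (log-ml at age 65), `wmh_sdlog`, age coefficient
#'   `wmh_age_coef` and latent-severity coefficient `wmh_sev_coef`; lacune
#'   and CMB counts are Poisson with log-rates
#'   `<marker>_lograte + <marker>_age_coef*(age-65) + <marker>_sev_coef*sev`;
#'   `sev_age_coef` couples the latent severity to age.
#' @param covariates List of covariate-distribution parameters
#'   (education mean/sd in years, EFC mean/sd, TIV mean/sd in litres, and
#'   Bernoulli prevalences for sex and the four vascular risk flags).
#' @param cognitive Named list of outcome models; each element is a list
#'   with `intercept`, `age_coef`, `edu_coef`, `sex_coef`, `b_m` (named
#'   vector: effect on the score per planted extra-aging year in each
#'   mediator region), `c_prime` (direct CSVD effect) and `sigma_y`.
#' @param seed Master RNG seed (integer).
#' @return A validated object of class `sim_config`.
#' @export
sim_config <- function(n_train = 1482, n_app = 734,
                       train_age_range = c(18, 92),
                       app_age_range = c(50, 90),
                       beta = NULL, slope_range = c(0.8, 1.8),
                       quad = 0, sigma_g = 5,
                       baseline_gmv = 650, voxel_sd = 20,
                       affected_regions = character(0), delta_years = 0,
                       delta_cv = 0, markers = list(), covariates = list(),
                       cognitive = NULL, seed = 1L) {
  mk <- utils::modifyList(list(
    wmh_meanlog = 0, wmh_sdlog = 0.8, wmh_age_coef = 0.04,
    wmh_sev_coef = 0.8, sev_age_coef = 0.03,
    lacune_lograte = -1.8, lacune_age_coef = 0.02, lacune_sev_coef = 0.8,
    cmb_lograte = -2.0, cmb_age_coef = 0.02, cmb_sev_coef = 0.8
  ), markers)
  cv <- utils::modifyList(list(
    education_mean = 8, education_sd = 4.5,
    efc_mean = 0.45, efc_sd = 0.04,
    tiv_mean_l = 1.45, tiv_sd_l = 0.13,
    p_male = 0.5, p_hypertension = 0.45, p_diabetes = 0.20,
    p_dyslipidemia = 0.30, p_smoking = 0.30
  ), covariates)
  if (is.null(cognitive)) {
    base <- function(intercept, age_coef, edu_coef) {
      list(intercept = intercept, age_coef = age_coef, edu_coef = edu_coef,
           sex_coef = 0, b_m = numeric(0), c_prime = 0, sigma_y = 2)
    }
    cognitive <- list(
      mmse  = base(27, -0.06, 0.15),
      cvvlt = base(7, -0.05, 0.10),
      vft   = base(14, -0.08, 0.20),
      cdt   = base(2.5, -0.01, 0.02)
    )
  }
  out <- structure(list(
    n_train = n_train, n_app = n_app,
    train_age_range = train_age_range, app_age_range = app_age_range,
    beta = beta, slope_range = slope_range, quad = quad, sigma_g = sigma_g,
    baseline_gmv = baseline_gmv, voxel_sd = voxel_sd,
    affected_regions = affected_regions, delta_years = delta_years,
    delta_cv = delta_cv, markers = mk, covariates = cv,
    cognitive = cognitive,
    seed = as.integer(seed)
  ), class = "sim_config")
  validate_sim_config(out)
}

validate_sim_config <- function(config, atlas = NULL) {
  stopifnot(inherits(config, "sim_config"))
  bad <- function(field, why) {
    stop("invalid sim_config field `", field, "`: ", why, call. = FALSE)
  }
  if (config$n_train < 1) bad("n_train", "must be >= 1")
  if (config$n_app < 1) bad("n_app", "must be >= 1")
  for (f in c("train_age_range", "app_age_range")) {
    r <- config[[f]]
    if (length(r) != 2 || !(r[1] < r[2])) bad(f, "must be a non-degenerate range")
  }
  if (config$sigma_g < 0) bad("sigma_g", "must be >= 0")
  if (config$markers$wmh_sdlog <= 0) bad("markers$wmh_sdlog", "must be > 0")
  for (nm in names(config$cognitive)) {
    if (config$cognitive[[nm]]$sigma_y < 0) {
      bad(paste0("cognitive$", nm, "$sigma_y"), "must be >= 0")
    }
  }
  if (any(config$delta_years < 0)) bad("delta_years", "must be >= 0")
  if (config$delta_cv < 0) bad("delta_cv", "must be >= 0")
  if (length(config$affected_regions) > 0 &&
      length(config$delta_years) > 1 &&
      length(config$delta_years) != length(config$affected_regions)) {
    bad("delta_years", "length must be 1 or match affected_regions")
  }
  if (!is.null(atlas)) {
    missing <- setdiff(config$affected_regions, atlas$regions$region_id)
    if (length(missing) > 0) {
      bad("affected_regions",
          paste("not in atlas:", paste(missing, collapse = ", ")))
    }
  }
  invisible(config)
}

# Region-level biology (slopes, voxel baselines) shared by the training and
# application cohorts; deterministic in the master seed and independent of
# the per-cohort noise streams.
region_params <- function(config, atlas) {
  set.seed(config$seed + 11L)
  R <- atlas$n_regions
  beta <- if (is.null(config$beta)) {
    stats::runif(R, config$slope_range[1], config$slope_range[2])
  } else {
    rep_len(config$beta, R)
  }
  names(beta) <- atlas$regions$region_id
  mu_region <- config$baseline_gmv + stats::rnorm(R, 0, 30)
  mu_voxel <- lapply(seq_len(R), function(i) {
    mu_region[i] + stats::rnorm(atlas$regions$n_voxels[i], 0, config$voxel_sd)
  })
  names(mu_voxel) <- atlas$regions$region_id
  list(beta = beta, mu_voxel = mu_voxel)
}

# age_eff: either a vector (same effective age in every region) or an
# n x n_regions matrix of per-region effective ages.
simulate_voxels <- function(config, atlas, params, age_eff) {
  n <- if (is.matrix(age_eff)) nrow(age_eff) else length(age_eff)
  blocks <- lapply(seq_len(atlas$n_regions), function(i) {
    rid <- atlas$regions$region_id[i]
    a <- if (is.matrix(age_eff)) age_eff[, i] else age_eff
    signal <- -params$beta[[rid]] * a - config$quad * a^2
    mu <- params$mu_voxel[[rid]]
    vox <- outer(signal, rep(1, length(mu))) +
      outer(rep(1, n), mu)
    if (config$sigma_g > 0) {
      vox <- vox + matrix(stats::rnorm(n * length(mu), 0, config$sigma_g),
                          nrow = n)
    }
    vox
  })
  voxels <- do.call(cbind, blocks)
  colnames(voxels) <- voxel_colnames(atlas)
  voxels
}

#' Generate the healthy training cohort
#'
#' Draws chronological ages uniformly over the training range and simulates
#' voxel-level GMV declining with age according to the shared region
#' parameters. Deterministic given `config$seed`.
#'
#' @param config A `sim_config`.
#' @param atlas An `atlas_spec`.
#' @return A list with `subjects` (data frame: subject_id, age, sex) and
#'   `features` (a [feature_set()]).
#' @export
generate_training_cohort <- function(config, atlas) {
  validate_sim_config(config, atlas)
  validate_atlas(atlas)
  params <- region_params(config, atlas)
  set.seed(config$seed + 21L)
  n <- config$n_train
  age <- stats::runif(n, config$train_age_range[1], config$train_age_range[2])
  sex <- stats::rbinom(n, 1, config$covariates$p_male)
  voxels <- simulate_voxels(config, atlas, params, age)
  ids <- sprintf("train_%05d", seq_len(n))
  subjects <- data.frame(subject_id = ids, age = age, sex = sex,
                         stringsAsFactors = FALSE)
  list(subjects = subjects, features = feature_set(voxels, atlas, ids))
}

#' Generate the application cohort with planted CSVD effects
#'
#' Simulates an older community cohort: covariates, a latent CSVD severity
#' coupled to age, the three MRI markers (lognormal WMH volume, Poisson
#' lacune and CMB counts), GMV features, and cognitive scores. CSVD group
#' membership is *not* written as a label: it arises from applying the
#' median-split marker rule ([classify_csvd()]) to the generated markers,
#' so the downstream classifier — not a stored column — defines the groups.
#' Subjects the rule designates as CSVD get GMV evaluated at effective age
#' `age + delta_r` in the affected regions, and cognitive scores receive
#' the planted mediation structure
#' `Y = intercept + covariate terms + sum_r b_r * extra_aging_r +
#'  c_prime * CSVD + N(0, sigma_y^2)`.
#'
#' @param config A `sim_config`.
#' @param atlas An `atlas_spec`.
#' @return A list with `subjects` (covariates, markers and cognitive
#'   scores), `features` (a [feature_set()]) and `truth` (the planted
#'   ground truth: CSVD assignment, per-subject extra aging, true mediation
#'   coefficients and true proportion mediated per region/outcome).
#' @export
generate_application_cohort <- function(config, atlas) {
  validate_sim_config(config, atlas)
  validate_atlas(atlas)
  params <- region_params(config, atlas)
  cv <- config$covariates
  mk <- config$markers
  set.seed(config$seed + 31L)
  n <- config$n_app
  age <- stats::runif(n, config$app_age_range[1], config$app_age_range[2])
  sex <- stats::rbinom(n, 1, cv$p_male)
  education <- pmax(0, stats::rnorm(n, cv$education_mean, cv$education_sd))
  efc <- stats::rnorm(n, cv$efc_mean, cv$efc_sd)
  tiv <- stats::rnorm(n, cv$tiv_mean_l, cv$tiv_sd_l)    # litres
  hypertension <- stats::rbinom(n, 1, cv$p_hypertension)
  diabetes <- stats::rbinom(n, 1, cv$p_diabetes)
  dyslipidemia <- stats::rbinom(n, 1, cv$p_dyslipidemia)
  smoking <- stats::rbinom(n, 1, cv$p_smoking)

  sev <- mk$sev_age_coef * (age - 65) + stats::rnorm(n)
  wmh_volume <- stats::rlnorm(
    n,
    meanlog = mk$wmh_meanlog + mk$wmh_age_coef * (age - 65) +
      mk$wmh_sev_coef * sev,
    sdlog = mk$wmh_sdlog
  )                                                      # ml
  lacune_count <- stats::rpois(n, exp(
    mk$lacune_lograte + mk$lacune_age_coef * (age - 65) +
      mk$lacune_sev_coef * sev))
  cmb_count <- stats::rpois(n, exp(
    mk$cmb_lograte + mk$cmb_age_coef * (age - 65) + mk$cmb_sev_coef * sev))

  ids <- sprintf("app_%05d", seq_len(n))
  markers <- data.frame(
    subject_id = ids, wmh_volume = wmh_volume, tiv = tiv * 1000,
    lacune_count = lacune_count, cmb_count = cmb_count,
    stringsAsFactors = FALSE
  )
  cls <- classify_csvd(markers)
  csvd <- cls$flags$csvd

  # planted extra aging: Delta_r years in affected regions of CSVD subjects
  aff <- config$affected_regions
  delta <- if (length(aff) > 0) {
    stats::setNames(rep_len(config$delta_years, length(aff)), aff)
  } else numeric(0)
  ridx <- match(aff, atlas$regions$region_id)
  age_eff <- matrix(age, nrow = n, ncol = atlas$n_regions)
  extra <- matrix(0, nrow = n, ncol = length(aff),
                  dimnames = list(ids, aff))
  # subject-level severity multiplier for the planted offsets (mean 1)
  u <- if (config$delta_cv > 0) {
    pmin(pmax(stats::rnorm(n, 1, config$delta_cv), 0), 2)
  } else rep(1, n)
  if (length(aff) > 0) {
    extra[csvd, ] <- u[csvd] %o% delta
    age_eff[, ridx] <- age_eff[, ridx] + extra
  }
  voxels <- simulate_voxels(config, atlas, params, age_eff)

  scores <- lapply(config$cognitive, function(m) {
    ind <- 0
    if (length(m$b_m) > 0) {
      bad <- setdiff(names(m$b_m), aff)
      if (length(bad) > 0) {
        stop("cognitive b_m names not in affected_regions: ",
             paste(bad, collapse = ", "))
      }
      ind <- as.vector(extra[, names(m$b_m), drop = FALSE] %*% m$b_m)
    }
    m$intercept + m$age_coef * (age - 65) + m$edu_coef * education +
      m$sex_coef * sex + ind + m$c_prime * csvd +
      stats::rnorm(n, 0, m$sigma_y)
  })

  subjects <- data.frame(
    subject_id = ids, age = age, sex = sex, education = education,
    efc = efc, tiv = tiv, hypertension = hypertension, diabetes = diabetes,
    dyslipidemia = dyslipidemia, smoking = smoking,
    wmh_volume = wmh_volume, tiv_ml = tiv * 1000,
    lacune_count = lacune_count, cmb_count = cmb_count,
    stringsAsFactors = FALSE
  )
  for (nm in names(scores)) subjects[[nm]] <- scores[[nm]]

  # true mediation quantities implied by the planted structure
  true_effects <- do.call(rbind, lapply(names(config$cognitive), function(o) {
    m <- config$cognitive[[o]]
    c_true <- m$c_prime + sum(m$b_m * delta[names(m$b_m)])
    if (length(m$b_m) == 0 && length(aff) == 0) return(NULL)
    data.frame(
      outcome = o,
      region = aff,
      ab_true = ifelse(aff %in% names(m$b_m),
                       m$b_m[match(aff, names(m$b_m))] * delta, 0),
      c_true = c_true,
      prop_true = ifelse(
        abs(c_true) > 1e-12,
        100 * ifelse(aff %in% names(m$b_m),
                     m$b_m[match(aff, names(m$b_m))] * delta, 0) / c_true,
        NA_real_),
      stringsAsFactors = FALSE
    )
  }))

  truth <- list(
    csvd = csvd,
    affected_regions = aff,
    delta_years = delta,
    extra_aging = extra,
    b_m = lapply(config$cognitive, `[[`, "b_m"),
    c_prime = vapply(config$cognitive, `[[`, numeric(1), "c_prime"),
    true_effects = true_effects,
    wmh_threshold = cls$threshold,
    mechanism = "median-split WMH/TIV ratio AND (lacunes or CMBs) applied to generated markers"
  )
  list(subjects = subjects, features = feature_set(voxels, atlas, ids),
       truth = truth)
}

#' Write ground truth as JSON
#'
#' @param truth The `truth` element of [generate_application_cohort()].
#' @param path Output JSON path.
#' @export
write_ground_truth_json <- function(truth, path) {
  out <- truth
  out$extra_aging <- as.data.frame(out$extra_aging)
  # keep names on length-1 vectors (auto_unbox would drop them)
  out$delta_years <- as.list(out$delta_years)
  out$b_m <- lapply(out$b_m, as.list)
  out$c_prime <- as.list(out$c_prime)
  jsonlite::write_json(out, path, dataframe = "columns", digits = NA,
                       auto_unbox = TRUE, na = "null")
  invisible(path)
}
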