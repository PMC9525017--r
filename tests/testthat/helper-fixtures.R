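# Shared desk-scale fixtures, all generated in code.

tiny_atlas <- function(nc = 4, ns = 1, nb = 1, v = 4) {
  atlas_spec(nc, ns, nb, voxels_per_region = v)
}

tiny_cfg <- function(..., seed = 42) {
  defaults <- list(n_train = 80, n_app = 60, sigma_g = 3, seed = seed)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# random covariate table in the shape build_covariates() produces
random_covs <- function(n, seed = 1, vascular = FALSE) {
  set.seed(seed)
  covs <- data.frame(
    age = runif(n, 50, 90), sex = rbinom(n, 1, 0.5),
    education = runif(n, 0, 16), efc = rnorm(n, 0.45, 0.04),
    tiv = rnorm(n, 1.45, 0.13)
  )
  if (vascular) {
    covs$hypertension <- rbinom(n, 1, 0.4)
    covs$diabetes <- rbinom(n, 1, 0.2)
    covs$dyslipidemia <- rbinom(n, 1, 0.3)
    covs$smoking <- rbinom(n, 1, 0.3)
  }
  covs$age2 <- covs$age^2
  covs[c("age", "age2", setdiff(names(covs), c("age", "age2")))]
}

# a mediation dataset with known planted structure
mediation_data <- function(n = 120, a = 2, b = -0.5, cprime = -1,
                           sd_m = 1, sd_y = 1, seed = 1) {
  set.seed(seed)
  covs <- random_covs(n, seed = seed + 1)
  x <- rbinom(n, 1, 0.4)
  m <- 1 + a * x + 0.05 * covs$age + rnorm(n, 0, sd_m)
  y <- 20 + b * m + cprime * x - 0.03 * covs$age +
    0.1 * covs$education + rnorm(n, 0, sd_y)
  list(x = x, m = m, y = y, covs = covs)
}

# independent normal-equations OLS oracle: coefficients, residual SS and
# the partial F test of one column
ols_oracle <- function(X, y) {
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  resid <- y - X %*% beta
  list(beta = drop(beta), sse = sum(resid^2),
       df = nrow(X) - ncol(X))
}
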