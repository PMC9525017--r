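test_that("path fits match a normal-equations oracle and obey c = c' + ab", {
  d <- mediation_data(n = 30, seed = 41)
  paths <- fit_mediation_paths(d$x, d$m, d$y, d$covs)
  cm <- as.matrix(d$covs)
  Xm <- cbind(1, d$x, cm)
  Xy <- cbind(1, d$m, d$x, cm)
  expect_equal(paths$a, unname(ols_oracle(Xm, d$m)$beta[2]),
               tolerance = 1e-10)
  expect_equal(paths$c, unname(ols_oracle(Xm, d$y)$beta[2]),
               tolerance = 1e-10)
  oy <- ols_oracle(Xy, d$y)
  expect_equal(paths$b, unname(oy$beta[2]), tolerance = 1e-10)
  expect_equal(paths$cprime, unname(oy$beta[3]), tolerance = 1e-10)
  expect_equal(paths$c, paths$cprime + paths$ab, tolerance = 1e-10)
})

test_that("the mediation identity holds on every fitted model", {
  for (seed in 1:20) {
    d <- mediation_data(n = 50 + seed, a = rnorm(1), b = rnorm(1),
                        cprime = rnorm(1), seed = seed)
    p <- fit_mediation_paths(d$x, d$m, d$y, d$covs)
    expect_lt(abs(p$c - (p$cprime + p$ab)), 1e-10 * max(1, abs(p$c)))
  }
})

test_that("covariate inclusion equals Frisch-Waugh pre-residualization", {
  d <- mediation_data(n = 80, seed = 42)
  paths <- fit_mediation_paths(d$x, d$m, d$y, d$covs)
  C <- as.matrix(d$covs)
  rx <- residuals(lm(d$x ~ C))
  rm_ <- residuals(lm(d$m ~ C))
  ry <- residuals(lm(d$y ~ C))
  a_fwl <- unname(coef(lm(rm_ ~ rx))[2])
  c_fwl <- unname(coef(lm(ry ~ rx))[2])
  byc <- coef(lm(ry ~ rm_ + rx))
  expect_equal(paths$a, a_fwl, tolerance = 1e-8)
  expect_equal(paths$c, c_fwl, tolerance = 1e-8)
  expect_equal(paths$b, unname(byc[2]), tolerance = 1e-8)
  expect_equal(paths$cprime, unname(byc[3]), tolerance = 1e-8)
})

test_that("rank-deficient or degenerate designs are rejected with names", {
  d <- mediation_data(n = 40, seed = 43)
  covs <- d$covs
  covs$copy <- covs$education
  expect_error(fit_mediation_paths(d$x, d$m, d$y, covs), "aliased|copy")
  expect_error(fit_mediation_paths(rep(1, 40), d$m, d$y, d$covs),
               "constant")
})

test_that("proportion mediated is 100*ab/c with an undefined flag", {
  expect_equal(as.numeric(proportion_mediated(0.7, 5)), 14)
  expect_equal(as.numeric(proportion_mediated(0, 5)), 0)
  expect_equal(as.numeric(proportion_mediated(5, 5)), 100)
  p <- proportion_mediated(0.7, 1e-12)
  expect_true(is.na(p))
  expect_false(attr(p, "defined"))
})

test_that("BCa reduces to the percentile interval when z0 = accel = 0", {
  # symmetric replicate set whose median equals the point estimate
  thetas <- c(seq(-1, -0.1, by = 0.1), seq(0.1, 1, by = 0.1))
  theta_hat <- 0          # exactly half the replicates lie below
  ci <- bca_interval(thetas, theta_hat, accel = 0, alpha = 0.1)
  expect_equal(attr(ci, "z0"), 0)
  expect_equal(as.numeric(ci),
               unname(quantile(thetas, c(0.05, 0.95), type = 7)))
})

test_that("BCa matches a hand-computed worked example at B = 10", {
  thetas <- c(0.5, 1.1, 0.8, 1.4, 0.9, 1.3, 0.7, 1.0, 1.2, 0.6)
  theta_hat <- 1.05
  accel <- 0.1
  # by hand: 6 of 10 replicates fall below 1.05
  z0 <- qnorm(6 / 10)
  zlo <- qnorm(0.025); zhi <- qnorm(0.975)
  a_lo <- pnorm(z0 + (z0 + zlo) / (1 - accel * (z0 + zlo)))
  a_hi <- pnorm(z0 + (z0 + zhi) / (1 - accel * (z0 + zhi)))
  expected <- quantile(thetas, c(a_lo, a_hi), type = 7, names = FALSE)
  ci <- bca_interval(thetas, theta_hat, accel = accel, alpha = 0.05)
  expect_equal(attr(ci, "z0"), z0, tolerance = 1e-12)
  expect_equal(as.numeric(ci), expected, tolerance = 1e-12)
})

test_that("bootstrap inference recovers a planted indirect effect", {
  d <- mediation_data(n = 150, a = 2, b = -0.6, cprime = -1, seed = 44)
  res <- bootstrap_mediation(d$x, d$m, d$y, d$covs, B = 500, seed = 7)
  boot <- res$boot
  expect_lt(boot$p[boot$stat == "ab"], 0.05)
  expect_lt(boot$p[boot$stat == "a"], 0.05)
  # interval orientation and sign of the indirect effect
  expect_lt(boot$ci_upper[boot$stat == "ab"], 0)
  # identical seed reproduces p-values and intervals exactly
  res2 <- bootstrap_mediation(d$x, d$m, d$y, d$covs, B = 500, seed = 7)
  expect_identical(res$boot, res2$boot)
})

test_that("a mediator independent of exposure yields a null a path", {
  set.seed(45)
  n <- 150
  covs <- random_covs(n, seed = 45)
  x <- rbinom(n, 1, 0.5)
  m <- rnorm(n)                       # independent of x
  y <- 10 - 0.5 * m + rnorm(n)
  res <- bootstrap_mediation(x, m, y, covs, B = 500, seed = 8)
  boot <- res$boot
  expect_gt(boot$p[boot$stat == "a"], 0.05)
  expect_gt(boot$p[boot$stat == "ab"], 0.05)
})

test_that("degenerate resamples are redrawn up to a capped retry count", {
  set.seed(46)
  n <- 9
  covs <- data.frame(age = runif(n, 50, 80))
  covs$age2 <- covs$age^2
  x <- c(1, rep(0, n - 1))            # resamples often drop the single 1
  m <- rnorm(n) + x
  y <- rnorm(n)
  expect_error(
    bootstrap_mediation(x, m, y, covs, B = 100, seed = 2, max_retries = 0,
                        method = "percentile"),
    "retry cap")
  res <- bootstrap_mediation(x, m, y, covs, B = 100, seed = 2,
                             max_retries = 200, method = "percentile")
  expect_gt(res$n_redraws, 0)
})

test_that("the screen covers every region-outcome pair once", {
  atlas <- tiny_atlas(nc = 2, ns = 0, nb = 0, v = 2)
  n <- 80
  set.seed(47)
  subjects <- cbind(
    data.frame(subject_id = sprintf("s%03d", 1:n)),
    random_covs(n, seed = 47)[c("age", "sex", "education", "efc", "tiv")]
  )
  subjects$mmse <- rnorm(n, 27)
  subjects$vft <- rnorm(n, 14)
  group <- rbinom(n, 1, 0.4)
  bag <- do.call(rbind, lapply(atlas$regions$region_id, function(r) {
    data.frame(subject_id = subjects$subject_id, scope = r,
               predicted_age = NA_real_, bag = rnorm(n))
  }))
  class(bag) <- c("bag_result", "data.frame")
  tab <- mediation_screen(bag, subjects, group,
                          regions = c("ctx_001", "ctx_002"),
                          outcomes = c("mmse", "vft"), B = 200, seed = 5)
  expect_equal(nrow(tab), 4)
  expect_setequal(paste(tab$region, tab$outcome),
                  c("ctx_001 mmse", "ctx_001 vft",
                    "ctx_002 mmse", "ctx_002 vft"))
  # all-null data: the joint a/b/ab requirement is conservative
  expect_equal(sum(tab$significant), 0)
  expect_error(
    mediation_screen(bag, subjects, group, "ctx_001", "bogus", B = 200),
    "bogus")
  expect_error(
    mediation_screen(bag, subjects, group, "ctx_099", "mmse", B = 200),
    "ctx_099")
})
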