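#' Fit the three mediation path regressions
#'
#' Single-level three-variable mediation of CSVD (X) on cognition (Y)
#' through regional BAG (M), with the confounders included as regressors
#' in all three ordinary-least-squares models:
#' \itemize{
#'   \item `M ~ X + covariates` — path a,
#'   \item `Y ~ X + covariates` — total effect, path c,
#'   \item `Y ~ M + X + covariates` — paths b and c'.
#' }
#' Because the three models share the same covariate set, the
#' decomposition `c = c' + a*b` is an exact algebraic identity of nested
#' least squares; it is asserted at fit time to 1e-10 (relative).
#'
#' @param x 0/1 exposure indicator (CSVD), non-constant.
#' @param m Mediator (regional BAG, years).
#' @param y Outcome (cognitive score).
#' @param covs Covariate data frame (age, age^2, sex, education, EFC, TIV;
#'   see [build_covariates()] with `vascular = FALSE`).
#' @return An object of class `mediation_paths`: coefficients `a`, `b`,
#'   `c`, `cprime`, `ab`, their standard errors, and `n`.
#' @export
fit_mediation_paths <- function(x, m, y, covs) {
  n <- length(x)
  stopifnot(length(m) == n, length(y) == n, nrow(covs) == n)
  if (stats::var(x) == 0) stop("exposure x is constant")
  cm <- as.matrix(covs)
  Xm <- cbind(`(Intercept)` = 1, x = x, cm)
  Xy <- cbind(`(Intercept)` = 1, m = m, x = x, cm)
  for (mat in list(Xm, Xy)) {
    q <- qr(mat)
    if (q$rank < ncol(mat)) {
      stop("rank-deficient design; aliased columns: ",
           paste(colnames(mat)[q$pivot[(q$rank + 1):ncol(mat)]],
                 collapse = ", "))
    }
  }
  fit_a <- stats::lm.fit(Xm, m)
  fit_c <- stats::lm.fit(Xm, y)
  fit_b <- stats::lm.fit(Xy, y)
  se_of <- function(fit, X) {
    rdf <- nrow(X) - ncol(X)
    s2 <- sum(fit$residuals^2) / rdf
    d <- diag(chol2inv(qr.R(fit$qr)))   # pivoted column order
    out <- numeric(ncol(X))
    out[fit$qr$pivot] <- d
    stats::setNames(sqrt(out * s2), colnames(X))
  }
  a <- fit_a$coefficients[["x"]]
  c_tot <- fit_c$coefficients[["x"]]
  b <- fit_b$coefficients[["m"]]
  cprime <- fit_b$coefficients[["x"]]
  ab <- a * b
  if (abs(c_tot - (cprime + ab)) > 1e-10 * max(1, abs(c_tot))) {
    stop("mediation identity c = c' + a*b violated beyond tolerance")
  }
  se_m <- se_of(fit_a, Xm)
  se_c <- se_of(fit_c, Xm)
  se_y <- se_of(fit_b, Xy)
  structure(list(
    a = a, b = b, c = c_tot, cprime = cprime, ab = ab,
    se = c(a = se_m[["x"]], b = se_y[["m"]], c = se_c[["x"]],
           cprime = se_y[["x"]]),
    n = n
  ), class = "mediation_paths")
}

#' @export
print.mediation_paths <- function(x, ...) {
  cat(sprintf(
    "mediation paths (n = %d): a = %.4f, b = %.4f, c = %.4f, c' = %.4f, a*b = %.4f\n",
    x$n, x$a, x$b, x$c, x$cprime, x$ab))
  invisible(x)
}

# BCa machinery -------------------------------------------------------------

#' Bias-corrected and accelerated bootstrap interval
#'
#' Given a vector of bootstrap replicates of a statistic, the point
#' estimate, the bias constant `z0 = qnorm(#\{theta* < theta_hat\}/B)` and
#' the acceleration `accel`, returns the BCa interval at level
#' `1 - alpha`: the empirical quantiles (type 7) of the replicates at the
#' adjusted tail probabilities
#' `pnorm(z0 + (z0 + z_alpha) / (1 - accel * (z0 + z_alpha)))`.
#' With `z0 = 0` and `accel = 0` this reduces exactly to the percentile
#' interval.
#'
#' @param thetas Bootstrap replicates.
#' @param theta_hat Point estimate on the original sample.
#' @param accel Acceleration constant (0 for the plain bias-corrected
#'   interval).
#' @param alpha Two-sided miscoverage level.
#' @param z0 Optional bias constant; computed from `thetas` when NULL.
#' @return Named vector `lower`, `upper`, with attributes `z0`, `accel`,
#'   `alpha_lower`, `alpha_upper`.
#' @export
bca_interval <- function(thetas, theta_hat, accel = 0, alpha = 0.05,
                         z0 = NULL) {
  B <- length(thetas)
  if (is.null(z0)) z0 <- bca_z0(thetas, theta_hat)
  adj <- function(z) stats::pnorm(z0 + (z0 + z) / (1 - accel * (z0 + z)))
  a_lo <- adj(stats::qnorm(alpha / 2))
  a_hi <- adj(stats::qnorm(1 - alpha / 2))
  ci <- stats::quantile(thetas, c(a_lo, a_hi), type = 7, names = FALSE)
  structure(c(lower = ci[1], upper = ci[2]),
            z0 = z0, accel = accel, alpha_lower = a_lo, alpha_upper = a_hi)
}

bca_z0 <- function(thetas, theta_hat) {
  B <- length(thetas)
  cnt <- sum(thetas < theta_hat)
  cnt <- min(max(cnt, 0.5), B - 0.5)   # keep qnorm finite at the extremes
  stats::qnorm(cnt / B)
}

jackknife_accel <- function(theta_jack) {
  d <- mean(theta_jack) - theta_jack
  denom <- sum(d^2)^1.5
  if (denom == 0) return(0)
  sum(d^3) / (6 * denom)
}

# Two-sided p by CI inversion: the smallest alpha at which the BCa interval
# excludes zero (bisection; endpoints are monotone in alpha).
bca_pvalue <- function(thetas, theta_hat, accel = 0, z0 = NULL) {
  if (is.null(z0)) z0 <- bca_z0(thetas, theta_hat)
  excl <- function(alpha) {
    ci <- bca_interval(thetas, theta_hat, accel, alpha, z0)
    ci[["lower"]] > 0 || ci[["upper"]] < 0
  }
  lo <- 1e-6; hi <- 1 - 1e-6
  if (excl(lo)) return(lo)
  if (!excl(hi)) return(1)
  for (i in 1:50) {
    mid <- (lo + hi) / 2
    if (excl(mid)) hi <- mid else lo <- mid
  }
  hi
}

#' Proportion of the total effect that is mediated
#'
#' `100 * ab / c`, the percentage of the total effect of CSVD on the
#' cognitive score explained by the brain-age-gap pathway. Undefined when
#' the total effect is (numerically) zero; the raw value is reported even
#' outside 0-100 (suppression/inconsistent mediation), flagged via the
#' `defined` attribute.
#'
#' @param ab Indirect effect `a*b`.
#' @param c Total effect.
#' @param tol Threshold on `|c|` below which the proportion is undefined.
#' @return Percentage (possibly outside 0-100), with attribute `defined`;
#'   `NA` when undefined.
#' @export
proportion_mediated <- function(ab, c, tol = 1e-8) {
  if (abs(c) <= tol) {
    return(structure(NA_real_, defined = FALSE))
  }
  structure(100 * ab / c, defined = TRUE)
}

#' BCa bootstrap inference for one mediation model
#'
#' Case resampling of whole subject rows, B bootstrap replicates (default
#' 10000) of the path coefficients a, b and a*b, bias constants from the
#' replicate distribution, acceleration constants from a leave-one-out
#' jackknife, BCa confidence intervals, and two-sided p-values by interval
#' inversion. Degenerate resamples (constant exposure or mediator) are
#' redrawn up to a capped retry count.
#'
#' @inheritParams fit_mediation_paths
#' @param B Number of bootstrap resamples, >= 100.
#' @param seed RNG seed; identical seeds give identical p-values and
#'   intervals.
#' @param alpha Level for the reported confidence intervals.
#' @param method `"bca"` (default), `"bc"` (no acceleration) or
#'   `"percentile"` (no bias correction either).
#' @param max_retries Cap on redraws of degenerate resamples.
#' @return An object of class `mediation_result`: the fitted
#'   `mediation_paths`, a `boot` table (estimate, z0, accel, CI, p for a,
#'   b, ab, plus a CI for the proportion mediated, which being a
#'   descriptive ratio carries no p-value), `prop_mediated`, and the
#'   B/seed/alpha/method used.
#' @export
bootstrap_mediation <- function(x, m, y, covs, B = 10000, seed = 1L,
                                alpha = 0.05, method = c("bca", "bc",
                                                         "percentile"),
                                max_retries = 100L) {
  method <- match.arg(method)
  if (B < 100) stop("B must be >= 100")
  paths <- fit_mediation_paths(x, m, y, covs)
  n <- paths$n
  cm <- as.matrix(covs)
  Xm <- cbind(1, x, cm)
  Xy <- cbind(1, m, x, cm)
  pm <- ncol(Xm)
  py <- ncol(Xy)

  coef_at <- function(fit, col, p) {
    cf <- numeric(p)
    cf[fit$pivot] <- fit$coefficients
    cf[col]
  }
  # replicates of (a, b, ab) plus the total effect c, from which the
  # proportion-mediated replicate 100*ab/c is derived
  stat_fun <- function(idx) {
    a <- coef_at(.lm.fit(Xm[idx, , drop = FALSE], m[idx]), 2L, pm)
    b <- coef_at(.lm.fit(Xy[idx, , drop = FALSE], y[idx]), 2L, py)
    cc <- coef_at(.lm.fit(Xm[idx, , drop = FALSE], y[idx]), 2L, pm)
    c(a, b, a * b, if (abs(cc) > 1e-8) 100 * a * b / cc else NA_real_)
  }

  set.seed(seed)
  thetas <- matrix(NA_real_, nrow = B, ncol = 4,
                   dimnames = list(NULL, c("a", "b", "ab", "prop")))
  redraws <- 0L
  for (bb in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    tries <- 0L
    while (stats::var(x[idx]) == 0 || stats::var(m[idx]) == 0) {
      tries <- tries + 1L
      if (tries > max_retries) stop("degenerate bootstrap resamples: retry cap reached")
      idx <- sample.int(n, n, replace = TRUE)
    }
    redraws <- redraws + tries
    thetas[bb, ] <- stat_fun(idx)
  }

  stat_names <- c("a", "b", "ab", "prop")
  accel <- stats::setNames(rep(0, 4), stat_names)
  if (method == "bca") {
    jack <- t(vapply(seq_len(n), function(i) stat_fun(seq_len(n)[-i]),
                     numeric(4)))
    accel <- apply(jack, 2, function(col) {
      jackknife_accel(col[!is.na(col)])
    })
    names(accel) <- stat_names
  }
  prop <- proportion_mediated(paths$ab, paths$c)
  est <- c(a = paths$a, b = paths$b, ab = paths$ab,
           prop = as.numeric(prop))
  rows <- lapply(stat_names, function(s) {
    th <- thetas[, s]
    th <- th[!is.na(th)]
    if (s == "prop" && (length(th) < 100 || is.na(est[[s]]))) {
      return(data.frame(stat = s, estimate = est[[s]], z0 = NA_real_,
                        accel = NA_real_, ci_lower = NA_real_,
                        ci_upper = NA_real_, p = NA_real_))
    }
    z0 <- if (method == "percentile") 0 else bca_z0(th, est[[s]])
    ci <- bca_interval(th, est[[s]], accel[[s]], alpha, z0)
    data.frame(
      stat = s, estimate = est[[s]], z0 = z0, accel = accel[[s]],
      ci_lower = ci[["lower"]], ci_upper = ci[["upper"]],
      # the proportion is a descriptive ratio, not a tested null
      p = if (s == "prop") NA_real_
          else bca_pvalue(th, est[[s]], accel[[s]], z0))
  })
  boot <- do.call(rbind, rows)
  rownames(boot) <- NULL
  structure(list(
    paths = paths, boot = boot, prop_mediated = prop,
    B = B, seed = seed, alpha = alpha, method = method,
    n_redraws = redraws, thetas = thetas
  ), class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  print(x$paths)
  print(x$boot, row.names = FALSE)
  cat(sprintf("proportion mediated: %s%% (B = %d, %s)\n",
              ifelse(attr(x$prop_mediated, "defined"),
                     sprintf("%.1f", x$prop_mediated), "undefined"),
              x$B, x$method))
  invisible(x)
}

#' Mediation screen over regions and cognitive outcomes
#'
#' Runs one covariate-adjusted BCa-bootstrap mediation model per
#' (region, outcome) pair, with CSVD as exposure, that region's BAG as
#' mediator and the cognitive score as outcome. A model is declared a
#' significant mediation when every required path (by default a, b and
#' a*b) has bootstrap p below `alpha`; an optional Bonferroni
#' family-wise-corrected flag over the number of models screened is also
#' reported.
#'
#' @param bag A `bag_result`.
#' @param subjects Application subject table (covariates and outcomes).
#' @param group 0/1 CSVD indicator.
#' @param regions Region ids to screen (typically the set flagged by
#'   [regional_bag_comparison()]).
#' @param outcomes Names of cognitive score columns in `subjects`.
#' @param B,alpha,seed Bootstrap settings; each model gets a distinct seed
#'   derived from `seed`.
#' @param fwer Also flag significance at the Bonferroni level
#'   `alpha / (number of models)`.
#' @param require Which paths must be individually significant.
#' @param method Passed to [bootstrap_mediation()].
#' @return Data frame, one row per (region, outcome): path coefficients,
#'   bootstrap p-values, a*b interval, proportion mediated, flags.
#' @export
mediation_screen <- function(bag, subjects, group, regions, outcomes,
                             B = 10000, alpha = 0.05, seed = 1L,
                             fwer = FALSE, require = c("a", "b", "ab"),
                             method = "bca") {
  bad <- setdiff(outcomes, names(subjects))
  if (length(bad) > 0) {
    stop("unknown outcome column(s): ", paste(bad, collapse = ", "))
  }
  covs <- build_covariates(subjects, vascular = FALSE)
  wide <- bag_wide(bag)[subjects$subject_id, , drop = FALSE]
  bad_r <- setdiff(regions, colnames(wide))
  if (length(bad_r) > 0) {
    stop("regions absent from BAG table: ", paste(bad_r, collapse = ", "))
  }
  grid <- expand.grid(region = regions, outcome = outcomes,
                      stringsAsFactors = FALSE)
  n_models <- nrow(grid)
  rows <- lapply(seq_len(n_models), function(i) {
    r <- grid$region[i]; o <- grid$outcome[i]
    res <- bootstrap_mediation(group, wide[, r], subjects[[o]], covs,
                               B = B, seed = seed + i, alpha = alpha,
                               method = method)
    p <- stats::setNames(res$boot$p, res$boot$stat)
    ci <- res$boot[res$boot$stat == "ab", c("ci_lower", "ci_upper")]
    pci <- res$boot[res$boot$stat == "prop", c("ci_lower", "ci_upper")]
    data.frame(
      region = r, outcome = o,
      a = res$paths$a, b = res$paths$b, c = res$paths$c,
      cprime = res$paths$cprime, ab = res$paths$ab,
      p_a = p[["a"]], p_b = p[["b"]], p_ab = p[["ab"]],
      ab_ci_lower = ci$ci_lower, ab_ci_upper = ci$ci_upper,
      prop_ci_lower = pci$ci_lower, prop_ci_upper = pci$ci_upper,
      prop_mediated = as.numeric(res$prop_mediated),
      prop_defined = isTRUE(attr(res$prop_mediated, "defined")),
      significant = all(p[require] < alpha),
      significant_fwer = if (fwer) {
        all(p[require] < bonferroni_threshold(alpha, n_models))
      } else NA,
      B = B, seed = seed + i,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
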