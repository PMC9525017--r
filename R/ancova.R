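#' Covariate sets used in the group comparisons and mediation models
#'
#' The ANCOVA nuisance set comprises chronological age, its square, sex,
#' education years, the entropy-focus-criterion image-quality index, total
#' intracranial volume, and the four vascular risk flags. Covarying age and
#' age^2 also adjusts the age bias of brain-age predictions, so no
#' prediction-time bias correction is applied. The mediation models adjust
#' for the same set minus the vascular risk flags.
#'
#' @param subjects Subject table containing `age`, `sex`, `education`,
#'   `efc`, `tiv` and (for the ANCOVA set) `hypertension`, `diabetes`,
#'   `dyslipidemia`, `smoking`.
#' @param vascular Include the four vascular risk flags.
#' @return Data frame of covariates with an `age2` column equal to
#'   `age^2` exactly.
#' @export
build_covariates <- function(subjects, vascular = TRUE) {
  need <- c("age", "sex", "education", "efc", "tiv")
  if (vascular) {
    need <- c(need, "hypertension", "diabetes", "dyslipidemia", "smoking")
  }
  miss <- setdiff(need, names(subjects))
  if (length(miss) > 0) {
    stop("subject table missing covariate columns: ",
         paste(miss, collapse = ", "))
  }
  covs <- subjects[need]
  covs$age2 <- covs$age^2
  covs <- covs[c("age", "age2", setdiff(need, "age"))]
  if (anyNA(covs)) stop("missing values in covariates")
  covs
}

#' ANCOVA group effect with partial eta-squared
#'
#' Fits the linear model `y ~ group + covariates` by ordinary least squares
#' and tests the single-degree-of-freedom group term. The effect size is
#' partial eta-squared, `SS_group / (SS_group + SS_residual)`, where
#' `SS_group` is the partial (drop-one) sum of squares of the group
#' indicator; for a single-df term this equals `t^2 / (t^2 + df_residual)`.
#'
#' @param y Response vector (e.g. BAG in years).
#' @param group 0/1 group indicator (non-constant).
#' @param covs Covariate data frame (see [build_covariates()]).
#' @return A one-row data frame: `estimate` (adjusted group difference, in
#'   the units of `y`), `t`, `df`, `p`, `eta2`, `ss_group`, `ss_resid`.
#' @export
ancova_group_effect <- function(y, group, covs) {
  n <- length(y)
  stopifnot(length(group) == n, nrow(covs) == n)
  if (stats::var(y) == 0) stop("constant response y")
  if (stats::var(group) == 0) stop("group indicator is constant")
  dat <- data.frame(y = y, group = group, covs)
  if (n <= ncol(dat) + 2) stop("too few rows for the model")
  fit <- stats::lm(y ~ ., data = dat)
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    stop("collinear predictors: ", paste(names(cf)[is.na(cf)], collapse = ", "))
  }
  sm <- summary(fit)
  t_stat <- sm$coefficients["group", "t value"]
  p <- sm$coefficients["group", "Pr(>|t|)"]
  df_res <- fit$df.residual
  ss_res <- sum(stats::residuals(fit)^2)
  # partial SS of the group term: extra SSE when the term is dropped
  fit0 <- stats::lm(y ~ . - group, data = dat)
  ss_group <- sum(stats::residuals(fit0)^2) - ss_res
  data.frame(
    estimate = cf[["group"]], t = t_stat, df = df_res, p = p,
    eta2 = ss_group / (ss_group + ss_res),
    ss_group = ss_group, ss_resid = ss_res
  )
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise error rate, in (0, 1).
#' @param k Number of comparisons, >= 1.
#' @return `alpha / k`.
#' @examples
#' bonferroni_threshold(0.05, 442)   # 0.000113...
#' @export
bonferroni_threshold <- function(alpha, k) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (k < 1) stop("k must be >= 1")
  alpha / k
}

#' Region-wise BAG comparison between CSVD and non-CSVD groups
#'
#' Runs one covariate-adjusted ANCOVA per atlas region on the regional BAG
#' and flags regions whose group p-value falls below the Bonferroni
#' threshold `alpha / K`, K being the number of regions tested. Returns the
#' per-region table plus tallies of the significant set by compartment and
#' network. The global scope, if present in `bag`, is tested without
#' multiplicity correction (the global BAG collapses the regional pattern
#' into one measure).
#'
#' @param bag A `bag_result` (see [predict_and_bag()]).
#' @param subjects Application subject table (covariates present).
#' @param group 0/1 CSVD indicator aligned with `subjects`.
#' @param atlas The `atlas_spec` providing compartment/network labels.
#' @param alpha Family-wise significance level (default 0.05).
#' @return A list: `table` (one row per region: estimate, t, p, eta2,
#'   significant), `threshold`, `n_regions`, `by_compartment`, `by_network`,
#'   `global` (one-row ANCOVA result or NULL).
#' @export
regional_bag_comparison <- function(bag, subjects, group, atlas,
                                    alpha = 0.05) {
  covs <- build_covariates(subjects, vascular = TRUE)
  wide <- bag_wide(bag)
  wide <- wide[subjects$subject_id, , drop = FALSE]
  regions <- intersect(atlas$regions$region_id, colnames(wide))
  missing <- setdiff(atlas$regions$region_id, colnames(wide))
  if (length(missing) > 0) {
    stop("BAG table missing regions: ", paste(missing, collapse = ", "))
  }
  k <- length(regions)
  thr <- bonferroni_threshold(alpha, k)
  rows <- lapply(regions, function(r) {
    res <- ancova_group_effect(wide[, r], group, covs)
    cbind(region_id = r, res,
          atlas$regions[match(r, atlas$regions$region_id),
                        c("compartment", "network")])
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab$significant <- tab$p < thr
  sig <- tab[tab$significant, ]
  glob <- if ("global" %in% colnames(wide)) {
    ancova_group_effect(wide[, "global"], group, covs)
  } else NULL
  list(
    table = tab, threshold = thr, n_regions = k, alpha = alpha,
    by_compartment = table(factor(sig$compartment,
                                  levels = unique(atlas$regions$compartment))),
    by_network = table(factor(sig$network,
                              levels = unique(atlas$regions$network))),
    global = glob
  )
}

#' Cohort demographics comparison table
#'
#' Table-1-style group comparison: Welch t-tests for continuous variables,
#' chi-squared tests for binary ones.
#'
#' @param subjects Subject table.
#' @param group 0/1 CSVD indicator.
#' @param continuous,binary Column names to compare.
#' @return Data frame with per-variable group means/proportions and p-values.
#' @export
cohort_summary_table <- function(subjects, group,
                                 continuous = c("age", "education", "efc",
                                                "tiv"),
                                 binary = c("sex", "hypertension", "diabetes",
                                            "dyslipidemia", "smoking")) {
  rows <- lapply(c(continuous, binary), function(v) {
    x <- subjects[[v]]
    if (v %in% continuous) {
      tt <- stats::t.test(x ~ group)
      data.frame(variable = v, type = "continuous",
                 group0 = mean(x[group == 0]), group1 = mean(x[group == 1]),
                 sd0 = stats::sd(x[group == 0]), sd1 = stats::sd(x[group == 1]),
                 p = tt$p.value)
    } else {
      tab <- table(factor(group, levels = 0:1), factor(x, levels = 0:1))
      p <- tryCatch(suppressWarnings(stats::chisq.test(tab)$p.value),
                    error = function(e) NA_real_)
      data.frame(variable = v, type = "binary",
                 group0 = mean(x[group == 0]), group1 = mean(x[group == 1]),
                 sd0 = NA_real_, sd1 = NA_real_, p = p)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
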