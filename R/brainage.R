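#' Specification of the brain-age prediction model
#'
#' Radial-basis-function epsilon-support-vector regression with
#' hyperparameters selected by grid search in a nested cross-validation.
#' Both the cost grid and the gamma grid default to the seven values
#' 0.001, 0.01, 0.1, 1, 10, 100, 1000.
#'
#' @param cost_grid,gamma_grid Candidate values for the SVR cost C and RBF
#'   gamma; sorted ascending internally (ties in the grid search break
#'   toward the smallest C, then the smallest gamma).
#' @param epsilon Width of the epsilon-insensitive loss, in (scaled) years.
#' @param k_outer,k_inner Number of outer and inner cross-validation folds.
#' @param seed RNG seed controlling fold assignment.
#' @param scale Z-score each feature column using training-fold statistics
#'   before kernel regression (RBF kernels need comparable feature scales).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(cost_grid = 10^(-3:3), gamma_grid = 10^(-3:3),
                       epsilon = 0.1, k_outer = 5, k_inner = 5,
                       seed = 1L, scale = TRUE) {
  if (length(cost_grid) < 1 || length(gamma_grid) < 1) {
    stop("hyperparameter grids must be non-empty")
  }
  if (k_outer < 2 || k_inner < 2) stop("folds must be >= 2")
  structure(list(
    cost_grid = sort(cost_grid), gamma_grid = sort(gamma_grid),
    epsilon = epsilon, k_outer = as.integer(k_outer),
    k_inner = as.integer(k_inner), seed = as.integer(seed),
    scale = isTRUE(scale)
  ), class = "model_spec")
}

#' Mean absolute error
#'
#' @param pred,true Equal-length numeric vectors (years).
#' @return Mean of `|pred - true|`, in years.
#' @export
mae <- function(pred, true) {
  stopifnot(length(pred) == length(true), length(pred) >= 1)
  mean(abs(pred - true))
}

#' Coefficient of determination
#'
#' `R^2 = 1 - SSE/SST` about the mean of `true`. When `true` has zero
#' variance the statistic is undefined: `NaN` is returned with a warning.
#'
#' @param pred,true Equal-length numeric vectors, length >= 2.
#' @return Unitless R^2 (may be negative for predictions worse than the
#'   mean baseline).
#' @export
r_squared <- function(pred, true) {
  stopifnot(length(pred) == length(true), length(pred) >= 2)
  sst <- sum((true - mean(true))^2)
  if (sst == 0) {
    warning("R^2 undefined: zero variance in true values")
    return(NaN)
  }
  1 - sum((true - pred)^2) / sst
}

# Age-decile-stratified fold assignment, shuffled once with `seed`.
# Residues are dealt consecutively across strata so every fold receives
# floor(n/k) or ceiling(n/k) subjects.
make_age_folds <- function(ages, k, seed) {
  n <- length(ages)
  if (n < k) stop("need at least as many subjects as folds (n = ", n,
                  ", k = ", k, ")")
  set.seed(seed)
  breaks <- unique(stats::quantile(ages, probs = seq(0, 1, 0.1), type = 7))
  strata <- if (length(breaks) > 2) {
    cut(ages, breaks, include.lowest = TRUE, labels = FALSE)
  } else rep(1L, n)
  fold <- integer(n)
  start <- 0L
  for (s in sort(unique(strata))) {
    idx <- which(strata == s)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- ((start + seq_along(idx) - 1L) %% k) + 1L
    start <- start + length(idx)
  }
  fold
}

# Training-column standardization; constant columns get unit scale with a
# warning so downstream division is safe.
fit_scaler <- function(x) {
  center <- colMeans(x)
  sdev <- apply(x, 2, stats::sd)
  if (any(sdev == 0)) {
    warning("constant feature column(s): ",
            paste(colnames(x)[sdev == 0], collapse = ", "),
            "; using unit scale")
    sdev[sdev == 0] <- 1
  }
  list(center = center, scale = sdev)
}

apply_scaler <- function(x, scaler) {
  sweep(sweep(x, 2, scaler$center, "-"), 2, scaler$scale, "/")
}

#' @importFrom e1071 svm
svr_fit_raw <- function(x, y, spec, cost, gamma) {
  e1071::svm(x = x, y = y, type = "eps-regression", kernel = "radial",
             cost = cost, gamma = gamma, epsilon = spec$epsilon,
             scale = FALSE)
}

# k-fold grid search over all (C, gamma) pairs; returns the pair with the
# smallest cross-validated MAE, ties broken toward smallest C then gamma.
svr_cv_select <- function(x, y, spec, k, seed) {
  fold <- make_age_folds(y, k, seed)
  grid <- expand.grid(gamma = spec$gamma_grid, cost = spec$cost_grid,
                      KEEP.OUT.ATTRS = FALSE)
  # expand.grid varies gamma fastest, so rows are ordered by (cost, gamma)
  grid <- grid[order(grid$cost, grid$gamma), ]
  abs_err <- matrix(NA_real_, nrow = length(y), ncol = nrow(grid))
  pred_best <- rep(NA_real_, length(y))
  for (f in seq_len(k)) {
    tr <- fold != f
    xs <- x[tr, , drop = FALSE]
    xt <- x[!tr, , drop = FALSE]
    if (spec$scale) {
      scaler <- suppressWarnings(fit_scaler(xs))
      xs <- apply_scaler(xs, scaler)
      xt <- apply_scaler(xt, scaler)
    }
    for (g in seq_len(nrow(grid))) {
      fit <- svr_fit_raw(xs, y[tr], spec, grid$cost[g], grid$gamma[g])
      abs_err[!tr, g] <- abs(predict(fit, xt) - y[!tr])
    }
  }
  cv_mae <- colMeans(abs_err)
  best <- which.min(cv_mae)          # first minimum: smallest C then gamma
  list(cost = grid$cost[best], gamma = grid$gamma[best],
       grid = cbind(grid, cv_mae = cv_mae), fold = fold,
       oof_abs_err = abs_err[, best])
}

#' Fit a brain-age SVR with nested cross-validation
#'
#' The outer loop estimates out-of-sample accuracy: for each outer fold,
#' the inner loop grid-searches (C, gamma) on the remaining folds only,
#' the selected model is refit on those folds, and the held-out fold is
#' predicted. Pooled MAE, R^2 and Pearson r are computed on the
#' concatenated out-of-fold predictions, so no subject is ever predicted
#' by a model that saw it. The final model is then refit on all subjects
#' with hyperparameters chosen by a plain k-fold grid search over the
#' whole training set.
#'
#' @param x Numeric feature matrix (subjects x features), no missing values.
#' @param ages Chronological ages in years, aligned with the rows of `x`.
#' @param spec A [model_spec()].
#' @param nested Run the outer loop. With `nested = FALSE` only the final
#'   whole-set grid search and refit are performed, and the reported CV
#'   metrics come from that single-level search's out-of-fold predictions
#'   at the selected pair (slightly optimistic; used in the desk-scale
#'   simulation experiments).
#' @return An object of class `brainage_model` carrying the fitted SVR,
#'   the scaler, the chosen hyperparameters and a `cv` element
#'   (per-outer-fold MAE/R^2 and chosen pairs, pooled metrics, out-of-fold
#'   predictions).
#' @export
nested_cv_fit <- function(x, ages, spec = model_spec(), nested = TRUE) {
  stopifnot(is.matrix(x))
  if (nrow(x) != length(ages)) stop("rows of x must align with ages")
  if (anyNA(x) || anyNA(ages)) stop("missing values not allowed")
  if (nrow(x) < spec$k_outer) {
    stop("need n >= k_outer (n = ", nrow(x), ", k_outer = ", spec$k_outer, ")")
  }
  degenerate <- stats::var(ages) == 0
  if (degenerate) {
    # all targets identical: the epsilon-SVR solution is the constant, and
    # R^2 has no baseline variance to explain
    warning("ages are constant: predictions fixed at that value, R^2 undefined")
    fold <- rep_len(seq_len(spec$k_outer), length(ages))
    oof <- data.frame(index = seq_along(ages), fold = fold, age = ages,
                      predicted = ages[1])
    cv <- list(
      fold_metrics = data.frame(fold = seq_len(spec$k_outer),
                                n_test = as.integer(table(fold)),
                                mae = 0, r2 = NaN,
                                cost = spec$cost_grid[1],
                                gamma = spec$gamma_grid[1]),
      pooled_mae = 0, pooled_r2 = NaN, pooled_r = NaN, oof = oof,
      final_cost = spec$cost_grid[1], final_gamma = spec$gamma_grid[1],
      grid = NULL
    )
    return(structure(list(
      fit = NULL, constant = ages[1],
      scaler = if (spec$scale) suppressWarnings(fit_scaler(x)) else NULL,
      feature_names = colnames(x),
      cost = spec$cost_grid[1], gamma = spec$gamma_grid[1],
      epsilon = spec$epsilon, spec = spec, cv = cv
    ), class = "brainage_model"))
  }

  fold_tab <- NULL
  oof <- NULL
  if (nested) {
    fold <- make_age_folds(ages, spec$k_outer, spec$seed)
    pred <- rep(NA_real_, length(ages))
    rows <- vector("list", spec$k_outer)
    for (f in seq_len(spec$k_outer)) {
      tr <- fold != f
      sel <- svr_cv_select(x[tr, , drop = FALSE], ages[tr], spec,
                           spec$k_inner, spec$seed + f)
      xs <- x[tr, , drop = FALSE]
      xt <- x[!tr, , drop = FALSE]
      if (spec$scale) {
        scaler <- suppressWarnings(fit_scaler(xs))
        xs <- apply_scaler(xs, scaler)
        xt <- apply_scaler(xt, scaler)
      }
      fit <- svr_fit_raw(xs, ages[tr], spec, sel$cost, sel$gamma)
      pred[!tr] <- predict(fit, xt)
      rows[[f]] <- data.frame(
        fold = f, n_test = sum(!tr),
        mae = mae(pred[!tr], ages[!tr]),
        r2 = if (degenerate || stats::var(ages[!tr]) == 0) NaN
             else r_squared(pred[!tr], ages[!tr]),
        cost = sel$cost, gamma = sel$gamma
      )
    }
    fold_tab <- do.call(rbind, rows)
    oof <- data.frame(index = seq_along(ages), fold = fold,
                      age = ages, predicted = pred)
  }

  final_sel <- svr_cv_select(x, ages, spec, spec$k_inner, spec$seed + 101L)
  scaler <- if (spec$scale) fit_scaler(x) else NULL
  xs <- if (spec$scale) apply_scaler(x, scaler) else x
  final_fit <- svr_fit_raw(xs, ages, spec, final_sel$cost, final_sel$gamma)

  if (!nested) {
    fold <- final_sel$fold
    # one extra CV pass at the selected pair yields out-of-fold predictions
    # for the pooled metrics
    pred <- cv_oof_predict(x, ages, spec, final_sel$cost, final_sel$gamma,
                           fold)
    fold_tab <- do.call(rbind, lapply(seq_len(max(fold)), function(f) {
      data.frame(fold = f, n_test = sum(fold == f),
                 mae = mae(pred[fold == f], ages[fold == f]),
                 r2 = if (degenerate || stats::var(ages[fold == f]) == 0) NaN
                      else r_squared(pred[fold == f], ages[fold == f]),
                 cost = final_sel$cost, gamma = final_sel$gamma)
    }))
    oof <- data.frame(index = seq_along(ages), fold = fold,
                      age = ages, predicted = pred)
  }

  pooled_r2 <- if (degenerate) {
    warning("ages are constant: R^2 undefined")
    NaN
  } else r_squared(oof$predicted, oof$age)
  cv <- list(
    fold_metrics = fold_tab,
    pooled_mae = mae(oof$predicted, oof$age),
    pooled_r2 = pooled_r2,
    pooled_r = if (degenerate) NaN else stats::cor(oof$predicted, oof$age),
    oof = oof,
    final_cost = final_sel$cost, final_gamma = final_sel$gamma,
    grid = final_sel$grid
  )
  structure(list(
    fit = final_fit, scaler = scaler, feature_names = colnames(x),
    cost = final_sel$cost, gamma = final_sel$gamma,
    epsilon = spec$epsilon, spec = spec, cv = cv
  ), class = "brainage_model")
}

cv_oof_predict <- function(x, ages, spec, cost, gamma, fold) {
  pred <- rep(NA_real_, length(ages))
  for (f in seq_len(max(fold))) {
    tr <- fold != f
    xs <- x[tr, , drop = FALSE]
    xt <- x[!tr, , drop = FALSE]
    if (spec$scale) {
      scaler <- suppressWarnings(fit_scaler(xs))
      xs <- apply_scaler(xs, scaler)
      xt <- apply_scaler(xt, scaler)
    }
    fit <- svr_fit_raw(xs, ages[tr], spec, cost, gamma)
    pred[!tr] <- predict(fit, xt)
  }
  pred
}

#' Predict brain age for new subjects
#'
#' @param object A `brainage_model`.
#' @param newdata Feature matrix whose columns match the training schema
#'   (same names; order is reconciled by name).
#' @param ... Unused.
#' @return Predicted ages in years.
#' @export
predict.brainage_model <- function(object, newdata, ...) {
  stopifnot(is.matrix(newdata))
  missing <- setdiff(object$feature_names, colnames(newdata))
  extra <- setdiff(colnames(newdata), object$feature_names)
  if (length(missing) > 0 || length(extra) > 0) {
    stop("feature schema mismatch; missing: [",
         paste(missing, collapse = ", "), "] extra: [",
         paste(extra, collapse = ", "), "]")
  }
  newdata <- newdata[, object$feature_names, drop = FALSE]
  if (is.null(object$fit)) {
    return(rep(object$constant, nrow(newdata)))
  }
  if (!is.null(object$scaler)) newdata <- apply_scaler(newdata, object$scaler)
  as.numeric(predict(object$fit, newdata))
}

#' @export
print.brainage_model <- function(x, ...) {
  cat("brainage_model: RBF SVR, C =", x$cost, ", gamma =", x$gamma,
      ", epsilon =", x$epsilon, "\n")
  cat("  pooled CV: MAE =", round(x$cv$pooled_mae, 3), "y, R^2 =",
      round(x$cv$pooled_r2, 3), "\n")
  invisible(x)
}

#' Fit the global brain-age model on region-mean GMV
#'
#' @param fs Training [feature_set()].
#' @param ages Chronological ages.
#' @param spec A [model_spec()].
#' @param nested Passed to [nested_cv_fit()].
#' @return A `brainage_model`.
#' @export
fit_global_model <- function(fs, ages, spec = model_spec(), nested = TRUE) {
  nested_cv_fit(region_means(fs), ages, spec, nested = nested)
}

#' Fit one brain-age model per atlas region
#'
#' Each regional model is trained independently on that region's
#' voxel-level features only; per-region CV metrics are retained in each
#' model's `cv` element.
#'
#' @param fs Training [feature_set()].
#' @param ages Chronological ages.
#' @param atlas The `atlas_spec` (defaults to the one inside `fs`).
#' @param spec A [model_spec()].
#' @param nested Passed to [nested_cv_fit()].
#' @return Named list of `brainage_model`, one per region.
#' @export
fit_regional_models <- function(fs, ages, atlas = fs$atlas,
                                spec = model_spec(), nested = TRUE) {
  ids <- atlas$regions$region_id
  models <- lapply(ids, function(r) {
    nested_cv_fit(region_features(fs, r), ages, spec, nested = nested)
  })
  names(models) <- ids
  models
}

#' Predicted ages and brain-age gaps per scope
#'
#' Applies previously fitted global and/or regional models to an
#' application cohort — no refitting occurs — and computes the brain-age
#' gap `BAG = predicted age - chronological age` for each subject in each
#' scope. A positive BAG indicates accelerated brain aging.
#'
#' @param models List with elements `global` (a `brainage_model` or NULL)
#'   and `regional` (named list of `brainage_model` or NULL).
#' @param fs Application [feature_set()].
#' @param ages Chronological ages of the application subjects.
#' @return A `bag_result` data frame with columns `subject_id`, `scope`
#'   (`"global"` or a region_id), `predicted_age`, `bag`.
#' @export
predict_and_bag <- function(models, fs, ages) {
  stopifnot(inherits(fs, "feature_set"), length(ages) == nrow(fs$voxels))
  out <- list()
  if (!is.null(models$global)) {
    pred <- predict(models$global, region_means(fs))
    out[[length(out) + 1L]] <- data.frame(
      subject_id = fs$subject_ids, scope = "global",
      predicted_age = pred, bag = pred - ages, stringsAsFactors = FALSE)
  }
  for (r in names(models$regional)) {
    pred <- predict(models$regional[[r]], region_features(fs, r))
    out[[length(out) + 1L]] <- data.frame(
      subject_id = fs$subject_ids, scope = r,
      predicted_age = pred, bag = pred - ages, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("bag_result", "data.frame")
  res
}

#' Wide matrix view of a BAG table
#'
#' @param bag A `bag_result`.
#' @return Numeric matrix, subjects x scopes, of BAG values in years.
#' @export
bag_wide <- function(bag) {
  scopes <- unique(bag$scope)
  ids <- unique(bag$subject_id)
  m <- matrix(NA_real_, nrow = length(ids), ncol = length(scopes),
              dimnames = list(ids, scopes))
  m[cbind(match(bag$subject_id, ids), match(bag$scope, scopes))] <- bag$bag
  m
}
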