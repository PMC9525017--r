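#' Write a table as TSV with a JSON schema sidecar
#'
#' The sidecar (`<path>.schema.json`) records column names, types and
#' optional unit tags, so readers can validate structure and reconcile
#' units instead of guessing.
#'
#' @param df Data frame to write.
#' @param path Output TSV path.
#' @param units Optional named list of unit tags (e.g. `list(tiv = "ml")`).
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(df, path, units = NULL) {
  out <- df
  for (col in names(out)) {          # full precision so round trips are exact
    if (is.double(out[[col]])) out[[col]] <- sprintf("%.17g", out[[col]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  schema <- list(
    columns = as.list(stats::setNames(vapply(df, function(x) class(x)[1],
                                             character(1)), names(df))),
    units = if (is.null(units)) stats::setNames(list(), character(0)) else units
  )
  jsonlite::write_json(schema, paste0(path, ".schema.json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' Read a TSV table, validating against its schema sidecar
#'
#' All schema violations (missing columns, type mismatches) are collected
#' and reported together, not first-error-only. Unit tags from the sidecar
#' are attached as the `"units"` attribute.
#'
#' @param path TSV path written by [write_table_tsv()] (the sidecar is
#'   optional for foreign tables).
#' @param required Character vector of columns that must be present.
#' @return The data frame, with attribute `units`.
#' @export
read_table_tsv <- function(path, required = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  problems <- character(0)
  units <- list()
  schema_path <- paste0(path, ".schema.json")
  if (file.exists(schema_path)) {
    schema <- jsonlite::read_json(schema_path, simplifyVector = TRUE)
    units <- as.list(schema$units)
    declared <- names(schema$columns)
    miss <- setdiff(declared, names(df))
    if (length(miss) > 0) {
      problems <- c(problems, paste("missing declared column(s):",
                                    paste(miss, collapse = ", ")))
    }
    for (col in intersect(declared, names(df))) {
      want <- schema$columns[[col]]
      got <- class(df[[col]])[1]
      compat <- got == want ||
        (want == "numeric" && got == "integer") ||
        (want == "logical" && got %in% c("integer", "logical"))
      if (!compat) {
        problems <- c(problems, sprintf(
          "column `%s`: declared %s, found %s", col, want, got))
      }
    }
  }
  miss_req <- setdiff(required, names(df))
  if (length(miss_req) > 0) {
    problems <- c(problems, paste("missing required column(s):",
                                  paste(miss_req, collapse = ", ")))
  }
  if (length(problems) > 0) {
    stop("schema violations in ", path, ":\n  ",
         paste(problems, collapse = "\n  "))
  }
  attr(df, "units") <- units
  df
}

#' Reconcile TIV units in a marker table
#'
#' TIV may be recorded in millilitres or litres; the sidecar unit tag
#' disambiguates. Litre-encoded TIV is converted to millilitres so the
#' WMH/TIV ratio is computed on a common scale.
#'
#' @param markers Marker data frame with a `tiv` column (with a `units`
#'   attribute, as returned by [read_table_tsv()]).
#' @return The marker table with `tiv` in millilitres.
#' @export
normalize_tiv_units <- function(markers) {
  units <- attr(markers, "units")
  unit <- if (!is.null(units) && !is.null(units$tiv)) units$tiv else "ml"
  if (unit == "l") {
    markers$tiv <- markers$tiv * 1000
    attr(markers, "units")$tiv <- "ml"
  } else if (unit != "ml") {
    stop("unknown tiv unit: ", unit)
  }
  markers
}

#' Write a feature set as TSV (+ schema)
#'
#' @param fs A [feature_set()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(fs, path) {
  df <- data.frame(subject_id = fs$subject_ids, fs$voxels,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_table_tsv(df, path, units = list(voxels = "gmv_units"))
}

#' Read a feature set from TSV
#'
#' @param path TSV written by [write_feature_table()].
#' @param atlas The `atlas_spec` describing the column layout.
#' @return A [feature_set()].
#' @export
read_feature_table <- function(path, atlas) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  voxels <- as.matrix(df[, setdiff(names(df), "subject_id"), drop = FALSE])
  feature_set(voxels, atlas, df$subject_id)
}

#' End-to-end run configuration
#'
#' @param atlas An [atlas_spec()].
#' @param sim A [sim_config()].
#' @param model A [model_spec()].
#' @param outdir Output directory for the report bundle.
#' @param percentile CSVD WMH percentile threshold (default 50).
#' @param alpha Significance level (default 0.05).
#' @param B Bootstrap resamples for the mediation screen.
#' @param outcomes Cognitive outcomes to screen.
#' @param nested Use the full nested CV in model training.
#' @return A validated `run_config` list.
#' @export
run_config <- function(atlas, sim, model, outdir,
                       percentile = 50, alpha = 0.05, B = 1000,
                       outcomes = c("mmse", "cvvlt", "vft"),
                       nested = FALSE) {
  validate_atlas(atlas)
  validate_sim_config(sim, atlas)
  stopifnot(inherits(model, "model_spec"))
  if (alpha <= 0 || alpha >= 1) stop("invalid run_config field `alpha`")
  structure(list(atlas = atlas, sim = sim, model = model, outdir = outdir,
                 percentile = percentile, alpha = alpha, B = B,
                 outcomes = outcomes, nested = nested),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes the stages in the order of the study workflow:
#' simulate (or load) cohorts, train the global and regional brain-age
#' models on the healthy cohort, predict BAG in the application cohort,
#' classify CSVD from the markers, compare regional BAG between groups
#' with ANCOVA under Bonferroni control, and run the mediation screen on
#' the significant regions. Emits a report bundle into `config$outdir`:
#' cohort summary, global BAG comparison, per-region comparison table,
#' mediation table, and a provenance JSON with the frozen config and its
#' checksum. Fully deterministic under the config seeds; a failure in any
#' stage aborts with the stage name.
#'
#' @param config A [run_config()].
#' @param resume Reuse a cached BAG table in `outdir` (skipping the
#'   training and prediction stages) when present.
#' @return Invisibly, a list with the per-stage results.
#' @export
run_pipeline <- function(config, resume = FALSE) {
  stopifnot(inherits(config, "run_config"))
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(outdir, "pipeline.log")
  log_line <- function(...) {
    cat(format(Sys.time(), "%H:%M:%S"), ..., "\n", file = logf,
        append = TRUE)
  }
  stage <- function(name, expr) {
    log_line("stage", name, "start")
    tryCatch(expr, error = function(e) {
      log_line("stage", name, "FAILED:", conditionMessage(e))
      stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # frozen config + checksum
  cfg_json <- file.path(outdir, "config.json")
  cfg <- config
  cfg$atlas <- cfg$atlas$regions
  jsonlite::write_json(cfg, cfg_json, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  cfg_hash <- unname(tools::md5sum(cfg_json))

  sim <- stage("simulate", {
    train <- generate_training_cohort(config$sim, config$atlas)
    app <- generate_application_cohort(config$sim, config$atlas)
    write_table_tsv(train$subjects, file.path(outdir, "train_subjects.tsv"))
    write_table_tsv(app$subjects, file.path(outdir, "app_subjects.tsv"),
                    units = list(tiv = "l", tiv_ml = "ml",
                                 wmh_volume = "ml"))
    write_ground_truth_json(app$truth, file.path(outdir, "ground_truth.json"))
    list(train = train, app = app)
  })

  bag_path <- file.path(outdir, "bag.tsv")
  models <- NULL
  if (resume && file.exists(bag_path)) {
    bag <- stage("bag", {
      b <- read_table_tsv(bag_path)
      class(b) <- c("bag_result", "data.frame")
      b
    })
  } else {
    models <- stage("train", {
      list(
        global = fit_global_model(sim$train$features, sim$train$subjects$age,
                                  config$model, nested = config$nested),
        regional = fit_regional_models(sim$train$features,
                                       sim$train$subjects$age,
                                       config$atlas, config$model,
                                       nested = config$nested)
      )
    })
    bag <- stage("bag", {
      b <- predict_and_bag(models, sim$app$features, sim$app$subjects$age)
      write_table_tsv(b, bag_path, units = list(bag = "years"))
      b
    })
  }

  cls <- stage("classify", {
    markers <- sim$app$subjects[c("subject_id", "wmh_volume", "tiv_ml",
                                  "lacune_count", "cmb_count")]
    names(markers)[names(markers) == "tiv_ml"] <- "tiv"
    classify_csvd(markers, percentile = config$percentile)
  })
  group <- as.integer(cls$flags$csvd)

  cmp <- stage("compare", {
    res <- regional_bag_comparison(bag, sim$app$subjects, group,
                                   config$atlas, alpha = config$alpha)
    write_table_tsv(res$table, file.path(outdir, "regional_comparison.tsv"))
    smry <- cohort_summary_table(sim$app$subjects, group)
    write_table_tsv(smry, file.path(outdir, "cohort_summary.tsv"))
    gb <- data.frame(
      group = c("non_csvd", "csvd"),
      n = c(sum(group == 0), sum(group == 1)),
      mean_bag = c(mean(bag$bag[bag$scope == "global"][group == 0]),
                   mean(bag$bag[bag$scope == "global"][group == 1])),
      sd_bag = c(stats::sd(bag$bag[bag$scope == "global"][group == 0]),
                 stats::sd(bag$bag[bag$scope == "global"][group == 1]))
    )
    write_table_tsv(gb, file.path(outdir, "global_bag.tsv"),
                    units = list(mean_bag = "years"))
    list(regional = res, global_groups = gb, cohort_summary = smry)
  })

  med <- stage("mediate", {
    sig <- cmp$regional$table$region_id[cmp$regional$table$significant]
    if (length(sig) == 0) {
      tab <- NULL
    } else {
      tab <- mediation_screen(bag, sim$app$subjects, group, sig,
                              config$outcomes, B = config$B,
                              alpha = config$alpha,
                              seed = config$sim$seed + 41L, fwer = TRUE)
      write_table_tsv(tab, file.path(outdir, "mediation.tsv"))
    }
    tab
  })

  stage("provenance", {
    jsonlite::write_json(list(
      config_hash = cfg_hash,
      wmh_threshold = cls$threshold,
      csvd_rule = cls$rule,
      bonferroni_threshold = cmp$regional$threshold,
      n_regions = cmp$regional$n_regions,
      n_significant = sum(cmp$regional$table$significant),
      alpha = config$alpha, B = config$B,
      seed = config$sim$seed
    ), file.path(outdir, "provenance.json"), auto_unbox = TRUE, digits = NA)
  })

  invisible(list(sim = sim, models = models, bag = bag, classification = cls,
                 comparison = cmp, mediation = med, config_hash = cfg_hash))
}
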