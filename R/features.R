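#' Construct a GMV feature set
#'
#' Holds the voxel-level grey-matter-volume feature matrix keyed to subjects
#' and atlas regions, together with the two views the brain-age models
#' consume: per-region voxel blocks (regional models) and region means
#' (global model).
#'
#' @param voxels Numeric matrix, one row per subject; columns named
#'   `<region_id>.v<j>`.
#' @param atlas The `atlas_spec` the columns are grouped by.
#' @param subject_ids Character vector of subject identifiers, one per row.
#' @return An object of class `feature_set`.
#' @export
feature_set <- function(voxels, atlas, subject_ids) {
  validate_atlas(atlas)
  stopifnot(is.matrix(voxels), nrow(voxels) == length(subject_ids))
  expected <- voxel_colnames(atlas)
  if (!identical(colnames(voxels), expected)) {
    stop("voxel columns do not match atlas layout")
  }
  rownames(voxels) <- subject_ids
  structure(list(voxels = voxels, atlas = atlas, subject_ids = subject_ids),
            class = "feature_set")
}

voxel_colnames <- function(atlas) {
  unlist(lapply(seq_len(atlas$n_regions), function(i) {
    r <- atlas$regions[i, ]
    paste0(r$region_id, ".v", seq_len(r$n_voxels))
  }), use.names = FALSE)
}

#' Extract the voxel feature block of one region
#'
#' @param fs A `feature_set`.
#' @param region_id A region identifier present in the atlas.
#' @return Numeric matrix of that region's voxel features.
#' @export
region_features <- function(fs, region_id) {
  stopifnot(inherits(fs, "feature_set"))
  if (!region_id %in% fs$atlas$regions$region_id) {
    stop("region not in atlas: ", region_id)
  }
  cols <- startsWith(colnames(fs$voxels), paste0(region_id, ".v"))
  if (!any(cols)) stop("region has zero feature columns: ", region_id)
  fs$voxels[, cols, drop = FALSE]
}

#' Region-mean GMV view of a feature set
#'
#' Averages the voxel features within each region; this is the feature
#' matrix of the global brain-age model.
#'
#' @param fs A `feature_set`.
#' @return Numeric matrix, one column per atlas region.
#' @export
region_means <- function(fs) {
  stopifnot(inherits(fs, "feature_set"))
  ids <- fs$atlas$regions$region_id
  out <- vapply(ids, function(r) {
    rowMeans(region_features(fs, r))
  }, numeric(nrow(fs$voxels)))
  out <- matrix(out, nrow = nrow(fs$voxels), dimnames = list(fs$subject_ids, ids))
  out
}

#' @export
print.feature_set <- function(x, ...) {
  cat("feature_set:", nrow(x$voxels), "subjects x", ncol(x$voxels),
      "voxel features in", x$atlas$n_regions, "regions\n")
  invisible(x)
}
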