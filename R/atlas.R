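#' Canonical cortical network labels
#'
#' The seven large-scale functional networks used to label cortical parcels.
#' Subcortical and cerebellar regions carry their compartment name instead.
#'
#' @export
CANONICAL_NETWORKS <- c(
  "visual", "somatomotor", "dorsal_attention", "ventral_attention",
  "limbic", "default_mode", "executive_control"
)

#' Construct an atlas specification
#'
#' Defines the brain parcellation used to group grey-matter-volume (GMV)
#' features: a set of named regions, each belonging to one compartment
#' (cortical, subcortical or cerebellar) and carrying a network label, plus
#' the number of voxel-level features per region. The default sizes
#' (400 cortical + 14 subcortical + 28 cerebellar = 442 regions) correspond
#' to a Schaefer-400 cortical parcellation combined with subcortical and
#' cerebellar parcellations; smaller atlases are used for desk-scale
#' simulation experiments.
#'
#' @param n_cortical,n_subcortical,n_cerebellar Number of regions per
#'   compartment. All must be >= 0 and the total >= 1.
#' @param voxels_per_region Number of voxel-level GMV features per region,
#'   a single positive integer or a vector with one entry per region.
#' @return An object of class `atlas_spec`: a list with `regions` (data frame
#'   with columns `region_id`, `name`, `compartment`, `network`, `n_voxels`)
#'   and `n_regions`.
#' @examples
#' atlas <- atlas_spec(28, 6, 6, voxels_per_region = 10)
#' table(atlas$regions$compartment)
#' @export
atlas_spec <- function(n_cortical = 400, n_subcortical = 14,
                       n_cerebellar = 28, voxels_per_region = 10) {
  counts <- c(cortical = n_cortical, subcortical = n_subcortical,
              cerebellar = n_cerebellar)
  if (any(counts < 0) || sum(counts) < 1) {
    stop("atlas must have non-negative compartment counts and >= 1 region")
  }
  ids <- c(
    if (n_cortical > 0) sprintf("ctx_%03d", seq_len(n_cortical)),
    if (n_subcortical > 0) sprintf("sub_%03d", seq_len(n_subcortical)),
    if (n_cerebellar > 0) sprintf("cbl_%03d", seq_len(n_cerebellar))
  )
  compartment <- rep(names(counts), counts)
  # cortical parcels cycle through the seven canonical networks; other
  # compartments are labelled by compartment name
  network <- ifelse(
    compartment == "cortical",
    CANONICAL_NETWORKS[((seq_along(ids) - 1L) %% 7L) + 1L],
    compartment
  )
  n_regions <- length(ids)
  nv <- rep_len(as.integer(voxels_per_region), n_regions)
  if (any(nv < 1L)) stop("every region needs >= 1 voxel feature")
  regions <- data.frame(
    region_id = ids,
    name = paste0(compartment, "_", sub("^[a-z]+_", "", ids)),
    compartment = compartment,
    network = network,
    n_voxels = nv,
    stringsAsFactors = FALSE
  )
  structure(list(regions = regions, n_regions = n_regions),
            class = "atlas_spec")
}

#' @export
print.atlas_spec <- function(x, ...) {
  tab <- table(x$regions$compartment)
  cat("atlas_spec:", x$n_regions, "regions (",
      paste(names(tab), tab, sep = "=", collapse = ", "), ")\n")
  invisible(x)
}

validate_atlas <- function(atlas) {
  stopifnot(inherits(atlas, "atlas_spec"))
  if (anyDuplicated(atlas$regions$region_id)) {
    stop("atlas region_ids must be unique")
  }
  invisible(atlas)
}

#' Write / read an atlas specification as JSON
#'
#' @param atlas An `atlas_spec`.
#' @param path File path for the JSON representation.
#' @return `write_atlas_json` returns `path` invisibly; `read_atlas_json`
#'   returns the reconstructed `atlas_spec`.
#' @export
write_atlas_json <- function(atlas, path) {
  validate_atlas(atlas)
  jsonlite::write_json(atlas$regions, path, dataframe = "rows", digits = NA)
  invisible(path)
}

#' @rdname write_atlas_json
#' @export
read_atlas_json <- function(path) {
  regions <- as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  out <- structure(list(regions = regions, n_regions = nrow(regions)),
                   class = "atlas_spec")
  validate_atlas(out)
}
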