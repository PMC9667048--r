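# Synthetic four-class FDG-PET cohorts with known ground truth.
#
# Volumes are generated directly in a shared grid (no spatial normalization
# stage): baseline radial uptake field x class-specific ROI hypometabolism
# multipliers x a lognormal per-subject global scale, plus iid voxel noise
# floored at a small positive value so the log transform stays defined.

#' Ellipsoidal brain mask for a toy grid
#'
#' @param grid_shape Integer length-3 grid dimensions.
#' @return Logical 3-D array, `TRUE` inside an axis-aligned ellipsoid filling
#'   ~90 percent of each grid half-extent.
#' @export
make_ellipsoid_mask <- function(grid_shape) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 3L))
  ctr <- (grid_shape + 1) / 2
  semi <- pmax((grid_shape - 1) / 2 * 0.9, 1)
  ax <- (seq_len(grid_shape[1]) - ctr[1]) / semi[1]
  ay <- (seq_len(grid_shape[2]) - ctr[2]) / semi[2]
  az <- (seq_len(grid_shape[3]) - ctr[3]) / semi[3]
  r2 <- outer(outer(ax^2, ay^2, "+"), az^2, "+")
  r2 <= 1
}

# Smooth baseline uptake field: higher centrally, positive everywhere.
baseline_uptake_field <- function(grid_shape) {
  grid_shape <- as.integer(grid_shape)
  ctr <- (grid_shape + 1) / 2
  semi <- pmax((grid_shape - 1) / 2 * 0.9, 1)
  ax <- (seq_len(grid_shape[1]) - ctr[1]) / semi[1]
  ay <- (seq_len(grid_shape[2]) - ctr[2]) / semi[2]
  az <- (seq_len(grid_shape[3]) - ctr[3]) / semi[3]
  r2 <- outer(outer(ax^2, ay^2, "+"), az^2, "+")
  1.5 - 0.5 * pmin(r2, 1.5)
}

#' Build a toy parcellation atlas by Voronoi tessellation
#'
#' Partitions an ellipsoidal brain mask into `n_rois` non-empty, connected
#' parcels: random interior points are drawn as Voronoi sites and every mask
#' voxel is assigned to its nearest site (Voronoi cells are convex, and convex
#' sets intersected with the ellipsoid stay connected). Stands in for a real
#' anatomical ROI atlas in tests and simulations.
#'
#' @param grid_shape Integer length-3 grid dimensions.
#' @param n_rois Number of parcels (>= 4, one per label 1..n_rois).
#' @param seed Integer seed; the same seed reproduces the same atlas exactly.
#' @param spacing_mm Voxel size recorded in the atlas (default 8 mm, giving a
#'   whole-head extent comparable to adult brain for the default 20^3 grid).
#' @return A [pet_atlas()] whose parcels tile the ellipsoid mask.
#' @export
make_toy_atlas <- function(grid_shape, n_rois, seed, spacing_mm = c(8, 8, 8)) {
  grid_shape <- as.integer(grid_shape)
  if (!is_count(n_rois) || n_rois < 4)
    stop("`n_rois` must be an integer >= 4", call. = FALSE)
  mask <- make_ellipsoid_mask(grid_shape)
  nvox <- sum(mask)
  if (nvox < n_rois)
    stop(sprintf("grid too small: %d mask voxels for %d parcels", nvox, n_rois),
         call. = FALSE)
  coords <- which(mask, arr.ind = TRUE)
  sites <- with_seed(seed, coords[sample.int(nvox, n_rois), , drop = FALSE])
  # squared Euclidean distance (voxel units) voxel -> site; nearest site wins,
  # ties to the lower label for determinism
  d2 <- outer(rowSums(coords^2), rowSums(sites^2), "+") -
    2 * coords %*% t(sites)
  assign <- max.col(-d2, ties.method = "first")
  labels <- array(0L, grid_shape)
  labels[mask] <- assign
  pet_atlas(labels,
            data.frame(id = seq_len(n_rois),
                       name = sprintf("ROI%02d", seq_len(n_rois)),
                       stringsAsFactors = FALSE),
            spacing_mm = spacing_mm)
}

#' Class-specific hypometabolic topography
#'
#' Describes, for one diagnostic class, which atlas regions are
#' hypometabolic, by how much on average, and how much that reduction varies
#' between subjects.
#'
#' @param class_label One of `"AD"`, `"DLB"`, `"FTD"`, `"NC"`.
#' @param affected_rois Integer vector of atlas label ids (empty for NC).
#' @param hypometabolism_fraction Mean relative uptake reduction in affected
#'   regions, in `[0, 1)`; 0.25 means affected regions run at 75 percent of
#'   baseline.
#' @param variability Between-subject SD of the reduction (>= 0).
#' @return An object of class `class_topography`.
#' @export
class_topography <- function(class_label, affected_rois = integer(),
                             hypometabolism_fraction = 0, variability = 0) {
  if (!class_label %in% CLASS_ORDER)
    stop("`class_label` must be one of ", paste(CLASS_ORDER, collapse = ", "),
         call. = FALSE)
  if (class_label == "NC" && length(affected_rois) > 0)
    stop("NC topography must have no affected ROIs", call. = FALSE)
  if (hypometabolism_fraction < 0 || hypometabolism_fraction >= 1)
    stop("`hypometabolism_fraction` must be in [0, 1)", call. = FALSE)
  if (variability < 0) stop("`variability` must be >= 0", call. = FALSE)
  structure(list(class_label = class_label,
                 affected_rois = as.integer(affected_rois),
                 hypometabolism_fraction = hypometabolism_fraction,
                 variability = variability),
            class = "class_topography")
}

#' Default planted topographies for the four study classes
#'
#' Each dementia class hypometabolizes two disjoint toy parcels by 25 percent
#' on average (a typical clinical FDG-PET effect magnitude) with 5 percent
#' between-subject SD; controls are unaffected. Designed for atlases with at
#' least 6 parcels.
#'
#' @param fraction Mean uptake reduction shared by the three dementia classes.
#' @param variability Between-subject SD of the reduction.
#' @return Named list of [class_topography()] objects (AD, DLB, FTD, NC).
#' @export
default_topographies <- function(fraction = 0.25, variability = 0.05) {
  list(AD  = class_topography("AD",  1:2, fraction, variability),
       DLB = class_topography("DLB", 3:4, fraction, variability),
       FTD = class_topography("FTD", 5:6, fraction, variability),
       NC  = class_topography("NC"))
}

#' Synthetic cohort specification
#'
#' Study conditions for [simulate_cohort()]: cohort sizes default to the
#' four-class design of 63 AD, 79 DLB, 23 FTD and 41 NC scans (206 in total),
#' on a 20^3 grid of 8 mm voxels parcellated into 8 toy regions.
#'
#' @param n_per_class Named counts for AD, DLB, FTD, NC.
#' @param grid_shape Integer length-3 grid dimensions.
#' @param voxel_size_mm Positive voxel size (mm).
#' @param n_rois Number of toy atlas parcels (>= 4).
#' @param global_scale_sd SD (log scale) of the lognormal per-subject global
#'   intensity factor; lognormal keeps intensities positive for the log
#'   transform downstream.
#' @param noise_sd SD of iid additive voxel noise (baseline uptake is O(1)).
#' @param seed Integer seed; the full cohort is a deterministic function of
#'   the spec.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_class = c(AD = 63, DLB = 79, FTD = 23, NC = 41),
                        grid_shape = c(20, 20, 20),
                        voxel_size_mm = c(8, 8, 8),
                        n_rois = 8,
                        global_scale_sd = 0.15,
                        noise_sd = 0.05,
                        seed = 42) {
  if (is.null(names(n_per_class)) || !all(names(n_per_class) %in% CLASS_ORDER))
    stop("`n_per_class` must be named with classes among AD, DLB, FTD, NC",
         call. = FALSE)
  if (any(n_per_class < 0) || any(n_per_class != round(n_per_class)))
    stop("all class counts must be nonnegative integers", call. = FALSE)
  if (global_scale_sd < 0 || noise_sd < 0)
    stop("`global_scale_sd` and `noise_sd` must be >= 0", call. = FALSE)
  structure(list(n_per_class = n_per_class,
                 grid_shape = as.integer(grid_shape),
                 voxel_size_mm = as.numeric(voxel_size_mm),
                 n_rois = as.integer(n_rois),
                 global_scale_sd = global_scale_sd,
                 noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a four-class FDG-PET cohort with planted topographies
#'
#' Each subject's volume is a smooth radial baseline uptake field multiplied,
#' inside each affected region, by `1 - fraction + subject noise`, scaled by a
#' lognormal per-subject global factor, with iid voxel noise added and floored
#' at 1e-6 so all masked intensities stay positive. Ground truth (class label,
#' leakage flag, seed) is recorded in the subject table.
#'
#' @param spec A [cohort_spec()].
#' @param topographies Named list of [class_topography()] covering every class
#'   in `spec$n_per_class`.
#' @param atlas Optional [pet_atlas()]; defaults to
#'   `make_toy_atlas(spec$grid_shape, spec$n_rois, spec$seed, spec$voxel_size_mm)`.
#' @return A list with `volumes` (named list of [pet_volume()]), `subjects`
#'   (data frame `id`, `class`, `leakage`, `seed`) and `atlas`.
#' @export
simulate_cohort <- function(spec, topographies = default_topographies(),
                            atlas = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.null(atlas))
    atlas <- make_toy_atlas(spec$grid_shape, spec$n_rois, spec$seed,
                            spec$voxel_size_mm)
  stopifnot(inherits(atlas, "pet_atlas"))
  known <- atlas$label_table$id
  for (tp in topographies) {
    bad <- setdiff(tp$affected_rois, known)
    if (length(bad) > 0)
      stop(sprintf("topography for %s names unknown ROI id(s): %s",
                   tp$class_label, paste(bad, collapse = ", ")), call. = FALSE)
  }
  mask <- atlas$labels > 0L
  baseline <- baseline_uptake_field(dim(atlas$labels))
  classes <- intersect(CLASS_ORDER, names(spec$n_per_class))

  volumes <- list()
  rows <- list()
  with_seed(spec$seed, {
    for (cl in classes) {
      n <- spec$n_per_class[[cl]]
      if (n == 0) next
      tp <- topographies[[cl]]
      if (is.null(tp)) stop("no topography for class ", cl, call. = FALSE)
      for (i in seq_len(n)) {
        mult_by_roi <- rep(1, length(known))
        if (length(tp$affected_rois) > 0) {
          draw <- 1 - tp$hypometabolism_fraction +
            stats::rnorm(length(tp$affected_rois), 0, tp$variability)
          mult_by_roi[match(tp$affected_rois, known)] <- pmax(draw, 0.01)
        }
        mult <- array(1, dim(atlas$labels))
        inside <- atlas$labels > 0L
        mult[inside] <- mult_by_roi[atlas$labels[inside]]
        gscale <- stats::rlnorm(1, 0, spec$global_scale_sd)
        dat <- baseline * mult * gscale
        if (spec$noise_sd > 0)
          dat <- dat + array(stats::rnorm(length(dat), 0, spec$noise_sd),
                             dim(dat))
        dat <- pmax(dat, 1e-6)
        id <- sprintf("%s%03d", cl, i)
        volumes[[id]] <- pet_volume(dat, spec$voxel_size_mm, mask)
        rows[[id]] <- data.frame(id = id, class = cl, leakage = FALSE,
                                 seed = spec$seed, stringsAsFactors = FALSE)
      }
    }
  })
  subjects <- do.call(rbind, rows)
  rownames(subjects) <- NULL
  list(volumes = volumes, subjects = subjects, atlas = atlas)
}

#' Flag subjects as pattern-derivation (leakage) cases
#'
#' Subjects used to derive a metabolic pattern may only ever appear in
#' training splits; this marks the first `n_per_class[cl]` subjects of each
#' class (in simulation order) as such.
#'
#' @param subjects Subject table from [simulate_cohort()].
#' @param n_per_class Named counts of derivation subjects per class.
#' @return The subject table with updated `leakage` column.
#' @export
flag_derivation_subjects <- function(subjects, n_per_class) {
  for (cl in names(n_per_class)) {
    idx <- which(subjects$class == cl)
    k <- n_per_class[[cl]]
    if (k > length(idx))
      stop(sprintf("cannot flag %d derivation subjects in class %s (only %d)",
                   k, cl, length(idx)), call. = FALSE)
    subjects$leakage[idx[seq_len(k)]] <- TRUE
  }
  subjects
}
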