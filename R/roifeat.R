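# Regional uptake features: mean globally-normalized uptake per atlas parcel.

#' Feature matrix container
#'
#' Subjects x named features with class labels and leakage flags; the input
#' surface of the classifier. Values are unitless (pattern Z-scores or ROI
#' uptake ratios).
#'
#' @param values Numeric matrix with subject ids as rownames and unique
#'   feature names as colnames; no missing values.
#' @param class_labels Character vector, one of AD/DLB/FTD/NC per subject.
#' @param leakage_flags Logical vector (recycled if length 1); `TRUE` marks
#'   pattern-derivation subjects that may never enter a test split.
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, class_labels, leakage_flags = FALSE) {
  values <- as.matrix(values)
  if (anyNA(values) || any(!is.finite(values)))
    stop("feature values must be finite and non-missing", call. = FALSE)
  if (is.null(colnames(values)) || !all(nzchar(colnames(values))) ||
      anyDuplicated(colnames(values)))
    stop("feature names must be present, non-empty and unique", call. = FALSE)
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("S%03d", seq_len(nrow(values)))
  if (anyDuplicated(rownames(values)))
    stop("subject ids must be unique", call. = FALSE)
  class_labels <- as.character(class_labels)
  if (length(class_labels) != nrow(values))
    stop("one class label per subject required", call. = FALSE)
  if (!all(class_labels %in% CLASS_ORDER))
    stop("class labels must be among ", paste(CLASS_ORDER, collapse = ", "),
         call. = FALSE)
  leakage_flags <- rep_len(as.logical(leakage_flags), nrow(values))
  structure(list(values = values,
                 feature_names = colnames(values),
                 subject_ids = rownames(values),
                 class_labels = class_labels,
                 leakage_flags = leakage_flags),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d subjects x %d features; classes: %s; %d leakage\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s=%d", names(table(x$class_labels)),
                            table(x$class_labels)), collapse = " "),
              sum(x$leakage_flags)))
  invisible(x)
}

#' Restrict a feature matrix to a subset of features
#'
#' @param fm A [feature_matrix()].
#' @param features Character vector of feature names (kept in the given order).
#' @return A [feature_matrix()] with the selected columns.
#' @export
select_features <- function(fm, features) {
  stopifnot(inherits(fm, "feature_matrix"))
  missing <- setdiff(features, fm$feature_names)
  if (length(missing) > 0)
    stop("unknown feature(s): ", paste(missing, collapse = ", "), call. = FALSE)
  feature_matrix(fm$values[, features, drop = FALSE],
                 fm$class_labels, fm$leakage_flags)
}

subjects_of <- function(fm) {
  data.frame(id = fm$subject_ids, class = fm$class_labels,
             leakage = fm$leakage_flags, stringsAsFactors = FALSE)
}

#' Mean uptake per atlas region
#'
#' For each entry of the atlas label table, the mean intensity over that
#' parcel's in-mask voxels, returned in label-table order. Composite regions
#' (from [merge_rois()]) average over the union of their members, which
#' equals the voxel-count-weighted mean of the member parcels. With a
#' globally scaled volume (masked mean 1) these are SUVR-like ratios to
#' global uptake.
#'
#' @param volume A preprocessed [pet_volume()] on the atlas grid.
#' @param atlas A [pet_atlas()].
#' @return Named numeric vector of regional means.
#' @export
roi_means <- function(volume, atlas) {
  stopifnot(inherits(volume, "pet_volume"), inherits(atlas, "pet_atlas"))
  if (!identical(dim(volume$data), dim(atlas$labels)))
    stop("volume grid does not match the atlas grid", call. = FALSE)
  out <- numeric(nrow(atlas$label_table))
  names(out) <- atlas$label_table$name
  for (i in seq_len(nrow(atlas$label_table))) {
    id <- atlas$label_table$id[i]
    key <- as.character(id)
    members <- if (key %in% names(atlas$composites))
      atlas$composites[[key]] else id
    vox <- (atlas$labels %in% members) & volume$mask
    if (!any(vox))
      stop(sprintf("region %d (%s) has no in-mask voxels", id,
                   atlas$label_table$name[i]), call. = FALSE)
    out[i] <- mean(volume$data[vox])
  }
  out
}

#' Add composite regions to an atlas
#'
#' Extends the label table with composite entries whose means are computed
#' over the union of member parcels (e.g. merged bilateral anterior cingulate
#' or thalamus entries in extended ROI sets). Member sets of distinct
#' composites must be disjoint.
#'
#' @param atlas A [pet_atlas()].
#' @param merge_spec Named list: composite name -> integer vector of existing
#'   base-parcel ids.
#' @return The extended [pet_atlas()]; an empty spec returns the atlas
#'   unchanged.
#' @export
merge_rois <- function(atlas, merge_spec) {
  stopifnot(inherits(atlas, "pet_atlas"))
  if (length(merge_spec) == 0) return(atlas)
  if (is.null(names(merge_spec)) || any(!nzchar(names(merge_spec))))
    stop("`merge_spec` must be a named list", call. = FALSE)
  base_ids <- setdiff(atlas$label_table$id, as.integer(names(atlas$composites)))
  all_members <- unlist(merge_spec, use.names = FALSE)
  if (anyDuplicated(all_members))
    stop("composite member sets must be disjoint", call. = FALSE)
  if (!all(all_members %in% base_ids))
    stop("composite members must be existing base-parcel ids", call. = FALSE)
  next_id <- max(atlas$label_table$id) + 1L
  tab <- atlas$label_table
  composites <- atlas$composites
  for (i in seq_along(merge_spec)) {
    id <- next_id + i - 1L
    tab <- rbind(tab, data.frame(id = id, name = names(merge_spec)[i],
                                 stringsAsFactors = FALSE))
    composites[[as.character(id)]] <- as.integer(merge_spec[[i]])
  }
  pet_atlas(atlas$labels, tab, atlas$spacing_mm, composites)
}

#' ROI-uptake feature matrix
#'
#' Stacks [roi_means()] of every subject into a subjects x regions
#' [feature_matrix()], carrying class labels and leakage flags from the
#' subject table.
#'
#' @param volumes Named list of preprocessed [pet_volume()] objects on the
#'   atlas grid.
#' @param atlas A [pet_atlas()].
#' @param subjects Subject table with `id`, `class`, `leakage`.
#' @return A [feature_matrix()].
#' @export
roi_feature_matrix <- function(volumes, atlas, subjects) {
  ids <- names(volumes)
  if (is.null(ids) || !all(ids %in% subjects$id))
    stop("volumes must be named by subject id present in the subject table",
         call. = FALSE)
  rows <- lapply(seq_along(volumes), function(i) {
    tryCatch(roi_means(volumes[[i]], atlas),
             error = function(e)
               stop(sprintf("ROI extraction failed for subject %s: %s",
                            ids[i], conditionMessage(e)), call. = FALSE))
  })
  vals <- do.call(rbind, rows)
  rownames(vals) <- ids
  m <- match(ids, subjects$id)
  feature_matrix(vals, class_labels = subjects$class[m],
                 leakage_flags = subjects$leakage[m])
}

#' Write / read a feature matrix as CSV
#'
#' Columns: id, class, leakage, then one column per feature.
#'
#' @param fm A [feature_matrix()].
#' @param path CSV path.
#' @return `path` (write) or a `feature_matrix` (read).
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  df <- cbind(subjects_of(fm), as.data.frame(fm$values))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  vals <- as.matrix(df[, setdiff(names(df), c("id", "class", "leakage")),
                       drop = FALSE])
  rownames(vals) <- df$id
  feature_matrix(vals, df$class, as.logical(df$leakage))
}
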