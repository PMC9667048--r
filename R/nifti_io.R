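# NIfTI serialization via RNifti. Volumes and atlases travel as .nii.gz with
# the voxel size in the header; masks as uint8 volumes; subject tables and
# label tables as plain CSV/TSV.

#' Write / read a volume as NIfTI
#'
#' The intensity grid and its binary mask are written as a pair of NIfTI
#' files (`<path>` and `<path stem>_mask.nii.gz`) with `pixdim` set to the
#' voxel spacing.
#'
#' @param volume A [pet_volume()].
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume_nifti <- function(volume, path) {
  stopifnot(inherits(volume, "pet_volume"))
  img <- RNifti::asNifti(volume$data)
  RNifti::pixdim(img) <- volume$spacing_mm
  RNifti::writeNifti(img, path)
  mimg <- RNifti::asNifti(array(as.integer(volume$mask), dim(volume$mask)))
  RNifti::pixdim(mimg) <- volume$spacing_mm
  RNifti::writeNifti(mimg, mask_path_for(path))
  invisible(path)
}

mask_path_for <- function(path) {
  sub("\\.nii(\\.gz)?$", "_mask.nii\\1", path)
}

#' @rdname write_volume_nifti
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  spacing <- RNifti::pixdim(img)[1:3]
  mp <- mask_path_for(path)
  mask <- if (file.exists(mp)) RNifti::readNifti(mp) > 0 else NULL
  pet_volume(array(as.numeric(img), dim(img)[1:3]), spacing,
             if (is.null(mask)) NULL else array(mask, dim(img)[1:3]))
}

#' Write / read a parcellation atlas (NIfTI label grid + TSV label table)
#'
#' @param atlas A [pet_atlas()].
#' @param path Label-grid path ending in `.nii` or `.nii.gz`; the label table
#'   goes to `<path stem>_labels.tsv` (columns id, name, members).
#' @return `path`, invisibly.
#' @export
write_atlas_nifti <- function(atlas, path) {
  stopifnot(inherits(atlas, "pet_atlas"))
  img <- RNifti::asNifti(atlas$labels)
  RNifti::pixdim(img) <- atlas$spacing_mm
  RNifti::writeNifti(img, path)
  tab <- atlas$label_table
  tab$members <- vapply(as.character(tab$id), function(id) {
    if (id %in% names(atlas$composites))
      paste(atlas$composites[[id]], collapse = ",") else ""
  }, character(1))
  utils::write.table(tab, atlas_table_path_for(path), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

atlas_table_path_for <- function(path) {
  sub("\\.nii(\\.gz)?$", "_labels.tsv", path)
}

#' @rdname write_atlas_nifti
#' @export
read_atlas_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  tab <- utils::read.table(atlas_table_path_for(path), sep = "\t",
                           header = TRUE, stringsAsFactors = FALSE,
                           na.strings = NULL)
  composites <- list()
  if ("members" %in% names(tab)) {
    has <- !is.na(tab$members) & nzchar(tab$members)
    for (i in which(has))
      composites[[as.character(tab$id[i])]] <-
        as.integer(strsplit(tab$members[i], ",")[[1]])
    tab$members <- NULL
  }
  pet_atlas(array(as.integer(img), dim(img)[1:3]), tab,
            RNifti::pixdim(img)[1:3], composites)
}

#' Write / read the subject table as CSV
#'
#' Columns: id, class, leakage, seed.
#'
#' @param subjects Subject table data frame.
#' @param path CSV path.
#' @return `path` (write) or the data frame (read).
#' @export
write_subject_table <- function(subjects, path) {
  utils::write.csv(subjects, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_subject_table
#' @export
read_subject_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$leakage <- as.logical(df$leakage)
  df
}
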