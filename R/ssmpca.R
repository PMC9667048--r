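# Scaled subprofile model / PCA: pattern derivation from a two-group cohort
# and prospective single-case scoring by topographic profile rating (TPR).
#
# The subjects x voxels log matrix is double centered (each subject's mean
# removed, then the group mean profile removed); PCA of the residual matrix
# yields covarying metabolic topographies, and a new scan is scored by the
# dot product of its own residual profile with a pattern's voxel weights.

#' Masked natural-log intensity vector of a volume
#'
#' @param volume A preprocessed [pet_volume()] (all masked intensities > 0).
#' @return Numeric vector `log(data[mask])` in voxel-index order
#'   (`which(mask)` order).
#' @export
log_transform <- function(volume) {
  stopifnot(inherits(volume, "pet_volume"))
  v <- volume$data[volume$mask]
  if (any(v <= 0))
    stop(sprintf("%d nonpositive voxel(s) inside the mask; log transform undefined",
                 sum(v <= 0)), call. = FALSE)
  log(v)
}

#' Double centering of a subjects-by-voxels log matrix
#'
#' Removes each subject's row mean, then the column means of the row-centered
#' matrix (the group mean profile, GMP). Rows and columns of the resulting
#' subject residual profile (SRP) matrix sum to ~0.
#'
#' @param log_matrix Numeric matrix, subjects in rows, masked voxels in
#'   columns (>= 2 of each).
#' @return List with `srp` (the double-centered matrix) and `gmp` (the column
#'   means removed, i.e. the group mean log profile).
#' @export
double_center <- function(log_matrix) {
  log_matrix <- as.matrix(log_matrix)
  if (nrow(log_matrix) < 2L)
    stop("double centering needs at least 2 subjects", call. = FALSE)
  if (ncol(log_matrix) < 2L)
    stop("double centering needs at least 2 voxels", call. = FALSE)
  rc <- log_matrix - rowMeans(log_matrix)
  gmp <- colMeans(rc)
  srp <- sweep(rc, 2, gmp)
  list(srp = srp, gmp = gmp)
}

#' Pattern derivation configuration
#'
#' @param var_threshold Candidate principal components are the leading ones
#'   jointly explaining at least this fraction of SRP variance (default 0.5).
#' @param mode `"best_t"` keeps the single candidate whose subject scores
#'   best separate the groups by two-sample t statistic; `"logistic"` combines
#'   all candidates with logistic-regression coefficients.
#' @return A list of class `pattern_config`.
#' @export
pattern_config <- function(var_threshold = 0.5,
                           mode = c("best_t", "logistic")) {
  mode <- match.arg(mode)
  if (var_threshold <= 0 || var_threshold > 1)
    stop("`var_threshold` must be in (0, 1]", call. = FALSE)
  structure(list(var_threshold = var_threshold, mode = mode),
            class = "pattern_config")
}

#' Derive a metabolic brain pattern by SSM/PCA
#'
#' Builds the SRP matrix from the combined disease + control derivation
#' cohort, decomposes it by PCA (singular value decomposition of the n x p
#' residual matrix, i.e. subject-space eigen-decomposition), restricts to the
#' leading components jointly explaining `config$var_threshold` of the
#' variance, and selects the component (or logistic combination of
#' candidates) whose subject scores best separate disease from controls. The
#' sign is fixed so the disease group's mean score exceeds the control
#' group's, and the control-group score mean/SD are stored so prospective
#' scores can be Z-transformed against the control identification cohort.
#'
#' @param disease_volumes,nc_volumes Lists of preprocessed [pet_volume()]
#'   objects sharing one mask (>= 3 subjects each).
#' @param config A [pattern_config()].
#' @param name Pattern name carried into feature matrices (e.g. `"ADRP"`).
#' @return An object of class `metabolic_pattern` with elements `weights`,
#'   `gmp`, `nc_score_mean`, `nc_score_sd`, `name`, `mask`, `spacing_mm`,
#'   `meta`.
#' @export
derive_pattern <- function(disease_volumes, nc_volumes,
                           config = pattern_config(), name = "pattern") {
  if (length(disease_volumes) < 3L || length(nc_volumes) < 3L)
    stop("pattern derivation needs >= 3 subjects per group", call. = FALSE)
  vols <- c(disease_volumes, nc_volumes)
  mask <- vols[[1]]$mask
  for (v in vols)
    if (!identical(v$mask, mask))
      stop("all derivation volumes must share one mask", call. = FALSE)
  grp <- rep(c("disease", "nc"), c(length(disease_volumes), length(nc_volumes)))
  L <- t(vapply(vols, log_transform, numeric(sum(mask))))
  dc <- double_center(L)
  if (max(abs(dc$srp)) < 1e-12)
    stop("degenerate SRP matrix (no residual variance); cannot derive a pattern",
         call. = FALSE)
  sv <- svd(dc$srp)
  keep <- sv$d > max(sv$d) * 1e-10
  d <- sv$d[keep]
  varfrac <- d^2 / sum(d^2)
  n_cand <- which(cumsum(varfrac) >= config$var_threshold)[1]
  cand <- seq_len(n_cand)
  scores <- sweep(sv$u[, cand, drop = FALSE], 2, d[cand], `*`)
  is_dis <- grp == "disease"

  if (config$mode == "best_t") {
    tstat <- apply(scores, 2, function(s) {
      unname(stats::t.test(s[is_dis], s[!is_dis])$statistic)
    })
    k <- which.max(abs(tstat))
    w <- sv$v[, cand[k]]
    s <- scores[, k]
    meta <- list(mode = "best_t", component = cand[k],
                 var_explained = varfrac[cand[k]], t_stat = tstat[k],
                 n_candidates = n_cand)
  } else {
    fit <- suppressWarnings(
      stats::glm(is_dis ~ scores, family = stats::binomial()))
    beta <- stats::coef(fit)[-1]
    beta[!is.finite(beta)] <- 0
    if (all(beta == 0))
      stop("logistic combination degenerate (all coefficients zero)",
           call. = FALSE)
    w <- sv$v[, cand, drop = FALSE] %*% beta
    w <- as.numeric(w) / sqrt(sum(w^2))
    s <- as.numeric(scores %*% beta) / sqrt(sum((sv$v[, cand, drop = FALSE] %*% beta)^2))
    meta <- list(mode = "logistic", components = cand,
                 var_explained = sum(varfrac[cand]), coefficients = beta,
                 n_candidates = n_cand)
  }
  if (mean(s[is_dis]) < mean(s[!is_dis])) {
    w <- -w
    s <- -s
  }
  nc_mean <- mean(s[!is_dis])
  nc_sd <- stats::sd(s[!is_dis])
  if (!is.finite(nc_sd) || nc_sd <= 0)
    stop("control-group score SD is not positive; Z reference undefined",
         call. = FALSE)
  structure(list(weights = as.numeric(w), gmp = dc$gmp,
                 nc_score_mean = nc_mean, nc_score_sd = nc_sd,
                 name = name, mask = mask,
                 spacing_mm = vols[[1]]$spacing_mm, meta = meta),
            class = "metabolic_pattern")
}

#' @export
print.metabolic_pattern <- function(x, ...) {
  cat(sprintf("<metabolic_pattern> %s: %d voxel weights (%s), NC ref %.3g +/- %.3g\n",
              x$name, length(x$weights), x$meta$mode,
              x$nc_score_mean, x$nc_score_sd))
  invisible(x)
}

#' Topographic profile rating of a single scan
#'
#' Prospective pattern-expression score of one preprocessed volume: the log
#' vector is row-centered, the pattern's stored group mean profile is
#' removed, and the residual is projected onto the pattern's voxel weights.
#' The raw score is Z-transformed against the stored control identification
#' cohort mean/SD. Scores are invariant to global intensity scaling of the
#' input (a positive factor only shifts the log vector, and row centering
#' removes the shift).
#'
#' @param volume A preprocessed [pet_volume()] on the pattern's mask/grid.
#' @param pattern A [metabolic_pattern()][derive_pattern].
#' @return List with `raw_score` and `z_score`.
#' @export
tpr_score <- function(volume, pattern) {
  stopifnot(inherits(volume, "pet_volume"),
            inherits(pattern, "metabolic_pattern"))
  if (!identical(volume$mask, pattern$mask))
    stop("volume mask does not match the pattern's mask", call. = FALSE)
  l <- log_transform(volume)
  srp <- l - mean(l) - pattern$gmp
  raw <- sum(srp * pattern$weights)
  list(raw_score = raw,
       z_score = (raw - pattern$nc_score_mean) / pattern$nc_score_sd)
}

#' Pattern-expression feature matrix
#'
#' Scores every subject against every pattern and assembles the Z-scores into
#' a subjects x patterns [feature_matrix()] (column order follows the pattern
#' list), carrying class labels and leakage flags from the subject table.
#'
#' @param volumes Named list of preprocessed [pet_volume()] objects.
#' @param patterns List of [metabolic_pattern][derive_pattern] objects (>= 1).
#' @param subjects Subject table with `id`, `class`, `leakage` covering all
#'   volumes.
#' @return A [feature_matrix()].
#' @export
pattern_feature_matrix <- function(volumes, patterns, subjects) {
  if (length(patterns) < 1L) stop("need at least one pattern", call. = FALSE)
  ids <- names(volumes)
  if (is.null(ids) || !all(ids %in% subjects$id))
    stop("volumes must be named by subject id present in the subject table",
         call. = FALSE)
  pnames <- vapply(patterns, `[[`, character(1), "name")
  vals <- matrix(NA_real_, length(volumes), length(patterns),
                 dimnames = list(ids, pnames))
  for (i in seq_along(volumes)) {
    for (j in seq_along(patterns)) {
      z <- tryCatch(tpr_score(volumes[[i]], patterns[[j]])$z_score,
                    error = function(e)
                      stop(sprintf("scoring failed for subject %s: %s",
                                   ids[i], conditionMessage(e)), call. = FALSE))
      vals[i, j] <- z
    }
  }
  m <- match(ids, subjects$id)
  feature_matrix(vals, class_labels = subjects$class[m],
                 leakage_flags = subjects$leakage[m])
}
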