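# Shapley-value explanations of per-class classifier scores, and their
# aggregation into class-specific regional importance maps.
#
# The sampling estimator draws random feature orderings (which visits
# coalitions with exactly the Shapley combinatorial weights) and imputes the
# features not yet added either from background rows (independent mode) or
# from the Gaussian conditional distribution given the present features
# (dependent mode). Each ordering telescopes, so attributions sum exactly to
# f(x) minus the mean background prediction.

#' Per-class score matrix of a model on new data
#'
#' Generic used by the Shapley estimators: returns an n x classes numeric
#' matrix of per-class scores. Implemented for [linear_score_model()],
#' [train_multiclass_linear()] models (decoded scores), and plain functions.
#'
#' @param model The model (or a function `X -> matrix`).
#' @param X Numeric matrix of inputs.
#' @return Numeric matrix, one column per class.
#' @export
score_matrix <- function(model, X) UseMethod("score_matrix")

#' @export
score_matrix.function <- function(model, X) as.matrix(model(as.matrix(X)))

#' @export
score_matrix.ovo_linear_model <- function(model, X)
  predict(model, X, type = "scores")

#' @export
score_matrix.linear_score_model <- function(model, X)
  sweep(as.matrix(X) %*% model$weights, 2, model$bias, `+`)

#' Linear per-class score model
#'
#' A per-class score that is linear in the features: `f_k(x) = x' W_k + b_k`.
#' Used for closed-form Shapley attribution and as the routing target when a
#' model is exactly linear.
#'
#' @param weights Numeric matrix, features x classes.
#' @param bias Numeric per-class intercept (default 0).
#' @return An object of class `linear_score_model`.
#' @export
linear_score_model <- function(weights, bias = 0) {
  weights <- as.matrix(weights)
  bias <- rep_len(bias, ncol(weights))
  structure(list(weights = weights, bias = bias), class = "linear_score_model")
}

#' Exact Shapley values for a linear per-class score
#'
#' Under the marginal (independent-feature) value function, the Shapley value
#' of feature j for class k is `W_jk * (x_j - reference_mean_j)`; efficiency
#' holds exactly.
#'
#' @param model A [linear_score_model()].
#' @param x Numeric feature vector of one subject.
#' @param reference_means Background expectation of each feature.
#' @return List with `phi` (features x classes matrix), `reference`
#'   (per-class expected score) and `method`.
#' @export
shapley_linear_exact <- function(model, x, reference_means) {
  if (!inherits(model, "linear_score_model"))
    stop("exact attribution requires a linear score model; use shapley_sampling()",
         call. = FALSE)
  x <- as.numeric(x)
  reference_means <- as.numeric(reference_means)
  stopifnot(length(x) == nrow(model$weights),
            length(reference_means) == length(x))
  phi <- model$weights * (x - reference_means)
  dimnames(phi) <- dimnames(model$weights)
  ref <- as.numeric(crossprod(reference_means, model$weights)) + model$bias
  list(phi = phi, reference = ref, method = "linear_exact")
}

# Draw masked features from the Gaussian conditional N(mu, Sigma) given the
# observed features fixed at x[obs]; ridge-regularize a singular Sigma_oo.
cond_mvn_draw <- function(x, obs, mu, Sigma, ridge = 1e-8) {
  d <- length(mu)
  mis <- setdiff(seq_len(d), obs)
  out <- x
  if (length(mis) == 0) return(out)
  if (length(obs) == 0) {
    cmu <- mu
    cS <- Sigma
  } else {
    Soo <- Sigma[obs, obs, drop = FALSE]
    ok <- FALSE
    for (r in c(0, ridge, ridge * 1e4)) {
      Soo_r <- Soo + diag(r, nrow(Soo))
      sol <- tryCatch(solve(Soo_r, t(Sigma[mis, obs, drop = FALSE])),
                      error = function(e) NULL)
      if (!is.null(sol)) { ok <- TRUE; break }
    }
    if (!ok) stop("background covariance is singular beyond repair", call. = FALSE)
    if (r > 0)
      warning("singular background covariance; ridge-regularized", call. = FALSE)
    B <- t(sol)                              # Sigma_mo %*% Soo^-1
    cmu <- mu[mis] + as.numeric(B %*% (x[obs] - mu[obs]))
    cS <- Sigma[mis, mis, drop = FALSE] - B %*% Sigma[obs, mis, drop = FALSE]
  }
  cS <- (cS + t(cS)) / 2
  ev <- eigen(cS, symmetric = TRUE)
  lam <- pmax(ev$values, 0)
  z <- stats::rnorm(length(mis))
  draw <- cmu + as.numeric(ev$vectors %*% (sqrt(lam) * z))
  out[mis] <- draw
  out
}

#' Shapley values by permutation (kernel-weighted coalition) sampling
#'
#' Estimates the Shapley value of every feature for every class score by
#' sampling random feature orderings; the coalitions visited by a uniform
#' random ordering occur with exactly the Shapley combinatorial weights.
#' Features not yet added are imputed from a sampled background row
#' (independent mode) or drawn from the Gaussian conditional distribution
#' given the features already present, using the background mean and
#' covariance (dependent mode, for correlated features). Because each
#' ordering telescopes, the attributions sum exactly to the subject's score
#' minus the mean sampled background score.
#'
#' @param model Anything with a [score_matrix()] method.
#' @param x Numeric feature vector of the subject to explain.
#' @param background Numeric matrix of background subjects (>= 10 rows).
#' @param n_samples Number of sampled orderings (>= 100).
#' @param seed Integer seed.
#' @param dependent Use Gaussian-conditional imputation (default `FALSE`).
#' @return List with `phi` and `se` (features x classes matrices),
#'   `reference` (per-class mean background score) and `meta`.
#' @export
shapley_sampling <- function(model, x, background, n_samples = 200, seed = 1,
                             dependent = FALSE) {
  x <- as.numeric(x)
  background <- as.matrix(background)
  d <- length(x)
  if (ncol(background) != d)
    stop("background and x disagree on the number of features", call. = FALSE)
  if (nrow(background) < 10)
    stop("need a background set of >= 10 subjects", call. = FALSE)
  if (n_samples < 100) stop("need n_samples >= 100", call. = FALSE)
  mu <- colMeans(background)
  Sigma <- if (dependent) stats::cov(background) else NULL

  with_seed(seed, {
    perms <- replicate(n_samples, sample.int(d), simplify = FALSE)
    Z <- matrix(NA_real_, n_samples * (d + 1L), d)
    row <- 0L
    for (s in seq_len(n_samples)) {
      if (dependent) {
        z <- cond_mvn_draw(x, integer(), mu, Sigma)
        for (t in 0:d) {
          if (t > 0) {
            obs <- perms[[s]][seq_len(t)]
            z <- cond_mvn_draw(x, obs, mu, Sigma)
            z[obs] <- x[obs]
          }
          Z[row + t + 1L, ] <- z
        }
      } else {
        b <- background[sample.int(nrow(background), 1L), ]
        z <- b
        Z[row + 1L, ] <- z
        for (t in seq_len(d)) {
          z[perms[[s]][t]] <- x[perms[[s]][t]]
          Z[row + t + 1L, ] <- z
        }
      }
      row <- row + d + 1L
    }
  })
  S <- score_matrix(model, Z)
  K <- ncol(S)
  contrib <- array(NA_real_, c(n_samples, d, K))
  ref_draws <- matrix(NA_real_, n_samples, K)
  for (s in seq_len(n_samples)) {
    base <- (s - 1L) * (d + 1L)
    ref_draws[s, ] <- S[base + 1L, ]
    diffs <- S[base + 1L + seq_len(d), , drop = FALSE] -
      S[base + seq_len(d), , drop = FALSE]
    contrib[s, perms[[s]], ] <- diffs
  }
  phi <- apply(contrib, c(2, 3), mean)
  se <- apply(contrib, c(2, 3), stats::sd) / sqrt(n_samples)
  cn <- colnames(S)
  dimnames(phi) <- dimnames(se) <- list(names(x) %||% NULL, cn)
  list(phi = phi, se = se, reference = colMeans(ref_draws),
       meta = list(method = if (dependent) "sampling_dependent"
                   else "sampling_independent",
                   n_samples = n_samples, seed = seed))
}

#' Shapley attributions for ensemble training subjects over several runs
#'
#' For each of `n_runs` resampling iterations, trains the multi-class model
#' on the training split and attributes every training subject's per-class
#' decoded score to the features by [shapley_sampling()], with that split's
#' training set as the background. Returns a long table suitable for
#' [class_importance_map()].
#'
#' @param fm A [feature_matrix()].
#' @param scheme A [split_scheme()] (only its first `n_runs` iterations are
#'   used).
#' @param config A [classifier_config()].
#' @param n_runs Number of resampling iterations to explain (default 50).
#' @param n_samples Sampled orderings per subject (default 100).
#' @param seed Master seed for the per-subject estimators.
#' @param dependent Passed to [shapley_sampling()].
#' @param subjects_per_run Optional cap on training subjects explained per
#'   run (subsampled deterministically; `NULL` explains all).
#' @return Data frame: run, subject_id, true_class, feature, class, phi, se.
#' @export
ensemble_shap_importance <- function(fm, scheme, config = classifier_config(),
                                     n_runs = 50, n_samples = 100, seed = 1,
                                     dependent = FALSE,
                                     subjects_per_run = NULL) {
  stopifnot(inherits(fm, "feature_matrix"), inherits(scheme, "split_scheme"))
  n_runs <- min(n_runs, scheme$n_iterations)
  if (length(scheme$leakage_ids) == 0 && any(fm$leakage_flags))
    scheme$leakage_ids <- fm$subject_ids[fm$leakage_flags]
  splits <- make_splits(subjects_of(fm), scheme)[seq_len(n_runs)]
  sub_seeds <- derive_seeds(seed, n_runs * nrow(fm$values))
  rows <- list()
  si <- 0L
  for (r in seq_len(n_runs)) {
    tr <- match(splits[[r]]$train, fm$subject_ids)
    Xtr <- fm$values[tr, , drop = FALSE]
    model <- train_multiclass_linear(Xtr, fm$class_labels[tr], config)
    explain_idx <- tr
    if (!is.null(subjects_per_run) && length(tr) > subjects_per_run)
      explain_idx <- tr[round(seq(1, length(tr), length.out = subjects_per_run))]
    for (i in explain_idx) {
      si <- si + 1L
      sh <- shapley_sampling(model, fm$values[i, ], Xtr,
                             n_samples = n_samples, seed = sub_seeds[si],
                             dependent = dependent)
      rows[[length(rows) + 1L]] <- data.frame(
        run = r, subject_id = fm$subject_ids[i],
        true_class = fm$class_labels[i],
        feature = rep(fm$feature_names, times = ncol(sh$phi)),
        class = rep(colnames(sh$phi), each = nrow(sh$phi)),
        phi = as.vector(sh$phi), se = as.vector(sh$se),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Class-specific regional importance map
#'
#' For each class c, the mean over runs and over training subjects whose true
#' label is c of the absolute Shapley value of each feature for the class-c
#' score; the per-feature values are painted back onto the atlas parcels, one
#' importance volume per class. Classes with no subjects yield a zero map
#' with a notice.
#'
#' @param shapley_table Long table from [ensemble_shap_importance()].
#' @param atlas A [pet_atlas()] whose region names match the feature names.
#' @return Object of class `importance_map`: `values` (features x classes
#'   matrix of mean absolute Shapley values, >= 0) and `maps` (named list of
#'   3-D arrays).
#' @export
class_importance_map <- function(shapley_table, atlas) {
  stopifnot(inherits(atlas, "pet_atlas"))
  classes <- order_classes(shapley_table$class)
  features <- unique(shapley_table$feature)
  vals <- matrix(0, length(features), length(classes),
                 dimnames = list(features, classes))
  for (cl in classes) {
    sub <- shapley_table[shapley_table$class == cl &
                           shapley_table$true_class == cl, ]
    if (nrow(sub) == 0) {
      message("no subjects with true class ", cl, "; importance map is zero")
      next
    }
    agg <- tapply(abs(sub$phi), sub$feature, mean)
    vals[names(agg), cl] <- agg
  }
  maps <- lapply(classes, function(cl) {
    m <- array(0, dim(atlas$labels))
    for (i in seq_len(nrow(atlas$label_table))) {
      nm <- atlas$label_table$name[i]
      if (!nm %in% features) next
      id <- atlas$label_table$id[i]
      key <- as.character(id)
      members <- if (key %in% names(atlas$composites))
        atlas$composites[[key]] else id
      m[atlas$labels %in% members] <- vals[nm, cl]
    }
    m
  })
  names(maps) <- classes
  structure(list(values = vals, maps = maps), class = "importance_map")
}
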