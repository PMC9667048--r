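# Neighborhood component analysis (NCA) feature weighting for classification.
#
# Learns per-feature weights maximizing a soft leave-one-out nearest-neighbor
# classification objective minus an L2 penalty on the weights. Distances are
# weighted L1: d(i,j) = sum_r w_r^2 |x_ir - x_jr|; reference probabilities
# p_ij are softmax of -d over j != i; the regularized average leave-one-out
# probability of correct classification is maximized by a limited-memory
# quasi-Newton method (L-BFGS-B) from the all-ones start.

#' NCA objective and analytic gradient
#'
#' Objective: `mean_i p_i - lambda * sum_r w_r^2`, where
#' `p_i = sum_{j: y_j = y_i, j != i} p_ij` and `p_ij` are the softmax
#' reference probabilities of the weighted L1 distances. Distances have the
#' row minimum subtracted before exponentiation to guard against underflow.
#'
#' @param w Numeric weight vector (one entry per feature).
#' @param X Numeric matrix, subjects x features (>= 2 subjects).
#' @param y Class labels.
#' @param lambda Regularization strength (>= 0).
#' @return List with `value` and `gradient`.
#' @export
nca_objective <- function(w, X, y, lambda) {
  X <- as.matrix(X)
  n <- nrow(X)
  d <- ncol(X)
  if (n < 2L) stop("NCA needs at least 2 subjects", call. = FALSE)
  if (length(w) != d) stop("`w` must have one entry per feature", call. = FALSE)
  if (lambda < 0) stop("`lambda` must be >= 0", call. = FALSE)
  y <- as.character(y)

  D <- matrix(0, n, n)
  A <- vector("list", d)
  for (r in seq_len(d)) {
    A[[r]] <- abs(outer(X[, r], X[, r], "-"))
    D <- D + w[r]^2 * A[[r]]
  }
  diag(D) <- Inf
  rmin <- apply(D, 1, min)
  E <- exp(-(D - rmin))
  E[!is.finite(E)] <- 0            # the Inf diagonal
  P <- E / rowSums(E)
  same <- outer(y, y, "==")
  diag(same) <- FALSE
  p_i <- rowSums(P * same)
  value <- mean(p_i) - lambda * sum(w^2)

  gradient <- numeric(d)
  for (r in seq_len(d)) {
    t1 <- p_i * rowSums(P * A[[r]])
    t2 <- rowSums(P * same * A[[r]])
    gradient[r] <- (2 * w[r] / n) * sum(t1 - t2) - 2 * lambda * w[r]
  }
  list(value = value, gradient = gradient)
}

#' Fit NCA feature weights
#'
#' Maximizes [nca_objective()] with L-BFGS-B from the all-ones start;
#' convergence when the projected gradient max-norm drops to 1e-6 or after
#' 400 iterations. The returned weights are nonnegative (the objective
#' depends on the weights only through their squares, so signs are projected
#' away at the end).
#'
#' @param X Standardized numeric matrix, subjects x features.
#' @param y Class labels.
#' @param lambda Regularization strength (>= 0).
#' @param seed Optional seed, used only when `restarts > 0`.
#' @param restarts Number of additional random restarts (default 0; the
#'   default path is fully deterministic).
#' @return Object of class `nca_weights`: `w` (nonnegative), `lambda`,
#'   `objective`, `objective_trace` (evaluations of the objective, in call
#'   order), `convergence`.
#' @export
fit_nca <- function(X, y, lambda = 0, seed = NULL, restarts = 0) {
  X <- as.matrix(X)
  trace_env <- new.env()
  trace_env$vals <- numeric()
  fn <- function(w) {
    v <- nca_objective(w, X, y, lambda)$value
    if (!is.finite(v))
      stop("non-finite NCA objective; trace: ",
           paste(signif(utils::tail(trace_env$vals, 5), 4), collapse = ", "),
           call. = FALSE)
    trace_env$vals <- c(trace_env$vals, v)
    v
  }
  gr <- function(w) nca_objective(w, X, y, lambda)$gradient
  run_once <- function(w0) {
    stats::optim(w0, fn, gr, method = "L-BFGS-B",
                 control = list(fnscale = -1, maxit = 400, pgtol = 1e-6))
  }
  best <- run_once(rep(1, ncol(X)))
  if (restarts > 0) {
    starts <- with_seed(seed %||% 1,
                        replicate(restarts, stats::runif(ncol(X), 0.1, 2),
                                  simplify = FALSE))
    for (w0 in starts) {
      cand <- run_once(w0)
      if (cand$value > best$value) best <- cand
    }
  }
  w <- abs(best$par)
  names(w) <- colnames(X)
  structure(list(w = w, lambda = lambda, objective = best$value,
                 objective_trace = trace_env$vals,
                 convergence = best$convergence),
            class = "nca_weights")
}

#' @export
print.nca_weights <- function(x, ...) {
  cat(sprintf("<nca_weights> %d features, lambda = %g, objective = %.4f\n",
              length(x$w), x$lambda, x$objective))
  invisible(x)
}

# 1-NN prediction in the weighted-L1 distance space defined by NCA weights.
nca_1nn_predict <- function(w, X_train, y_train, X_test) {
  d <- length(w)
  pred <- character(nrow(X_test))
  for (i in seq_len(nrow(X_test))) {
    dist <- colSums(w^2 * t(abs(sweep(X_train, 2, X_test[i, ]))))
    pred[i] <- y_train[which.min(dist)]
  }
  pred
}

#' Select the NCA regularization by cross-validation
#'
#' For each candidate lambda, fits NCA on the training folds and classifies
#' the held-out fold by 1-nearest-neighbor in the learned weighted-distance
#' space; returns the lambda with minimum mean misclassification loss (ties
#' go to the smaller lambda).
#'
#' @param X Standardized numeric matrix.
#' @param y Class labels.
#' @param lambda_grid Positive candidate values (non-empty).
#' @param n_folds Number of stratified folds (>= 2).
#' @param seed Seed for the fold assignment.
#' @return List with `lambda` (the selected value) and `losses` (data frame
#'   lambda, mean_loss).
#' @export
select_lambda <- function(X, y, lambda_grid, n_folds = 5, seed = 1) {
  if (length(lambda_grid) == 0) stop("empty lambda grid", call. = FALSE)
  if (any(lambda_grid <= 0)) stop("lambda grid must be positive", call. = FALSE)
  if (n_folds < 2) stop("need >= 2 folds", call. = FALSE)
  X <- as.matrix(X)
  y <- as.character(y)
  n <- nrow(X)
  fold <- integer(n)
  with_seed(seed, {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  lambda_grid <- sort(lambda_grid)
  mean_loss <- vapply(lambda_grid, function(lam) {
    losses <- vapply(seq_len(n_folds), function(f) {
      tr <- fold != f
      if (length(unique(y[tr])) < 2 || sum(!tr) == 0) return(NA_real_)
      wfit <- fit_nca(X[tr, , drop = FALSE], y[tr], lam)
      mean(nca_1nn_predict(wfit$w, X[tr, , drop = FALSE], y[tr],
                           X[!tr, , drop = FALSE]) != y[!tr])
    }, numeric(1))
    mean(losses, na.rm = TRUE)
  }, numeric(1))
  list(lambda = lambda_grid[which.min(mean_loss)],
       losses = data.frame(lambda = lambda_grid, mean_loss = mean_loss))
}

#' Feature-selection frequency over resampling iterations
#'
#' Per scheme iteration, fits NCA on the (standardized) training split and
#' marks the features whose weight exceeds `threshold_frac` of that
#' iteration's maximum weight; the frequency of each feature is the fraction
#' of successful iterations in which it was marked. Iterations whose fit
#' fails are skipped with a warning and counted.
#'
#' @param fm A [feature_matrix()].
#' @param scheme A [split_scheme()].
#' @param lambda Regularization used in every iteration.
#' @param threshold_frac Selection cutoff as a fraction of the maximum
#'   weight (default 0.3).
#' @return List with `frequency` (named vector in `[0,1]`), `n_iterations`,
#'   `n_failed`.
#' @export
selection_frequency <- function(fm, scheme, lambda = 0.01,
                                threshold_frac = 0.3) {
  stopifnot(inherits(fm, "feature_matrix"), inherits(scheme, "split_scheme"))
  if (scheme$n_iterations < 1) stop("need >= 1 iteration", call. = FALSE)
  splits <- make_splits(subjects_of(fm), scheme)
  marks <- numeric(ncol(fm$values))
  names(marks) <- fm$feature_names
  failed <- 0L
  for (sp in splits) {
    tr <- match(sp$train, fm$subject_ids)
    Xt <- scale(fm$values[tr, , drop = FALSE])
    Xt[, apply(fm$values[tr, , drop = FALSE], 2, stats::sd) == 0] <- 0
    res <- tryCatch(fit_nca(Xt, fm$class_labels[tr], lambda),
                    error = function(e) {
                      warning("NCA fit failed in one iteration: ",
                              conditionMessage(e), call. = FALSE)
                      NULL
                    })
    if (is.null(res)) { failed <- failed + 1L; next }
    marks <- marks + (res$w > threshold_frac * max(res$w))
  }
  ok <- length(splits) - failed
  if (ok == 0) stop("all NCA iterations failed", call. = FALSE)
  list(frequency = marks / ok, n_iterations = length(splits),
       n_failed = failed)
}

#' Per-class F1 as a function of the number of top-ranked features
#'
#' For each k, reruns the classifier ensemble on the k top-ranked features
#' (same scheme, hence identical splits across k) and records the per-class
#' F1; with k equal to the full feature count this reproduces the full-model
#' F1 exactly.
#'
#' @param fm A [feature_matrix()].
#' @param ranked_features Feature names ranked most-to-least important (e.g.
#'   by NCA weight on the full data set).
#' @param scheme A [split_scheme()].
#' @param config A [classifier_config()].
#' @param k_values Values of k to evaluate (default `1:length(ranked_features)`;
#'   values beyond the feature count are dropped with a notice).
#' @return List with `curve` (data frame k, class, f1) and `best_k` (named
#'   vector: smallest k attaining each class's maximum F1).
#' @export
f1_vs_topk <- function(fm, ranked_features, scheme,
                       config = classifier_config(), k_values = NULL) {
  stopifnot(inherits(fm, "feature_matrix"))
  k_values <- k_values %||% seq_along(ranked_features)
  if (any(k_values > length(ranked_features))) {
    message("dropping k values beyond the number of ranked features")
    k_values <- k_values[k_values <= length(ranked_features)]
  }
  rows <- list()
  for (k in k_values) {
    sub <- select_features(fm, ranked_features[seq_len(k)])
    ev <- evaluate_ensemble(run_ensemble(sub, scheme, config), sub)
    rows[[length(rows) + 1L]] <-
      data.frame(k = k, class = ev$per_class$class, f1 = ev$per_class$f1,
                 stringsAsFactors = FALSE)
  }
  curve <- do.call(rbind, rows)
  best_k <- vapply(split(curve, curve$class), function(df) {
    df$k[which(df$f1 >= max(df$f1) - 1e-12)[1]]
  }, numeric(1))
  list(curve = curve, best_k = best_k)
}
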