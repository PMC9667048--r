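# Repeated stratified multi-class linear-SVM ensemble with majority voting.
#
# One binary maximum-margin linear learner per unordered class pair
# (one-vs-one error-correcting output coding), loss-weighted decoding with a
# hinge-type binary loss, 500 stratified 70/30 resamples by default, and a
# leakage rule keeping pattern-derivation subjects out of every test split.

#' Resampling scheme for the classifier ensemble
#'
#' @param n_iterations Number of stratified train/test resamples (default
#'   500).
#' @param train_fraction Fraction of each class assigned to training
#'   (default 0.7; sizes rounded half-to-even, adjusted by one if a class's
#'   test set would otherwise be empty).
#' @param stratified Stratify splits by class (always `TRUE` in this design;
#'   kept explicit for the record).
#' @param leakage_ids Subject ids never eligible for testing (forced into
#'   every training split first).
#' @param master_seed Integer master seed; iteration i uses a seed derived
#'   from it, so the full split sequence is reproducible.
#' @return An object of class `split_scheme`.
#' @export
split_scheme <- function(n_iterations = 500, train_fraction = 0.7,
                         stratified = TRUE, leakage_ids = character(),
                         master_seed = 1) {
  if (!is_count(n_iterations) || n_iterations < 1)
    stop("`n_iterations` must be a positive integer", call. = FALSE)
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("`train_fraction` must be in (0, 1)", call. = FALSE)
  if (!isTRUE(stratified))
    stop("only stratified resampling is implemented", call. = FALSE)
  structure(list(n_iterations = as.integer(n_iterations),
                 train_fraction = train_fraction,
                 stratified = TRUE,
                 leakage_ids = as.character(leakage_ids),
                 master_seed = as.integer(master_seed)),
            class = "split_scheme")
}

#' Stratified train/test splits with leakage control
#'
#' Per iteration and class, `round(train_fraction * n_class)` subjects go to
#' training (round half to even); leakage subjects are forced into training
#' first and the remaining training slots are filled at random from the
#' non-leakage subjects, the rest forming the test set. Test sets therefore
#' never contain leakage ids, and a class whose subjects are all leakage is
#' simply never tested. Deterministic given the scheme's master seed.
#'
#' @param subjects Subject table with `id` and `class` columns.
#' @param scheme A [split_scheme()].
#' @return List of length `n_iterations`; each element has `train` and
#'   `test` character vectors of subject ids.
#' @export
make_splits <- function(subjects, scheme) {
  stopifnot(inherits(scheme, "split_scheme"))
  classes <- order_classes(subjects$class)
  by_class <- split(subjects$id, factor(subjects$class, classes))
  leak <- scheme$leakage_ids
  seeds <- derive_seeds(scheme$master_seed, scheme$n_iterations)
  lapply(seq_len(scheme$n_iterations), function(i) {
    with_seed(seeds[i], {
      train <- character()
      test <- character()
      for (cl in classes) {
        ids <- by_class[[cl]]
        n <- length(ids)
        if (n == 0) next
        lk <- intersect(ids, leak)
        nl <- setdiff(ids, lk)
        n_train <- max(1L, round(scheme$train_fraction * n))
        n_extra <- n_train - length(lk)
        if (n_extra < 0) n_extra <- 0L
        if (n_extra >= length(nl) && length(nl) > 0)
          n_extra <- length(nl) - 1L       # keep one test subject if possible
        picked <- if (n_extra > 0) sample(nl, n_extra) else character()
        train <- c(train, lk, picked)
        test <- c(test, setdiff(nl, picked))
      }
      list(train = train, test = test)
    })
  })
}

#' Multi-class classifier configuration
#'
#' @param cost Regularization cost C of the binary linear SVM learners
#'   (default 1; no tuning is performed).
#' @param standardize Z-score feature columns using training-split statistics
#'   before fitting (default `TRUE`); test data reuse the training statistics
#'   so application stays prospective.
#' @param coding `"onevsone"` (default: one learner per class pair) or
#'   `"onevsall"`.
#' @return A list of class `classifier_config`.
#' @export
classifier_config <- function(cost = 1, standardize = TRUE,
                              coding = c("onevsone", "onevsall")) {
  coding <- match.arg(coding)
  if (cost <= 0) stop("`cost` must be positive", call. = FALSE)
  structure(list(cost = cost, standardize = isTRUE(standardize),
                 coding = coding),
            class = "classifier_config")
}

# Coding matrix M (classes x learners): +1 / -1 / 0 per ECOC design.
coding_matrix <- function(classes, coding) {
  K <- length(classes)
  if (coding == "onevsone") {
    pairs <- utils::combn(K, 2)
    M <- matrix(0L, K, ncol(pairs),
                dimnames = list(classes, apply(pairs, 2, function(p)
                  paste(classes[p], collapse = "/"))))
    for (l in seq_len(ncol(pairs))) {
      M[pairs[1, l], l] <- 1L
      M[pairs[2, l], l] <- -1L
    }
  } else {
    M <- matrix(-1L, K, K, dimnames = list(classes, paste0(classes, "/rest")))
    diag(M) <- 1L
  }
  M
}

#' Train a multi-class maximum-margin linear classifier
#'
#' Fits one binary linear-kernel SVM per learner of the error-correcting
#' output code (one-vs-one by default: K classes give K(K-1)/2 learners).
#' Prediction decodes the binary decision values against the coding matrix
#' with a hinge-type loss, `max(0, 1 - m f) / 2`, and the predicted label is
#' the class minimizing the mean loss over its learners; per-class decoded
#' scores (negative mean loss) are exposed.
#'
#' @param X Numeric training matrix (subjects x features).
#' @param y Class labels (character or factor); >= 2 classes required.
#' @param config A [classifier_config()].
#' @return An object of class `ovo_linear_model`.
#' @export
train_multiclass_linear <- function(X, y, config = classifier_config()) {
  X <- as.matrix(X)
  y <- as.character(y)
  classes <- order_classes(y)
  if (length(classes) < 2L)
    stop("training set contains a single class; cannot fit", call. = FALSE)
  if (config$standardize) {
    ctr <- colMeans(X)
    scl <- apply(X, 2, stats::sd)
    scl[!is.finite(scl) | scl == 0] <- 1
  } else {
    ctr <- rep(0, ncol(X)); scl <- rep(1, ncol(X))
  }
  Xs <- scale(X, center = ctr, scale = scl)
  M <- coding_matrix(classes, config$coding)
  learners <- vector("list", ncol(M))
  for (l in seq_len(ncol(M))) {
    pos <- classes[M[, l] == 1L]
    neg <- classes[M[, l] == -1L]
    idx <- y %in% c(pos, neg)
    lab <- factor(ifelse(y[idx] %in% pos, "pos", "neg"),
                  levels = c("pos", "neg"))
    learners[[l]] <- e1071::svm(Xs[idx, , drop = FALSE], lab,
                                kernel = "linear", cost = config$cost,
                                scale = FALSE)
  }
  structure(list(learners = learners, coding = M, classes = classes,
                 center = ctr, scale = scl, config = config,
                 feature_names = colnames(X)),
            class = "ovo_linear_model")
}

# Decision-value matrix (n x learners), oriented so positive favours the
# learner's +1 class.
decision_values <- function(model, X) {
  Xs <- scale(as.matrix(X), center = model$center, scale = model$scale)
  out <- matrix(NA_real_, nrow(Xs), length(model$learners))
  for (l in seq_along(model$learners)) {
    p <- stats::predict(model$learners[[l]], Xs, decision.values = TRUE)
    dv <- attr(p, "decision.values")
    # libsvm labels the column "<first>/<second>"; positive favours <first>
    flip <- !startsWith(colnames(dv)[1], "pos")
    out[, l] <- if (flip) -dv[, 1] else dv[, 1]
  }
  out
}

#' Predict classes or decoded scores from a fitted multi-class model
#'
#' @param object An `ovo_linear_model` from [train_multiclass_linear()].
#' @param newdata Numeric matrix of features.
#' @param type `"class"` for labels, `"scores"` for the per-class decoded
#'   scores (negative mean hinge loss; larger is better).
#' @param ... Unused.
#' @return Character vector of labels or a numeric matrix n x classes.
#' @export
predict.ovo_linear_model <- function(object, newdata,
                                     type = c("class", "scores"), ...) {
  type <- match.arg(type)
  Fv <- decision_values(object, newdata)
  M <- object$coding
  loss <- matrix(NA_real_, nrow(Fv), nrow(M),
                 dimnames = list(NULL, object$classes))
  for (k in seq_len(nrow(M))) {
    active <- M[k, ] != 0L
    mf <- sweep(Fv[, active, drop = FALSE], 2, M[k, active], `*`)
    loss[, k] <- rowMeans(pmax(1 - mf, 0) / 2)
  }
  if (type == "scores") return(-loss)
  object$classes[apply(loss, 1, which.min)]
}

#' Run the repeated-resampling classifier ensemble
#'
#' For each iteration of the scheme, standardizes on the training split, fits
#' the multi-class linear model, and predicts the test split. The final label
#' of a subject is the modal predicted label over its test appearances (ties
#' broken by higher vote fraction, then by the fixed class order AD < DLB <
#' FTD < NC); `class_scores` are the per-class vote fractions, summing to 1
#' per tested subject. Subjects never tested (all-leakage) are excluded from
#' final labels with a notice.
#'
#' @param fm A [feature_matrix()].
#' @param scheme A [split_scheme()]; its `leakage_ids` default to the
#'   feature matrix's leakage flags if empty.
#' @param config A [classifier_config()].
#' @return An object of class `ensemble_result` with `per_iteration` (long
#'   data frame), `final_labels`, `test_counts`, `class_scores`, `classes`,
#'   `scheme`, `config`.
#' @export
run_ensemble <- function(fm, scheme, config = classifier_config()) {
  stopifnot(inherits(fm, "feature_matrix"), inherits(scheme, "split_scheme"))
  subjects <- subjects_of(fm)
  if (length(scheme$leakage_ids) == 0 && any(fm$leakage_flags))
    scheme$leakage_ids <- fm$subject_ids[fm$leakage_flags]
  splits <- make_splits(subjects, scheme)
  classes <- order_classes(fm$class_labels)
  ids <- fm$subject_ids
  votes <- matrix(0L, length(ids), length(classes),
                  dimnames = list(ids, classes))
  per_iter <- vector("list", length(splits))
  for (i in seq_along(splits)) {
    tr <- match(splits[[i]]$train, ids)
    te <- match(splits[[i]]$test, ids)
    model <- train_multiclass_linear(fm$values[tr, , drop = FALSE],
                                     fm$class_labels[tr], config)
    if (length(te) == 0) next
    pred <- predict(model, fm$values[te, , drop = FALSE])
    votes[cbind(te, match(pred, classes))] <-
      votes[cbind(te, match(pred, classes))] + 1L
    per_iter[[i]] <- data.frame(iteration = i, subject_id = ids[te],
                                true = fm$class_labels[te], predicted = pred,
                                stringsAsFactors = FALSE)
  }
  per_iteration <- do.call(rbind, per_iter)
  test_counts <- rowSums(votes)
  tested <- test_counts > 0
  if (any(!tested))
    message(sprintf("%d subject(s) never tested (leakage); excluded from final labels",
                    sum(!tested)))
  class_scores <- votes[tested, , drop = FALSE] / test_counts[tested]
  # modal label; which.max resolves count ties by the fixed class order
  final_labels <- classes[apply(votes[tested, , drop = FALSE], 1, which.max)]
  names(final_labels) <- ids[tested]
  structure(list(per_iteration = per_iteration,
                 final_labels = final_labels,
                 test_counts = test_counts,
                 class_scores = class_scores,
                 classes = classes, scheme = scheme, config = config),
            class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf("<ensemble_result> %d iterations, %d/%d subjects labelled\n",
              x$scheme$n_iterations, length(x$final_labels),
              length(x$test_counts)))
  invisible(x)
}

#' Evaluate an ensemble result against the true labels
#'
#' Builds the confusion matrix of final labels, per-class
#' specificity/precision/sensitivity/F1, overall accuracy, and one-vs-all
#' AUC using each subject's per-class vote fraction as the ROC score.
#'
#' @param result An [run_ensemble()] result.
#' @param fm The [feature_matrix()] the ensemble was run on (source of true
#'   labels).
#' @return List with `confusion`, `per_class` (data frame including `auc`),
#'   `overall_accuracy`, `n`.
#' @export
evaluate_ensemble <- function(result, fm) {
  stopifnot(inherits(result, "ensemble_result"), inherits(fm, "feature_matrix"))
  ids <- names(result$final_labels)
  truth <- fm$class_labels[match(ids, fm$subject_ids)]
  cm <- confusion(truth, result$final_labels, class_order = result$classes)
  rep <- per_class_metrics(cm)
  rep$per_class$auc <- vapply(result$classes, function(cl) {
    roc_auc_one_vs_all(result$class_scores[, cl], truth, cl)
  }, numeric(1))
  rep$confusion <- cm
  rep$n <- length(ids)
  rep
}
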