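study_table <- function(sizes = c(AD = 63, DLB = 79, FTD = 23, NC = 41)) {
  do.call(rbind, lapply(names(sizes), function(cl)
    data.frame(id = sprintf("%s%03d", cl, seq_len(sizes[[cl]])), class = cl,
               stringsAsFactors = FALSE)))
}

test_that("stratified 70/30 splits give the round-half-to-even train sizes", {
  tab <- study_table()
  sp <- make_splits(tab, split_scheme(3, master_seed = 5))
  for (s in sp) {
    tr <- table(tab$class[match(s$train, tab$id)])[c("AD", "DLB", "FTD", "NC")]
    expect_equal(as.integer(tr), c(44L, 55L, 16L, 29L))
    te <- table(tab$class[match(s$test, tab$id)])[c("AD", "DLB", "FTD", "NC")]
    expect_equal(as.integer(te), c(19L, 24L, 7L, 12L))
    expect_length(intersect(s$train, s$test), 0)
  }
})

test_that("leakage subjects never reach a test set and eligibility matches the reduced design", {
  tab <- study_table()
  leak <- unlist(lapply(list(c("AD", 20), c("DLB", 20), c("FTD", 10), c("NC", 29)),
                        function(x) sprintf("%s%03d", x[1], seq_len(as.integer(x[2])))))
  sp <- make_splits(tab, split_scheme(200, leakage_ids = leak, master_seed = 2))
  tested <- unique(unlist(lapply(sp, `[[`, "test")))
  expect_length(intersect(tested, leak), 0)
  per_class <- table(tab$class[match(tested, tab$id)])[c("AD", "DLB", "FTD", "NC")]
  expect_equal(as.integer(per_class), c(43L, 59L, 13L, 12L))
  expect_equal(length(tested), 127)
})

test_that("a fully-leaked class is absent from every test set", {
  tab <- study_table(c(AD = 10, DLB = 10, NC = 8))
  leak <- sprintf("DLB%03d", 1:10)
  sp <- make_splits(tab, split_scheme(20, leakage_ids = leak, master_seed = 4))
  tested <- unlist(lapply(sp, `[[`, "test"))
  expect_false(any(grepl("^DLB", tested)))
})

test_that("the split sequence is deterministic in the master seed", {
  tab <- study_table(c(AD = 15, DLB = 15, FTD = 10, NC = 10))
  s1 <- make_splits(tab, split_scheme(10, master_seed = 99))
  s2 <- make_splits(tab, split_scheme(10, master_seed = 99))
  expect_identical(s1, s2)
  s3 <- make_splits(tab, split_scheme(10, master_seed = 100))
  expect_false(identical(s1, s3))
})

test_that("every non-leakage subject is tested often enough at 500 iterations", {
  tab <- study_table()
  sp <- make_splits(tab, split_scheme(500, master_seed = 7))
  counts <- table(unlist(lapply(sp, `[[`, "test")))
  expect_setequal(names(counts), tab$id)
  expect_true(all(counts >= 50))
  # ~30 percent of 500 iterations = ~150 test appearances per subject
  expect_equal(mean(counts), 150, tolerance = 0.1)
  # with leakage, leaked subjects never accrue test appearances
  leak <- sprintf("AD%03d", 1:20)
  sp2 <- make_splits(tab, split_scheme(120, leakage_ids = leak, master_seed = 7))
  counts2 <- table(unlist(lapply(sp2, `[[`, "test")))
  expect_setequal(names(counts2), setdiff(tab$id, leak))
})

test_that("one-vs-one coding trains one learner per class pair", {
  set.seed(8)
  X <- matrix(rnorm(80), 40, 2)
  y <- rep(c("AD", "DLB", "FTD", "NC"), each = 10)
  m <- train_multiclass_linear(X, y)
  expect_length(m$learners, 6)
  expect_equal(dim(m$coding), c(4, 6))
  expect_error(train_multiclass_linear(X, rep("AD", 40)), "single class")
})

test_that("a linearly separable toy problem is fit perfectly", {
  X <- rbind(matrix(rnorm(40, -3, 0.3), 20, 2), matrix(rnorm(40, 3, 0.3), 20, 2))
  y <- rep(c("AD", "NC"), each = 20)
  m <- train_multiclass_linear(X, y)
  expect_equal(predict(m, X), y)
  sc <- predict(m, X, type = "scores")
  expect_equal(colnames(sc), c("AD", "NC"))
})

test_that("duplicating a feature column does not change predictions", {
  set.seed(12)
  X <- matrix(rnorm(120), 60, 2)
  y <- ifelse(X[, 1] + 0.5 * X[, 2] + rnorm(60, 0, 0.3) > 0, "AD", "NC")
  colnames(X) <- c("f1", "f2")
  Xdup <- cbind(X, f1b = X[, 1])
  Xnew <- matrix(rnorm(60), 30, 2, dimnames = list(NULL, colnames(X)))
  m1 <- train_multiclass_linear(X, y)
  m2 <- train_multiclass_linear(Xdup, y)
  expect_equal(predict(m1, Xnew), predict(m2, cbind(Xnew, Xnew[, 1])))
})

test_that("ensemble voting is reproducible, sums to one, and respects leakage", {
  co <- fixture_cohort()
  fm <- roi_feature_matrix(co$volumes_pp, co$atlas, co$subjects)
  sch <- split_scheme(25, master_seed = 31)   # leakage picked up from fm flags
  r1 <- suppressMessages(run_ensemble(fm, sch))
  r2 <- suppressMessages(run_ensemble(fm, sch))
  expect_identical(r1$final_labels, r2$final_labels)
  expect_identical(r1$per_iteration, r2$per_iteration)
  expect_equal(unname(rowSums(r1$class_scores)),
               rep(1, nrow(r1$class_scores)))
  # modal label's vote fraction is at least 1/K
  modal <- r1$class_scores[cbind(seq_along(r1$final_labels),
                                 match(r1$final_labels, r1$classes))]
  expect_true(all(modal >= 1 / length(r1$classes)))
  # leakage subjects are excluded from final labels
  expect_length(intersect(names(r1$final_labels),
                          co$subjects$id[co$subjects$leakage]), 0)
  expect_setequal(names(r1$final_labels),
                  co$subjects$id[!co$subjects$leakage])
})

test_that("the ensemble separates the default planted cohort accurately", {
  co <- fixture_cohort()
  fm <- roi_feature_matrix(co$volumes_pp, co$atlas, co$subjects)
  fm_all <- feature_matrix(fm$values, fm$class_labels, FALSE)
  ev <- evaluate_ensemble(run_ensemble(fm_all, split_scheme(40, master_seed = 6)),
                          fm_all)
  expect_gte(ev$overall_accuracy, 0.9)
  expect_true(all(ev$per_class$auc > 0.9))
})
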