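test_that("linear-model Shapley values match the exhaustive-subset oracle", {
  mod <- linear_score_model(matrix(c(2, 3), 2, 1,
                                   dimnames = list(c("x1", "x2"), "f")))
  ex <- shapley_linear_exact(mod, c(1, 1), c(0, 0))
  expect_equal(as.numeric(ex$phi), c(2, 3))
  bg <- matrix(0, 12, 2)
  brute <- shapley_brute(function(Z) Z %*% mod$weights, c(1, 1), bg)
  expect_equal(unname(ex$phi), brute, ignore_attr = TRUE)
  # x at the reference attributes nothing; efficiency is exact
  expect_equal(as.numeric(shapley_linear_exact(mod, c(0, 0), c(0, 0))$phi),
               c(0, 0))
  set.seed(22)
  x <- rnorm(2); ref <- rnorm(2)
  ex2 <- shapley_linear_exact(mod, x, ref)
  expect_equal(sum(ex2$phi), sum(x * mod$weights) - sum(ref * mod$weights))
  expect_error(shapley_linear_exact(list(), c(1, 1), c(0, 0)), "linear")
})

test_that("sampling estimator is consistent with the exact linear attribution", {
  set.seed(23)
  W <- matrix(rnorm(8), 4, 2, dimnames = list(paste0("f", 1:4), c("AD", "NC")))
  mod <- linear_score_model(W, bias = c(0.3, -0.1))
  bg <- matrix(rnorm(80), 20, 4)
  x <- rnorm(4)
  sh <- shapley_sampling(mod, x, bg, n_samples = 400, seed = 5)
  ex <- shapley_linear_exact(mod, x, colMeans(bg))
  expect_true(all(abs(sh$phi - ex$phi) <= 3 * sh$se + 1e-8))
  # efficiency holds exactly by telescoping
  f_x <- as.numeric(score_matrix(mod, matrix(x, 1)))
  expect_equal(unname(colSums(sh$phi)), f_x - sh$reference, tolerance = 1e-10)
})

test_that("sampling matches exhaustive subset enumeration for a nonlinear score", {
  set.seed(24)
  f <- function(Z) cbind(s = Z[, 1] * Z[, 2] + sin(Z[, 3]) + 0.5 * Z[, 4]^2)
  bg <- matrix(rnorm(60), 15, 4)
  x <- c(1.2, -0.7, 0.4, 0.9)
  sh <- shapley_sampling(f, x, bg, n_samples = 600, seed = 11)
  brute <- shapley_brute(f, x, bg)
  expect_true(all(abs(sh$phi - brute) <= 3 * sh$se + 1e-8))
})

test_that("Monte-Carlo standard errors shrink as samples double", {
  set.seed(25)
  W <- matrix(rnorm(6), 3, 2)
  mod <- linear_score_model(W)
  bg <- matrix(rnorm(45), 15, 3)
  x <- c(1, -1, 0.5)
  se1 <- mean(shapley_sampling(mod, x, bg, n_samples = 100, seed = 3)$se)
  se2 <- mean(shapley_sampling(mod, x, bg, n_samples = 400, seed = 3)$se)
  expect_lt(se2, se1)
})

test_that("functionally identical features receive equal attribution in expectation", {
  set.seed(26)
  W <- matrix(c(1.5, 1.5, -0.8), 3, 1)
  mod <- linear_score_model(W)
  bg <- cbind(a = rnorm(30), b = rnorm(30), c = rnorm(30))
  x <- c(1, 1, 0.2)   # duplicated features share value and weight
  sh <- shapley_sampling(mod, x, bg, n_samples = 400, seed = 7)
  # exact expectations differ only through the background means
  ex <- shapley_linear_exact(mod, x, colMeans(bg))
  expect_true(abs((sh$phi[1] - sh$phi[2]) - (ex$phi[1] - ex$phi[2])) <=
                3 * sqrt(sh$se[1]^2 + sh$se[2]^2))
})

test_that("dependent and independent modes agree for uncorrelated backgrounds", {
  set.seed(27)
  W <- matrix(c(2, -1, 0.5, 1, 0.3, -0.7), 3, 2)
  mod <- linear_score_model(W)
  bg <- matrix(rnorm(300), 100, 3)   # empirically near-diagonal covariance
  x <- c(0.8, -0.3, 1.1)
  ind <- shapley_sampling(mod, x, bg, n_samples = 400, seed = 8,
                          dependent = FALSE)
  dep <- shapley_sampling(mod, x, bg, n_samples = 400, seed = 9,
                          dependent = TRUE)
  tol <- 3 * sqrt(ind$se^2 + dep$se^2) + 0.02
  expect_true(all(abs(ind$phi - dep$phi) <= tol))
})

test_that("sampling estimator validates its preconditions", {
  mod <- linear_score_model(matrix(1, 2, 1))
  bg <- matrix(rnorm(30), 15, 2)
  expect_error(shapley_sampling(mod, c(1, 1), bg[1:5, ], n_samples = 200),
               ">= 10")
  expect_error(shapley_sampling(mod, c(1, 1), bg, n_samples = 10), ">= 100")
  expect_error(shapley_sampling(mod, c(1, 1, 1), bg, n_samples = 200),
               "disagree")
})

test_that("class importance maps aggregate absolute values onto atlas parcels", {
  at <- make_toy_atlas(c(12, 12, 12), 6, seed = 2)
  tab <- expand.grid(feature = at$label_table$name, class = c("AD", "NC"),
                     subject_id = c("s1", "s2"), run = 1,
                     stringsAsFactors = FALSE)
  tab$true_class <- ifelse(tab$subject_id == "s1", "AD", "NC")
  tab$phi <- 0
  # subject s1 (true AD): AD-score attribution -2 on ROI01, +1 on ROI02
  tab$phi[tab$true_class == "AD" & tab$class == "AD" &
            tab$feature == "ROI01"] <- -2
  tab$phi[tab$true_class == "AD" & tab$class == "AD" &
            tab$feature == "ROI02"] <- 1
  imp <- class_importance_map(tab, at)
  expect_true(all(imp$values >= 0))
  expect_equal(imp$values["ROI01", "AD"], 2)   # absolute mean
  expect_equal(imp$values["ROI02", "AD"], 1)
  expect_equal(max(imp$maps$NC), 0)            # no NC attribution planted
  expect_equal(unique(imp$maps$AD[at$labels == 1L]), 2)
})
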