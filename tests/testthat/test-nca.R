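test_that("the analytic NCA gradient matches central finite differences", {
  set.seed(14)
  X <- matrix(rnorm(50), 10, 5)
  y <- rep(c("AD", "NC"), 5)
  w <- runif(5, 0.2, 1.5)
  lam <- 0.05
  g <- nca_objective(w, X, y, lam)$gradient
  h <- 1e-5
  g_fd <- vapply(1:5, function(r) {
    wp <- w; wm <- w
    wp[r] <- w[r] + h; wm[r] <- w[r] - h
    (nca_objective(wp, X, y, lam)$value - nca_objective(wm, X, y, lam)$value) /
      (2 * h)
  }, numeric(1))
  expect_lt(max(abs(g - g_fd)) / max(abs(g_fd)), 1e-4)
})

test_that("two subjects of different classes reduce to the closed form", {
  X <- matrix(c(0, 1, 2, 5), 2, 2)
  y <- c("AD", "NC")
  w <- c(0.7, 1.2)
  lam <- 0.3
  ob <- nca_objective(w, X, y, lam)
  expect_equal(ob$value, -lam * sum(w^2))
  expect_equal(ob$gradient, -2 * lam * w)
  expect_error(nca_objective(1, matrix(1, 1, 1), "AD", 0), "2 subjects")
})

test_that("strong regularization drives all weights to zero", {
  set.seed(15)
  X <- matrix(rnorm(60), 20, 3)
  y <- rep(c("AD", "NC"), 10)
  fit <- fit_nca(X, y, lambda = 50)
  expect_lt(max(fit$w), 1e-3)
})

test_that("uninformative and constant features are down-weighted, informative ones kept", {
  set.seed(16)
  n <- 40
  y <- rep(c("AD", "NC"), each = n / 2)
  informative <- ifelse(y == "AD", -1, 1) + rnorm(n, 0, 0.3)
  X <- cbind(inf = as.numeric(scale(informative)),
             noise1 = rnorm(n), noise2 = rnorm(n), flat = rep(0, n))
  fit <- fit_nca(X, y, lambda = 0.01)
  expect_equal(which.max(fit$w), c(inf = 1L))
  expect_lt(fit$w["flat"], 1e-3)
  expect_gte(fit$objective, fit$objective_trace[1])  # optimizer improved
})

test_that("duplicated informative features share the weight symmetrically", {
  set.seed(17)
  n <- 40
  y <- rep(c("AD", "NC"), each = n / 2)
  f <- as.numeric(scale(ifelse(y == "AD", -1, 1) + rnorm(n, 0, 0.3)))
  X <- cbind(a = f, b = f, noise = rnorm(n))
  fit <- fit_nca(X, y, lambda = 0)
  expect_equal(fit$w["a"], fit$w["b"], tolerance = 1e-6, ignore_attr = TRUE)
  expect_gt(min(fit$w[c("a", "b")]), 1)
  # with a small penalty the duplicated pair dominates the noise feature
  fit2 <- fit_nca(X, y, lambda = 0.02)
  expect_equal(fit2$w["a"], fit2$w["b"], tolerance = 1e-6, ignore_attr = TRUE)
  expect_gt(min(fit2$w[c("a", "b")]), fit2$w["noise"])
})

test_that("lambda selection is deterministic and handles degenerate grids", {
  set.seed(18)
  X <- matrix(rnorm(80), 20, 4)
  y <- rep(c("AD", "NC"), 10)
  expect_equal(select_lambda(X, y, 0.5, n_folds = 2)$lambda, 0.5)
  s1 <- select_lambda(X, y, c(0.01, 0.1, 1), n_folds = 3, seed = 4)
  s2 <- select_lambda(X, y, c(0.01, 0.1, 1), n_folds = 3, seed = 4)
  expect_identical(s1, s2)
  expect_error(select_lambda(X, y, numeric()), "empty")
})

test_that("pure-noise data leaves the cross-validated loss near chance", {
  set.seed(19)
  X <- matrix(rnorm(40 * 3), 40, 3)
  y <- rep(c("AD", "NC"), c(24, 16))
  sel <- select_lambda(X, y, c(0.05, 0.5), n_folds = 4, seed = 2)
  chance <- 1 - max(table(y)) / length(y)   # 0.4
  expect_true(all(abs(sel$losses$mean_loss - chance) < 0.25))
})

test_that("selection frequency singles out planted informative features", {
  set.seed(20)
  n <- 48
  y <- rep(c("AD", "DLB", "NC"), each = n / 3)
  mu <- cbind(AD = c(1, 0, 0), DLB = c(0, 1, 0), NC = c(0, 0, 1))
  X <- t(vapply(y, function(cl) mu[, cl] * 2 + rnorm(3, 0, 0.4), numeric(3)))
  X <- cbind(X, matrix(rnorm(n * 3), n, 3))
  dimnames(X) <- list(NULL, c(paste0("inf", 1:3), paste0("noise", 1:3)))
  fm <- feature_matrix(X, y)
  freq <- selection_frequency(fm, split_scheme(8, master_seed = 3),
                              lambda = 0.01)
  expect_true(all(freq$frequency >= 0 & freq$frequency <= 1))
  expect_gt(min(freq$frequency[1:3]), max(freq$frequency[4:6]))
  expect_error(split_scheme(0), "positive integer")
})

test_that("F1 improves with k and k = all features reproduces the full model", {
  set.seed(21)
  n <- 45
  y <- rep(c("AD", "DLB", "NC"), each = n / 3)
  mu <- cbind(AD = c(1, 0, 0), DLB = c(0, 1, 0), NC = c(0, 0, 1))
  X <- t(vapply(y, function(cl) mu[, cl] * 3 + rnorm(3, 0, 0.4), numeric(3)))
  X <- cbind(X, noise = rnorm(n))
  dimnames(X) <- list(NULL, c("inf1", "inf2", "inf3", "noise"))
  fm <- feature_matrix(X, y)
  sch <- split_scheme(15, master_seed = 9)
  ranked <- c("inf1", "inf2", "inf3", "noise")
  res <- f1_vs_topk(fm, ranked, sch)
  full <- evaluate_ensemble(run_ensemble(fm, sch), fm)
  at_full <- res$curve[res$curve$k == 4, ]
  expect_equal(at_full$f1[match(full$per_class$class, at_full$class)],
               full$per_class$f1)
  # mean F1 does not deteriorate as informative features accumulate
  mean_f1 <- tapply(res$curve$f1, res$curve$k, mean)
  expect_true(all(diff(mean_f1[1:3]) >= -0.02))
  expect_message(f1_vs_topk(fm, ranked, sch, k_values = c(2, 9)), "dropping")
})
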