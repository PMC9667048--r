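test_that("log transform maps masked intensities and rejects nonpositive voxels", {
  mask <- make_ellipsoid_mask(c(9, 9, 9))
  v <- pet_volume(array(exp(1), c(9, 9, 9)), c(4, 4, 4), mask)
  expect_equal(log_transform(v), rep(1, sum(mask)))
  v1 <- pet_volume(array(1, c(9, 9, 9)), c(4, 4, 4), mask)
  expect_equal(log_transform(v1), rep(0, sum(mask)))
  bad <- array(1, c(9, 9, 9))
  bad[5, 5, 5] <- 0
  expect_error(log_transform(pet_volume(bad, c(4, 4, 4), mask)), "nonpositive")
})

test_that("double centering matches the hand-computed example and annihilates constants", {
  dc <- double_center(matrix(c(1, 4, 2, 5, 3, 6), 2))
  expect_equal(dc$gmp, c(-1, 0, 1))
  expect_equal(dc$srp, matrix(0, 2, 3), ignore_attr = TRUE)
  const <- double_center(matrix(7, 4, 5))
  expect_equal(const$srp, matrix(0, 4, 5), ignore_attr = TRUE)
  expect_error(double_center(matrix(1, 1, 5)), "2 subjects")
})

test_that("SRP rows and columns sum to zero and permutation is equivariant", {
  set.seed(4)
  L <- matrix(rnorm(15 * 40), 15)
  dc <- double_center(L)
  expect_lt(max(abs(rowSums(dc$srp))), 1e-8 * ncol(L))
  expect_lt(max(abs(colSums(dc$srp))), 1e-8 * nrow(L))
  perm <- sample(15)
  expect_equal(double_center(L[perm, ])$srp, dc$srp[perm, ],
               ignore_attr = TRUE)
})

test_that("SRP is reconstructed from all retained principal components", {
  set.seed(5)
  dc <- double_center(matrix(rnorm(10 * 30, sd = 0.2), 10))
  sv <- svd(dc$srp)
  rec <- sv$u %*% diag(sv$d) %*% t(sv$v)
  expect_lt(max(abs(rec - dc$srp)), 1e-6)
})

test_that("pattern derivation concentrates negative weight on the planted region", {
  topo <- list(AD = class_topography("AD", 2, 0.3, 0), NC = class_topography("NC"))
  spec <- cohort_spec(n_per_class = c(AD = 8, NC = 8), grid_shape = c(12, 12, 12),
                      n_rois = 8, global_scale_sd = 0.1, noise_sd = 0, seed = 17)
  co <- simulate_cohort(spec, topo)
  vols <- lapply(co$volumes, preprocess_volume, fwhm_mm = 0)
  is_ad <- grepl("^AD", names(vols))
  pat <- derive_pattern(vols[is_ad], vols[!is_ad], name = "ADRP")
  mask <- co$atlas$labels > 0
  in_roi <- co$atlas$labels[mask] == 2
  expect_gt(abs(mean(pat$weights[in_roi])), abs(mean(pat$weights[!in_roi])))
  expect_lt(mean(pat$weights[in_roi]), 0)   # hypometabolic -> negative loading
})

test_that("NC derivation scores have Z mean 0 / SD 1 and disease mean Z > 0", {
  co <- fixture_cohort()
  ids <- derivation_ids(co)
  pat <- derive_pattern(co$volumes_pp[ids$AD], co$volumes_pp[ids$NC],
                        name = "ADRP")
  z_nc <- vapply(co$volumes_pp[ids$NC], function(v) tpr_score(v, pat)$z_score,
                 numeric(1))
  expect_equal(mean(z_nc), 0, tolerance = 1e-8)
  expect_equal(sd(z_nc), 1, tolerance = 1e-8)
  z_ad <- vapply(co$volumes_pp[ids$AD], function(v) tpr_score(v, pat)$z_score,
                 numeric(1))
  expect_gt(mean(z_ad), 0)
})

test_that("TPR scoring annihilates constants and is scale invariant", {
  co <- fixture_cohort()
  ids <- derivation_ids(co)
  pat <- derive_pattern(co$volumes_pp[ids$AD], co$volumes_pp[ids$NC],
                        name = "ADRP")
  # a volume whose log vector is gmp + constant scores raw 0
  g <- array(1, dim(pat$mask))
  g[pat$mask] <- exp(pat$gmp + 2)
  s <- tpr_score(pet_volume(g, pat$spacing_mm, pat$mask), pat)
  expect_equal(s$raw_score, 0, tolerance = 1e-10)
  expect_equal(s$z_score, -pat$nc_score_mean / pat$nc_score_sd,
               tolerance = 1e-10)
  # positive global rescaling leaves the score unchanged
  v <- co$volumes_pp[[which(!co$subjects$leakage)[1]]]
  vk <- pet_volume(v$data * 3.7, v$spacing_mm, v$mask)
  expect_equal(tpr_score(vk, pat)$z_score, tpr_score(v, pat)$z_score,
               tolerance = 1e-8)
  # mask mismatch is an alignment error
  other <- random_volume(1, grid = dim(pat$mask), spacing = pat$spacing_mm)
  other$mask[1, 1, 1] <- !other$mask[1, 1, 1]
  expect_error(tpr_score(other, pat), "mask")
})

test_that("held-out disease vs control Z-scores separate well at default effect size", {
  co <- fixture_cohort()
  ids <- derivation_ids(co)
  pat <- derive_pattern(co$volumes_pp[ids$AD], co$volumes_pp[ids$NC],
                        name = "ADRP")
  held <- co$subjects$id[!co$subjects$leakage &
                           co$subjects$class %in% c("AD", "NC")]
  z <- vapply(co$volumes_pp[held], function(v) tpr_score(v, pat)$z_score,
              numeric(1))
  lab <- co$subjects$class[match(held, co$subjects$id)]
  expect_gte(roc_auc_one_vs_all(z, lab, "AD"), 0.95)
})

test_that("pattern feature matrix has one Z column per pattern in list order", {
  co <- fixture_cohort()
  ids <- derivation_ids(co)
  pats <- list(
    derive_pattern(co$volumes_pp[ids$AD], co$volumes_pp[ids$NC], name = "ADRP"),
    derive_pattern(co$volumes_pp[ids$DLB], co$volumes_pp[ids$NC], name = "DLBRP"),
    derive_pattern(co$volumes_pp[ids$FTD], co$volumes_pp[ids$NC], name = "FTDRP"))
  fm <- pattern_feature_matrix(co$volumes_pp, pats, co$subjects)
  expect_equal(dim(fm$values), c(46, 3))
  expect_equal(fm$feature_names, c("ADRP", "DLBRP", "FTDRP"))
  # NC-derivation rows average ~0 in every column by Z construction
  ncd <- fm$values[ids$NC, , drop = FALSE]
  expect_lt(max(abs(colMeans(ncd))), 1e-8)
})

test_that("logistic combination mode also satisfies the sign and Z conventions", {
  co <- fixture_cohort()
  ids <- derivation_ids(co)
  pat <- derive_pattern(co$volumes_pp[ids$DLB], co$volumes_pp[ids$NC],
                        config = pattern_config(mode = "logistic"),
                        name = "DLBRP")
  z_nc <- vapply(co$volumes_pp[ids$NC], function(v) tpr_score(v, pat)$z_score,
                 numeric(1))
  z_d <- vapply(co$volumes_pp[ids$DLB], function(v) tpr_score(v, pat)$z_score,
                numeric(1))
  expect_equal(mean(z_nc), 0, tolerance = 1e-8)
  expect_equal(sd(z_nc), 1, tolerance = 1e-8)
  expect_gt(mean(z_d), 0)
})
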