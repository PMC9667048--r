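# Shared fixtures and independent oracles, built in code at test time.

# One moderate synthetic cohort reused across test files (built lazily once).
fixture_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- cohort_spec(n_per_class = c(AD = 12, DLB = 12, FTD = 10, NC = 12),
                          grid_shape = c(14, 14, 14), n_rois = 8, seed = 7)
      co <- simulate_cohort(spec)
      co$spec <- spec
      co$subjects <- flag_derivation_subjects(
        co$subjects, c(AD = 5, DLB = 5, FTD = 4, NC = 6))
      co$volumes_pp <- lapply(co$volumes, preprocess_volume, fwhm_mm = 10)
      cache <<- co
    }
    cache
  }
})

derivation_ids <- function(co) {
  split(co$subjects$id[co$subjects$leakage],
        co$subjects$class[co$subjects$leakage])
}

random_volume <- function(seed, grid = c(10, 10, 10), spacing = c(4, 4, 4)) {
  mask <- make_ellipsoid_mask(grid)
  dat <- array(0, grid)
  set.seed(seed)
  dat[] <- exp(rnorm(prod(grid), 0, 0.3))
  pet_volume(dat, spacing, mask)
}

# Brute-force AUC: exhaustive pair counting, ties count 1/2.
auc_brute <- function(scores, labels, positive) {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Brute-force Shapley values by exhaustive subset enumeration under the
# marginal (independent-feature) value function.
shapley_brute <- function(score_fun, x, background) {
  d <- length(x)
  v <- function(S) {
    Z <- background
    if (length(S) > 0) Z[, S] <- matrix(x[S], nrow(Z), length(S), byrow = TRUE)
    colMeans(score_fun(Z))
  }
  K <- length(v(integer()))
  phi <- matrix(0, d, K)
  subsets <- lapply(0:(2^d - 1), function(m) which(bitwAnd(m, 2^(0:(d - 1))) > 0))
  for (j in seq_len(d)) {
    for (S in subsets) {
      if (j %in% S) next
      wgt <- factorial(length(S)) * factorial(d - length(S) - 1) / factorial(d)
      phi[j, ] <- phi[j, ] + wgt * (v(c(S, j)) - v(S))
    }
  }
  phi
}
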