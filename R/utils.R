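# Internal helpers shared across modules.

# Canonical class order used for tie-breaking and reporting.
CLASS_ORDER <- c("AD", "DLB", "FTD", "NC")

`%||%` <- function(x, y) if (is.null(x)) y else x

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# One derived 31-bit seed per iteration, reproducible from a master seed.
derive_seeds <- function(master_seed, n) {
  with_seed(master_seed, sample.int(.Machine$integer.max, n, replace = FALSE))
}

# Order class labels canonically (AD < DLB < FTD < NC), unknown labels last.
order_classes <- function(labels) {
  u <- unique(as.character(labels))
  c(intersect(CLASS_ORDER, u), sort(setdiff(u, CLASS_ORDER)))
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 0 && x == round(x)
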