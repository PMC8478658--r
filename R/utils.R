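#' @keywords internal
"_PACKAGE"

# Stop with a call-free, formatted message.
stop2 <- function(...) stop(sprintf(...), call. = FALSE)

warn2 <- function(...) warning(sprintf(...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 1 && x == round(x)

is_scalar <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same samples.
#' Used throughout to score recovery of planted cluster structure.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return A single number in \[-1, 1\]; 1 means identical partitions, values
#'   near 0 are expected for unrelated partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop2("partitions must have equal length")
  tab <- table(a, b)
  n <- sum(tab)
  if (n < 2) return(1)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(0)
  (sum_ij - expected) / (max_idx - expected)
}

# Deterministic per-purpose seed derived from a master seed; kept < 2^31.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483579)
}

# Run expr with a local RNG state seeded deterministically.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Stratified k-fold assignment: returns integer fold id per sample.
# Within each class, samples are shuffled and dealt round-robin so every
# fold sees every class when sizes permit.
stratified_folds <- function(labels, k, seed = 1L) {
  labels <- as.character(labels)
  n <- length(labels)
  if (k < 2 || k > n) stop2("k_folds must be in [2, n]")
  fold <- integer(n)
  with_seed(derive_seed(seed, "folds"), {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

# Column standardization to zero mean / unit SD; constant columns -> 0.
standardize_columns <- function(x) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  scale(x, center = mu, scale = sdv)[, , drop = FALSE]
}
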