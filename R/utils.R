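# internal numerical helpers

# row-wise log-sum-exp of a matrix, stable under large negative log-densities
logsumexp_rows <- function(m) {
  mx <- m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]
  mx + log(rowSums(exp(m - mx)))
}

# evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# derive a stream of reproducible child seeds (kept below 2^31)
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# all permutations of 1..k (k small; used for component label matching)
all_permutations <- function(k) {
  if (k == 1L) return(list(1L))
  out <- list()
  for (perm in all_permutations(k - 1L)) {
    for (pos in seq_len(k)) {
      out[[length(out) + 1L]] <- append(perm, k, after = pos - 1L)
    }
  }
  out
}

#' Match fitted components to reference components
#'
#' Finds the permutation of fitted component indices minimising the total
#' Euclidean distance between fitted and reference component mean vectors
#' (exhaustive search over permutations; intended for small K). Useful for
#' parameter-recovery experiments where component labels are arbitrary.
#'
#' @param reference numeric matrix, one row per reference component.
#' @param fitted numeric matrix with the same dimensions, one row per fitted
#'   component.
#' @return An integer vector `p` such that `fitted[p[k], ]` corresponds to
#'   `reference[k, ]`.
#' @export
match_components <- function(reference, fitted) {
  stopifnot(is.matrix(reference), is.matrix(fitted),
            all(dim(reference) == dim(fitted)))
  k <- nrow(reference)
  if (k > 8L) stop("exhaustive matching supported for K <= 8 only")
  best <- NULL
  best_cost <- Inf
  for (perm in all_permutations(k)) {
    p <- unlist(perm)
    cost <- sum((reference - fitted[p, , drop = FALSE])^2)
    if (cost < best_cost) {
      best_cost <- cost
      best <- p
    }
  }
  best
}

#' Wilson score confidence interval for a binomial proportion
#'
#' @param x number of successes.
#' @param n number of trials.
#' @param conf confidence level (default 0.95).
#' @return Named numeric vector `c(lower, upper)` on the proportion scale.
#' @export
wilson_ci <- function(x, n, conf = 0.95) {
  stopifnot(n >= 1, x >= 0, x <= n)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}
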