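# Monti consensus clustering: repeated subsampling, re-clustering, and
# accumulation of the pairwise co-clustering fraction
#   C(i, j) = sum_t M_t(i, j) / sum_t I_t(i, j)
# where I_t flags pairs co-sampled in iteration t and M_t flags pairs
# co-assigned by that iteration's clustering.

#' Consensus matrix by repeated subsampling
#'
#' For each of `T` iterations, draws a subsample of `floor(a * n)` patients
#' (without replacement by default), fits the K-component mixture on the
#' subsample, and accumulates the pair co-sampling indicator and the pair
#' co-assignment indicator. Entries never co-sampled are `NaN` (undefined),
#' not 0. Per-iteration seeds are derived from the master seed, so runs are
#' reproducible. An iteration whose fit fails is retried once with a fresh
#' seed, then skipped with a warning (`T_effective` reports the iterations
#' actually used).
#'
#' @param enc a `psa_encoded` data object.
#' @param K number of mixture components per iteration.
#' @param T number of subsampling iterations (default 200).
#' @param a sampling fraction in (0, 1] (default 0.80).
#' @param seed master seed.
#' @param n_restarts EM restarts per iteration (default 3: reduced relative
#'   to a full fit, for tractability).
#' @param replace sample with replacement instead of without (default
#'   `FALSE`; with-replacement duplicates are collapsed to unique patients
#'   before pair accounting).
#' @param ... further arguments to [fit_em()].
#' @return A `psa_consensus`: list with `C` (n x n consensus fractions,
#'   `NaN` where undefined), `n_pairs` (co-sampling counts), `T`,
#'   `T_effective`, `a`, `seed`, `patient_id`.
#' @export
consensus_matrix <- function(enc, K, T = 200L, a = 0.80, seed = NULL,
                             n_restarts = 3L, replace = FALSE, ...) {
  stopifnot(inherits(enc, "psa_encoded"))
  if (!(a > 0 && a <= 1)) stop("sampling fraction a must be in (0, 1]")
  n <- length(enc$patient_id)
  n_sub <- max(K, floor(a * n))
  if (n_sub > n) stop("subsample larger than cohort")
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max - 1L, 1)
  seeds <- derive_seeds(seed, 2L * T)

  M <- matrix(0, n, n)
  I <- matrix(0, n, n)
  t_eff <- 0L
  subset_enc <- function(idx) {
    structure(list(
      x_cont = enc$x_cont[idx, , drop = FALSE],
      x_cat = enc$x_cat[idx, , drop = FALSE],
      cat_levels = enc$cat_levels,
      patient_id = enc$patient_id[idx],
      groups = enc$groups), class = "psa_encoded")
  }
  for (t in seq_len(T)) {
    st <- seeds[t]
    idx <- with_seed(st, sort(unique(sample.int(n, n_sub, replace = replace))))
    sub <- subset_enc(idx)
    fit <- tryCatch(
      suppressWarnings(fit_em(sub, K, n_restarts = n_restarts, seed = st, ...)),
      error = function(e) NULL)
    if (is.null(fit)) {
      st2 <- seeds[T + t]
      idx <- with_seed(st2, sort(unique(sample.int(n, n_sub, replace = replace))))
      sub <- subset_enc(idx)
      fit <- tryCatch(
        suppressWarnings(fit_em(sub, K, n_restarts = n_restarts, seed = st2, ...)),
        error = function(e) NULL)
    }
    if (is.null(fit)) {
      warning("consensus iteration ", t, " failed twice; skipped", call. = FALSE)
      next
    }
    lab <- assign_clusters(fit)
    Z <- matrix(0, length(idx), K)
    Z[cbind(seq_along(idx), lab)] <- 1
    M[idx, idx] <- M[idx, idx] + tcrossprod(Z)
    I[idx, idx] <- I[idx, idx] + 1
    t_eff <- t_eff + 1L
  }
  C <- M / I                 # 0/0 -> NaN marks never-co-sampled pairs
  structure(list(C = C, n_pairs = I, T = T, T_effective = t_eff, a = a,
                 seed = seed, patient_id = enc$patient_id),
            class = "psa_consensus")
}

#' @export
print.psa_consensus <- function(x, ...) {
  def <- is.finite(x$C[upper.tri(x$C)])
  cat(sprintf("Consensus matrix: %d patients, T = %d (effective %d), a = %.2f\n",
              length(x$patient_id), x$T, x$T_effective, x$a))
  cat(sprintf("  defined off-diagonal pairs: %.1f%%; mean consensus %.3f\n",
              100 * mean(def), mean(x$C[upper.tri(x$C)][def])))
  invisible(x)
}

#' Summarise clustering stability from a consensus matrix
#'
#' Computes the mean consensus over defined same-cluster pairs (per
#' cluster), the mean over defined different-cluster pairs, and a display
#' ordering of patients: by cluster label, then by descending mean
#' consensus with same-cluster peers. Singleton clusters have an undefined
#' within-cluster mean (`NA`, flagged).
#'
#' @param cons a `psa_consensus`.
#' @param labels integer cluster assignment covering every patient in the
#'   matrix.
#' @return A `psa_stability`: list with `within` (per-cluster mean
#'   consensus), `between` (overall between-cluster mean), `ordering`
#'   (permutation of patient indices), `labels`.
#' @export
stability_summary <- function(cons, labels) {
  stopifnot(inherits(cons, "psa_consensus"))
  n <- length(cons$patient_id)
  if (length(labels) != n) stop("labels must cover all patients in the matrix")
  C <- cons$C
  ut <- upper.tri(C)
  same <- outer(labels, labels, "==")
  def <- is.finite(C)
  clusters <- sort(unique(labels))
  within <- vapply(clusters, function(k) {
    sel <- ut & def & same & outer(labels == k, labels == k, "&")
    if (!any(sel)) NA_real_ else mean(C[sel])
  }, numeric(1))
  names(within) <- as.character(clusters)
  bet_sel <- ut & def & !same
  between <- if (any(bet_sel)) mean(C[bet_sel]) else NA_real_
  # per-patient mean consensus with same-cluster peers (defined entries)
  own <- vapply(seq_len(n), function(i) {
    peers <- which(labels == labels[i] & seq_len(n) != i)
    vals <- C[i, peers]
    vals <- vals[is.finite(vals)]
    if (!length(vals)) 0 else mean(vals)
  }, numeric(1))
  ordering <- order(labels, -own)
  structure(list(within = within, between = between, ordering = ordering,
                 labels = labels), class = "psa_stability")
}

#' @export
print.psa_stability <- function(x, ...) {
  cat("Cluster stability (mean consensus):\n")
  for (k in names(x$within)) {
    cat(sprintf("  cluster %s: within = %s\n", k,
                if (is.na(x$within[[k]])) "undefined (singleton)" else
                  sprintf("%.3f", x$within[[k]])))
  }
  cat(sprintf("  between clusters: %.3f\n", x$between))
  invisible(x)
}
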