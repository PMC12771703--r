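# Finite mixture model for mixed-type baseline data.
#
# Component density: conditional independence within a component — diagonal
# Gaussian for continuous features, independent multinomial (Bernoulli for
# two levels) for categorical features. The observed-data likelihood is
# h(y | phi) = sum_k pi_k f_k(y | theta_k), maximised by EM.

#' Construct mixture parameters
#'
#' @param weights numeric vector of K mixing proportions (must sum to 1).
#' @param mu K x p_cont matrix of component means for continuous features.
#' @param sigma2 K x p_cont matrix of component variances (> 0).
#' @param cat_probs named list, one K x L probability matrix per categorical
#'   feature (rows sum to 1).
#' @return A `psa_mixparams` object.
#' @export
mixture_params <- function(weights, mu = NULL, sigma2 = NULL, cat_probs = list()) {
  K <- length(weights)
  stopifnot(K >= 1, all(weights > 0), abs(sum(weights) - 1) < 1e-10)
  if (is.null(mu)) mu <- matrix(numeric(0), nrow = K, ncol = 0)
  if (is.null(sigma2)) sigma2 <- matrix(numeric(0), nrow = K, ncol = 0)
  stopifnot(is.matrix(mu), is.matrix(sigma2), nrow(mu) == K, nrow(sigma2) == K,
            ncol(mu) == ncol(sigma2), all(sigma2 > 0))
  for (p in cat_probs) {
    stopifnot(is.matrix(p), nrow(p) == K, all(p >= 0),
              all(abs(rowSums(p) - 1) < 1e-10))
  }
  structure(list(K = K, weights = weights, mu = mu, sigma2 = sigma2,
                 cat_probs = cat_probs),
            class = "psa_mixparams")
}

# n x K matrix of per-component log joint densities log(pi_k) + log f_k(y_i)
component_logdens <- function(enc, params) {
  n <- length(enc$patient_id)
  K <- params$K
  pc <- ncol(enc$x_cont)
  pd <- ncol(enc$x_cat)
  ll <- matrix(0, n, K)
  for (k in seq_len(K)) {
    s <- rep(log(params$weights[k]), n)
    if (pc) {
      for (j in seq_len(pc)) {
        s <- s + stats::dnorm(enc$x_cont[, j], params$mu[k, j],
                              sqrt(params$sigma2[k, j]), log = TRUE)
      }
    }
    if (pd) {
      for (j in seq_len(pd)) {
        s <- s + log(params$cat_probs[[j]][k, enc$x_cat[, j]])
      }
    }
    ll[, k] <- s
  }
  ll
}

#' E step: posterior component memberships
#'
#' Computes responsibilities r(i,k) proportional to pi_k f_k(y_i | theta_k)
#' (rows normalised) and the total observed-data log-likelihood via
#' log-sum-exp.
#'
#' @param enc a `psa_encoded` data object.
#' @param params a `psa_mixparams`.
#' @return List with `resp` (n x K matrix, rows sum to 1) and `loglik`.
#' @export
e_step <- function(enc, params) {
  ll <- component_logdens(enc, params)
  lse <- logsumexp_rows(ll)
  if (any(!is.finite(lse))) {
    stop("zero total density (numeric underflow) for row(s): ",
         paste(utils::head(which(!is.finite(lse)), 5), collapse = ", "))
  }
  resp <- exp(ll - lse)
  list(resp = resp, loglik = sum(lse))
}

#' M step: maximise the expected complete-data log-likelihood
#'
#' Weights become mean responsibilities; continuous parameters are
#' responsibility-weighted means and variances (variance floored);
#' categorical probabilities are responsibility-weighted level frequencies
#' with Laplace smoothing `alpha`.
#'
#' @param enc a `psa_encoded` data object.
#' @param resp n x K responsibility matrix with rows summing to 1.
#' @param var_floor per-feature variance floor (numeric vector, one per
#'   continuous feature); defaults to `1e-4` times each feature's pooled
#'   variance.
#' @param alpha Laplace smoothing count for categorical probabilities
#'   (default 0.5; 0 disables smoothing).
#' @return A `psa_mixparams`.
#' @export
m_step <- function(enc, resp, var_floor = NULL, alpha = 0.5) {
  n <- nrow(resp)
  K <- ncol(resp)
  pc <- ncol(enc$x_cont)
  pd <- ncol(enc$x_cat)
  if (is.null(var_floor)) {
    var_floor <- if (pc) 1e-4 * apply(enc$x_cont, 2, stats::var) else numeric(0)
    var_floor[!is.finite(var_floor) | var_floor <= 0] <- 1e-8
  }
  Nk <- colSums(resp)
  weights <- Nk / n
  mu <- matrix(0, K, pc)
  sigma2 <- matrix(1, K, pc)
  if (pc) {
    mu <- t(resp) %*% enc$x_cont / Nk
    for (j in seq_len(pc)) {
      d2 <- (matrix(enc$x_cont[, j], n, K) - matrix(mu[, j], n, K, byrow = TRUE))^2
      sigma2[, j] <- pmax(colSums(resp * d2) / Nk, var_floor[j])
    }
    colnames(mu) <- colnames(sigma2) <- colnames(enc$x_cont)
  }
  cat_probs <- list()
  if (pd) {
    for (j in seq_len(pd)) {
      L <- length(enc$cat_levels[[j]])
      cnt <- matrix(0, K, L)
      for (l in seq_len(L)) {
        sel <- enc$x_cat[, j] == l
        cnt[, l] <- if (any(sel)) colSums(resp[sel, , drop = FALSE]) else 0
      }
      p <- (cnt + alpha) / (Nk + alpha * L)
      cat_probs[[colnames(enc$x_cat)[j]]] <- p / rowSums(p)
    }
  }
  mixture_params(weights, mu, sigma2, cat_probs)
}

# initial responsibilities, blended with Dirichlet noise. Restarts cycle
# four styles so the search covers basins separated along either feature
# type: "mixed" = k-means on standardised continuous features plus one-hot
# categorical indicators; "cat" = k-means on the one-hot indicators alone
# (components that differ mainly in categorical profile); "subspace" =
# k-means on the mixed design with random exponential column weights, so
# each such restart emphasises a different feature subset; "random" = a
# uniform random hard partition. k-means failures fall back to random.
init_resp <- function(enc, K, style = c("mixed", "cat", "subspace", "random")) {
  style <- match.arg(style)
  n <- length(enc$patient_id)
  pc <- ncol(enc$x_cont)
  pd <- ncol(enc$x_cat)
  blocks <- list()
  if (pc && style %in% c("mixed", "subspace")) {
    xs <- scale(enc$x_cont)
    xs[, apply(enc$x_cont, 2, stats::sd) == 0] <- 0
    blocks$cont <- xs
  }
  if (pd && style != "random") {
    oh <- lapply(seq_len(pd), function(j) {
      L <- length(enc$cat_levels[[j]])
      m <- matrix(0, n, L)
      m[cbind(seq_len(n), enc$x_cat[, j])] <- 1
      m
    })
    blocks$cat <- do.call(cbind, oh)
  }
  hard_lab <- NULL
  if (length(blocks) && style != "random") {
    design <- do.call(cbind, blocks)
    if (style == "subspace") {
      design <- sweep(design, 2, stats::rexp(ncol(design)), "*")
    }
    hard_lab <- tryCatch(
      stats::kmeans(design, centers = K, nstart = 2, iter.max = 50)$cluster,
      error = function(e) NULL)
  }
  if (is.null(hard_lab)) hard_lab <- sample.int(K, n, replace = TRUE)
  hard <- matrix(0, n, K)
  hard[cbind(seq_len(n), hard_lab)] <- 1
  g <- matrix(stats::rgamma(n * K, shape = 0.5), n, K)
  dir <- g / rowSums(g)
  resp <- 0.85 * hard + 0.15 * dir
  resp / rowSums(resp)
}

# rescue components whose total responsibility has collapsed: reassign the
# point with the weakest best membership wholly to the empty component
rescue_empty <- function(resp, eps_frac = 1e-6) {
  n <- nrow(resp)
  Nk <- colSums(resp)
  for (k in which(Nk < eps_frac * n)) {
    i <- which.min(resp[cbind(seq_len(n), max.col(resp, ties.method = "first"))])
    resp[i, ] <- 0
    resp[i, k] <- 1
  }
  resp
}

n_free_params <- function(enc, K) {
  pc <- ncol(enc$x_cont)
  Ls <- vapply(enc$cat_levels, length, integer(1))
  (K - 1L) + K * (2L * pc + sum(Ls - 1L))
}

#' Fit the mixture model by EM with random restarts
#'
#' Alternates [e_step()] and [m_step()] until the relative change in
#' log-likelihood drops below `tol`, independently from `n_restarts`
#' initialisations, and returns the restart with the highest final
#' log-likelihood. The per-restart log-likelihood trace is nondecreasing
#' (EM monotonicity).
#'
#' @param enc a `psa_encoded` data object.
#' @param K number of components (rows must be >= K).
#' @param tol relative log-likelihood convergence tolerance (default 1e-6).
#' @param max_iter maximum EM iterations per restart (default 500).
#' @param n_restarts number of random restarts (default 10).
#' @param seed integer seed; restarts use derived sub-seeds.
#' @param alpha Laplace smoothing for categorical probabilities.
#' @return A `psa_fit`: list with `params`, `resp`, `loglik`,
#'   `loglik_trace`, `converged`, `n_iter`, `n_free_params`, `bic`, `n`,
#'   `K`, `seed`.
#' @export
fit_em <- function(enc, K, tol = 1e-6, max_iter = 500L, n_restarts = 10L,
                   seed = NULL, alpha = 0.5) {
  stopifnot(inherits(enc, "psa_encoded"), K >= 1)
  n <- length(enc$patient_id)
  if (n < K) stop("need at least K rows (n = ", n, ", K = ", K, ")")
  pc <- ncol(enc$x_cont)
  var_floor <- if (pc) {
    vf <- 1e-4 * apply(enc$x_cont, 2, stats::var)
    vf[!is.finite(vf) | vf <= 0] <- 1e-8
    vf
  } else numeric(0)

  if (is.null(seed)) seed <- sample.int(.Machine$integer.max - 1L, 1)
  sub_seeds <- derive_seeds(seed, n_restarts)

  styles <- c("mixed", "cat", "subspace", "random", "subspace", "random")
  run_one <- function(rs, style) {
    with_seed(rs, {
      resp <- init_resp(enc, K, style)
      trace <- numeric(0)
      params <- m_step(enc, resp, var_floor, alpha)
      converged <- FALSE
      prev <- -Inf
      it <- 0L
      while (it < max_iter) {
        it <- it + 1L
        es <- e_step(enc, params)
        trace <- c(trace, es$loglik)
        resp <- rescue_empty(es$resp)
        params <- m_step(enc, resp, var_floor, alpha)
        if (is.finite(prev) &&
            abs(es$loglik - prev) <= tol * (abs(prev) + 1e-12)) {
          converged <- TRUE
          break
        }
        prev <- es$loglik
      }
      final <- e_step(enc, params)
      list(params = params, resp = final$resp, loglik = final$loglik,
           trace = c(trace, final$loglik), converged = converged, n_iter = it)
    })
  }

  best <- NULL
  for (r in seq_len(n_restarts)) {
    cand <- run_one(sub_seeds[r], styles[(r - 1L) %% length(styles) + 1L])
    if (is.null(best) || cand$loglik > best$loglik) best <- cand
  }
  if (!best$converged) {
    warning("EM did not converge in any restart; returning best restart",
            call. = FALSE)
  }
  p_free <- n_free_params(enc, K)
  structure(list(params = best$params, resp = best$resp, loglik = best$loglik,
                 loglik_trace = best$trace, converged = best$converged,
                 n_iter = best$n_iter, n_free_params = p_free,
                 bic = -2 * best$loglik + p_free * log(n),
                 n = n, K = K, seed = seed),
            class = "psa_fit")
}

#' Bayesian Information Criterion of a mixture fit
#'
#' BIC = -2 * loglik + p * log(n), where p counts the free parameters:
#' (K - 1) mixing weights plus, per component, a mean and variance for each
#' continuous feature and (levels - 1) probabilities per categorical
#' feature. Lower is better.
#'
#' @param object a `psa_fit`.
#' @param ... ignored.
#' @return Numeric BIC score.
#' @export
BIC.psa_fit <- function(object, ...) {
  if (object$n <= 1) stop("BIC undefined for n <= 1")
  -2 * object$loglik + object$n_free_params * log(object$n)
}

#' @export
logLik.psa_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_free_params, nobs = object$n,
            class = "logLik")
}

#' @export
print.psa_fit <- function(x, ...) {
  cat(sprintf("Mixture fit: K = %d, n = %d, loglik = %.2f, BIC = %.1f (%s, %d iter)\n",
              x$K, x$n, x$loglik, x$bic,
              if (x$converged) "converged" else "not converged", x$n_iter))
  cat("  weights:", paste(sprintf("%.3f", sort(x$params$weights, decreasing = TRUE)),
                          collapse = ", "), "\n")
  invisible(x)
}

#' Hard cluster assignment from a fitted mixture
#'
#' Assigns each patient to the component with the largest posterior
#' responsibility; ties break toward the lower component index.
#'
#' @param fit a `psa_fit`.
#' @return Integer vector of component labels in 1..K, named by patient id.
#' @export
assign_clusters <- function(fit) {
  stopifnot(inherits(fit, "psa_fit"))
  lab <- max.col(fit$resp, ties.method = "first")
  names(lab) <- rownames(fit$resp)
  lab
}

#' Select the number of components by a BIC elbow rule over a grid
#'
#' Fits the mixture for every K on the grid (shared restart protocol, per-K
#' derived seeds) and applies the elbow rule: the selected K is the smallest
#' grid value whose next BIC decrease falls below `tau` times the first
#' decrease on the grid; if the global BIC minimiser is interior to the grid
#' and smaller than the elbow K, it is preferred. If BIC does not decrease
#' from the first step at all, the grid minimum is returned with a
#' `no_elbow` flag.
#'
#' @param enc a `psa_encoded` data object.
#' @param grid integer vector of candidate K values (default 2:10).
#' @param tau relative-gain threshold for the elbow (default 0.10).
#' @param n_restarts EM restarts per K (default 10).
#' @param seed master seed; each K gets a derived sub-seed.
#' @param ... further arguments passed to [fit_em()].
#' @return A `psa_kselect`: list with `grid`, `bic`, `loglik`, `selected_K`,
#'   `no_elbow`, `decreases`, `ratios`, and `fit` (the fit at the selected
#'   K).
#' @export
select_k <- function(enc, grid = 2:10, tau = 0.10, n_restarts = 10L,
                     seed = NULL, ...) {
  grid <- as.integer(grid)
  stopifnot(length(grid) >= 2L, all(diff(grid) > 0))
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max - 1L, 1)
  seeds <- derive_seeds(seed, length(grid))
  fits <- vector("list", length(grid))
  bics <- numeric(length(grid))
  lls <- numeric(length(grid))
  for (i in seq_along(grid)) {
    fits[[i]] <- fit_em(enc, grid[i], n_restarts = n_restarts,
                        seed = seeds[i], ...)
    bics[i] <- fits[[i]]$bic
    lls[i] <- fits[[i]]$loglik
  }
  dec <- -diff(bics)                       # positive = BIC decreased
  ratios <- if (dec[1] > 0) dec / dec[1] else rep(NA_real_, length(dec))
  no_elbow <- dec[1] <= 0
  if (no_elbow) {
    sel_i <- 1L
  } else {
    below <- which(dec < tau * dec[1])
    sel_i <- if (length(below)) below[1] else length(grid)
    gmin <- which.min(bics)
    if (gmin > 1L && gmin < length(grid) && gmin < sel_i) sel_i <- gmin
  }
  structure(list(grid = grid, bic = bics, loglik = lls,
                 selected_K = grid[sel_i], no_elbow = no_elbow,
                 decreases = dec, ratios = ratios, tau = tau,
                 fit = fits[[sel_i]], seed = seed),
            class = "psa_kselect")
}

#' @export
print.psa_kselect <- function(x, ...) {
  cat("BIC grid search (tau =", x$tau, ")\n")
  tab <- data.frame(K = x$grid, BIC = round(x$bic, 1))
  print(tab, row.names = FALSE)
  cat("selected K =", x$selected_K,
      if (x$no_elbow) "(no elbow: BIC nondecreasing from first step)" else "", "\n")
  invisible(x)
}
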