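make_encoded <- function(x_cont = NULL, x_cat = NULL, cat_levels = list()) {
  n <- if (!is.null(x_cont)) nrow(x_cont) else nrow(x_cat)
  if (is.null(x_cont)) x_cont <- matrix(numeric(0), nrow = n, ncol = 0)
  if (is.null(x_cat)) x_cat <- matrix(integer(0), nrow = n, ncol = 0)
  structure(list(x_cont = x_cont, x_cat = x_cat, cat_levels = cat_levels,
                 patient_id = sprintf("P%03d", seq_len(n)),
                 groups = character(0)), class = "psa_encoded")
}

test_that("E step reproduces Bayes-rule posteriors", {
  # single component: responsibilities are exactly one
  enc <- make_encoded(x_cont = matrix(rnorm(10), ncol = 1,
                                      dimnames = list(NULL, "x")))
  p1 <- mixture_params(1, mu = matrix(0, 1, 1), sigma2 = matrix(1, 1, 1))
  es <- e_step(enc, p1)
  expect_equal(es$resp, matrix(1, 10, 1))

  # symmetric two-component mixture, equidistant point -> (0.5, 0.5)
  enc0 <- make_encoded(x_cont = matrix(0, 1, 1, dimnames = list(NULL, "x")))
  p2 <- mixture_params(c(0.5, 0.5), mu = matrix(c(-1, 1), 2, 1),
                       sigma2 = matrix(1, 2, 1))
  expect_equal(e_step(enc0, p2)$resp[1, ], c(0.5, 0.5))

  # hand-specified parameters against a direct Bayes computation
  y <- 1.3
  pi_k <- c(0.3, 0.7); mu_k <- c(0, 2); var_k <- c(1, 4)
  ency <- make_encoded(x_cont = matrix(y, 1, 1, dimnames = list(NULL, "x")))
  p <- mixture_params(pi_k, mu = matrix(mu_k, 2, 1),
                      sigma2 = matrix(var_k, 2, 1))
  es <- e_step(ency, p)
  joint <- pi_k * dnorm(y, mu_k, sqrt(var_k))
  expect_equal(es$resp[1, ], joint / sum(joint), tolerance = 1e-12)
  expect_equal(es$loglik, log(sum(joint)), tolerance = 1e-12)
})

test_that("M step equals direct weighted-moment computation", {
  set.seed(42)
  n <- 5
  xc <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("a", "b")))
  xcat <- matrix(sample(1:3, n, replace = TRUE), n, 1,
                 dimnames = list(NULL, "g"))
  enc <- make_encoded(xc, xcat, cat_levels = list(g = c("x", "y", "z")))
  resp <- matrix(rgamma(n * 2, 1), n, 2)
  resp <- resp / rowSums(resp)
  params <- m_step(enc, resp, alpha = 0)

  Nk <- colSums(resp)
  expect_equal(params$weights, Nk / n, tolerance = 1e-12)
  for (k in 1:2) {
    for (j in 1:2) {
      mu_kj <- unname(sum(resp[, k] * xc[, j]) / Nk[k])
      expect_equal(unname(params$mu[k, j]), mu_kj, tolerance = 1e-12)
      expect_equal(unname(params$sigma2[k, j]),
                   unname(sum(resp[, k] * (xc[, j] - mu_kj)^2) / Nk[k]),
                   tolerance = 1e-10)
    }
    for (l in 1:3) {
      expect_equal(unname(params$cat_probs$g[k, l]),
                   unname(sum(resp[xcat[, 1] == l, k]) / Nk[k]),
                   tolerance = 1e-12)
    }
  }

  # hard 0/1 responsibilities reduce to per-group sample statistics
  hard <- matrix(0, n, 2); hard[cbind(1:n, c(1, 1, 2, 2, 2))] <- 1
  ph <- m_step(enc, hard, alpha = 0)
  expect_equal(unname(ph$mu[1, "a"]), mean(xc[1:2, "a"]))
  expect_equal(unname(ph$mu[2, "b"]), mean(xc[3:5, "b"]))
})

test_that("K = 1 fit equals closed-form sample statistics", {
  set.seed(1)
  xc <- matrix(rnorm(60, 5, 2), ncol = 1, dimnames = list(NULL, "x"))
  xcat <- matrix(sample(1:2, 60, replace = TRUE), ncol = 1,
                 dimnames = list(NULL, "b"))
  enc <- make_encoded(xc, xcat, cat_levels = list(b = c("no", "yes")))
  fit <- fit_em(enc, 1, n_restarts = 1, seed = 9, alpha = 0)
  expect_equal(fit$params$weights, 1)
  expect_equal(unname(fit$params$mu[1, 1]), mean(xc), tolerance = 1e-10)
  expect_equal(unname(fit$params$sigma2[1, 1]), mean((xc - mean(xc))^2),
               tolerance = 1e-10)
  expect_equal(fit$params$cat_probs$b[1, ],
               as.numeric(table(factor(xcat, 1:2)) / 60), tolerance = 1e-10)
})

test_that("EM recovers two separated Gaussian groups", {
  set.seed(4)
  g1 <- rnorm(100, 0, 1); g2 <- rnorm(100, 10, 1)
  enc <- make_encoded(matrix(c(g1, g2), ncol = 1,
                             dimnames = list(NULL, "x")))
  fit <- fit_em(enc, 2, n_restarts = 4, seed = 5)
  mu <- sort(fit$params$mu[, 1])
  expect_lt(abs(mu[1] - mean(g1)), 0.5)
  expect_lt(abs(mu[2] - mean(g2)), 0.5)
  expect_lt(max(abs(fit$params$weights - 0.5)), 0.05)
  expect_true(fit$converged)
  # per-restart trace is nondecreasing
  expect_true(all(diff(fit$loglik_trace) >= -1e-8))
})

test_that("BIC counts free parameters as the model family dictates", {
  set.seed(8)
  enc1 <- make_encoded(matrix(rnorm(100), ncol = 1,
                              dimnames = list(NULL, "x")))
  f1 <- fit_em(enc1, 1, n_restarts = 1, seed = 1)
  # K = 1, one continuous feature: p = 2
  expect_equal(f1$n_free_params, 2)
  expect_equal(BIC(f1), -2 * f1$loglik + 2 * log(100))
  expect_equal(f1$bic, BIC(f1))

  # 2 components, 1 continuous + 1 three-level categorical: p = 9
  enc2 <- make_encoded(matrix(rnorm(30), ncol = 1, dimnames = list(NULL, "x")),
                       matrix(sample(1:3, 30, TRUE), ncol = 1,
                              dimnames = list(NULL, "g")),
                       cat_levels = list(g = c("a", "b", "c")))
  f2 <- fit_em(enc2, 2, n_restarts = 2, seed = 2)
  expect_equal(f2$n_free_params, 9)

  # penalty monotonicity at equal likelihood
  expect_gt(-2 * f1$loglik + 5 * log(100), -2 * f1$loglik + 2 * log(100))
})

test_that("likelihood and BIC are invariant to component relabeling", {
  set.seed(10)
  enc <- blob_encoded(25, sep = 6)
  fit <- fit_em(enc, 2, n_restarts = 2, seed = 3)
  p <- fit$params
  swapped <- mixture_params(p$weights[2:1], p$mu[2:1, , drop = FALSE],
                            p$sigma2[2:1, , drop = FALSE])
  expect_equal(e_step(enc, swapped)$loglik, e_step(enc, p)$loglik,
               tolerance = 1e-10)
})

test_that("cluster assignment takes the argmax with lower-index ties", {
  fit <- structure(list(resp = rbind(c(0.9, 0.1), c(0.5, 0.5), c(0.2, 0.8))),
                   class = "psa_fit")
  lab <- assign_clusters(fit)
  expect_equal(unname(lab), c(1L, 1L, 2L))
  # labels partition the patients
  expect_equal(sum(table(lab)), 3)
})

test_that("affine rescaling of a feature transforms the fit equivariantly", {
  set.seed(12)
  enc <- blob_encoded(40, sep = 8)
  fit <- fit_em(enc, 2, n_restarts = 3, seed = 6)
  enc2 <- enc
  a <- 3.5; b <- -20
  enc2$x_cont <- enc$x_cont * a + b
  fit2 <- fit_em(enc2, 2, n_restarts = 3, seed = 6)
  o1 <- order(fit$params$mu[, 1]); o2 <- order(fit2$params$mu[, 1])
  expect_equal(fit2$params$mu[o2, 1], a * fit$params$mu[o1, 1] + b,
               tolerance = 1e-2)
  expect_equal(fit2$params$sigma2[o2, 1], a^2 * fit$params$sigma2[o1, 1],
               tolerance = 1e-2)
  # the induced partition is unchanged (up to label permutation)
  l1 <- assign_clusters(fit); l2 <- assign_clusters(fit2)
  expect_true(all(table(l1, l2)[o1, o2][cbind(1:2, 1:2)] ==
                    as.numeric(table(l1)[o1])))
})

test_that("fitted continuous mixture agrees with an independent GMM fit", {
  library(mclust)
  set.seed(14)
  x <- c(rnorm(120, 0, 1), rnorm(80, 6, 1.5))
  enc <- make_encoded(matrix(x, ncol = 1, dimnames = list(NULL, "x")))
  fit <- fit_em(enc, 2, n_restarts = 5, seed = 7, tol = 1e-9)
  mc <- Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(fit$params$mu[, 1]), sort(as.numeric(mc$parameters$mean)),
               tolerance = 0.05)
  expect_equal(fit$loglik, mc$loglik, tolerance = 1e-3)
})

test_that("select_k finds an elbow on structured data and flags its absence", {
  set.seed(16)
  enc <- blob_encoded(60, sep = 12)
  ks <- select_k(enc, grid = 2:5, n_restarts = 3, seed = 8)
  expect_equal(ks$selected_K, 2)
  expect_s3_class(ks, "psa_kselect")
  expect_equal(ks$grid, 2:5)

  # one homogeneous blob: BIC nondecreasing from the first step
  enc1 <- make_encoded(matrix(rnorm(150), ncol = 1,
                              dimnames = list(NULL, "x")))
  ks1 <- select_k(enc1, grid = 2:4, n_restarts = 2, seed = 9)
  if (ks1$no_elbow) expect_equal(ks1$selected_K, 2)
  expect_true(ks1$selected_K %in% 2:3)  # no spurious fine structure
})

test_that("mixture parameter recovery on the default phenotype generator", {
  gb <- generate_baseline(2500, seed = 21)
  enc <- encode_features(gb$cohort)
  fit <- fit_em(enc, 5, n_restarts = 6, seed = 21)
  cfg <- default_generator_config()
  # match fitted components to the truth by their continuous mean profiles
  truth_mu <- cbind(cfg$continuous$tjc$mean, cfg$continuous$sjc$mean,
                    cfg$continuous$pain$mean)
  fitted_mu <- fit$params$mu[, c("tjc", "sjc", "pain")]
  perm <- match_components(truth_mu, fitted_mu)
  expect_lt(max(abs(fit$params$weights[perm] - cfg$weights)), 0.04)
  for (j in 1:3) {
    sds <- list(cfg$continuous$tjc$sd, cfg$continuous$sjc$sd,
                cfg$continuous$pain$sd)[[j]]
    expect_true(all(abs(fitted_mu[perm, j] - truth_mu[, j]) < 0.5 * sds))
  }
})
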