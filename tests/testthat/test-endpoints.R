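test_that("DAPSA sums its components and LDA includes the boundary", {
  expect_equal(dapsa(0, 0, 0, 0, 0), 0)
  expect_true(dapsa_lda(dapsa(0, 0, 0, 0, 0)))

  s <- dapsa(10, 7, 0.5, 5.0, 5.0)
  expect_equal(s, 27.5)
  expect_false(dapsa_lda(s))

  expect_true(dapsa_lda(14))        # score <= 14 is inclusive
  expect_false(dapsa_lda(14.0001))
  expect_true(is.na(dapsa(10, NA, 0.5, 5, 5)))
})

test_that("MDA applies the 5-of-7 rule with strict missingness", {
  # all zero: 7 of 7
  expect_true(mda(0, 0, 0, 0, 0, 0, 0))
  # exactly 5 met (tjc and sjc fail)
  expect_true(mda(5, 5, 0, 0, 0, 0, 0))
  # exactly 4 met (tjc, sjc, bsa fail)
  expect_false(mda(5, 5, 10, 0, 0, 0, 0))
  # one criterion failing still leaves 6 of 7
  expect_true(mda(2, 0, 0, 0, 0, 0, 0))
  # boundaries are inclusive
  expect_true(mda(1, 1, 3, 15, 20, 0.5, 1))
  # a missing component always yields a missing flag
  expect_true(is.na(mda(0, 0, NA, 0, 0, 0, 0)))
})

test_that("percent-improvement flags use an inclusive threshold and the zero-baseline rule", {
  expect_true(pct_improvement_flag(10, 5))     # exactly 50%
  expect_false(pct_improvement_flag(10, 6))    # 40%
  expect_true(pct_improvement_flag(0, 0))      # zero baseline, still zero
  expect_false(pct_improvement_flag(0, 1))     # zero baseline, worsened
  expect_true(is.na(pct_improvement_flag(10, NA)))
})

test_that("ACR50 matches an independent rule-by-rule evaluator", {
  expect_true(acr50(
    list(tjc68 = 10, sjc66 = 8, pain = 60, patient_global = 55,
         physician_global = 50, haq_di = 1.5, crp = 12),
    list(tjc68 = 0, sjc66 = 0, pain = 0, patient_global = 0,
         physician_global = 0, haq_di = 0, crp = 0)))
  # joints improved 50% but only 2 of 5 auxiliaries did
  expect_false(acr50(
    list(tjc68 = 10, sjc66 = 8, pain = 60, patient_global = 55,
         physician_global = 50, haq_di = 1.5, crp = 12),
    list(tjc68 = 5, sjc66 = 4, pain = 10, patient_global = 10,
         physician_global = 45, haq_di = 1.4, crp = 11)))

  # randomized records vs a naive per-patient evaluation
  naive_acr50 <- function(b, v) {
    imp <- function(b0, v0) if (b0 == 0) v0 == 0 else (b0 - v0) / b0 >= 0.5
    aux <- c(imp(b$pain, v$pain), imp(b$patient_global, v$patient_global),
             imp(b$physician_global, v$physician_global),
             imp(b$haq_di, v$haq_di), imp(b$crp, v$crp))
    imp(b$tjc68, v$tjc68) && imp(b$sjc66, v$sjc66) && sum(aux) >= 3
  }
  set.seed(51)
  for (i in 1:50) {
    b <- list(tjc68 = sample(0:30, 1), sjc66 = sample(0:20, 1),
              pain = runif(1, 0, 100), patient_global = runif(1, 0, 100),
              physician_global = runif(1, 0, 100), haq_di = runif(1, 0, 3),
              crp = runif(1, 0, 40))
    v <- list(tjc68 = sample(0:30, 1), sjc66 = sample(0:20, 1),
              pain = runif(1, 0, 100), patient_global = runif(1, 0, 100),
              physician_global = runif(1, 0, 100), haq_di = runif(1, 0, 3),
              crp = runif(1, 0, 40))
    expect_equal(acr50(b, v), naive_acr50(b, v))
  }
})

test_that("MCID thresholds are inclusive and direction-correct", {
  mc <- mcid_flags(list(haq_di = 1.00, pain = 50, facit_f = 30),
                   list(haq_di = 0.65, pain = 41, facit_f = 34))
  expect_true(mc$mcid_haq)      # decrease exactly 0.35
  expect_false(mc$mcid_pain)    # decrease 9 mm < 10
  expect_true(mc$mcid_facitf)   # increase exactly 4

  mc2 <- mcid_flags(list(haq_di = 1.00, pain = 50, facit_f = 30),
                    list(haq_di = 0.70, pain = 40, facit_f = 33))
  expect_false(mc2$mcid_haq)
  expect_true(mc2$mcid_pain)
  expect_false(mc2$mcid_facitf)
})

test_that("eligibility gates use the baseline thresholds", {
  base <- list(haq_di = c(0.25, 0.35, 2.0), pain = c(8, 10, 50))
  expect_equal(eligibility_filter(base, "mcid_haq"), c(FALSE, TRUE, TRUE))
  expect_equal(eligibility_filter(base, "mcid_pain"), c(FALSE, TRUE, TRUE))
  expect_equal(eligibility_filter(base, "mda"), rep(TRUE, 3))
})

test_that("Wilson interval matches its closed form", {
  ci <- wilson_ci(5, 10)
  z <- qnorm(0.975)
  centre <- (0.5 + z^2 / 20) / (1 + z^2 / 10)
  half <- z * sqrt(0.025 + z^2 / 400) / (1 + z^2 / 10)
  expect_equal(unname(ci), c(centre - half, centre + half), tolerance = 1e-12)
  expect_equal(unname(ci), c(0.2365931, 0.7634069), tolerance = 1e-6)
})

make_flag_table <- function(n, week = 12, flag, reason = "none",
                            elig = TRUE) {
  data.frame(patient_id = sprintf("P%02d", seq_len(n)), week = week,
             missing_reason = reason, mda = flag,
             elig_mcid_haq = elig, elig_mcid_pain = elig,
             stringsAsFactors = FALSE)
}

test_that("as-observed rates use the non-missing denominator", {
  fl <- make_flag_table(10, flag = rep(c(TRUE, FALSE), 5))
  rr <- responder_rates(fl, labels = rep(1, 10), endpoints = "mda")
  expect_equal(rr$rate, 50)
  expect_equal(rr$n_evaluable, 10)
  expect_lt(rr$ci_lower, 50); expect_gt(rr$ci_upper, 50)

  fl2 <- fl
  fl2$mda[10] <- NA; fl2$missing_reason[10] <- "other"   # a non-responder goes missing
  rr2 <- responder_rates(fl2, labels = rep(1, 10), endpoints = "mda")
  expect_equal(rr2$n_evaluable, 9)
  expect_equal(rr2$rate, 100 * 5 / 9, tolerance = 1e-10)
})

test_that("endpoint flags propagate visit-level missingness", {
  base <- visit_rows(c("A", "B"), 0, c(10, 8), c(6, 5), c(50, 60), c(50, 55),
                     c(45, 50), c(1.2, 1.0), c(30, 28), c(12, 9), c(5, 4),
                     c(2, 3))
  v12 <- visit_rows(c("A", "B"), 12, c(2, NA), c(1, NA), c(10, NA), c(10, NA),
                    c(8, NA), c(0.4, NA), c(38, NA), c(3, NA), c(1, NA),
                    c(0, NA), missing_reason = c("none", "covid_geo"))
  fl <- endpoint_flags(rbind(base, v12))
  expect_equal(nrow(fl), 2)
  a <- fl[fl$patient_id == "A", ]
  expect_false(is.na(a$mda))
  expect_true(a$tjc50)                # 10 -> 2
  b <- fl[fl$patient_id == "B", ]
  expect_true(all(is.na(unlist(b[endpoint_names()]))))
  expect_equal(b$missing_reason, "covid_geo")
})

test_that("NRI-MI equals AO with nothing to impute and dilutes under NRI", {
  fl <- make_flag_table(12, flag = rep(c(TRUE, TRUE, FALSE), 4))
  ao <- responder_rates(fl, rep(1, 12), endpoints = "mda")
  nri <- nri_mi_rates(fl, rep(1, 12), endpoints = "mda", m = 5, seed = 1)
  expect_equal(nri$rate, ao$rate)                     # exact equality
  expect_equal(nri$var_between, 0)

  # missing for reason `other` counts as non-response: rate can only drop
  fl2 <- fl
  fl2$mda[1:3] <- NA
  fl2$missing_reason[1:3] <- c("other", "dropout", "other")
  ao2 <- responder_rates(fl2, rep(1, 12), endpoints = "mda")
  nri2 <- nri_mi_rates(fl2, rep(1, 12), endpoints = "mda", m = 5, seed = 1)
  expect_lte(nri2$rate, ao2$rate)
  expect_equal(nri2$rate, 100 * sum(fl2$mda, na.rm = TRUE) / 12)
})

test_that("covid/geopolitical missingness is imputed from the observed rate", {
  # 9 observed (4 responders, observed rate 4/9), 1 covid_geo-missing
  fl <- make_flag_table(10, flag = c(rep(TRUE, 4), rep(FALSE, 5), NA),
                        reason = c(rep("none", 9), "covid_geo"))
  nri <- nri_mi_rates(fl, rep(1, 10), endpoints = "mda", m = 4000, seed = 3)
  expected <- 100 * (4 + 4 / 9) / 10   # expectation under the imputation model
  expect_equal(nri$rate, expected, tolerance = 1.5)
  expect_gt(nri$var_between, 0)
  expect_true(nri$ci_lower <= nri$rate && nri$ci_upper >= nri$rate)

  # no observed data at all: falls back to non-responder with a warning
  fl0 <- make_flag_table(3, flag = NA, reason = "covid_geo")
  expect_warning(nri0 <- nri_mi_rates(fl0, rep(1, 3), endpoints = "mda",
                                      m = 3, seed = 4),
                 "non-responder")
  expect_equal(nri0$rate, 0)
})

test_that("pipeline rates rise over weeks under the improving response model", {
  gb <- generate_baseline(1500, seed = 55)
  vis <- generate_visits(gb$cohort, gb$truth, default_visit_config(0, 0, 0),
                         seed = 55)
  fl <- endpoint_flags(vis)
  lab <- stats::setNames(gb$truth$component, gb$truth$patient_id)
  rr <- responder_rates(fl, lab, endpoints = c("mda", "dapsa_lda"))
  for (k in 1:5) {
    for (ep in c("mda", "dapsa_lda")) {
      r <- rr[rr$cluster == k & rr$endpoint == ep, ]
      r <- r[order(r$week), ]
      expect_gt(r$rate[r$week == 196], r$rate[r$week == 12])
    }
  }
})
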