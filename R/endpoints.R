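# Responder endpoints per patient-visit, aggregated by phenotype and week
# under as-observed (AO) and non-responder-imputation-with-multiple-
# imputation (NRI-MI) analyses.
#
# Endpoint definitions (standard clinical instruments):
#   DAPSA    = TJC68 + SJC66 + CRP(mg/dL) + pain(cm) + patient global(cm);
#              low disease activity (LDA) = DAPSA <= 14.
#   MDA      = at least 5 of 7: TJC68 <= 1, SJC66 <= 1, BSA <= 3%,
#              pain <= 15 mm, patient global <= 20 mm, HAQ-DI <= 0.5,
#              tender entheseal points <= 1.
#   ACR50    = >= 50% improvement in both TJC and SJC and in >= 3 of 5 of:
#              pain, patient global, physician global, HAQ-DI, CRP.
#   MCIDs    = HAQ-DI decrease >= 0.35; pain VAS decrease >= 10 mm;
#              FACIT-F increase >= 4.
# Flags are three-valued: TRUE / FALSE / NA (missing visit or component).

#' DAPSA score and low-disease-activity flag
#'
#' DAPSA is the plain sum of five components; note the unit conventions:
#' CRP in mg/dL and the two visual-analogue scales in cm.
#'
#' @param tjc68 tender joint count (0-68).
#' @param sjc66 swollen joint count (0-66).
#' @param crp_mg_dl C-reactive protein in mg/dL.
#' @param pain_cm patient pain VAS in cm (0-10).
#' @param patient_global_cm patient global assessment VAS in cm (0-10).
#' @return Numeric DAPSA score (NA if any component missing).
#' @export
dapsa <- function(tjc68, sjc66, crp_mg_dl, pain_cm, patient_global_cm) {
  tjc68 + sjc66 + crp_mg_dl + pain_cm + patient_global_cm
}

#' @rdname dapsa
#' @param score a DAPSA score.
#' @return `dapsa_lda()`: logical flag, `TRUE` when score <= 14 (boundary
#'   inclusive).
#' @export
dapsa_lda <- function(score) score <= 14

#' Minimal disease activity (5-of-7 rule)
#'
#' TRUE when at least 5 of the 7 cut-offs hold: TJC68 <= 1, SJC66 <= 1,
#' BSA <= 3%, pain <= 15 mm, patient global <= 20 mm, HAQ-DI <= 0.5,
#' tender entheseal points <= 1. Any missing component makes the flag
#' missing, even if 5 criteria are already met.
#'
#' @param tjc68,sjc66 joint counts.
#' @param bsa body surface area with psoriasis, percent.
#' @param pain_mm,patient_global_mm VAS in mm (0-100).
#' @param haq_di HAQ disability index (0-3).
#' @param entheseal_points tender entheseal point count.
#' @return Logical flag (NA if any component missing).
#' @export
mda <- function(tjc68, sjc66, bsa, pain_mm, patient_global_mm, haq_di,
                entheseal_points) {
  crit <- cbind(tjc68 <= 1, sjc66 <= 1, bsa <= 3, pain_mm <= 15,
                patient_global_mm <= 20, haq_di <= 0.5, entheseal_points <= 1)
  met <- rowSums(crit)
  ifelse(is.na(met), NA, met >= 5)
}

#' Percent-improvement responder flag
#'
#' TRUE when (baseline - visit) / baseline >= threshold. A zero baseline
#' cannot improve in relative terms: the flag is TRUE iff the visit value is
#' also 0.
#'
#' @param baseline,visit component values at baseline and at the visit.
#' @param threshold required improvement fraction (default 0.50, boundary
#'   inclusive).
#' @return Logical flag (NA when the visit value is missing).
#' @export
pct_improvement_flag <- function(baseline, visit, threshold = 0.50) {
  ifelse(is.na(baseline) | is.na(visit), NA,
         ifelse(baseline == 0, visit == 0,
                (baseline - visit) / baseline >= threshold))
}

#' ACR50 responder flag
#'
#' Requires >= 50% improvement in both joint counts and >= 50% improvement
#' in at least 3 of the 5 auxiliary measures: pain, patient global,
#' physician global, HAQ-DI, CRP.
#'
#' @param baseline,visit data frames (or lists) holding `tjc68`, `sjc66`,
#'   `pain`, `patient_global`, `physician_global`, `haq_di`, `crp` at the
#'   two timepoints (vectorised over patients).
#' @return Logical flag vector (NA where required components are missing).
#' @export
acr50 <- function(baseline, visit) {
  joint <- pct_improvement_flag(baseline$tjc68, visit$tjc68) &
    pct_improvement_flag(baseline$sjc66, visit$sjc66)
  aux <- cbind(pct_improvement_flag(baseline$pain, visit$pain),
               pct_improvement_flag(baseline$patient_global, visit$patient_global),
               pct_improvement_flag(baseline$physician_global, visit$physician_global),
               pct_improvement_flag(baseline$haq_di, visit$haq_di),
               pct_improvement_flag(baseline$crp, visit$crp))
  naux <- rowSums(aux)
  ifelse(is.na(joint) | is.na(naux), NA, joint & naux >= 3)
}

#' Minimal clinically important difference flags
#'
#' HAQ-DI: decrease >= 0.35; pain: decrease >= 10 mm; FACIT-F: increase
#' >= 4. All boundaries inclusive.
#'
#' @param baseline,visit data frames (or lists) holding `haq_di`, `pain`
#'   (mm) and `facit_f` at the two timepoints (vectorised over patients).
#' @return Data frame with logical columns `mcid_haq`, `mcid_pain`,
#'   `mcid_facitf`.
#' @export
mcid_flags <- function(baseline, visit) {
  data.frame(
    mcid_haq = baseline$haq_di - visit$haq_di >= 0.35,
    mcid_pain = baseline$pain - visit$pain >= 10,
    mcid_facitf = visit$facit_f - baseline$facit_f >= 4)
}

#' Baseline eligibility for an endpoint denominator
#'
#' The HAQ-DI MCID is analysed only in patients with baseline HAQ-DI >=
#' 0.35 and the pain MCID only in patients with baseline pain VAS >= 10 mm
#' (both inclusive); every patient is eligible for the other endpoints.
#'
#' @param baseline data frame (or list) with `haq_di` and `pain` at
#'   baseline.
#' @param endpoint endpoint name (one of the columns produced by
#'   [endpoint_flags()]).
#' @return Logical eligibility vector.
#' @export
eligibility_filter <- function(baseline, endpoint) {
  switch(endpoint,
         mcid_haq = !is.na(baseline$haq_di) & baseline$haq_di >= 0.35,
         mcid_pain = !is.na(baseline$pain) & baseline$pain >= 10,
         rep(TRUE, length(baseline$haq_di)))
}

endpoint_names <- function() {
  c("mda", "dapsa_lda", "tjc50", "sjc50", "acr50",
    "mcid_haq", "mcid_pain", "mcid_facitf")
}

#' Compute all responder flags per patient-week
#'
#' Takes a long visit table (one row per patient per week, week 0 =
#' baseline, CRP in mg/L) and returns one row per patient per post-baseline
#' week with the eight endpoint flags and the per-endpoint baseline
#' eligibility. CRP is converted to mg/dL and the VAS scales to cm where
#' the instrument requires it. A visit with a recorded missing reason, or a
#' missing required component, yields a missing flag.
#'
#' @param visits data frame of visit records with columns `patient_id`,
#'   `week`, `tjc68`, `sjc66`, `pain`, `patient_global`,
#'   `physician_global`, `haq_di`, `facit_f`, `crp`, `bsa`,
#'   `entheseal_points`, `missing_reason`.
#' @return A data frame with `patient_id`, `week`, `missing_reason`, one
#'   logical column per endpoint, and `elig_mcid_haq` / `elig_mcid_pain`.
#' @export
endpoint_flags <- function(visits) {
  need <- c("patient_id", "week", "tjc68", "sjc66", "pain", "patient_global",
            "physician_global", "haq_di", "facit_f", "crp", "bsa",
            "entheseal_points", "missing_reason")
  absent <- setdiff(need, names(visits))
  if (length(absent)) stop("visit table lacks columns: ", paste(absent, collapse = ", "))
  base <- visits[visits$week == 0, ]
  if (anyDuplicated(base$patient_id)) stop("duplicated baseline rows")
  post <- visits[visits$week > 0, ]
  if (!all(post$patient_id %in% base$patient_id)) {
    stop("visit rows without a week-0 baseline record")
  }
  b <- base[match(post$patient_id, base$patient_id), ]

  out <- data.frame(patient_id = post$patient_id, week = post$week,
                    missing_reason = post$missing_reason,
                    stringsAsFactors = FALSE)
  out$mda <- mda(post$tjc68, post$sjc66, post$bsa, post$pain,
                 post$patient_global, post$haq_di, post$entheseal_points)
  out$dapsa_lda <- dapsa_lda(dapsa(post$tjc68, post$sjc66, post$crp / 10,
                                   post$pain / 10, post$patient_global / 10))
  out$tjc50 <- pct_improvement_flag(b$tjc68, post$tjc68)
  out$sjc50 <- pct_improvement_flag(b$sjc66, post$sjc66)
  out$acr50 <- acr50(b, post)
  mc <- mcid_flags(b, post)
  out$mcid_haq <- mc$mcid_haq
  out$mcid_pain <- mc$mcid_pain
  out$mcid_facitf <- mc$mcid_facitf
  out$elig_mcid_haq <- eligibility_filter(b, "mcid_haq")
  out$elig_mcid_pain <- eligibility_filter(b, "mcid_pain")
  out
}

flag_eligible <- function(flags, endpoint) {
  switch(endpoint,
         mcid_haq = flags$elig_mcid_haq,
         mcid_pain = flags$elig_mcid_pain,
         rep(TRUE, nrow(flags)))
}

#' As-observed responder rates by cluster and week
#'
#' For each cluster x week x endpoint, the denominator is the eligible
#' patients with a non-missing flag at that week; the rate carries a Wilson
#' 95% confidence interval. A zero denominator yields an absent rate.
#'
#' @param flags output of [endpoint_flags()].
#' @param labels named integer vector of cluster labels (names = patient
#'   ids) or a vector aligned with the unique patients of `flags`.
#' @param endpoints endpoint columns to summarise (default: all eight).
#' @param conf confidence level (default 0.95).
#' @return A `ResponderSummary` data frame: cluster, week, endpoint,
#'   n_evaluable, responders, rate (percent), ci_lower, ci_upper, analysis
#'   = "AO".
#' @export
responder_rates <- function(flags, labels, endpoints = endpoint_names(),
                            conf = 0.95) {
  lab <- label_lookup(flags$patient_id, labels)
  weeks <- sort(unique(flags$week))
  rows <- list()
  for (k in sort(unique(lab))) {
    for (w in weeks) {
      sel_cw <- lab == k & flags$week == w
      for (ep in endpoints) {
        sel <- sel_cw & flag_eligible(flags, ep)
        f <- flags[[ep]][sel]
        n_eval <- sum(!is.na(f))
        resp <- sum(f, na.rm = TRUE)
        if (n_eval > 0) {
          ci <- 100 * wilson_ci(resp, n_eval, conf)
          rate <- 100 * resp / n_eval
        } else {
          ci <- c(lower = NA_real_, upper = NA_real_)
          rate <- NA_real_
        }
        rows[[length(rows) + 1L]] <- data.frame(
          cluster = k, week = w, endpoint = ep, n_evaluable = n_eval,
          responders = resp, rate = rate,
          ci_lower = ci[["lower"]], ci_upper = ci[["upper"]],
          analysis = "AO", stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

label_lookup <- function(patient_id, labels) {
  if (!is.null(names(labels))) {
    lab <- labels[patient_id]
    if (anyNA(lab)) stop("labels missing for some patients in the flag table")
    unname(lab)
  } else {
    ids <- unique(patient_id)
    if (length(labels) != length(ids)) {
      stop("unnamed labels must align with the unique patients of the flag table")
    }
    labels[match(patient_id, ids)]
  }
}

#' NRI-MI responder rates by cluster and week
#'
#' Non-responder imputation with multiple imputation: flags missing for
#' reason `other` or `dropout` (or with a missing component despite an
#' attended visit) are counted as non-responders; flags missing for reason
#' `covid_geo` are imputed `m` times as Bernoulli draws from the cluster x
#' week as-observed response rate, and the per-imputation rates are pooled
#' by Rubin's rules (total variance = within + (1 + 1/m) x between) for a
#' normal-approximation confidence interval. The denominator is all
#' eligible patients of the cluster at that week. With no missingness the
#' NRI-MI rate equals the as-observed rate exactly. A cluster-week with no
#' observed data to impute from falls back to non-responder imputation with
#' a warning.
#'
#' @param flags output of [endpoint_flags()] (must retain
#'   `missing_reason`).
#' @param labels cluster labels as in [responder_rates()].
#' @param endpoints endpoint columns to summarise.
#' @param m number of imputations (default 20).
#' @param seed integer seed for the imputation draws.
#' @param conf confidence level (default 0.95).
#' @return A `ResponderSummary` data frame with analysis = "NRI_MI" and
#'   columns `m`, `var_within`, `var_between` in addition to the AO
#'   columns.
#' @export
nri_mi_rates <- function(flags, labels, endpoints = endpoint_names(),
                         m = 20L, seed = NULL, conf = 0.95) {
  lab <- label_lookup(flags$patient_id, labels)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max - 1L, 1)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  weeks <- sort(unique(flags$week))
  rows <- list()
  with_seed(seed, {
    for (k in sort(unique(lab))) {
      for (w in weeks) {
        sel_cw <- lab == k & flags$week == w
        for (ep in endpoints) {
          sel <- sel_cw & flag_eligible(flags, ep)
          f <- flags[[ep]][sel]
          reason <- flags$missing_reason[sel]
          n_tot <- sum(sel)
          if (n_tot == 0) {
            rows[[length(rows) + 1L]] <- data.frame(
              cluster = k, week = w, endpoint = ep, n_evaluable = 0L,
              responders = 0L, rate = NA_real_, ci_lower = NA_real_,
              ci_upper = NA_real_, analysis = "NRI_MI", m = m,
              var_within = NA_real_, var_between = NA_real_)
            next
          }
          obs <- !is.na(f)
          r_obs <- sum(f[obs])
          n_obs <- sum(obs)
          impute <- !obs & reason == "covid_geo"
          n_imp <- sum(impute)
          if (n_imp > 0 && n_obs == 0) {
            warning("no observed data to impute from (cluster ", k, ", week ",
                    w, ", ", ep, "); covid_geo treated as non-responder",
                    call. = FALSE)
            n_imp <- 0L
          }
          p_hat <- if (n_obs > 0) r_obs / n_obs else 0
          q <- numeric(m)
          wv <- numeric(m)
          for (i in seq_len(m)) {
            r_i <- r_obs + if (n_imp > 0) stats::rbinom(1, n_imp, p_hat) else 0L
            q[i] <- r_i / n_tot
            wv[i] <- q[i] * (1 - q[i]) / n_tot
          }
          qbar <- mean(q)
          B <- if (m > 1) stats::var(q) else 0
          Tv <- mean(wv) + (1 + 1 / m) * B
          rows[[length(rows) + 1L]] <- data.frame(
            cluster = k, week = w, endpoint = ep, n_evaluable = n_tot,
            responders = r_obs, rate = 100 * qbar,
            ci_lower = 100 * max(0, qbar - z * sqrt(Tv)),
            ci_upper = 100 * min(1, qbar + z * sqrt(Tv)),
            analysis = "NRI_MI", m = m, var_within = mean(wv),
            var_between = B, stringsAsFactors = FALSE)
        }
      }
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
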