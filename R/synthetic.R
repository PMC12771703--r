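# Synthetic cohort generator emulating a biologic-naive PsA trial baseline:
# 5 latent phenotypes with published mixing proportions, per-phenotype
# continuous means/SDs and categorical frequencies, optional planted
# missingness and collinear duplicate columns, and a longitudinal response
# surface for endpoint analysis.

#' Default baseline generator configuration
#'
#' Five latent phenotypes with mixing proportions (0.403, 0.208, 0.140,
#' 0.138, 0.111) in the order: Moderate-to-High Disease Activity, Enthesitis
#' and Large Joints Dominant, Very High Disease Activity, Hand Dominant,
#' Dactylitis and Feet Dominant. Continuous features (TJC68, SJC66, pain
#' VAS) carry the per-phenotype means and SDs of the source population;
#' categorical features (sex, age band, BMI band, dactylitis presence,
#' enthesitis band, body-surface-area band, CRP band, disease-duration
#' band, psoriatic spondylitis, and per-location involvement indicators for
#' tender/swollen hands and feet, swollen large joints and dactylitis of
#' hands/feet) carry the per-phenotype level frequencies. Features are
#' conditionally independent within a phenotype, matching the density
#' family the mixture module fits.
#'
#' When `missingness = TRUE` the config additionally plants (a) a
#' low-information extra feature (`facit_f`) with 25% missing values, (b)
#' three exact duplicate columns (`tjc_dup`, `sjc_dup`, `pain_dup`) that are
#' perfectly collinear with their sources, and (c) sporadic missingness at
#' rate 0.00415 per core feature, so that roughly 6.4% of patients are
#' incomplete on the final feature set — emulating the screening structure
#' the ingestion module is designed to remove.
#'
#' @param missingness logical; include the planted missingness/collinearity
#'   layer (default `FALSE`: a clean, complete cohort).
#' @return A generator config list (weights, continuous, categorical,
#'   missingness).
#' @export
default_generator_config <- function(missingness = FALSE) {
  cfg <- list(
    K = 5L,
    weights = c(0.403, 0.208, 0.140, 0.138, 0.111) /
      sum(c(0.403, 0.208, 0.140, 0.138, 0.111)),
    continuous = list(
      tjc  = list(mean = c(10.1, 20.0, 46.6, 25.3, 24.7),
                  sd = c(3.3, 7.2, 9.8, 7.0, 8.4),
                  min = 0, integer = TRUE, group = "tender-joint",
                  units = "tender joints (0-68)"),
      sjc  = list(mean = c(7.4, 10.1, 24.0, 15.0, 15.5),
                  sd = c(2.1, 4.0, 11.3, 5.5, 7.9),
                  min = 0, integer = TRUE, group = "swollen-joint",
                  units = "swollen joints (0-66)"),
      pain = list(mean = c(52.6, 57.7, 66.5, 59.0, 54.8),
                  sd = c(23.0, 21.6, 19.7, 20.3, 23.9),
                  integer = FALSE, group = "other",
                  units = "mm VAS")
    ),
    categorical = list(
      sex = list(levels = c("female", "male"), group = "demographic",
                 probs = rbind(c(44.3, 55.7), c(62.2, 37.8), c(59.9, 40.1),
                               c(54.5, 45.5), c(36.3, 63.7)) / 100),
      age_band = list(levels = c("<=45", "45-65", ">65"), group = "demographic",
                      probs = rbind(c(39.0, 48.8, 12.2), c(31.3, 53.2, 15.5),
                                    c(22.3, 63.7, 14.0), c(29.9, 54.5, 15.6),
                                    c(46.0, 50.0, 4.0)) / 100),
      bmi_band = list(levels = c("<25", "25-30", ">=30"), group = "demographic",
                      probs = rbind(c(18.6, 40.8, 40.6), c(14.2, 28.3, 57.5),
                                    c(15.3, 28.7, 56.1), c(14.3, 44.2, 41.6),
                                    c(25.8, 34.7, 39.5)) / 100),
      dactylitis = list(levels = c("no", "yes"), group = "dactylitis",
                        probs = rbind(c(81.6, 18.4), c(79.0, 21.0),
                                      c(52.9, 47.1), c(73.4, 26.6),
                                      c(39.5, 60.5)) / 100),
      enthesitis_band = list(levels = c("0", "1-5", "6-16"), group = "enthesitis",
                             probs = rbind(c(54.1, 45.0, 0.9), c(1.3, 31.3, 67.4),
                                           c(4.5, 14.0, 81.5), c(28.6, 52.6, 18.8),
                                           c(23.4, 61.3, 15.3)) / 100),
      bsa_band = list(levels = c("0", "<3", "3-10", ">=10"), group = "psoriasis",
                      probs = rbind(c(4.4, 37.7, 34.4, 23.5),
                                    c(6.0, 45.9, 27.5, 20.6),
                                    c(3.2, 41.4, 27.4, 28.0),
                                    c(5.2, 35.1, 36.4, 23.4),
                                    c(7.3, 31.5, 31.5, 29.8)) / 100),
      crp_band = list(levels = c("<1", "1-3", "3-10", ">=10"), group = "other",
                      probs = rbind(c(12.2, 18.6, 43.0, 26.2),
                                    c(6.4, 25.8, 39.9, 27.9),
                                    c(10.8, 19.1, 43.9, 26.1),
                                    c(6.5, 26.6, 41.6, 25.3),
                                    c(4.0, 22.6, 35.5, 37.9)) / 100),
      duration_band = list(levels = c("<2", "2-5", "5-10", ">=10"), group = "other",
                           probs = rbind(c(30.2, 26.6, 23.1, 20.2),
                                         c(25.3, 30.5, 24.5, 19.7),
                                         c(26.8, 22.9, 21.0, 29.3),
                                         c(24.7, 24.0, 25.3, 26.0),
                                         c(23.4, 34.7, 21.8, 20.2)) / 100),
      psoriatic_spondylitis = list(levels = c("no", "yes"), group = "psoriasis",
                                   probs = rbind(c(81.8, 18.2), c(83.3, 16.7),
                                                 c(77.7, 22.3), c(85.7, 14.3),
                                                 c(71.0, 29.0)) / 100),
      # per-location joint involvement indicators: the axis that separates
      # the hand-dominant, feet-dominant and large-joint phenotypes
      tender_hands = list(levels = c("no", "yes"), group = "tender-joint",
                          probs = rbind(c(50, 50), c(55, 45), c(5, 95),
                                        c(3, 97), c(80, 20)) / 100),
      tender_feet = list(levels = c("no", "yes"), group = "tender-joint",
                         probs = rbind(c(55, 45), c(60, 40), c(5, 95),
                                       c(75, 25), c(3, 97)) / 100),
      swollen_hands = list(levels = c("no", "yes"), group = "swollen-joint",
                           probs = rbind(c(55, 45), c(60, 40), c(10, 90),
                                         c(5, 95), c(85, 15)) / 100),
      swollen_feet = list(levels = c("no", "yes"), group = "swollen-joint",
                          probs = rbind(c(60, 40), c(65, 35), c(10, 90),
                                        c(80, 20), c(5, 95)) / 100),
      swollen_large_joints = list(levels = c("no", "yes"), group = "swollen-joint",
                                  probs = rbind(c(70, 30), c(8, 92), c(15, 85),
                                                c(75, 25), c(60, 40)) / 100),
      dactylitis_hands = list(levels = c("no", "yes"), group = "dactylitis",
                              probs = rbind(c(90, 10), c(88, 12), c(70, 30),
                                            c(75, 25), c(80, 20)) / 100),
      dactylitis_feet = list(levels = c("no", "yes"), group = "dactylitis",
                             probs = rbind(c(92, 8), c(90, 10), c(72, 28),
                                           c(92, 8), c(45, 55)) / 100)
    ),
    missingness = NULL
  )
  # normalise categorical rows (printed percentages round to one decimal)
  for (nm in names(cfg$categorical)) {
    p <- cfg$categorical[[nm]]$probs
    cfg$categorical[[nm]]$probs <- p / rowSums(p)
  }
  if (missingness) {
    cfg$missingness <- list(
      core_rate = 0.00415,
      high_missing = list(name = "facit_f", rate = 0.25,
                          mean = c(30, 28, 24, 27, 29), sd = rep(9, 5),
                          min = 0, max = 52, integer = FALSE, group = "other",
                          units = "FACIT-F (0-52)"),
      duplicates = c(tjc = "tjc_dup", sjc = "sjc_dup", pain = "pain_dup")
    )
  }
  cfg
}

validate_generator_config <- function(cfg) {
  stopifnot(is.numeric(cfg$weights), all(cfg$weights > 0),
            abs(sum(cfg$weights) - 1) < 1e-12)
  K <- length(cfg$weights)
  for (nm in names(cfg$continuous)) {
    f <- cfg$continuous[[nm]]
    stopifnot(length(f$mean) == K, length(f$sd) == K, all(f$sd > 0))
  }
  for (nm in names(cfg$categorical)) {
    f <- cfg$categorical[[nm]]
    stopifnot(nrow(f$probs) == K, ncol(f$probs) == length(f$levels),
              all(abs(rowSums(f$probs) - 1) < 1e-12))
  }
  invisible(K)
}

#' Schema for a generated baseline cohort
#'
#' @param config a generator config, as from [default_generator_config()].
#' @return The [feature_schema()] describing the generated columns
#'   (including planted extras when the config carries a missingness layer).
#' @export
generator_schema <- function(config = default_generator_config()) {
  names <- character(0); kinds <- character(0); groups <- character(0)
  lvls <- list(); units <- character(0)
  for (nm in names(config$continuous)) {
    f <- config$continuous[[nm]]
    names <- c(names, nm); kinds <- c(kinds, "continuous")
    groups <- c(groups, f$group); lvls <- c(lvls, list(NULL))
    units <- c(units, f$units %||% "")
  }
  for (nm in names(config$categorical)) {
    f <- config$categorical[[nm]]
    names <- c(names, nm)
    kinds <- c(kinds, if (length(f$levels) == 2L) "binary" else "categorical")
    groups <- c(groups, f$group); lvls <- c(lvls, list(f$levels))
    units <- c(units, "")
  }
  ms <- config$missingness
  if (!is.null(ms)) {
    hm <- ms$high_missing
    names <- c(names, hm$name); kinds <- c(kinds, "continuous")
    groups <- c(groups, hm$group); lvls <- c(lvls, list(NULL))
    units <- c(units, hm$units %||% "")
    for (src in names(ms$duplicates)) {
      dup <- ms$duplicates[[src]]
      i <- match(src, names)
      names <- c(names, dup); kinds <- c(kinds, kinds[i])
      groups <- c(groups, groups[i]); lvls <- c(lvls, lvls[i])
      units <- c(units, units[i])
    }
  }
  feature_schema(names, kinds, groups, lvls, units)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# truncated-normal draw by inverse CDF (no boundary point masses)
draw_continuous <- function(f, z) {
  mu <- f$mean[z]
  sd <- f$sd[z]
  lo <- stats::pnorm(f$min %||% -Inf, mu, sd)
  hi <- stats::pnorm(f$max %||% Inf, mu, sd)
  v <- stats::qnorm(lo + stats::runif(length(z)) * (hi - lo), mu, sd)
  v <- pmin(pmax(v, f$min %||% -Inf), f$max %||% Inf)   # numeric safety only
  if (isTRUE(f$integer)) v <- round(v)
  v
}

#' Generate a baseline cohort with known phenotype labels
#'
#' Draws each patient's latent phenotype from the configured mixing
#' proportions, then draws features independently within phenotype:
#' continuous features from truncated Gaussians (counts rounded to
#' integers, floored at physiologic minima), categoricals from
#' phenotype-specific level frequencies. Planted missingness and collinear
#' duplicate columns (if configured) are applied after the truth labels are
#' recorded. Output is bit-identical for a fixed seed.
#'
#' @param n number of patients.
#' @param config generator config (default [default_generator_config()]).
#' @param seed integer seed.
#' @return List with `cohort` (a `psa_cohort`), `truth` (data frame
#'   `patient_id`, `component`), and `schema`.
#' @export
generate_baseline <- function(n, config = default_generator_config(),
                              seed = NULL) {
  K <- validate_generator_config(config)
  if (n < K) stop("n_patients must be >= number of components (", K, ")")
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max - 1L, 1)
  with_seed(seed, {
    z <- sample.int(K, n, replace = TRUE, prob = config$weights)
    dat <- data.frame(patient_id = sprintf("P%05d", seq_len(n)),
                      stringsAsFactors = FALSE)
    for (nm in names(config$continuous)) {
      dat[[nm]] <- draw_continuous(config$continuous[[nm]], z)
    }
    for (nm in names(config$categorical)) {
      f <- config$categorical[[nm]]
      u <- stats::runif(n)
      cum <- t(apply(f$probs, 1, cumsum))
      idx <- integer(n)
      for (k in seq_len(K)) {
        sel <- z == k
        idx[sel] <- findInterval(u[sel], cum[k, ], left.open = TRUE) + 1L
      }
      dat[[nm]] <- f$levels[idx]
    }
    ms <- config$missingness
    if (!is.null(ms)) {
      core <- c(names(config$continuous), names(config$categorical))
      for (nm in core) {
        hit <- stats::runif(n) < ms$core_rate
        dat[[nm]][hit] <- NA
      }
      hm <- ms$high_missing
      v <- draw_continuous(hm, z)
      v[stats::runif(n) < hm$rate] <- NA
      dat[[hm$name]] <- v
      for (src in names(ms$duplicates)) dat[[ms$duplicates[[src]]]] <- dat[[src]]
    }
    sch <- generator_schema(config)
    list(cohort = cohort(dat, sch),
         truth = data.frame(patient_id = dat$patient_id, component = z,
                            stringsAsFactors = FALSE),
         schema = sch)
  })
}

#' Default longitudinal (visit) generator configuration
#'
#' Scheduled post-baseline visits at weeks 12, 24, 52, 100 and 196. Each
#' phenotype has a mean improvement fraction per clinical domain that rises
#' log-linearly in week from the week-12 value to the week-196 value;
#' per-patient-visit improvements are Beta draws around those means
#' (concentration `phi`). Visit-level missingness carries a reason:
#' `covid_geo` (pandemic/geopolitical interruption), `other`, or absorbing
#' `dropout`.
#'
#' @param covid_geo per-visit probability of covid/geopolitical missingness.
#' @param other per-visit probability of other-reason missingness.
#' @param dropout per-visit dropout hazard (absorbing).
#' @return A visit config list.
#' @export
default_visit_config <- function(covid_geo = 0.03, other = 0.03,
                                 dropout = 0.03) {
  stopifnot(covid_geo >= 0, other >= 0, dropout >= 0,
            covid_geo + other + dropout <= 1)
  list(
    weeks = c(12L, 24L, 52L, 100L, 196L),
    # mean improvement fraction at week 12 and week 196, per phenotype;
    # calibrated once so component week-196 MDA rates bracket ~43-59%
    improve12  = c(0.50, 0.47, 0.44, 0.46, 0.47),
    improve196 = c(0.74, 0.80, 0.83, 0.81, 0.82),
    phi = 5,                    # Beta concentration of patient-level draws
    missing_rates = c(covid_geo = covid_geo, other = other, dropout = dropout),
    # phenotype-specific baseline distributions for components not in the
    # baseline feature table
    baseline = list(
      haq_di = list(mean = c(1.05, 1.30, 1.60, 1.35, 1.25), sd = rep(0.55, 5),
                    min = 0, max = 3),
      facit_f = list(mean = c(30, 28, 24, 27, 29), sd = rep(9, 5),
                     min = 0, max = 52),
      crp = list(meanlog = log(c(5, 6, 6, 6, 8)), sdlog = rep(1, 5)),   # mg/L
      entheseal_points = list(mean = c(1.2, 6.9, 10.0, 4.0, 3.9),
                              sd = c(1.2, 3.0, 3.7, 2.4, 2.3),
                              min = 0, max = 16, integer = TRUE),
      bsa = list(mean = c(10.1, 8.3, 11.8, 7.6, 12.1),
                 sd = c(16.9, 15.7, 18.4, 11.1, 19.6), min = 0, max = 100)
    )
  )
}

beta_draw <- function(n, mean, phi) {
  mean <- pmin(pmax(mean, 1e-3), 1 - 1e-3)
  stats::rbeta(n, mean * phi, (1 - mean) * phi)
}

improve_mean <- function(cfg, z, week) {
  w12 <- cfg$improve12[z]
  w196 <- cfg$improve196[z]
  frac <- log(week / 12) / log(196 / 12)
  w12 + (w196 - w12) * frac
}

#' Generate longitudinal visit records
#'
#' Produces one row per patient per scheduled week (including week 0
#' baseline). Baseline endpoint components missing from the baseline
#' feature table (HAQ-DI, FACIT-F, CRP, globals, entheseal points, BSA) are
#' drawn from phenotype-specific distributions; post-baseline values apply
#' per-domain Beta-distributed improvement fractions whose means rise with
#' week and differ by phenotype. Visits interrupted for a recorded reason
#' have all endpoint components set missing; dropout is absorbing.
#'
#' @param coh a complete `psa_cohort` holding `tjc`, `sjc` and `pain`
#'   baseline features.
#' @param truth truth record from [generate_baseline()].
#' @param config visit config from [default_visit_config()].
#' @param seed integer seed.
#' @return Data frame of visit records with endpoint components and a
#'   `missing_reason` column.
#' @export
generate_visits <- function(coh, truth, config = default_visit_config(),
                            seed = NULL) {
  stopifnot(inherits(coh, "psa_cohort"))
  stopifnot(all(c("tjc", "sjc", "pain") %in% coh$schema$feature_name))
  if (!identical(coh$data$patient_id, truth$patient_id)) {
    truth <- truth[match(coh$data$patient_id, truth$patient_id), ]
    if (anyNA(truth$component)) stop("cohort and truth record are not aligned")
  }
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max - 1L, 1)
  n <- n_patients(coh)
  z <- truth$component
  cfg <- config
  with_seed(seed, {
    b <- cfg$baseline
    draw_tn <- function(f) {
      v <- stats::rnorm(n, f$mean[z], f$sd[z])
      v <- pmin(pmax(v, f$min), f$max)
      if (isTRUE(f$integer)) v <- round(v)
      v
    }
    base <- data.frame(
      patient_id = coh$data$patient_id,
      week = 0L,
      tjc68 = as.numeric(coh$data$tjc),
      sjc66 = as.numeric(coh$data$sjc),
      pain = as.numeric(coh$data$pain),
      stringsAsFactors = FALSE)
    base$patient_global <- pmin(pmax(base$pain + stats::rnorm(n, 0, 10), 0), 100)
    base$physician_global <- pmin(pmax(base$pain + stats::rnorm(n, -5, 12), 0), 100)
    base$haq_di <- round(draw_tn(b$haq_di) / 0.125) * 0.125
    base$facit_f <- round(draw_tn(b$facit_f))
    base$crp <- stats::rlnorm(n, b$crp$meanlog[z], b$crp$sdlog[z])
    base$bsa <- draw_tn(b$bsa)
    base$entheseal_points <- draw_tn(b$entheseal_points)
    base$missing_reason <- "none"

    rows <- list(base)
    dropped <- rep(FALSE, n)
    for (w in cfg$weeks) {
      m <- improve_mean(cfg, z, w)
      f_joint <- beta_draw(n, m, cfg$phi)
      f_pain <- beta_draw(n, m, cfg$phi)
      f_func <- beta_draw(n, m, cfg$phi)
      f_fat <- beta_draw(n, pmin(m * 0.8, 0.99), cfg$phi)
      f_skin <- beta_draw(n, m, cfg$phi)
      f_crp <- beta_draw(n, m, cfg$phi)
      vis <- data.frame(
        patient_id = base$patient_id,
        week = w,
        tjc68 = round(base$tjc68 * (1 - f_joint)),
        sjc66 = round(base$sjc66 * (1 - f_joint)),
        pain = pmin(pmax(base$pain * (1 - f_pain) + stats::rnorm(n, 0, 4), 0), 100),
        stringsAsFactors = FALSE)
      vis$patient_global <- pmin(pmax(base$patient_global * (1 - f_pain) +
                                        stats::rnorm(n, 0, 4), 0), 100)
      vis$physician_global <- pmin(pmax(base$physician_global * (1 - f_pain) +
                                          stats::rnorm(n, 0, 4), 0), 100)
      vis$haq_di <- pmin(pmax(round((base$haq_di * (1 - f_func)) / 0.125) * 0.125, 0), 3)
      vis$facit_f <- pmin(pmax(round(base$facit_f + f_fat * (48 - base$facit_f)), 0), 52)
      vis$crp <- base$crp * (1 - f_crp)
      vis$bsa <- pmin(pmax(base$bsa * (1 - f_skin), 0), 100)
      vis$entheseal_points <- round(base$entheseal_points * (1 - f_joint))
      # visit-level missingness with a recorded reason; dropout absorbs
      u <- stats::runif(n)
      r <- cfg$missing_rates
      reason <- rep("none", n)
      reason[u < r["covid_geo"]] <- "covid_geo"
      reason[u >= r["covid_geo"] & u < r["covid_geo"] + r["other"]] <- "other"
      newdrop <- u >= r["covid_geo"] + r["other"] &
        u < r["covid_geo"] + r["other"] + r["dropout"]
      dropped <- dropped | newdrop
      reason[dropped] <- "dropout"
      vis$missing_reason <- reason
      comp_cols <- setdiff(names(vis), c("patient_id", "week", "missing_reason"))
      vis[reason != "none", comp_cols] <- NA
      rows[[length(rows) + 1L]] <- vis
    }
    out <- do.call(rbind, rows)
    out <- out[order(out$patient_id, out$week), ]
    rownames(out) <- NULL
    out
  })
}
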