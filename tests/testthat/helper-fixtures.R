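# shared fixture builders (all data generated in code)

toy_schema <- function() {
  feature_schema(
    feature_name = c("tjc", "sjc", "pain", "sex", "severity"),
    kind = c("continuous", "continuous", "continuous", "binary", "categorical"),
    group = c("tender-joint", "swollen-joint", "other", "demographic", "other"),
    levels = list(NULL, NULL, NULL, c("female", "male"), c("low", "mid", "high")),
    units = c("joints", "joints", "mm VAS", "", "")
  )
}

toy_cohort_df <- function(n = 6) {
  data.frame(
    patient_id = paste0("P", seq_len(n)),
    tjc = seq_len(n) + 4,
    sjc = seq_len(n),
    pain = 10 * seq_len(n),
    sex = rep(c("female", "male"), length.out = n),
    severity = rep(c("low", "mid", "high"), length.out = n),
    stringsAsFactors = FALSE
  )
}

write_cohort_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}

# two well-separated 1-D Gaussian blobs as an encoded object
blob_encoded <- function(n_per = 30, sep = 20, sd = 1, seed = 1) {
  set.seed(seed)
  x <- c(rnorm(n_per, 0, sd), rnorm(n_per, sep * sd, sd))
  structure(list(
    x_cont = matrix(x, ncol = 1, dimnames = list(NULL, "x")),
    x_cat = matrix(integer(0), nrow = 2 * n_per, ncol = 0),
    cat_levels = list(),
    patient_id = sprintf("B%03d", seq_len(2 * n_per)),
    groups = c(x = "other")), class = "psa_encoded")
}

blob_truth <- function(n_per = 30) rep(1:2, each = n_per)

# minimal visit table for endpoint tests: one baseline + one follow-up row
# per patient, all components explicit
visit_rows <- function(patient_id, week, tjc68, sjc66, pain, patient_global,
                       physician_global, haq_di, facit_f, crp, bsa,
                       entheseal_points, missing_reason = "none") {
  data.frame(patient_id = patient_id, week = week, tjc68 = tjc68,
             sjc66 = sjc66, pain = pain, patient_global = patient_global,
             physician_global = physician_global, haq_di = haq_di,
             facit_f = facit_f, crp = crp, bsa = bsa,
             entheseal_points = entheseal_points,
             missing_reason = missing_reason, stringsAsFactors = FALSE)
}
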