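# Cohort ingestion, exclusion rules and model encoding.

#' Construct a cohort table
#'
#' Wraps a patient-level baseline table together with its schema after
#' validating every value against the declared feature kinds and levels.
#' Invalid cells are converted to the missing marker (`NA`) with a warning.
#'
#' @param data data frame with a `patient_id` column plus one column per
#'   schema feature.
#' @param schema a [feature_schema()].
#' @return A `psa_cohort`: list with elements `data` (validated data frame)
#'   and `schema`.
#' @export
cohort <- function(data, schema) {
  if (!inherits(schema, "psa_schema")) stop("schema must be a psa_schema")
  if (!"patient_id" %in% names(data)) stop("missing required id column 'patient_id'")
  ids <- as.character(data$patient_id)
  if (anyDuplicated(ids)) {
    stop("duplicated patient_id: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  extra <- setdiff(names(data), c("patient_id", schema$feature_name))
  if (length(extra)) stop("columns not in schema: ", paste(extra, collapse = ", "))
  absent <- setdiff(schema$feature_name, names(data))
  if (length(absent)) stop("schema features absent from data: ", paste(absent, collapse = ", "))

  out <- data.frame(patient_id = ids, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(schema))) {
    nm <- schema$feature_name[i]
    raw <- data[[nm]]
    if (schema$kind[i] == "continuous") {
      if (is.numeric(raw)) {
        val <- as.numeric(raw)
      } else {
        chr <- trimws(as.character(raw))
        chr[chr == ""] <- NA_character_
        val <- suppressWarnings(as.numeric(chr))
        bad <- !is.na(chr) & is.na(val)
        if (any(bad)) {
          warning(sum(bad), " unparseable value(s) in continuous feature '", nm,
                  "' set to missing", call. = FALSE)
        }
      }
    } else {
      lv <- schema$levels[[i]]
      chr <- trimws(as.character(raw))
      chr[chr == ""] <- NA_character_
      bad <- !is.na(chr) & !(chr %in% lv)
      if (any(bad)) {
        warning(sum(bad), " value(s) outside declared levels in feature '", nm,
                "' set to missing", call. = FALSE)
        chr[bad] <- NA_character_
      }
      val <- chr
    }
    out[[nm]] <- val
  }
  structure(list(data = out, schema = schema), class = "psa_cohort")
}

#' Load a baseline cohort table from CSV
#'
#' Reads a comma-separated UTF-8 file with a header row; the header must be
#' exactly `patient_id` plus the schema's feature names (any order). Cells
#' that cannot be parsed under the declared kind become missing markers with
#' a warning; a missing id column, an unknown column, or duplicated patient
#' ids are fatal.
#'
#' @param path path to the CSV file.
#' @param schema a [feature_schema()].
#' @return A `psa_cohort`.
#' @export
load_cohort <- function(path, schema) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         fileEncoding = "UTF-8")
  cohort(raw, schema)
}

#' Number of patients / features in a cohort
#' @param x a `psa_cohort`.
#' @return Integer count.
#' @export
n_patients <- function(x) nrow(x$data)

#' @rdname n_patients
#' @export
n_features <- function(x) nrow(x$schema)

#' @export
print.psa_cohort <- function(x, ...) {
  cat("PsA cohort:", n_patients(x), "patients,", n_features(x), "features\n")
  miss <- vapply(x$schema$feature_name, function(f) mean(is.na(x$data[[f]])), numeric(1))
  if (any(miss > 0)) {
    cat("  features with missing values:",
        paste(sprintf("%s (%.1f%%)", names(miss)[miss > 0], 100 * miss[miss > 0]),
              collapse = ", "), "\n")
  }
  invisible(x)
}

# numeric coding used only for the collinearity screen: continuous values
# pass through, categorical/binary become level indices
numeric_coding <- function(coh) {
  sch <- coh$schema
  m <- matrix(NA_real_, nrow = n_patients(coh), ncol = nrow(sch),
              dimnames = list(NULL, sch$feature_name))
  for (i in seq_len(nrow(sch))) {
    nm <- sch$feature_name[i]
    if (sch$kind[i] == "continuous") {
      m[, i] <- coh$data[[nm]]
    } else {
      m[, i] <- match(coh$data[[nm]], sch$levels[[i]])
    }
  }
  m
}

#' Screen features for excess missingness and collinearity
#'
#' Applies the two feature-level exclusion rules used before model fitting:
#' first any feature whose missing fraction (over all loaded patients)
#' exceeds `missing_threshold` is removed; then, among the remaining
#' features, pairs with absolute pairwise correlation (complete cases, on a
#' numeric coding) at or above `collinearity_threshold` are resolved by
#' dropping the feature that appears later in schema order.
#'
#' @param coh a `psa_cohort`.
#' @param missing_threshold maximum tolerated missing fraction (default 0.20).
#' @param collinearity_threshold absolute correlation at or above which the
#'   later feature of a pair is dropped (default 0.95).
#' @return List with `cohort` (features removed) and `report`, a
#'   `psa_exclusions` object listing each dropped feature with its single
#'   reason.
#' @export
apply_feature_exclusions <- function(coh, missing_threshold = 0.20,
                                     collinearity_threshold = 0.95) {
  stopifnot(inherits(coh, "psa_cohort"), n_patients(coh) > 0)
  sch <- coh$schema
  dropped <- data.frame(feature_name = character(0), reason = character(0),
                        stringsAsFactors = FALSE)

  miss <- vapply(sch$feature_name, function(f) mean(is.na(coh$data[[f]])), numeric(1))
  high <- sch$feature_name[miss > missing_threshold]
  for (f in high) {
    dropped <- rbind(dropped, data.frame(feature_name = f,
                                         reason = "missing_gt_threshold"))
  }

  keep <- setdiff(sch$feature_name, high)
  if (length(keep) >= 2L) {
    num <- numeric_coding(coh)[, keep, drop = FALSE]
    cc <- suppressWarnings(stats::cor(num, use = "pairwise.complete.obs"))
    cc[is.na(cc)] <- 0
    alive <- rep(TRUE, length(keep))
    for (i in seq_along(keep)) {
      if (!alive[i]) next
      for (j in seq_along(keep)) {
        if (j <= i || !alive[j]) next
        if (abs(cc[i, j]) >= collinearity_threshold) {
          alive[j] <- FALSE
          dropped <- rbind(dropped, data.frame(
            feature_name = keep[j],
            reason = paste0("collinear_with:", keep[i])))
        }
      }
    }
    keep <- keep[alive]
  }

  if (!length(keep)) {
    stop("all features excluded (thresholds: missing > ", missing_threshold,
         ", |r| >= ", collinearity_threshold, ")")
  }

  idx <- match(keep, sch$feature_name)
  new_sch <- sch[sort(idx), , drop = FALSE]
  class(new_sch) <- class(sch)
  new_coh <- structure(
    list(data = coh$data[, c("patient_id", new_sch$feature_name), drop = FALSE],
         schema = new_sch),
    class = "psa_cohort")
  report <- structure(
    list(dropped_features = dropped, dropped_patients = 0L,
         thresholds = list(missing = missing_threshold,
                           collinearity = collinearity_threshold)),
    class = "psa_exclusions")
  list(cohort = new_coh, report = report)
}

#' @export
print.psa_exclusions <- function(x, ...) {
  cat("Exclusion report:", nrow(x$dropped_features), "feature(s) dropped,",
      x$dropped_patients, "patient(s) dropped\n")
  if (nrow(x$dropped_features)) {
    for (i in seq_len(nrow(x$dropped_features))) {
      cat("  -", x$dropped_features$feature_name[i], "|",
          x$dropped_features$reason[i], "\n")
    }
  }
  invisible(x)
}

#' Serialize an exclusion report to JSON
#'
#' @param report a `psa_exclusions` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_exclusion_report <- function(report, path) {
  stopifnot(inherits(report, "psa_exclusions"))
  jsonlite::write_json(
    list(dropped_features = report$dropped_features,
         dropped_patients = report$dropped_patients,
         thresholds = report$thresholds),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Drop patients with any missing value on the final feature set
#'
#' Applied after [apply_feature_exclusions()]: a patient is removed if any
#' remaining feature is missing, so the model never sees incomplete rows.
#'
#' @param coh a `psa_cohort` with exclusions already applied.
#' @return List with `cohort` (complete rows only) and `n_dropped`.
#' @export
drop_incomplete_patients <- function(coh) {
  stopifnot(inherits(coh, "psa_cohort"))
  feat <- coh$schema$feature_name
  ok <- stats::complete.cases(coh$data[, feat, drop = FALSE])
  if (!any(ok)) stop("no complete patients remain")
  out <- coh
  out$data <- coh$data[ok, , drop = FALSE]
  rownames(out$data) <- NULL
  list(cohort = out, n_dropped = sum(!ok))
}

age_band_levels <- c("<=45", "45-65", ">65")
race_classes <- c("White", "Black/African American", "Asian", "multiple/others")

band_age <- function(age) {
  # 45 falls in the lowest band, 65 in the middle band, so bands partition
  ifelse(age <= 45, age_band_levels[1L],
         ifelse(age <= 65, age_band_levels[2L], age_band_levels[3L]))
}

collapse_race <- function(race) {
  ifelse(race %in% race_classes[1:3], race, race_classes[4L])
}

#' Encode a complete cohort for mixture modelling
#'
#' Produces the numeric representation consumed by [fit_em()]: continuous
#' features pass through; binary and categorical features become integer
#' level codes; a continuous feature named `age` is recoded to the three
#' bands `<=45`, `45-65`, `>65` (45 belongs to the first band, 65 to the
#' second); a categorical feature named `race` is collapsed to White,
#' Black/African American, Asian, and multiple/others.
#'
#' @param coh a complete `psa_cohort` (no missing values; run
#'   [drop_incomplete_patients()] first).
#' @param schema schema to encode against (defaults to the cohort's own).
#' @return A `psa_encoded`: list with `x_cont` (numeric matrix), `x_cat`
#'   (integer matrix of level codes), `cat_levels` (named list of level
#'   labels), `patient_id`, and `groups` (named character vector of feature
#'   groups for all encoded columns).
#' @export
encode_features <- function(coh, schema = coh$schema) {
  stopifnot(inherits(coh, "psa_cohort"))
  feat <- schema$feature_name
  if (any(is.na(coh$data[, feat]))) {
    stop("cohort has missing values; apply drop_incomplete_patients() first")
  }
  n <- n_patients(coh)
  cont <- list(); cat_codes <- list(); cat_levels <- list(); groups <- character(0)

  for (i in seq_len(nrow(schema))) {
    nm <- schema$feature_name[i]
    v <- coh$data[[nm]]
    if (schema$kind[i] == "continuous" && identical(nm, "age")) {
      lab <- band_age(as.numeric(v))
      cat_codes[[nm]] <- match(lab, age_band_levels)
      cat_levels[[nm]] <- age_band_levels
      groups[nm] <- schema$group[i]
    } else if (schema$kind[i] == "continuous") {
      cont[[nm]] <- as.numeric(v)
      groups[nm] <- schema$group[i]
    } else if (identical(nm, "race")) {
      lv <- schema$levels[[i]]
      if (!all(v %in% lv)) stop("race value outside schema levels")
      lab <- collapse_race(v)
      cat_codes[[nm]] <- match(lab, race_classes)
      cat_levels[[nm]] <- race_classes
      groups[nm] <- schema$group[i]
    } else {
      lv <- schema$levels[[i]]
      code <- match(v, lv)
      if (anyNA(code)) stop("value outside schema levels in feature '", nm, "'")
      cat_codes[[nm]] <- code
      cat_levels[[nm]] <- lv
      groups[nm] <- schema$group[i]
    }
  }

  x_cont <- if (length(cont)) do.call(cbind, cont) else matrix(numeric(0), nrow = n, ncol = 0)
  x_cat <- if (length(cat_codes)) do.call(cbind, cat_codes) else matrix(integer(0), nrow = n, ncol = 0)
  structure(list(x_cont = x_cont, x_cat = x_cat, cat_levels = cat_levels,
                 patient_id = coh$data$patient_id, groups = groups),
            class = "psa_encoded")
}

#' @export
print.psa_encoded <- function(x, ...) {
  cat("Encoded cohort:", length(x$patient_id), "patients;",
      ncol(x$x_cont), "continuous and", ncol(x$x_cat), "categorical features\n")
  invisible(x)
}
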