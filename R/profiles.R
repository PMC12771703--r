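# Per-phenotype descriptive profiles and the cluster-ordered heatmap layout.

#' Per-cluster descriptive profile of baseline features
#'
#' Produces a table-one style summary stratified by cluster: cluster sizes
#' and cohort percentages; mean (SD, n) per continuous feature; n (%) per
#' level of each categorical feature. `conditional_specs` restricts
#' designated continuous features to patients positive on a paired
#' indicator before computing the mean — e.g. a dactylitis joint count
#' summarised only over patients with dactylitis. A condition met by no
#' patient in a cluster yields an absent (`NA`) statistic, never 0; an
#' empty cluster is emitted with n = 0 and absent statistics.
#'
#' @param coh a `psa_cohort`.
#' @param labels integer cluster labels aligned with the cohort rows.
#' @param conditional_specs optional list of specs
#'   `list(feature =, indicator =, positive_level = NULL)`: the feature is
#'   summarised over patients whose `indicator` feature equals
#'   `positive_level` (categorical) or is `> 0` (continuous).
#' @return A `psa_profile`: list with `clusters` (data frame of n, pct),
#'   `continuous` (cluster x feature mean/sd/n), `categorical` (cluster x
#'   feature x level n/pct), `conditional_specs`.
#' @export
cluster_profile <- function(coh, labels, conditional_specs = NULL) {
  stopifnot(inherits(coh, "psa_cohort"))
  n <- n_patients(coh)
  if (length(labels) != n) stop("labels must align with cohort rows")
  sch <- coh$schema
  clusters <- sort(unique(labels))
  sizes <- data.frame(cluster = clusters,
                      n = vapply(clusters, function(k) sum(labels == k), integer(1)))
  sizes$pct <- 100 * sizes$n / n

  cond_for <- function(feature) {
    if (is.null(conditional_specs)) return(NULL)
    for (sp in conditional_specs) if (identical(sp$feature, feature)) return(sp)
    NULL
  }
  cond_mask <- function(sp) {
    ind <- coh$data[[sp$indicator]]
    i <- match(sp$indicator, sch$feature_name)
    if (sch$kind[i] == "continuous") {
      !is.na(ind) & as.numeric(ind) > 0
    } else {
      pos <- sp$positive_level %||% utils::tail(sch$levels[[i]], 1)
      !is.na(ind) & ind == pos
    }
  }

  cont_rows <- list(); cat_rows <- list()
  for (i in seq_len(nrow(sch))) {
    nm <- sch$feature_name[i]
    v <- coh$data[[nm]]
    if (sch$kind[i] == "continuous") {
      sp <- cond_for(nm)
      mask <- if (is.null(sp)) rep(TRUE, n) else cond_mask(sp)
      for (k in clusters) {
        sel <- labels == k & mask & !is.na(v)
        m <- sum(sel)
        cont_rows[[length(cont_rows) + 1L]] <- data.frame(
          cluster = k, feature = nm, n = m,
          mean = if (m) mean(as.numeric(v[sel])) else NA_real_,
          sd = if (m > 1) stats::sd(as.numeric(v[sel])) else NA_real_,
          conditional = !is.null(sp))
      }
    } else {
      lv <- sch$levels[[i]]
      for (k in clusters) {
        sel <- labels == k & !is.na(v)
        denom <- sum(sel)
        for (l in lv) {
          cnt <- sum(v[sel] == l)
          cat_rows[[length(cat_rows) + 1L]] <- data.frame(
            cluster = k, feature = nm, level = l, n = cnt,
            pct = if (denom) 100 * cnt / denom else NA_real_)
        }
      }
    }
  }
  structure(list(clusters = sizes,
                 continuous = if (length(cont_rows)) do.call(rbind, cont_rows) else NULL,
                 categorical = if (length(cat_rows)) do.call(rbind, cat_rows) else NULL,
                 conditional_specs = conditional_specs),
            class = "psa_profile")
}

#' @export
print.psa_profile <- function(x, ...) {
  cat("Phenotype profile:", nrow(x$clusters), "clusters\n")
  for (i in seq_len(nrow(x$clusters))) {
    cat(sprintf("  cluster %s: n = %d (%.1f%%)\n", x$clusters$cluster[i],
                x$clusters$n[i], x$clusters$pct[i]))
  }
  if (!is.null(x$continuous)) {
    cat("continuous features, mean (SD):\n")
    for (f in unique(x$continuous$feature)) {
      sub <- x$continuous[x$continuous$feature == f, ]
      cat(sprintf("  %-18s %s\n", f,
                  paste(ifelse(is.na(sub$mean), "-",
                               sprintf("%.1f (%.1f)", sub$mean, sub$sd)),
                        collapse = "  ")))
    }
  }
  invisible(x)
}

#' Serialize a phenotype profile to JSON (full precision)
#'
#' @param profile a `psa_profile`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "psa_profile"))
  jsonlite::write_json(
    list(clusters = profile$clusters, continuous = profile$continuous,
         categorical = profile$categorical),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read back a serialized phenotype profile
#' @param path JSON file written by [write_profile()].
#' @return A `psa_profile` (without conditional specs).
#' @export
read_profile <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(clusters = as.data.frame(x$clusters),
                 continuous = if (is.null(x$continuous)) NULL else as.data.frame(x$continuous),
                 categorical = if (is.null(x$categorical)) NULL else as.data.frame(x$categorical),
                 conditional_specs = NULL),
            class = "psa_profile")
}

#' Patient and feature ordering for a cluster heatmap
#'
#' Patients are ordered by cluster label, and within a cluster by
#' descending posterior responsibility for their own cluster. Features are
#' ordered by clinical group in the canonical order (tender-joint,
#' swollen-joint, psoriasis, dactylitis, enthesitis, other, demographic),
#' then alphabetically by name within a group.
#'
#' @param coh a `psa_cohort`.
#' @param labels integer cluster labels aligned with cohort rows.
#' @param responsibilities n x K posterior membership matrix aligned with
#'   cohort rows.
#' @param schema schema to order features from (defaults to the cohort's).
#' @return List with `patients` (permutation of row indices) and `features`
#'   (feature names in display order).
#' @export
heatmap_order <- function(coh, labels, responsibilities, schema = coh$schema) {
  n <- n_patients(coh)
  stopifnot(length(labels) == n, nrow(responsibilities) == n)
  own <- responsibilities[cbind(seq_len(n), labels)]
  patients <- order(labels, -own)
  grp <- factor(schema$group, levels = feature_groups())
  features <- schema$feature_name[order(grp, schema$feature_name)]
  list(patients = patients, features = features)
}
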