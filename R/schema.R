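# Feature schema: the declared contract for every baseline feature.

#' Clinical feature groups, in display order
#'
#' The canonical grouping of baseline features used for heatmap layout:
#' tender-joint, swollen-joint, psoriasis, dactylitis, enthesitis, other,
#' and demographic.
#'
#' @return Character vector of group names in canonical order.
#' @export
feature_groups <- function() {
  c("tender-joint", "swollen-joint", "psoriasis", "dactylitis",
    "enthesitis", "other", "demographic")
}

#' Construct a feature schema
#'
#' A schema declares, for every baseline feature, its name, measurement kind,
#' admissible levels (categorical/binary), clinical group and units. All
#' cohort ingestion, encoding and profiling is driven by the schema; nothing
#' is inferred from the data.
#'
#' @param feature_name character vector of unique feature names.
#' @param kind character vector, each one of `"continuous"`, `"binary"`,
#'   `"categorical"`.
#' @param group character vector of clinical groups; see [feature_groups()].
#' @param levels list of character vectors giving the ordered admissible
#'   levels for binary/categorical features (`NULL` entries for continuous).
#' @param units character vector of free-text units (optional).
#' @return A `psa_schema` data frame with one row per feature.
#' @examples
#' feature_schema(
#'   feature_name = c("tjc", "sex"),
#'   kind = c("continuous", "binary"),
#'   group = c("tender-joint", "demographic"),
#'   levels = list(NULL, c("female", "male"))
#' )
#' @export
feature_schema <- function(feature_name, kind, group,
                           levels = vector("list", length(feature_name)),
                           units = rep("", length(feature_name))) {
  feature_name <- as.character(feature_name)
  kind <- as.character(kind)
  group <- as.character(group)
  n <- length(feature_name)
  if (length(kind) != n || length(group) != n || length(levels) != n ||
      length(units) != n) {
    stop("feature_name, kind, group, levels and units must have equal length")
  }
  if (anyDuplicated(feature_name)) {
    stop("feature names must be unique: ",
         paste(unique(feature_name[duplicated(feature_name)]), collapse = ", "))
  }
  bad_kind <- setdiff(kind, c("continuous", "binary", "categorical"))
  if (length(bad_kind)) stop("unknown feature kind: ", paste(bad_kind, collapse = ", "))
  bad_group <- setdiff(group, feature_groups())
  if (length(bad_group)) stop("unknown feature group: ", paste(bad_group, collapse = ", "))
  for (i in seq_len(n)) {
    lv <- levels[[i]]
    if (kind[i] == "continuous") {
      if (!is.null(lv)) stop("continuous feature '", feature_name[i], "' must not declare levels")
    } else {
      if (is.null(lv) || length(lv) < 2L) {
        stop("feature '", feature_name[i], "' needs >= 2 levels")
      }
      if (kind[i] == "binary" && length(lv) != 2L) {
        stop("binary feature '", feature_name[i], "' needs exactly 2 levels")
      }
      if (anyDuplicated(lv)) stop("duplicate levels in feature '", feature_name[i], "'")
      levels[[i]] <- as.character(lv)
    }
  }
  out <- data.frame(feature_name = feature_name, kind = kind, group = group,
                    units = as.character(units), stringsAsFactors = FALSE)
  out$levels <- levels
  class(out) <- c("psa_schema", "data.frame")
  out
}

#' Read a feature schema from a YAML or JSON config file
#'
#' The file holds a top-level `features` list; each element has `name`,
#' `kind`, `group`, and (for binary/categorical features) `levels`, plus an
#' optional `units` string.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` schema file.
#' @return A `psa_schema`, as from [feature_schema()].
#' @export
read_schema <- function(path) {
  if (!file.exists(path)) stop("schema file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  feats <- cfg$features
  if (is.null(feats) || !length(feats)) stop("schema file declares no features")
  feature_schema(
    feature_name = vapply(feats, function(f) f$name, character(1)),
    kind = vapply(feats, function(f) f$kind, character(1)),
    group = vapply(feats, function(f) f$group, character(1)),
    levels = lapply(feats, function(f) if (is.null(f$levels)) NULL else unlist(f$levels)),
    units = vapply(feats, function(f) if (is.null(f$units)) "" else f$units, character(1))
  )
}

schema_levels <- function(schema, feature) {
  schema$levels[[match(feature, schema$feature_name)]]
}

#' @export
print.psa_schema <- function(x, ...) {
  cat("Feature schema:", nrow(x), "features\n")
  for (i in seq_len(nrow(x))) {
    lv <- x$levels[[i]]
    cat(sprintf("  %-24s %-11s %-13s%s\n", x$feature_name[i], x$kind[i],
                x$group[i],
                if (is.null(lv)) "" else paste0(" {", paste(lv, collapse = ", "), "}")))
  }
  invisible(x)
}
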