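#' Declare a single plan feature
#'
#' A feature spec describes one named parameter extracted from a treatment
#' plan, how many per-field slots it occupies, and whether its values are
#' continuous reals or categorical levels.
#'
#' @param name feature identifier (letters, digits, underscore).
#' @param field_group which delivery fields carry the feature: `"IMRT"`,
#'   `"tangent"`, or `"both"`.
#' @param per_field_count number of raw feature slots (one per field).
#' @param value_kind `"continuous"` or `"categorical"`.
#' @param unit free-text unit label (`"cm"`, `"degree"`, `"MU"`, `"count"`).
#' @param levels ordered character vector of allowed category labels
#'   (categorical features only, at least two).
#' @return an object of class `feature_spec`.
#' @export
feature_spec <- function(name,
                         field_group = c("both", "IMRT", "tangent"),
                         per_field_count = 4L,
                         value_kind = c("continuous", "categorical"),
                         unit = "",
                         levels = NULL) {
  field_group <- match.arg(field_group)
  value_kind <- match.arg(value_kind)
  stopifnot(is_string(name), grepl("^[A-Za-z][A-Za-z0-9_]*$", name))
  per_field_count <- as.integer(per_field_count)
  if (is.na(per_field_count) || per_field_count < 1L) {
    stop("per_field_count must be a positive integer")
  }
  if (value_kind == "categorical") {
    levels <- as.character(levels)
    if (length(levels) < 2L || anyDuplicated(levels)) {
      stop(sprintf("categorical feature '%s' needs >= 2 distinct levels", name))
    }
  } else if (!is.null(levels)) {
    stop(sprintf("continuous feature '%s' must not declare levels", name))
  }
  structure(
    list(name = name, field_group = field_group,
         per_field_count = per_field_count, value_kind = value_kind,
         unit = unit, levels = levels),
    class = "feature_spec"
  )
}

#' Assemble feature specs into a schema
#'
#' @param specs list of [feature_spec()] objects; order defines the raw
#'   column order of plan tables.
#' @return an object of class `feature_schema`.
#' @export
feature_schema <- function(specs) {
  if (inherits(specs, "feature_spec")) specs <- list(specs)
  stopifnot(length(specs) >= 1L,
            all(vapply(specs, inherits, logical(1), "feature_spec")))
  nms <- vapply(specs, `[[`, character(1), "name")
  if (anyDuplicated(nms)) {
    stop("feature names must be unique within a schema: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  structure(list(specs = specs), class = "feature_schema")
}

#' Total number of raw feature slots in a schema
#' @param schema a [feature_schema()].
#' @return integer, the sum of per-field counts.
#' @export
raw_feature_count <- function(schema) {
  stopifnot(inherits(schema, "feature_schema"))
  sum(vapply(schema$specs, `[[`, integer(1), "per_field_count"))
}

#' Raw column names of a schema
#'
#' Columns are named `<feature>_f<k>` with field slots ordered IMRT1,
#' IMRT2, tangent1, tangent2 (features with fewer slots use the leading
#' indices of that order).
#' @param schema a [feature_schema()].
#' @return character vector of length [raw_feature_count()].
#' @export
schema_columns <- function(schema) {
  stopifnot(inherits(schema, "feature_schema"))
  unlist(lapply(schema$specs, function(sp) {
    paste0(sp$name, "_f", seq_len(sp$per_field_count))
  }), use.names = FALSE)
}

# one row per raw column: feature, slot, kind, unit
schema_slots <- function(schema) {
  do.call(rbind, lapply(schema$specs, function(sp) {
    data.frame(column = paste0(sp$name, "_f", seq_len(sp$per_field_count)),
               feature = sp$name, slot = seq_len(sp$per_field_count),
               kind = sp$value_kind, unit = sp$unit,
               stringsAsFactors = FALSE)
  }))
}

schema_spec <- function(schema, name) {
  for (sp in schema$specs) if (sp$name == name) return(sp)
  stop("no feature named '", name, "' in schema")
}

schema_fingerprint <- function(schema) {
  poly_fingerprint(unlist(lapply(schema$specs, function(sp) {
    c(sp$name, sp$field_group, sp$per_field_count, sp$value_kind,
      sp$unit, sp$levels)
  })))
}

# Protocol grids shared by the default schema and the synthetic generator.
# Gantry angles live on a 30-degree grid; IMRT segment counts are small
# integers with the institutional protocol accepting 4..7.
gantry_levels_default <- function() as.character(seq(0L, 330L, by = 30L))
segment_levels_default <- function() as.character(1:10)

#' Default breast-plan feature schema
#'
#' Eight features over four delivery fields (two IMRT, two tangent):
#' per-IMRT-field segment counts, and per-field SSD, the four collimator
#' jaw positions, gantry angle and monitor units, for 30 raw feature slots
#' in total. Gantry angle and segment count are categorical (protocol
#' level sets); the remaining features are continuous.
#'
#' @return a `feature_schema` with 8 specs and raw feature total 30.
#' @export
#' @examples
#' sch <- default_schema()
#' raw_feature_count(sch)  # 30
default_schema <- function() {
  feature_schema(list(
    feature_spec("segments", "IMRT", 2L, "categorical", unit = "count",
                 levels = segment_levels_default()),
    feature_spec("ssd", "both", 4L, "continuous", unit = "cm"),
    feature_spec("collx1", "both", 4L, "continuous", unit = "cm"),
    feature_spec("collx2", "both", 4L, "continuous", unit = "cm"),
    feature_spec("colly1", "both", 4L, "continuous", unit = "cm"),
    feature_spec("colly2", "both", 4L, "continuous", unit = "cm"),
    feature_spec("gantry", "both", 4L, "categorical", unit = "degree",
                 levels = gantry_levels_default()),
    feature_spec("meterset", "both", 4L, "continuous", unit = "MU")
  ))
}

#' @export
print.feature_schema <- function(x, ...) {
  cat(sprintf("<feature_schema> %d features, %d raw columns\n",
              length(x$specs), raw_feature_count(x)))
  for (sp in x$specs) {
    lev <- if (sp$value_kind == "categorical") {
      sprintf(" [%d levels]", length(sp$levels))
    } else ""
    cat(sprintf("  %-10s %-8s x%d %-12s %s%s\n", sp$name, sp$field_group,
                sp$per_field_count, sp$value_kind, sp$unit, lev))
  }
  invisible(x)
}

#' Construct a plan table
#'
#' A plan table holds one row per treatment plan in the raw (pre-encoding)
#' column layout of a schema, with optional ground-truth labels and plan
#' identifiers.
#'
#' @param data data.frame with the columns of [schema_columns()].
#' @param schema the [feature_schema()] the rows must conform to.
#' @param labels optional per-plan labels; accepted encodings are
#'   logical (`TRUE` = abnormal), 0/1, or the strings
#'   `"normal"`/`"abnormal"`.
#' @param ids optional character plan identifiers.
#' @param validate check values against the schema (default `TRUE`).
#' @return an object of class `plan_table`.
#' @export
plan_table <- function(data, schema, labels = NULL, ids = NULL,
                       validate = TRUE) {
  stopifnot(is.data.frame(data), inherits(schema, "feature_schema"))
  cols <- schema_columns(schema)
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0L) {
    stop_planomaly(
      paste0("plan table does not match schema; missing column(s): ",
             paste(missing, collapse = ", ")),
      "planomaly_schema_mismatch")
  }
  data <- data[, cols, drop = FALSE]
  if (!is.null(labels)) {
    labels <- normalize_labels(labels)
    if (length(labels) != nrow(data)) {
      stop("labels must have one entry per plan record")
    }
  }
  if (!is.null(ids)) {
    ids <- as.character(ids)
    stopifnot(length(ids) == nrow(data))
  }
  out <- structure(
    list(data = data, schema = schema, labels = labels, ids = ids),
    class = "plan_table"
  )
  if (validate) validate_plan_table(out)
  out
}

#' @export
print.plan_table <- function(x, ...) {
  cat(sprintf("<plan_table> %d plans x %d raw features%s\n",
              nrow(x$data), ncol(x$data),
              if (is.null(x$labels)) "" else
                sprintf(" (%d abnormal)", sum(x$labels == "abnormal"))))
  invisible(x)
}

#' Number of plans in a plan table
#' @param x a `plan_table`.
#' @export
n_plans <- function(x) {
  stopifnot(inherits(x, "plan_table"))
  nrow(x$data)
}

# Map any accepted label encoding onto factor(normal, abnormal).
normalize_labels <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.logical(labels)) {
    labels <- ifelse(labels, "abnormal", "normal")
  } else if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) {
      stop("numeric labels must be 0 (normal) or 1 (abnormal)")
    }
    labels <- ifelse(labels == 1, "abnormal", "normal")
  } else if (is.character(labels)) {
    if (!all(labels %in% c("normal", "abnormal"))) {
      stop("character labels must be 'normal' or 'abnormal'")
    }
  } else {
    stop("unsupported label encoding")
  }
  factor(labels, levels = c("normal", "abnormal"))
}

label_is_abnormal <- function(labels) {
  normalize_labels(labels) == "abnormal"
}

#' Validate a plan table against its schema
#'
#' Checks column presence, numeric parseability of continuous cells and
#' level membership of categorical cells. All offending cells are
#' collected and reported with row/column locations before erroring.
#'
#' @param table a [plan_table()].
#' @return the table, invisibly, if valid.
#' @export
validate_plan_table <- function(table) {
  stopifnot(inherits(table, "plan_table"))
  schema <- table$schema
  data <- table$data
  problems <- character(0)
  for (sp in schema$specs) {
    for (k in seq_len(sp$per_field_count)) {
      col <- paste0(sp$name, "_f", k)
      v <- data[[col]]
      if (sp$value_kind == "continuous") {
        num <- suppressWarnings(as.numeric(v))
        bad <- which(!is.finite(num))
        if (length(bad) > 0L) {
          problems <- c(problems, sprintf(
            "column '%s': non-numeric value(s) at row(s) %s", col,
            paste(utils::head(bad, 5), collapse = ", ")))
        }
      } else {
        v <- as.character(v)
        bad <- which(!(v %in% sp$levels))
        if (length(bad) > 0L) {
          offenders <- unique(v[bad])
          problems <- c(problems, sprintf(
            "column '%s': value(s) outside declared levels {%s} at row(s) %s: %s",
            col, paste(sp$levels, collapse = ","),
            paste(utils::head(bad, 5), collapse = ", "),
            paste(utils::head(offenders, 5), collapse = ", ")))
        }
      }
    }
  }
  if (length(problems) > 0L) {
    stop_planomaly(
      paste0("plan table failed validation:\n  ",
             paste(problems, collapse = "\n  ")),
      "planomaly_validation_error")
  }
  invisible(table)
}

#' Read a plan table from CSV or JSON
#'
#' CSV files carry one header row and one plan per row; JSON files carry a
#' list of objects keyed by the same column names. An optional `plan_id`
#' column supplies identifiers and an optional `is_abnormal` column
#' (0/1, logical, or normal/abnormal) supplies ground-truth labels.
#'
#' @param source path to the file.
#' @param schema the [feature_schema()] rows must conform to.
#' @param format `"csv"` or `"json"`; inferred from the file extension
#'   when omitted.
#' @return a [plan_table()].
#' @export
load_plan_table <- function(source, schema, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", source, ignore.case = TRUE)) "json" else "csv"
  }
  if (!file.exists(source)) stop("file not found: ", source)
  raw <- switch(format,
    csv = utils::read.csv(source, stringsAsFactors = FALSE,
                          check.names = FALSE, colClasses = "character"),
    json = {
      x <- jsonlite::fromJSON(source, simplifyVector = TRUE)
      as.data.frame(x, stringsAsFactors = FALSE, check.names = FALSE)
    })
  labels <- NULL
  ids <- NULL
  if ("is_abnormal" %in% names(raw)) {
    lab_raw <- raw[["is_abnormal"]]
    if (is.character(lab_raw) && all(lab_raw %in% c("0", "1"))) {
      lab_raw <- as.numeric(lab_raw)
    }
    labels <- normalize_labels(lab_raw)
  }
  if ("plan_id" %in% names(raw)) ids <- as.character(raw[["plan_id"]])
  cols <- schema_columns(schema)
  missing <- setdiff(cols, names(raw))
  if (length(missing) > 0L) {
    stop_planomaly(
      paste0("input does not match schema; missing column(s): ",
             paste(missing, collapse = ", ")),
      "planomaly_schema_mismatch")
  }
  data <- raw[, cols, drop = FALSE]
  slots <- schema_slots(schema)
  for (i in seq_len(nrow(slots))) {
    col <- slots$column[i]
    if (slots$kind[i] == "continuous") {
      data[[col]] <- suppressWarnings(as.numeric(data[[col]]))
    } else {
      data[[col]] <- as.character(data[[col]])
    }
  }
  plan_table(data, schema, labels = labels, ids = ids, validate = TRUE)
}

#' Write a plan table to CSV or JSON
#'
#' @param table a [plan_table()].
#' @param path output file path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_plan_table <- function(table, path, format = c("csv", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(table, "plan_table"))
  out <- table$data
  if (!is.null(table$ids)) out <- cbind(plan_id = table$ids, out)
  if (!is.null(table$labels)) {
    out$is_abnormal <- as.integer(table$labels == "abnormal")
  }
  if (format == "csv") {
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(out, path, dataframe = "rows", digits = NA)
  }
  invisible(path)
}

#' Serialize a feature schema to disk
#'
#' JSON is the primary format; `.yaml`/`.yml` paths are written with the
#' optional `yaml` package when installed.
#' @param schema a [feature_schema()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_schema <- function(schema, path) {
  stopifnot(inherits(schema, "feature_schema"))
  obj <- lapply(schema$specs, function(sp) {
    sp["levels"] <- list(sp$levels)  # keep NULL explicit
    unclass(sp)
  })
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("writing YAML schemas requires the 'yaml' package; use .json")
    }
    yaml::write_yaml(obj, path)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, null = "null",
                         pretty = TRUE)
  }
  invisible(path)
}

#' Read a feature schema written by [write_schema()]
#' @param path schema file (JSON or YAML).
#' @return a [feature_schema()].
#' @export
read_schema <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML schemas requires the 'yaml' package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  }
  feature_schema(lapply(obj, function(sp) {
    feature_spec(sp$name, sp$field_group, sp$per_field_count,
                 sp$value_kind, sp$unit %||% "",
                 levels = if (length(sp$levels)) unlist(sp$levels))
  }))
}
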