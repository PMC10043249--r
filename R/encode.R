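#' One-hot encode a categorical value
#'
#' @param value a single level label.
#' @param levels ordered character vector of allowed levels.
#' @return a 0/1 integer vector of length `length(levels)` with a single 1
#'   at the position of `value`.
#' @export
#' @examples
#' one_hot_encode("tangent", c("IMRT", "tangent"))  # c(0, 1)
one_hot_encode <- function(value, levels) {
  value <- as.character(value)
  levels <- as.character(levels)
  stopifnot(length(value) == 1L)
  idx <- match(value, levels)
  if (is.na(idx)) {
    stop_planomaly(
      sprintf("value '%s' is not among the declared levels {%s}",
              value, paste(levels, collapse = ", ")),
      "planomaly_validation_error")
  }
  out <- integer(length(levels))
  out[idx] <- 1L
  out
}

# The dimension mask is the bookkeeping that lets the composite loss route
# one-hot (binary) columns to BCE and continuous columns to MSE: one row
# per encoded column with its kind and raw-feature back-reference.
make_dim_mask <- function(schema) {
  rows <- lapply(schema$specs, function(sp) {
    do.call(rbind, lapply(seq_len(sp$per_field_count), function(k) {
      raw <- paste0(sp$name, "_f", k)
      if (sp$value_kind == "continuous") {
        data.frame(column = raw, kind = "continuous", feature = sp$name,
                   slot = k, level = NA_character_, stringsAsFactors = FALSE)
      } else {
        data.frame(column = paste0(raw, "=", sp$levels), kind = "binary",
                   feature = sp$name, slot = k, level = sp$levels,
                   stringsAsFactors = FALSE)
      }
    }))
  })
  mask <- do.call(rbind, rows)
  rownames(mask) <- NULL
  class(mask) <- c("dim_mask", "data.frame")
  mask
}

#' @export
print.dim_mask <- function(x, ...) {
  cat(sprintf("<dim_mask> %d encoded columns (%d binary, %d continuous)\n",
              nrow(x), sum(x$kind == "binary"), sum(x$kind == "continuous")))
  invisible(x)
}

mask_fingerprint <- function(mask) {
  poly_fingerprint(c(mask$column, mask$kind))
}

#' Encode a plan table into the mixed binary/continuous design matrix
#'
#' Continuous features occupy one column each (optionally rescaled);
#' each categorical feature slot expands into a contiguous one-hot block,
#' one binary column per level. The result is the numeric matrix consumed
#' by the autoencoder and the baseline detectors, together with the
#' dimension mask that distinguishes binary from continuous columns and a
#' scaler state enabling exact inverse transforms.
#'
#' @param table a [plan_table()].
#' @param scale scaling applied to continuous columns: `"minmax"`
#'   (default; maps the observed range onto `[0, 1]`), `"zscore"`, or
#'   `"none"` (values kept as obtained).
#' @return an object of class `encoded_matrix` with elements `values`
#'   (plans x encoded dims), `mask` (the dimension mask), `scaler`, and
#'   the source labels/ids carried through.
#' @export
encode_table <- function(table, scale = c("minmax", "none", "zscore")) {
  scale <- match.arg(scale)
  stopifnot(inherits(table, "plan_table"))
  if (nrow(table$data) == 0L) stop("cannot encode an empty plan table")
  validate_plan_table(table)
  schema <- table$schema
  mask <- make_dim_mask(schema)
  n <- nrow(table$data)
  values <- matrix(0, nrow = n, ncol = nrow(mask),
                   dimnames = list(NULL, mask$column))
  scaler <- data.frame(column = character(0), center = numeric(0),
                       scale = numeric(0), stringsAsFactors = FALSE)
  for (sp in schema$specs) {
    for (k in seq_len(sp$per_field_count)) {
      raw <- paste0(sp$name, "_f", k)
      v <- table$data[[raw]]
      if (sp$value_kind == "continuous") {
        x <- as.numeric(v)
        cs <- c(0, 1)
        if (scale == "minmax") {
          rng <- range(x)
          if (diff(rng) == 0) {
            # constant column: leave centred at 0, unit scale
            cs <- c(rng[1], 1)
          } else {
            cs <- c(rng[1], diff(rng))
          }
        } else if (scale == "zscore") {
          s <- stats::sd(x)
          if (!is.finite(s) || s == 0) {
            warning(sprintf(
              "column '%s' is constant; passed through unscaled", raw))
            cs <- c(0, 1)
          } else {
            cs <- c(mean(x), s)
          }
        }
        values[, raw] <- (x - cs[1]) / cs[2]
        scaler <- rbind(scaler, data.frame(column = raw, center = cs[1],
                                           scale = cs[2]))
      } else {
        v <- as.character(v)
        idx <- match(v, sp$levels)
        block <- matrix(0, nrow = n, ncol = length(sp$levels))
        block[cbind(seq_len(n), idx)] <- 1
        values[, paste0(raw, "=", sp$levels)] <- block
      }
    }
  }
  structure(
    list(values = values, mask = mask, scaler = list(method = scale,
                                                     params = scaler),
         labels = table$labels, ids = table$ids,
         schema = schema, fingerprint = mask_fingerprint(mask)),
    class = "encoded_matrix")
}

#' @export
print.encoded_matrix <- function(x, ...) {
  cat(sprintf("<encoded_matrix> %d plans x %d dims (%d binary, %d continuous), scale=%s\n",
              nrow(x$values), ncol(x$values), sum(x$mask$kind == "binary"),
              sum(x$mask$kind == "continuous"), x$scaler$method))
  invisible(x)
}

#' Number of encoded dimensions
#' @param x an `encoded_matrix`.
#' @export
n_dims <- function(x) {
  stopifnot(inherits(x, "encoded_matrix"))
  ncol(x$values)
}

#' Decode an encoded matrix back to a raw plan table
#'
#' One-hot blocks are decoded by arg-max; continuous columns are passed
#' through the inverse of the recorded scaler. Useful for round-trip
#' checking and for materialising reconstructed plans.
#'
#' @param encoded an `encoded_matrix` (or a plain numeric matrix plus the
#'   `mask`/`scaler`/`schema` of one, via `template`).
#' @param values optional replacement value matrix with the same columns
#'   (e.g. an autoencoder reconstruction).
#' @return a [plan_table()].
#' @export
decode_table <- function(encoded, values = NULL) {
  stopifnot(inherits(encoded, "encoded_matrix"))
  M <- values %||% encoded$values
  stopifnot(ncol(M) == nrow(encoded$mask))
  schema <- encoded$schema
  n <- nrow(M)
  out <- list()
  sc <- encoded$scaler$params
  for (sp in schema$specs) {
    for (k in seq_len(sp$per_field_count)) {
      raw <- paste0(sp$name, "_f", k)
      if (sp$value_kind == "continuous") {
        j <- match(raw, encoded$mask$column)
        p <- sc[sc$column == raw, ]
        out[[raw]] <- M[, j] * p$scale + p$center
      } else {
        jj <- which(encoded$mask$feature == sp$name & encoded$mask$slot == k)
        block <- M[, jj, drop = FALSE]
        out[[raw]] <- sp$levels[max.col(block, ties.method = "first")]
      }
    }
  }
  plan_table(as.data.frame(out, stringsAsFactors = FALSE), schema,
             labels = encoded$labels, ids = encoded$ids, validate = FALSE)
}
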