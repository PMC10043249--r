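#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Polynomial text fingerprint
#'
#' Cheap deterministic 31-adic rolling hash used to fingerprint schemas,
#' dimension masks and generator configs (not cryptographic).
#' @param x character vector; elements are concatenated before hashing.
#' @return a single hexadecimal string.
#' @keywords internal
poly_fingerprint <- function(x) {
  s <- paste(x, collapse = "")
  bytes <- utf8ToInt(s)
  h <- 0
  m <- 2^31 - 1
  for (b in bytes) h <- (h * 31 + b) %% m
  sprintf("%08x", as.integer(h))
}

# Truncated normal draw by rejection; falls back to clipping after
# `max_tries` so a pathological (mean, sd, lo, hi) cannot hang generation.
rtrunc_norm <- function(n, mean, sd, lo = -Inf, hi = Inf, max_tries = 100L) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  tries <- 0L
  while (length(bad) > 0L && tries < max_tries) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x < lo | x > hi)
    tries <- tries + 1L
  }
  clamp(x, lo, hi)
}

# Derive a child seed from a user seed; stays inside 32-bit integer range.
derive_seed <- function(seed, offset = 0L) {
  as.integer((as.numeric(seed) + 1664525 * as.numeric(offset)) %% 2147483647)
}

stop_planomaly <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "planomaly_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

read_config_file <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the 'yaml' package; use JSON instead")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
}
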