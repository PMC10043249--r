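#' Institutional protocol preset for synthetic plan generation
#'
#' States the protocol the generator emulates: a four-field breast plan
#' (two IMRT fields then two tangent fields) prescribed at 290 MU per
#' IMRT field and 200 MU per tangent field, SSD near 100 cm, jaw
#' positions in rectangular ranges with correlated within-plan noise,
#' gantry angles on a 30-degree grid placed as an equally spaced beam
#' arrangement, and 4 to 7 segments per IMRT field.
#'
#' @param imrt_mu_mean,tangent_mu_mean protocol monitor units per field
#'   type (MU).
#' @param mu_sd MU standard deviation around the protocol value
#'   (truncated at 4 sd).
#' @param mu_pair_correlation correlation of the two MU values within a
#'   field-type pair (opposed tangent beams and the paired IMRT beams
#'   deliver the same prescription, so their MU track each other).
#' @param ssd_mean,ssd_sd source-to-skin distance mean and sd (cm,
#'   truncated at 4 sd).
#' @param ssd_field_correlation correlation of SSD across the four
#'   fields of one plan (shared patient setup).
#' @param jaw_means,jaw_sds named per-jaw (collx1, collx2, colly1,
#'   colly2) position means and sds in cm.
#' @param jaw_position_ranges named list of allowed cm intervals per jaw.
#' @param gantry_levels allowed gantry angles (degrees, the categorical
#'   level grid).
#' @param gantry_start_levels protocol starting angles for the beam
#'   arrangement (two lateralities with two standard starts each; the
#'   remaining beams follow at the equal spacing).
#' @param gantry_spacings allowed equal beam spacings (degrees); each
#'   plan uses one spacing for all four beams.
#' @param segment_range inclusive integer interval of protocol-conformant
#'   IMRT segment counts.
#' @param segment_levels full declared level set for segment counts
#'   (includes out-of-protocol values so that injected violations remain
#'   schema-valid).
#' @param continuous_noise_correlation equicorrelation of the jaw
#'   position noise within a plan (exercises the multivariate structure
#'   a multivariate detector can exploit).
#' @return an object of class `protocol_config`.
#' @export
protocol_config <- function(imrt_mu_mean = 290, tangent_mu_mean = 200,
                            mu_sd = 10, mu_pair_correlation = 0.9,
                            ssd_mean = 100, ssd_sd = 1,
                            ssd_field_correlation = 0.8,
                            jaw_means = c(collx1 = -7, collx2 = 7,
                                          colly1 = -9, colly2 = 9),
                            jaw_sds = c(collx1 = 1.5, collx2 = 1.5,
                                        colly1 = 1.8, colly2 = 1.8),
                            jaw_position_ranges = list(
                              collx1 = c(-15, -1), collx2 = c(1, 15),
                              colly1 = c(-18, -2), colly2 = c(2, 18)),
                            gantry_levels = as.numeric(gantry_levels_default()),
                            gantry_start_levels = c(30, 60, 210, 240),
                            gantry_spacings = 90,
                            segment_range = c(4L, 7L),
                            segment_levels = segment_levels_default(),
                            continuous_noise_correlation = 0.5) {
  stopifnot(mu_sd > 0, ssd_sd > 0, all(jaw_sds > 0),
            mu_pair_correlation >= 0, mu_pair_correlation < 1,
            ssd_field_correlation >= 0, ssd_field_correlation < 1,
            length(gantry_levels) >= 2L, length(gantry_spacings) >= 1L,
            all(gantry_start_levels %in% gantry_levels),
            segment_range[1] <= segment_range[2],
            continuous_noise_correlation >= 0,
            continuous_noise_correlation < 1)
  jaws <- c("collx1", "collx2", "colly1", "colly2")
  stopifnot(all(jaws %in% names(jaw_means)), all(jaws %in% names(jaw_sds)),
            all(jaws %in% names(jaw_position_ranges)))
  if (!all(as.character(segment_range[1]:segment_range[2]) %in%
           segment_levels)) {
    stop("segment_range must be covered by segment_levels")
  }
  structure(
    list(imrt_mu_mean = imrt_mu_mean, tangent_mu_mean = tangent_mu_mean,
         mu_sd = mu_sd, mu_pair_correlation = mu_pair_correlation,
         ssd_mean = ssd_mean, ssd_sd = ssd_sd,
         ssd_field_correlation = ssd_field_correlation,
         jaw_means = jaw_means, jaw_sds = jaw_sds,
         jaw_position_ranges = jaw_position_ranges,
         gantry_levels = gantry_levels,
         gantry_start_levels = gantry_start_levels,
         gantry_spacings = gantry_spacings,
         segment_range = as.integer(segment_range),
         segment_levels = segment_levels,
         continuous_noise_correlation = continuous_noise_correlation),
    class = "protocol_config")
}

#' Schema implied by a protocol preset
#'
#' [default_schema()] with the gantry and segment level sets taken from
#' the protocol, so generated plans always validate.
#' @param protocol a [protocol_config()].
#' @return a [feature_schema()].
#' @export
protocol_schema <- function(protocol) {
  stopifnot(inherits(protocol, "protocol_config"))
  feature_schema(list(
    feature_spec("segments", "IMRT", 2L, "categorical", unit = "count",
                 levels = protocol$segment_levels),
    feature_spec("ssd", "both", 4L, "continuous", unit = "cm"),
    feature_spec("collx1", "both", 4L, "continuous", unit = "cm"),
    feature_spec("collx2", "both", 4L, "continuous", unit = "cm"),
    feature_spec("colly1", "both", 4L, "continuous", unit = "cm"),
    feature_spec("colly2", "both", 4L, "continuous", unit = "cm"),
    feature_spec("gantry", "both", 4L, "categorical", unit = "degree",
                 levels = as.character(as.integer(protocol$gantry_levels))),
    feature_spec("meterset", "both", 4L, "continuous", unit = "MU")
  ))
}

# Circular equal-spacing predicate: of the four circular gaps between the
# sorted beam angles, at least three must equal a common positive spacing
# (an arithmetic beam arrangement leaves one closing remainder gap).
beams_equally_spaced <- function(angles) {
  a <- sort(as.numeric(angles) %% 360)
  gaps <- c(diff(a), 360 - (a[length(a)] - a[1]))
  tab <- table(gaps)
  any(tab >= length(a) - 1L & as.numeric(names(tab)) > 0)
}

#' Draw one protocol-conformant plan record
#'
#' Uses the current R random number generator state (seed with
#' [set.seed()] for reproducibility). Monitor units and SSD are truncated
#' normals around the protocol values; jaw positions share an
#' equicorrelated plan-level noise factor; gantry angles form an equally
#' spaced arrangement on the protocol grid; segment counts are uniform in
#' the protocol range.
#'
#' @param protocol a [protocol_config()].
#' @return a named list (one plan record in raw schema columns).
#' @export
generate_normal_plan <- function(protocol = protocol_config()) {
  stopifnot(inherits(protocol, "protocol_config"))
  rec <- list()
  rec$segments_f1 <- as.character(sample(
    protocol$segment_range[1]:protocol$segment_range[2], 1L))
  rec$segments_f2 <- as.character(sample(
    protocol$segment_range[1]:protocol$segment_range[2], 1L))
  # SSD shares a plan-level setup term across the four fields
  r_s <- protocol$ssd_field_correlation
  z_ssd <- stats::rnorm(1L)
  for (k in 1:4) {
    dev <- sqrt(r_s) * z_ssd + sqrt(1 - r_s) * stats::rnorm(1L)
    rec[[paste0("ssd_f", k)]] <- protocol$ssd_mean +
      protocol$ssd_sd * clamp(dev, -4, 4)
  }
  rho <- protocol$continuous_noise_correlation
  z <- stats::rnorm(1L)                     # shared plan-level factor
  for (jaw in c("collx1", "collx2", "colly1", "colly2")) {
    mu <- protocol$jaw_means[[jaw]]
    sd <- protocol$jaw_sds[[jaw]]
    rng <- protocol$jaw_position_ranges[[jaw]]
    for (k in 1:4) {
      val <- mu + sd * (sqrt(rho) * z + sqrt(1 - rho) * stats::rnorm(1L))
      rec[[paste0(jaw, "_f", k)]] <- clamp(val, rng[1], rng[2])
    }
  }
  spacing <- if (length(protocol$gantry_spacings) == 1L)
    protocol$gantry_spacings else sample(protocol$gantry_spacings, 1L)
  start <- if (length(protocol$gantry_start_levels) == 1L)
    protocol$gantry_start_levels else sample(protocol$gantry_start_levels, 1L)
  angles <- (start + (0:3) * spacing) %% 360
  for (k in 1:4) {
    rec[[paste0("gantry_f", k)]] <- as.character(as.integer(angles[k]))
  }
  # MU of a field-type pair tracks a shared prescription factor
  r_m <- protocol$mu_pair_correlation
  for (pair in list(c(1L, 2L, protocol$imrt_mu_mean),
                    c(3L, 4L, protocol$tangent_mu_mean))) {
    z_mu <- stats::rnorm(1L)
    for (k in pair[1:2]) {
      dev <- sqrt(r_m) * z_mu + sqrt(1 - r_m) * stats::rnorm(1L)
      rec[[paste0("meterset_f", k)]] <- pair[3] +
        protocol$mu_sd * clamp(dev, -4, 4)
    }
  }
  rec
}

ANOMALY_TYPES <- c("mu_offset", "unequal_beam_spacing", "jaw_asymmetry",
                   "segment_count_violation", "ssd_outlier", "mixed")

#' Declare an anomaly to inject
#'
#' @param type one of `"mu_offset"`, `"unequal_beam_spacing"`,
#'   `"jaw_asymmetry"`, `"segment_count_violation"`, `"ssd_outlier"`,
#'   `"mixed"` (two distinct single types applied in sequence).
#' @param magnitude effect size in feature standard deviations (or grid
#'   steps for discrete features); must be positive.
#' @param n_features_perturbed number of feature slots perturbed per
#'   affected feature family.
#' @return an object of class `anomaly_spec`.
#' @export
anomaly_spec <- function(type = ANOMALY_TYPES, magnitude = 3,
                         n_features_perturbed = 1L) {
  type <- match.arg(type)
  stopifnot(magnitude > 0, n_features_perturbed >= 1L)
  structure(list(type = type, magnitude = magnitude,
                 n_features_perturbed = as.integer(n_features_perturbed)),
            class = "anomaly_spec")
}

#' Inject a protocol violation into a plan record
#'
#' The returned record differs from the input in at least one feature yet
#' remains schema-valid: anomalies are subtle protocol violations, not
#' parse errors. Discrete perturbations that would leave the declared
#' level set are clipped to the nearest extreme level with a warning.
#'
#' @param record a plan record (named list) from
#'   [generate_normal_plan()].
#' @param spec an [anomaly_spec()].
#' @param protocol the [protocol_config()] the record was drawn under.
#' @return the perturbed record.
#' @export
inject_anomaly <- function(record, spec, protocol = protocol_config()) {
  stopifnot(inherits(spec, "anomaly_spec"),
            inherits(protocol, "protocol_config"))
  mag <- spec$magnitude
  nf <- spec$n_features_perturbed
  types <- if (spec$type == "mixed") {
    sample(setdiff(ANOMALY_TYPES, "mixed"), 2L)
  } else spec$type
  for (type in types) {
    record <- switch(type,
      mu_offset = {
        cols <- paste0("meterset_f", sample(1:4, min(nf, 4L)))
        for (col in cols) {
          record[[col]] <- record[[col]] +
            sample(c(-1, 1), 1L) * mag * protocol$mu_sd
        }
        record
      },
      ssd_outlier = {
        cols <- paste0("ssd_f", sample(1:4, min(nf, 4L)))
        for (col in cols) {
          record[[col]] <- record[[col]] +
            sample(c(-1, 1), 1L) * mag * protocol$ssd_sd
        }
        record
      },
      jaw_asymmetry = {
        jaws <- c("collx1", "collx2", "colly1", "colly2")
        picks <- sample(16L, min(nf, 16L))
        for (p in picks) {
          jaw <- jaws[(p - 1L) %/% 4L + 1L]
          col <- paste0(jaw, "_f", (p - 1L) %% 4L + 1L)
          record[[col]] <- record[[col]] +
            sample(c(-1, 1), 1L) * mag * protocol$jaw_sds[[jaw]]
        }
        record
      },
      unequal_beam_spacing = {
        step <- min(diff(sort(unique(protocol$gantry_levels))))
        lev <- as.numeric(protocol$gantry_levels)
        for (k in sample(1:4)) {      # first field whose shift breaks spacing
          col <- paste0("gantry_f", k)
          old <- as.numeric(record[[col]])
          for (delta in sample(c(-step, step))) {
            cand <- (old + delta) %% 360
            if (!cand %in% lev) next
            trial <- record
            trial[[col]] <- as.character(as.integer(cand))
            angles <- vapply(paste0("gantry_f", 1:4), function(cc)
              as.numeric(trial[[cc]]), numeric(1))
            if (!beams_equally_spaced(angles)) {
              record <- trial
              break
            }
          }
          if (!identical(record[[col]], as.character(as.integer(old)))) break
        }
        record
      },
      segment_count_violation = {
        col <- paste0("segments_f", sample(1:2, 1L))
        lev <- as.integer(protocol$segment_levels)
        lo <- protocol$segment_range[1]; hi <- protocol$segment_range[2]
        old <- as.integer(record[[col]])
        shift <- max(1L, as.integer(round(mag)))
        dir <- sample(c(-1L, 1L), 1L)
        cand <- if (dir > 0) hi + shift else lo - shift
        if (cand > max(lev) || cand < min(lev)) {
          warning("segment violation clipped to the declared level range")
          cand <- clamp(cand, min(lev), max(lev))
        }
        record[[col]] <- as.character(cand)
        record
      })
  }
  record
}

#' Generation settings for a labelled synthetic benchmark
#'
#' Defaults mirror the study population this generator stands in for:
#' 557 normal plus 19 abnormal breast plans, anomalies drawn uniformly
#' over the five single violation types at 3 sd magnitude.
#'
#' @param n_normal,n_abnormal class sizes (>= 0).
#' @param protocol a [protocol_config()].
#' @param anomaly_mix named non-negative weights over anomaly types
#'   (normalised to sum 1).
#' @param magnitude anomaly effect size in feature sds.
#' @param n_features_perturbed slots perturbed per anomaly.
#' @param seed integer seed; fully determines the dataset.
#' @return an object of class `gen_config`.
#' @export
gen_config <- function(n_normal = 557L, n_abnormal = 19L,
                       protocol = protocol_config(),
                       anomaly_mix = NULL, magnitude = 3,
                       n_features_perturbed = 1L, seed = 0L) {
  stopifnot(n_normal >= 0L, n_abnormal >= 0L,
            inherits(protocol, "protocol_config"), magnitude > 0)
  single <- setdiff(ANOMALY_TYPES, "mixed")
  if (is.null(anomaly_mix)) {
    anomaly_mix <- stats::setNames(rep(1 / length(single), length(single)),
                                   single)
  }
  stopifnot(all(names(anomaly_mix) %in% ANOMALY_TYPES),
            all(anomaly_mix >= 0), sum(anomaly_mix) > 0)
  anomaly_mix <- anomaly_mix / sum(anomaly_mix)
  structure(
    list(n_normal = as.integer(n_normal), n_abnormal = as.integer(n_abnormal),
         protocol = protocol, anomaly_mix = anomaly_mix,
         magnitude = magnitude,
         n_features_perturbed = as.integer(n_features_perturbed),
         seed = as.integer(seed)),
    class = "gen_config")
}

gen_config_fingerprint <- function(config) {
  poly_fingerprint(utils::capture.output(utils::str(
    config[setdiff(names(config), "seed")], digits.d = 12)))
}

#' Generate a labelled synthetic plan benchmark
#'
#' Draws `n_normal` protocol-conformant plans and `n_abnormal` plans
#' obtained by injecting a sampled violation into a fresh normal draw,
#' shuffles the rows, and returns the labelled table together with a
#' manifest recording the seed, a config fingerprint and the per-type
#' anomaly counts. Two runs with the same config are byte-identical.
#'
#' @param config a [gen_config()].
#' @return list with `table` (a labelled [plan_table()]) and `manifest`.
#' @export
generate_dataset <- function(config = gen_config()) {
  stopifnot(inherits(config, "gen_config"))
  set.seed(config$seed)
  schema <- protocol_schema(config$protocol)
  records <- vector("list", config$n_normal + config$n_abnormal)
  labels <- character(length(records))
  types <- character(0)
  i <- 0L
  for (k in seq_len(config$n_normal)) {
    i <- i + 1L
    records[[i]] <- generate_normal_plan(config$protocol)
    labels[i] <- "normal"
  }
  if (config$n_abnormal > 0L) {
    types <- sample(names(config$anomaly_mix), config$n_abnormal,
                    replace = TRUE, prob = config$anomaly_mix)
    for (k in seq_len(config$n_abnormal)) {
      i <- i + 1L
      base <- generate_normal_plan(config$protocol)
      records[[i]] <- inject_anomaly(
        base, anomaly_spec(types[k], config$magnitude,
                           config$n_features_perturbed),
        config$protocol)
      labels[i] <- "abnormal"
    }
  }
  n <- length(records)
  data <- do.call(rbind, lapply(records, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  perm <- if (n > 0L) sample.int(n) else integer(0)
  data <- data[perm, , drop = FALSE]
  rownames(data) <- NULL
  labels <- labels[perm]
  ids <- sprintf("plan_%04d", seq_len(n))
  table <- plan_table(data, schema, labels = labels, ids = ids)
  manifest <- list(
    seed = config$seed,
    config_fingerprint = gen_config_fingerprint(config),
    n_normal = config$n_normal, n_abnormal = config$n_abnormal,
    anomaly_type_counts = as.list(table(factor(types,
                                               levels = names(config$anomaly_mix)))))
  list(table = table, manifest = manifest)
}

#' Write a generated dataset and its manifest
#'
#' @param dataset result of [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  plans <- file.path(dir, "plans.csv")
  manifest <- file.path(dir, "manifest.json")
  write_plan_table(dataset$table, plans)
  jsonlite::write_json(dataset$manifest, manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(c(plans, manifest))
}
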