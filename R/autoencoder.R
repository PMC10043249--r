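#' Autoencoder architecture and training hyperparameters
#'
#' @param depth number of encoder blocks (1 to 9); the decoder always
#'   mirrors the encoder, so the network has `2 * depth` layers.
#' @param latent_dim bottleneck width (must stay below the input width).
#' @param hidden_widths optional explicit encoder block output widths
#'   (length `depth`, last entry is the bottleneck); when `NULL` a
#'   geometric taper from the input width down to `latent_dim` is used.
#' @param dropout_rate dropout probability applied after every hidden
#'   activation (never after the output layer).
#' @param leaky_slope negative-side slope of the leaky ReLU activations.
#' @param lambda_weight weight of the MSE (continuous-column) part in the
#'   composite reconstruction loss `BCE + lambda * MSE`.
#' @param learning_rate Adam step size.
#' @param epochs number of passes over the training rows. The default
#'   2000 reflects that Adam at the fixed learning rate 1e-3 moves an
#'   output logit by at most ~`learning_rate * steps`; the one-hot heads
#'   need logit magnitudes of 5-10, which 500-epoch training cannot
#'   reach on a ~576-plan table with batch 64.
#' @param batch_size mini-batch size (mini-batches are reshuffled every
#'   epoch).
#' @param seed integer seed controlling weight initialisation, shuffling
#'   and dropout; fixed seed gives bit-identical runs.
#' @return an object of class `ae_config`.
#' @export
ae_config <- function(depth = 6L, latent_dim = 8L, hidden_widths = NULL,
                      dropout_rate = 0.1, leaky_slope = 0.01,
                      lambda_weight = 0.99, learning_rate = 1e-3,
                      epochs = 2000L, batch_size = 64L, seed = 1L) {
  depth <- as.integer(depth)
  if (is.na(depth) || depth < 1L || depth > 9L) {
    stop("depth must be an integer between 1 and 9")
  }
  if (!is.null(hidden_widths)) {
    hidden_widths <- as.integer(hidden_widths)
    if (length(hidden_widths) != depth) {
      stop("hidden_widths must have one entry per encoder block")
    }
    latent_dim <- hidden_widths[depth]
  }
  latent_dim <- as.integer(latent_dim)
  stopifnot(latent_dim >= 1L, dropout_rate >= 0, dropout_rate < 1,
            leaky_slope > 0, lambda_weight >= 0, learning_rate > 0,
            epochs >= 1L, batch_size >= 1L)
  structure(
    list(depth = depth, latent_dim = latent_dim,
         hidden_widths = hidden_widths, dropout_rate = dropout_rate,
         leaky_slope = leaky_slope, lambda_weight = lambda_weight,
         learning_rate = learning_rate, epochs = as.integer(epochs),
         batch_size = as.integer(batch_size), seed = as.integer(seed)),
    class = "ae_config")
}

# Encoder width sequence input_dim -> ... -> latent_dim (geometric taper).
taper_widths <- function(input_dim, latent_dim, depth) {
  ratio <- (latent_dim / input_dim)^(seq_len(depth) / depth)
  w <- as.integer(round(input_dim * ratio))
  w <- pmax(w, latent_dim)
  w <- cummin(w)              # enforce non-increasing widths
  w[depth] <- latent_dim
  w
}

#' Build a symmetric fully connected autoencoder
#'
#' Every block is a fully connected layer `W x + B` followed by a leaky
#' ReLU; the decoder widths mirror the encoder widths in reverse so the
#' output layer recovers the input width. On the output layer the
#' activation is a sigmoid on binary (one-hot) columns and the identity on
#' continuous columns; dropout is applied after every hidden activation
#' during training only.
#'
#' @param config an [ae_config()].
#' @param input either the input width (integer) or an `encoded_matrix`,
#'   from which the width and dimension mask are taken.
#' @param mask optional dimension mask (`dim_mask`); when absent all
#'   columns are treated as continuous.
#' @return an object of class `ae_model` holding the encoder parameters
#'   theta_E and decoder parameters theta_D as (weight, bias) pairs.
#' @export
build_autoencoder <- function(config, input, mask = NULL) {
  stopifnot(inherits(config, "ae_config"))
  if (inherits(input, "encoded_matrix")) {
    mask <- input$mask
    input_dim <- ncol(input$values)
  } else {
    input_dim <- as.integer(input)
  }
  if (is.na(input_dim) || input_dim < 2L) stop("input_dim must be >= 2")
  if (config$latent_dim >= input_dim) {
    stop_planomaly(
      sprintf("latent_dim (%d) must be smaller than input_dim (%d)",
              config$latent_dim, input_dim),
      "planomaly_config_error")
  }
  enc_w <- config$hidden_widths %||%
    taper_widths(input_dim, config$latent_dim, config$depth)
  if (any(enc_w >= c(input_dim, enc_w[-config$depth]) + 1L)) {
    # explicit widths may legitimately plateau; only forbid widening
    if (any(diff(c(input_dim, enc_w)) > 0)) {
      stop("encoder widths must not increase towards the bottleneck")
    }
  }
  widths <- c(input_dim, enc_w, rev(c(input_dim, enc_w[-config$depth])))
  binary_cols <- if (is.null(mask)) logical(input_dim) else
    mask$kind == "binary"
  if (length(binary_cols) != input_dim) {
    stop("dimension mask does not match input_dim")
  }
  set.seed(config$seed)
  layers <- vector("list", length(widths) - 1L)
  for (l in seq_along(layers)) {
    d_in <- widths[l]
    d_out <- widths[l + 1L]
    layers[[l]] <- list(
      W = matrix(stats::rnorm(d_in * d_out, sd = sqrt(2 / d_in)),
                 nrow = d_in, ncol = d_out),
      b = numeric(d_out))
  }
  structure(
    list(layers = layers, widths = widths, depth = config$depth,
         input_dim = input_dim, latent_dim = config$latent_dim,
         binary_cols = binary_cols, mask = mask,
         fingerprint = if (is.null(mask)) NA_character_ else
           mask_fingerprint(mask),
         config = config),
    class = "ae_model")
}

#' @export
print.ae_model <- function(x, ...) {
  cat(sprintf("<ae_model> depth %d, widths %s (%d binary / %d continuous outputs)\n",
              x$depth, paste(x$widths, collapse = "-"),
              sum(x$binary_cols), sum(!x$binary_cols)))
  invisible(x)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Forward pass; returns activations needed for backprop when cache = TRUE.
# drop_masks (list of 0/1 matrices per hidden layer) is supplied during
# training; inference never applies dropout.
ae_forward <- function(model, X, drop_masks = NULL, cache = FALSE) {
  L <- length(model$layers)
  keep <- 1 - model$config$dropout_rate
  A <- X
  As <- if (cache) vector("list", L + 1L)
  Zs <- if (cache) vector("list", L)
  if (cache) As[[1L]] <- A
  n <- nrow(A)
  for (l in seq_len(L)) {
    lay <- model$layers[[l]]
    Z <- A %*% lay$W
    Z <- Z + rep(lay$b, each = n)       # column-major bias broadcast
    if (l < L) {
      A <- Z * ((Z > 0) + model$config$leaky_slope * (Z <= 0))
      if (!is.null(drop_masks)) A <- A * drop_masks[[l]] / keep
    } else {
      A <- Z
      if (any(model$binary_cols)) {
        A[, model$binary_cols] <- sigmoid(Z[, model$binary_cols, drop = FALSE])
      }
    }
    if (cache) {
      Zs[[l]] <- Z
      As[[l + 1L]] <- A
    }
  }
  if (cache) list(out = A, As = As, Zs = Zs) else A
}

resolve_matrix <- function(model, X) {
  if (inherits(X, "encoded_matrix")) {
    if (!is.na(model$fingerprint) && X$fingerprint != model$fingerprint) {
      stop_planomaly(
        "encoded matrix fingerprint does not match the mask this model was built with",
        "planomaly_fingerprint_mismatch")
    }
    X <- X$values
  }
  X <- as.matrix(X)
  if (ncol(X) != model$input_dim) {
    stop(sprintf("input has %d columns but the model expects %d",
                 ncol(X), model$input_dim))
  }
  X
}

#' Reconstruct plans through the autoencoder
#'
#' Runs `X_hat = D(E(X, theta_E), theta_D)` with dropout inactive.
#' Binary (one-hot) output columns pass through a sigmoid and lie in
#' (0, 1); continuous outputs are linear.
#'
#' @param model an [build_autoencoder()] model (trained or not).
#' @param X an `encoded_matrix` or numeric matrix with matching columns.
#' @return a numeric matrix of the same shape as the input rows.
#' @export
reconstruct <- function(model, X) {
  stopifnot(inherits(model, "ae_model"))
  ae_forward(model, resolve_matrix(model, X))
}

BCE_EPS <- 1e-7

#' Composite reconstruction loss
#'
#' `L_recon = L_BCE + lambda * L_MSE`: binary cross-entropy averaged over
#' the binary (one-hot) cells plus `lambda` times the mean squared error
#' over the continuous cells. Both parts are means over their own cell
#' sets so that `lambda` trades off comparable magnitudes. Predictions on
#' binary columns are clipped to `[1e-7, 1 - 1e-7]` before the logarithm.
#'
#' @param X_hat reconstruction matrix.
#' @param X target matrix (binary cells must be exactly 0 or 1).
#' @param mask a `dim_mask` (or character vector of `"binary"` /
#'   `"continuous"` kinds, one per column).
#' @param lambda_weight the MSE weight `lambda >= 0`.
#' @return list with `total`, `bce_part`, `mse_part`.
#' @export
recon_loss <- function(X_hat, X, mask, lambda_weight) {
  X_hat <- as.matrix(X_hat)
  X <- as.matrix(X)
  stopifnot(identical(dim(X_hat), dim(X)), lambda_weight >= 0)
  kinds <- if (inherits(mask, "data.frame")) mask$kind else as.character(mask)
  stopifnot(length(kinds) == ncol(X))
  bin <- kinds == "binary"
  bce <- 0
  if (any(bin)) {
    y <- X[, bin, drop = FALSE]
    if (!all(y %in% c(0, 1))) {
      stop("binary target cells must be exactly 0 or 1")
    }
    p <- clamp(X_hat[, bin, drop = FALSE], BCE_EPS, 1 - BCE_EPS)
    bce <- -mean(y * log(p) + (1 - y) * log(1 - p))
  }
  mse <- 0
  if (any(!bin)) {
    d <- X[, !bin, drop = FALSE] - X_hat[, !bin, drop = FALSE]
    mse <- mean(d * d)
  }
  list(total = bce + lambda_weight * mse, bce_part = bce, mse_part = mse)
}

adam_init <- function(layers) {
  lapply(layers, function(lay) list(
    mW = lay$W * 0, vW = lay$W * 0,
    mb = lay$b * 0, vb = lay$b * 0))
}

#' Train an autoencoder by Adam on the composite reconstruction loss
#'
#' Runs `epochs` passes of shuffled mini-batch Adam updates (beta1 = 0.9,
#' beta2 = 0.999) minimising [recon_loss()]. The per-epoch loss history is
#' evaluated on the full training rows with dropout inactive. Training is
#' fully determined by `config$seed`.
#'
#' @param model an `ae_model` built with a mask matching `data`.
#' @param data an `encoded_matrix` (or plain matrix with matching width).
#' @param config an [ae_config()]; defaults to the one the model was
#'   built with.
#' @param rows optional integer subset of rows to train on (e.g. only
#'   plans labelled normal); default trains on the full unlabelled table,
#'   anomalies included.
#' @return an object of class `ae_fit` with elements `model` (trained),
#'   `history` (epoch, total, bce_part, mse_part) and `seed`.
#' @export
ae_train <- function(model, data, config = model$config, rows = NULL) {
  stopifnot(inherits(model, "ae_model"), inherits(config, "ae_config"))
  X <- resolve_matrix(model, data)
  if (!is.null(rows)) X <- X[rows, , drop = FALSE]
  n <- nrow(X)
  if (n < 2L) stop("training needs at least 2 rows")
  L <- length(model$layers)
  bin <- model$binary_cols
  nb_cols <- sum(bin)
  nc_cols <- sum(!bin)
  lambda <- config$lambda_weight
  keep <- 1 - config$dropout_rate
  lr <- config$learning_rate
  beta1 <- 0.9; beta2 <- 0.999; adam_eps <- 1e-8
  state <- adam_init(model$layers)
  t_step <- 0L
  history <- data.frame(epoch = seq_len(config$epochs), total = NA_real_,
                        bce_part = NA_real_, mse_part = NA_real_)
  set.seed(config$seed)
  for (epoch in seq_len(config$epochs)) {
    perm <- sample.int(n)
    starts <- seq(1L, n, by = config$batch_size)
    for (s in starts) {
      idx <- perm[s:min(s + config$batch_size - 1L, n)]
      Xb <- X[idx, , drop = FALSE]
      m <- nrow(Xb)
      drop_masks <- NULL
      if (config$dropout_rate > 0) {
        drop_masks <- lapply(seq_len(L - 1L), function(l) {
          matrix(as.numeric(stats::runif(m * model$widths[l + 1L]) < keep),
                 nrow = m)
        })
      }
      fw <- ae_forward(model, Xb, drop_masks = drop_masks, cache = TRUE)
      # output-layer gradient of the mean-reduced composite loss
      dZ <- matrix(0, nrow = m, ncol = model$input_dim)
      if (nb_cols > 0L) {
        p <- clamp(fw$out[, bin, drop = FALSE], BCE_EPS, 1 - BCE_EPS)
        dZ[, bin] <- (p - Xb[, bin, drop = FALSE]) / (m * nb_cols)
      }
      if (nc_cols > 0L) {
        dZ[, !bin] <- lambda * 2 *
          (fw$out[, !bin, drop = FALSE] - Xb[, !bin, drop = FALSE]) /
          (m * nc_cols)
      }
      for (l in rev(seq_len(L))) {
        dW <- crossprod(fw$As[[l]], dZ)
        db <- colSums(dZ)
        if (l > 1L) {
          dA <- tcrossprod(dZ, model$layers[[l]]$W)
          if (!is.null(drop_masks)) dA <- dA * drop_masks[[l - 1L]] / keep
          Zp <- fw$Zs[[l - 1L]]
          dZ <- dA * ((Zp > 0) + config$leaky_slope * (Zp <= 0))
        }
        st <- state[[l]]
        t_local <- t_step + 1L
        st$mW <- beta1 * st$mW + (1 - beta1) * dW
        st$vW <- beta2 * st$vW + (1 - beta2) * dW * dW
        st$mb <- beta1 * st$mb + (1 - beta1) * db
        st$vb <- beta2 * st$vb + (1 - beta2) * db * db
        corr1 <- 1 - beta1^t_local
        corr2 <- 1 - beta2^t_local
        model$layers[[l]]$W <- model$layers[[l]]$W -
          lr * (st$mW / corr1) / (sqrt(st$vW / corr2) + adam_eps)
        model$layers[[l]]$b <- model$layers[[l]]$b -
          lr * (st$mb / corr1) / (sqrt(st$vb / corr2) + adam_eps)
        state[[l]] <- st
      }
      t_step <- t_step + 1L
    }
    ep_loss <- recon_loss(ae_forward(model, X), X,
                          kinds_from_model(model), lambda)
    if (!is.finite(ep_loss$total)) {
      stop(sprintf("training diverged: non-finite loss at epoch %d", epoch))
    }
    history$total[epoch] <- ep_loss$total
    history$bce_part[epoch] <- ep_loss$bce_part
    history$mse_part[epoch] <- ep_loss$mse_part
  }
  if (history$total[config$epochs] > history$total[1L]) {
    warning("final training loss exceeds initial loss; model may not have converged")
  }
  structure(list(model = model, history = history, seed = config$seed,
                 config = config),
            class = "ae_fit")
}

kinds_from_model <- function(model) {
  ifelse(model$binary_cols, "binary", "continuous")
}

#' @export
print.ae_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf("<ae_fit> %d epochs, loss %.5f -> %.5f (seed %d)\n",
              nrow(h), h$total[1], h$total[nrow(h)], x$seed))
  invisible(x)
}

#' Per-plan composite reconstruction errors
#'
#' The anomaly score of a plan is its own [recon_loss()]: BCE averaged
#' over the plan's binary cells plus `lambda` times the MSE over its
#' continuous cells. Row order is preserved; the mean of the per-row
#' scores equals the full-batch loss because every row has the same cell
#' counts.
#'
#' @param model a trained `ae_model` or an `ae_fit`.
#' @param data an `encoded_matrix` or numeric matrix.
#' @param lambda_weight the MSE weight; defaults to the training value.
#' @return numeric vector with one score per row.
#' @export
sample_errors <- function(model, data, lambda_weight = NULL) {
  if (inherits(model, "ae_fit")) model <- model$model
  stopifnot(inherits(model, "ae_model"))
  lambda <- lambda_weight %||% model$config$lambda_weight
  X <- resolve_matrix(model, data)
  X_hat <- ae_forward(model, X)
  bin <- model$binary_cols
  bce <- 0
  if (any(bin)) {
    y <- X[, bin, drop = FALSE]
    p <- clamp(X_hat[, bin, drop = FALSE], BCE_EPS, 1 - BCE_EPS)
    bce <- -rowMeans(y * log(p) + (1 - y) * log(1 - p))
  }
  mse <- 0
  if (any(!bin)) {
    d <- X[, !bin, drop = FALSE] - X_hat[, !bin, drop = FALSE]
    mse <- rowMeans(d * d)
  }
  scores <- as.numeric(bce + lambda * mse)
  if (inherits(data, "encoded_matrix") && !is.null(data$ids)) {
    names(scores) <- data$ids
  }
  scores
}

#' Save an autoencoder checkpoint
#'
#' Single-file JSON checkpoint holding the trained weights, the
#' [ae_config()] and the dimension-mask fingerprint; [load_ae_model()]
#' restores a model that refuses to score tables whose encoded
#' fingerprint differs.
#'
#' @param model an `ae_model` or `ae_fit`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_ae_model <- function(model, path) {
  if (inherits(model, "ae_fit")) model <- model$model
  stopifnot(inherits(model, "ae_model"))
  obj <- list(
    config = unclass(model$config),
    widths = model$widths,
    binary_cols = model$binary_cols,
    fingerprint = model$fingerprint,
    mask = if (!is.null(model$mask)) lapply(
      as.data.frame(unclass(model$mask)), as.vector),
    layers = lapply(model$layers, function(l)
      list(W = as.numeric(l$W), dim = dim(l$W), b = l$b)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Load an autoencoder checkpoint written by [save_ae_model()]
#' @param path checkpoint file.
#' @return an `ae_model`.
#' @export
load_ae_model <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE)
  cfg_fields <- obj$config[!vapply(obj$config, is.null, logical(1))]
  cfg <- do.call(ae_config, cfg_fields)
  layers <- lapply(obj$layers, function(l) {
    list(W = matrix(as.numeric(l$W), nrow = l$dim[1]),
         b = as.numeric(l$b))
  })
  mask <- NULL
  if (!is.null(obj$mask)) {
    mask <- as.data.frame(lapply(obj$mask, unlist),
                          stringsAsFactors = FALSE)
    mask$slot <- as.integer(mask$slot)
    class(mask) <- c("dim_mask", "data.frame")
  }
  widths <- as.integer(obj$widths)
  structure(
    list(layers = layers, widths = widths, depth = cfg$depth,
         input_dim = widths[1], latent_dim = cfg$latent_dim,
         binary_cols = as.logical(obj$binary_cols), mask = mask,
         fingerprint = obj$fingerprint %||% NA_character_, config = cfg),
    class = "ae_model")
}
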