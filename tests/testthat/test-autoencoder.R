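test_that("architecture is symmetric for every depth 1..9", {
  for (d in 1:9) {
    cfg <- ae_config(depth = d, latent_dim = 4, seed = 1)
    m <- build_autoencoder(cfg, 64)
    enc <- m$widths[1:(d + 1)]
    dec <- m$widths[(d + 1):(2 * d + 1)]
    expect_identical(rev(dec), enc)
    expect_identical(m$widths[1], 64L)
    expect_identical(m$widths[d + 1], 4L)
    expect_identical(length(m$layers), 2L * d)
    expect_true(all(diff(enc) <= 0))
  }
  # explicit structural examples
  m1 <- build_autoencoder(ae_config(depth = 1, latent_dim = 4), 10)
  expect_identical(m1$widths, c(10L, 4L, 10L))
  m6 <- build_autoencoder(ae_config(depth = 6, latent_dim = 8), 58)
  expect_identical(length(m6$layers), 12L)
  expect_error(build_autoencoder(ae_config(latent_dim = 12), 10),
               class = "planomaly_config_error")
})

test_that("same seed gives bit-identical initial parameters", {
  cfg <- ae_config(depth = 3, seed = 77)
  m1 <- build_autoencoder(cfg, 20)
  m2 <- build_autoencoder(cfg, 20)
  expect_identical(m1$layers, m2$layers)
  m3 <- build_autoencoder(ae_config(depth = 3, seed = 78), 20)
  expect_false(identical(m1$layers[[1]]$W, m3$layers[[1]]$W))
})

test_that("reconstruct respects output activations and shape", {
  em <- encode_table(tiny_table(4), scale = "minmax")
  m <- build_autoencoder(fast_ae(), em)
  # zero weights: sigmoid(0) = 0.5 on binary, 0 on continuous
  for (l in seq_along(m$layers)) {
    m$layers[[l]]$W[] <- 0
    m$layers[[l]]$b[] <- 0
  }
  out <- reconstruct(m, em)
  bin <- m$binary_cols
  expect_true(all(out[, bin] == 0.5))
  expect_true(all(out[, !bin] == 0))
  # single-row shape preserved; inference deterministic
  m2 <- build_autoencoder(fast_ae(), em)
  one <- reconstruct(m2, em$values[1, , drop = FALSE])
  expect_identical(dim(one), c(1L, ncol(em$values)))
  expect_identical(reconstruct(m2, em), reconstruct(m2, em))
  expect_true(all(reconstruct(m2, em)[, bin] > 0 &
                    reconstruct(m2, em)[, bin] < 1))
  expect_error(reconstruct(m2, em$values[, 1:3]), "expects")
})

test_that("recon_loss follows its closed forms and decomposition", {
  kinds <- c("binary", "binary", "continuous")
  X <- cbind(c(1, 0), c(0, 1), c(0.2, -0.4))
  # perfect reconstruction -> loss ~ 0 (up to the 1e-7 clipping)
  perfect <- recon_loss(X, X, kinds, 0.99)
  expect_lt(perfect$total, 1e-6)
  # all-0.5 binary predictions, ignore continuous via lambda irrelevance
  Xb <- X[, 1:2]
  half <- recon_loss(matrix(0.5, 2, 2), Xb, c("binary", "binary"), 0.5)
  expect_equal(half$bce_part, log(2), tolerance = 1e-12)
  expect_equal(half$mse_part, 0)
  # lambda scales a pure-MSE loss: total = 0.99 * m
  Xc <- matrix(c(1, 2, 3, 4), 2)
  Xh <- Xc + 0.5
  pure <- recon_loss(Xh, Xc, c("continuous", "continuous"), 0.99)
  expect_equal(pure$total, 0.99 * 0.25, tolerance = 1e-12)
  expect_equal(pure$bce_part, 0)
  # predictions at exactly 0/1 are clipped, not an error
  clipped <- recon_loss(matrix(c(0, 1), 1), matrix(c(1, 0), 1),
                        c("binary", "binary"), 1)
  expect_true(is.finite(clipped$total))
  expect_error(recon_loss(matrix(0.5, 1, 1), matrix(0.3, 1, 1), "binary", 1),
               "exactly 0 or 1")
})

test_that("loss decomposition total = bce + lambda * mse on random batches", {
  set.seed(31)
  for (rep in 1:20) {
    p <- sample(4:12, 1)
    n <- sample(2:20, 1)
    kinds <- sample(c("binary", "continuous"), p, replace = TRUE)
    kinds[1:2] <- c("binary", "continuous")
    X <- matrix(rnorm(n * p), n)
    X[, kinds == "binary"] <- rbinom(sum(kinds == "binary") * n, 1, 0.4)
    Xh <- matrix(rnorm(n * p), n)
    Xh[, kinds == "binary"] <- stats::runif(sum(kinds == "binary") * n)
    lam <- stats::runif(1, 0, 2)
    l <- recon_loss(Xh, X, kinds, lam)
    expect_equal(l$total, l$bce_part + lam * l$mse_part, tolerance = 1e-10)
    expect_gte(l$bce_part, 0)
    expect_gte(l$mse_part, 0)
  }
})

test_that("training memorizes degenerate identical-row data", {
  em <- encode_table(tiny_table(2), scale = "minmax")
  X <- em$values[rep(1, 24), ]
  # lr raised so the one-hot logits can actually travel within 400 epochs
  # (Adam moves a parameter by at most ~lr per step)
  cfg <- ae_config(depth = 1, latent_dim = 2, epochs = 400,
                   dropout_rate = 0, batch_size = 8, seed = 3,
                   learning_rate = 0.01)
  m <- build_autoencoder(cfg, ncol(X), mask = em$mask)
  fit <- ae_train(m, X, cfg)
  expect_lt(fit$history$total[400], 0.01 * fit$history$total[1])
})

test_that("training is seed-deterministic and lambda=0 reduces to BCE", {
  ds <- small_benchmark()
  em <- encode_table(ds$table)
  cfg <- fast_ae(epochs = 10)
  f1 <- ae_train(build_autoencoder(cfg, em), em, cfg)
  f2 <- ae_train(build_autoencoder(cfg, em), em, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$layers, f2$model$layers)

  cfg0 <- fast_ae(epochs = 10, lambda_weight = 0)
  f0 <- ae_train(build_autoencoder(cfg0, em), em, cfg0)
  expect_equal(f0$history$total, f0$history$bce_part, tolerance = 1e-12)
  expect_true(all(is.finite(f0$history$total)))
})

test_that("sample_errors preserves order and averages to the batch loss", {
  ds <- small_benchmark()
  em <- encode_table(ds$table)
  cfg <- fast_ae(epochs = 15)
  fit <- ae_train(build_autoencoder(cfg, em), em, cfg)
  sc <- sample_errors(fit$model, em)
  expect_length(sc, nrow(em$values))
  # permutation equivariance (row independence)
  perm <- sample(length(sc))
  sc_perm <- sample_errors(fit$model, em$values[perm, ])
  expect_equal(unname(sc_perm), unname(sc[perm]), tolerance = 1e-12)
  # mean of per-row scores equals the full-batch composite loss
  full <- recon_loss(reconstruct(fit$model, em), em$values, em$mask,
                     cfg$lambda_weight)
  expect_equal(mean(sc), full$total, tolerance = 1e-10)
})

test_that("checkpoints round-trip and refuse mismatched fingerprints", {
  ds <- small_benchmark()
  em <- encode_table(ds$table)
  cfg <- fast_ae(epochs = 5)
  fit <- ae_train(build_autoencoder(cfg, em), em, cfg)
  path <- withr::local_tempfile(fileext = ".json")
  save_ae_model(fit, path)
  back <- load_ae_model(path)
  expect_equal(sample_errors(back, em), sample_errors(fit$model, em),
               tolerance = 1e-12)
  # a different schema encodes to a different fingerprint -> refused
  other <- encode_table(tiny_table(6))
  expect_error(sample_errors(back, other),
               class = "planomaly_fingerprint_mismatch")
})
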