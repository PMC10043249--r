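as_values <- function(X) {
  if (inherits(X, "encoded_matrix")) X$values else as.matrix(X)
}

#' PCA reconstruction-error scores
#'
#' The linear analogue of the autoencoder: centre the data, project each
#' row onto the top `n_components` principal components, and score it by
#' the squared norm of its residual (the reconstruction loss of the
#' linear mapping). Higher scores are more anomalous.
#'
#' @param X an `encoded_matrix` or numeric matrix.
#' @param n_components number of principal components, `1 <= n < n_dims`.
#' @return numeric score per row.
#' @export
pca_scores <- function(X, n_components) {
  M <- as_values(X)
  p <- ncol(M)
  n_components <- as.integer(n_components)
  if (is.na(n_components) || n_components < 1L || n_components >= p) {
    stop("n_components must satisfy 1 <= n_components < n_dims")
  }
  ctr <- colMeans(M)
  C <- sweep(M, 2L, ctr)
  sv <- svd(C, nu = 0, nv = n_components)
  V <- sv$v
  resid <- C - (C %*% V) %*% t(V)
  rowSums(resid * resid)
}

#' Local outlier factor scores
#'
#' Classic density-ratio LOF: for each plan, the mean local reachability
#' density of its k-distance neighbourhood (ties included) divided by its
#' own. Values near 1 indicate inliers; larger values indicate lower
#' local density than the neighbours. Deterministic given the matrix.
#'
#' @param X an `encoded_matrix` or numeric matrix.
#' @param n_neighbors neighbourhood size `k < n_plans`.
#' @return numeric score per row (higher = more outlying).
#' @export
lof_scores <- function(X, n_neighbors) {
  M <- as_values(X)
  n <- nrow(M)
  k <- as.integer(n_neighbors)
  if (is.na(k) || k < 1L || k >= n) {
    stop("n_neighbors must satisfy 1 <= n_neighbors < n_plans")
  }
  D <- as.matrix(stats::dist(M))
  diag(D) <- Inf
  kdist <- numeric(n)
  nbrs <- vector("list", n)
  for (i in seq_len(n)) {
    d <- D[i, ]
    kdist[i] <- sort(d, partial = k)[k]
    nbrs[[i]] <- which(d <= kdist[i])   # all points within k-distance
  }
  lrd <- numeric(n)
  for (i in seq_len(n)) {
    nb <- nbrs[[i]]
    reach <- pmax(kdist[nb], D[i, nb])
    lrd[i] <- 1 / max(mean(reach), 1e-12)
  }
  vapply(seq_len(n), function(i) mean(lrd[nbrs[[i]]]) / lrd[i], numeric(1))
}

#' One-class SVM scores
#'
#' RBF-kernel one-class SVM in the dual: minimise `0.5 t(a) K a` subject
#' to `0 <= a_i <= 1/(nu n)` and `sum(a) = 1`, solved by projected
#' gradient descent with exact projection onto the capped simplex. The
#' score is the negated signed distance to the learned boundary,
#' `rho - sum_j a_j K(x_j, x)`, so higher means more anomalous.
#'
#' @param X an `encoded_matrix` or numeric matrix.
#' @param nu upper bound on the training outlier fraction, `0 < nu <= 1`.
#' @param gamma RBF kernel width `exp(-gamma * ||x - y||^2)`.
#' @param max_iter projected-gradient iterations.
#' @param tol stop when the iterate moves less than this (sup-norm).
#' @return numeric score per row.
#' @export
ocsvm_scores <- function(X, nu, gamma, max_iter = 2000L, tol = 1e-10) {
  M <- as_values(X)
  n <- nrow(M)
  stopifnot(n >= 2L)
  if (!is.numeric(nu) || nu <= 0 || nu > 1) stop("nu must be in (0, 1]")
  if (!is.numeric(gamma) || gamma <= 0) stop("gamma must be positive")
  sq <- rowSums(M * M)
  D2 <- outer(sq, sq, "+") - 2 * tcrossprod(M)
  D2[D2 < 0] <- 0
  K <- exp(-gamma * D2)
  if (any(!is.finite(K))) {
    stop("degenerate kernel matrix: non-finite entries (check gamma and inputs)")
  }
  C <- 1 / (nu * n)
  alpha <- rep(1 / n, n)
  step <- 1 / max(rowSums(abs(K)))     # 1 / upper bound on ||K||_inf
  for (it in seq_len(max_iter)) {
    g <- as.numeric(K %*% alpha)
    new <- project_capped_simplex(alpha - step * g, C)
    if (max(abs(new - alpha)) < tol) {
      alpha <- new
      break
    }
    alpha <- new
  }
  f <- as.numeric(K %*% alpha)
  on_margin <- alpha > 1e-8 & alpha < C - 1e-8
  rho <- if (any(on_margin)) stats::median(f[on_margin]) else
    stats::median(f[alpha > 1e-8])
  rho - f
}

# Euclidean projection onto {a : 0 <= a_i <= C, sum(a) = 1} by bisection
# on the simplex shift.
project_capped_simplex <- function(v, C) {
  n <- length(v)
  if (n * C < 1) stop("infeasible capped simplex: n * C < 1 (nu too large?)")
  f <- function(tau) sum(clamp(v - tau, 0, C)) - 1
  lo <- min(v) - C - 1
  hi <- max(v)
  for (i in 1:100) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  clamp(v - (lo + hi) / 2, 0, C)
}

#' HDBSCAN (GLOSH) outlier scores
#'
#' Density-hierarchy outlier scores: build the mutual-reachability minimum
#' spanning tree (core distance = distance to the `min_cluster_size`-th
#' nearest point, counting the point itself), grow components in order of
#' increasing reachability, and record for every plan the level
#' `eps(x)` at which it first joins a component of at least
#' `min_cluster_size` points and the birth level `eps_max` of the densest
#' cluster inside that component. The GLOSH score is
#' `1 - eps_max / eps(x)`, in `[0, 1]`, higher = more anomalous.
#'
#' @param X an `encoded_matrix` or numeric matrix.
#' @param min_cluster_size minimum cluster size (>= 2).
#' @return numeric score per row.
#' @export
hdbscan_scores <- function(X, min_cluster_size) {
  M <- as_values(X)
  n <- nrow(M)
  m <- as.integer(min_cluster_size)
  if (is.na(m) || m < 2L) stop("min_cluster_size must be >= 2")
  if (m > n) {
    warning("min_cluster_size exceeds the number of plans; all points are noise")
    return(rep(1, n))
  }
  D <- as.matrix(stats::dist(M))
  core <- apply(D, 1L, function(d) sort(d, partial = m)[m])  # self included (d=0)
  MR <- pmax(D, outer(core, core, pmax))
  diag(MR) <- 0
  mst <- prim_mst(MR)
  mst <- mst[order(mst$w), , drop = FALSE]

  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  size <- rep(1L, n)
  members <- lapply(seq_len(n), identity)
  is_cluster <- rep(FALSE, n)
  min_birth <- rep(Inf, n)
  eps_attach <- rep(NA_real_, n)
  eps_max_at <- rep(NA_real_, n)

  for (e in seq_len(nrow(mst))) {
    a <- find(mst$i[e]); b <- find(mst$j[e]); w <- mst$w[e]
    if (a == b) next
    if (size[a] < size[b]) { tmp <- a; a <- b; b <- tmp }
    new_members <- NULL
    if (is_cluster[a] && is_cluster[b]) {
      # two clusters merge; every point already attached
      min_birth[a] <- min(min_birth[a], min_birth[b])
    } else if (is_cluster[a] && !is_cluster[b]) {
      new_members <- members[[b]]
    } else if (!is_cluster[a] && is_cluster[b]) {
      new_members <- members[[a]]
      min_birth[a] <- min_birth[b]
      is_cluster[a] <- TRUE
    } else if (size[a] + size[b] >= m) {
      # a cluster is born at level w
      new_members <- c(members[[a]], members[[b]])
      min_birth[a] <- w
      is_cluster[a] <- TRUE
    }
    if (!is.null(new_members)) {
      eps_attach[new_members] <- w
      eps_max_at[new_members] <- min_birth[a]
    }
    parent[b] <- a
    size[a] <- size[a] + size[b]
    members[[a]] <- c(members[[a]], members[[b]])
    members[[b]] <- integer(0)
  }
  scores <- ifelse(eps_attach > 0, 1 - eps_max_at / eps_attach, 0)
  clamp(scores, 0, 1)
}

# Prim's MST on a dense symmetric weight matrix; returns edge list.
prim_mst <- function(W) {
  n <- nrow(W)
  in_tree <- rep(FALSE, n)
  best <- rep(Inf, n)
  from <- rep(NA_integer_, n)
  in_tree[1L] <- TRUE
  best <- W[1L, ]
  from[] <- 1L
  edges <- data.frame(i = integer(n - 1L), j = integer(n - 1L),
                      w = numeric(n - 1L))
  for (e in seq_len(n - 1L)) {
    cand <- which(!in_tree)
    nxt <- cand[which.min(best[cand])]
    edges$i[e] <- from[nxt]; edges$j[e] <- nxt; edges$w[e] <- best[nxt]
    in_tree[nxt] <- TRUE
    upd <- which(!in_tree & W[nxt, ] < best)
    best[upd] <- W[nxt, upd]
    from[upd] <- nxt
  }
  edges
}

#' Declare a detector
#'
#' @param kind one of `"lof"`, `"hdbscan"`, `"ocsvm"`, `"pca"`,
#'   `"autoencoder"`.
#' @param ... detector parameters (validated when scoring): LOF
#'   `n_neighbors`; HDBSCAN `min_cluster_size`; OC-SVM `nu`, `gamma`;
#'   PCA `n_components`; autoencoder any [ae_config()] argument.
#' @return an object of class `detector_spec`.
#' @export
detector_spec <- function(kind = c("lof", "hdbscan", "ocsvm", "pca",
                                   "autoencoder"), ...) {
  kind <- match.arg(kind)
  structure(list(kind = kind, params = list(...)), class = "detector_spec")
}

#' @export
print.detector_spec <- function(x, ...) {
  p <- paste(names(x$params), vapply(x$params, format, character(1)),
             sep = "=", collapse = ", ")
  cat(sprintf("<detector_spec> %s(%s)\n", x$kind, p))
  invisible(x)
}

#' Score a matrix with any detector
#'
#' Uniform interface: every detector consumes the encoded matrix and
#' emits one finite score per plan, oriented so that higher means more
#' anomalous, enabling the identical downstream threshold/metric
#' pipeline for all five detector kinds.
#'
#' @param spec a [detector_spec()].
#' @param X an `encoded_matrix` (autoencoder requires one) or matrix.
#' @return numeric score per row.
#' @export
detector_scores <- function(spec, X) {
  stopifnot(inherits(spec, "detector_spec"))
  p <- spec$params
  switch(spec$kind,
    lof = lof_scores(X, p$n_neighbors %||% 10L),
    hdbscan = hdbscan_scores(X, p$min_cluster_size %||% 25L),
    ocsvm = ocsvm_scores(X, p$nu %||% 0.001, p$gamma %||% 0.1),
    pca = pca_scores(X, p$n_components %||% 2L),
    autoencoder = {
      cfg <- do.call(ae_config, p)
      model <- build_autoencoder(cfg, X)
      fit <- ae_train(model, X, cfg)
      sample_errors(fit$model, X)
    })
}

#' Default parameter grids for the baseline detectors
#'
#' Neighbourhoods of the optima reported for this problem class:
#' LOF `n_neighbors` in {5, 10, 20, 40}; OC-SVM `nu` in {1e-3, 1e-2, 0.1}
#' crossed with `gamma` in {0.01, 0.1, 1}; HDBSCAN `min_cluster_size` in
#' {25, 50, 100, 200}; PCA component counts spanning 4 to `n_dims - 1`.
#'
#' @param n_dims encoded dimensionality (bounds the PCA grid).
#' @param kinds which detector kinds to include.
#' @return list of [detector_spec()] candidates.
#' @export
default_grids <- function(n_dims,
                          kinds = c("lof", "hdbscan", "ocsvm", "pca")) {
  specs <- list()
  if ("lof" %in% kinds) {
    specs <- c(specs, lapply(c(5L, 10L, 20L, 40L), function(k)
      detector_spec("lof", n_neighbors = k)))
  }
  if ("hdbscan" %in% kinds) {
    specs <- c(specs, lapply(c(25L, 50L, 100L, 200L), function(m)
      detector_spec("hdbscan", min_cluster_size = m)))
  }
  if ("ocsvm" %in% kinds) {
    for (nu in c(1e-3, 1e-2, 0.1)) for (g in c(0.01, 0.1, 1)) {
      specs <- c(specs, list(detector_spec("ocsvm", nu = nu, gamma = g)))
    }
  }
  if ("pca" %in% kinds) {
    ns <- unique(round(seq(4L, n_dims - 1L, length.out = 8L)))
    ns <- ns[ns >= 1L & ns < n_dims]
    specs <- c(specs, lapply(as.integer(ns), function(k)
      detector_spec("pca", n_components = k)))
  }
  specs
}

#' Grid search over detector candidates
#'
#' Every candidate is evaluated with the shared pipeline (score, TPR==1
#' threshold, metric suite, AUC). The best candidate maximises the stated
#' objective; ties are broken by the smaller number of flagged plans and
#' then by grid order.
#'
#' @param candidates non-empty list of [detector_spec()] objects.
#' @param X an `encoded_matrix`.
#' @param labels ground-truth labels (both classes present).
#' @param objective `"auc"` or `"precision_at_tpr1"`.
#' @return an object of class `grid_result`: `results` data.frame (one
#'   row per candidate) and `best` (the winning spec).
#' @export
grid_search <- function(candidates, X, labels,
                        objective = c("auc", "precision_at_tpr1")) {
  objective <- match.arg(objective)
  if (inherits(candidates, "detector_spec")) candidates <- list(candidates)
  if (length(candidates) == 0L) stop("candidate grid must be non-empty")
  stopifnot(all(vapply(candidates, inherits, logical(1), "detector_spec")))
  rows <- lapply(seq_along(candidates), function(i) {
    spec <- candidates[[i]]
    res <- tryCatch({
      scores <- detector_scores(spec, X)
      ev <- evaluate_scores(scores, labels)
      m <- ev$metrics
      data.frame(candidate = i, kind = spec$kind,
                 params = as.character(jsonlite::toJSON(spec$params,
                                                        auto_unbox = TRUE)),
                 auc = ev$auc, accuracy = m$accuracy,
                 precision = m$precision, recall = m$recall, fpr = m$fpr,
                 f1 = m$f1, anomalies = m$anomalies, failed = FALSE,
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(candidate = i, kind = spec$kind,
                 params = as.character(jsonlite::toJSON(spec$params,
                                                        auto_unbox = TRUE)),
                 auc = NA_real_, accuracy = NA_real_, precision = NA_real_,
                 recall = NA_real_, fpr = NA_real_, f1 = NA_real_,
                 anomalies = NA_integer_, failed = TRUE,
                 stringsAsFactors = FALSE)
    })
    res
  })
  results <- do.call(rbind, rows)
  obj_col <- if (objective == "auc") results$auc else results$precision
  ok <- which(!results$failed & is.finite(obj_col))
  if (length(ok) == 0L) stop("every grid candidate failed")
  ord <- ok[order(-obj_col[ok], results$anomalies[ok], ok)]
  best_idx <- ord[1L]
  structure(
    list(results = results, best = candidates[[best_idx]],
         best_index = best_idx, objective = objective),
    class = "grid_result")
}

#' @export
print.grid_result <- function(x, ...) {
  cat(sprintf("<grid_result> %d candidates, objective=%s; best: ",
              nrow(x$results), x$objective))
  print(x$best)
  invisible(x)
}
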