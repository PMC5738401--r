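#' Normalize particle configurations to zero centroid and unit RMS size
#'
#' Each configuration is translated so the centroid of its k points is at
#' the origin and divided by its root-mean-square point-to-centroid
#' distance, so shapes are compared free of position and scale. The removed
#' centroids and scale factors are recorded so size can be analyzed as a
#' separate question.
#'
#' @param ps a `particle_system`, n x 3k matrix, or list of k x 3 matrices.
#' @param groups optional group labels (length n).
#' @return an object of class `shape_matrix`: fields `X` (n x 3k), `k`,
#'   `groups`, `centroids` (n x 3), `scales` (length n).
#' @export
center_and_scale <- function(ps, groups = NULL) {
  X <- if (is.matrix(ps)) ps else particle_matrix(ps)
  n <- nrow(X)
  k <- ncol(X) / 3L
  stopifnot(k >= 2, ncol(X) %% 3 == 0)
  centroids <- matrix(0, n, 3)
  scales <- numeric(n)
  for (a in seq_len(n)) {
    p <- matrix(X[a, ], k, 3, byrow = TRUE)
    cen <- colMeans(p)
    p <- sweep(p, 2, cen)
    sc <- sqrt(mean(rowSums(p^2)))
    if (sc < 1e-300) {
      stop(sprintf("configuration %d has zero scale (all points coincident)",
                   a))
    }
    X[a, ] <- as.vector(t(p / sc))
    centroids[a, ] <- cen
    scales[a] <- sc
  }
  if (!is.null(groups)) stopifnot(length(groups) == n)
  structure(list(X = X, k = as.integer(k), groups = groups,
                 centroids = centroids, scales = scales),
            class = "shape_matrix")
}

#' @export
print.shape_matrix <- function(x, ...) {
  cat(sprintf("<shape_matrix> %d specimens x %d points\n", nrow(x$X), x$k))
  invisible(x)
}

# one configuration of a shape_matrix as k x 3
shape_config <- function(sm, a) matrix(sm$X[a, ], sm$k, 3, byrow = TRUE)

#' Generalized Procrustes rotation alignment
#'
#' Rotation-only (no scaling, no reflection) alignment of all
#' configurations to their iteratively updated mean. Disabled, it returns
#' the input untouched, which realizes the scale-only reading of the
#' normalization.
#'
#' @param sm a [center_and_scale()] result.
#' @param enable logical flag.
#' @param max_iter,tol iteration cap and convergence threshold on the mean
#'   change (Frobenius norm).
#' @return a `shape_matrix` with rotations applied and recorded in
#'   `$rotations`.
#' @export
procrustes_rotate <- function(sm, enable = TRUE, max_iter = 100L,
                              tol = 1e-8) {
  stopifnot(inherits(sm, "shape_matrix"))
  if (!enable) return(sm)
  n <- nrow(sm$X)
  configs <- lapply(seq_len(n), function(a) shape_config(sm, a))
  rots <- rep(list(diag(3)), n)
  mean_cfg <- Reduce(`+`, configs) / n
  for (it in seq_len(max_iter)) {
    for (a in seq_len(n)) {
      sv <- svd(crossprod(configs[[a]], mean_cfg))
      d <- sign(det(sv$u %*% t(sv$v)))
      R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
      configs[[a]] <- configs[[a]] %*% R
      rots[[a]] <- rots[[a]] %*% R
    }
    new_mean <- Reduce(`+`, configs) / n
    delta <- sqrt(sum((new_mean - mean_cfg)^2))
    mean_cfg <- new_mean
    if (delta < tol) break
  }
  for (a in seq_len(n)) sm$X[a, ] <- as.vector(t(configs[[a]]))
  sm$rotations <- rots
  sm
}

#' Principal component analysis of a shape matrix
#'
#' Eigen-decomposition of the sample covariance through the dual n x n
#' problem (thin SVD of the centered matrix), appropriate since n << 3k.
#'
#' @param sm a `shape_matrix` with n >= 3 rows.
#' @return an object of class `pca_model`: `mean` (length 3k), `E` (3k x r
#'   orthonormal), `lambda` (descending, length r), `loadings` (n x r),
#'   `k`, `m` (retained modes; initialized to r, set by
#'   [parallel_analysis()]).
#' @export
fit_pca <- function(sm) {
  stopifnot(inherits(sm, "shape_matrix"))
  n <- nrow(sm$X)
  if (n < 3) stop("PCA requires at least 3 specimens")
  mu <- colMeans(sm$X)
  Y <- sweep(sm$X, 2, mu)
  sv <- svd(Y)
  r <- min(n - 1L, ncol(sm$X))
  keep <- seq_len(r)
  lambda <- sv$d[keep]^2 / (n - 1)
  E <- sv$v[, keep, drop = FALSE]
  loadings <- Y %*% E
  structure(list(mean = mu, E = E, lambda = lambda, loadings = loadings,
                 k = sm$k, n = n, m = r, groups = sm$groups),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> n=%d, r=%d modes, m=%d retained\n",
              x$n, length(x$lambda), x$m))
  invisible(x)
}

# leading eigenvalues (descending) of the covariance of an n x p matrix,
# via the dual Gram problem
.dual_eigenvalues <- function(M) {
  n <- nrow(M)
  Y <- sweep(M, 2, colMeans(M))
  ev <- eigen(tcrossprod(Y), symmetric = TRUE, only.values = TRUE)$values
  pmax(ev[seq_len(n - 1)], 0) / (n - 1)
}

#' Retained mode count by parallel analysis
#'
#' Horn-style criterion: the j-th data eigenvalue is retained while it
#' exceeds the chosen quantile of the j-th eigenvalue distribution obtained
#' from synthetic datasets of matched dimensions with independent normal
#' entries scaled to the data's per-column standard deviations. `m` is the
#' length of the leading run of retained eigenvalues.
#'
#' @param sm a `shape_matrix` (or any n x p matrix).
#' @param n_draws number of synthetic datasets (>= 100).
#' @param quantile_level criterion quantile in (0.5, 1); default 0.95.
#' @param seed integer seed; result is deterministic given it.
#' @return integer retained mode count `m` (possibly 0).
#' @export
parallel_analysis <- function(sm, n_draws = 500L, quantile_level = 0.95,
                              seed = 1L) {
  stopifnot(n_draws >= 100L, quantile_level > 0.5, quantile_level < 1)
  X <- if (inherits(sm, "shape_matrix")) sm$X else as.matrix(sm)
  n <- nrow(X)
  p <- ncol(X)
  lam <- .dual_eigenvalues(X)
  if (all(lam <= 0)) return(0L)
  colsd <- apply(X, 2, stats::sd)
  set.seed(as.integer(seed))
  null_lam <- matrix(0, n_draws, n - 1L)
  for (b in seq_len(n_draws)) {
    Z <- matrix(stats::rnorm(n * p), n, p) *
      matrix(colsd, n, p, byrow = TRUE)
    null_lam[b, ] <- .dual_eigenvalues(Z)
  }
  thresh <- apply(null_lam, 2, stats::quantile, probs = quantile_level,
                  names = FALSE)
  above <- lam > thresh
  m <- if (above[1]) which.min(c(above, FALSE)) - 1L else 0L
  as.integer(m)
}

#' Apply parallel analysis to a fitted PCA model
#'
#' @param model a `pca_model`.
#' @param sm the `shape_matrix` the model was fit on.
#' @inheritParams parallel_analysis
#' @return the model with `m` set (floored at 1 if `ensure_one`).
#' @param ensure_one keep at least one mode even if the criterion retains
#'   none (downstream tests need m >= 1).
#' @export
retain_modes <- function(model, sm, n_draws = 500L, quantile_level = 0.95,
                         seed = 1L, ensure_one = TRUE) {
  m <- parallel_analysis(sm, n_draws = n_draws,
                         quantile_level = quantile_level, seed = seed)
  if (ensure_one) m <- max(m, 1L)
  model$m <- min(as.integer(m), length(model$lambda))
  model
}

#' Reconstruct a configuration at s standard deviations along one mode
#'
#' `mu + s * sqrt(lambda_j) * E_j`, reshaped to k x 3 — the "mode walk"
#' visualization of a shape model.
#'
#' @param model a `pca_model`.
#' @param mode mode index j (1 <= j <= m).
#' @param s number of standard deviations (|s| <= 5).
#' @return k x 3 point configuration.
#' @export
reconstruct_at_sd <- function(model, mode, s) {
  stopifnot(inherits(model, "pca_model"), abs(s) <= 5)
  if (mode < 1 || mode > model$m) {
    stop(sprintf("mode %d out of retained range 1..%d", mode, model$m))
  }
  v <- model$mean + s * sqrt(model$lambda[mode]) * model$E[, mode]
  matrix(v, model$k, 3, byrow = TRUE)
}
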