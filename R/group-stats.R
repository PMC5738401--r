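#' Two-sample Hotelling T-squared statistic and Fisher discriminant
#'
#' With group scatter matrices `S_a, S_b` (sums of outer products of
#' within-group deviations), the discriminant is
#' `w = (S_a + S_b)^{-1} (mu_a - mu_b)` and
#' `T2 = n_a n_b (n_a + n_b - 2) / (n_a + n_b) * (mu_a - mu_b)' w`
#' (the standard two-sample scaling; with m = 1 this is the squared
#' pooled-variance t statistic). The `prefactor` argument exists to verify
#' that permutation inference is invariant to the constant in front of the
#' quadratic form.
#'
#' @param A,B loading matrices (n_a x m and n_b x m).
#' @param prefactor `"standard"` or `"printed"` (`n_a + n_b - 2`).
#' @return list with `T2` and discriminant `w` (length m).
#' @export
hotelling_t2 <- function(A, B, prefactor = c("standard", "printed")) {
  prefactor <- match.arg(prefactor)
  A <- rbind(A); B <- rbind(B)
  m <- ncol(A)
  na <- nrow(A); nb <- nrow(B)
  if (na + nb - 2 <= m) {
    stop("too few observations: need n_a + n_b - 2 > m; reduce m")
  }
  mu_a <- colMeans(A); mu_b <- colMeans(B)
  Sa <- crossprod(sweep(A, 2, mu_a))
  Sb <- crossprod(sweep(B, 2, mu_b))
  d <- mu_a - mu_b
  w <- tryCatch(solve(Sa + Sb, d), error = function(e) {
    stop("singular pooled scatter; reduce the number of retained modes")
  })
  pf <- if (prefactor == "standard") {
    na * nb * (na + nb - 2) / (na + nb)
  } else {
    na + nb - 2  # the printed prefactor simplifies to this constant
  }
  list(T2 = as.numeric(pf * sum(d * w)), w = as.numeric(w))
}

#' Parametric p-value of the two-sample Hotelling T-squared test
#'
#' Uses the exact F transform `F = T2 (N - m - 1) / (m (N - 2))` on
#' `(m, N - m - 1)` degrees of freedom, `N = n_a + n_b`.
#'
#' @param T2 statistic value (standard scaling).
#' @param n_a,n_b group sizes.
#' @param m dimension of the loading space.
#' @return upper-tail p-value.
#' @export
parametric_p <- function(T2, n_a, n_b, m) {
  N <- n_a + n_b
  if (N - m - 1 < 1) stop("degrees of freedom N - m - 1 must be >= 1")
  stopifnot(T2 >= 0)
  fstat <- T2 * (N - m - 1) / (m * (N - 2))
  stats::pf(fstat, m, N - m - 1, lower.tail = FALSE)
}

# all label assignments for exhaustive permutation (columns = index sets)
.exhaustive_sets <- function(N, n_a) utils::combn(N, n_a)

# canonical group order so Monte-Carlo permutation p-values are invariant
# under swapping the two groups: smaller group first; exact ties broken by
# lexicographic comparison of the flattened data
.canonical_first <- function(A, B) {
  if (nrow(A) != nrow(B)) return(nrow(A) < nrow(B))
  va <- as.vector(A); vb <- as.vector(B)
  i <- which(va != vb)[1]
  is.na(i) || va[i] < vb[i]
}

#' Permutation p-value of the Hotelling T-squared test
#'
#' Group labels are permuted uniformly at random `B_perms` times and the
#' statistic recomputed; `p = (1 + #\{T2_perm >= T2_obs\}) / (1 + B)`. When
#' the total number of assignments `choose(n_a + n_b, n_a)` does not exceed
#' `B_perms`, exhaustive enumeration is used instead and `p` is the exact
#' fraction. The result is invariant to the T2 prefactor (a constant across
#' permutations) and deterministic given `seed`.
#'
#' @inheritParams hotelling_t2
#' @param B_perms number of random permutations (>= 100).
#' @param seed integer seed.
#' @return list with `p`, `B` (permutations used), `exhaustive`, `T2`, `w`,
#'   `n_redrawn` (singular permutations re-drawn).
#' @export
permutation_p <- function(A, B, B_perms = 20000L, seed = 1L,
                          prefactor = c("standard", "printed")) {
  prefactor <- match.arg(prefactor)
  stopifnot(B_perms >= 100L)
  A <- rbind(A); B <- rbind(B)
  obs <- hotelling_t2(A, B, prefactor)
  if (!.canonical_first(A, B)) { tmp <- A; A <- B; B <- tmp }
  na <- nrow(A); nb <- nrow(B)
  pooled <- rbind(A, B)
  N <- na + nb
  stat <- function(idx) {
    hotelling_t2(pooled[idx, , drop = FALSE],
                 pooled[-idx, , drop = FALSE], prefactor)$T2
  }
  eps <- 1e-12 * max(obs$T2, 1)
  if (choose(N, na) <= B_perms) {
    sets <- .exhaustive_sets(N, na)
    t2s <- apply(sets, 2, stat)
    return(list(p = mean(t2s >= obs$T2 - eps), B = ncol(sets),
                exhaustive = TRUE, T2 = obs$T2, w = obs$w, n_redrawn = 0L))
  }
  set.seed(as.integer(seed))
  count <- 0L
  redrawn <- 0L
  b <- 0L
  while (b < B_perms) {
    idx <- sample.int(N, na)
    t2p <- tryCatch(stat(idx), error = function(e) NA_real_)
    if (is.na(t2p)) { redrawn <- redrawn + 1L; next }
    if (t2p >= obs$T2 - eps) count <- count + 1L
    b <- b + 1L
  }
  list(p = (1 + count) / (1 + B_perms), B = B_perms, exhaustive = FALSE,
       T2 = obs$T2, w = obs$w, n_redrawn = redrawn)
}

#' Back-project a PCA-space discriminant into shape space
#'
#' Pads `w` (length m) with zeros to the full mode count r, maps through
#' the orthonormal basis (`w_hat = E w_tilde`, realizing the inverse-basis
#' convention via orthonormality), and reshapes to per-correspondence
#' arrow vectors. Arrow scaling for display is the caller's concern.
#'
#' @param w discriminant in loading space (length m <= r).
#' @param model a `pca_model`.
#' @return list with `w_hat` (length 3k), `arrows` (k x 3), `w_tilde`.
#' @export
map_discriminant <- function(w, model) {
  r <- length(model$lambda)
  m <- length(w)
  if (m > r) stop("discriminant has more components than PCA modes")
  w_tilde <- c(w, rep(0, r - m))
  w_hat <- as.numeric(model$E %*% w_tilde)
  list(w_hat = w_hat, arrows = matrix(w_hat, model$k, 3, byrow = TRUE),
       w_tilde = w_tilde)
}

# deviation of each row from its group's center (mean or coordinate-wise
# median), Euclidean norm in loading space
.levene_deviations <- function(A, B, center = c("mean", "median")) {
  center <- match.arg(center)
  cen <- function(M) {
    if (center == "mean") colMeans(M) else apply(M, 2, stats::median)
  }
  list(da = row_norms(sweep(A, 2, cen(A))),
       db = row_norms(sweep(B, 2, cen(B))))
}

# pooled-variance two-sample t on deviation magnitudes
.levene_t <- function(da, db) {
  na <- length(da); nb <- length(db)
  sp2 <- (sum((da - mean(da))^2) + sum((db - mean(db))^2)) / (na + nb - 2)
  if (sp2 < 1e-300) return(0)
  (mean(da) - mean(db)) / sqrt(sp2 * (1 / na + 1 / nb))
}

#' Multivariate Levene variance-test battery
#'
#' Tests equality of multivariate dispersion between two groups of PCA
#' loadings. Each observation's deviation is its Euclidean distance from
#' its group center (mean, or coordinate-wise median in the
#' Brown-Forsythe-style variant); the deviations are compared with a
#' pooled-variance two-sample t test. The "randomized" variants replace
#' the parametric reference by a group-label permutation null on the
#' deviations (exhaustive when feasible).
#'
#' @param A,B loading matrices.
#' @param B_perms permutations for the randomized variants.
#' @param seed integer seed.
#' @return an object of class `levene_result`: p-values `mean`, `median`,
#'   `randomized_mean`, `randomized_median`, plus `B`.
#' @export
levene_tests <- function(A, B, B_perms = 20000L, seed = 1L) {
  A <- rbind(A); B <- rbind(B)
  if (!.canonical_first(A, B)) { tmp <- A; A <- B; B <- tmp }
  na <- nrow(A); nb <- nrow(B)
  stopifnot(na >= 3, nb >= 3)
  out <- list(B = B_perms)
  warned <- FALSE
  for (variant in c("mean", "median")) {
    dv <- .levene_deviations(A, B, variant)
    if (all(c(dv$da, dv$db) == 0)) {
      if (!warned) warning("all deviations zero in both groups; p = 1")
      warned <- TRUE
      out[[variant]] <- 1
      out[[paste0("randomized_", variant)]] <- 1
      next
    }
    tobs <- .levene_t(dv$da, dv$db)
    out[[variant]] <- 2 * stats::pt(-abs(tobs), df = na + nb - 2)
    pooled <- c(dv$da, dv$db)
    N <- na + nb
    eps <- 1e-12 * max(abs(tobs), 1)
    if (choose(N, na) <= B_perms) {
      sets <- .exhaustive_sets(N, na)
      tp <- apply(sets, 2, function(idx) {
        .levene_t(pooled[idx], pooled[-idx])
      })
      out[[paste0("randomized_", variant)]] <-
        mean(abs(tp) >= abs(tobs) - eps)
    } else {
      set.seed(derive_seed(seed, paste0("levene_", variant)))
      count <- 0L
      for (b in seq_len(B_perms)) {
        idx <- sample.int(N, na)
        if (abs(.levene_t(pooled[idx], pooled[-idx])) >= abs(tobs) - eps) {
          count <- count + 1L
        }
      }
      out[[paste0("randomized_", variant)]] <- (1 + count) / (1 + B_perms)
    }
  }
  structure(out, class = "levene_result")
}

#' @export
print.levene_result <- function(x, ...) {
  cat(sprintf(paste0("<levene_result> mean p=%.3g, median p=%.3g, ",
                     "randomized mean p=%.3g, randomized median p=%.3g\n"),
              x$mean, x$median, x$randomized_mean, x$randomized_median))
  invisible(x)
}

#' Group mean shape as a point configuration
#'
#' @param sm a `shape_matrix` with group labels.
#' @param group group label.
#' @return k x 3 coordinate-wise mean configuration.
#' @export
group_mean_shape <- function(sm, group) {
  stopifnot(inherits(sm, "shape_matrix"))
  rows <- which(sm$groups == group)
  if (length(rows) == 0) stop("empty group: ", group)
  v <- colMeans(sm$X[rows, , drop = FALSE])
  matrix(v, sm$k, 3, byrow = TRUE)
}

#' Full two-group comparison in PCA space
#'
#' Convenience wrapper running [hotelling_t2()], [parametric_p()],
#' [permutation_p()], [levene_tests()] and [map_discriminant()] on the
#' retained loadings of a fitted model.
#'
#' @param model a `pca_model` carrying group labels (or pass `groups`).
#' @param group_a,group_b labels of the reference and contrast groups; the
#'   discriminant and arrows are oriented from `group_a` toward `group_b`.
#' @param B_perms permutation count.
#' @param seed integer seed.
#' @param groups optional explicit label vector.
#' @return an object of class `group_comparison`.
#' @export
compare_groups <- function(model, group_a, group_b, B_perms = 20000L,
                           seed = 1L, groups = model$groups) {
  stopifnot(inherits(model, "pca_model"), !is.null(groups))
  m <- model$m
  L <- model$loadings[, seq_len(m), drop = FALSE]
  A <- L[groups == group_a, , drop = FALSE]
  B <- L[groups == group_b, , drop = FALSE]
  ht <- hotelling_t2(A, B)
  # orientation: arrows point from group_a toward group_b
  w_ab <- -ht$w
  pp <- permutation_p(A, B, B_perms = B_perms, seed = seed)
  disc <- map_discriminant(w_ab, model)
  structure(list(
    group_a = group_a, group_b = group_b,
    n_a = nrow(A), n_b = nrow(B), m = m,
    T2 = ht$T2,
    p_parametric = parametric_p(ht$T2, nrow(A), nrow(B), m),
    p_permutation = pp$p, B = pp$B, exhaustive = pp$exhaustive,
    w = w_ab, w_hat = disc$w_hat, arrows = disc$arrows,
    levene = levene_tests(A, B, B_perms = B_perms, seed = seed)
  ), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s vs %s (n=%d/%d, m=%d)\n",
              x$group_a, x$group_b, x$n_a, x$n_b, x$m))
  cat(sprintf("  T2 = %.4g, parametric p = %.4g, permutation p = %.4g (B=%d)\n",
              x$T2, x$p_parametric, x$p_permutation, x$B))
  cat(sprintf("  Levene p: mean %.3g / median %.3g / rand mean %.3g / rand median %.3g\n",
              x$levene$mean, x$levene$median, x$levene$randomized_mean,
              x$levene$randomized_median))
  invisible(x)
}
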