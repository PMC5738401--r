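#' Configuration of the particle-based correspondence optimizer
#'
#' The optimizer minimizes the combined model entropy
#' `Q = H(Z) - sum_a H(P_a)`: the ensemble term `H(Z) = 1/2 sum_j
#' log(lambda_j + alpha)` (eigenvalues of the covariance of the flattened,
#' centered particle configurations) rewards compact, low-entropy models,
#' while maximizing the per-shape Parzen entropies `H(P_a)` spreads
#' particles uniformly over each surface. All length-like settings are
#' expressed relative to the ensemble's mean foreground bounding-box
#' diagonal, so converged configurations are equivariant under global
#' rescaling.
#'
#' @param k_target particle count per shape; a power of two (splitting
#'   doubles the count each level).
#' @param target_neighbors Parzen kernel widths adapt per particle so the
#'   Gaussian-weighted neighbor count hits this value.
#' @param sampling_weight,ensemble_weight relative weights of the two terms
#'   in the joint phase. The ensemble term is applied as `ensemble_weight *
#'   n * H(Z)` (its per-shape gradient dilutes like 1/n, so n-scaling keeps
#'   the correspondence anchoring commensurate with the per-shape sampling
#'   term at any cohort size); the default 0.1 reproduces a classical 1:1
#'   balance at n = 10.
#' @param alpha_rel ensemble regularization: `alpha = alpha_rel * mean
#'   sigma^2`, frozen per iteration.
#' @param step0 initial step size (dimensionless; steps are preconditioned
#'   by per-particle `sigma^2`).
#' @param iter_spread per-level iterations of the uniform-spread phase run
#'   after each split.
#' @param iter_joint iterations of the final joint phase.
#' @param conv_tol_rel stop a phase when the mean particle displacement
#'   falls below this fraction of the ensemble diagonal.
#' @param split_frac child perturbation at splits, fraction of the diagonal.
#' @param surface_tol_frac surface tolerance, fraction of the voxel spacing.
#' @param max_backtrack step-halvings allowed before an iteration is
#'   rejected.
#' @param seed integer seed (only the split offsets are stochastic).
#' @return an object of class `corr_config`.
#' @export
corr_config <- function(k_target = 128L, target_neighbors = 6,
                        sampling_weight = 1, ensemble_weight = 0.1,
                        alpha_rel = 0.05, step0 = 1, iter_spread = 6L,
                        iter_joint = 60L, conv_tol_rel = 2e-4,
                        split_frac = 0.02, surface_tol_frac = 0.05,
                        max_backtrack = 10L, seed = 1L) {
  stopifnot(k_target >= 1, bitwAnd(as.integer(k_target),
                                   as.integer(k_target) - 1L) == 0L,
            target_neighbors > 0, alpha_rel > 0, step0 > 0,
            conv_tol_rel > 0, split_frac > 0, surface_tol_frac > 0,
            sampling_weight >= 0, ensemble_weight >= 0)
  structure(list(k_target = as.integer(k_target),
                 target_neighbors = target_neighbors,
                 sampling_weight = sampling_weight,
                 ensemble_weight = ensemble_weight, alpha_rel = alpha_rel,
                 step0 = step0, iter_spread = as.integer(iter_spread),
                 iter_joint = as.integer(iter_joint),
                 conv_tol_rel = conv_tol_rel, split_frac = split_frac,
                 surface_tol_frac = surface_tol_frac,
                 max_backtrack = as.integer(max_backtrack),
                 seed = as.integer(seed)),
            class = "corr_config")
}

# foreground (phi < 0) bounding-box diagonal of one surface, world units
.surface_diag <- function(s) {
  idx <- which(s$phi < 0, arr.ind = TRUE) - 1
  ext <- (apply(idx, 2, max) - apply(idx, 2, min) + 1) * s$spacing
  vnorm(ext)
}

.surface_tol <- function(s, cfg) cfg$surface_tol_frac * min(s$spacing)

#' Initialize a particle system with one particle per shape
#'
#' The single particle is placed at the surface point nearest each shape's
#' foreground centroid (centroid projected onto the zero level set), which
#' is deterministic given the inputs.
#'
#' @param surfaces list of >= 2 [implicit_surface()] objects.
#' @param cfg a [corr_config()].
#' @return an object of class `particle_system`.
#' @export
initialize_particles <- function(surfaces, cfg = corr_config()) {
  if (length(surfaces) < 2L) {
    stop("at least 2 surfaces are required (ensemble undefined)")
  }
  positions <- vector("list", length(surfaces))
  for (a in seq_along(surfaces)) {
    s <- surfaces[[a]]
    idx <- which(s$phi < 0, arr.ind = TRUE) - 1
    cen <- colMeans(idx) * matrix(s$spacing, nrow(idx), 3, byrow = TRUE)[1, ] +
      s$origin
    # nearest zero-band voxel to the centroid; near-ties broken toward
    # larger z, then y, then x, so that equally-near candidates (e.g. the
    # two poles of a symmetric shape) resolve consistently across aligned
    # specimens rather than by noise
    band <- which(abs(s$phi) <= max(s$spacing), arr.ind = TRUE) - 1
    if (nrow(band) == 0L) stop(sprintf("no surface band on shape %d", a))
    w <- band * matrix(s$spacing, nrow(band), 3, byrow = TRUE) +
      matrix(s$origin, nrow(band), 3, byrow = TRUE)
    dcen <- row_norms(sweep(w, 2, cen))
    cand <- which(dcen <= min(dcen) + max(s$spacing))
    pick <- cand[order(w[cand, 3], w[cand, 2], w[cand, 1],
                       decreasing = TRUE)[1]]
    p <- tryCatch(
      project_to_surface(w[pick, ], s, tol = .surface_tol(s, cfg)),
      error = function(e) stop(sprintf("initialization failed on shape %d: %s",
                                       a, conditionMessage(e)))
    )
    positions[[a]] <- matrix(p[1, ], 1, 3)
  }
  structure(list(positions = positions, surfaces = surfaces, k = 1L,
                 cfg = cfg,
                 diag = mean(vapply(surfaces, .surface_diag, 0)),
                 meta = list(converged = NA, trace = NULL)),
            class = "particle_system")
}

#' @export
print.particle_system <- function(x, ...) {
  cat(sprintf("<particle_system> %d shapes x %d particles\n",
              length(x$positions), x$k))
  invisible(x)
}

#' Double the particle count by splitting
#'
#' Every particle spawns one child displaced by the same random offset
#' vector for a given particle index across all shapes (so correspondence
#' is preserved by construction), then projected back to each surface.
#'
#' @param ps a `particle_system`.
#' @param perturbation offset magnitude in world units; default
#'   `split_frac` of the ensemble diagonal.
#' @param level integer label deriving the offset seed from `cfg$seed`.
#' @return the particle system with `k` doubled.
#' @export
split_particles <- function(ps, perturbation = NULL, level = ps$k) {
  cfg <- ps$cfg
  if (is.null(perturbation)) perturbation <- cfg$split_frac * ps$diag
  stopifnot(perturbation > 0)
  set.seed(derive_seed(cfg$seed, sprintf("split%06d", level)))
  dirs <- matrix(stats::rnorm(3 * ps$k), ps$k, 3)
  offsets <- dirs / row_norms(dirs) * perturbation
  for (a in seq_along(ps$positions)) {
    s <- ps$surfaces[[a]]
    children <- ps$positions[[a]] + offsets
    children <- tryCatch(
      project_to_surface(children, s, tol = .surface_tol(s, cfg)),
      error = function(e) stop(sprintf("split failed on shape %d: %s",
                                       a, conditionMessage(e)))
    )
    ps$positions[[a]] <- rbind(ps$positions[[a]], children)
  }
  ps$k <- 2L * ps$k
  ps
}

# tangent-plane projection of per-particle vectors on a surface
.tangent_project <- function(g, s, pts) {
  n <- sdf_gradient(s, pts)
  n <- n / pmax(row_norms(n), 1e-12)
  g - n * rowSums(g * n)
}

#' Per-shape sampling-entropy gradient
#'
#' Gradient of the (negative) Parzen sampling entropy of one shape's
#' particles, i.e. the crowding term `E_a = 1/k sum_i log(S_i / (k-1))`
#' whose descent direction is a pairwise Gaussian repulsion. Kernel widths
#' adapt per particle to the configured neighbor count; the gradient is
#' projected into the local tangent plane.
#'
#' @param ps a `particle_system` with `k >= 2`.
#' @param a shape index.
#' @param sigma optional fixed kernel widths (length k); adapted if NULL.
#' @return list with `grad` (k x 3, tangent-projected), `value` (the
#'   crowding term) and `sigma`.
#' @export
sampling_entropy_gradient <- function(ps, a, sigma = NULL) {
  stopifnot(ps$k >= 2L)
  pts <- ps$positions[[a]]
  if (is.null(sigma)) {
    sigma <- .adapt_sigma(pts, ps$cfg$target_neighbors,
                          1e-6 * ps$diag, 2 * ps$diag)
  }
  terms <- .parzen_terms(pts, sigma, 1e3 / ps$diag * ps$k)
  g <- .tangent_project(terms$grad / ps$k, ps$surfaces[[a]], pts)
  list(grad = g, value = terms$value / ps$k, sigma = sigma)
}

# ensemble entropy 1/2 sum log(lambda_j + alpha) and its exact gradient on
# the flattened configuration matrix X (n x 3k); used by the optimizer and
# directly testable against finite differences
.ensemble_terms <- function(X, alpha) {
  n <- nrow(X)
  Y <- sweep(X, 2, colMeans(X))
  sv <- svd(Y)
  lam <- sv$d^2 / (n - 1)
  value <- 0.5 * sum(log(lam[seq_len(min(n - 1, length(lam)))] + alpha))
  coef <- sv$d / ((lam + alpha) * (n - 1))
  G <- sv$u %*% (coef * t(sv$v))
  G <- G - matrix(colMeans(G), n, ncol(X), byrow = TRUE)  # centering chain
  list(value = value, grad = G, lambda = lam)
}

#' Ensemble (model) entropy gradient
#'
#' Gradient of `H(Z) = 1/2 sum_j log(lambda_j + alpha)` where `lambda_j`
#' are eigenvalues of the covariance of the n flattened, centered particle
#' configurations, computed through the dual (thin SVD) problem. Each
#' shape's gradient rows are projected into its tangent planes.
#'
#' @param ps a `particle_system` with >= 2 shapes.
#' @param alpha regularization floor added to the eigenvalues (> 0).
#' @return list with `grads` (list of k x 3 per shape), `value` and
#'   `lambda`.
#' @export
ensemble_entropy_gradient <- function(ps, alpha) {
  stopifnot(alpha > 0, length(ps$positions) >= 2L)
  X <- t(vapply(ps$positions, function(p) as.vector(t(p)),
                numeric(3L * ps$k)))
  et <- .ensemble_terms(X, alpha)
  grads <- vector("list", length(ps$positions))
  for (a in seq_along(ps$positions)) {
    g <- matrix(et$grad[a, ], ps$k, 3, byrow = TRUE)
    grads[[a]] <- .tangent_project(g, ps$surfaces[[a]], ps$positions[[a]])
  }
  list(grads = grads, value = et$value, lambda = et$lambda)
}

# combined objective at given positions with frozen sigma/alpha
.objective <- function(positions, k, sigmas, alpha, w_s, w_e) {
  val <- 0
  if (w_s > 0 && k >= 2) {
    for (a in seq_along(positions)) {
      val <- val + w_s *
        .parzen_terms(positions[[a]], sigmas[[a]], Inf)$value / k
    }
  }
  if (w_e > 0) {
    n <- length(positions)
    X <- t(vapply(positions, function(p) as.vector(t(p)), numeric(3L * k)))
    val <- val + w_e * .ensemble_terms(X, alpha)$value
  }
  val
}

# one optimization phase: preconditioned projected gradient descent with
# backtracking; returns updated system plus trace rows
.run_phase <- function(ps, n_iter, w_s, w_e, phase_name) {
  cfg <- ps$cfg
  n <- length(ps$positions)
  # the ensemble term enters as w_e * n * H(Z): the gradient of H(Z) on any
  # single shape shrinks like 1/n, so n-scaling keeps the anchoring force
  # per shape commensurate with the (n-independent) sampling term as the
  # cohort grows
  w_e <- w_e * n
  eta <- cfg$step0
  trace <- list()
  tols <- vapply(ps$surfaces, .surface_tol, 0, cfg = cfg)
  converged <- FALSE
  for (it in seq_len(n_iter)) {
    sigmas <- lapply(seq_len(n), function(a) {
      .adapt_sigma(ps$positions[[a]], cfg$target_neighbors,
                   1e-6 * ps$diag, 2 * ps$diag)
    })
    alpha <- cfg$alpha_rel * mean(vapply(sigmas, function(s) mean(s^2), 0))
    # raw gradients accumulated first, one tangent projection per shape
    # (projection is linear, so combining before projecting is exact)
    grads <- vector("list", n)
    for (a in seq_len(n)) grads[[a]] <- matrix(0, ps$k, 3)
    if (w_s > 0 && ps$k >= 2) {
      for (a in seq_len(n)) {
        terms <- .parzen_terms(ps$positions[[a]], sigmas[[a]],
                               1e3 / ps$diag * ps$k)
        grads[[a]] <- grads[[a]] + (w_s / ps$k) * terms$grad
      }
    }
    if (w_e > 0) {
      X <- t(vapply(ps$positions, function(p) as.vector(t(p)),
                    numeric(3L * ps$k)))
      et <- .ensemble_terms(X, alpha)
      for (a in seq_len(n)) {
        grads[[a]] <- grads[[a]] + w_e * matrix(et$grad[a, ], ps$k, 3,
                                                byrow = TRUE)
      }
    }
    for (a in seq_len(n)) {
      grads[[a]] <- .tangent_project(grads[[a]], ps$surfaces[[a]],
                                     ps$positions[[a]])
    }
    q_old <- .objective(ps$positions, ps$k, sigmas, alpha, w_s, w_e)
    accepted <- FALSE
    disp <- NA_real_
    for (bt in 0:cfg$max_backtrack) {
      step <- eta / 2^bt
      trial <- vector("list", n)
      ok <- TRUE
      for (a in seq_len(n)) {
        delta <- -step * sigmas[[a]]^2 * grads[[a]]
        # trust region: no particle moves more than half its kernel width
        rn <- row_norms(delta)
        cap <- 0.5 * sigmas[[a]]
        over <- rn > cap
        if (any(over)) delta[over, ] <- delta[over, ] * (cap / rn)[over]
        pr <- project_to_surface(ps$positions[[a]] + delta,
                                 ps$surfaces[[a]], tol = tols[a],
                                 strict = FALSE)
        if (!all(attr(pr, "converged"))) { ok <- FALSE; break }
        trial[[a]] <- matrix(as.numeric(pr), nrow(pr), 3L)
      }
      if (!ok) next
      q_new <- .objective(trial, ps$k, sigmas, alpha, w_s, w_e)
      if (q_new <= q_old + 1e-12 * abs(q_old)) {
        disp <- mean(vapply(seq_len(n), function(a) {
          mean(row_norms(trial[[a]] - ps$positions[[a]]))
        }, 0))
        ps$positions <- trial
        accepted <- TRUE
        eta <- if (bt == 0) min(eta * 1.5, 20 * cfg$step0) else 2 * step
        trace[[length(trace) + 1]] <-
          data.frame(phase = phase_name, k = ps$k, iter = it,
                     q_before = q_old, q_after = q_new, step = step,
                     disp = disp)
        break
      }
    }
    if (!accepted) { converged <- TRUE; break }
    if (disp < cfg$conv_tol_rel * ps$diag) { converged <- TRUE; break }
  }
  ps$meta$trace <- rbind(ps$meta$trace,
                         if (length(trace)) do.call(rbind, trace))
  ps$meta$phase_converged <- c(ps$meta$phase_converged,
                               stats::setNames(converged, phase_name))
  ps
}

#' Optimize particle correspondences over an ensemble of surfaces
#'
#' Alternates a splitting schedule (1 -> 2 -> ... -> `k_target` particles,
#' identical per-index split offsets across shapes) with a uniform-spread
#' phase after each split, and finishes with a joint phase combining the
#' per-shape sampling term and the ensemble entropy term. Fully
#' reproducible given `cfg$seed`. Non-convergence of a phase is recorded in
#' `$meta` (warning flag), not raised as an error.
#'
#' @param surfaces list of >= 2 [implicit_surface()] objects.
#' @param cfg a [corr_config()].
#' @return a converged `particle_system` with `k = cfg$k_target`.
#' @export
optimize_correspondence <- function(surfaces, cfg = corr_config()) {
  ps <- initialize_particles(surfaces, cfg)
  while (ps$k < cfg$k_target) {
    ps <- split_particles(ps)
    ps <- .run_phase(ps, cfg$iter_spread, w_s = cfg$sampling_weight,
                     w_e = 0, phase_name = sprintf("spread_k%d", ps$k))
    # keep shapes in correspondence while k grows: a joint phase follows
    # every split, including the earliest levels, so particles on different
    # specimens never settle into different symmetry basins
    if (cfg$iter_joint > 0 && cfg$ensemble_weight > 0) {
      iters <- if (ps$k < cfg$k_target) {
        max(10L, cfg$iter_joint %/% 2L)
      } else {
        cfg$iter_joint
      }
      ps <- .run_phase(ps, iters, w_s = cfg$sampling_weight,
                       w_e = cfg$ensemble_weight,
                       phase_name = sprintf("joint_k%d", ps$k))
    }
  }
  ps$meta$converged <- all(ps$meta$phase_converged)
  if (!ps$meta$converged) {
    ps$meta$warning <- "optimizer hit iteration limits; best-so-far returned"
  }
  ps
}

#' Particle positions as an n x 3k matrix
#'
#' Rows are specimens; columns are flattened `(x1 y1 z1 ... xk yk zk)`
#' particle coordinates, the layout used by all downstream statistics.
#'
#' @param ps a `particle_system` (or plain list of k x 3 matrices).
#' @return n x 3k numeric matrix.
#' @export
particle_matrix <- function(ps) {
  pos <- if (inherits(ps, "particle_system")) ps$positions else ps
  t(vapply(pos, function(p) as.vector(t(p)), numeric(3L * nrow(pos[[1]]))))
}

#' Write a particle system as per-shape point files plus a JSON manifest
#'
#' @param ps a `particle_system`.
#' @param dir output directory.
#' @param ids optional specimen ids (default shape01, ...).
#' @return manifest path, invisibly.
#' @export
write_particles <- function(ps, dir, ids = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(ps$positions)
  if (is.null(ids)) ids <- sprintf("shape%02d", seq_len(n))
  paths <- file.path(dir, paste0(ids, ".pts"))
  for (a in seq_len(n)) write_points(ps$positions[[a]], paths[a])
  manifest <- list(k = ps$k, n = n, ids = ids, files = basename(paths),
                   converged = ps$meta$converged)
  mp <- file.path(dir, "particles.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE)
  invisible(mp)
}
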