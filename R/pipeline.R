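#' End-to-end pipeline configuration
#'
#' Bundles every setting of the synthetic-population-to-statistics
#' workflow. Each stochastic stage derives its seed deterministically from
#' the master seed and the stage name, so one integer reproduces the whole
#' run bit-identically.
#'
#' @param spec a [population_spec()] (synthetic input), or NULL when
#'   `volume_paths` is given.
#' @param volume_paths optional character vector of segmentation files (one
#'   per specimen) used instead of the synthetic generator.
#' @param groups group labels, required with `volume_paths`.
#' @param comparisons list of 2-element character vectors
#'   `c(reference, contrast)`; default: every group pair.
#' @param k_target particles per shape.
#' @param align enable generalized Procrustes rotation before PCA.
#' @param smoothing_sigma mask smoothing before distancing (world units).
#' @param n_draws,quantile_level parallel-analysis settings.
#' @param B_perms permutation count for T2 and randomized Levene tests.
#' @param master_seed integer master seed.
#' @param corr optional [corr_config()] overriding optimizer defaults
#'   (its `k_target`/`seed` are taken from this config).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(spec = NULL, volume_paths = NULL, groups = NULL,
                            comparisons = NULL, k_target = 128L,
                            align = TRUE, smoothing_sigma = NULL,
                            n_draws = 500L, quantile_level = 0.95,
                            B_perms = 20000L, master_seed = 1L,
                            corr = NULL) {
  if (is.null(spec) && is.null(volume_paths)) {
    stop("either a population spec or volume paths must be given")
  }
  if (!is.null(volume_paths) && is.null(groups)) {
    stop("groups are required with volume_paths")
  }
  structure(list(spec = spec, volume_paths = volume_paths, groups = groups,
                 comparisons = comparisons, k_target = as.integer(k_target),
                 align = isTRUE(align), smoothing_sigma = smoothing_sigma,
                 n_draws = as.integer(n_draws),
                 quantile_level = quantile_level,
                 B_perms = as.integer(B_perms),
                 master_seed = as.integer(master_seed), corr = corr),
            class = "pipeline_config")
}

.default_comparisons <- function(groups) {
  gl <- unique(groups)
  pairs <- utils::combn(gl, 2, simplify = FALSE)
  lapply(pairs, function(p) c(p[1], p[2]))
}

#' Run the full shape-analysis pipeline
#'
#' synth (or load) -> signed distance fields -> particle correspondence ->
#' scale normalization (+ optional Procrustes rotation) -> per-comparison
#' PCA with parallel-analysis mode retention -> Hotelling T2 (parametric +
#' permutation), Levene variance battery, and discriminant arrows for each
#' comparison pair. PCA is fit per comparison on the union of the two
#' groups compared, so each comparison reports its own retained mode
#' count.
#'
#' @param cfg a [pipeline_config()].
#' @return a result bundle (class `pipeline_result`): `report` (plain
#'   machine-readable list mirroring the statistics tables), `comparisons`
#'   (full `group_comparison` objects plus their `pca_model`s), `sm`
#'   (normalized shape matrix), `ps` (particle system), `truth` (synthetic
#'   ground truth, if any).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (!is.null(cfg$spec)) {
    spec <- cfg$spec
    spec$seed <- derive_seed(cfg$master_seed, "synth")
    pop <- generate_population(spec)
    volumes <- pop$volumes
    groups <- pop$truth$group
    truth <- pop$truth
  } else {
    volumes <- lapply(cfg$volume_paths, read_volume)
    groups <- cfg$groups
    truth <- NULL
  }
  surfaces <- lapply(volumes, function(v) {
    if (is.null(cfg$smoothing_sigma)) mask_to_sdf(v)
    else mask_to_sdf(v, cfg$smoothing_sigma)
  })
  ccfg <- cfg$corr %||% corr_config()
  ccfg$k_target <- cfg$k_target
  ccfg$seed <- derive_seed(cfg$master_seed, "correspondence")
  ps <- optimize_correspondence(surfaces, ccfg)

  sm <- center_and_scale(ps, groups = groups)
  sm <- procrustes_rotate(sm, enable = cfg$align)

  comparisons <- cfg$comparisons %||% .default_comparisons(groups)
  comp_results <- list()
  report_rows <- list()
  for (ci in seq_along(comparisons)) {
    pair <- comparisons[[ci]]
    rows <- groups %in% pair
    sub <- structure(list(X = sm$X[rows, , drop = FALSE], k = sm$k,
                          groups = groups[rows]), class = "shape_matrix")
    model <- fit_pca(sub)
    model <- retain_modes(model, sub, n_draws = cfg$n_draws,
                          quantile_level = cfg$quantile_level,
                          seed = derive_seed(cfg$master_seed,
                                             paste0("pa_", ci)))
    gc <- compare_groups(model, pair[1], pair[2], B_perms = cfg$B_perms,
                         seed = derive_seed(cfg$master_seed,
                                            paste0("perm_", ci)))
    comp_results[[ci]] <- list(comparison = gc, model = model, sub = sub)
    report_rows[[ci]] <- list(
      reference = pair[1], contrast = pair[2],
      n_a = gc$n_a, n_b = gc$n_b, pc_modes = gc$m,
      T2 = gc$T2, p_parametric = gc$p_parametric,
      p_permutation = gc$p_permutation, B = gc$B,
      levene_mean = gc$levene$mean, levene_median = gc$levene$median,
      levene_randomized_mean = gc$levene$randomized_mean,
      levene_randomized_median = gc$levene$randomized_median
    )
  }
  report <- list(
    settings = list(
      k_target = cfg$k_target, align = cfg$align,
      n_draws = cfg$n_draws, quantile_level = cfg$quantile_level,
      B_perms = cfg$B_perms, master_seed = cfg$master_seed,
      n_specimens = length(volumes),
      n_per_group = as.list(table(groups)),
      optimizer = unclass(ccfg),
      spec = if (!is.null(cfg$spec)) unclass(cfg$spec)
    ),
    comparisons = report_rows
  )
  structure(list(report = report, comparisons = comp_results, sm = sm,
                 ps = ps, truth = truth, groups = groups),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d specimens, %d comparisons\n",
              length(x$groups), length(x$comparisons)))
  for (cr in x$comparisons) print(cr$comparison)
  invisible(x)
}

#' Serialize a pipeline report as JSON
#'
#' The report embeds every effective parameter, so a rerun from the same
#' config and master seed is byte-identical.
#'
#' @param result a `pipeline_result`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path) {
  jsonlite::write_json(result$report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Export mode walks and discriminant-arrow polydata
#'
#' Per comparison and retained mode, writes point configurations at
#' s in {-3,-2,-1,+1,+2,+3} standard deviations ("mode walks"), plus the
#' two group mean shapes and a VTK polydata of the reference-group mean
#' correspondence positions carrying the discriminant arrows (oriented
#' reference -> contrast) as point-data vectors.
#'
#' @param result a `pipeline_result`.
#' @param dir output directory.
#' @return character vector of files written, invisibly.
#' @export
export_visuals <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  for (ci in seq_along(result$comparisons)) {
    cr <- result$comparisons[[ci]]
    gc <- cr$comparison
    tag <- sprintf("%s_vs_%s", gc$group_a, gc$group_b)
    for (j in seq_len(cr$model$m)) {
      for (s in c(-3, -2, -1, 1, 2, 3)) {
        f <- file.path(dir, sprintf("%s_mode%d_sd%+d.pts", tag, j, s))
        write_points(reconstruct_at_sd(cr$model, j, s), f)
        files <- c(files, f)
      }
    }
    mean_a <- group_mean_shape(cr$sub, gc$group_a)
    mean_b <- group_mean_shape(cr$sub, gc$group_b)
    fa <- file.path(dir, sprintf("%s_mean_%s.pts", tag, gc$group_a))
    fb <- file.path(dir, sprintf("%s_mean_%s.pts", tag, gc$group_b))
    write_points(mean_a, fa)
    write_points(mean_b, fb)
    fv <- file.path(dir, sprintf("%s_arrows.vtk", tag))
    .write_vtk_polydata(mean_a, NULL, fv, vectors = gc$arrows,
                        title = sprintf("discriminant arrows %s", tag))
    files <- c(files, fa, fb, fv)
  }
  invisible(files)
}
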