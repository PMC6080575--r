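#' Default pipeline configuration
#'
#' All defaults mirror the module-level defaults: 100 consensus runs, 100
#' factorization restarts, regularization weights 0.1, selection fractions
#' 2 percent.
#'
#' @param out_dir artifact directory.
#' @param seed top-level seed; per-stage child seeds derive from it via
#'   \code{\link{child_seed}}.
#' @param ... overrides for any configuration field (see Details).
#' @details Fields: \code{measurements} (vector of per-age table files) and
#'   \code{covariates_file}, or \code{stack} (a stack TSV), or
#'   \code{simulate = TRUE} to use the planted-model generator;
#'   \code{confounds}; \code{G_range}; \code{p_range} or fixed \code{p};
#'   \code{lambda}, \code{alpha}, \code{beta}; \code{n_runs},
#'   \code{n_init}, \code{max_iter}, \code{tol}; \code{top_fraction}.
#' @return a \code{pipeline_config} list.
#' @export
pipeline_config <- function(out_dir = "devmeta_out", seed = 1, ...) {
  cfg <- list(out_dir = out_dir, seed = seed,
              simulate = FALSE, measurements = NULL, covariates_file = NULL,
              stack = NULL, confounds = c("gender", "mean_thickness"),
              G_range = 2:7, p_range = 2:6, p = NULL,
              lambda = 0.1, alpha = 0.1, beta = 0.1,
              n_runs = 100, n_init = 100, max_iter = 1000, tol = 1e-6,
              top_fraction = 0.02)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0)
    dm_stop("unknown pipeline configuration field(s): %s",
            "devmeta_config_error", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML file.
#' @return a \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' @rdname read_pipeline_config
#' @param config a \code{pipeline_config}.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full decomposition pipeline
#'
#' Orchestrates input loading (or simulation), stage identification,
#' meta-network count selection, factorization, connection
#' characterization, and split-half reproducibility, writing every
#' intermediate artifact plus a machine-readable run manifest.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return invisibly, a list with the in-memory results and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character(0)
  timings <- list()
  step <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      dm_stop("pipeline stage '%s' failed: %s", "devmeta_pipeline_error",
              name, conditionMessage(e)))
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }
  emit <- function(path) { artifacts <<- c(artifacts, path); path }

  # 1. input
  X <- step("input", {
    if (isTRUE(config$simulate)) {
      sim <- generate_planted_networks(seed = child_seed(config$seed, 1L))
      sim$networks
    } else if (!is.null(config$stack)) {
      read_stack_tsv(config$stack)
    } else if (!is.null(config$measurements)) {
      tables <- read_measurement_tables(config$measurements,
                                        config$covariates_file)
      nets <- lapply(tables, function(tb)
        build_correlation_network(regress_confounds(tb, config$confounds)))
      assemble_developmental_networks(nets)
    } else {
      dm_stop("configuration names no input (simulate / stack / measurements)",
              "devmeta_config_error")
    }
  })
  write_stack_tsv(X, emit(file.path(config$out_dir, "stack.tsv")))

  # 2. stages
  stages <- step("stages", select_stage_partition(
    X, G_range = config$G_range, n_runs = config$n_runs,
    seed = child_seed(config$seed, 2L)))
  part <- stages$partition
  jsonlite::write_json(
    list(G = part$G, labels = part$labels,
         blocks = part$blocks, time_labels = part$time_labels,
         dispersion = as.list(stages$dispersion)),
    emit(file.path(config$out_dir, "stages.json")), auto_unbox = TRUE)

  # 3. meta-network count
  base_cfg <- dmd_config(p = 2, lambda = config$lambda, alpha = config$alpha,
                         beta = config$beta, n_init = config$n_init,
                         max_iter = config$max_iter, tol = config$tol,
                         seed = child_seed(config$seed, 3L))
  p_star <- step("select_p", {
    if (!is.null(config$p)) {
      utils::write.table(
        data.frame(p = config$p, mtd = NA),
        emit(file.path(config$out_dir, "mtd_curve.tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
      config$p
    } else {
      sel <- select_num_dms(X, part, config$p_range, base_cfg)
      utils::write.table(
        data.frame(p = as.integer(names(sel$mtd)), mtd = sel$mtd),
        emit(file.path(config$out_dir, "mtd_curve.tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
      sel$p
    }
  })

  # 4. factorization
  fit_cfg <- base_cfg
  fit_cfg$p <- as.integer(p_star)
  fit_cfg$seed <- child_seed(config$seed, 4L)
  fit <- step("fit", dmd_fit(X, part, fit_cfg))
  write_trajectories_tsv(fit, emit(file.path(config$out_dir, "trajectories.tsv")))
  for (t in seq_len(part$G))
    write_stage_state_tsv(fit, t,
                          emit(file.path(config$out_dir,
                                         sprintf("meta_networks_stage%d.tsv", t))))

  # 5. characterization
  reports <- step("characterize", characterize_dms(fit, config$top_fraction))
  for (r in seq_along(reports$stable))
    utils::write.table(reports$stable[[r]],
                       emit(file.path(config$out_dir,
                                      sprintf("stable_connections_dm%d.tsv", r))),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(contributions = reports$contributions,
         rapid = lapply(reports$rapid, function(per_dm)
           lapply(per_dm, function(tr)
             list(direction = tr$direction, delta_vbar = tr$delta_vbar,
                  edges = tr$edges)))),
    emit(file.path(config$out_dir, "characterization.json")),
    auto_unbox = TRUE, digits = NA)

  # 6. reproducibility
  rep_cfg <- fit_cfg
  rep_cfg$seed <- child_seed(config$seed, 5L)
  repro <- step("reproducibility",
                split_half_reproducibility(X, part, rep_cfg))
  jsonlite::write_json(
    list(permutation = repro$match$permutation,
         mean_similarity_U = repro$mean_similarity_U,
         mean_similarity_V = repro$mean_similarity_V,
         table = repro$table),
    emit(file.path(config$out_dir, "reproducibility.json")),
    auto_unbox = TRUE, digits = NA)

  manifest <- list(package_version = as.character(utils::packageVersion("devmeta")),
                   seed = config$seed,
                   parameters = unclass(config)[c("G_range", "p_range", "p",
                                                  "lambda", "alpha", "beta",
                                                  "n_runs", "n_init",
                                                  "top_fraction")],
                   selected = list(G = part$G, p = as.integer(p_star)),
                   artifacts = artifacts,
                   timings_sec = timings)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(networks = X, stages = stages, p = p_star, fit = fit,
                 reports = reports, reproducibility = repro,
                 manifest = manifest))
}
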