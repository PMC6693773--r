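#' Run configuration for an end-to-end pipeline stage
#'
#' @param command one of `"cohort-report"`, `"group-report"`, `"predict"`,
#'   `"simulate-ventricle"`, `"calibrate-2g"`, `"biaxial-fit"`, `"mesh-study"`.
#' @param out_dir writable output directory (created if missing).
#' @param seed global seed; every stochastic stage receives a seed derived
#'   deterministically from it and the stage name.
#' @param ... command-specific parameters (see `run_pipeline`).
#' @export
run_config <- function(command, out_dir, seed = 1, ...) {
  commands <- c("cohort-report", "group-report", "predict",
                "simulate-ventricle", "calibrate-2g", "biaxial-fit",
                "mesh-study")
  if (!command %in% commands) {
    stop("run_config: unknown command '", command, "'; expected one of ",
         paste(commands, collapse = ", "))
  }
  structure(list(command = command, out_dir = out_dir, seed = seed,
                 args = list(...)), class = "run_config")
}

# deterministic per-stage seed from the global seed and the stage name
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((seed * 7919 + h) %% .Machine$integer.max)
}

#' Execute a pipeline stage and write its artifacts plus a manifest
#'
#' Runs the configured command, writes delimited-text artifacts under the
#' output directory and a `manifest.txt` recording the command, inputs,
#' derived seeds, package version and an MD5 checksum per artifact, so a run
#' is fully reconstructable and identical deterministic configs give
#' identical checksums.
#'
#' Supported commands and their `run_config(...)` arguments:
#' \describe{
#'   \item{cohort-report}{`fixture` (path, defaults to the bundled cohort):
#'     writes the tidy long-format table.}
#'   \item{group-report}{`fixture`, `cv` (logical), `repeats`: writes the
#'     group means, percent differences, test and correlation tables.}
#'   \item{predict}{`fixture`, `predictor`, `repeats`: repeated-CV metrics.}
#'   \item{simulate-ventricle}{geometry arguments forwarded to
#'     `make_idealized_ventricle`: writes the mesh (VTK) and slice stack.}
#'   \item{calibrate-2g}{`targets` (named list BF/EF/BE/EE volumes),
#'     `p_max`, plus optional geometry arguments: runs `calibrate_twog`
#'     and writes the calibration traces.}
#'   \item{biaxial-fit}{`data` (path to a biaxial CSV): writes the fit report.}
#'   \item{mesh-study}{`densities` (circumferential counts): writes the
#'     mesh-independence error curve.}
#' }
#'
#' @param config a `run_config`.
#' @return (invisibly) the manifest as a data.frame.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  a <- config$args
  fixture <- a$fixture
  if (config$command %in% c("cohort-report", "group-report", "predict")) {
    if (is.null(fixture)) fixture <- cohort_fixture_path()
    if (!file.exists(fixture)) {
      stop("run_pipeline: configuration error: fixture not found: ", fixture)
    }
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- character(0)
  put <- function(obj, name) {
    path <- file.path(config$out_dir, name)
    utils::write.csv(obj, path, row.names = FALSE)
    artifacts <<- c(artifacts, path)
    path
  }
  stage_seed <- derive_seed(config$seed, config$command)
  log_lines <- c(sprintf("command: %s", config$command),
                 sprintf("seed: %d (derived stage seed %d)", config$seed,
                         stage_seed))

  switch(config$command,
    "cohort-report" = {
      cohort <- load_cohort(fixture)
      put(cohort_long(cohort), "cohort_long.csv")
      log_lines <- c(log_lines, sprintf("input: %s", fixture))
    },
    "group-report" = {
      cohort <- load_cohort(fixture)
      rep <- group_report(cohort, cv = isTRUE(a$cv),
                          repeats = a$repeats %||% 200, seed = stage_seed)
      put(rep$means, "group_means.csv")
      put(rep$pct_differences, "percent_differences.csv")
      put(rep$rank_sum, "rank_sum_tests.csv")
      put(rep$signed_rank, "signed_rank_tests.csv")
      put(rep$spearman, "spearman_correlations.csv")
      if (!is.null(rep$prediction_2g)) {
        put(rep$prediction_2g, "prediction_2g.csv")
        put(rep$prediction_1g, "prediction_1g.csv")
      }
      log_lines <- c(log_lines, sprintf("input: %s", fixture))
    },
    "predict" = {
      cohort <- load_cohort(fixture)
      predictor <- a$predictor %||% "stress_2g_ef"
      r <- cross_validate(predictor, cohort, repeats = a$repeats %||% 200,
                          seed = stage_seed)
      put(data.frame(predictor = predictor, accuracy = r$accuracy,
                     sensitivity = r$sensitivity, specificity = r$specificity,
                     auc = r$auc, repeats = r$n_repeats, seed = r$seed),
          "prediction.csv")
      put(r$per_repeat, "prediction_per_repeat.csv")
    },
    "simulate-ventricle" = {
      geo <- do.call(make_idealized_ventricle,
                     a[intersect(names(a),
                                 names(formals(make_idealized_ventricle)))])
      vtk <- file.path(config$out_dir, "ventricle.vtk")
      write_mesh_vtk(geo$mesh, vtk)
      artifacts <- c(artifacts, vtk)
      put(stack_as_table(geo$stack), "slice_stack.csv")
    },
    "calibrate-2g" = {
      geo <- do.call(make_idealized_ventricle,
                     a[intersect(names(a),
                                 names(formals(make_idealized_ventricle)))])
      targets <- a$targets
      if (is.null(targets)) {
        stop("run_pipeline: configuration error: calibrate-2g needs 'targets'")
      }
      profile <- make_pressure_profile(p_max = a$p_max %||% 30,
                                       p_min = a$p_min %||% 3,
                                       p_ed = a$p_ed %||% 8,
                                       p_es = a$p_es %||% 12)
      model <- calibrate_twog(geo$stack, targets, profile,
                              a$params_diastole %||% material_params(),
                              a$params_systole %||%
                                scale_stiffness(material_params(), 4))
      put(model$diastole_geom$trace, "calibration_trace_diastole.csv")
      put(model$systole_geom$trace, "calibration_trace_systole.csv")
      put(model$material_trace$diastole$trace, "material_trace_diastole.csv")
      put(model$material_trace$systole$trace, "material_trace_systole.csv")
    },
    "biaxial-fit" = {
      if (is.null(a$data) || !file.exists(a$data)) {
        stop("run_pipeline: configuration error: biaxial-fit needs 'data' (path)")
      }
      dat <- utils::read.csv(a$data)
      fit <- fit_biaxial(dat, a$init %||% material_params())
      put(data.frame(parameter = names(coef(fit)), value = coef(fit),
                     residual_norm = fit$residual_norm), "biaxial_fit.csv")
    },
    "mesh-study" = {
      densities <- a$densities %||% c(8, 12, 16)
      base <- make_idealized_ventricle()
      solve_case <- function(nc) {
        g <- make_idealized_ventricle(n_circ = nc)
        f <- assign_fibers(g$mesh)
        solve_inflation(g$mesh, f, a$params %||% material_params(),
                        a$pressure %||% 8)
      }
      ms <- mesh_independence(solve_case, densities, base$stack)
      put(ms$error_curve, "mesh_error_curve.csv")
      log_lines <- c(log_lines,
                     sprintf("selected density: %s",
                             if (is.null(ms$selected)) "none" else ms$selected))
    })

  manifest <- data.frame(
    artifact = basename(artifacts),
    md5 = unname(tools::md5sum(artifacts)),
    stringsAsFactors = FALSE)
  writeLines(c(log_lines,
               sprintf("package: ventmech2g %s",
                       as.character(utils::packageVersion("ventmech2g"))),
               "artifacts:",
               sprintf("  %s  %s", manifest$md5, manifest$artifact)),
             file.path(config$out_dir, "manifest.txt"))
  invisible(manifest)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# slice stack as a flat table (slice, z, contour, vertex, x, y)
stack_as_table <- function(stack) {
  do.call(rbind, lapply(seq_along(stack$slices), function(i) {
    s <- stack$slices[[i]]
    rbind(
      data.frame(slice = i, z = s$z, contour = "inner",
                 vertex = seq_len(nrow(s$inner)),
                 x = s$inner[, 1], y = s$inner[, 2]),
      data.frame(slice = i, z = s$z, contour = "outer",
                 vertex = seq_len(nrow(s$outer)),
                 x = s$outer[, 1], y = s$outer[, 2]))
  }))
}
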