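#' Calibration configuration for the two-geometry construction
#'
#' @param init_shrink_diastole initial pre-shrink fraction for the zero-load
#'   diastole geometry (published starting point: 2\%).
#' @param init_shrink_systole initial pre-shrink fraction for the zero-load
#'   systole geometry (published starting point: 15\%, reflecting 10-15\%
#'   sarcomere shortening).
#' @param volume_tol relative inflated-volume tolerance of the zero-load
#'   geometry calibration (published: 0.5\%).
#' @param param_volume_tol relative volume tolerance of the material-parameter
#'   calibration (published: 0.2\%).
#' @param max_outer_iters iteration cap for each calibration loop.
#' @export
calibration_config <- function(init_shrink_diastole = 0.02,
                               init_shrink_systole = 0.15,
                               volume_tol = 0.005,
                               param_volume_tol = 0.002,
                               max_outer_iters = 30) {
  stopifnot(volume_tol > 0, volume_tol < 1,
            param_volume_tol > 0, param_volume_tol < 1,
            init_shrink_diastole > 0, init_shrink_diastole < 0.5,
            init_shrink_systole > 0, init_shrink_systole < 0.5,
            max_outer_iters >= 1)
  structure(list(init_shrink_diastole = init_shrink_diastole,
                 init_shrink_systole = init_shrink_systole,
                 volume_tol = volume_tol,
                 param_volume_tol = param_volume_tol,
                 max_outer_iters = max_outer_iters),
            class = "calibration_config")
}

shrunk_solution <- function(source_stack, shrink, params, fiber_config,
                            n_layers, applied_pressure, solver) {
  stack <- preshrink(source_stack, shrink, shrink)
  mesh <- mesh_from_slices(stack, n_layers = n_layers)
  fibers <- assign_fibers(mesh, fiber_config$endo_angle, fiber_config$epi_angle)
  sol <- solve_inflation(mesh, fibers, params, applied_pressure, solver)
  list(stack = stack, mesh = mesh, fibers = fibers, sol = sol,
       volume = sol$cavity_volume)
}

#' Calibrate a zero-load geometry by iterative pre-shrinking
#'
#' Finds the pre-shrink fraction such that the shrunk geometry, inflated to
#' the phase's applied pressure, recovers the target cavity volume: the target
#' is the imaged minimum-volume state, the applied pressure is the
#' begin-diastole minimum pressure (diastole phase) or the end-systole
#' pressure (systole phase). The shrink rate is updated by bracketing plus
#' secant (regula-falsi) steps on the signed volume error until the relative
#' error drops below `config$volume_tol`.
#'
#' @param source_stack `slice_stack` of the in-vivo minimum-volume state.
#' @param target_volume target pressurized cavity volume (cm^3).
#' @param applied_pressure phase pressure (mmHg).
#' @param params `material_params` for the phase.
#' @param fiber_config list with `endo_angle`, `epi_angle` (degrees).
#' @param config a `calibration_config`.
#' @param phase `"diastole"` or `"systole"` (selects the initial shrink).
#' @param n_layers transmural mesh layers.
#' @param solver a `solver_config`.
#' @return a `zero_load_geometry`: phase, shrunk `slice_stack` and mesh, the
#'   shrink rates, fibers, achieved inflated volume, relative error, and the
#'   iteration `trace` (shrink, inflated volume, relative error per step).
#' @export
calibrate_zero_load <- function(source_stack, target_volume, applied_pressure,
                                params,
                                fiber_config = list(endo_angle = 40,
                                                    epi_angle = -45),
                                config = calibration_config(),
                                phase = c("diastole", "systole"),
                                n_layers = 2, solver = solver_config()) {
  phase <- match.arg(phase)
  stopifnot(target_volume > 0, applied_pressure >= 0)
  source_wall <- stack_wall_volume(source_stack)

  trace <- list()
  best <- NULL
  evaluate <- function(s) {
    r <- shrunk_solution(source_stack, s, params, fiber_config, n_layers,
                         applied_pressure, solver)
    err <- (r$volume - target_volume) / target_volume
    trace[[length(trace) + 1L]] <<- data.frame(
      iteration = length(trace), shrink = s, inflated_volume = r$volume,
      rel_error = err)
    if (is.null(best) || abs(err) < abs(best$err)) best <<- c(r, list(err = err, shrink = s))
    err
  }
  finish <- function() {
    tr <- do.call(rbind, trace)
    wall <- stack_wall_volume(best$stack)
    if (abs(wall - source_wall) / source_wall > 0.001) {
      stop("calibrate_zero_load: wall volume drifted beyond 0.1% (internal error)")
    }
    structure(list(phase = phase, stack = best$stack, mesh = best$mesh,
                   fibers = best$fibers, params = params,
                   shrink_rate_short_axis = best$shrink,
                   shrink_rate_long_axis = best$shrink,
                   applied_pressure = applied_pressure,
                   inflated_volume = best$volume,
                   target_volume = target_volume,
                   rel_error = best$err, trace = tr),
              class = "zero_load_geometry")
  }
  fail <- function(msg) {
    stop(sprintf("calibrate_zero_load (%s): %s\ntrace:\n%s", phase, msg,
                 paste(utils::capture.output(print(do.call(rbind, trace))),
                       collapse = "\n")))
  }

  # trivial acceptance at shrink 0 (e.g. zero pressure with target = source)
  if (applied_pressure == 0) {
    if (abs(evaluate(0)) < config$volume_tol) return(finish())
  }
  s0 <- if (phase == "diastole") config$init_shrink_diastole else
    config$init_shrink_systole
  e0 <- evaluate(s0)
  if (abs(e0) < config$volume_tol) return(finish())

  # bracket: volume (hence error) decreases as the shrink grows
  s_lo <- s_hi <- s0; e_lo <- e_hi <- e0
  if (e0 > 0) {                      # too large -> shrink more
    while (e_hi > 0) {
      s_hi <- min(s_hi * 1.6 + 0.01, 0.499)
      e_hi <- evaluate(s_hi)
      if (abs(e_hi) < config$volume_tol) return(finish())
      if (e_hi > 0 && s_hi >= 0.499) fail("no bracket: target volume below the reachable range (shrink > 0.5 needed)")
    }
  } else {                           # too small -> shrink less
    while (e_lo < 0) {
      s_lo <- s_lo / 1.8
      if (s_lo < 1e-5) {
        e_at0 <- evaluate(0)
        if (abs(e_at0) < config$volume_tol) return(finish())
        if (e_at0 < 0) fail("no bracket: target volume above the unshrunk inflated volume")
        s_lo <- 0; e_lo <- e_at0
        break
      }
      e_lo <- evaluate(s_lo)
      if (abs(e_lo) < config$volume_tol) return(finish())
    }
  }

  # Illinois-damped regula falsi inside the bracket [s_lo (err>0), s_hi (err<0)]
  f_lo <- e_lo; f_hi <- e_hi
  for (k in seq_len(config$max_outer_iters)) {
    s_new <- (s_lo * f_hi - s_hi * f_lo) / (f_hi - f_lo)
    s_new <- min(max(s_new, s_lo + 1e-6), s_hi - 1e-6)
    e_new <- evaluate(s_new)
    if (abs(e_new) < config$volume_tol) return(finish())
    if (e_new > 0) {
      s_lo <- s_new; f_lo <- e_new; f_hi <- f_hi / 2
    } else {
      s_hi <- s_new; f_hi <- e_new; f_lo <- f_lo / 2
    }
  }
  fail(sprintf("did not reach tolerance %.3g in %d iterations",
               config$volume_tol, config$max_outer_iters))
}

#' @export
print.zero_load_geometry <- function(x, ...) {
  cat(sprintf(paste0("Zero-load %s geometry: shrink %.4f, inflated volume ",
                     "%.3f cm^3 (target %.3f, error %.3g%%) at %.2f mmHg\n"),
              x$phase, x$shrink_rate_short_axis, x$inflated_volume,
              x$target_volume, 100 * abs(x$rel_error), x$applied_pressure))
  invisible(x)
}

#' Calibrate material stiffness against pressure-volume targets
#'
#' Scales the stiffness parameters (c1, D1, K1, and c2 if nonzero) of the
#' phase material by one common factor until the geometry inflated to each
#' target pressure matches the target volume within `tol` (relative). With a
#' single target pair the scale is solved by bracketing + secant root finding
#' on the signed volume error; with several pairs a least-squares scale is
#' found by golden-section minimization. c2, D2 and K2 stay frozen at their
#' published values throughout.
#'
#' @param geometry a `zero_load_geometry`.
#' @param pressure_volume_targets data.frame with columns `pressure` (mmHg)
#'   and `volume` (cm^3), at least one row.
#' @param base_params starting `material_params` (scale 1).
#' @param tol relative volume tolerance (published: 0.2\%).
#' @param solver a `solver_config`.
#' @param scale_bracket allowed stiffness-scale range.
#' @param max_iters iteration cap.
#' @return a `material_calibration`: fitted `params`, `scale`, achieved
#'   per-target errors, and the iteration `trace`.
#' @export
calibrate_material <- function(geometry, pressure_volume_targets, base_params,
                               tol = 0.002, solver = solver_config(),
                               scale_bracket = c(1e-3, 1e3),
                               max_iters = 60) {
  stopifnot(inherits(geometry, "zero_load_geometry"),
            is.data.frame(pressure_volume_targets),
            nrow(pressure_volume_targets) >= 1,
            all(c("pressure", "volume") %in% names(pressure_volume_targets)),
            all(pressure_volume_targets$volume > 0))
  tg <- pressure_volume_targets
  trace <- list()
  errors_at <- function(scale) {
    p <- scale_stiffness(base_params, scale)
    errs <- vapply(seq_len(nrow(tg)), function(i) {
      sol <- solve_inflation(geometry$mesh, geometry$fibers, p,
                             tg$pressure[i], solver)
      (sol$cavity_volume - tg$volume[i]) / tg$volume[i]
    }, numeric(1))
    trace[[length(trace) + 1L]] <<- data.frame(
      iteration = length(trace), scale = scale,
      max_abs_rel_error = max(abs(errs)))
    errs
  }
  finish <- function(scale, errs) {
    structure(list(params = scale_stiffness(base_params, scale),
                   scale = scale, rel_errors = errs,
                   trace = do.call(rbind, trace)),
              class = "material_calibration")
  }
  fail <- function(msg) {
    stop(sprintf("calibrate_material: %s\ntrace:\n%s", msg,
                 paste(utils::capture.output(print(do.call(rbind, trace))),
                       collapse = "\n")))
  }

  e1 <- errors_at(1)
  if (max(abs(e1)) < tol) return(finish(1, e1))

  if (nrow(tg) == 1L) {
    # signed error increases with stiffness scale is FALSE: stiffer -> smaller
    # volume -> error decreases with scale. Bracket on the log scale.
    s_lo <- s_hi <- 1; e_lo <- e_hi <- e1[1]
    while (e_hi > 0) {               # too large -> stiffen
      s_hi <- s_hi * 2
      if (s_hi > scale_bracket[2]) fail("target unreachable: scale above bracket")
      e_hi <- errors_at(s_hi)[1]
      if (abs(e_hi) < tol) return(finish(s_hi, e_hi))
    }
    while (e_lo < 0) {               # too small -> soften
      s_lo <- s_lo / 2
      if (s_lo < scale_bracket[1]) fail("target unreachable: scale below bracket")
      e_lo <- errors_at(s_lo)[1]
      if (abs(e_lo) < tol) return(finish(s_lo, e_lo))
    }
    x_lo <- log(s_lo); x_hi <- log(s_hi); f_lo <- e_lo; f_hi <- e_hi
    for (k in seq_len(max_iters)) {
      x_new <- (x_lo * f_hi - x_hi * f_lo) / (f_hi - f_lo)
      x_new <- min(max(x_new, x_lo + 1e-9), x_hi - 1e-9)
      e_new <- errors_at(exp(x_new))[1]
      if (abs(e_new) < tol) return(finish(exp(x_new), e_new))
      if (e_new > 0) {
        x_lo <- x_new; f_lo <- e_new; f_hi <- f_hi / 2
      } else {
        x_hi <- x_new; f_hi <- e_new; f_lo <- f_lo / 2
      }
    }
    fail(sprintf("did not reach tolerance %.3g in %d iterations", tol, max_iters))
  } else {
    obj <- function(x) sum(errors_at(exp(x))^2)
    opt <- stats::optimize(obj, log(scale_bracket), tol = 1e-6)
    errs <- errors_at(exp(opt$minimum))
    if (max(abs(errs)) >= tol) {
      warning(sprintf(paste0("calibrate_material: least-squares scale leaves ",
                             "max error %.3g above tolerance %.3g ",
                             "(inconsistent targets)"), max(abs(errs)), tol))
    }
    finish(exp(opt$minimum), errs)
  }
}

#' @export
print.material_calibration <- function(x, ...) {
  cat(sprintf(paste0("Material calibration: stiffness scale %.4f, max ",
                     "volume error %.3g%% over %d target(s)\n"),
              x$scale, 100 * max(abs(x$rel_errors)), length(x$rel_errors)))
  invisible(x)
}

#' Build a calibrated two-geometry (2G) ventricle model
#'
#' Runs the full 2G construction on a minimum-volume source geometry:
#' for each phase, alternately (i) calibrate the zero-load geometry by
#' pre-shrinking until the inflated volume at the phase pressure matches the
#' minimum cavity volume, and (ii) calibrate the material stiffness until the
#' maximum-volume state is matched at the phase's high pressure (end-diastolic
#' pressure for diastole, maximum pressure for systole), repeating until both
#' tolerances hold. The diastole and systole phases are calibrated
#' independently -- the 2G model is literally two models.
#'
#' @param source_stack `slice_stack` of the minimum-volume in-vivo state.
#' @param target_volumes named list/vector with entries BF, EF, BE, EE (cm^3);
#'   the cycle definition demands V(BF) = V(EE) (minimum) and V(EF) = V(BE)
#'   (maximum).
#' @param pressure_profile a `pressure_profile`.
#' @param params_diastole,params_systole starting `material_params` per phase.
#' @param fiber_config list with `endo_angle`, `epi_angle`.
#' @param config a `calibration_config`.
#' @param n_layers transmural mesh layers.
#' @param solver a `solver_config`.
#' @param max_phase_rounds alternating geometry/material rounds per phase.
#' @return a `twog_model`.
#' @export
calibrate_twog <- function(source_stack, target_volumes, pressure_profile,
                           params_diastole, params_systole,
                           fiber_config = list(endo_angle = 40,
                                               epi_angle = -45),
                           config = calibration_config(), n_layers = 2,
                           solver = solver_config(), max_phase_rounds = 5) {
  tv <- as.list(target_volumes)
  stopifnot(all(c("BF", "EF", "BE", "EE") %in% names(tv)))
  if (abs(tv$BF - tv$EE) > 1e-9 * tv$BF || abs(tv$EF - tv$BE) > 1e-9 * tv$EF) {
    stop("calibrate_twog: cycle definition requires V(BF) = V(EE) and V(EF) = V(BE)")
  }
  if (tv$BF >= tv$EF) stop("calibrate_twog: minimum volume must be below maximum")
  kp <- pressure_profile$key_points
  p_of <- function(tp) kp$pressure[kp$timepoint == tp]

  calibrate_phase <- function(phase, params, p_low_tp, p_high_tp) {
    p_low <- p_of(p_low_tp); p_high <- p_of(p_high_tp)
    geom <- NULL
    for (round in seq_len(max_phase_rounds)) {
      geom <- calibrate_zero_load(source_stack, tv$BF, p_low, params,
                                  fiber_config, config, phase, n_layers,
                                  solver)
      mc <- calibrate_material(geom, data.frame(pressure = p_high,
                                                volume = tv$EF),
                               params, tol = config$param_volume_tol,
                               solver = solver)
      params <- mc$params
      # re-check the low-pressure match under the new stiffness
      chk <- solve_inflation(geom$mesh, geom$fibers, params, p_low, solver)
      low_err <- abs(chk$cavity_volume - tv$BF) / tv$BF
      if (low_err < config$volume_tol) {
        geom$params <- params
        geom$inflated_volume <- chk$cavity_volume
        geom$rel_error <- (chk$cavity_volume - tv$BF) / tv$BF
        return(list(geom = geom, params = params, material = mc))
      }
    }
    stop(sprintf(paste0("calibrate_twog (%s): alternating calibration did ",
                        "not satisfy both tolerances in %d rounds"),
                 phase, max_phase_rounds))
  }

  dia <- calibrate_phase("diastole", params_diastole, "BF", "EF")
  sys <- calibrate_phase("systole", params_systole, "EE", "BE")

  if (stack_cavity_volume(sys$geom$stack) >= stack_cavity_volume(dia$geom$stack)) {
    stop("calibrate_twog: systolic zero-load cavity is not smaller than diastolic")
  }
  structure(list(diastole_geom = dia$geom, systole_geom = sys$geom,
                 params_diastole = dia$params, params_systole = sys$params,
                 material_trace = list(diastole = dia$material,
                                       systole = sys$material),
                 pressure_profile = pressure_profile,
                 target_volumes = tv),
            class = "twog_model")
}

#' @export
print.twog_model <- function(x, ...) {
  cat("Two-geometry ventricle model\n")
  cat(sprintf("  diastole: shrink %.4f, stiffness scale x%.3f\n",
              x$diastole_geom$shrink_rate_short_axis,
              x$material_trace$diastole$scale))
  cat(sprintf("  systole:  shrink %.4f, stiffness scale x%.3f\n",
              x$systole_geom$shrink_rate_short_axis,
              x$material_trace$systole$scale))
  cat(sprintf("  target volumes: min %.2f / max %.2f cm^3\n",
              x$target_volumes$BF, x$target_volumes$EF))
  invisible(x)
}

#' Run the cardiac cycle on a calibrated 2G model
#'
#' Evaluates the four key states for three successive periods with warm
#' starts: BF and EF on the diastole geometry at the begin-filling and
#' end-filling pressures, BE and EE on the systole geometry at the
#' begin-ejection and end-ejection pressures. The solutions of the final
#' period are returned after verifying that the last two periods differ by
#' less than 0.1\% (relative, on displacement and cavity volume).
#'
#' @param model a `twog_model`.
#' @param solver a `solver_config`.
#' @param n_periods number of periods (>= 2).
#' @return named list of `solution_field`s (BF, EF, BE, EE) with attribute
#'   `period_difference`.
#' @export
run_cardiac_cycle_2g <- function(model, solver = solver_config(),
                                 n_periods = 3) {
  stopifnot(inherits(model, "twog_model"), n_periods >= 2)
  kp <- model$pressure_profile$key_points
  p_of <- function(tp) kp$pressure[kp$timepoint == tp]
  geo_of <- list(BF = "diastole", EF = "diastole", BE = "systole",
                 EE = "systole")
  warm <- list()
  prev <- NULL
  states <- NULL
  for (period in seq_len(n_periods)) {
    states <- list()
    for (tp in c("BF", "EF", "BE", "EE")) {
      g <- if (geo_of[[tp]] == "diastole") model$diastole_geom else
        model$systole_geom
      par <- if (geo_of[[tp]] == "diastole") model$params_diastole else
        model$params_systole
      states[[tp]] <- tryCatch(
        solve_inflation(g$mesh, g$fibers, par, p_of(tp), solver,
                        init_disp = warm[[tp]]),
        error = function(e) stop(sprintf("cardiac cycle, period %d, %s: %s",
                                         period, tp, conditionMessage(e))))
      warm[[tp]] <- states[[tp]]$displacement
    }
    if (!is.null(prev)) {
      diffs <- vapply(c("BF", "EF", "BE", "EE"), function(tp) {
        du <- max(abs(states[[tp]]$displacement - prev[[tp]]$displacement))
        u_ref <- max(abs(states[[tp]]$displacement), 1e-9)
        dv <- abs(states[[tp]]$cavity_volume - prev[[tp]]$cavity_volume) /
          states[[tp]]$cavity_volume
        max(du / u_ref, dv)
      }, numeric(1))
      period_diff <- max(diffs)
    }
    prev <- states
  }
  if (period_diff >= 0.001) {
    warning(sprintf(paste0("run_cardiac_cycle_2g: last two periods differ by ",
                           "%.3g%% (>= 0.1%%)"), 100 * period_diff))
  }
  attr(states, "period_difference") <- period_diff
  states
}

#' Run the cardiac cycle on a single-geometry (1G) model
#'
#' Only two states exist natively: begin-filling at the minimum pressure and
#' begin-ejection at the maximum pressure, both on the single zero-load
#' geometry. When a four-point table is requested downstream, EF is aliased to
#' the BE state and EE to the BF state; the aliasing is flagged in the result,
#' which is exactly the 1G limitation the two-geometry construction removes.
#'
#' @param geometry a calibrated `zero_load_geometry`.
#' @param p_min,p_max minimum and maximum pressures (mmHg), p_min <= p_max.
#' @param params `material_params` (defaults to the geometry's).
#' @param solver a `solver_config`.
#' @return named list with native `BF`, `BE` and aliased `EF`, `EE` states,
#'   with attribute `aliased = c(EF = "BE", EE = "BF")`.
#' @export
run_cardiac_cycle_1g <- function(geometry, p_min, p_max,
                                 params = geometry$params,
                                 solver = solver_config()) {
  stopifnot(inherits(geometry, "zero_load_geometry"), p_min <= p_max)
  bf <- solve_inflation(geometry$mesh, geometry$fibers, params, p_min, solver)
  be <- solve_inflation(geometry$mesh, geometry$fibers, params, p_max, solver,
                        init_disp = bf$displacement)
  out <- list(BF = bf, EF = be, BE = be, EE = bf)
  attr(out, "aliased") <- c(EF = "BE", EE = "BF")
  out
}
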