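#' @useDynLib ventmech2g, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Millimetres of mercury to kilopascal
#' @param p_mmHg pressure in mmHg.
#' @return pressure in kPa.
#' @export
mmHg_to_kPa <- function(p_mmHg) p_mmHg * 0.1333224

#' Solver configuration for quasi-static inflation
#'
#' @param load_steps initial number of pressure increments (adaptively refined).
#' @param newton_tol relative residual tolerance (vs the applied load norm).
#' @param max_newton_iters Newton iterations per load step.
#' @param density myocardium density (kg/mm^3); carried for documentation only,
#'   the inertial term is dropped and states are quasi-static equilibria.
#' @export
solver_config <- function(load_steps = 4, newton_tol = 1e-8,
                          max_newton_iters = 25, density = 1.055e-6) {
  stopifnot(load_steps >= 1, newton_tol > 0, max_newton_iters >= 1)
  structure(list(load_steps = load_steps, newton_tol = newton_tol,
                 max_newton_iters = max_newton_iters, density = density),
            class = "solver_config")
}

mat_par_vec <- function(params) {
  c(params$c1, params$c2, params$D1, params$D2, params$K1, params$K2,
    params$kappa)
}

fixed_dof_index <- function(mesh) {
  fd <- mesh$fixed_dofs
  sort(unique(3L * (as.integer(fd[, 1]) - 1L) + as.integer(fd[, 2])))
}

# internal force / energy of a displacement state (used by tests and solver)
assemble_internal <- function(mesh, fibers, params, disp, want_tangent = FALSE) {
  .asm_internal(mesh$nodes, disp, mesh$elems, unclass(fibers),
                mat_par_vec(params), want_tangent)
}

#' Quasi-static finite-element inflation under endocardial pressure
#'
#' Solves total-Lagrangian equilibrium of the hexahedral ventricle mesh under
#' a follower pressure on the deformed endocardial faces, with a traction-free
#' epicardium and the mesh's base constraints. Full Newton with a consistent
#' analytic tangent, residual line search, and adaptive load stepping (halved
#' on failure, doubled after fast convergence).
#'
#' @param mesh a `ventricle_mesh`.
#' @param fibers a `fiber_field` (one unit vector per element).
#' @param params a `material_params`.
#' @param pressure cavity pressure in mmHg, >= 0.
#' @param config a `solver_config`.
#' @param init_disp optional warm-start displacement (n_nodes x 3).
#' @return a `solution_field`: displacement (mm), per-quadrature-point Cauchy
#'   stress and Green-Lagrange strain, cavity volume (cm^3), applied pressure,
#'   strain energy, and the per-step residual history.
#' @export
solve_inflation <- function(mesh, fibers, params, pressure,
                            config = solver_config(), init_disp = NULL) {
  stopifnot(inherits(mesh, "ventricle_mesh"), pressure >= 0,
            nrow(fibers) == nrow(mesh$elems))
  nn <- nrow(mesh$nodes)
  disp <- if (is.null(init_disp)) matrix(0, nn, 3) else {
    stopifnot(all(dim(init_disp) == c(nn, 3)))
    init_disp
  }
  p_kPa <- mmHg_to_kPa(pressure)
  fixed <- fixed_dof_index(mesh)
  free <- setdiff(seq_len(3L * nn), fixed)
  history <- list()

  ramp_needed <- p_kPa > 0 || !is.null(init_disp)
  if (ramp_needed && !is.null(init_disp)) {
    # warm start: try the full load in one step; an already-converged state
    # returns unchanged, keeping repeated cycles exactly periodic
    res <- newton_solve(mesh, fibers, params, p_kPa, disp, free, config)
    history[[1L]] <- data.frame(
      step = 0L, target_fraction = 1, iterations = res$iters,
      residual = res$residual, converged = res$converged)
    if (res$converged) {
      disp <- res$disp
      ramp_needed <- FALSE
    }
  }
  if (ramp_needed) {
    t_now <- 0
    dt <- 1 / config$load_steps
    step_id <- 0L
    while (t_now < 1 - 1e-12) {
      dt <- min(dt, 1 - t_now)
      step_id <- step_id + 1L
      res <- newton_solve(mesh, fibers, params, p_kPa * (t_now + dt),
                          disp, free, config)
      history[[length(history) + 1L]] <- data.frame(
        step = step_id, target_fraction = t_now + dt,
        iterations = res$iters, residual = res$residual,
        converged = res$converged)
      if (res$converged) {
        disp <- res$disp
        t_now <- t_now + dt
        if (res$iters <= 5) dt <- dt * 2
      } else {
        dt <- dt / 2
        if (dt < 1 / 4096) {
          stop(sprintf(paste0("solve_inflation: Newton divergence at load ",
                              "step %d (pressure fraction %.4f): %s\n",
                              "residual history:\n%s"),
                       step_id, t_now + 2 * dt, res$reason,
                       paste(utils::capture.output(print(
                         do.call(rbind, history))), collapse = "\n")))
        }
      }
    }
  }

  gp <- .gp_fields(mesh$nodes, disp, mesh$elems, unclass(fibers),
                   mat_par_vec(params))
  asm <- assemble_internal(mesh, fibers, params, disp)
  structure(list(
    displacement = disp,
    gp = gp,
    cavity_volume = cavity_volume(mesh, disp),
    applied_pressure = pressure,
    energy = asm$energy,
    residual_history = if (length(history)) do.call(rbind, history) else NULL,
    converged = TRUE),
    class = "solution_field")
}

#' @export
print.solution_field <- function(x, ...) {
  cat(sprintf(paste0("Inflation solution: p = %.3f mmHg, cavity volume ",
                     "%.3f cm^3, max |u| = %.3f mm\n"),
              x$applied_pressure, x$cavity_volume,
              max(abs(x$displacement))))
  invisible(x)
}

# one Newton solve at fixed pressure level (kPa); returns converged state
newton_solve <- function(mesh, fibers, params, p_kPa, disp0, free, config) {
  nn <- nrow(mesh$nodes)
  disp <- disp0
  residual_of <- function(d) {
    a <- assemble_internal(mesh, fibers, params, d)
    if (!isTRUE(a$ok)) return(list(ok = FALSE, reason = a$reason,
                                   elem = a$bad_elem))
    pr <- .asm_pressure(mesh$nodes, d, mesh$endo_faces, p_kPa, FALSE)
    list(ok = TRUE, R = a$fint - pr$fext, ref = sqrt(sum(pr$fext[free]^2)))
  }
  last_res <- NA_real_
  for (it in seq_len(config$max_newton_iters)) {
    a <- assemble_internal(mesh, fibers, params, disp, want_tangent = TRUE)
    if (!isTRUE(a$ok)) {
      return(list(converged = FALSE, iters = it, residual = last_res,
                  reason = sprintf("%s in element %d", a$reason, a$bad_elem)))
    }
    pr <- .asm_pressure(mesh$nodes, disp, mesh$endo_faces, p_kPa, TRUE)
    R <- a$fint - pr$fext
    rnorm <- sqrt(sum(R[free]^2))
    ref <- max(sqrt(sum(pr$fext[free]^2)), 1e-10)
    last_res <- rnorm
    if (rnorm < config$newton_tol * ref || rnorm < 1e-12) {
      return(list(converged = TRUE, iters = it - 1L, residual = rnorm,
                  disp = disp))
    }
    K <- Matrix::sparseMatrix(
      i = c(a$ti, pr$ti), j = c(a$tj, pr$tj), x = c(a$tv, -pr$tv),
      dims = c(3L * nn, 3L * nn))
    du_free <- tryCatch(
      as.numeric(Matrix::solve(K[free, free, drop = FALSE], -R[free])),
      error = function(e) NULL)
    if (is.null(du_free) || !all(is.finite(du_free))) {
      return(list(converged = FALSE, iters = it, residual = rnorm,
                  reason = "singular tangent system"))
    }
    du <- numeric(3L * nn)
    du[free] <- du_free
    dU <- matrix(du, nn, 3, byrow = TRUE)

    alpha <- 1
    accepted <- FALSE
    for (ls in seq_len(9L)) {
      trial <- disp + alpha * dU
      rt <- residual_of(trial)
      if (rt$ok) {
        rnew <- sqrt(sum(rt$R[free]^2))
        if (rnew < rnorm || rnew < config$newton_tol * ref) {
          disp <- trial
          accepted <- TRUE
          break
        }
      }
      alpha <- alpha / 2
    }
    if (!accepted) {
      return(list(converged = FALSE, iters = it, residual = rnorm,
                  reason = "line search failed to reduce the residual"))
    }
  }
  list(converged = FALSE, iters = config$max_newton_iters,
       residual = last_res, reason = "maximum Newton iterations reached")
}

# dU built with matrix(du, nn, 3, byrow = TRUE) assumes dof order
# (node1 x,y,z, node2 x,y,z, ...), which matches the C++ assembly layout.

#' Cavity volume of a (possibly deformed) ventricle mesh
#'
#' Divergence-theorem volume over the deformed endocardial surface. Open
#' (basal-truncated) meshes are closed with a flat base cap and an apex disc
#' spanned from the respective endocardial ring centroids; closed meshes
#' (`sphere_shell_mesh`) need no caps.
#'
#' @param mesh a `ventricle_mesh`.
#' @param disp optional nodal displacement (n_nodes x 3); default undeformed.
#' @return volume in cm^3.
#' @export
cavity_volume <- function(mesh, disp = NULL) {
  x <- mesh$nodes
  if (!is.null(disp)) x <- x + disp
  tri <- list()
  qf <- mesh$endo_faces
  tri[[1]] <- cbind(qf[, 1], qf[, 2], qf[, 3])
  tri[[2]] <- cbind(qf[, 1], qf[, 3], qf[, 4])
  v1 <- x[c(tri[[1]][, 1], tri[[2]][, 1]), , drop = FALSE]
  v2 <- x[c(tri[[1]][, 2], tri[[2]][, 2]), , drop = FALSE]
  v3 <- x[c(tri[[1]][, 3], tri[[2]][, 3]), , drop = FALSE]
  vol6 <- sum(v1[, 1] * (v2[, 2] * v3[, 3] - v2[, 3] * v3[, 2]) +
                v1[, 2] * (v2[, 3] * v3[, 1] - v2[, 1] * v3[, 3]) +
                v1[, 3] * (v2[, 1] * v3[, 2] - v2[, 2] * v3[, 1]))
  if (!isTRUE(mesh$closed)) {
    if (is.null(mesh$endo_base_ring) || is.null(mesh$endo_apex_ring)) {
      stop("cavity_volume: open endocardial surface is not closable ",
           "(missing base/apex rings)")
    }
    cap6 <- function(ring, flip) {
      pts <- x[ring, , drop = FALSE]
      ctr <- colMeans(pts)
      nxt <- pts[c(2:nrow(pts), 1), , drop = FALSE]
      a <- pts; b <- nxt
      if (flip) { a <- nxt; b <- pts }
      sum(ctr[1] * (a[, 2] * b[, 3] - a[, 3] * b[, 2]) +
            ctr[2] * (a[, 3] * b[, 1] - a[, 1] * b[, 3]) +
            ctr[3] * (a[, 1] * b[, 2] - a[, 2] * b[, 1]))
    }
    vol6 <- vol6 + cap6(mesh$endo_base_ring, flip = FALSE) +
      cap6(mesh$endo_apex_ring, flip = TRUE)
  }
  vol <- vol6 / 6 / 1000
  if (vol <= 0) stop("cavity_volume: non-positive volume; surface orientation broken")
  vol
}

#' Semi-analytic inflation of an incompressible thick-walled sphere
#'
#' Verification oracle for the finite-element solver in spherical symmetry.
#' With exactly incompressible kinematics r^3 = R^3 + a^3 - A^3, the internal
#' pressure needed to hold inner radius a is the 1-D equilibrium integral
#' P(a) = integral over lambda in [lambda_out, lambda_in] of
#' (dW/dlambda) / (lambda^3 - 1) d lambda, with lambda = r / R and the
#' isotropic energy evaluated at I1 = 2 lambda^2 + lambda^-4,
#' I2 = lambda^4 + 2 lambda^-2. The target pressure is inverted by root
#' finding on a.
#'
#' @param inner_radius,outer_radius reference radii A < B (mm).
#' @param params isotropic `material_params` (K1 is ignored with a warning if
#'   nonzero; the volumetric penalty plays no role in incompressible kinematics).
#' @param pressure cavity pressure in kPa (note: kPa, not mmHg).
#' @return list with `inner_radius_inflated` (mm), `cavity_volume` (cm^3),
#'   and `pressure` (kPa).
#' @export
thick_sphere_inflation <- function(inner_radius, outer_radius, params,
                                   pressure) {
  stopifnot(inner_radius > 0, outer_radius > inner_radius, pressure >= 0)
  if (params$K1 > 0) {
    warning("thick_sphere_inflation: anisotropic K1 ignored (isotropic oracle)")
  }
  A <- inner_radius; B <- outer_radius
  if (pressure == 0) {
    return(list(inner_radius_inflated = A,
                cavity_volume = 4 / 3 * pi * A^3 / 1000, pressure = 0))
  }
  integrand <- function(lam) {
    I1 <- 2 * lam^2 + lam^-4
    # guard D1 = 0: 0 * exp(overflow) would give NaN at large stretch
    W1 <- params$c1 +
      if (params$D1 > 0) params$D1 * params$D2 * exp(params$D2 * (I1 - 3)) else 0
    W2 <- params$c2
    # dW/dlam / (lam^3 - 1) with the common factor cancelled exactly,
    # so the integrand stays finite as lam -> 1
    W1 * 4 * (lam^3 + 1) / lam^5 + W2 * 4 * (lam^3 + 1) / lam^3
  }
  p_of_a <- function(a) {
    if (a <= A) return(0)
    b <- (B^3 + a^3 - A^3)^(1 / 3)
    stats::integrate(integrand, lower = b / B, upper = a / A,
                     rel.tol = 1e-10, abs.tol = 1e-12)$value
  }
  hi <- A * 1.05
  while (p_of_a(hi) < pressure && hi < A * 20) hi <- hi * 1.25
  if (p_of_a(hi) < pressure) {
    stop(sprintf(paste0("thick_sphere_inflation: pressure %.4g kPa above the ",
                        "solvable range (max %.4g kPa on the search bracket)"),
                 pressure, p_of_a(hi)))
  }
  a <- stats::uniroot(function(a) p_of_a(a) - pressure, c(A, hi),
                      tol = 1e-10)$root
  list(inner_radius_inflated = a, cavity_volume = 4 / 3 * pi * a^3 / 1000,
       pressure = pressure)
}
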