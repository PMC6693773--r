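#' Modified Mooney-Rivlin material parameters
#'
#' Parameter container for the myocardium strain-energy density
#' \deqn{W = c_1(I_1-3) + c_2(I_2-3) + D_1[e^{D_2(I_1-3)}-1]
#'        + \frac{K_1}{K_2}[e^{K_2(I_4-1)^2}-1] + \frac{\kappa}{2}(J-1)^2}
#' where \eqn{I_1 = \mathrm{tr}\,C}, \eqn{I_2 = \frac12(I_1^2 - C\!:\!C)} are the
#' isotropic invariants of the right Cauchy-Green tensor, \eqn{I_4 = n_f^T C n_f}
#' is the squared fiber stretch, and the quadratic \eqn{\kappa} term is the
#' volumetric penalty that enforces near-incompressibility numerically.
#' `kappa` defaults to `100 * (c1 + D1 + K1)`, large enough to keep volumetric
#' strains well below 1\% at physiological pressures.
#'
#' The exponents `D2` and `K2` and the second Mooney constant `c2` are frozen at
#' the published values (0 kPa, 3.0, 3.0) during fitting and calibration; only
#' the stiffness-like parameters `c1`, `D1`, `K1` vary per subject.
#'
#' @param c1,c2,D1 isotropic stiffness constants (kPa); `D2` dimensionless exponent.
#' @param K1 fiber stiffness constant (kPa); `K2` dimensionless exponent.
#' @param kappa volumetric penalty modulus (kPa).
#' @param model_kind `"anisotropic"` (default) or `"isotropic"` (drops the I4 term).
#' @return a `material_params` object.
#' @export
material_params <- function(c1 = 0.8, c2 = 0, D1 = 0.6, D2 = 3.0,
                            K1 = 1.2, K2 = 3.0,
                            kappa = 100 * (c1 + D1 + K1),
                            model_kind = c("anisotropic", "isotropic")) {
  model_kind <- match.arg(model_kind)
  if (model_kind == "isotropic") K1 <- 0
  stopifnot(c1 >= 0, D1 >= 0, K1 >= 0, D2 > 0, K2 > 0, kappa > 0)
  structure(list(c1 = c1, c2 = c2, D1 = D1, D2 = D2, K1 = K1, K2 = K2,
                 kappa = kappa, model_kind = model_kind),
            class = "material_params")
}

#' @export
print.material_params <- function(x, ...) {
  cat(sprintf("Modified Mooney-Rivlin (%s)\n", x$model_kind))
  cat(sprintf("  c1 = %g kPa, c2 = %g kPa, D1 = %g kPa, D2 = %g\n",
              x$c1, x$c2, x$D1, x$D2))
  cat(sprintf("  K1 = %g kPa, K2 = %g, volumetric penalty kappa = %g kPa\n",
              x$K1, x$K2, x$kappa))
  invisible(x)
}

#' Scale the free stiffness parameters by a common factor
#' @param params a `material_params` object.
#' @param scale positive stiffness multiplier applied to c1, c2, D1, K1.
#' @export
scale_stiffness <- function(params, scale) {
  stopifnot(inherits(params, "material_params"), scale > 0)
  params$c1 <- params$c1 * scale
  params$c2 <- params$c2 * scale
  params$D1 <- params$D1 * scale
  params$K1 <- params$K1 * scale
  params$kappa <- params$kappa * scale
  params
}

#' One-dimensional bar stress and strain
#'
#' Engineering strain (L - L0)/L0 of a bar stretched from rest length L0 to L,
#' and the linear-elastic stress YM * strain: the textbook illustration of why a
#' correct zero-stress reference length is required before stress or strain can
#' be computed at all.
#'
#' @param L0 rest (zero-stress) length, positive.
#' @param L current length.
#' @param YM Young's modulus (kPa), non-negative.
#' @return list with `strain` (dimensionless) and `stress` (kPa).
#' @export
bar_stress_strain <- function(L0, L, YM) {
  if (any(L0 <= 0)) stop("bar_stress_strain: rest length must be positive")
  if (any(YM < 0)) stop("bar_stress_strain: Young's modulus must be non-negative")
  strain <- (L - L0) / L0
  list(strain = strain, stress = YM * strain)
}

#' Strain invariants of the right Cauchy-Green tensor
#'
#' I1 = tr C, I2 = (I1^2 - C:C)/2, and the fiber invariant I4 = n_f^T C n_f
#' (the squared stretch along the fiber direction).
#'
#' @param C symmetric positive-definite 3x3 matrix.
#' @param n_f unit fiber direction (any nonzero vector; normalised internally).
#' @return list with I1, I2, I4.
#' @export
cg_invariants <- function(C, n_f = c(1, 0, 0)) {
  C <- as.matrix(C)
  if (!isTRUE(all.equal(C, t(C), tolerance = 1e-8))) {
    stop("cg_invariants: C must be symmetric")
  }
  n_f <- n_f / sqrt(sum(n_f^2))
  I1 <- sum(diag(C))
  I2 <- 0.5 * (I1^2 - sum(C * C))
  I4 <- drop(crossprod(n_f, C %*% n_f))
  list(I1 = I1, I2 = I2, I4 = I4)
}

#' Deformation state derived from a deformation gradient
#'
#' @param F 3x3 deformation gradient (must have positive determinant).
#' @param n_f unit fiber direction in the reference configuration.
#' @return a `deformation_state`: F, C = F'F, Green-Lagrange E = (C - I)/2,
#'   J = det F, and the invariants I1, I2, I4.
#' @export
deformation_state <- function(F, n_f = c(1, 0, 0)) {
  F <- as.matrix(F)
  J <- det(F)
  if (J <= 0) stop("deformation_state: det(F) must be positive (inverted state)")
  C <- crossprod(F)
  inv <- cg_invariants(C, n_f)
  structure(list(F = F, C = C, E = 0.5 * (C - diag(3)), J = J,
                 n_f = n_f / sqrt(sum(n_f^2)),
                 I1 = inv$I1, I2 = inv$I2, I4 = inv$I4),
            class = "deformation_state")
}

#' Strain-energy density of the modified Mooney-Rivlin model
#'
#' @param params a `material_params` object.
#' @param state a `deformation_state` (or a deformation gradient matrix).
#' @param n_f fiber direction, used when `state` is given as a matrix.
#' @return energy density W in kPa; zero at the reference state.
#' @export
strain_energy <- function(params, state, n_f = c(1, 0, 0)) {
  if (is.matrix(state)) state <- deformation_state(state, n_f)
  with(params, {
    W <- c1 * (state$I1 - 3) + c2 * (state$I2 - 3) +
      D1 * (exp(D2 * (state$I1 - 3)) - 1)
    # -beta ln J compensation: the straight-invariant terms alone carry a rest
    # hydrostatic stress 2 c1 + 4 c2 + 2 D1 D2; this term cancels it exactly
    # and vanishes on incompressible (J = 1) paths
    beta <- 2 * c1 + 4 * c2 + 2 * D1 * D2
    W <- W - beta * log(state$J)
    if (K1 > 0) {
      W <- W + (K1 / K2) * (exp(K2 * (state$I4 - 1)^2) - 1)
    }
    W + 0.5 * kappa * (state$J - 1)^2
  })
}

#' Second Piola-Kirchhoff and Cauchy stress from the strain energy
#'
#' Analytic S = dW/dE evaluated from the invariant derivatives, and the
#' push-forward Cauchy stress sigma = J^-1 F S F'.
#'
#' @inheritParams strain_energy
#' @return list with `S` (PK2, kPa) and `sigma` (Cauchy, kPa), both 3x3 symmetric.
#' @export
stress_from_energy <- function(params, state, n_f = c(1, 0, 0)) {
  if (is.matrix(state)) state <- deformation_state(state, n_f)
  if (state$J <= 0) stop("stress_from_energy: inverted state (J <= 0)")
  I3 <- diag(3)
  C <- state$C
  nf <- state$n_f
  W1 <- params$c1 + params$D1 * params$D2 * exp(params$D2 * (state$I1 - 3))
  W2 <- params$c2
  S <- 2 * W1 * I3 + 2 * W2 * (state$I1 * I3 - C)
  if (params$K1 > 0) {
    W4 <- 2 * params$K1 * (state$I4 - 1) * exp(params$K2 * (state$I4 - 1)^2)
    S <- S + 2 * W4 * tcrossprod(nf)
  }
  Cinv <- solve(C)
  beta <- 2 * params$c1 + 4 * params$c2 + 2 * params$D1 * params$D2
  S <- S - beta * Cinv
  S <- S + params$kappa * (state$J - 1) * state$J * Cinv
  sigma <- (state$F %*% S %*% t(state$F)) / state$J
  list(S = (S + t(S)) / 2, sigma = (sigma + t(sigma)) / 2)
}
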