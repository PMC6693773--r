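#' Planar biaxial response of the anisotropic Mooney-Rivlin sheet
#'
#' Emulates the five-ratio biaxial testing protocol on a thin myocardium sheet
#' with the fiber direction along the first in-plane axis. Kinematics are
#' incompressible thin-sheet: the thickness stretch is 1/(lambda_f *
#' lambda_c) and the through-thickness Cauchy stress is zero, which determines
#' the hydrostatic reaction in closed form. For each fiber stretch on the grid
#' the cross-fiber stretch is solved (by root finding) so that the Cauchy
#' stress ratio sigma_fiber : sigma_cross equals the requested test ratio.
#'
#' @param params a `material_params` object.
#' @param stretch_grid fiber-direction stretches, all >= 1 (loading branch).
#' @param ratio stress ratio, one of the protocol labels `"10:10"`, `"7.5:10"`,
#'   `"5:10"`, `"10:7.5"`, `"10:5"` or a positive number fiber/cross.
#' @return a `biaxial_dataset` data.frame with columns ratio_label,
#'   stretch_fiber, stretch_crossfiber, stress_fiber, stress_crossfiber (kPa).
#' @export
biaxial_response <- function(params, stretch_grid = seq(1, 1.25, by = 0.025),
                             ratio = "10:10") {
  stopifnot(inherits(params, "material_params"), all(stretch_grid >= 1))
  if (is.character(ratio)) {
    parts <- as.numeric(strsplit(ratio, ":", fixed = TRUE)[[1]])
    if (length(parts) != 2 || any(is.na(parts)) || any(parts <= 0)) {
      stop("biaxial_response: unparseable ratio label '", ratio, "'")
    }
    label <- ratio
    r <- parts[1] / parts[2]
  } else {
    stopifnot(is.numeric(ratio), ratio > 0)
    label <- format(ratio)
    r <- ratio
  }

  out <- lapply(stretch_grid, function(lf) {
    if (abs(lf - 1) < 1e-12) {
      return(data.frame(ratio_label = label, stretch_fiber = 1,
                        stretch_crossfiber = 1, stress_fiber = 0,
                        stress_crossfiber = 0, stringsAsFactors = FALSE))
    }
    # sigma_f(lc) * 1 - r * sigma_c(lc) = 0 defines the cross stretch
    h <- function(lc) {
      s <- biaxial_stresses(params, lf, lc)
      s$sigma_f - r * s$sigma_c
    }
    lo <- 1 + 1e-9; hi <- max(lf * 1.5, 1.6)
    hlo <- h(lo); hhi <- h(hi)
    tries <- 0
    while (hlo * hhi > 0 && tries < 6) {
      lo <- 1 - (1 - 0.7) * (tries + 1) / 6  # allow mild lateral contraction
      hlo <- h(lo); tries <- tries + 1
    }
    if (hlo * hhi > 0) {
      stop(sprintf(paste0("biaxial_response: plane-stress ratio solve failed ",
                          "(ratio %s, stretch %.4f): h(%.3f)=%.4g h(%.3f)=%.4g"),
                   label, lf, lo, hlo, hi, hhi))
    }
    lc <- stats::uniroot(h, c(lo, hi), tol = 1e-12)$root
    s <- biaxial_stresses(params, lf, lc)
    data.frame(ratio_label = label, stretch_fiber = lf, stretch_crossfiber = lc,
               stress_fiber = s$sigma_f, stress_crossfiber = s$sigma_c,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  class(out) <- c("biaxial_dataset", "data.frame")
  out
}

# Closed-form principal Cauchy stresses of the incompressible sheet,
# fiber along axis 1, through-thickness stress condensed out.
biaxial_stresses <- function(params, lf, lc) {
  lt <- 1 / (lf * lc)
  I1 <- lf^2 + lc^2 + lt^2
  X <- exp(params$D2 * (I1 - 3))
  W1 <- params$c1 + params$D1 * params$D2 * X
  W2 <- params$c2
  I4 <- lf^2
  aniso <- if (params$K1 > 0) {
    4 * params$K1 * (I4 - 1) * exp(params$K2 * (I4 - 1)^2) * lf^2
  } else 0
  dev <- function(l2) 2 * W1 * l2 + 2 * W2 * (I1 * l2 - l2^2)
  p <- dev(lt^2)
  list(sigma_f = dev(lf^2) + aniso - p, sigma_c = dev(lc^2) - p)
}

#' Fit Mooney-Rivlin stiffness parameters to biaxial data
#'
#' Least-squares estimation of (c1, D1, K1) from measured biaxial
#' stress-stretch records, with c2, D2 and K2 frozen at their published values
#' (taken from `init`). With the exponents frozen the predicted Cauchy
#' stresses are linear in the free parameters, so the fit is an exact linear
#' least-squares solve over both stress components of every record.
#'
#' Residuals are weighted by the inverse measured stress magnitude (floored at
#' 1% of the largest stress), i.e. a relative-error fit. Biaxial stresses span
#' orders of magnitude across the stretch range and rig noise is predominantly
#' multiplicative, so relative weighting keeps the small-stretch toe region
#' from being drowned out by the stiff end of the curves and conditions the
#' near-collinear c1/D1 pair far better than an absolute-error fit.
#'
#' @param data a `biaxial_dataset` (columns stretch_fiber, stretch_crossfiber,
#'   stress_fiber, stress_crossfiber, ratio_label).
#' @param init a `material_params` supplying the frozen c2, D2, K2 (and kappa).
#' @return a `biaxial_fit` with elements `params` (fitted `material_params`),
#'   `residual_norm`, `rmse_by_curve`, and `n_records`.
#' @export
fit_biaxial <- function(data, init = material_params()) {
  stopifnot(all(c("stretch_fiber", "stretch_crossfiber", "stress_fiber",
                  "stress_crossfiber") %in% names(data)))
  if (length(unique(data$ratio_label)) < 2) {
    stop("fit_biaxial: need records from at least two stress-ratio protocols")
  }
  D2 <- init$D2; K2 <- init$K2; c2 <- init$c2

  basis <- function(lf, lc) {
    lt <- 1 / (lf * lc)
    I1 <- lf^2 + lc^2 + lt^2
    X <- exp(D2 * (I1 - 3))
    I4 <- lf^2
    # columns: d sigma / d c1, d sigma / d D1, d sigma / d K1; rows: fiber, cross
    a_c1 <- 2 * c(lf^2 - lt^2, lc^2 - lt^2)
    a_D1 <- D2 * X * a_c1
    a_K1 <- c(4 * (I4 - 1) * exp(K2 * (I4 - 1)^2) * lf^2, 0)
    off <- 2 * c2 * c(I1 * lf^2 - lf^4 - (I1 * lt^2 - lt^4),
                      I1 * lc^2 - lc^4 - (I1 * lt^2 - lt^4))
    cbind(a_c1, a_D1, a_K1, off)
  }

  B <- do.call(rbind, Map(function(lf, lc) basis(lf, lc),
                          data$stretch_fiber, data$stretch_crossfiber))
  s <- as.vector(t(cbind(data$stress_fiber, data$stress_crossfiber)))
  w <- if (max(abs(s)) == 0) rep(1, length(s)) else {
    1 / pmax(abs(s), 0.01 * max(abs(s)))
  }
  y <- s - B[, 4]
  A <- B[, 1:3, drop = FALSE]
  dec <- qr(A * w)
  if (dec$rank < 3) {
    stop("fit_biaxial: rank-deficient design (add stretch levels or ratios)")
  }
  theta <- qr.coef(dec, y * w)
  if (any(theta < -1e-8)) {
    warning("fit_biaxial: negative fitted stiffness parameter(s); data may be ",
            "inconsistent with the model")
  }
  fitted <- A %*% theta + B[, 4]
  resid <- y + B[, 4] - fitted
  curve <- rep(data$ratio_label, each = 2)
  rmse <- tapply(resid^2, curve, function(z) sqrt(mean(z)))

  params <- material_params(c1 = max(theta[1], 0), c2 = c2,
                            D1 = max(theta[2], 0), D2 = D2,
                            K1 = max(theta[3], 0), K2 = K2,
                            kappa = init$kappa)
  structure(list(params = params,
                 coefficients = c(c1 = unname(theta[1]), D1 = unname(theta[2]),
                                  K1 = unname(theta[3])),
                 residual_norm = sqrt(sum(resid^2)),
                 rmse_by_curve = rmse,
                 n_records = nrow(data)),
            class = "biaxial_fit")
}

#' @export
coef.biaxial_fit <- function(object, ...) object$coefficients

#' @export
print.biaxial_fit <- function(x, ...) {
  cat("Biaxial Mooney-Rivlin fit (c2, D2, K2 frozen)\n")
  cat(sprintf("  c1 = %.4g kPa, D1 = %.4g kPa, K1 = %.4g kPa\n",
              x$coefficients[1], x$coefficients[2], x$coefficients[3]))
  cat(sprintf("  residual norm %.4g kPa over %d records\n",
              x$residual_norm, x$n_records))
  invisible(x)
}
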