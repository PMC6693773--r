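#' Largest principal value of a symmetric tensor
#'
#' @param tensor symmetric 3x3 (or 2x2) matrix.
#' @return the largest eigenvalue.
#' @export
principal_max <- function(tensor) {
  tensor <- as.matrix(tensor)
  if (nrow(tensor) != ncol(tensor) ||
      !isTRUE(all.equal(tensor, t(tensor), tolerance = 1e-7))) {
    stop("principal_max: input must be a symmetric matrix")
  }
  max(eigen(tensor, symmetric = TRUE, only.values = TRUE)$values)
}

# 6-component (xx,yy,zz,xy,xz,yz) rows -> max principal values, vectorized
# closed-form via the symmetric 3x3 eigenvalue trigonometric identity
principal_max_rows <- function(m6) {
  a <- m6[, 1]; b <- m6[, 2]; c <- m6[, 3]
  d <- m6[, 4]; e <- m6[, 5]; f <- m6[, 6]
  q <- (a + b + c) / 3
  p2 <- (a - q)^2 + (b - q)^2 + (c - q)^2 + 2 * (d^2 + e^2 + f^2)
  p <- sqrt(p2 / 6)
  out <- numeric(nrow(m6))
  z <- p < 1e-14
  out[z] <- q[z]
  if (any(!z)) {
    aa <- (a - q) / p; bb <- (b - q) / p; cc <- (c - q) / p
    dd <- d / p; ee <- e / p; ff <- f / p
    # det of the scaled deviator
    r <- 0.5 * (aa * (bb * cc - ff^2) - dd * (dd * cc - ff * ee) +
                  ee * (dd * ff - bb * ee))
    r <- pmin(pmax(r, -1), 1)
    phi <- acos(r) / 3
    out[!z] <- (q + 2 * p * cos(phi))[!z]
  }
  out
}

#' Sample stress/strain at evenly spaced mid-wall points per slice
#'
#' Places `n_per_slice` points at equal arc-length spacing along each slice's
#' mid-wall contour (average of the inner and outer contour, in reference
#' coordinates), interpolates the Cauchy stress and Green-Lagrange strain
#' tensors by inverse-distance weighting over the 4 nearest element quadrature
#' points, and reduces each tensor to its maximum principal value. Placement
#' is fully deterministic.
#'
#' @param solution a `solution_field` from the mesh built on `stack`.
#' @param stack the `slice_stack` defining the sampling contours.
#' @param n_per_slice points per slice (published protocol: 100).
#' @param surface `"mid"` (default), `"endo"` or `"epi"` contour.
#' @return data.frame with slice, point, x, y, z, stress_max (kPa),
#'   strain_max columns, `n_per_slice * n_slices` rows.
#' @export
sample_slice_points <- function(solution, stack, n_per_slice = 100,
                                surface = c("mid", "endo", "epi")) {
  surface <- match.arg(surface)
  stopifnot(inherits(solution, "solution_field"), n_per_slice >= 1)
  gp_ref <- solution$gp$ref
  out <- vector("list", length(stack$slices))
  for (si in seq_along(stack$slices)) {
    s <- stack$slices[[si]]
    contour <- switch(surface, mid = (s$inner + s$outer) / 2,
                      endo = s$inner, epi = s$outer)
    if (nrow(contour) < 3) {
      stop("sample_slice_points: slice ", si, " has fewer than 3 contour vertices")
    }
    pts <- equal_arclength_points(contour, n_per_slice)
    P <- cbind(pts, s$z)
    # squared distances sample x quadrature point
    d2 <- outer(rowSums(P^2), rowSums(gp_ref^2), "+") - 2 * P %*% t(gp_ref)
    d2[d2 < 0] <- 0
    stress <- numeric(n_per_slice)
    strain <- numeric(n_per_slice)
    for (i in seq_len(n_per_slice)) {
      nb <- order(d2[i, ])[1:4]
      d <- sqrt(d2[i, nb])
      w <- if (d[1] < 1e-9) {
        c(1, 0, 0, 0)
      } else {
        wi <- 1 / d
        wi / sum(wi)
      }
      stress[i] <- principal_max_rows(
        matrix(colSums(w * solution$gp$sigma[nb, , drop = FALSE]), 1))
      strain[i] <- principal_max_rows(
        matrix(colSums(w * solution$gp$E[nb, , drop = FALSE]), 1))
    }
    out[[si]] <- data.frame(slice = si, point = seq_len(n_per_slice),
                            x = P[, 1], y = P[, 2], z = P[, 3],
                            stress_max = stress, strain_max = strain)
  }
  do.call(rbind, out)
}

# n points at equal arc-length spacing along a closed polyline (m x 2)
equal_arclength_points <- function(contour, n) {
  closed <- rbind(contour, contour[1, , drop = FALSE])
  seg <- sqrt(rowSums(diff(closed)^2))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  targets <- (seq_len(n) - 1) * total / n
  idx <- findInterval(targets, cum, rightmost.closed = TRUE)
  frac <- (targets - cum[idx]) / pmax(seg[idx], 1e-300)
  closed[idx, , drop = FALSE] +
    frac * (closed[idx + 1, , drop = FALSE] - closed[idx, , drop = FALSE])
}

#' Summarize a cardiac cycle into per-time-point mean stress/strain
#'
#' The published scalar summaries: mean maximum-principal Cauchy stress and
#' Green-Lagrange strain over `n_per_slice` points on every slice, at each
#' requested time point. 1G cycles natively hold only BF/BE; their EF/EE
#' entries are aliased copies and are flagged.
#'
#' @param states named list of `solution_field`s (from `run_cardiac_cycle_2g`
#'   or `run_cardiac_cycle_1g`).
#' @param stack the sampling `slice_stack` (a mesh-matching stack per state is
#'   required; pass the model's phase stacks via `stacks` for 2G).
#' @param stacks optional named list of per-time-point stacks overriding `stack`.
#' @param generation `"2G"` or `"1G"`.
#' @param id case identifier carried into the summary.
#' @param n_per_slice sampling density per slice.
#' @return a `stress_strain_summary`: data.frame (timepoint, mean_stress,
#'   mean_strain, n_points) with attributes `generation`, `id`, `aliased`.
#' @export
summarize_cycle <- function(states, stack = NULL, stacks = NULL,
                            generation = c("2G", "1G"), id = "case",
                            n_per_slice = 100) {
  generation <- match.arg(generation)
  tps <- c("BF", "EF", "BE", "EE")
  if (!all(tps %in% names(states))) {
    stop("summarize_cycle: missing time point(s): ",
         paste(setdiff(tps, names(states)), collapse = ", "))
  }
  rows <- lapply(tps, function(tp) {
    st <- if (!is.null(stacks)) stacks[[tp]] else stack
    if (is.null(st)) stop("summarize_cycle: no sampling stack for ", tp)
    smp <- sample_slice_points(states[[tp]], st, n_per_slice)
    data.frame(timepoint = tp, mean_stress = mean(smp$stress_max),
               mean_strain = mean(smp$strain_max), n_points = nrow(smp))
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("stress_strain_summary", "data.frame"),
            generation = generation, id = id,
            aliased = attr(states, "aliased"))
}

#' Mesh-independence study on a sequence of mesh densities
#'
#' Runs a user-supplied case at each density, samples stress and strain on a
#' fixed slice stack, and reports the relative L1 difference between
#' consecutive densities. The first density whose successor difference (both
#' stress and strain) falls below `tol` is selected, mirroring the published
#' protocol of refining until consecutive solutions differ by less than 2\%.
#'
#' @param solve_case function(density) returning a `solution_field`.
#' @param densities numeric vector (>= 3 values) in the order to be compared.
#' @param sample_stack fixed `slice_stack` for sampling all solutions.
#' @param tol relative L1 tolerance (published: 0.02).
#' @param n_per_slice sampling density.
#' @return list with `selected` (density or NULL when never converged),
#'   `error_curve` data.frame (density_from, density_to, stress_l1, strain_l1),
#'   and `converged` flag.
#' @export
mesh_independence <- function(solve_case, densities, sample_stack, tol = 0.02,
                              n_per_slice = 100) {
  stopifnot(length(densities) >= 3)
  samples <- lapply(densities, function(d) {
    sample_slice_points(solve_case(d), sample_stack, n_per_slice)
  })
  rel_l1 <- function(a, b) sum(abs(a - b)) / max(sum(abs(b)), 1e-300)
  rows <- lapply(seq_len(length(densities) - 1L), function(i) {
    data.frame(density_from = densities[i], density_to = densities[i + 1L],
               stress_l1 = rel_l1(samples[[i]]$stress_max,
                                  samples[[i + 1L]]$stress_max),
               strain_l1 = rel_l1(samples[[i]]$strain_max,
                                  samples[[i + 1L]]$strain_max))
  })
  curve <- do.call(rbind, rows)
  ok <- which(curve$stress_l1 < tol & curve$strain_l1 < tol)
  list(selected = if (length(ok)) densities[ok[1]] else NULL,
       error_curve = curve, converged = length(ok) > 0)
}
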