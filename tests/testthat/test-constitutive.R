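test_that("bar stress/strain follows the 1-D definitions", {
  expect_equal(bar_stress_strain(1, 1, 123), list(strain = 0, stress = 0))
  expect_equal(bar_stress_strain(1.0, 1.2, 50),
               list(strain = 0.2, stress = 10))
  expect_equal(bar_stress_strain(2.0, 1.0, 10),
               list(strain = -0.5, stress = -5))
  expect_error(bar_stress_strain(0, 1, 10), "positive")
  expect_error(bar_stress_strain(1, 1, -1), "non-negative")
})

test_that("invariants of the right Cauchy-Green tensor", {
  inv <- cg_invariants(diag(3))
  expect_equal(inv, list(I1 = 3, I2 = 3, I4 = 1))
  # incompressible uniaxial stretch 1.2 along the fiber
  C <- diag(c(1.44, 1 / 1.2, 1 / 1.2))
  inv <- cg_invariants(C, c(1, 0, 0))
  expect_equal(inv$I1, 1.44 + 2 / 1.2)
  expect_equal(inv$I4, 1.44)
  # equibiaxial 1.1 in-plane with in-plane fiber
  lam <- 1.1
  C <- diag(c(lam^2, lam^2, 1 / lam^4))
  expect_equal(cg_invariants(C, c(1, 0, 0))$I4, 1.21)
  expect_error(cg_invariants(matrix(1:9, 3)), "symmetric")
})

test_that("strain energy: reference zero, linear term, fiber closed form", {
  p <- material_params()
  expect_equal(strain_energy(p, diag(3)), 0)

  # c1-only response on an incompressible state: W = c1 (I1 - 3)
  # (the -beta ln J compensation vanishes at J = 1)
  p1 <- material_params(c1 = 1, D1 = 1e-12, K1 = 0, kappa = 1)
  lam <- 1.05
  F1 <- diag(c(lam, 1 / sqrt(lam), 1 / sqrt(lam)))
  I1 <- lam^2 + 2 / lam
  expect_equal(strain_energy(p1, F1), 1 * (I1 - 3), tolerance = 1e-9)

  # anisotropic term (K1/K2)[exp(K2 (I4-1)^2) - 1] at I4 = 1.1
  pk <- material_params(c1 = 1e-12, D1 = 1e-12, K1 = 2, K2 = 3, kappa = 1)
  lam4 <- sqrt(1.1)
  F4 <- diag(c(lam4, 1 / sqrt(lam4), 1 / sqrt(lam4)))
  expect_equal(strain_energy(pk, F4, n_f = c(1, 0, 0)),
               (2 / 3) * (exp(3 * 0.1^2) - 1), tolerance = 1e-8)
})

test_that("analytic stress matches finite differences of the energy", {
  set.seed(42)
  p <- material_params()
  w_of_C <- function(C, n_f) strain_energy(p, chol(C), n_f)  # F^T F = C
  for (rep in 1:5) {
    F <- diag(3) + matrix(stats::rnorm(9, sd = 0.08), 3)
    if (det(F) <= 0.2) next
    n_f <- stats::rnorm(3); n_f <- n_f / sqrt(sum(n_f^2))
    S <- stress_from_energy(p, F, n_f)$S
    C <- crossprod(F)
    h <- 1e-6
    S_fd <- matrix(0, 3, 3)
    for (i in 1:3) for (j in i:3) {
      dC <- matrix(0, 3, 3)
      dC[i, j] <- dC[j, i] <- h
      # symmetric perturbation: dE = dC/2, so S:dE = h S_ij for i != j
      # and (h/2) S_ii on the diagonal
      dW <- (w_of_C(C + dC, n_f) - w_of_C(C - dC, n_f)) / (2 * h)
      S_fd[i, j] <- S_fd[j, i] <- if (i == j) 2 * dW else dW
    }
    expect_equal(S, S_fd, tolerance = 1e-5)
  }
})

test_that("stress at reference vanishes and inverted states error", {
  p <- material_params()
  s <- stress_from_energy(p, diag(3))
  expect_equal(s$S, matrix(0, 3, 3), tolerance = 1e-12)
  expect_equal(s$sigma, matrix(0, 3, 3), tolerance = 1e-12)
  expect_error(deformation_state(-diag(3)), "positive")
})

test_that("frame indifference and the isotropic limit", {
  set.seed(7)
  p <- material_params()
  F <- diag(3) + matrix(stats::rnorm(9, sd = 0.05), 3)
  n_f <- c(0.6, 0.8, 0)
  w0 <- strain_energy(p, F, n_f)
  for (rep in 1:5) {
    A <- matrix(stats::rnorm(9), 3)
    Q <- qr.Q(qr(A))
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    expect_equal(strain_energy(p, Q %*% F, n_f), w0, tolerance = 1e-10)
  }
  # K1 = 0 collapses the anisotropic model onto the isotropic one
  pa <- material_params(K1 = 0)
  pi_ <- material_params(model_kind = "isotropic")
  expect_equal(strain_energy(pa, F, n_f), strain_energy(pi_, F, n_f))
  expect_equal(stress_from_energy(pa, F, n_f)$S,
               stress_from_energy(pi_, F, n_f)$S)
})

test_that("energy increases along uniaxial fiber stretch", {
  p <- material_params()
  lams <- seq(1.02, 1.3, by = 0.02)
  w <- vapply(lams, function(l) {
    strain_energy(p, diag(c(l, 1 / sqrt(l), 1 / sqrt(l))), c(1, 0, 0))
  }, numeric(1))
  expect_true(all(diff(c(0, w)) > 0))
})

test_that("pure volumetric deformation gives the hydrostatic penalty stress", {
  # isochoric terms off: W = (kappa/2)(J-1)^2 - with F = alpha I,
  # S = kappa (J - 1) J C^-1 = kappa (J - 1) J / alpha^2 I
  kap <- 50
  p <- material_params(c1 = 1e-12, D1 = 1e-12, K1 = 0, kappa = kap)
  alpha <- 1.06
  s <- stress_from_energy(p, diag(rep(alpha, 3)))
  J <- alpha^3
  expect_equal(s$S, kap * (J - 1) * J / alpha^2 * diag(3), tolerance = 1e-6)
  # Cauchy stress is hydrostatic
  expect_equal(s$sigma, kap * (J - 1) * diag(3), tolerance = 1e-6)
})

test_that("biaxial response: symmetry, anisotropy, degenerate input", {
  # "10:10" is an equal-stress protocol: both directions carry the same stress
  iso <- material_params(model_kind = "isotropic")
  d <- biaxial_response(iso, stretch_grid = seq(1, 1.2, by = 0.05),
                        ratio = "10:10")
  expect_equal(d$stress_fiber[d$stretch_fiber == 1], 0, tolerance = 1e-9)
  expect_equal(d$stress_fiber, d$stress_crossfiber, tolerance = 1e-8)
  # an isotropic sheet under equal stress stretches equally in both directions
  expect_equal(d$stretch_crossfiber, d$stretch_fiber, tolerance = 1e-6)

  # the fiber direction is stiffer: at equal stress it stretches less
  ani <- material_params(K1 = 1.2)
  da <- biaxial_response(ani, stretch_grid = seq(1.025, 1.2, by = 0.025),
                         ratio = "10:10")
  expect_equal(da$stress_fiber, da$stress_crossfiber, tolerance = 1e-8)
  expect_true(all(da$stretch_crossfiber > da$stretch_fiber))
})

test_that("biaxial fitting recovers known parameters from noiseless data", {
  truth <- material_params(c1 = 0.8, D1 = 0.6, K1 = 1.2)
  dat <- do.call(rbind, lapply(c("10:10", "7.5:10", "5:10", "10:7.5", "10:5"),
                               function(r) biaxial_response(truth, ratio = r)))
  fit <- fit_biaxial(dat, init = material_params(c1 = 0.3, D1 = 0.2, K1 = 0.5))
  cf <- coef(fit)
  expect_lt(abs(cf["c1"] - 0.8) / 0.8, 0.01)
  expect_lt(abs(cf["D1"] - 0.6) / 0.6, 0.01)
  expect_lt(abs(cf["K1"] - 1.2) / 1.2, 0.01)

  # all-zero stress data drive the free parameters to zero
  z <- dat
  z$stress_fiber <- 0
  z$stress_crossfiber <- 0
  fz <- coef(fit_biaxial(z))
  expect_lt(max(abs(fz)), 1e-6)

  # a single stretch level is rank-deficient
  one <- dat[abs(dat$stretch_fiber - dat$stretch_fiber[5]) < 1e-12, ][1, ]
  expect_error(fit_biaxial(one), "rank|single|insufficient|need")
})
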