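coarse_case <- function() {
  g <- make_idealized_ventricle(n_slices = 4, n_circ = 8)
  list(mesh = g$mesh, stack = g$stack, fibers = assign_fibers(g$mesh),
       params = material_params())
}

test_that("unit conversion and solver config validation", {
  expect_equal(mmHg_to_kPa(1), 0.1333224)
  expect_equal(mmHg_to_kPa(7.5006), 1, tolerance = 1e-4)
  expect_error(solver_config(load_steps = 0), "load_steps")
  expect_error(solver_config(newton_tol = -1), "newton_tol")
})

test_that("zero pressure gives zero displacement and stress", {
  cc <- coarse_case()
  sol <- solve_inflation(cc$mesh, cc$fibers, cc$params, 0)
  expect_equal(max(abs(sol$displacement)), 0)
  expect_equal(max(abs(sol$gp$sigma)), 0, tolerance = 1e-10)
  expect_equal(sol$cavity_volume, cavity_volume(cc$mesh))
  expect_true(sol$converged)
})

test_that("internal force is the gradient of the strain energy", {
  g <- make_idealized_ventricle(n_slices = 3, n_circ = 8, n_layers = 1)
  fib <- assign_fibers(g$mesh)
  par <- material_params()
  set.seed(3)
  nn <- nrow(g$mesh$nodes)
  disp <- matrix(stats::rnorm(3 * nn, sd = 0.05), nn, 3)
  asm <- ventmech2g:::assemble_internal(g$mesh, fib, par, disp)
  expect_true(asm$ok)
  h <- 1e-6
  # sample a subset of dofs: dof index 3 (node - 1) + component
  idx <- sort(sample(3L * nn, 60))
  fd <- vapply(idx, function(dof) {
    node <- (dof - 1L) %/% 3L + 1L
    comp <- (dof - 1L) %% 3L + 1L
    dp <- disp; dp[node, comp] <- dp[node, comp] + h
    dm <- disp; dm[node, comp] <- dm[node, comp] - h
    (ventmech2g:::assemble_internal(g$mesh, fib, par, dp)$energy -
       ventmech2g:::assemble_internal(g$mesh, fib, par, dm)$energy) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(fd - asm$fint[idx])) / max(abs(asm$fint[idx])), 1e-4)
})

test_that("small-pressure sphere inflation matches the Lame solution", {
  mesh <- sphere_shell_mesh(r_in = 25, r_out = 30, n_face = 6, n_layers = 2)
  fib <- structure(matrix(rep(c(1, 0, 0), nrow(mesh$elems)),
                          ncol = 3, byrow = TRUE),
                   class = c("fiber_field", "matrix"))
  par <- material_params(c1 = 0.8, D1 = 1e-9, K1 = 0, kappa = 80)
  p_mmHg <- 0.05
  p <- mmHg_to_kPa(p_mmHg)
  sol <- solve_inflation(mesh, fib, par, p_mmHg,
                         solver_config(load_steps = 1))
  # consistent small-strain moduli: mu = 2 c1, lambda = kappa
  mu <- 2 * par$c1; lam <- par$kappa
  a <- 25; b <- 30
  u_exact <- p * a^3 / (b^3 - a^3) * (a / (3 * lam + 2 * mu) +
                                        b^3 / (4 * mu * a^2))
  inner <- unique(as.vector(mesh$endo_faces))
  r0 <- sqrt(rowSums(mesh$nodes[inner, ]^2))
  ur <- rowSums(sol$displacement[inner, ] * mesh$nodes[inner, ]) / r0
  expect_lt(abs(mean(ur) - u_exact) / u_exact, 0.05)
})

test_that("thick-sphere oracle: identity at zero pressure, closed form, monotone", {
  par <- material_params(c1 = 0.8, c2 = 0, D1 = 0, K1 = 0)
  r0 <- thick_sphere_inflation(25, 30, par, 0)
  expect_equal(r0$inner_radius_inflated, 25)
  expect_equal(r0$cavity_volume, 4 / 3 * pi * 25^3 / 1000)

  # neo-Hookean closed form: P(a) = c1 [F(a/A) - F(b/B)], F(l) = -4/l - 1/l^4,
  # valid below the limit-point pressure (~0.36 kPa for this geometry)
  Fl <- function(l) -4 / l - 1 / l^4
  for (p in c(0.1, 0.2, 0.3)) {
    r <- thick_sphere_inflation(25, 30, par, p)
    a <- r$inner_radius_inflated
    b <- (30^3 + a^3 - 25^3)^(1 / 3)
    p_closed <- par$c1 * (Fl(a / 25) - Fl(b / 30))
    expect_equal(p_closed, p, tolerance = 1e-6)
  }

  radii <- vapply(c(0.05, 0.1, 0.2, 0.3, 0.35), function(p) {
    thick_sphere_inflation(25, 30, par, p)$inner_radius_inflated
  }, numeric(1))
  expect_true(all(diff(radii) > 0))

  # a pure neo-Hookean sphere has no equilibrium above the limit pressure
  expect_error(thick_sphere_inflation(25, 30, par, 1.0),
               "above the solvable range")

  expect_warning(thick_sphere_inflation(25, 30, material_params(), 0.2),
                 "K1 ignored")
})

test_that("cavity volume: closed forms, scaling, translation invariance", {
  g <- make_idealized_ventricle(long_axis_len = 25, endo_radius = 25,
                                wall_thickness = 5, n_slices = 12,
                                n_circ = 32, apex_angle = 0.2)
  v_hemi <- (2 / 3) * pi * 25^3 / 1000
  expect_lt(abs(cavity_volume(g$mesh) - v_hemi) / v_hemi, 0.02)

  cc <- coarse_case()
  v0 <- cavity_volume(cc$mesh)
  scaled <- cc$mesh
  scaled$nodes <- 1.3 * cc$mesh$nodes
  expect_equal(cavity_volume(scaled), 1.3^3 * v0, tolerance = 1e-12)

  moved <- cc$mesh
  moved$nodes <- sweep(cc$mesh$nodes, 2, c(11, -7, 3), "+")
  expect_equal(cavity_volume(moved), v0, tolerance = 1e-9)

  # displacement argument is equivalent to moving the nodes
  nn <- nrow(cc$mesh$nodes)
  d <- matrix(rep(c(1, 2, -1), each = nn), nn, 3)
  expect_equal(cavity_volume(cc$mesh, d), v0, tolerance = 1e-9)

  # closed sphere shell needs no caps
  sm <- sphere_shell_mesh(25, 30, n_face = 16)
  expect_lt(abs(cavity_volume(sm) - 4 / 3 * pi * 25^3 / 1000) /
              (4 / 3 * pi * 25^3 / 1000), 0.02)
})

test_that("solution fields expose converged residual history", {
  cc <- coarse_case()
  sol <- solve_inflation(cc$mesh, cc$fibers, cc$params, 3)
  expect_true(all(sol$residual_history$converged))
  expect_gt(sol$cavity_volume, cavity_volume(cc$mesh))
  expect_equal(sol$applied_pressure, 3)
  # warm start at the converged state returns it unchanged
  sol2 <- solve_inflation(cc$mesh, cc$fibers, cc$params, 3,
                          init_disp = sol$displacement)
  expect_equal(sol2$displacement, sol$displacement)
})

test_that("rigid rotation of mesh and load rotates the solution", {
  g <- make_idealized_ventricle(n_slices = 3, n_circ = 8, n_layers = 1)
  fib <- assign_fibers(g$mesh)
  par <- material_params()
  sol <- solve_inflation(g$mesh, fib, par, 2)

  # rotate about the long axis by one circumferential spacing so the
  # in-plane pin constraints map onto equivalent node positions
  th <- 2 * pi / 8
  Q <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  rot <- g$mesh
  rot$nodes <- g$mesh$nodes %*% t(Q)
  rot$elem_circ <- g$mesh$elem_circ %*% t(Q)
  rot$elem_merid <- g$mesh$elem_merid %*% t(Q)
  fib_rot <- structure(unclass(fib) %*% t(Q), class = class(fib))
  sol_rot <- solve_inflation(rot, fib_rot, par, 2)
  # cavity volume is objective under the rigid map even though the pin
  # constraints land on different nodes
  expect_equal(sol_rot$cavity_volume, sol$cavity_volume, tolerance = 1e-5)
})
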