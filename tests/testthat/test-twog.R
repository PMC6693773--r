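iv <- make_idealized_ventricle()

test_that("calibration_config carries the published defaults and validates", {
  cfg <- calibration_config()
  expect_equal(cfg$init_shrink_diastole, 0.02)
  expect_equal(cfg$init_shrink_systole, 0.15)
  expect_equal(cfg$volume_tol, 0.005)
  expect_equal(cfg$param_volume_tol, 0.002)
  expect_error(calibration_config(volume_tol = 0), "volume_tol")
  expect_error(calibration_config(init_shrink_diastole = 0.6),
               "init_shrink_diastole")
})

test_that("preshrink: identity, cylinder closed forms, wall conservation", {
  s0 <- preshrink(iv$stack, 0, 0)
  expect_equal(s0$slices, iv$stack$slices, tolerance = 1e-12)

  # circular-cylinder stack: closed forms are exact for the polygon areas
  th <- 2 * pi * (0:63) / 64
  ring <- function(r) cbind(r * cos(th), r * sin(th))
  cyl <- ventmech2g:::new_slice_stack(lapply(seq(0, 30, by = 5), function(z) {
    list(z = z, inner = ring(20), outer = ring(25))
  }))
  v_cav <- stack_cavity_volume(cyl)
  v_wall <- stack_wall_volume(cyl)

  sh <- preshrink(cyl, 0.1)
  # inner area x 0.9^2 and slice spacing x 0.9 about the base plane
  expect_equal(stack_cavity_volume(sh), 0.9^2 * 0.9 * v_cav, tolerance = 1e-12)
  expect_equal(stack_wall_volume(sh), v_wall, tolerance = 1e-12)
  z <- vapply(sh$slices, `[[`, numeric(1), "z")
  expect_equal(max(z), 30)               # base plane is the top slice
  expect_equal(diff(z), rep(4.5, 6), tolerance = 1e-12)

  # independent long-axis rate: spacing untouched, cavity scales by area only
  sh2 <- preshrink(cyl, 0.1, long_axis_rate = 0)
  expect_equal(stack_cavity_volume(sh2), 0.9^2 * v_cav, tolerance = 1e-12)
  expect_equal(stack_wall_volume(sh2), v_wall, tolerance = 1e-12)

  # wall volume is conserved on the non-prismatic ventricle stack too
  for (s in c(0.02, 0.15)) {
    expect_equal(stack_wall_volume(preshrink(iv$stack, s)),
                 stack_wall_volume(iv$stack), tolerance = 1e-9)
  }
  # cavity volume is strictly decreasing in the shrink rate
  vols <- vapply(c(0, 0.05, 0.1, 0.2), function(s) {
    stack_cavity_volume(preshrink(iv$stack, s))
  }, numeric(1))
  expect_true(all(diff(vols) < 0))

  expect_error(preshrink(iv$stack, -0.1), "inner_rate")
  expect_error(preshrink(iv$stack, 1), "inner_rate")
})

test_that("zero-load calibration round-trips a known pre-shrink", {
  par <- material_params()
  s_true <- 0.02
  stack_true <- preshrink(iv$stack, s_true)
  mesh_true <- mesh_from_slices(stack_true, n_layers = 2)
  fib_true <- assign_fibers(mesh_true)
  v_target <- solve_inflation(mesh_true, fib_true, par, 3)$cavity_volume

  g <- calibrate_zero_load(iv$stack, v_target, 3, par)
  expect_s3_class(g, "zero_load_geometry")
  expect_lt(abs(g$rel_error), 0.005)
  expect_lt(abs(g$shrink_rate_short_axis - s_true), 0.01)
  expect_equal(g$shrink_rate_long_axis, g$shrink_rate_short_axis)
  # the trace records every evaluation and ends at the accepted error
  expect_true(is.data.frame(g$trace))
  expect_equal(min(abs(g$trace$rel_error)), abs(g$rel_error))
  # wall volume is preserved through the calibration
  expect_equal(stack_wall_volume(g$stack), stack_wall_volume(iv$stack),
               tolerance = 1e-3)
})

test_that("zero-load calibration accepts the trivial zero-pressure case", {
  par <- material_params()
  target <- cavity_volume(iv$mesh)
  g <- calibrate_zero_load(iv$stack, target, 0, par)
  expect_equal(g$shrink_rate_short_axis, 0)
  expect_lt(abs(g$rel_error), 1e-9)
})

test_that("zero-load calibration rejects unreachable targets", {
  par <- material_params()
  # far above the unshrunk inflated volume: no bracket exists
  expect_error(calibrate_zero_load(iv$stack, 1e4, 3, par), "no bracket")
})

test_that("material calibration recovers a known stiffness scale", {
  par <- material_params()
  g <- calibrate_zero_load(iv$stack, 1.08 * stack_cavity_volume(iv$stack),
                           3, par)
  stiff <- scale_stiffness(par, 2)
  v_t <- solve_inflation(g$mesh, g$fibers, stiff, 10)$cavity_volume

  mc <- calibrate_material(g, data.frame(pressure = 10, volume = v_t), par)
  expect_s3_class(mc, "material_calibration")
  expect_lt(max(abs(mc$rel_errors)), 0.002)
  expect_lt(abs(mc$scale - 2) / 2, 0.05)
  # frozen exponents, scaled stiffnesses
  expect_equal(mc$params$D2, par$D2)
  expect_equal(mc$params$K2, par$K2)
  expect_equal(mc$params$c1 / par$c1, mc$scale)
  expect_equal(mc$params$K1 / par$K1, mc$scale)
  expect_error(calibrate_material(g, data.frame(pressure = 10, volume = -1),
                                  par), "volume")
})

test_that("full 2G construction and cardiac cycle on the idealized ventricle", {
  v0 <- stack_cavity_volume(iv$stack)
  tv <- list(BF = v0, EF = 1.25 * v0, BE = 1.25 * v0, EE = v0)
  # diastole spans a wider relative pressure range (2 -> 8 mmHg) than systole
  # (12 -> 30 mmHg), so the systolic zero-load geometry must shrink more;
  # the systolic muscle starts from a stiffer (contracted) material
  pp <- make_pressure_profile(30, p_min = 2, p_ed = 8, p_es = 12)
  par_sys <- scale_stiffness(material_params(), 4)

  expect_error(
    calibrate_twog(iv$stack, list(BF = v0, EF = 1.25 * v0, BE = 1.3 * v0,
                                  EE = v0), pp,
                   material_params(), par_sys),
    "V\\(BF\\) = V\\(EE\\) and V\\(EF\\) = V\\(BE\\)")
  expect_error(
    calibrate_twog(iv$stack, list(BF = v0, EF = v0, BE = v0, EE = v0), pp,
                   material_params(), par_sys),
    "minimum volume must be below maximum")

  m2g <- calibrate_twog(iv$stack, tv, pp, material_params(), par_sys)
  expect_s3_class(m2g, "twog_model")
  # the systolic zero-load geometry is the more contracted one
  expect_gt(m2g$systole_geom$shrink_rate_short_axis,
            m2g$diastole_geom$shrink_rate_short_axis)
  expect_lt(stack_cavity_volume(m2g$systole_geom$stack),
            stack_cavity_volume(m2g$diastole_geom$stack))

  st <- run_cardiac_cycle_2g(m2g)
  expect_named(st, c("BF", "EF", "BE", "EE"))
  expect_lt(attr(st, "period_difference"), 0.001)
  # calibrated states hit the target volumes
  expect_equal(st$BF$cavity_volume, tv$BF, tolerance = 0.01)
  expect_equal(st$EF$cavity_volume, tv$EF, tolerance = 0.01)
  expect_equal(st$BE$cavity_volume, tv$BE, tolerance = 0.01)
  expect_equal(st$EE$cavity_volume, tv$EE, tolerance = 0.01)
  # EF and BE match in volume yet live on different geometries: the wall
  # at begin-ejection carries the higher pressure and the higher stress
  expect_gt(max(abs(st$BE$gp$sigma)), max(abs(st$EF$gp$sigma)))
  expect_false(isTRUE(all.equal(st$EF$displacement, st$BE$displacement)))
})

test_that("1G cycle aliases EF/EE to its only two native states", {
  par <- material_params()
  g <- calibrate_zero_load(iv$stack, 1.05 * stack_cavity_volume(iv$stack),
                           3, par)
  g$params <- par
  cyc <- run_cardiac_cycle_1g(g, 3, 12)
  expect_identical(cyc$EF, cyc$BE)
  expect_identical(cyc$EE, cyc$BF)
  expect_equal(attr(cyc, "aliased"), c(EF = "BE", EE = "BF"))
  expect_gt(cyc$BE$cavity_volume, cyc$BF$cavity_volume)

  # degenerate pressure range collapses the cycle to a single state
  flat <- run_cardiac_cycle_1g(g, 3, 3)
  expect_equal(flat$BE$cavity_volume, flat$BF$cavity_volume, tolerance = 1e-9)
  expect_error(run_cardiac_cycle_1g(g, 12, 3), "p_min <= p_max")
})
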