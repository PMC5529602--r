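water <- fluid_properties(eta = 1e-3, rho = 1000)

test_that("squeeze pressure takes its boundary and centre values", {
  rect <- chamber_geometry("rectangular", L = 1, W = 1, opening = 0.3)
  expect_equal(squeeze_pressure(rect, cbind(c(-0.5, 0.5, 0), 0)),
               c(0, 0, -1 / 8))
  circ <- chamber_geometry("circular", R = 1, theta = 0.3)
  expect_equal(squeeze_pressure(circ, cbind(c(1, 0), 0)), c(0, -1 / 4))
  expect_error(squeeze_pressure(rect, cbind(0.7, 0)), "outside")
  expect_error(squeeze_pressure(circ, cbind(1.2, 0)), "outside")
})

test_that("coupling constant K obeys the f-factor identities", {
  prob <- proboscis_geometry(l_p = 10.1e-3, d_p = 494.6e-6)
  rec <- atropos_record()
  h <- rec$h_max
  f <- f_factor(prob, h)
  circ <- chamber_from_record(rec, shape = "circular")
  rect <- chamber_from_record(rec, shape = "rectangular")
  # geometry cancels for the circular chamber: K_c = -(32/3) f
  expect_equal(compute_K(circ, prob, h), -(32 / 3) * f, tolerance = 1e-12)
  expect_equal(compute_K(circ, prob, h), -(32 / 3) * 75.8, tolerance = 0.01)
  # rectangular: K_r = -(32/(3 pi)) f (W/L)
  expect_equal(compute_K(rect, prob, h),
               -(32 / (3 * pi)) * f * rect$aspect, tolerance = 1e-12)
  expect_equal(compute_K(rect, prob, 0), 0)
  expect_lte(compute_K(rect, prob, h), 0)
})

test_that("assembled pressure equals K on the opening and solves the Poisson problem", {
  res <- cached_solve("circular", theta = 0.3)
  prob <- proboscis_geometry(5e-3, 60e-6)
  ch <- chamber_geometry("circular", R = 200e-6, theta = 0.3)
  asm <- assemble_pressure(res$field, ch, prob, h = 90e-6)
  dirn <- unique(unlist(
    res$mesh$boundary[res$mesh$boundary$tag == "opening", c("n1", "n2")]))
  expect_equal(asm$field$values[dirn], rep(asm$K, length(dirn)),
               tolerance = 1e-12)
  # interior Poisson residual: lap(P) = 1, checked with an independent
  # five-point stencil on interpolated values. Run on the rectangular
  # chamber, whose interior mesh is uniform, so interpolation noise stays
  # well below the signal.
  resr <- cached_solve("rectangular", aspect = 1, g = 0.3)
  chr <- chamber_geometry("rectangular", L = 300e-6, W = 300e-6,
                          opening = 90e-6)
  asmr <- assemble_pressure(resr$field, chr, prob, h = 90e-6)
  hfd <- 0.1
  ctr <- cbind(c(-0.2, 0, 0.2, 0.1, -0.1, 0.3, -0.25, 0.15),
               c(0.05, -0.3, 0.25, 0, 0.2, -0.15, -0.1, 0.35))
  lap <- vapply(seq_len(nrow(ctr)), function(i) {
    p0 <- ctr[i, ]
    st <- rbind(p0, p0 + c(hfd, 0), p0 - c(hfd, 0),
                p0 + c(0, hfd), p0 - c(0, hfd))
    v <- field_interpolate(asmr$field, st)
    (sum(v[-1]) - 4 * v[1]) / hfd^2
  }, 0)
  expect_equal(mean(lap), 1, tolerance = 0.05)
  expect_true(all(abs(lap - 1) < 0.25))
  # geometry mismatch is refused
  ch2 <- chamber_geometry("circular", R = 200e-6, theta = 0.5)
  expect_error(assemble_pressure(res$field, ch2, prob, h = 90e-6),
               "mismatch")
})

test_that("wall-normal pressure gradient vanishes on the chamber walls", {
  res <- cached_solve("circular", theta = 0.5)
  prob <- proboscis_geometry(5e-3, 60e-6)
  ch <- chamber_geometry("circular", R = 200e-6, theta = 0.5)
  asm <- assemble_pressure(res$field, ch, prob, h = 90e-6)
  # sample the radial derivative of total P just inside the wall arc by a
  # one-sided difference, away from the singular corners
  ang <- seq(1.2, pi - 0.2, length.out = 15)
  hfd <- 0.01
  dPdr <- vapply(ang, function(a) {
    v <- field_interpolate(asm$field,
                           rbind(c(cos(a), sin(a)) * (1 - hfd),
                                 c(cos(a), sin(a)) * (1 - 2 * hfd)))
    (v[1] - v[2]) / hfd
  }, 0)
  # gradient magnitude in the chamber is O(1); the wall-normal part is small
  expect_lt(median(abs(dPdr)), 0.05)
})

test_that("dimensional pressure scales and signs follow the stroke", {
  res <- cached_solve("circular", theta = 0.3)
  prob <- proboscis_geometry(5e-3, 60e-6)
  ch <- chamber_geometry("circular", R = 200e-6, theta = 0.3)
  h <- 90e-6
  asm <- assemble_pressure(res$field, ch, prob, h)
  up <- dimensional_pressure(asm, water,
                             plunger_kinematics(h = h, dhdt = 1e-3))
  expect_true(all(up$values <= 1e-9))   # suction everywhere during uptake
  expect_equal(attr(up, "unit"), "Pa")
  still <- dimensional_pressure(asm, water,
                                plunger_kinematics(h = h, dhdt = 0))
  expect_equal(max(abs(still$values)), 0)
  # tripling h at fixed dh/dt divides the scale by 27 (fresh assembly: K
  # changes too, so compare the pure scale attribute)
  asm3 <- assemble_pressure(res$field, ch, prob, 3 * h)
  up3 <- dimensional_pressure(asm3, water,
                              plunger_kinematics(h = 3 * h, dhdt = 1e-3))
  expect_equal(attr(up, "scale") / attr(up3, "scale"), 27,
               tolerance = 1e-12)
  expect_error(
    dimensional_pressure(asm, water, plunger_kinematics(h = 2 * h)),
    "differs")
})

test_that("lubrication velocity follows the pressure gradient", {
  res <- cached_solve("rectangular", aspect = 1, g = 0.3)
  prob <- proboscis_geometry(5e-3, 60e-6)
  ch <- chamber_geometry("rectangular", L = 300e-6, W = 300e-6,
                         opening = 90e-6)
  h <- 80e-6
  asm <- assemble_pressure(res$field, ch, prob, h)
  p <- dimensional_pressure(asm, water, plunger_kinematics(h = h, dhdt = 1e-3))
  v <- velocity_field(p, h, water)
  expect_equal(dim(v), c(nrow(res$mesh$tri), 2L))
  # halving h at fixed pressure gradient quarters the speed
  v2 <- velocity_field(p, h / 2, water)
  expect_equal(v2, v / 4, tolerance = 1e-12)
  # uniform pressure moves nothing
  pu <- structure(list(mesh = res$mesh,
                       values = rep(3, nrow(res$mesh$nodes))),
                  class = "scalar_field")
  expect_equal(max(abs(velocity_field(pu, h, water, yardstick = 300e-6))), 0)
  # no-penetration: near the zero-flux side walls the normal (Y) velocity
  # component is small compared to the overall flow speed
  wz <- res$mesh$boundary[res$mesh$boundary$tag == "wall_zero", ]
  wzn <- unique(c(wz$n1, wz$n2))
  touch <- which(apply(matrix(res$mesh$tri %in% wzn,
                              nrow(res$mesh$tri)), 1, any))
  vmax <- max(sqrt(rowSums(v^2)))
  expect_lt(median(abs(v[touch, 2])) / vmax, 0.05)
})

test_that("Poiseuille coupling closes the volume balance exactly", {
  prob <- proboscis_geometry(l_p = 10e-3, d_p = 100e-6)
  expect_equal(poiseuille_discharge(100, prob, water),
               pi * (100e-6)^4 * 100 / (128 * 1e-3 * 10e-3),
               tolerance = 1e-12)
  expect_equal(poiseuille_discharge(100, prob, water), 2.45e-11,
               tolerance = 1e-3)
  expect_equal(poiseuille_discharge(0, prob, water), 0)
  # fourth-power diameter dependence
  prob2 <- proboscis_geometry(10e-3, 200e-6)
  expect_equal(poiseuille_discharge(100, prob2, water) /
                 poiseuille_discharge(100, prob, water), 16,
               tolerance = 1e-12)
  # round trip: Q(P_p(dhdt)) = -A dhdt (conservation of liquid volume)
  ch <- chamber_geometry("rectangular", L = 1e-3, W = 0.8e-3,
                         opening = 100e-6)
  for (dhdt in c(1e-3, -2e-4)) {
    kin <- plunger_kinematics(h = 1e-4, dhdt = dhdt)
    Pp <- coupling_pressure(ch, prob, water, kin)
    expect_equal(poiseuille_discharge(Pp, prob, water), -ch$area * dhdt,
                 tolerance = 1e-12)
    if (dhdt > 0) expect_lt(Pp, 0)   # suction during uptake
  }
  # linear in chamber area
  ch2 <- chamber_geometry("rectangular", L = 2e-3, W = 0.8e-3,
                          opening = 100e-6)
  kin <- plunger_kinematics(h = 1e-4, dhdt = 1e-3)
  expect_equal(coupling_pressure(ch2, prob, water, kin),
               2 * coupling_pressure(ch, prob, water, kin),
               tolerance = 1e-12)
  expect_error(poiseuille_discharge(10, proboscis_geometry(0, 1e-4), water),
               "l_p = 0")
})

test_that("discrete opening flux balances the swept volume", {
  prob <- proboscis_geometry(5e-3, 60e-6)
  for (cfg in list(list(shape = "rectangular", aspect = 1, g = 0.1),
                   list(shape = "circular", theta = 0.3))) {
    res <- do.call(cached_solve, cfg)
    ch <- if (cfg$shape == "circular")
      chamber_geometry("circular", R = 250e-6, theta = cfg$theta)
    else
      chamber_geometry("rectangular", L = 250e-6, W = 250e-6 * cfg$aspect,
                       opening = 250e-6 * cfg$g)
    asm <- assemble_pressure(res$field, ch, prob, h = 80e-6)
    for (dhdt in c(2e-3, 0, -1e-3)) {
      kin <- plunger_kinematics(h = 80e-6, dhdt = dhdt)
      expect_equal(opening_flux(asm, water, kin), ch$area * dhdt,
                   tolerance = 0.01)
    }
  }
})

test_that("nodal velocity averaging preserves a uniform flow", {
  res <- cached_solve("rectangular", aspect = 1, g = 0.3)
  v <- matrix(rep(c(2, -1), each = nrow(res$mesh$tri)), ncol = 2)
  vn <- nodal_velocity(v, res$mesh)
  expect_equal(vn[, 1], rep(2, nrow(res$mesh$nodes)), tolerance = 1e-12)
  expect_equal(vn[, 2], rep(-1, nrow(res$mesh$nodes)), tolerance = 1e-12)
})
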