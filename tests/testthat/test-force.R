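water <- fluid_properties(eta = 1e-3, rho = 1000)

test_that("shape constants hit their closed-form limits", {
  # full-opening rectangle: C_r = integral of -X/2 - 1/4 = -W/(4L)
  m <- build_mesh(chamber_geometry("rectangular", L = 1, W = 1, opening = 1),
                  base_nx = 24)
  C <- shape_constant(solve_mixed_laplace(m))
  expect_equal(C$C, -1 / 4, tolerance = 1e-10)
  # all-open disk: zero field, zero constant
  mc <- build_mesh(chamber_geometry("circular", R = 1, theta = pi),
                   base_nphi = 64, base_rings = 6)
  Cc <- shape_constant(solve_mixed_laplace(mc))
  expect_equal(Cc$C, 0)
  # partial openings give strictly negative constants
  res <- cached_solve("circular", theta = 0.3)
  expect_lt(shape_constant(res$field)$C, 0)
  # a non-converged record flags the constant
  expect_warning(
    flagged <- shape_constant(res$field,
                              structure(list(converged = FALSE),
                                        class = "convergence_record")),
    "non-converged")
  expect_false(flagged$converged)
})

test_that("computed C_c agrees with the published log-fit at theta = 0.3", {
  res <- cached_solve("circular", theta = 0.3)
  expect_equal(shape_constant(res$field)$C, 3.1 * log(0.3) - 2.25,
               tolerance = 0.02)
})

test_that("plunger force decomposes into Stefan and column terms", {
  prob <- proboscis_geometry(l_p = 10e-3, d_p = 100e-6)
  res <- cached_solve("circular", theta = 0.3)
  C <- shape_constant(res$field)
  ch <- chamber_geometry("circular", R = 300e-6, theta = 0.3)
  kin <- plunger_kinematics(h = 100e-6, dhdt = 1e-3)
  F1 <- plunger_force(C, ch, prob, water, kin)
  expect_equal(F1$total, F1$stefan_term + F1$column_term, tolerance = 1e-12)
  expect_lt(F1$stefan_term, 0)   # resistive during uptake
  expect_lt(F1$column_term, 0)
  # halving the gap at fixed rate multiplies the Stefan term by 8
  kin2 <- plunger_kinematics(h = 50e-6, dhdt = 1e-3)
  expect_equal(plunger_force(C, ch, prob, water, kin2)$stefan_term,
               8 * F1$stefan_term, tolerance = 1e-12)
  # the column term is untouched by h
  expect_equal(plunger_force(C, ch, prob, water, kin2)$column_term,
               F1$column_term, tolerance = 1e-12)
  # no motion, no force; separated galeae, no column term
  expect_equal(plunger_force(C, ch, prob, water,
                             plunger_kinematics(h = 1e-4))$total, 0)
  F0 <- plunger_force(C, ch, proboscis_geometry(0, 100e-6), water, kin)
  expect_equal(F0$column_term, 0)
  # energy sign: the fluid only dissipates, F dh/dt <= 0 either stroke
  for (dhdt in c(1e-3, -1e-3, 0)) {
    k <- plunger_kinematics(h = 80e-6, dhdt = dhdt)
    expect_lte(plunger_force(C, ch, prob, water, k)$total * dhdt, 0)
  }
  # a constant computed for the other shape is rejected
  chr <- chamber_geometry("rectangular", L = 1e-3, W = 1e-3,
                          opening = 1e-4)
  expect_error(plunger_force(C, chr, prob, water, kin), "rectangular")
})

test_that("integrated pressure over the plunger reproduces the force formula", {
  prob <- proboscis_geometry(l_p = 8e-3, d_p = 80e-6)
  for (cfg in list(list(shape = "circular", theta = 0.3),
                   list(shape = "rectangular", aspect = 1, g = 0.1))) {
    res <- do.call(cached_solve, cfg)
    li <- 300e-6
    ch <- if (cfg$shape == "circular")
      chamber_geometry("circular", R = li, theta = cfg$theta)
    else
      chamber_geometry("rectangular", L = li, W = li * cfg$aspect,
                       opening = li * cfg$g)
    kin <- plunger_kinematics(h = 90e-6, dhdt = 1.3e-3)
    asm <- assemble_pressure(res$field, ch, prob, kin$h)
    p <- dimensional_pressure(asm, water, kin)
    areas <- tri_areas(res$mesh) * li^2
    pmean <- (p$values[res$mesh$tri[, 1]] + p$values[res$mesh$tri[, 2]] +
              p$values[res$mesh$tri[, 3]]) / 3
    Fquad <- sum(areas * pmean)
    Fform <- plunger_force(shape_constant(res$field), ch, prob, water,
                           kin)$total
    expect_equal(Fquad, Fform, tolerance = 0.01)
  }
})

test_that("impulse-height relation equals -int F dt on any path", {
  prob <- proboscis_geometry(l_p = 8e-3, d_p = 80e-6)
  res <- cached_solve("circular", theta = 0.3)
  C <- shape_constant(res$field)
  li <- 300e-6
  ch <- chamber_geometry("circular", R = li, theta = 0.3)
  h0 <- 60e-6; h1 <- 150e-6
  H0 <- h0 / prob$d_p; H1 <- h1 / prob$d_p
  paths <- list(function(t) h0 + (h1 - h0) * t,
                function(t) h0 + (h1 - h0) * t^2,
                function(t) h0 + (h1 - h0) * (1 - cos(pi * t)) / 2)
  Pi_rel <- impulse_height_relation(H1, H0, C, ch, prob)
  for (path in paths) {
    tt <- seq(0, 1, length.out = 20001)
    h <- path(tt)
    dh <- diff(h)
    hm <- (h[-1] + h[-length(h)]) / 2
    # -int F dt = -int (F / (dh/dt)) dh, and F/(dh/dt) depends on h only
    Fover <- vapply(hm, function(hh)
      plunger_force(C, ch, prob, water,
                    plunger_kinematics(h = hh, dhdt = 1))$total, 0)
    Pi_dim <- -sum(Fover * dh)
    Pi_norm <- Pi_dim * prob$d_p^2 / (6 * water$eta * li^4)
    expect_equal(Pi_norm, Pi_rel, tolerance = 1e-3)
  }
  # endpoints only: H = H0 gives zero
  expect_equal(impulse_height_relation(H0, H0, C, ch, prob), 0)
})

test_that("height_from_impulse inverts the relation", {
  prob <- proboscis_geometry(l_p = 8e-3, d_p = 80e-6)
  res <- cached_solve("rectangular", aspect = 0.8, g = 0.2)
  C <- shape_constant(res$field)
  ch <- chamber_geometry("rectangular", L = 400e-6, W = 320e-6,
                         opening = 80e-6)
  H0 <- 0.6
  Hs <- c(0.8, 1.5, 3, 7)
  Pis <- impulse_height_relation(Hs, H0, C, ch, prob)
  expect_true(all(diff(Pis) > 0))     # strictly increasing relation
  back <- vapply(Pis, height_from_impulse, 0, H0 = H0, C = C,
                 chamber = ch, proboscis = prob)
  expect_equal(back, Hs, tolerance = 1e-8)
  expect_equal(height_from_impulse(0, H0, C, ch, prob), H0)
  # output increases with impulse
  expect_true(all(diff(back) > 0))
  expect_error(height_from_impulse(1e9, H0, C, ch, prob, H_max = 10),
               "bracket")
})
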