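test_that("f-factor follows its definition and limits", {
  prob <- proboscis_geometry(10.1e-3, 494.6e-6)
  expect_equal(f_factor(prob, 765.9e-6),
               10.1e-3 * (765.9e-6)^3 / (494.6e-6)^4, tolerance = 1e-12)
  expect_equal(f_factor(proboscis_geometry(0, 1e-4), 1e-4), 0)
  # unit invariance: micrometre inputs give the same dimensionless value
  expect_equal(f_factor(proboscis_geometry(10.1e3, 494.6), 765.9),
               f_factor(prob, 765.9e-6), tolerance = 1e-12)
})

test_that("boundary f-values match the closed-form constants", {
  # all-open disk: C_c = 0 so f_c = (3/(32 pi)) * pi/8 = 3/256
  Cc <- structure(list(shape = "circular", parameters = list(theta = pi),
                       C = 0, converged = TRUE), class = "shape_constants")
  expect_equal(boundary_f(Cc), 3 / 256, tolerance = 1e-12)
  # full-opening square: C_r = -1/4 so f_r = pi/32
  Cr <- structure(list(shape = "rectangular",
                       parameters = list(aspect = 1, g = 1),
                       C = -1 / 4, converged = TRUE),
                  class = "shape_constants")
  expect_equal(boundary_f(Cr), pi / 32, tolerance = 1e-12)
  # narrow circular opening, via the published empirical fit for C_c
  Cfit <- structure(list(shape = "circular", parameters = list(theta = 0.2),
                         C = 3.1 * log(0.2) - 2.25, converged = TRUE),
                    class = "shape_constants")
  expect_equal(boundary_f(Cfit), 0.23, tolerance = 0.02)
})

test_that("boundary curves decrease with opening size and stay positive", {
  sw <- cc_sweep(c(0.1, 0.4, 1.0, 2.0), tol = 0.01)
  expect_true(all(diff(sw$C) > 0))           # C_c increases toward zero
  fb <- (3 / (32 * pi)) * (pi / 8 - sw$C)
  expect_true(all(fb > 0))
  expect_true(all(diff(fb) < 0))             # f_c strictly decreasing
  swr <- cr_sweep(c(0.1, 0.3, 0.8), aspect = 1, tol = 0.01)
  expect_true(all(diff(swr$C) > 0))
  fbr <- (3 * pi / 32) * (1 / 12 - swr$C)
  expect_true(all(diff(fbr) < 0))
})

test_that("dissipation ratio exceeds one and handles the separated limit", {
  d <- dissipation_ratio(75.8, 0.23)
  expect_equal(d$Ec_over_Ep, 0.23 / 75.8, tolerance = 1e-12)
  expect_equal(d$total_over_Ep, 1 + 0.23 / 75.8, tolerance = 1e-12)
  expect_gt(d$total_over_Ep, 1)
  # f = 0: pump-limited extreme reported as infinite ratio, not an error
  d0 <- dissipation_ratio(0, 0.23)
  expect_identical(d0$Ec_over_Ep, Inf)
  # consistency with the direct evaluation of the dissipation split:
  # Ec/Ep = (3 pi d_p^4 / (32 l_p h^3)) (L/W)^2 [W/(12L) - C_r]
  lp <- 8e-3; dp <- 90e-6; h <- 2e-4; L <- 5e-4; W <- 4e-4; Cr <- -0.8
  f <- lp * h^3 / dp^4
  fb <- (3 * pi / 32) * (L / W)^2 * (W / (12 * L) - Cr)
  direct <- (3 * pi * dp^4 / (32 * lp * h^3)) * (L / W)^2 *
    (W / (12 * L) - Cr)
  expect_equal(dissipation_ratio(f, fb)$Ec_over_Ep, direct,
               tolerance = 1e-12)
})

test_that("B-factor reproduces the honey/nectar capacity comparison", {
  atr <- atropos_record()
  sex <- sexta_record()
  B_atr <- b_factor(atr$proboscis, chamber_from_record(atr))
  B_sex <- b_factor(sex$proboscis, chamber_from_record(sex))
  expect_equal(B_atr, 0.17e3, tolerance = 0.03)
  expect_equal(B_sex, 765e3, tolerance = 0.03)
  # about four orders of magnitude apart: the viscosity-capacity ratio
  expect_equal(round(log10(B_atr / B_sex)), -4)
  expect_equal(proboscis_power(B_atr, 1e-3, 1e-3), B_atr * 1e-6 * 1e-3,
               tolerance = 1e-12)
})

test_that("empirical log fit validates its inputs", {
  th <- seq(0.1, 0.8, length.out = 6)
  Cv <- 3 * log(th) - 2 + c(1, -1, 1, -1, 1, -1) * 1e-6
  fit <- empirical_cc_fit(th, Cv)
  expect_equal(fit$slope, 3, tolerance = 1e-5)
  expect_equal(fit$intercept, -2, tolerance = 1e-5)
  expect_error(empirical_cc_fit(th[1:3], Cv[1:3]), "at least 5")
  expect_error(empirical_cc_fit(c(th, 2.5), c(Cv, -1)), "theta < 2")
  expect_error(empirical_cc_fit(th, Cv[-1]), "length")
})

test_that("small-opening fit slope approaches the point-sink value pi", {
  th <- seq(0.02, 0.1, length.out = 6)
  sw <- cc_sweep(th, tol = 0.004)
  fit <- empirical_cc_fit(th, sw$C)
  expect_equal(fit$slope, pi, tolerance = 0.03)
})

test_that("classification follows the three-step boundary comparison", {
  rec <- atropos_record()
  rep <- classify_species(rec)
  expect_s3_class(rep, "regime_report")
  expect_equal(rep$regime, "proboscis_limited")
  expect_gt(rep$f, rep$f_boundary)
  expect_equal(rep$Ec_over_Ep, rep$f_boundary / rep$f, tolerance = 1e-12)
  expect_gt(rep$total_over_Ep, 1)
  # separated galeae flip the regime
  rep0 <- classify_species(rec, l_p_override = 0)
  expect_equal(rep0$regime, "pump_limited")
  expect_equal(rep0$f, 0)
  # a species engineered to sit on the boundary is labelled boundary
  C <- shape_constant_for(chamber_from_record(rec), tol = 0.005)
  fb <- boundary_f(C)
  # choose l_p so that f = fb exactly at this record's h_max and d_p
  lp_tie <- fb * rec$proboscis$d_p^4 / rec$h_max^3
  tie <- classify_species(
    species_record(rec$name, proboscis_geometry(lp_tie, rec$proboscis$d_p),
                   L = rec$L, W = rec$W, h_max = rec$h_max))
  expect_equal(tie$regime, "boundary")
})

test_that("classification under both idealizations flags disagreement only when present", {
  rec <- atropos_record()
  both <- classify_species(rec, shape = "both")
  expect_named(both, c("rectangular", "circular"))
  expect_equal(both$rectangular$regime, both$circular$regime)
})

test_that("diagram data carries boundary curves and species points", {
  rec <- atropos_record()
  dat <- regime_diagram_data(list(rec), gs = c(0.1, 0.4),
                             aspects = 1, tol = 0.02)
  expect_setequal(unique(dat$curves$shape), c("rectangular", "circular"))
  expect_true(all(dat$curves$f_boundary > 0))
  # within each curve, larger openings give lower boundaries
  rectc <- dat$curves[dat$curves$shape == "rectangular", ]
  expect_true(all(diff(rectc$f_boundary[order(rectc$parameter)]) < 0))
  expect_equal(dat$points$species, "Acherontia atropos")
  expect_equal(dat$points$f, f_factor(rec$proboscis, rec$h_max),
               tolerance = 1e-12)
})
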