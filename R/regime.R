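## Classification of species into proboscis-limited vs pump-limited energy
## dissipation. The single dimensionless factor f = l_p h^3 / d_p^4 is
## compared against a geometry-dependent boundary value f_r(W/L, g) or
## f_c(theta): above the boundary, viscous losses in the food canal
## dominate; below it, Stefan losses in the pump chamber dominate.

#' Dissipation f-factor
#'
#' `f = l_p h^3 / d_p^4` (dimensionless; consistent SI units enforced by the
#' constructors). `l_p = 0` (separated galeae) legitimately yields `f = 0`.
#'
#' @param proboscis A [proboscis_geometry()] object.
#' @param h Gap height (m), typically the maximum pump expansion `h_max`.
#' @return Dimensionless f-factor.
#' @export
#' @examples
#' f_factor(proboscis_geometry(10.1e-3, 494.6e-6), 765.9e-6)  # ~ 75.8
f_factor <- function(proboscis, h) {
  stopifnot(inherits(proboscis, "proboscis"), h >= 0)
  proboscis$l_p * h^3 / proboscis$d_p^4
}

#' Boundary f-value separating the dissipation regimes
#'
#' `f_r(W/L, g) = (3 pi / 32) (L/W)^2 [W/(12L) - C_r]` for rectangular
#' chambers and `f_c(theta) = (3/(32 pi)) [pi/8 - C_c]` for circular ones;
#' strictly positive because the shape constants are non-positive.
#'
#' @param C A `"shape_constants"` object (carries shape and parameters).
#' @return The boundary f-value (dimensionless).
#' @export
boundary_f <- function(C) {
  stopifnot(inherits(C, "shape_constants"))
  if (C$shape == "rectangular") {
    w <- C$parameters$aspect
    (3 * pi / 32) * (1 / w)^2 * (w / 12 - C$C)
  } else {
    (3 / (32 * pi)) * (pi / 8 - C$C)
  }
}

#' Relative energy dissipation split
#'
#' With reference to the proboscis losses, the chamber adds
#' `Ec/Ep = f_boundary / f`, so total relative dissipation is
#' `1 + f_boundary / f > 1` for any finite f. `f = 0` returns the
#' pump-limited extreme `Inf` rather than an error.
#'
#' @param f The species' f-factor.
#' @param f_boundary The geometry's boundary f-value.
#' @return List with `Ec_over_Ep` and `total_over_Ep`.
#' @export
dissipation_ratio <- function(f, f_boundary) {
  stopifnot(f >= 0, f_boundary > 0)
  r <- if (f == 0) Inf else f_boundary / f
  list(Ec_over_Ep = r, total_over_Ep = 1 + r)
}

#' Geometric B-factor of the proboscis-pump pair
#'
#' `B = 128 l_p A^2 / (pi d_p^4)` (units m): the purely geometric constant
#' such that the proboscis dissipation power is `B (dh/dt)^2 eta`. Species
#' that feed on fluids of very different viscosity can share pump anatomy
#' when their B-factors compensate (`B_1 eta_1 ~ B_2 eta_2`).
#'
#' @param proboscis A [proboscis_geometry()] object.
#' @param chamber A [chamber_geometry()] object (supplies the area A).
#' @return B in metres.
#' @export
b_factor <- function(proboscis, chamber) {
  stopifnot(inherits(proboscis, "proboscis"), inherits(chamber, "chamber"))
  128 * proboscis$l_p * chamber$area^2 / (pi * proboscis$d_p^4)
}

#' Proboscis dissipation power
#'
#' `Edot_p = B (dh/dt)^2 eta` (W).
#'
#' @param B Geometric B-factor (m), from [b_factor()].
#' @param dhdt Plunger expansion rate (m/s).
#' @param eta Dynamic viscosity (Pa s).
#' @return Power (W).
#' @export
proboscis_power <- function(B, dhdt, eta) B * dhdt^2 * eta

#' Least-squares fit of the circular shape constant against log opening
#'
#' Ordinary least squares of `C_c = a ln(theta) + b` over a sweep of
#' computed shape constants. The logarithmic form reflects the point-sink
#' asymptotics of the opening (slope tends to pi as theta -> 0); it is only
#' a sensible description for theta well below 2, where the fitted line
#' would cross zero while the true constant stays negative.
#'
#' @param theta_grid Opening half-angles (rad), at least 5, all `< 2`.
#' @param C_values Computed `C_c` values, same length.
#' @return List with `slope`, `intercept`, `n` and the residual standard
#'   error.
#' @export
empirical_cc_fit <- function(theta_grid, C_values) {
  if (length(theta_grid) != length(C_values))
    stop("theta_grid and C_values differ in length")
  if (length(theta_grid) < 5L)
    stop("need at least 5 points to fit 2 parameters robustly")
  if (any(theta_grid >= 2))
    stop("fit restricted to theta < 2 (the log fit is invalid beyond)")
  fit <- stats::lm(C_values ~ log(theta_grid))
  co <- stats::coef(fit)
  list(slope = unname(co[2L]), intercept = unname(co[1L]),
       n = length(theta_grid),
       sigma = summary(fit)$sigma)
}

#' Sweep the circular shape constant over opening half-angles
#'
#' Solves the circular chamber problem for each `theta` and returns the
#' sweep table (the data behind the shape-constant/opening-size curve).
#'
#' @param thetas Opening half-angles (rad).
#' @param tol,max_refinements,... Passed to [refine_until_converged()].
#' @return Data frame with `shape`, `parameter` (theta), `aspect` (NA), `C`,
#'   `refinements`, `rel_change`.
#' @export
cc_sweep <- function(thetas = seq(0.05, 0.8, length.out = 20L),
                     tol = 0.005, max_refinements = 30L, ...) {
  rows <- lapply(thetas, function(th) {
    res <- refine_until_converged(
      chamber_geometry("circular", R = 1, theta = th),
      tol = tol, max_refinements = max_refinements, ...)
    data.frame(shape = "circular", parameter = th, aspect = NA_real_,
               C = res$constant,
               refinements = res$convergence$refinement_count,
               rel_change = res$convergence$final_rel_change)
  })
  do.call(rbind, rows)
}

#' Sweep the rectangular shape constant over opening fractions
#'
#' @param gs Opening fractions `g = |AB|/L` (clamped at `W/L`).
#' @param aspect Chamber aspect ratio `W/L`.
#' @param tol,max_refinements,... Passed to [refine_until_converged()].
#' @return Data frame with the same columns as [cc_sweep()].
#' @export
cr_sweep <- function(gs, aspect = 1, tol = 0.005, max_refinements = 30L,
                     ...) {
  rows <- lapply(gs, function(g) {
    res <- refine_until_converged(
      chamber_geometry("rectangular", L = 1, W = aspect,
                       opening = min(g, aspect)),
      tol = tol, max_refinements = max_refinements, ...)
    data.frame(shape = "rectangular", parameter = g, aspect = aspect,
               C = res$constant,
               refinements = res$convergence$refinement_count,
               rel_change = res$convergence$final_rel_change)
  })
  do.call(rbind, rows)
}

#' Classify a species' dissipation regime
#'
#' Runs the three-step procedure: derive the dimensionless chamber
#' parameters (`W/L` and `g`, or `theta`); solve the chamber problem for
#' the shape constant and the boundary value `f_r` / `f_c`; compare the
#' species' `f = l_p h_max^3 / d_p^4`. Species with `f` above the boundary
#' dissipate mostly in the proboscis; below it, mostly in the pump. Ties
#' within `tie_tol` (relative) are labelled `"boundary"`.
#'
#' @param record A [species_record()].
#' @param shape Chamber idealization to use; default the record's own. Use
#'   `"both"` to classify under both and flag disagreement.
#' @param tie_tol Relative width of the boundary band (default 1\%).
#' @param l_p_override Optional replacement for the record's proboscis
#'   length (e.g. `0` for behaviourally separated galeae). Records whose
#'   `galeae` state is `"separated"` default to `l_p = 0`: without a closed
#'   food canal, capillarity delivers fluid to the pump at negligible
#'   viscous cost.
#' @param beat_frequency Optional pump beat rate (1/s) for the Womersley
#'   screening entry of the report.
#' @param fluid Fluid for the Womersley number (default water-like).
#' @param tol,... Solver arguments for [refine_until_converged()].
#' @param cache Optional environment memoising shape constants across calls
#'   (keyed by shape and rounded geometry parameters).
#' @return A `"regime_report"` (or a list of two, for `shape = "both"`).
#' @export
classify_species <- function(record, shape = record$shape, tie_tol = 0.01,
                             l_p_override = NULL, beat_frequency = NA_real_,
                             fluid = fluid_properties(), tol = 0.005,
                             cache = NULL, ...) {
  stopifnot(inherits(record, "species_record"))
  if (identical(shape, "both")) {
    reps <- lapply(c("rectangular", "circular"), function(s)
      classify_species(record, shape = s, tie_tol = tie_tol,
                       l_p_override = l_p_override,
                       beat_frequency = beat_frequency, fluid = fluid,
                       tol = tol, cache = cache, ...))
    if (reps[[1L]]$regime != reps[[2L]]$regime)
      warning(sprintf(
        "%s: chamber idealizations disagree (rectangular: %s, circular: %s)",
        record$name, reps[[1L]]$regime, reps[[2L]]$regime))
    names(reps) <- c("rectangular", "circular")
    return(reps)
  }
  prob <- record$proboscis
  if (is.null(l_p_override) && identical(record$galeae, "separated"))
    l_p_override <- 0
  if (!is.null(l_p_override))
    prob <- proboscis_geometry(l_p_override, prob$d_p)
  chamber <- chamber_from_record(record, shape = shape)
  dimless <- derive_dimensionless(record)

  key <- if (shape == "rectangular")
    sprintf("rect_%.6g_%.6g", min(chamber$g, chamber$aspect), chamber$aspect)
  else sprintf("circ_%.6g", min(chamber$theta, pi))
  C <- if (!is.null(cache)) get0(key, envir = cache, inherits = FALSE)
  if (is.null(C)) {
    C <- shape_constant_for(chamber, tol = tol, ...)
    if (!is.null(cache)) assign(key, C, envir = cache)
  }
  fb <- boundary_f(C)
  f <- f_factor(prob, record$h_max)
  regime <- if (f > fb * (1 + tie_tol)) "proboscis_limited"
  else if (f < fb * (1 - tie_tol)) "pump_limited"
  else "boundary"
  ratio <- dissipation_ratio(f, fb)
  Wo <- if (is.na(beat_frequency)) NA_real_ else
    womersley(plunger_kinematics(h = record$h_max,
                                 beat_frequency = beat_frequency), fluid)
  structure(list(
    species = record$name, shape = shape, f = f,
    g = dimless$g, theta = dimless$theta, aspect = dimless$aspect,
    C = C$C, f_boundary = fb,
    Ec_over_Ep = ratio$Ec_over_Ep, total_over_Ep = ratio$total_over_Ep,
    regime = regime,
    B = b_factor(prob, chamber),
    K = compute_K(chamber, prob, record$h_max),
    Wo = Wo,
    l_p_used = prob$l_p,
    converged = C$converged),
    class = "regime_report")
}

#' @export
print.regime_report <- function(x, ...) {
  cat(sprintf("<regime_report> %s (%s chamber)\n", x$species, x$shape))
  cat(sprintf("  f = %.6g vs boundary %.4g -> %s\n", x$f, x$f_boundary,
              x$regime))
  cat(sprintf("  Ec/Ep = %.4g, B = %.4g m, K = %.4g\n",
              x$Ec_over_Ep, x$B, x$K))
  invisible(x)
}

#' Classify every record of a species table
#'
#' @param records List of [species_record()]s (e.g. from
#'   [read_species_csv()]).
#' @param ... Passed to [classify_species()]; a shared shape-constant cache
#'   is installed automatically.
#' @return List of `"regime_report"`s, named by species.
#' @export
classify_all <- function(records, ...) {
  cache <- new.env(parent = emptyenv())
  reps <- lapply(records, classify_species, cache = cache, ...)
  names(reps) <- vapply(reps, `[[`, "", "species")
  reps
}

#' Regime-diagram data: boundary curves and species points
#'
#' The data behind the classification diagram: boundary curves
#' `f_r(g)` for a set of aspect ratios, `f_c(theta)`, and one point per
#' species (its opening fraction and f-factor).
#'
#' @param records Optional list of [species_record()]s for the points.
#' @param gs Opening-fraction grid for the curves.
#' @param aspects Aspect ratios for the rectangular curves (the sweep used
#'   for the published diagram steps 0.5 ... 2 by 0.5).
#' @param tol,... Solver arguments.
#' @return List of data frames `curves` (shape, aspect, parameter, f_boundary)
#'   and `points` (species, g, f).
#' @export
regime_diagram_data <- function(records = NULL,
                                gs = exp(seq(log(0.02), log(1), length.out = 12L)),
                                aspects = c(0.5, 1, 1.5, 2),
                                tol = 0.005, ...) {
  curves <- list()
  for (w in aspects) {
    sw <- cr_sweep(gs[gs <= w], aspect = w, tol = tol, ...)
    fb <- vapply(seq_len(nrow(sw)), function(i) {
      boundary_f(structure(list(shape = "rectangular",
                                parameters = list(aspect = w,
                                                  g = sw$parameter[i]),
                                C = sw$C[i], converged = TRUE),
                           class = "shape_constants"))
    }, 0)
    curves[[length(curves) + 1L]] <-
      data.frame(shape = "rectangular", aspect = w, parameter = sw$parameter,
                 f_boundary = fb)
  }
  swc <- cc_sweep(gs[gs <= pi], tol = tol, ...)
  fbc <- (3 / (32 * pi)) * (pi / 8 - swc$C)
  curves[[length(curves) + 1L]] <-
    data.frame(shape = "circular", aspect = NA_real_,
               parameter = swc$parameter, f_boundary = fbc)
  points <- NULL
  if (!is.null(records)) {
    points <- do.call(rbind, lapply(records, function(r) {
      d <- derive_dimensionless(r)
      data.frame(species = r$name, g = d$g,
                 f = f_factor(r$proboscis, r$h_max))
    }))
  }
  list(curves = do.call(rbind, curves), points = points)
}
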