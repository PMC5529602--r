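#' Proboscis food-canal geometry
#'
#' The food canal is modelled as a straight cylindrical tube of length `l_p`
#' and diameter `d_p`. All lengths are SI metres. `l_p = 0` is the legitimate
#' "separated galeae" limit in which the canal offers no viscous resistance.
#'
#' @param l_p Food-canal length (m), `>= 0`.
#' @param d_p Food-canal diameter (m), `> 0`.
#' @return An object of class `"proboscis"`.
#' @export
#' @examples
#' proboscis_geometry(l_p = 10.1e-3, d_p = 494.6e-6)
proboscis_geometry <- function(l_p, d_p) {
  stopifnot(is.numeric(l_p), length(l_p) == 1L, is.finite(l_p),
            is.numeric(d_p), length(d_p) == 1L, is.finite(d_p))
  if (d_p <= 0) stop("d_p must be strictly positive")
  if (l_p < 0) stop("l_p must be non-negative (0 = separated galeae)")
  structure(list(l_p = as.numeric(l_p), d_p = as.numeric(d_p)),
            class = "proboscis")
}

#' Pump chamber footprint geometry
#'
#' The pump chamber floor is either a rectangle of length `L` (the axis that
#' carries the opening toward the food canal) and width `W`, or a disk of
#' radius `R`. The opening `AB` where the chamber meets the food canal has
#' physical width `opening` (usually identified with the food-canal diameter
#' `d_p`). All lengths in metres.
#'
#' Derived dimensionless parameters: `g = opening / L`, the arc half-angle
#' `theta = opening / (2 R)` (chord-ratio identification), and the aspect
#' ratio `W / L`.
#'
#' @param shape `"rectangular"` or `"circular"`.
#' @param L Chamber length (m). For circular chambers the default radius is
#'   `R = L / 2` (chamber length = diameter) unless `R` is given.
#' @param W Chamber width (m); required for rectangular chambers.
#' @param R Chamber radius (m); circular chambers only.
#' @param opening Width of the opening `|AB|` (m).
#' @param theta Circular chambers only: arc half-angle of the opening in
#'   radians, in `(0, pi]`. When supplied it overrides `opening` (which is
#'   then taken as `2 R theta`); this is how wide-opening configurations up
#'   to the all-open disk `theta = pi` are expressed, while morphometric
#'   records use the small-angle chord identification `theta = d_p / (2 R)`.
#' @return An object of class `"chamber"` with fields `shape`, `L`, `W`, `R`,
#'   `opening`, and derived `g`, `theta`, `aspect`, `area`.
#' @export
#' @examples
#' chamber_geometry("rectangular", L = 2417.6e-6, W = 2030.3e-6,
#'                  opening = 494.6e-6)
#' chamber_geometry("circular", R = 1, theta = pi / 5)
chamber_geometry <- function(shape = c("rectangular", "circular"),
                             L = NULL, W = NULL, R = NULL, opening = NULL,
                             theta = NULL) {
  shape <- match.arg(shape)
  if (shape == "circular" && !is.null(theta)) {
    stopifnot(is.numeric(theta), length(theta) == 1L, theta > 0)
    if (theta > pi * (1 + 1e-12))
      stop("theta must lie in (0, pi]")
    if (is.null(R)) {
      if (is.null(L)) stop("circular chamber needs R (or L with R = L/2)")
      R <- L / 2
    }
    opening <- 2 * R * theta
  }
  if (is.null(opening)) stop("opening (or theta, circular) is required")
  stopifnot(is.numeric(opening), length(opening) == 1L, opening > 0)
  if (shape == "rectangular") {
    if (is.null(L) || is.null(W)) stop("rectangular chamber needs L and W")
    stopifnot(L > 0, W > 0)
    if (opening > W * (1 + 1e-12))
      stop(sprintf(paste0("invalid opening: opening (= %g m) exceeds pump ",
                          "width W (= %g m)"), opening, W))
    out <- list(shape = shape, L = as.numeric(L), W = as.numeric(W),
                R = NA_real_, opening = as.numeric(opening))
    out$g <- out$opening / out$L
    out$theta <- NA_real_
    out$aspect <- out$W / out$L
    out$area <- out$L * out$W
  } else {
    if (is.null(R)) {
      if (is.null(L)) stop("circular chamber needs R (or L with R = L/2)")
      R <- L / 2
    }
    stopifnot(R > 0)
    if (is.null(L)) L <- 2 * R
    if (is.null(theta) && opening > 2 * R * (1 + 1e-12))
      stop(sprintf(paste0("invalid opening: opening (= %g m) exceeds pump ",
                          "diameter 2R (= %g m)"), opening, 2 * R))
    out <- list(shape = shape, L = as.numeric(L), W = NA_real_,
                R = as.numeric(R), opening = as.numeric(opening))
    out$g <- out$opening / out$L
    out$theta <- if (is.null(theta)) out$opening / (2 * out$R) else
      as.numeric(theta)
    out$aspect <- NA_real_
    out$area <- pi * out$R^2
  }
  structure(out, class = "chamber")
}

#' Working-fluid properties
#'
#' @param eta Dynamic viscosity (Pa s), `> 0`.
#' @param rho Density (kg/m^3), `> 0`.
#' @return An object of class `"fluid"`.
#' @export
fluid_properties <- function(eta = 1e-3, rho = 1000) {
  stopifnot(is.numeric(eta), eta > 0, is.numeric(rho), rho > 0)
  structure(list(eta = as.numeric(eta), rho = as.numeric(rho)),
            class = "fluid")
}

#' Plunger kinematics
#'
#' State of the moving pump roof: current gap height `h`, expansion rate
#' `dhdt` (positive during the uptake stroke), initial height `h0` and the
#' pump beat frequency used in the Womersley screening.
#'
#' @param h Gap height (m), `> 0`.
#' @param dhdt Expansion rate (m/s); positive = uptake stroke.
#' @param h0 Initial gap height (m), `> 0`; defaults to `h`.
#' @param beat_frequency Pump beat rate (1/s), `>= 0`.
#' @return An object of class `"kinematics"`.
#' @export
plunger_kinematics <- function(h, dhdt = 0, h0 = h, beat_frequency = 0) {
  stopifnot(is.numeric(h), h > 0, is.numeric(h0), h0 > 0,
            is.numeric(dhdt), is.finite(dhdt),
            is.numeric(beat_frequency), beat_frequency >= 0)
  structure(list(h = as.numeric(h), dhdt = as.numeric(dhdt),
                 h0 = as.numeric(h0),
                 beat_frequency = as.numeric(beat_frequency)),
            class = "kinematics")
}

#' One species' morphometric record
#'
#' Bundles the proboscis and pump measurements of one organism. Internal
#' units are SI metres; see [read_species_csv()] for the tabular conventions
#' (mm for proboscis length, micrometres for pump dimensions).
#'
#' @param name Species name.
#' @param proboscis A [proboscis_geometry()] object.
#' @param L,W,h_max Pump length, width and greatest mid-sagittal height (m).
#' @param shape Chamber idealization: `"rectangular"` (default; uses both
#'   measured L and W) or `"circular"` (radius `R`, default `L/2`).
#' @param R Optional circular radius override (m).
#' @param galeae `"linked"` (default: the galeae enclose a food canal of
#'   diameter `d_p`) or `"separated"` (no closed canal; capillarity fills
#'   the intergaleal gap, so the canal contributes no viscous resistance
#'   and the effective `l_p` for dissipation is zero).
#' @param provenance Free-text provenance note.
#' @return An object of class `"species_record"`.
#' @export
species_record <- function(name, proboscis, L, W, h_max,
                           shape = c("rectangular", "circular"),
                           R = NULL, galeae = c("linked", "separated"),
                           provenance = "") {
  shape <- match.arg(shape)
  galeae <- match.arg(galeae)
  stopifnot(inherits(proboscis, "proboscis"),
            is.numeric(L), L > 0, is.numeric(W), W > 0,
            is.numeric(h_max), h_max > 0)
  structure(list(name = as.character(name), proboscis = proboscis,
                 L = as.numeric(L), W = as.numeric(W),
                 h_max = as.numeric(h_max), shape = shape,
                 R = if (is.null(R)) NA_real_ else as.numeric(R),
                 galeae = galeae,
                 provenance = as.character(provenance)),
            class = "species_record")
}

#' @export
print.species_record <- function(x, ...) {
  cat(sprintf("<species_record> %s [%s chamber]\n", x$name, x$shape))
  cat(sprintf("  proboscis: l_p = %.4g mm, d_p = %.4g um\n",
              x$proboscis$l_p * 1e3, x$proboscis$d_p * 1e6))
  cat(sprintf("  pump: L = %.4g um, W = %.4g um, h_max = %.4g um\n",
              x$L * 1e6, x$W * 1e6, x$h_max * 1e6))
  invisible(x)
}

#' Chamber geometry implied by a species record
#'
#' @param record A [species_record()].
#' @param shape Chamber shape; defaults to the record's own.
#' @param canals Number of galeal food canals forming the opening; the
#'   opening width is `canals * d_p`. Species with unlinked galeae carry two
#'   separate canals, so their effective opening is twice the single-canal
#'   diameter.
#' @return A [chamber_geometry()] object.
#' @export
chamber_from_record <- function(record, shape = record$shape, canals = 1L) {
  stopifnot(inherits(record, "species_record"), canals >= 1L)
  opening <- canals * record$proboscis$d_p
  if (shape == "rectangular") {
    chamber_geometry("rectangular", L = record$L, W = record$W,
                     opening = opening)
  } else {
    R <- if (is.na(record$R)) record$L / 2 else record$R
    chamber_geometry("circular", L = record$L, R = R, opening = opening)
  }
}

#' Dimensionless geometry of a species record
#'
#' Derives the opening fraction `g = d_p / L`, the circular arc half-angle
#' `theta = d_p / (2 R)` (with the default radius convention `R = L / 2`,
#' making `g` and `theta` numerically equal), the chamber aspect ratio
#' `W / L`, and the footprint areas for both chamber idealizations.
#'
#' @inheritParams chamber_from_record
#' @return A list with `g`, `theta`, `aspect`, `area_rectangular`,
#'   `area_circular`, and the opening width used.
#' @export
#' @examples
#' atropos <- species_record("Acherontia atropos",
#'   proboscis_geometry(10.1e-3, 494.6e-6),
#'   L = 2417.6e-6, W = 2030.3e-6, h_max = 765.9e-6)
#' derive_dimensionless(atropos)$g  # ~ 0.20
derive_dimensionless <- function(record, canals = 1L) {
  stopifnot(inherits(record, "species_record"))
  opening <- canals * record$proboscis$d_p
  R <- if (is.na(record$R)) record$L / 2 else record$R
  if (opening > record$W * (1 + 1e-12))
    stop(sprintf(paste0("invalid opening: food canal (opening = %g m) wider ",
                        "than pump_width W = %g m"), opening, record$W))
  if (opening > 2 * R * (1 + 1e-12))
    stop(sprintf(paste0("invalid opening: food canal (opening = %g m) wider ",
                        "than pump diameter 2R = %g m"), opening, 2 * R))
  list(g = opening / record$L,
       theta = opening / (2 * R),
       aspect = record$W / record$L,
       area_rectangular = record$L * record$W,
       area_circular = pi * R^2,
       opening = opening)
}

#' Womersley number of the pump stroke
#'
#' `Wo = h * sqrt(2 * pi * f * rho / eta)` with `f` the pump beat frequency.
#' `Wo < 1` is the quasi-steady validity flag for the lubrication model: at
#' small Womersley number, flow unsteadiness is negligible and the pressure
#' field follows the instantaneous plunger velocity.
#'
#' @param kin A [plunger_kinematics()] object.
#' @param fluid A [fluid_properties()] object.
#' @return Dimensionless Womersley number.
#' @export
#' @examples
#' womersley(plunger_kinematics(h = 0.16e-3, beat_frequency = 3),
#'           fluid_properties())  # ~ 0.69
womersley <- function(kin, fluid) {
  stopifnot(inherits(kin, "kinematics"), inherits(fluid, "fluid"))
  kin$h * sqrt(2 * pi * kin$beat_frequency * fluid$rho / fluid$eta)
}

#' In-plane velocity scale and flow anisotropy
#'
#' Order-of-magnitude screening for the Hele-Shaw (thin-gap) reduction: the
#' mean in-plane speed at discharge `Q` is `Q / (W h)`, and the ratio of
#' in-plane to trans-plane velocities scales as `L / h`.
#'
#' @param Q Volumetric discharge (m^3/s).
#' @param chamber A [chamber_geometry()] object.
#' @param h Current gap height (m), `> 0`.
#' @return List with `v_inplane` (m/s) and `anisotropy` (`L/h`).
#' @export
velocity_scales <- function(Q, chamber, h) {
  stopifnot(inherits(chamber, "chamber"), is.numeric(h))
  if (h <= 0) stop("h must be strictly positive")
  width <- if (chamber$shape == "rectangular") chamber$W else 2 * chamber$R
  if (width <= 0) stop("chamber width must be strictly positive")
  list(v_inplane = Q / (width * h), anisotropy = chamber$L / h)
}

#' Crossover gap height between dissipation regimes
#'
#' The gap scale `h* = d_p * (d_p / l_p)^(1/3)` at which the f-factor
#' `l_p h^3 / d_p^4` is of order one, i.e. proboscis and pump dissipation
#' are comparable for any chamber geometry.
#'
#' @param proboscis A [proboscis_geometry()] object with `l_p > 0`.
#' @return Crossover height (m).
#' @export
crossover_height <- function(proboscis) {
  stopifnot(inherits(proboscis, "proboscis"))
  if (proboscis$l_p <= 0)
    stop("crossover height is undefined for l_p = 0 (separated galeae)")
  proboscis$d_p * (proboscis$d_p / proboscis$l_p)^(1 / 3)
}
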