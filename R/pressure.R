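## Assembly of the chamber pressure field and the proboscis coupling.
##
## The dimensionless chamber pressure is the superposition
##   P = P_squeeze + P~ + K,
## where P_squeeze is the particular (volumetric squeezing) solution,
## P~ the harmonic correction solved by solve_mixed_laplace(), and K the
## uniform coupling pressure imposed at the opening by Hagen-Poiseuille
## flow in the food canal. Dimensional pressure follows from the scale
## 12 eta l_i^2 / h^3 * dh/dt with yardstick l_r = L or l_c = R.

#' Squeeze-film part of the dimensionless chamber pressure
#'
#' The particular solution of the chamber Poisson problem driven by plunger
#' motion: `X^2/2 - 1/8` for rectangular chambers, `r^2/4 - 1/4` for
#' circular ones (dimensionless coordinates; the coupling constant K is
#' added at assembly, not here). Both vanish on the chamber rim `X = +-1/2`
#' / `r = 1`.
#'
#' @param chamber A [chamber_geometry()] object (provides shape and the
#'   domain bounds for validation).
#' @param coords Matrix (n x 2) of dimensionless coordinates.
#' @return Numeric vector of squeeze-pressure values.
#' @export
squeeze_pressure <- function(chamber, coords) {
  coords <- rbind(coords)
  tol <- 1e-9
  if (chamber$shape == "rectangular") {
    w <- chamber$aspect
    if (any(abs(coords[, 1L]) > 0.5 + tol) ||
        any(abs(coords[, 2L]) > w / 2 + tol))
      stop("coordinates outside the dimensionless chamber domain")
    coords[, 1L]^2 / 2 - 1 / 8
  } else {
    r2 <- rowSums(coords^2)
    if (any(r2 > 1 + tol))
      stop("coordinates outside the dimensionless chamber domain")
    r2 / 4 - 1 / 4
  }
}

#' Dimensionless coupling pressure K at the opening
#'
#' The uniform dimensionless pressure the Hagen-Poiseuille food-canal
#' resistance imposes on the chamber opening:
#' `K_i = -32 h^3 l_p A_i / (3 l_i^2 pi d_p^4)` with yardstick/area pairs
#' `(l_r, A_r) = (L, L W)` and `(l_c, A_c) = (R, pi R^2)`. For circular
#' chambers the geometry cancels and `K_c = -(32/3) f` with the dissipation
#' f-factor `f = l_p h^3 / d_p^4`; for rectangular chambers
#' `K_r = -(32/(3 pi)) f (W/L)`. Non-positive by construction.
#'
#' @param chamber A [chamber_geometry()] object.
#' @param proboscis A [proboscis_geometry()] object.
#' @param h Gap height (m), `> 0` (the value `h = 0` gives K = 0).
#' @return Dimensionless K (\eqn{\le 0}).
#' @export
compute_K <- function(chamber, proboscis, h) {
  stopifnot(inherits(chamber, "chamber"), inherits(proboscis, "proboscis"))
  if (h < 0) stop("h must be non-negative")
  li <- .yardstick(chamber)
  -32 * h^3 * proboscis$l_p * chamber$area /
    (3 * li^2 * pi * proboscis$d_p^4)
}

.yardstick <- function(chamber) {
  if (chamber$shape == "rectangular") chamber$L else chamber$R
}

#' Assemble the total dimensionless chamber pressure
#'
#' Adds the squeeze solution, the harmonic correction and the coupling
#' constant K nodewise: `P = P_squeeze + P~ + K`. On the opening `P = K`
#' exactly (the correction vanishes there by construction).
#'
#' @param ptilde A `"scalar_field"` with the solved correction pressure on a
#'   mesh matching `chamber`'s dimensionless parameters.
#' @param chamber,proboscis,h Geometry and gap height used for K.
#' @return A `"pressure_assembly"`: `field` (total dimensionless P),
#'   `ptilde`, `K`, `yardstick` (m), plus the geometry actually used.
#' @export
assemble_pressure <- function(ptilde, chamber, proboscis, h) {
  stopifnot(inherits(ptilde, "scalar_field"))
  mesh <- ptilde$mesh
  if (mesh$shape != chamber$shape)
    stop("geometry/field mismatch: mesh shape ", mesh$shape,
         " vs chamber shape ", chamber$shape)
  if (mesh$shape == "rectangular") {
    if (abs(mesh$params$g - min(chamber$g, chamber$aspect)) > 1e-9 ||
        abs(mesh$params$aspect - chamber$aspect) > 1e-9)
      stop("geometry/field mismatch: mesh (g, W/L) differ from chamber")
  } else {
    if (abs(mesh$params$theta - min(chamber$theta, pi)) > 1e-9)
      stop("geometry/field mismatch: mesh theta differs from chamber")
  }
  K <- compute_K(chamber, proboscis, h)
  tot <- squeeze_pressure(chamber, mesh$nodes) + ptilde$values + K
  structure(list(
    field = structure(list(mesh = mesh, values = tot),
                      class = "scalar_field"),
    ptilde = ptilde, K = K, chamber = chamber, proboscis = proboscis,
    h = h, yardstick = .yardstick(chamber)),
    class = "pressure_assembly")
}

#' @export
print.pressure_assembly <- function(x, ...) {
  cat(sprintf("<pressure_assembly> %s chamber, K = %.6g, h = %.4g m\n",
              x$chamber$shape, x$K, x$h))
  invisible(x)
}

#' Dimensional pressure field (Pa)
#'
#' Scales the dimensionless assembly by `12 eta l_i^2 / h^3 * dh/dt`.
#' During the uptake stroke (`dh/dt > 0`) every nodal pressure is
#' non-positive: the whole chamber is under suction relative to atmosphere.
#'
#' @param assembly A [assemble_pressure()] result.
#' @param fluid A [fluid_properties()] object.
#' @param kin A [plunger_kinematics()] object; its `h` must equal the
#'   assembly's `h` (K depends on it).
#' @return A `"scalar_field"` of pressures in Pa, with attributes `unit`,
#'   `scale` and `yardstick`.
#' @export
dimensional_pressure <- function(assembly, fluid, kin) {
  stopifnot(inherits(assembly, "pressure_assembly"),
            inherits(fluid, "fluid"), inherits(kin, "kinematics"))
  if (abs(kin$h - assembly$h) > 1e-12 * max(kin$h, assembly$h))
    stop("kinematics gap height differs from the assembly's h")
  scale <- 12 * fluid$eta * assembly$yardstick^2 / assembly$h^3 * kin$dhdt
  structure(list(mesh = assembly$field$mesh,
                 values = scale * assembly$field$values),
            class = "scalar_field",
            unit = "Pa", scale = scale, yardstick = assembly$yardstick)
}

#' Depth-averaged velocity field from a dimensional pressure field
#'
#' Lubrication closure: `(V_x, V_y) = -h^2/(12 eta) grad p`, evaluated per
#' triangle (piecewise-constant gradients; nodal exports use area-weighted
#' averages to avoid spurious extrema at the opening corners).
#'
#' @param p A dimensional `"scalar_field"` (Pa) from
#'   [dimensional_pressure()].
#' @param h Gap height (m), `> 0`.
#' @param fluid A [fluid_properties()] object.
#' @param yardstick Physical length (m) of one dimensionless mesh unit;
#'   defaults to the attribute carried by `p`.
#' @return Matrix (n_triangles x 2) of velocities (m/s).
#' @export
velocity_field <- function(p, h, fluid, yardstick = attr(p, "yardstick")) {
  stopifnot(inherits(p, "scalar_field"), h > 0)
  if (is.null(yardstick))
    stop("yardstick not supplied and not carried by the field")
  grad <- field_gradient(p) / yardstick
  -h^2 / (12 * fluid$eta) * grad
}

#' Hagen-Poiseuille discharge through the food canal
#'
#' `Q = pi d_p^4 P_p / (128 eta l_p)`; sign follows the driving pressure.
#'
#' @param P_p Pressure at the canal-chamber junction relative to atmosphere
#'   (Pa).
#' @param proboscis A [proboscis_geometry()] with `l_p > 0` (the separated-
#'   galeae limit bypasses the canal entirely).
#' @param fluid A [fluid_properties()] object.
#' @return Discharge (m^3/s).
#' @export
poiseuille_discharge <- function(P_p, proboscis, fluid) {
  stopifnot(inherits(proboscis, "proboscis"), inherits(fluid, "fluid"))
  if (proboscis$l_p <= 0)
    stop("l_p = 0: Poiseuille resistance undefined for separated galeae")
  pi * proboscis$d_p^4 * P_p / (128 * fluid$eta * proboscis$l_p)
}

#' Coupling pressure at the chamber opening
#'
#' Volume conservation ties the canal discharge to the chamber expansion
#' (`Q = -A dh/dt`), so the junction pressure is
#' `P_p = -A (128 eta l_p / (pi d_p^4)) dh/dt`: suction (negative) during
#' uptake, proportional to the expansion rate.
#'
#' @param chamber,proboscis,fluid,kin Model components.
#' @return Junction pressure (Pa).
#' @export
coupling_pressure <- function(chamber, proboscis, fluid, kin) {
  stopifnot(inherits(chamber, "chamber"), inherits(proboscis, "proboscis"),
            inherits(fluid, "fluid"), inherits(kin, "kinematics"))
  -chamber$area * 128 * fluid$eta * proboscis$l_p /
    (pi * proboscis$d_p^4) * kin$dhdt
}

#' Discharge through the opening from the discrete solution
#'
#' Evaluates the volumetric inflow through the opening AB from the solved
#' pressure assembly using the flux-consistent boundary residual of the
#' finite-element system (not raw gradient sampling): the discrete reaction
#' at the Dirichlet nodes recovers the boundary flux of the correction
#' pressure to the same order as the solution itself; the squeeze part's
#' opening flux is added in closed form. At a converged refinement the
#' result balances the volume swept by the plunger, `A dh/dt`, within the
#' discretization tolerance.
#'
#' @param assembly A [assemble_pressure()] result.
#' @param fluid A [fluid_properties()] object (enters the dimensional
#'   scaling and cancels, as conservation requires).
#' @param kin A [plunger_kinematics()] object.
#' @return Volumetric inflow through AB (m^3/s); sign follows `dh/dt`.
#' @export
opening_flux <- function(assembly, fluid, kin) {
  stopifnot(inherits(assembly, "pressure_assembly"),
            inherits(kin, "kinematics"))
  flux_pt <- attr(assembly$ptilde, "opening_flux")
  if (is.null(flux_pt))
    stop("assembly's correction field does not carry its boundary flux; ",
         "solve it with solve_mixed_laplace()")
  ch <- assembly$chamber
  flux_sq <- if (ch$shape == "rectangular") min(ch$g, ch$aspect) / 2 else
    min(ch$theta, pi)
  assembly$yardstick^2 * kin$dhdt * (flux_pt + flux_sq)
}

#' Area-weighted nodal velocities
#'
#' Averages the piecewise-constant triangle velocities onto nodes, weighting
#' by triangle area. This is the smoothing used for nodal exports: it avoids
#' the spurious extrema raw gradients show at the singular opening corners.
#'
#' @param v Matrix (n_triangles x 2) from [velocity_field()].
#' @param mesh The `"trimesh"` the velocities were computed on.
#' @return Matrix (n_nodes x 2) of nodal velocities (m/s).
#' @export
nodal_velocity <- function(v, mesh) {
  stopifnot(inherits(mesh, "trimesh"), nrow(v) == nrow(mesh$tri))
  areas <- abs(tri_areas(mesh))
  n <- nrow(mesh$nodes)
  out <- matrix(0, n, 2L)
  wgt <- numeric(n)
  for (a in 1:3) {
    idx <- mesh$tri[, a]
    for (d in 1:2) {
      tab <- tapply(areas * v[, d], idx, sum)
      ids <- as.integer(names(tab))
      out[ids, d] <- out[ids, d] + as.numeric(tab)
    }
    tab <- tapply(areas, idx, sum)
    ids <- as.integer(names(tab))
    wgt[ids] <- wgt[ids] + as.numeric(tab)
  }
  out / wgt
}
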