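## Plunger force, chamber shape constants, and impulse-height relations.
##
## The total force the fluid exerts on the plunger splits into a Stefan
## squeeze-film term (~ dh/dt / h^3, through the chamber shape constant)
## and a liquid-column term from the proboscis coupling. Because the force
## diverges as h -> 0 while its time integral stays finite, plunger
## position is governed by the impulse of muscular force, not the force.

#' Chamber shape constant from a solved correction field
#'
#' Integrates the correction pressure over the chamber footprint by
#' vertex-average quadrature (triangle area times the mean of its three
#' vertex values): `C_r` over the dimensionless rectangle, `C_c` over the
#' unit disk. The constant is negative for any partial opening and tends to
#' zero only in the all-open limit `theta = pi`.
#'
#' @param field A `"scalar_field"` with the solved correction pressure.
#' @param convergence Optional `"convergence_record"` from
#'   [refine_until_converged()]; a non-converged record flags (but does not
#'   suppress) the constant.
#' @return A `"shape_constants"` object: `shape`, `parameters`, `C`,
#'   `convergence`, `converged`.
#' @export
shape_constant <- function(field, convergence = NULL) {
  stopifnot(inherits(field, "scalar_field"))
  mesh <- field$mesh
  C <- .integrate_field(mesh, field$values)
  converged <- is.null(convergence) || isTRUE(convergence$converged)
  if (!converged)
    warning("shape constant computed from a non-converged field")
  structure(list(shape = mesh$shape, parameters = mesh$params, C = C,
                 convergence = convergence, converged = converged),
            class = "shape_constants")
}

#' Solve for the shape constant of a chamber geometry
#'
#' Convenience wrapper: adaptive solve via [refine_until_converged()]
#' followed by [shape_constant()].
#'
#' @param chamber A [chamber_geometry()] object.
#' @param tol,max_refinements,... Passed to [refine_until_converged()].
#' @return A `"shape_constants"` object.
#' @export
shape_constant_for <- function(chamber, tol = 0.005, max_refinements = 30L,
                               ...) {
  res <- refine_until_converged(chamber, tol = tol,
                                max_refinements = max_refinements, ...)
  shape_constant(res$field, res$convergence)
}

#' @export
print.shape_constants <- function(x, ...) {
  par <- paste(sprintf("%s = %.4g", names(x$parameters),
                       unlist(x$parameters)), collapse = ", ")
  cat(sprintf("<shape_constants> %s (%s): C = %.6g%s\n", x$shape, par, x$C,
              if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

.match_constant <- function(C, chamber) {
  stopifnot(inherits(C, "shape_constants"))
  if (C$shape != chamber$shape)
    stop("shape constant computed for a ", C$shape,
         " chamber, but a ", chamber$shape, " chamber was supplied")
  C$C
}

#' Total force on the pump plunger
#'
#' Force exerted by the fluid on the plunger during a stroke with gap `h`
#' and rate `dh/dt`:
#' \deqn{F_r = \frac{12\eta}{h^3}\dot h\, L^4\Big[C_r - \frac{W}{12L}\Big]
#'       - \dot h\,\frac{128\eta l_p}{\pi d_p^4}(LW)^2}
#' for rectangular chambers, and with \eqn{R^4 [C_c - \pi/8]} and column
#' coefficient \eqn{128\eta\pi l_p R^4 / d_p^4} for circular ones. The
#' first (Stefan squeeze-film) term scales as the inverse cube of the gap;
#' the second is the viscous drag of the liquid column in the food canal.
#' Both terms resist the motion, so the muscles must supply `-F`.
#'
#' @param C A `"shape_constants"` object matching the chamber shape.
#' @param chamber,proboscis,fluid,kin Model components; `kin$h > 0`.
#' @return A `"force_result"`: `total`, `stefan_term`, `column_term` (N).
#' @export
plunger_force <- function(C, chamber, proboscis, fluid, kin) {
  stopifnot(inherits(chamber, "chamber"), inherits(proboscis, "proboscis"),
            inherits(fluid, "fluid"), inherits(kin, "kinematics"))
  Cv <- .match_constant(C, chamber)
  eta <- fluid$eta; h <- kin$h; dhdt <- kin$dhdt
  lp <- proboscis$l_p; dp <- proboscis$d_p
  if (chamber$shape == "rectangular") {
    L <- chamber$L; W <- chamber$W
    stefan <- (12 * eta / h^3) * dhdt * L^4 * (Cv - W / (12 * L))
    column <- -dhdt * 128 * eta * lp / (pi * dp^4) * (L * W)^2
  } else {
    R <- chamber$R
    stefan <- (12 * eta / h^3) * dhdt * R^4 * (Cv - pi / 8)
    column <- -dhdt * 128 * eta * pi * lp / dp^4 * R^4
  }
  structure(list(total = stefan + column, stefan_term = stefan,
                 column_term = column),
            class = "force_result")
}

#' @export
print.force_result <- function(x, ...) {
  cat(sprintf("<force_result> F = %.6g N (Stefan %.6g N + column %.6g N)\n",
              x$total, x$stefan_term, x$column_term))
  invisible(x)
}

.impulse_terms <- function(C, chamber, proboscis) {
  Cv <- .match_constant(C, chamber)
  if (chamber$shape == "rectangular") {
    s <- chamber$W / (12 * chamber$L)
    col <- (64 / 3) * (proboscis$l_p / (pi * proboscis$d_p)) *
      chamber$aspect^2
  } else {
    s <- pi / 8
    col <- (64 / 3) * pi * proboscis$l_p / proboscis$d_p
  }
  list(Cs = Cv - s, col = col)
}

#' Normalized impulse of muscular force between two gap heights
#'
#' The impulse `Pi = -int F dt` needed to move the plunger from the
#' dimensionless height `H0 = h0/d_p` to `H = h/d_p` depends only on the
#' endpoints, not on the path `h(t)`. In the normalization
#' `Pi d_p^2 / (6 eta l_i^4)` (yardstick `l_i = L` or `R`):
#' \deqn{-\Big(C - s\Big)\Big(\frac{1}{H_0^2}-\frac{1}{H^2}\Big) +
#'       \frac{64}{3}\frac{l_p}{\pi d_p}\Big(\frac{W}{L}\Big)^2 (H - H_0)}
#' for rectangular chambers (`s = W/(12L)`), and with `s = pi/8` and column
#' coefficient `(64/3) pi l_p/d_p` for circular ones.
#'
#' @param H,H0 Dimensionless gap heights `h/d_p`, both `> 0`. `H` may be a
#'   vector.
#' @param C A `"shape_constants"` object matching the chamber shape.
#' @param chamber,proboscis Geometry.
#' @return Normalized impulse (dimensionless); zero iff `H = H0`, strictly
#'   increasing in `H` on the expansion branch.
#' @export
impulse_height_relation <- function(H, H0, C, chamber, proboscis) {
  stopifnot(all(H > 0), H0 > 0)
  tm <- .impulse_terms(C, chamber, proboscis)
  -tm$Cs * (1 / H0^2 - 1 / H^2) + tm$col * (H - H0)
}

#' Gap height reached for a given impulse
#'
#' Inverts [impulse_height_relation()] on the expansion branch by bracketed
#' root finding (the relation is strictly increasing in `H` since `C < s`).
#'
#' @param Pi_normalized Normalized impulse (`>= 0` for expansion).
#' @param H0 Initial dimensionless height.
#' @param C,chamber,proboscis As in [impulse_height_relation()].
#' @param H_max Upper bound for the bracket search (default `1e6 * H0`).
#' @return The unique `H >= H0` with the requested impulse, to 1e-10
#'   relative tolerance.
#' @export
height_from_impulse <- function(Pi_normalized, H0, C, chamber, proboscis,
                                H_max = 1e6 * H0) {
  stopifnot(Pi_normalized >= 0, H0 > 0)
  if (Pi_normalized == 0) return(H0)
  f <- function(H) impulse_height_relation(H, H0, C, chamber, proboscis) -
    Pi_normalized
  hi <- 2 * H0
  while (f(hi) < 0) {
    hi <- hi * 2
    if (hi > H_max)
      stop(sprintf("no bracket found below H_max = %g; impulse %g may be ",
                   H_max, Pi_normalized),
           "unreachable for this geometry")
  }
  uniroot(f, lower = H0, upper = hi, tol = 1e-10 * H0)$root
}
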