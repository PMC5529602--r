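## Piecewise-linear finite elements for the mixed Dirichlet-Neumann Laplace
## problem satisfied by the correction pressure P~:
##   lap(P~) = 0 in the chamber footprint,
##   P~ = 0 on the opening AB (Dirichlet),
##   dP~/dn = -1/2 on the flux walls (X = +-1/2 sides / the wall arc),
##   dP~/dn = 0 on the remaining walls (Y = +-w/2 sides).

.tri_geometry <- function(mesh) {
  p <- mesh$nodes; t <- mesh$tri
  x1 <- p[t[, 1L], 1L]; y1 <- p[t[, 1L], 2L]
  x2 <- p[t[, 2L], 1L]; y2 <- p[t[, 2L], 2L]
  x3 <- p[t[, 3L], 1L]; y3 <- p[t[, 3L], 2L]
  area <- ((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)) / 2
  ## P1 shape-function gradient coefficients: grad(N_i) = (b_i, c_i) / (2 A)
  list(area = area,
       b = cbind(y2 - y3, y3 - y1, y1 - y2),
       c = cbind(x3 - x2, x1 - x3, x2 - x1))
}

.dirichlet_nodes <- function(mesh) {
  op <- mesh$boundary$tag == "opening"
  sort(unique(c(mesh$boundary$n1[op], mesh$boundary$n2[op])))
}

.assemble_system <- function(mesh, wall_flux = -0.5) {
  n <- nrow(mesh$nodes)
  geo <- .tri_geometry(mesh)
  if (any(geo$area <= 0)) stop("mesh contains non-positively oriented triangles")
  inv4A <- 1 / (4 * geo$area)
  ii <- jj <- vv <- vector("list", 9L)
  k <- 0L
  for (a in 1:3) for (b in 1:3) {
    k <- k + 1L
    ii[[k]] <- mesh$tri[, a]
    jj[[k]] <- mesh$tri[, b]
    vv[[k]] <- (geo$b[, a] * geo$b[, b] + geo$c[, a] * geo$c[, b]) * inv4A
  }
  K <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(vv),
                            dims = c(n, n))
  rhs <- numeric(n)
  fe <- mesh$boundary[mesh$boundary$tag == "wall_flux", , drop = FALSE]
  if (nrow(fe)) {
    len <- sqrt(rowSums((mesh$nodes[fe$n1, , drop = FALSE] -
                         mesh$nodes[fe$n2, , drop = FALSE])^2))
    contrib <- wall_flux * len / 2
    add <- tapply(c(contrib, contrib), c(fe$n1, fe$n2), sum)
    idx <- as.integer(names(add))
    rhs[idx] <- rhs[idx] + as.numeric(add)
  }
  list(K = K, rhs = rhs)
}

#' Solve the mixed Laplace problem for the correction pressure
#'
#' Solves the discrete harmonic problem for the dimensionless correction
#' pressure on a chamber mesh: zero Dirichlet data on the opening, outward
#' flux -1/2 on the pressure-active walls, zero flux elsewhere. Linear
#' (P1) elements; the reduced symmetric positive-definite system is solved
#' by sparse Cholesky factorization.
#'
#' @param mesh A `"trimesh"` from [build_mesh()] with at least one opening
#'   edge (otherwise the Neumann problem is singular and an error is thrown).
#' @return A `"scalar_field"`: list with `mesh`, `values` (one per node) and
#'   attributes `opening_flux` (the flux-consistent discrete boundary flux of
#'   the field through the opening) and `residual`.
#' @export
solve_mixed_laplace <- function(mesh) {
  stopifnot(inherits(mesh, "trimesh"))
  dir <- .dirichlet_nodes(mesh)
  if (!length(dir))
    stop("singular system: no opening (Dirichlet) edges on the boundary")
  sys <- .assemble_system(mesh)
  n <- nrow(mesh$nodes)
  free <- setdiff(seq_len(n), dir)
  u <- numeric(n)
  Kff <- Matrix::forceSymmetric(sys$K[free, free, drop = FALSE])
  sol <- tryCatch(Matrix::solve(Kff, sys$rhs[free]),
                  error = function(e)
                    stop("sparse solve failed: ", conditionMessage(e)))
  u[free] <- as.numeric(sol)
  res <- as.numeric(Kff %*% u[free]) - sys$rhs[free]
  resnorm <- sqrt(sum(res^2)) / max(1e-300, sqrt(sum(sys$rhs[free]^2)))
  if (!is.finite(resnorm) || resnorm > 1e-8)
    stop(sprintf("solver did not converge: relative residual %.3e", resnorm))
  ## consistent boundary flux through the Dirichlet (opening) part:
  ## sum over opening nodes of (K u - rhs)
  flux <- sum((sys$K %*% u)[dir] - sys$rhs[dir])
  structure(list(mesh = mesh, values = u),
            class = "scalar_field",
            opening_flux = flux, residual = resnorm)
}

#' @export
print.scalar_field <- function(x, ...) {
  cat(sprintf("<scalar_field> on %s mesh (%d nodes): range [%.5g, %.5g]\n",
              x$mesh$shape, nrow(x$mesh$nodes),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Per-triangle gradient of a nodal scalar field
#'
#' @param field A `"scalar_field"`.
#' @return Matrix (n_triangles x 2) of piecewise-constant gradients.
#' @export
field_gradient <- function(field) {
  mesh <- field$mesh
  geo <- .tri_geometry(mesh)
  u <- field$values
  u1 <- u[mesh$tri[, 1L]]; u2 <- u[mesh$tri[, 2L]]; u3 <- u[mesh$tri[, 3L]]
  gx <- (u1 * geo$b[, 1L] + u2 * geo$b[, 2L] + u3 * geo$b[, 3L]) /
    (2 * geo$area)
  gy <- (u1 * geo$c[, 1L] + u2 * geo$c[, 2L] + u3 * geo$c[, 3L]) /
    (2 * geo$area)
  cbind(gx, gy)
}

## vertex-average quadrature of a nodal field over the mesh (the triangle
## area times the mean of its three vertex values)
.integrate_field <- function(mesh, values) {
  areas <- tri_areas(mesh)
  vmean <- (values[mesh$tri[, 1L]] + values[mesh$tri[, 2L]] +
            values[mesh$tri[, 3L]]) / 3
  sum(areas * vmean)
}

#' Adaptively refine the chamber mesh until the shape constant converges
#'
#' Iterates solve/refine passes: after each solve the chamber shape constant
#' (the integral of the correction pressure) is evaluated by vertex-average
#' quadrature, triangles with the largest gradient indicator
#' `|grad P~| * sqrt(area)` - concentrated at the opening corners A and B
#' where the mixed boundary condition makes the gradient singular - are
#' bisected (longest-edge/Rivara, which preserves mesh quality), and the
#' loop stops when the constant changes by less than `tol` between passes.
#'
#' @param chamber A [chamber_geometry()] object (only its dimensionless
#'   parameters are used).
#' @param tol Relative convergence tolerance on the shape constant
#'   (default 0.5\%). `tol = Inf` performs exactly one pass.
#' @param max_refinements Cap on solve/refine passes; if reached without
#'   convergence the result is flagged (not silently accepted).
#' @param mark_frac Triangles with indicator above `mark_frac * max` are
#'   refined each pass.
#' @param verbose If `TRUE`, log one line per pass (pass number, node count,
#'   shape-constant estimate, relative change) so convergence is auditable.
#' @param ... Base-mesh resolution arguments passed to [build_mesh()].
#' @return List with `mesh`, `field` (the converged `"scalar_field"`),
#'   `constant` (the shape-constant estimate) and `convergence`
#'   (a `"convergence_record"`: `refinement_count`, `constant_history`,
#'   `final_rel_change`, `converged`, `message`).
#' @export
refine_until_converged <- function(chamber, tol = 0.005,
                                   max_refinements = 30L,
                                   mark_frac = 0.25, verbose = FALSE, ...) {
  stopifnot(tol > 0)
  mesh <- build_mesh(chamber, refinement_level = 0L, ...)
  history <- numeric(0)
  field <- NULL
  converged <- FALSE
  rel <- NA_real_
  pass <- 0L
  repeat {
    pass <- pass + 1L
    field <- solve_mixed_laplace(mesh)
    C <- .integrate_field(mesh, field$values)
    history <- c(history, C)
    if (verbose)
      message(sprintf("pass %2d: %6d nodes, C = %.6g, rel change = %s",
                      pass, nrow(mesh$nodes), C,
                      if (pass >= 2L)
                        sprintf("%.3g", abs(C - history[pass - 1L]) /
                                  max(abs(C), 1e-12)) else "-"))
    if (pass >= 2L) {
      rel <- abs(C - history[pass - 1L]) / max(abs(C), 1e-12)
      if (rel < tol) { converged <- TRUE; break }
    }
    if (!is.finite(tol)) { converged <- TRUE; rel <- 0; break }
    if (pass >= max_refinements) break
    grad <- field_gradient(field)
    eta <- sqrt(grad[, 1L]^2 + grad[, 2L]^2) * sqrt(abs(tri_areas(mesh)))
    marked <- which(eta >= mark_frac * max(eta))
    mesh <- refine_marked(mesh, marked)
  }
  record <- structure(
    list(refinement_count = pass,
         constant_history = history,
         final_rel_change = rel,
         converged = converged,
         message = if (converged) "converged" else
           sprintf("not converged after %d refinements (rel change %.3g)",
                   pass, rel)),
    class = "convergence_record")
  if (!converged)
    warning(record$message)
  list(mesh = mesh, field = field,
       constant = history[length(history)], convergence = record)
}

#' @export
print.convergence_record <- function(x, ...) {
  cat(sprintf("<convergence_record> %d passes, final C = %.6g (%s)\n",
              x$refinement_count,
              x$constant_history[length(x$constant_history)], x$message))
  invisible(x)
}

#' Interpolate a nodal field at arbitrary points
#'
#' Barycentric (piecewise-linear) evaluation of a `"scalar_field"` at given
#' dimensionless coordinates, by brute-force point location. Points outside
#' every triangle (beyond a small tolerance) yield `NA`.
#'
#' @param field A `"scalar_field"`.
#' @param points Matrix (n x 2) of coordinates.
#' @return Numeric vector of interpolated values.
#' @export
field_interpolate <- function(field, points) {
  mesh <- field$mesh
  points <- rbind(points)
  p <- mesh$nodes; tr <- mesh$tri
  x1 <- p[tr[, 1L], 1L]; y1 <- p[tr[, 1L], 2L]
  x2 <- p[tr[, 2L], 1L]; y2 <- p[tr[, 2L], 2L]
  x3 <- p[tr[, 3L], 1L]; y3 <- p[tr[, 3L], 2L]
  den <- (y2 - y3) * (x1 - x3) + (x3 - x2) * (y1 - y3)
  u <- field$values
  tol <- 1e-9
  out <- rep(NA_real_, nrow(points))
  for (q in seq_len(nrow(points))) {
    px <- points[q, 1L]; py <- points[q, 2L]
    l1 <- ((y2 - y3) * (px - x3) + (x3 - x2) * (py - y3)) / den
    l2 <- ((y3 - y1) * (px - x3) + (x1 - x3) * (py - y3)) / den
    l3 <- 1 - l1 - l2
    hit <- which(l1 >= -tol & l2 >= -tol & l3 >= -tol)
    if (length(hit)) {
      t1 <- hit[1L]
      out[q] <- l1[t1] * u[tr[t1, 1L]] + l2[t1] * u[tr[t1, 2L]] +
        l3[t1] * u[tr[t1, 3L]]
    }
  }
  out
}
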