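## Triangular meshes for the dimensionless chamber footprint.
##
## Rectangular chamber: X in [-1/2, 1/2], Y in [-w/2, w/2] with w = W/L.
## The opening AB (length g = |AB|/L) sits centered on the X = -1/2 side.
## Circular chamber: unit disk, opening on the arc |phi| <= theta.
##
## Boundary tags:
##   "opening"   - Dirichlet part (P~ = 0)
##   "wall_flux" - Neumann part with outward flux dP~/dn = -1/2
##               (X = +-1/2 walls of the rectangle; the wall arc of the disk)
##   "wall_zero" - zero-flux part (Y = +-w/2 sides of the rectangle)

.edge_key <- function(a, b) {
  lo <- pmin(a, b); hi <- pmax(a, b)
  paste(lo, hi, sep = "_")
}

#' Construct a triangular mesh of the dimensionless chamber footprint
#'
#' Builds a structured, boundary-graded triangulation of the unit-length
#' rectangle or the unit disk (polygonized to at least 256 boundary segments
#' at the base level), with mesh lines placed exactly at the opening
#' endpoints A and B where the boundary condition changes and the pressure
#' gradient is singular. Higher `refinement_level` yields strictly more
#' nodes. Adaptive refinement on top of this base mesh is performed by
#' [refine_until_converged()].
#'
#' @param chamber A [chamber_geometry()] object, or a list with dimensionless
#'   fields (`shape`, `aspect`, `g`) or (`shape`, `theta`).
#' @param refinement_level Non-negative integer; scales the base resolution.
#' @param base_nx,base_nphi,base_rings Base resolution knobs (rectangle grid
#'   columns; disk boundary segments and radial rings).
#' @return An object of class `"trimesh"`: `nodes` (n x 2), `tri` (m x 3,
#'   positively oriented), `boundary` (data.frame `n1`, `n2`, `tag`), plus
#'   `shape` and the dimensionless parameters.
#' @export
build_mesh <- function(chamber, refinement_level = 0L,
                       base_nx = 40L, base_nphi = 256L, base_rings = 10L) {
  stopifnot(refinement_level >= 0)
  lev <- as.integer(refinement_level)
  shape <- chamber$shape
  if (shape == "rectangular") {
    w <- chamber$aspect
    g <- chamber$g
    if (!is.finite(w) || w <= 0) stop("degenerate aspect ratio W/L <= 0")
    if (g <= 0) stop("opening fraction g must be positive")
    if (g > w * (1 + 1e-12)) {
      warning(sprintf(
        "g = %g exceeds W/L = %g; clamped to the full-opening limit", g, w))
      g <- w
    }
    mesh_rectangle(w, g, nx = base_nx + 8L * lev)
  } else {
    theta <- chamber$theta
    if (!is.finite(theta) || theta <= 0) stop("theta must be positive")
    if (theta > pi * (1 + 1e-12)) {
      warning(sprintf(
        "theta = %g exceeds pi; clamped to the full-opening limit", theta))
      theta <- pi
    }
    mesh_disk(theta, nphi = base_nphi + 32L * lev, nrings = base_rings + lev)
  }
}

## tensor grid with exact lines at the opening endpoints; near-duplicate
## uniform lines are dropped so no sliver cells appear
.grid_with <- function(lo, hi, n, inserts) {
  gr <- seq(lo, hi, length.out = n + 1L)
  dx <- (hi - lo) / n
  inserts <- inserts[inserts > lo + 1e-14 & inserts < hi - 1e-14]
  if (length(inserts)) {
    keep <- vapply(gr, function(v) {
      v <= lo + 1e-14 || v >= hi - 1e-14 ||
        all(abs(v - inserts) > 0.35 * dx)
    }, logical(1))
    gr <- sort(c(gr[keep], inserts))
  }
  gr
}

mesh_rectangle <- function(w, g, nx = 40L) {
  xg <- seq(-0.5, 0.5, length.out = nx + 1L)
  ny <- max(8L, as.integer(round(nx * w)))
  yg <- .grid_with(-w / 2, w / 2, ny, c(-g / 2, 0, g / 2))
  nxp <- length(xg); nyp <- length(yg)
  nodes <- cbind(rep(xg, times = nyp), rep(yg, each = nxp))
  id <- function(i, j) (j - 1L) * nxp + i

  ii <- rep(seq_len(nxp - 1L), times = nyp - 1L)
  jj <- rep(seq_len(nyp - 1L), each = nxp - 1L)
  a <- id(ii, jj); b <- id(ii + 1L, jj)
  cc <- id(ii + 1L, jj + 1L); d <- id(ii, jj + 1L)
  tri <- rbind(cbind(a, b, cc), cbind(a, cc, d))

  tol <- 1e-12
  jseq <- seq_len(nyp - 1L)
  ymid <- (yg[jseq] + yg[jseq + 1L]) / 2
  left_tag <- ifelse(ymid > -g / 2 - tol & ymid < g / 2 + tol,
                     "opening", "wall_flux")
  boundary <- rbind(
    data.frame(n1 = id(1L, jseq), n2 = id(1L, jseq + 1L),
               tag = left_tag, stringsAsFactors = FALSE),
    data.frame(n1 = id(nxp, jseq), n2 = id(nxp, jseq + 1L),
               tag = "wall_flux", stringsAsFactors = FALSE),
    data.frame(n1 = id(seq_len(nxp - 1L), 1L),
               n2 = id(seq_len(nxp - 1L) + 1L, 1L),
               tag = "wall_zero", stringsAsFactors = FALSE),
    data.frame(n1 = id(seq_len(nxp - 1L), nyp),
               n2 = id(seq_len(nxp - 1L) + 1L, nyp),
               tag = "wall_zero", stringsAsFactors = FALSE))

  structure(list(nodes = nodes, tri = tri, boundary = boundary,
                 shape = "rectangular", params = list(aspect = w, g = g)),
            class = "trimesh")
}

mesh_disk <- function(theta, nphi = 256L, nrings = 10L) {
  full <- theta >= pi * (1 - 1e-12)
  phig <- .grid_with(-pi, pi, nphi,
                     if (full) numeric(0) else c(-theta, theta))
  phig <- phig[-length(phig)]            # periodic: drop duplicate +pi
  np <- length(phig)
  ## radial rings graded toward the rim where the action is
  j <- seq_len(nrings)
  rg <- 1 - (1 - j / nrings)^1.7
  nodes <- rbind(c(0, 0),
                 cbind(cos(rep(phig, nrings)) * rep(rg, each = np),
                       sin(rep(phig, nrings)) * rep(rg, each = np)))
  id <- function(ring, k) 1L + (ring - 1L) * np + ((k - 1L) %% np) + 1L

  k <- seq_len(np)
  tri <- cbind(rep(1L, np), id(1L, k), id(1L, k + 1L))  # center fan
  if (nrings > 1L) {
    for (ring in seq_len(nrings - 1L)) {
      i1 <- id(ring, k); i2 <- id(ring, k + 1L)
      o1 <- id(ring + 1L, k); o2 <- id(ring + 1L, k + 1L)
      tri <- rbind(tri, cbind(i1, o1, o2), cbind(i1, o2, i2))
    }
  }
  phimid <- phig + c(diff(phig), 2 * pi + phig[1L] - phig[np]) / 2
  phimid <- atan2(sin(phimid), cos(phimid))
  tag <- if (full) rep("opening", np) else
    ifelse(abs(phimid) < theta, "opening", "wall_flux")
  boundary <- data.frame(n1 = id(nrings, k), n2 = id(nrings, k + 1L),
                         tag = tag, stringsAsFactors = FALSE)
  structure(list(nodes = nodes, tri = unname(tri), boundary = boundary,
                 shape = "circular", params = list(theta = theta)),
            class = "trimesh")
}

#' Signed areas of all mesh triangles
#' @param mesh A `"trimesh"`.
#' @return Numeric vector of triangle areas (positive for the package's
#'   counter-clockwise orientation convention).
#' @export
tri_areas <- function(mesh) {
  p <- mesh$nodes; t <- mesh$tri
  x1 <- p[t[, 1L], 1L]; y1 <- p[t[, 1L], 2L]
  x2 <- p[t[, 2L], 1L]; y2 <- p[t[, 2L], 2L]
  x3 <- p[t[, 3L], 1L]; y3 <- p[t[, 3L], 2L]
  ((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)) / 2
}

#' @export
print.trimesh <- function(x, ...) {
  cat(sprintf("<trimesh> %s: %d nodes, %d triangles, %d boundary edges\n",
              x$shape, nrow(x$nodes), nrow(x$tri), nrow(x$boundary)))
  cat("  boundary tags:",
      paste(sprintf("%s=%d", names(table(x$boundary$tag)),
                    as.integer(table(x$boundary$tag))), collapse = ", "),
      "\n")
  invisible(x)
}

## ---- Rivara longest-edge bisection -------------------------------------

## refine every triangle in `marked` (and whatever conformity demands) by
## longest-edge bisection; boundary midpoints of circular meshes are
## projected back to the unit circle
refine_marked <- function(mesh, marked) {
  nodes <- mesh$nodes
  ntri0 <- nrow(mesh$tri)
  ## growable storage
  ncap <- nrow(nodes) + 4L * length(marked) + 64L
  tcap <- ntri0 + 8L * length(marked) + 64L
  P <- rbind(nodes, matrix(NA_real_, ncap - nrow(nodes), 2L))
  TR <- rbind(mesh$tri, matrix(NA_integer_, tcap - ntri0, 3L))
  nP <- nrow(nodes); nT <- ntri0

  ## adjacency: edge key -> triangle ids
  keys <- .edge_key(c(TR[1:nT, 1L], TR[1:nT, 2L], TR[1:nT, 3L]),
                    c(TR[1:nT, 2L], TR[1:nT, 3L], TR[1:nT, 1L]))
  adj <- new.env(hash = TRUE, size = as.integer(4L * nT))
  sp <- split(rep.int(seq_len(nT), 3L), keys)
  list2env(sp, envir = adj)

  ## boundary tag map
  btag <- new.env(hash = TRUE, size = as.integer(4L * nrow(mesh$boundary)))
  bk <- .edge_key(mesh$boundary$n1, mesh$boundary$n2)
  for (i in seq_along(bk)) assign(bk[i], mesh$boundary$tag[i], envir = btag)

  circ <- identical(mesh$shape, "circular")

  longest_edge <- function(t) {
    v <- TR[t, ]
    d12 <- sum((P[v[1L], ] - P[v[2L], ])^2)
    d23 <- sum((P[v[2L], ] - P[v[3L], ])^2)
    d31 <- sum((P[v[3L], ] - P[v[1L], ])^2)
    k <- which.max(c(d12, d23, d31))
    if (k == 1L) c(v[1L], v[2L]) else if (k == 2L) c(v[2L], v[3L])
    else c(v[3L], v[1L])
  }
  grow_P <- function() {
    P <<- rbind(P, matrix(NA_real_, nrow(P), 2L))
  }
  grow_T <- function() {
    TR <<- rbind(TR, matrix(NA_integer_, nrow(TR), 3L))
  }
  adj_replace <- function(key, old, new) {
    v <- get0(key, envir = adj, inherits = FALSE)
    v[v == old] <- new
    assign(key, v, envir = adj)
  }

  ## split triangle t across edge (a, b) with midpoint m; returns new tri id
  split_tri <- function(t, a, b, m) {
    v <- TR[t, ]
    pos <- which(v == a)
    nxt <- v[pos %% 3L + 1L]
    if (nxt == b) { u <- a; vv <- b } else { u <- b; vv <- a }
    pos <- which(v == u)
    cc <- v[(pos + 1L) %% 3L + 1L]
    nT <<- nT + 1L
    if (nT > nrow(TR)) grow_T()
    tn <- nT
    TR[t, ] <<- c(u, m, cc)
    TR[tn, ] <<- c(m, vv, cc)
    ## adjacency updates
    adj_replace(.edge_key(vv, cc), t, tn)
    assign(.edge_key(u, m), c(get0(.edge_key(u, m), envir = adj,
                                   inherits = FALSE), t), envir = adj)
    assign(.edge_key(m, vv), c(get0(.edge_key(m, vv), envir = adj,
                                    inherits = FALSE), tn), envir = adj)
    assign(.edge_key(m, cc), c(t, tn), envir = adj)
    tn
  }

  bisect_edge <- function(a, b) {
    key <- .edge_key(a, b)
    ts <- get0(key, envir = adj, inherits = FALSE)
    mxy <- (P[a, ] + P[b, ]) / 2
    tag <- get0(key, envir = btag, inherits = FALSE)
    if (!is.null(tag) && circ) mxy <- mxy / sqrt(sum(mxy^2))
    nP <<- nP + 1L
    if (nP > nrow(P)) grow_P()
    P[nP, ] <<- mxy
    m <- nP
    if (!is.null(tag)) {
      rm(list = key, envir = btag)
      assign(.edge_key(a, m), tag, envir = btag)
      assign(.edge_key(m, b), tag, envir = btag)
    }
    for (t in ts) split_tri(t, a, b, m)
    rm(list = key, envir = adj)
  }

  same_edge <- function(e1, e2) {
    (e1[1L] == e2[1L] && e1[2L] == e2[2L]) ||
      (e1[1L] == e2[2L] && e1[2L] == e2[1L])
  }

  refine_one <- function(t0) {
    stack <- t0
    guard <- 0L
    while (length(stack)) {
      guard <- guard + 1L
      if (guard > 200000L) stop("refinement propagation did not terminate")
      t <- stack[length(stack)]
      e <- longest_edge(t)
      ts <- get0(.edge_key(e[1L], e[2L]), envir = adj, inherits = FALSE)
      nb <- ts[ts != t]
      if (length(nb) == 1L && !same_edge(longest_edge(nb), e)) {
        stack <- c(stack, nb)
      } else {
        bisect_edge(e[1L], e[2L])
        stack <- stack[-length(stack)]
      }
    }
  }

  split_count <- rep.int(0L, tcap)  # detect triangles already bisected
  area0 <- abs(tri_areas(mesh))
  for (t0 in marked) {
    ## skip if this triangle has been split already by propagation: detect
    ## by area change (its row now holds a child half the size)
    v <- TR[t0, ]
    a <- abs(((P[v[2L], 1L] - P[v[1L], 1L]) * (P[v[3L], 2L] - P[v[1L], 2L]) -
              (P[v[3L], 1L] - P[v[1L], 1L]) * (P[v[2L], 2L] - P[v[1L], 2L])) / 2)
    if (a < 0.75 * area0[t0]) next
    refine_one(t0)
  }

  bkeys <- ls(envir = btag)
  bn <- do.call(rbind, strsplit(bkeys, "_", fixed = TRUE))
  boundary <- data.frame(n1 = as.integer(bn[, 1L]),
                         n2 = as.integer(bn[, 2L]),
                         tag = vapply(bkeys, get, "", envir = btag,
                                      USE.NAMES = FALSE),
                         stringsAsFactors = FALSE)
  out <- mesh
  out$nodes <- P[seq_len(nP), , drop = FALSE]
  out$tri <- TR[seq_len(nT), , drop = FALSE]
  out$boundary <- boundary
  out
}
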