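## Second-order finite-difference solution of the same mixed
## Dirichlet-Neumann Laplace problem, on a structured grid. This is the
## package's independent cross-check of the finite-element solver: the two
## methods share no code beyond the boundary-value problem itself.
##
## Rectangle: tensor grid with lines exactly at the opening endpoints,
## graded toward the singular corners A, B. Disk: uniform radial rings x
## graded angular grid with nodes exactly at phi = +-theta; the polar axis
## r = 0 is a single center unknown. Both use the conservation
## (control-volume) form of the 5-point scheme, which imposes the known
## wall flux exactly on the boundary faces and stays second order on the
## smoothly graded grids.

#' Finite-difference oracle for the chamber correction pressure
#'
#' Solves the same boundary-value problem as [solve_mixed_laplace()] by
#' second-order central finite differences on a structured grid (Cartesian
#' for rectangular chambers, polar for circular ones), independently of the
#' finite-element path. Intended for cross-method verification.
#'
#' @param chamber A [chamber_geometry()] object.
#' @param grid_n Resolution parameter (`>= 16`): number of grid intervals
#'   across the unit length (rectangle) or radius (disk). The angular grid of
#'   the disk uses about `4 * grid_n` intervals. If the opening would span
#'   fewer than 2 grid intervals the function refuses with an error.
#' @return An object of class `"fd_field"` holding the grid and nodal values;
#'   evaluate anywhere with [fd_interpolate()].
#' @export
fd_oracle <- function(chamber, grid_n = 64L) {
  stopifnot(inherits(chamber, "chamber") || is.list(chamber))
  if (grid_n < 16L) stop("grid_n must be at least 16")
  if (chamber$shape == "rectangular")
    .fd_rectangle(chamber$aspect, min(chamber$g, chamber$aspect), grid_n)
  else
    .fd_disk(min(chamber$theta, pi), grid_n)
}

.seg_grid <- function(lo, hi, h_target, n_min = 1L,
                      cluster = c("none", "left", "right", "both"), p = 2) {
  cluster <- match.arg(cluster)
  n <- max(n_min, as.integer(round((hi - lo) / h_target)))
  t <- seq(0, 1, length.out = n + 1L)
  s <- switch(cluster,
              none = t,
              left = t^p,
              right = 1 - (1 - t)^p,
              both = (1 - cos(pi * t)) / 2)
  out <- lo + (hi - lo) * s
  out[1L] <- lo; out[length(out)] <- hi   # exact segment junctions
  out
}

.fd_rectangle <- function(w, g, grid_n) {
  hyt <- w / max(4L, as.integer(round(grid_n * w)))
  if (g / hyt < 2 && g < w * (1 - 1e-12))
    stop(sprintf(paste0("grid too coarse to resolve opening: g = %g spans ",
                        "fewer than 2 grid intervals (h_y = %g); ",
                        "increase grid_n"), g, hyt))
  ## grids graded toward the opening corners A, B at (-1/2, +-g/2) where the
  ## mixed boundary condition makes the solution gradient singular
  xg <- .seg_grid(-0.5, 0.5, 1 / grid_n, 8L, cluster = "left")
  yg <- if (g >= w * (1 - 1e-12)) .seg_grid(-w / 2, w / 2, hyt, 4L) else
    unique(c(.seg_grid(-w / 2, -g / 2, hyt, cluster = "right"),
             .seg_grid(-g / 2, g / 2, hyt, 2L, cluster = "both"),
             .seg_grid(g / 2, w / 2, hyt, cluster = "left")))
  nx <- length(xg); ny <- length(yg)
  n <- nx * ny
  id <- function(i, j) (j - 1L) * nx + i
  q <- -0.5  # outward flux on the X walls
  tol <- 1e-12

  ii <- rep(seq_len(nx), times = ny)
  jj <- rep(seq_len(ny), each = nx)
  rid <- id(ii, jj)
  dirich <- ii == 1L & abs(yg[jj]) <= g / 2 + tol
  act <- !dirich

  hxv <- diff(xg); hyv <- diff(yg)
  hxl <- c(NA, hxv)[ii]; hxr <- c(hxv, NA)[ii]
  hyl <- c(NA, hyv)[jj]; hyr <- c(hyv, NA)[jj]
  ## control-volume extents (half cells at the boundary)
  wx <- (ifelse(is.na(hxl), 0, hxl) + ifelse(is.na(hxr), 0, hxr)) / 2
  wy <- (ifelse(is.na(hyl), 0, hyl) + ifelse(is.na(hyr), 0, hyr)) / 2

  aW <- ifelse(ii == 1L, 0, wy / hxl)
  aE <- ifelse(ii == nx, 0, wy / hxr)
  aS <- ifelse(jj == 1L, 0, wx / hyl)
  aN <- ifelse(jj == ny, 0, wx / hyr)
  ac <- -(aW + aE + aS + aN)
  ## known outward flux q through the X-wall faces enters the balance
  rhs_all <- ifelse(ii == 1L | ii == nx, -q * wy, 0)

  xl <- ifelse(ii == 1L, 1L, ii - 1L); xr <- ifelse(ii == nx, nx, ii + 1L)
  yl <- ifelse(jj == 1L, 1L, jj - 1L); yr <- ifelse(jj == ny, ny, jj + 1L)
  tri_i <- c(rid[act], rid[act], rid[act], rid[act], rid[act], rid[dirich])
  tri_j <- c(rid[act], id(xl, jj)[act], id(xr, jj)[act],
             id(ii, yl)[act], id(ii, yr)[act], rid[dirich])
  tri_x <- c(ac[act], aW[act], aE[act], aS[act], aN[act],
             rep(1, sum(dirich)))
  rhs <- numeric(n)
  rhs[act] <- rhs_all[act]
  A <- Matrix::sparseMatrix(i = tri_i, j = tri_j, x = tri_x, dims = c(n, n))
  u <- as.numeric(Matrix::solve(A, rhs))
  structure(list(shape = "rectangular", x = xg, y = yg,
                 values = matrix(u, nrow = nx, ncol = ny),
                 params = list(aspect = w, g = g)),
            class = "fd_field")
}

.fd_disk <- function(theta, grid_n) {
  m <- as.integer(grid_n)          # radial intervals
  dr <- 1 / m
  full <- theta >= pi * (1 - 1e-12)
  dphit <- 2 * pi / (4L * grid_n)
  if (!full && 2 * theta / dphit < 2)
    stop(sprintf(paste0("grid too coarse to resolve opening: arc 2*theta ",
                        "= %g spans fewer than 2 angular intervals (dphi = ",
                        "%g); increase grid_n"), 2 * theta, dphit))
  ## angular grid graded toward the opening endpoints +-theta
  phig <- if (full) seq(-pi, pi, length.out = 4L * grid_n + 1L) else
    unique(c(.seg_grid(-theta, theta, dphit, 2L, cluster = "both"),
             .seg_grid(theta, 2 * pi - theta, dphit, 8L, cluster = "both")))
  phig <- phig[-length(phig)]      # periodic
  np <- length(phig)
  hphi <- diff(c(phig, phig[1L] + 2 * pi))
  n <- m * np + 1L                 # + center
  idc <- n
  id <- function(j, k) (j - 1L) * np + ((k - 1L) %% np) + 1L
  tol <- 1e-12

  kk <- rep(seq_len(np), times = m)
  jj <- rep(seq_len(m), each = np)
  rid <- id(jj, kk)
  rj <- jj * dr
  hl <- hphi[ifelse(kk == 1L, np, kk - 1L)]
  hr <- hphi[kk]
  wphi <- (hl + hr) / 2                         # angular CV width
  drcv <- ifelse(jj == m, dr / 2, dr)           # radial CV extent

  wang <- abs(atan2(sin(phig), cos(phig)))
  dirich <- jj == m & (full | wang[kk] <= theta + tol)
  wallrim <- jj == m & !dirich

  ## control-volume (conservation-form) coefficients
  a_in <- (rj - dr / 2) * wphi / dr             # inner radial face
  a_out <- ifelse(jj == m, 0, (rj + dr / 2) * wphi / dr)
  a_l <- drcv / (rj * hl)
  a_r <- drcv / (rj * hr)
  ac <- -(a_in + a_out + a_l + a_r)
  rhs_all <- numeric(m * np)
  rhs_all[wallrim] <- 0.5 * wphi[wallrim]       # outward flux -1/2 at r = 1
  id_in <- ifelse(jj == 1L, idc, id(pmax(jj - 1L, 1L), kk))
  id_out <- id(pmin(jj + 1L, m), kk)            # weight 0 at the rim
  id_l <- id(jj, kk - 1L)
  id_r <- id(jj, kk + 1L)

  act <- !dirich
  ## center control volume (radius dr/2) balances fluxes to ring 1
  a_c <- wphi[jj == 1L] / 2
  tri_i <- c(rid[act], rid[act], rid[act], rid[act], rid[act],
             rid[dirich], rep(idc, np + 1L))
  tri_j <- c(rid[act], id_in[act], id_out[act], id_l[act], id_r[act],
             rid[dirich], id(1L, seq_len(np)), idc)
  tri_x <- c(ac[act], a_in[act], a_out[act], a_l[act], a_r[act],
             rep(1, sum(dirich)), a_c, -sum(a_c))
  rhs <- c(rhs_all, 0)
  rhs[dirich] <- 0
  A <- Matrix::sparseMatrix(i = tri_i, j = tri_j, x = tri_x, dims = c(n, n))
  u <- as.numeric(Matrix::solve(A, rhs))
  structure(list(shape = "circular", r = seq_len(m) * dr, phi = phig,
                 values = matrix(u[seq_len(m * np)], nrow = np, ncol = m),
                 center = u[idc], params = list(theta = theta)),
            class = "fd_field")
}

#' Evaluate a finite-difference field at arbitrary points
#'
#' Bilinear interpolation on the structured grid (tensor Cartesian for the
#' rectangle, polar with periodic wrap for the disk).
#'
#' @param fd An `"fd_field"` from [fd_oracle()].
#' @param points Matrix (n x 2) of dimensionless coordinates.
#' @return Numeric vector of interpolated values.
#' @export
fd_interpolate <- function(fd, points) {
  stopifnot(inherits(fd, "fd_field"))
  points <- rbind(points)
  if (fd$shape == "rectangular") {
    xg <- fd$x; yg <- fd$y
    i <- pmin(pmax(findInterval(points[, 1L], xg), 1L), length(xg) - 1L)
    j <- pmin(pmax(findInterval(points[, 2L], yg), 1L), length(yg) - 1L)
    tx <- (points[, 1L] - xg[i]) / (xg[i + 1L] - xg[i])
    ty <- (points[, 2L] - yg[j]) / (yg[j + 1L] - yg[j])
    tx <- pmin(pmax(tx, 0), 1); ty <- pmin(pmax(ty, 0), 1)
    v <- fd$values
    v[cbind(i, j)] * (1 - tx) * (1 - ty) +
      v[cbind(i + 1L, j)] * tx * (1 - ty) +
      v[cbind(i, j + 1L)] * (1 - tx) * ty +
      v[cbind(i + 1L, j + 1L)] * tx * ty
  } else {
    rr <- sqrt(rowSums(points^2))
    ph <- atan2(points[, 2L], points[, 1L])
    np <- length(fd$phi)
    per <- c(fd$phi, fd$phi[1L] + 2 * pi)
    ph <- fd$phi[1L] + (ph - fd$phi[1L]) %% (2 * pi)
    k <- pmin(pmax(findInterval(ph, per), 1L), np)
    tp <- (ph - per[k]) / (per[k + 1L] - per[k])
    k2 <- k %% np + 1L
    rg <- fd$r
    m <- length(rg)
    dr <- rg[1L]
    out <- numeric(nrow(points))
    inner <- rr < dr
    if (any(inner)) {
      t1 <- rr[inner] / dr
      ring <- fd$values[cbind(k[inner], 1L)] * (1 - tp[inner]) +
        fd$values[cbind(k2[inner], 1L)] * tp[inner]
      out[inner] <- fd$center * (1 - t1) + ring * t1
    }
    if (any(!inner)) {
      ro <- pmin(rr[!inner], 1)
      j <- pmin(pmax(findInterval(ro, rg), 1L), m - 1L)
      tr <- (ro - rg[j]) / (rg[j + 1L] - rg[j])
      tr <- pmin(pmax(tr, 0), 1)
      kk <- k[!inner]; kk2 <- k2[!inner]; tpp <- tp[!inner]
      out[!inner] <-
        fd$values[cbind(kk, j)] * (1 - tpp) * (1 - tr) +
        fd$values[cbind(kk2, j)] * tpp * (1 - tr) +
        fd$values[cbind(kk, j + 1L)] * (1 - tpp) * tr +
        fd$values[cbind(kk2, j + 1L)] * tpp * tr
    }
    out
  }
}

#' Relative L2 difference between a finite-element field and the FD oracle
#'
#' Evaluates the finite-difference solution at the finite-element nodes and
#' returns `||u_fem - u_fd|| / ||u_fd||` in the lumped-mass (node-area
#' weighted) L2 norm.
#'
#' @param field A `"scalar_field"` from the finite-element solver.
#' @param fd An `"fd_field"` from [fd_oracle()].
#' @return Relative L2 difference (dimensionless).
#' @export
field_l2_difference <- function(field, fd) {
  mesh <- field$mesh
  areas <- tri_areas(mesh)
  wgt <- numeric(nrow(mesh$nodes))
  for (a in 1:3) {
    tab <- tapply(areas / 3, mesh$tri[, a], sum)
    idx <- as.integer(names(tab))
    wgt[idx] <- wgt[idx] + as.numeric(tab)
  }
  ufd <- fd_interpolate(fd, mesh$nodes)
  num <- sqrt(sum(wgt * (field$values - ufd)^2))
  den <- sqrt(sum(wgt * ufd^2))
  if (den == 0) return(num)
  num / den
}
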