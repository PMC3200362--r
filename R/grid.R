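## Finite-difference grids: specification, dielectric/ion-accessibility
## maps, trilinear charge spreading, boundary conditions, interpolation.

#' Define a cubic finite-difference grid
#'
#' @param center 3-vector, Angstrom
#' @param spacing grid spacing h in Angstrom
#' @param npoints nodes per axis (odd, so the center is a node)
#' @return object of class \code{"grid_spec"}
#' @export
grid_spec <- function(center, spacing, npoints) {
  stopifnot(length(center) == 3, spacing > 0, npoints >= 5)
  if (npoints %% 2 == 0) stop("npoints must be odd (centered grid)")
  structure(list(center = as.numeric(center), spacing = spacing,
                 npoints = as.integer(npoints)),
            class = "grid_spec")
}

grid_axes <- function(g) {
  half <- (g$npoints - 1) / 2
  off <- (-half:half) * g$spacing
  list(x = g$center[1] + off, y = g$center[2] + off, z = g$center[3] + off)
}

grid_extent <- function(g) (g$npoints - 1) * g$spacing

# mark grid nodes (optionally offset by `shift`) lying inside the sphere
# union of `atoms` with radii `rad`; increments `counts` in place semantics
# by returning updated counts
.mark_inside <- function(counts, ax_x, ax_y, ax_z, atoms, rad, shift = c(0, 0, 0)) {
  nx <- length(ax_x); ny <- length(ax_y); nz <- length(ax_z)
  xs <- ax_x + shift[1]; ys <- ax_y + shift[2]; zs <- ax_z + shift[3]
  seen <- logical(length(counts))
  for (a in seq_len(nrow(atoms))) {
    r <- rad[a]
    if (is.na(r) || r <= 0) next
    cx <- atoms$x[a]; cy <- atoms$y[a]; cz <- atoms$z[a]
    ii <- which(abs(xs - cx) <= r)
    jj <- which(abs(ys - cy) <= r)
    kk <- which(abs(zs - cz) <= r)
    if (!length(ii) || !length(jj) || !length(kk)) next
    dx2 <- (xs[ii] - cx)^2
    dy2 <- (ys[jj] - cy)^2
    dz2 <- (zs[kk] - cz)^2
    block <- outer(outer(dx2, dy2, "+"), dz2, "+") <= r * r
    if (!any(block)) next
    idx <- which(block, arr.ind = TRUE)
    flat <- ii[idx[, 1]] + nx * (jj[idx[, 2]] - 1) + nx * ny * (kk[idx[, 3]] - 1)
    seen[flat] <- TRUE
  }
  counts + as.integer(seen)
}

#' Build dielectric and ion-accessibility maps for a grid
#'
#' The molecular region is the van der Waals union of the atom spheres.
#' Edge dielectrics are harmonic means weighted by the fraction of the edge
#' inside the molecular region (estimated from \code{nsamp} sample points
#' per edge), which smooths the dielectric boundary.  Cavities left by
#' removed waters are not patched: any point outside the sphere union gets
#' the solvent dielectric.  Mobile ions are excluded within
#' \code{env$ion_exclusion} of the van der Waals surface.
#'
#' @param atoms data frame with x, y, z, radius (may have zero rows), or a
#'   \code{pdb_structure}
#' @param env a \code{\link{pka_env}}
#' @param g a \code{\link{grid_spec}}
#' @param uniform_eps if non-NULL, ignore atoms and use this uniform
#'   dielectric everywhere (ions still present away from atoms)
#' @param nsamp sample points per edge for the boundary fraction
#' @return list with epsx/epsy/epsz (edge dielectrics), lam (screening
#'   term per node), grid, env
#' @export
build_dielectric_map <- function(atoms, env, g, uniform_eps = NULL,
                                 nsamp = 5) {
  if (inherits(atoms, "pdb_structure")) atoms <- atoms$atoms
  if (is.null(atoms)) atoms <- data.frame(x = numeric(), y = numeric(),
                                          z = numeric(), radius = numeric())
  ax <- grid_axes(g)
  n <- g$npoints
  N <- n^3
  h <- g$spacing
  if (nrow(atoms) > 0 && is.null(uniform_eps)) {
    hw <- grid_extent(g) / 2
    covered <- any(abs(atoms$x - g$center[1]) < hw &
                   abs(atoms$y - g$center[2]) < hw &
                   abs(atoms$z - g$center[3]) < hw)
    if (!covered) stop("grid does not cover any atom")
  }
  if (!is.null(uniform_eps)) {
    epsx <- epsy <- epsz <- rep(uniform_eps, N)
  } else if (nrow(atoms) == 0) {
    epsx <- epsy <- epsz <- rep(env$eps_water, N)
  } else {
    ts <- (seq_len(nsamp) - 0.5) / nsamp
    mkeps <- function(dir) {
      counts <- integer(N)
      for (t in ts) {
        shift <- c(0, 0, 0)
        shift[dir] <- t * h
        counts <- .mark_inside(counts, ax$x, ax$y, ax$z, atoms,
                               atoms$radius, shift)
      }
      f <- counts / nsamp
      1 / (f / env$eps_protein + (1 - f) / env$eps_water)
    }
    epsx <- mkeps(1); epsy <- mkeps(2); epsz <- mkeps(3)
  }
  # ion accessibility: nodes outside every (radius + stern) sphere
  lamcoef <- eps_kappa2(env$ionic_strength, env$temperature) * h^2
  if (lamcoef > 0 && nrow(atoms) > 0) {
    excl <- .mark_inside(integer(N), ax$x, ax$y, ax$z, atoms,
                         atoms$radius + env$ion_exclusion)
    lam <- lamcoef * (excl == 0)
  } else {
    lam <- rep(lamcoef, N)
  }
  list(epsx = epsx, epsy = epsy, epsz = epsz, lam = lam, grid = g,
       env = env,
       bc_eps = if (!is.null(uniform_eps)) uniform_eps else env$eps_water)
}

#' Spread point charges onto grid nodes (trilinear)
#' @param g grid_spec
#' @param pos n x 3 matrix of positions
#' @param q charges (e)
#' @return vector of node charges summing to sum(q)
#' @export
spread_charges <- function(g, pos, q) {
  pos <- matrix(pos, ncol = 3)
  ax <- grid_axes(g)
  n <- g$npoints
  h <- g$spacing
  qa <- numeric(n^3)
  for (a in seq_along(q)) {
    fx <- (pos[a, 1] - ax$x[1]) / h
    fy <- (pos[a, 2] - ax$y[1]) / h
    fz <- (pos[a, 3] - ax$z[1]) / h
    i0 <- floor(fx); j0 <- floor(fy); k0 <- floor(fz)
    if (i0 < 1 || i0 > n - 3 || j0 < 1 || j0 > n - 3 ||
        k0 < 1 || k0 > n - 3) {
      stop("charge ", a, " lies outside (or on the border of) the grid")
    }
    wx <- fx - i0; wy <- fy - j0; wz <- fz - k0
    for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
      w <- (if (di == 1) wx else 1 - wx) *
           (if (dj == 1) wy else 1 - wy) *
           (if (dk == 1) wz else 1 - wz)
      id <- (i0 + di + 1) + n * (j0 + dj) + n * n * (k0 + dk)
      qa[id] <- qa[id] + q[a] * w
    }
  }
  qa
}

#' Trilinear interpolation of a grid field at arbitrary points
#' @param phi node values (length npoints^3)
#' @param g grid_spec
#' @param pts m x 3 matrix
#' @return numeric vector; NA where a point is outside the grid
#' @export
interp_grid <- function(phi, g, pts) {
  pts <- matrix(pts, ncol = 3)
  ax <- grid_axes(g)
  n <- g$npoints
  h <- g$spacing
  out <- rep(NA_real_, nrow(pts))
  for (a in seq_len(nrow(pts))) {
    fx <- (pts[a, 1] - ax$x[1]) / h
    fy <- (pts[a, 2] - ax$y[1]) / h
    fz <- (pts[a, 3] - ax$z[1]) / h
    i0 <- floor(fx); j0 <- floor(fy); k0 <- floor(fz)
    if (i0 < 0 || i0 > n - 2 || j0 < 0 || j0 > n - 2 ||
        k0 < 0 || k0 > n - 2) next
    wx <- fx - i0; wy <- fy - j0; wz <- fz - k0
    v <- 0
    for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
      w <- (if (di == 1) wx else 1 - wx) *
           (if (dj == 1) wy else 1 - wy) *
           (if (dk == 1) wz else 1 - wz)
      id <- (i0 + di + 1) + n * (j0 + dj) + n * n * (k0 + dk)
      v <- v + w * phi[id]
    }
    out[a] <- v
  }
  out
}

# Debye-Hueckel analytic potential (kT/e) of source charges at points;
# bc_eps is the ambient (far-field) dielectric
.dh_potential <- function(pts, pos, q, env, bc_eps = env$eps_water) {
  pts <- matrix(pts, ncol = 3)
  pos <- matrix(pos, ncol = 3)
  C <- coulomb_kT(env$temperature)
  kap <- debye_kappa(env$ionic_strength, env$temperature, bc_eps)
  out <- numeric(nrow(pts))
  for (a in seq_along(q)) {
    d <- sqrt((pts[, 1] - pos[a, 1])^2 + (pts[, 2] - pos[a, 2])^2 +
              (pts[, 3] - pos[a, 3])^2)
    d <- pmax(d, 0.5)
    out <- out + C * q[a] * exp(-kap * d) / (bc_eps * d)
  }
  out
}

# indices of the 6 boundary faces of an n^3 grid
.face_index <- function(n) {
  idx <- array(seq_len(n^3), dim = c(n, n, n))
  unique(c(idx[1, , ], idx[n, , ], idx[, 1, ], idx[, n, ],
           idx[, , 1], idx[, , n]))
}

.grid_points <- function(g, ids) {
  n <- g$npoints
  ax <- grid_axes(g)
  k <- (ids - 1) %/% (n * n)
  j <- ((ids - 1) %/% n) %% n
  i <- (ids - 1) %% n
  cbind(ax$x[i + 1], ax$y[j + 1], ax$z[k + 1])
}
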