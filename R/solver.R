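## Linearized Poisson-Boltzmann solver: single-grid SOR solve, multi-level
## grid focusing, transfer energies, and the analytic Born oracle.

#' Solve the linearized Poisson-Boltzmann equation on one grid
#'
#' Successive over-relaxation with red-black ordering on the
#' finite-difference discretization.  Boundary condition is the analytic
#' Debye-Hueckel potential of the source charges (or values supplied in
#' \code{phi0}).  The potential is returned in kT/e at the environment
#' temperature.
#'
#' @param pos n x 3 matrix of source-charge positions
#' @param q source charges (e)
#' @param dmap dielectric map from \code{\link{build_dielectric_map}}
#' @param tol relative-update convergence tolerance; \code{tol = 0} runs
#'   exactly \code{maxit} sweeps, making the solve strictly linear in the
#'   sources (used by the superposition tests)
#' @param maxit maximum SOR sweeps
#' @param omega over-relaxation factor; default near-optimal
#'   \code{2/(1+sin(pi/n))}
#' @param phi0 optional initial/boundary field (length npoints^3); boundary
#'   nodes are held fixed at these values
#' @return list with phi (node potentials), grid, iters, rel_update
#' @export
solve_lpb <- function(pos, q, dmap, tol = 1e-6, maxit = 10000,
                      omega = NULL, phi0 = NULL) {
  g <- dmap$grid
  n <- g$npoints
  if (is.null(omega)) omega <- 2 / (1 + sin(pi / n))
  qgrid <- spread_charges(g, pos, q)
  C <- coulomb_kT(dmap$env$temperature)
  src <- 4 * pi * C * qgrid / g$spacing
  if (is.null(phi0)) {
    phi <- numeric(n^3)
    face <- .face_index(n)
    phi[face] <- .dh_potential(.grid_points(g, face), pos, q, dmap$env,
                               dmap$bc_eps %||% dmap$env$eps_water)
  } else {
    stopifnot(length(phi0) == n^3)
    phi <- phi0
  }
  res <- cpp_sor_lpb(phi, dmap$epsx, dmap$epsy, dmap$epsz, dmap$lam, src,
                     n, n, n, omega, tol, maxit)
  if (tol > 0 && res$rel_update > tol) {
    stop("LPB solver did not converge in ", maxit,
         " sweeps (last relative update ", signif(res$rel_update, 3), ")")
  }
  list(phi = res$phi, grid = g, iters = res$iters,
       rel_update = res$rel_update, env = dmap$env)
}

#' Multi-level focused LPB solve
#'
#' Solves on a coarse grid spanning the whole context plus margin, then on
#' successively finer grids centered on the focus region, each taking its
#' boundary values (and initial guess) by interpolation from the coarser
#' solution.
#'
#' @param pos,q source-charge positions and values
#' @param context atoms defining the dielectric (data frame or
#'   \code{pdb_structure}); may be NULL together with \code{uniform_eps}
#' @param env a \code{\link{pka_env}}
#' @param focus_center 3-vector; default centroid of the source charges
#' @param levels strictly decreasing grid spacings, coarse to fine
#' @param margin_coarse margin around the context at the coarsest level (A)
#' @param margin_fine margin around the source charges at finer levels (A)
#' @param cap_n maximum nodes per axis at any level
#' @param uniform_eps optional uniform dielectric (context ignored)
#' @param grids optional explicit list of \code{grid_spec}s (one per
#'   level), e.g. to reuse identical grids across two contexts
#' @param tol,maxit solver controls per level
#' @return object of class \code{"focus_result"}: list of per-level
#'   solutions (finest last) plus the grids used
#' @export
focus_solve <- function(pos, q, context, env,
                        focus_center = NULL,
                        levels = c(2.5, 1.0, 0.3),
                        margin_coarse = 20, margin_fine = 10,
                        cap_n = 97, uniform_eps = NULL, grids = NULL,
                        tol = 1e-6, maxit = 10000) {
  if (any(diff(levels) >= 0)) stop("levels must be strictly decreasing")
  pos <- matrix(pos, ncol = 3)
  if (inherits(context, "pdb_structure")) context <- context$atoms
  if (is.null(focus_center)) focus_center <- colMeans(pos)
  if (is.null(grids)) {
    grids <- .focus_grids(pos, context, focus_center, levels,
                          margin_coarse, margin_fine, cap_n)
  }
  sols <- vector("list", length(grids))
  for (l in seq_along(grids)) {
    g <- grids[[l]]
    dmap <- build_dielectric_map(context, env, g, uniform_eps = uniform_eps)
    if (l == 1) {
      sols[[l]] <- solve_lpb(pos, q, dmap, tol = tol, maxit = maxit)
    } else {
      prev <- sols[[l - 1]]
      .check_nested(grids[[l - 1]], g)
      pts <- .grid_points(g, seq_len(g$npoints^3))
      phi0 <- interp_grid(prev$phi, prev$grid, pts)
      if (anyNA(phi0)) stop("finer grid extends beyond the coarser grid")
      sols[[l]] <- solve_lpb(pos, q, dmap, tol = tol, maxit = maxit,
                             phi0 = phi0)
    }
  }
  structure(list(levels = sols, grids = grids, pos = pos, q = q, env = env),
            class = "focus_result")
}

.focus_grids <- function(pos, context, focus_center, levels,
                         margin_coarse, margin_fine, cap_n) {
  allpts <- if (!is.null(context) && nrow(context) > 0) {
    rbind(pos, as.matrix(context[, c("x", "y", "z")]))
  } else pos
  lo <- apply(allpts, 2, min); hi <- apply(allpts, 2, max)
  grids <- vector("list", length(levels))
  for (l in seq_along(levels)) {
    h <- levels[l]
    if (l == 1) {
      center <- (lo + hi) / 2
      ext <- max(hi - lo) + 2 * margin_coarse
    } else {
      center <- focus_center
      half <- max(abs(sweep(pos, 2, focus_center))) + margin_fine
      ext <- 2 * half
      # the finer grid must sit strictly inside the coarser one
      gprev <- grids[[l - 1]]
      lim <- grid_extent(gprev) / 2 - gprev$spacing
      maxoff <- max(abs(center - gprev$center))
      ext <- min(ext, 2 * (lim - maxoff))
      if (ext <= 4 * h) stop("focus region does not fit inside the ",
                             "coarser grid")
    }
    np <- ceiling(ext / h) + 1
    if (np %% 2 == 0) np <- np + 1
    np <- min(np, if (cap_n %% 2 == 1) cap_n else cap_n - 1)
    grids[[l]] <- grid_spec(center, h, max(np, 9))
  }
  grids
}

.check_nested <- function(gc, gf) {
  half_c <- grid_extent(gc) / 2
  half_f <- grid_extent(gf) / 2
  if (any(abs(gf$center - gc$center) + half_f > half_c + 1e-9)) {
    stop("finer grid extends beyond the coarser grid")
  }
  invisible(TRUE)
}

#' Evaluate a focused potential at points
#'
#' Each point is evaluated on the finest level that contains it with at
#' least one cell of clearance from the level boundary, falling back to
#' coarser levels outside the focus region.
#'
#' @param fr a \code{focus_result}
#' @param pts m x 3 matrix
#' @return potential in kT/e
#' @export
eval_potential <- function(fr, pts) {
  pts <- matrix(pts, ncol = 3)
  out <- rep(NA_real_, nrow(pts))
  for (l in rev(seq_along(fr$levels))) {
    g <- fr$levels[[l]]$grid
    half <- grid_extent(g) / 2 - g$spacing
    inl <- abs(pts[, 1] - g$center[1]) < half &
           abs(pts[, 2] - g$center[2]) < half &
           abs(pts[, 3] - g$center[3]) < half & is.na(out)
    if (any(inl)) {
      out[inl] <- interp_grid(fr$levels[[l]]$phi, g,
                              pts[inl, , drop = FALSE])
    }
  }
  if (anyNA(out)) stop("point(s) outside even the coarsest grid")
  out
}

#' Grid electrostatic energy of charges in a focused potential
#'
#' 0.5 * sum q_i phi(r_i), in kT.  Contains the grid self-energy, which
#' cancels between two solves on identical grids.
#' @param fr focus_result
#' @param pos,q charge set (defaults to the source set of \code{fr})
#' @keywords internal
grid_energy <- function(fr, pos = fr$pos, q = fr$q) {
  0.5 * sum(q * eval_potential(fr, pos))
}

#' Electrostatic transfer energy of a charging process between contexts
#'
#' Solves for the site charges in context A and context B on identical
#' grids (so the grid self-energy cancels exactly) and returns the energy
#' difference \code{E_A - E_B} in kT.  Context B is typically the model
#' compound in water, context A the protein.
#'
#' @param site_pos,site_q site charge set (identical atoms in both
#'   contexts)
#' @param context_A,context_B dielectric-defining atom sets (data frame /
#'   \code{pdb_structure}), or a list \code{list(uniform_eps = e)}
#' @param env \code{\link{pka_env}}
#' @param levels focusing spacings
#' @param ... further arguments to \code{\link{focus_solve}}
#' @return energy difference in kT
#' @export
transfer_energy <- function(site_pos, site_q, context_A, context_B, env,
                            levels = c(2.5, 1.0, 0.3), ...) {
  site_pos <- matrix(site_pos, ncol = 3)
  ua <- if (is.list(context_A) && !is.data.frame(context_A) &&
            !inherits(context_A, "pdb_structure")) context_A$uniform_eps
  ub <- if (is.list(context_B) && !is.data.frame(context_B) &&
            !inherits(context_B, "pdb_structure")) context_B$uniform_eps
  ca <- if (is.null(ua)) context_A else NULL
  cb <- if (is.null(ub)) context_B else NULL
  if (inherits(ca, "pdb_structure")) ca <- ca$atoms
  if (inherits(cb, "pdb_structure")) cb <- cb$atoms
  ctx_all <- rbind(if (!is.null(ca)) ca[, c("x", "y", "z")],
                   if (!is.null(cb)) cb[, c("x", "y", "z")])
  fc <- colMeans(site_pos)
  dummy <- if (!is.null(ctx_all)) {
    data.frame(x = ctx_all$x, y = ctx_all$y, z = ctx_all$z, radius = 1)
  } else NULL
  grids <- .focus_grids(site_pos, dummy, fc, levels, 20, 10, 97)
  fa <- focus_solve(site_pos, site_q, ca, env, fc, levels,
                    uniform_eps = ua, grids = grids, ...)
  fb <- focus_solve(site_pos, site_q, cb, env, fc, levels,
                    uniform_eps = ub, grids = grids, ...)
  grid_energy(fa) - grid_energy(fb)
}

#' Analytic Born transfer energy
#'
#' Energy of moving a charged sphere from a bulk dielectric
#' \code{eps_out} into a bulk dielectric \code{eps_in}:
#' \code{(q^2 / 2r) (1/eps_in - 1/eps_out)} in Coulomb units, returned in
#' kT.  Positive when moving into the lower dielectric.  Used as the
#' closed-form oracle for the grid solver.
#'
#' @param q charge (e)
#' @param r sphere radius (Angstrom)
#' @param eps_in,eps_out destination and origin dielectric constants
#' @param temperature Kelvin
#' @return energy in kT
#' @export
born_energy <- function(q, r, eps_in, eps_out, temperature = 300) {
  if (r <= 0) stop("radius must be positive")
  if (eps_in < 1 || eps_out < 1) stop("dielectric constants must be >= 1")
  coulomb_kT(temperature) * q^2 / (2 * r) * (1 / eps_in - 1 / eps_out)
}
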