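C300 <- contpka:::coulomb_kT(300)

test_that("Born formula oracle behaves analytically", {
  expect_equal(born_energy(1, 2, 80, 80), 0)
  expect_gt(born_energy(1, 2, 4, 80), 0)   # penalty entering low dielectric
  expect_lt(born_energy(1, 2, 80, 4), 0)
  expect_equal(born_energy(1, 2, 4, 80),
               C300 / 4 * (1 / 4 - 1 / 80))
  expect_error(born_energy(1, -1, 4, 80), "radius")
  expect_error(born_energy(1, 2, 0.5, 80), "dielectric")
})

test_that("uniform-dielectric solution matches Coulomb and screened Coulomb", {
  g <- grid_spec(c(0, 0, 0), 0.5, 41)
  d0 <- build_dielectric_map(NULL, env_nosalt(), g, uniform_eps = 80)
  sol <- solve_lpb(matrix(0, 1, 3), 1, d0, tol = 1e-8)
  for (r in c(2, 3, 5, 8)) {
    phi <- interp_grid(sol$phi, g, matrix(c(r, 0, 0), 1))
    expect_equal(phi, C300 / (80 * r), tolerance = 0.025,
                 label = paste("Coulomb at r =", r))
  }
  env1 <- pka_env(ionic_strength = 0.1)
  d1 <- build_dielectric_map(NULL, env1, g, uniform_eps = 80)
  sol1 <- solve_lpb(matrix(0, 1, 3), 1, d1, tol = 1e-8)
  kap <- debye_kappa(0.1, 300, 80)
  for (r in c(3, 5, 8)) {
    phi <- interp_grid(sol1$phi, g, matrix(c(0, r, 0), 1))
    expect_equal(phi, C300 * exp(-kap * r) / (80 * r), tolerance = 0.02,
                 label = paste("screened at r =", r))
  }
  # zero source -> identically zero potential
  sol0 <- solve_lpb(matrix(0, 1, 3), 0, d0, tol = 1e-8)
  expect_equal(max(abs(sol0$phi)), 0)
})

test_that("solution is strictly linear in the sources (superposition)", {
  g <- grid_spec(c(0, 0, 0), 1.0, 25)
  dm <- build_dielectric_map(NULL, env_nosalt(), g, uniform_eps = 80)
  p1 <- matrix(c(-3, 0, 0), 1); p2 <- matrix(c(4, 1, 0), 1)
  # fixed sweep count keeps the iteration affine in the source
  s1 <- solve_lpb(p1, 1, dm, tol = 0, maxit = 300)
  s2 <- solve_lpb(p2, -0.5, dm, tol = 0, maxit = 300)
  s12 <- solve_lpb(rbind(p1, p2), c(1, -0.5), dm, tol = 0, maxit = 300)
  relerr <- max(abs(s12$phi - (s1$phi + s2$phi))) / max(abs(s12$phi))
  expect_lt(relerr, 1e-10)
})

test_that("dielectric map marks sphere interiors and ion exclusion", {
  env <- pka_env(ionic_strength = 0.1)
  g <- grid_spec(c(0, 0, 0), 0.5, 33)
  # no atoms: uniform solvent, uniform screening
  d0 <- build_dielectric_map(NULL, env, g)
  expect_true(all(d0$epsx == 80))
  expect_true(all(d0$lam > 0))
  # single 2 A sphere: protein-dielectric edge fraction tracks the
  # analytic volume within one voxel shell
  atom <- data.frame(x = 0, y = 0, z = 0, radius = 2)
  d1 <- build_dielectric_map(atom, env, g)
  inner <- sum(d1$epsx < 10) * g$spacing^3
  vol <- 4 / 3 * pi * 2^3
  shell <- 4 * pi * 2^2 * g$spacing
  expect_lt(abs(inner - vol), shell)
  # ions excluded within radius + stern of the atom
  pts <- .grid_points_for_test(g)
  r <- sqrt(rowSums(pts^2))
  expect_true(all(d1$lam[r < 2 + env$ion_exclusion - 0.1] == 0))
  expect_true(all(d1$lam[r > 2 + env$ion_exclusion + 0.1] > 0))
  # union of overlapping spheres: no interstitial solvent (brute force)
  two <- data.frame(x = c(-1, 1), y = 0, z = 0, radius = 2)
  d2 <- build_dielectric_map(two, env, g)
  mid <- which(abs(pts[, 1]) < 0.9 & abs(pts[, 2]) < 0.9 &
                 abs(pts[, 3]) < 0.9)
  expect_true(all(d2$epsx[mid] < 4.5))
  expect_error(build_dielectric_map(data.frame(x = 90, y = 0, z = 0,
                                               radius = 1), env, g),
               "cover")
})

test_that("grid focusing is consistent and converges with refinement", {
  env <- env_nosalt()
  # one level degenerates to a plain solve
  f1 <- focus_solve(matrix(0, 1, 3), 1, NULL, env, levels = 1.0,
                    uniform_eps = 80, cap_n = 25)
  g <- f1$grids[[1]]
  d <- build_dielectric_map(NULL, env, g, uniform_eps = 80)
  s <- solve_lpb(matrix(0, 1, 3), 1, d)
  expect_equal(f1$levels[[1]]$phi, s$phi)
  # focused 2-level solution matches a single fine-grid solution
  f2 <- focus_solve(matrix(0, 1, 3), 1, NULL, env, levels = c(2.0, 0.5),
                    uniform_eps = 80, cap_n = 61)
  pts <- cbind(seq(1, 5, 0.5), 0, 0)
  fine_only <- focus_solve(matrix(0, 1, 3), 1, NULL, env, levels = 0.5,
                           uniform_eps = 80, cap_n = 61)
  expect_equal(eval_potential(f2, pts), eval_potential(fine_only, pts),
               tolerance = 0.01)
  expect_error(focus_solve(matrix(0, 1, 3), 1, NULL, env,
                           levels = c(1, 2), uniform_eps = 80),
               "decreasing")
  # Born-sphere error shrinks monotonically with the finest spacing
  atom <- data.frame(x = 0, y = 0, z = 0, radius = 2)
  ref <- born_energy(1, 2, 4, 80)
  errs <- vapply(c(1.0, 0.5, 0.3), function(h) {
    e <- transfer_energy(matrix(0, 1, 3), 1, list(uniform_eps = 4),
                         atom, env, levels = c(2.5, h))
    abs(e - ref) / ref
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("transfer energies cancel self-terms and scale quadratically", {
  env <- env_nosalt()
  atom <- data.frame(x = 0, y = 0, z = 0, radius = 2)
  e0 <- transfer_energy(matrix(0, 1, 3), 1, atom, atom, env,
                        levels = c(2.0, 1.0))
  expect_equal(e0, 0)
  e1 <- transfer_energy(matrix(0, 1, 3), 1, list(uniform_eps = 4), atom,
                        env, levels = c(2.5, 1.0, 0.5))
  e2 <- transfer_energy(matrix(0, 1, 3), 2, list(uniform_eps = 4), atom,
                        env, levels = c(2.5, 1.0, 0.5))
  expect_equal(e2 / e1, 4, tolerance = 1e-6)  # linear response
})

test_that("two-dielectric cavity energy matches the Kirkwood closed form", {
  # unit charge at the center of a perfect 8 A sphere: reaction-field
  # difference against the bare 1.6 A atom cavity is analytic
  env <- env_nosalt()
  site <- data.frame(x = 0, y = 0, z = 0, radius = 1.6)
  cavity <- rbind(site, data.frame(x = 0, y = 0, z = 0, radius = 8))
  e <- transfer_energy(matrix(0, 1, 3), 1, cavity, site, env,
                       levels = c(2.5, 1.0, 0.4), cap_n = 81)
  ref <- C300 / 2 * (1 / 80 - 1 / 4) * (1 / 8 - 1 / 1.6)
  expect_equal(e, ref, tolerance = 0.02)
})

test_that("site-site couplings are reciprocal before symmetrization", {
  toy <- make_toy_multisite(list(site_kinds = c("ASP", "TYR"),
                                 distances = 8, seed = 9))
  sys <- pka_system(toy$structure, env = env_nosalt(), uniform_eps = 80,
                    levels = c(2.0, 1.0))
  expect_lt(sys$W_asymmetry, 0.05)
  expect_equal(diag(sys$W), rep(0, nrow(sys$sites)))
  expect_equal(sys$W, t(sys$W))
})

test_that("zero ionic strength reduces the LPB operator to Poisson", {
  g <- grid_spec(c(0, 0, 0), 1.0, 21)
  d0 <- build_dielectric_map(NULL, env_nosalt(), g, uniform_eps = 80)
  expect_true(all(d0$lam == 0))
  dmanual <- d0
  dmanual$lam <- rep(0, g$npoints^3)   # explicit Poisson operator
  s1 <- solve_lpb(matrix(0, 1, 3), 1, d0, tol = 0, maxit = 200)
  s2 <- solve_lpb(matrix(0, 1, 3), 1, dmanual, tol = 0, maxit = 200)
  expect_identical(s1$phi, s2$phi)
})
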