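test_that("single-site populations follow Henderson-Hasselbalch exactly", {
  sys <- stat_system(pkintr = 6.2)
  for (pH in c(4, 6.2, 8.5)) {
    expect_equal(unname(exact_populations(sys, pH = pH)),
                 1 / (1 + 10^(pH - 6.2)), tolerance = 1e-12)
  }
  # curve monotonically decreasing in pH
  cur <- titration_curves(sys, seq(2, 12, 0.5))
  expect_true(all(diff(cur[, 1]) < 0))
})

test_that("uncoupled sites titrate independently; coupling matches the 4-state sum", {
  sys0 <- stat_system(pkintr = c(5, 9))
  m <- exact_populations(sys0, pH = 7)
  expect_equal(unname(m), c(1 / (1 + 10^2), 1 / (1 + 10^-2)),
               tolerance = 1e-12)
  # two acids, W = 3 pK: against the hand-written 4-state partition sum
  W <- matrix(c(0, 3, 3, 0), 2)
  sys3 <- stat_system(pkintr = c(6, 7), W = W)
  got <- exact_populations(sys3, pH = 7)
  oracle <- brute_force_means(c(6, 7), W, xref = c(1, 1), pH = 7)
  expect_equal(unname(got), unname(oracle), tolerance = 1e-10)
})

test_that("microstate energies match independent brute-force sums", {
  sys <- stat_system(pkintr = 6)
  lnkT <- log(10)
  expect_equal(microstate_energy(sys, 1, pH = 6),
               microstate_energy(sys, 0, pH = 6))
  e0 <- microstate_energy(sys, 1, pH = 7) - microstate_energy(sys, 0, pH = 7)
  e1 <- microstate_energy(sys, 1, pH = 7, bias = 1) -
    microstate_energy(sys, 0, pH = 7, bias = 1)
  expect_equal(e0 - e1, lnkT)   # +1 pK bias shifts the gap by ln10 kT
  # 3-site toy with couplings: all 8 microstates
  W <- matrix(c(0, 1.2, -0.4, 1.2, 0, 0.7, -0.4, 0.7, 0), 3)
  xref <- c(1L, 0L, 1L)
  sys3 <- stat_system(pkintr = c(4.5, 10.1, 7.7), W = W, xref = xref,
                      kind = c("acid", "base", "acid"))
  for (x1 in 0:1) for (x2 in 0:1) for (x3 in 0:1) {
    x <- c(x1, x2, x3)
    P <- x - xref
    hand <- log(10) * (sum(x * (7 - c(4.5, 10.1, 7.7))) +
                         W[1, 2] * P[1] * P[2] + W[1, 3] * P[1] * P[3] +
                         W[2, 3] * P[2] * P[3])
    expect_equal(microstate_energy(sys3, x, pH = 7), hand,
                 tolerance = 1e-12)
  }
})

test_that("Monte Carlo converges to the exact populations on seeded toys", {
  set.seed(99)
  for (n in c(2, 5, 8, 12)) {
    pk <- runif(n, 3, 11)
    W <- matrix(0, n, n)
    W[upper.tri(W)] <- runif(n * (n - 1) / 2, -1.5, 2.5)
    W <- W + t(W)
    xref <- sample(0:1, n, replace = TRUE)
    sys <- stat_system(pk, W, xref)
    exact <- exact_populations(sys)
    runs <- vapply(1:4, function(k)
      mc_sample(sys, seed = 1000 + k, n_sweeps = 20000)$mean,
      numeric(n))
    mcm <- rowMeans(runs)
    se <- pmax(apply(runs, 1, sd) / sqrt(4), 0.004)
    expect_true(all(abs(mcm - exact) < 3 * se),
                label = paste("n =", n, "max dev",
                              signif(max(abs(mcm - exact) / se), 3), "SE"))
  }
})

test_that("Monte Carlo trajectories are bit-reproducible for a fixed seed", {
  sys <- stat_system(pkintr = c(5, 8), W = matrix(c(0, 1, 1, 0), 2))
  a <- mc_sample(sys, seed = 7, n_sweeps = 5000)
  b <- mc_sample(sys, seed = 7, n_sweeps = 5000)
  expect_identical(a$mean, b$mean)
  expect_identical(a$final, b$final)
  c2 <- mc_sample(sys, seed = 8, n_sweeps = 5000)
  expect_false(identical(a$mean, c2$mean))
})

test_that("bias titration recovers intrinsic pKa and matches enumeration", {
  sys <- stat_system(pkintr = 6.35)
  tr <- titrate_pka(sys, 1, seed = 1)
  expect_equal(tr$pka, 6.35, tolerance = 0.05)
  # Henderson-Hasselbalch limit: far below the pKa the site is protonated
  expect_gt(unname(exact_populations(sys, pH = 6.35 - 5)), 0.999)
  # 2-site coupled toy: titration root against the enumeration root
  W <- matrix(c(0, 2.2, 2.2, 0), 2)
  sys2 <- stat_system(pkintr = c(6.8, 7.4), W = W)
  tr2 <- titrate_pka(sys2, 1, seed = 1)
  f <- function(bias)
    exact_populations(sys2, bias = c(bias, 0))[1] - 0.5
  root <- uniroot(f, c(-20, 20), tol = 1e-9)$root
  expect_equal(tr2$pka, 7 - root, tolerance = 0.1)
  # MC and exact titration agree
  tr2mc <- titrate_pka(sys2, 1, method = "mc", seed = 3,
                       n_sweeps = 20000)
  expect_equal(tr2mc$pka, tr2$pka, tolerance = 0.1)
  expect_error(titrate_pka(stat_system(60), 1, seed = 1, bracket = 30),
               "not bracketed")
})

test_that("a nearby fixed charge shifts pKa with the correct sign", {
  rc <- mini_rc_dark()
  sys <- rc$sys
  # place a -1 perturbation on the cofactor ring nearest the phenol
  rk <- paste(sys$atoms$chain, sys$atoms$resseq, sep = ":")
  pa <- which(rk == "P:10")
  neg <- apply_background(sys, pa, rep(-1 / length(pa), length(pa)))
  i <- which(sys$sites$site_id == "A:1:TYR")
  expect_gt(neg$pkintr[i], sys$pkintr[i])   # acid pKa raised
  pos <- apply_background(sys, pa, rep(+1 / length(pa), length(pa)))
  j <- which(sys$sites$site_id == "A:3:HIS:NE2")
  expect_lt(pos$pkintr[j], sys$pkintr[j])   # base proton affinity lowered
})

test_that("titration is invariant under relabeling and rigid motion", {
  env0 <- env_nosalt()
  toy <- make_toy_multisite(list(site_kinds = c("ASP", "TYR"),
                                 distances = 8, eps_context = "sphere",
                                 seed = 9))
  s1 <- toy$structure
  sys1 <- pka_system(s1, env = env0, levels = c(2.5, 1.0))
  p1 <- titrate_pka(sys1, "A:1:ASP", seed = 1)$pka
  # permuted site table
  sites <- detect_titratable_sites(assign_state_charges(s1))
  sysP <- pka_system(s1, env = env0, sites = sites[rev(seq_len(nrow(sites))), ],
                     levels = c(2.5, 1.0))
  expect_equal(titrate_pka(sysP, "A:1:ASP", seed = 1)$pka, p1,
               tolerance = 1e-9)
  # rotated + translated copy
  s2 <- s1
  R <- contpka:::rot_matrix(0.4, 0.9, 1.7)
  xyz <- as.matrix(s1$atoms[, c("x", "y", "z")]) %*% t(R)
  s2$atoms$x <- xyz[, 1] + 11.3
  s2$atoms$y <- xyz[, 2] - 6.1
  s2$atoms$z <- xyz[, 3] + 3.3
  sys2 <- pka_system(s2, env = env0, levels = c(2.5, 1.0))
  expect_equal(titrate_pka(sys2, "A:1:ASP", seed = 1)$pka, p1,
               tolerance = 0.05)
})

test_that("redox sites follow the Nernst relation", {
  expect_equal(mv_per_pk(300), log(10) * 8.617333262e-5 * 300 * 1000)
  r <- make_model_compound("RDX")
  sys <- pka_system(r, levels = c(2.0, 1.0), redox_ref = c("A:1" = -120))
  rm <- redox_midpoint(sys, 1, seed = 1)
  expect_equal(rm$midpoint_mV, -120, tolerance = 0.05 * mv_per_pk(300))
  # midpoint shift from a fixed -1 charge at distance r in uniform eps 4
  env4 <- pka_env(eps_protein = 4, eps_water = 4, ionic_strength = 0)
  two <- contpka:::.new_structure(rbind(
    contpka:::.make_fragment("RDX", "A", 1),
    contpka:::.make_fragment("ASP", "B", 2, origin = c(9, 0, 0))))
  s2 <- assign_state_charges(two)
  sites <- detect_titratable_sites(s2)
  sys2 <- pka_system(s2, env = env4, sites = sites[sites$resname == "RDX", ],
                     uniform_eps = 4, levels = c(2.0, 1.0, 0.5))
  # reduced state carries -1: a -1 neighbor destabilizes it, shifting the
  # midpoint negative by the Coulomb coupling
  at <- s2$atoms
  x1 <- which(at$name == "X1")
  dq <- -at$charge
  keep <- abs(dq) > 0 & seq_along(dq) != x1
  base <- apply_background(sys2, which(keep), dq[keep])  # zero background
  dmv <- (sys2$pkintr[1] - base$pkintr[1]) * mv_per_pk(300)
  # closed form: sum over ASP charges of C q / (eps r), converted to mV
  C <- contpka:::coulomb_kT(300)
  r <- sqrt((at$x - at$x[x1])^2 + (at$y - at$y[x1])^2 +
              (at$z - at$z[x1])^2)
  ref <- sum(-C * (-at$charge[keep]) / (4 * r[keep])) / log(10) *
    mv_per_pk(300)
  expect_equal(dmv, ref, tolerance = abs(ref) * 0.05)
  expect_lt(dmv, 0)
})
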