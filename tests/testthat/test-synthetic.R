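test_that("model compounds recover their reference pKa in pure water", {
  # context cancellation makes this exact up to the bisection tolerance
  mc <- make_model_compound("Glu")
  sys <- pka_system(mc, levels = c(2.0, 1.0))
  expect_equal(unname(intrinsic_pka(sys)), 4.4, tolerance = 1e-6)
  expect_equal(titrate_pka(sys, 1, seed = 1)$pka, 4.4, tolerance = 0.05)
  expect_error(make_model_compound("Pro"), "unsupported")
})

test_that("every generator output survives round-trip and charge assignment", {
  gens <- list(
    make_model_compound("Asp"), make_model_compound("His"),
    make_toy_multisite(list(site_kinds = c("ASP", "LYS"),
                            distances = 6, seed = 2))$structure,
    resolve_conformer(make_mini_rc(seed = 3)$structure, "A")
  )
  for (s in gens) {
    tf <- tempfile(fileext = ".pdb")
    write_structure(s, tf)
    s2 <- read_structure(tf)
    expect_equal(nrow(s2$atoms), nrow(s$atoms))
    expect_equal(round(s2$atoms$x, 3), round(s$atoms$x, 3))
    charged <- assign_state_charges(s2)   # no waivers needed
    expect_true(all(charged$atoms$radius > 0))
  }
})

test_that("the committed toy fixture is regenerable from its seed", {
  committed <- system.file("extdata", "toy_two_asp_seed3.pdb",
                           package = "contpka")
  toy <- make_toy_multisite(list(site_kinds = c("ASP", "ASP"),
                                 distances = 10, seed = 3))
  tf <- tempfile(fileext = ".pdb")
  write_structure(toy$structure, tf)
  expect_identical(readLines(tf), readLines(committed))
})

test_that("toy expectations are self-consistent with their geometry", {
  env0 <- env_nosalt()
  toy <- make_toy_multisite(list(site_kinds = c("ASP", "ASP"),
                                 distances = 10, seed = 3))
  ex <- toy_expectations(toy$structure, "uniform", env0)
  # independent recomputation of the closed form from the stored geometry
  C <- contpka:::coulomb_kT(env0$temperature)
  expect_equal(ex$W_coulomb, C / (80 * ex$r * log(10)), tolerance = 1e-12)
  expect_error(make_toy_multisite(list(site_kinds = c("ASP", "ASP"),
                                       distances = 2, seed = 1)),
               ">= 3")
  expect_error(make_toy_multisite(list(site_kinds = "ASP")), "seed")
})

test_that("solver couplings match the toy closed form within 5 percent", {
  env0 <- env_nosalt()
  toy <- make_toy_multisite(list(site_kinds = c("ASP", "ASP"),
                                 distances = 10, seed = 3))
  sys <- pka_system(toy$structure, env = env0, uniform_eps = 80,
                    levels = c(2.0, 1.0, 0.5))
  ex <- toy_expectations(toy$structure, "uniform", env0)
  expect_equal(sys$W[1, 2], ex$W_coulomb, tolerance = 0.05)
  expect_gt(sys$W[1, 2], 0)    # two acids: mutual deprotonation penalized
  # far-separated sites decouple (under physiological screening)
  far <- make_toy_multisite(list(site_kinds = c("ASP", "ASP"),
                                 distances = 60, seed = 3))
  sysf <- pka_system(far$structure, env = pka_env(), uniform_eps = 80,
                     levels = c(2.5, 1.0))
  expect_lt(abs(sysf$W[1, 2]), 0.02)
})

test_that("a single-site toy titrates to its reference", {
  toy <- make_toy_multisite(list(site_kinds = "TYR", seed = 6))
  sys <- pka_system(toy$structure, levels = c(2.0, 1.0))
  expect_equal(titrate_pka(sys, 1, seed = 1)$pka, 9.6, tolerance = 0.05)
})

test_that("burial in a low-dielectric sphere raises an acid's pKa", {
  toy <- make_toy_multisite(list(site_kinds = "TYR",
                                 eps_context = "sphere", seed = 21))
  sys <- pka_system(toy$structure, env = env_nosalt(),
                    levels = c(2.5, 1.0))
  expect_gt(unname(intrinsic_pka(sys)), 9.6)  # anion desolvation penalty
})

test_that("the mini reaction center is deterministic and has the stated geometry", {
  rc1 <- make_mini_rc(seed = 5)
  rc2 <- make_mini_rc(seed = 5)
  t1 <- tempfile(fileext = ".pdb"); t2 <- tempfile(fileext = ".pdb")
  write_structure(rc1$structure, t1)
  write_structure(rc2$structure, t2)
  expect_identical(readLines(t1), readLines(t2))
  rc3 <- make_mini_rc(seed = 6)
  t3 <- tempfile(fileext = ".pdb")
  write_structure(rc3$structure, t3)
  expect_false(identical(readLines(t1), readLines(t3)))
  sA <- resolve_conformer(rc1$structure, "A")
  sB <- resolve_conformer(rc1$structure, "B")
  expect_equal(measure_distance(sA, "A:1:OH", "A:2:OG1"),
               rc1$expectations$d_OO_A, tolerance = 1e-6)
  expect_equal(measure_distance(sB, "A:1:OH", "A:2:OG1"),
               rc1$expectations$d_OO_B, tolerance = 0.01)
})

test_that("the cofactor hole lowers the phenol pKa, ordered by proximity", {
  dark <- mini_rc_dark()
  i <- which(dark$sys$sites$site_id == "A:1:TYR")
  expect_lt(dark$sys_hole$pkintr[i], dark$sys$pkintr[i])
  # 2:1 vs 1:2 split at asymmetric distances: the ring nearer the phenol
  # dominates, so 2:1 (larger share on the near ring) shifts more
  rc <- mini_rc_fixture()
  h21 <- apply_special_pair_hole(dark$structure, rc$cofactors[["PA"]],
                                 rc$cofactors[["PB"]], c(2, 1))
  h12 <- apply_special_pair_hole(dark$structure, rc$cofactors[["PA"]],
                                 rc$cofactors[["PB"]], c(1, 2))
  s21 <- apply_background(dark$sys, h21$idx, h21$dq)
  s12 <- apply_background(dark$sys, h12$idx, h12$dq)
  expect_lt(s21$pkintr[i], s12$pkintr[i])
  # direction agrees with the closed-form Coulomb band
  expect_lt(rc$expectations$dpk_hole_coulomb_eps_protein, 0)
})
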