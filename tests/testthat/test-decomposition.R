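test_that("contribution rows split exactly into side chain plus backbone", {
  rc <- mini_rc_dark()
  tb <- contribution_table(rc$sys, "A:1:TYR", state_label = "P0_Ydark")
  expect_s3_class(tb, "contribution_table")
  amino <- !is.na(tb$side_chain)
  expect_true(any(amino))
  expect_equal(tb$side_chain[amino] + tb$backbone[amino],
               tb$total[amino], tolerance = 1e-9)
  # cofactors and waters report total only
  cf <- tb[tb$resname %in% c("CFR", "HOH"), ]
  expect_true(all(is.na(cf$side_chain)))
  # sorted by |total|
  expect_true(all(diff(abs(tb$total)) <= 1e-12))
  # zero-charge groups (packing shell carries none) never appear
  expect_false("Z:500" %in% tb$group)
  # the target's own residue is not a row and is rejected explicitly
  expect_false("A:1" %in% tb$group)
  expect_error(residue_contribution(rc$sys, "A:1:TYR", "A:1"),
               "own residue")
  # all-zero group gives an exactly zero contribution
  z <- residue_contribution(rc$sys, "A:1:TYR", "Z:500")
  expect_equal(unname(z[["total"]]), 0)
})

test_that("group contributions are additive to the full background shift", {
  # with the protonation pattern frozen at the neutral reference, the
  # target's frozen-pattern pKa equals pkintr; removing every other
  # group's charge must shift it by exactly the summed contributions
  rc <- mini_rc_dark()
  sys <- rc$sys
  i <- which(sys$sites$site_id == "A:1:TYR")
  n <- nrow(sys$sites)
  mean_ref <- sys$sites$xref
  tb <- contribution_table(sys, i, mean_x = mean_ref)
  # zero out all groups outside the target residue
  rk <- paste(sys$atoms$chain, sys$atoms$resseq, sep = ":")
  outside <- which(rk != sys$sites$key[i])
  qeq <- contpka:::.equilibrium_charges(sys, mean_ref)
  sys0 <- apply_background(sys, outside, -qeq[outside])
  direct <- sys$pkintr[i] - sys0$pkintr[i]
  expect_equal(sum(tb$total), direct, tolerance = 1e-6)
  # and the titration route agrees within the decomposition tolerance
  frozen <- rep(TRUE, n); frozen[i] <- FALSE
  tr <- titrate_pka(sys, i, seed = 1,
                    freeze_pattern = list(frozen = frozen,
                                          xfix = mean_ref))
  expect_equal(tr$pka, sys$pkintr[i], tolerance = 0.3)
})

test_that("hydrogen-bond detection finds ideal donors and flags missing H", {
  w1 <- place_polar_hydrogens(make_model_compound("HOH", hydrogens = FALSE))
  at2 <- contpka:::.make_fragment("HOH", "W", 2, origin = c(2.9, 0, 0))
  s <- contpka:::.new_structure(rbind(w1$atoms[, colnames(at2)], at2))
  s <- place_polar_hydrogens(s)
  hb <- hbond_network(s)
  expect_equal(nrow(hb), 1)
  expect_equal(hb$d_DA, 2.9, tolerance = 0.05)
  expect_gte(hb$angle, 120)
  # rigid-body invariance of the edge set
  s2 <- s
  R <- contpka:::rot_matrix(1.0, 0.2, 2.4)
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")]) %*% t(R)
  s2$atoms$x <- xyz[, 1] + 5; s2$atoms$y <- xyz[, 2] - 3
  s2$atoms$z <- xyz[, 3] + 1
  hb2 <- hbond_network(s2)
  expect_equal(paste(hb2$donor, hb2$acceptor),
               paste(hb$donor, hb$acceptor))
  expect_equal(hb2$d_HA, hb$d_HA, tolerance = 1e-9)
  bare <- make_model_compound("HOH", hydrogens = FALSE)
  expect_error(hbond_network(bare), "place_polar_hydrogens")
})

test_that("the dark-state network runs hydroxyl -> imidazole and flips on deprotonation", {
  dark <- mini_rc_dark()
  hb_dark <- hbond_network(dark$structure)
  key_dark <- paste(hb_dark$donor, hb_dark$donor_atom, "->",
                    hb_dark$acceptor, hb_dark$acceptor_atom)
  expect_true("A:2 OG1 -> A:3 ND1" %in% key_dark)
  dep <- mini_rc_deprot()
  hb_dep <- hbond_network(dep$structure)
  key_dep <- paste(hb_dep$donor, hb_dep$donor_atom, "->",
                   hb_dep$acceptor, hb_dep$acceptor_atom)
  # hydroxyl now donates to the phenolate; the imidazole N-H donates back
  expect_true("A:2 OG1 -> A:1 OH" %in% key_dep)
  expect_true("A:3 ND1 -> A:2 OG1" %in% key_dep)
  expect_false("A:2 OG1 -> A:1 OH" %in% key_dark)
})

test_that("state comparison reports pKa deltas, changed groups and edge turnover", {
  dark <- mini_rc_dark()
  dep <- mini_rc_deprot()
  pk_dark <- c("A:1:TYR" = titrate_pka(dark$sys_hole, "A:1:TYR",
                                       seed = 1)$pka)
  pk_dep <- c("A:1:TYR" = titrate_pka(dep$sys_hole, "A:1:TYR",
                                      seed = 1)$pka)
  tb_dark <- contribution_table(dark$sys_hole, "A:1:TYR",
                                state_label = "P+_Ydark")
  tb_dep <- contribution_table(dep$sys_hole, "A:1:TYR",
                               state_label = "P+_Ydeprot")
  cmp <- compare_states(
    list(Pp_Ydark = pk_dark, Pp_Ydeprot = pk_dep),
    tables = list(Pp_Ydark = tb_dark, Pp_Ydeprot = tb_dep),
    networks = list(Pp_Ydark = hbond_network(dark$structure),
                    Pp_Ydeprot = hbond_network(dep$structure)))
  expect_lt(cmp$dpka["A:1:TYR", "Pp_Ydeprot"], 0)
  expect_true(!is.null(cmp$edges_gained) || !is.null(cmp$edges_lost))
  # identical states give all-zero deltas and no turnover
  same <- compare_states(list(a = pk_dark, b = pk_dark),
                         tables = list(a = tb_dark, b = tb_dark),
                         networks = list(a = hbond_network(dark$structure),
                                         b = hbond_network(dark$structure)))
  expect_true(all(same$dpka == 0))
  expect_null(same$edges_gained)
  expect_null(same$changed_groups)
  expect_error(compare_states(list(a = c(X = 1), b = c(Y = 2))),
               "share no sites")
})

test_that("perturbing one group changes exactly its contribution row", {
  rc <- mini_rc_dark()
  sys <- rc$sys
  mean_ref <- sys$sites$xref
  tb1 <- contribution_table(sys, "A:1:TYR", mean_x = mean_ref)
  rk <- paste(sys$atoms$chain, sys$atoms$resseq, sep = ":")
  wat <- which(rk == "W:2001" & sys$atoms$element == "O")
  sys2 <- apply_background(sys, wat, 0.2)
  tb2 <- contribution_table(sys2, "A:1:TYR", mean_x = mean_ref)
  m1 <- setNames(tb1$total, tb1$group)
  m2 <- setNames(tb2$total, tb2$group)
  common <- intersect(names(m1), names(m2))
  changed <- common[abs(m1[common] - m2[common]) > 1e-9]
  expect_equal(changed, "W:2001")
})
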