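# Shared fixtures.  Expensive electrostatic systems are built once per
# test run and cached; everything is generated in code from fixed seeds.

.fx <- new.env(parent = emptyenv())

# hand-written 4-atom PDB with an altloc pair and three waters
fixture_pdb_lines <- function() {
  c(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00           C",
    "ATOM      3  CB AALA A   1      12.564   7.243  -4.850  0.50  0.00           C",
    "ATOM      4  CB BALA A   1      12.901   6.862  -5.063  0.50  0.00           C",
    "ATOM      5  C   ALA A   1      10.521   6.080  -4.113  1.00  0.00           C",
    "ATOM      6  O   ALA A   1       9.343   6.243  -4.447  1.00  0.00           O",
    "HETATM    7  O   HOH W   1       2.000   0.000   0.000  1.00  0.00           O",
    "HETATM    8  O   HOH W   2       6.000   0.000   0.000  1.00  0.00           O",
    "HETATM    9  O   HOH W   3       0.000   5.000   0.000  1.00  0.00           O",
    "END"
  )
}

fixture_structure <- function() read_structure(fixture_pdb_lines())

# grid-level test environments
env_nosalt <- function() pka_env(ionic_strength = 0)

# mini reaction-center fixture and its two state systems, built once.
# Test-scale focusing levels (2.5/1.0 A) keep the suite fast; the
# acceptance script uses the same fixture.
mini_rc_fixture <- function() {
  if (is.null(.fx$rc)) .fx$rc <- make_mini_rc(seed = 1)
  .fx$rc
}

mini_rc_dark <- function() {
  if (is.null(.fx$dark)) {
    rc <- mini_rc_fixture()
    st <- list("A:3" = "HSE")
    s <- resolve_conformer(rc$structure, "A", "Y_dark")
    s <- apply_water_policy(s, "W:2001")
    s <- place_polar_hydrogens(s, assignment = st)
    s <- assign_state_charges(s, assignment = st)
    sys <- pka_system(s, levels = c(2.5, 1.0), cap_n = 81)
    hole <- apply_special_pair_hole(s, rc$cofactors[["PA"]],
                                    rc$cofactors[["PB"]])
    .fx$dark <- list(structure = s, sys = sys,
                     sys_hole = apply_background(sys, hole$idx, hole$dq),
                     hole = hole)
  }
  .fx$dark
}

mini_rc_deprot <- function() {
  if (is.null(.fx$deprot)) {
    rc <- mini_rc_fixture()
    st <- list("A:1" = "deprot", "A:3" = "HSP")
    s <- resolve_conformer(rc$structure, "B", "Y_deprot")
    s <- apply_water_policy(s, "W:2001")
    s <- place_polar_hydrogens(s, assignment = st)
    s <- assign_state_charges(s, assignment = st)
    sys <- pka_system(s, levels = c(2.5, 1.0), cap_n = 81)
    hole <- apply_special_pair_hole(s, rc$cofactors[["PA"]],
                                    rc$cofactors[["PB"]])
    .fx$deprot <- list(structure = s, sys = sys,
                       sys_hole = apply_background(sys, hole$idx, hole$dq),
                       hole = hole)
  }
  .fx$deprot
}

# bare statistical-mechanics system (no solver): intrinsic pKas and
# couplings given directly, for unit tests of the microstate layer
stat_system <- function(pkintr, W = NULL, xref = NULL, kind = NULL,
                        excl_pairs = matrix(integer(), 0, 2),
                        excl_pen = numeric(0), pH = 7) {
  n <- length(pkintr)
  if (is.null(W)) W <- matrix(0, n, n)
  if (is.null(xref)) xref <- rep(1L, n)
  if (is.null(kind)) kind <- rep("acid", n)
  sites <- data.frame(site_id = paste0("S", seq_len(n)),
                      key = paste0("K", seq_len(n)),
                      resname = "TOY", subsite = NA, kind = kind,
                      pka_ref = pkintr, xref = xref,
                      stringsAsFactors = FALSE)
  structure(list(sites = sites, pkintr = pkintr, W = W,
                 excl_pairs = excl_pairs, excl_pen = excl_pen,
                 env = pka_env(pH = pH)),
            class = "pka_system")
}

.grid_points_for_test <- function(g) {
  contpka:::.grid_points(g, seq_len(g$npoints^3))
}

single_atom_structure <- function(resname) {
  at <- data.frame(serial = 1, name = "C1", element = "C",
                   resname = resname, chain = "A", resseq = 1,
                   altloc = "", x = 0, y = 0, z = 0, occupancy = 1,
                   het = FALSE, radius = NA_real_, charge = 0,
                   stringsAsFactors = FALSE)
  structure(list(atoms = at, conformer_label = NA,
                 waters_kept = character()), class = "pdb_structure")
}

.make_two_residue_ser <- function() {
  ser <- contpka:::.make_fragment("SER", "A", 1)
  # carboxylate acceptor (no competing protons) with OD1 off the CB-OG
  # axis, reachable by the hydroxyl rotation cone
  asp <- contpka:::.make_fragment("ASP", "B", 2, origin = c(4.31, 3.5, 0),
                                  rot = contpka:::rot_matrix(0, 0, pi))
  contpka:::.new_structure(rbind(ser, asp))
}

# independent Boltzmann oracle: direct loop over all microstates using
# plain arithmetic (no shared code with exact_populations)
brute_force_means <- function(pkintr, W, xref, pH, bias = 0,
                              excl_pairs = NULL, excl_pen = 30) {
  n <- length(pkintr)
  bias <- rep_len(bias, n)
  states <- as.matrix(expand.grid(rep(list(0:1), n)))
  wts <- numeric(nrow(states))
  for (r in seq_len(nrow(states))) {
    x <- states[r, ]
    e <- sum(x * (pH - pkintr - bias))
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i < j) e <- e + W[i, j] * (x[i] - xref[i]) * (x[j] - xref[j])
    }
    if (!is.null(excl_pairs)) {
      for (p in seq_len(nrow(excl_pairs))) {
        e <- e + excl_pen * (1 - x[excl_pairs[p, 1]]) *
          (1 - x[excl_pairs[p, 2]])
      }
    }
    wts[r] <- 10^(-e)
  }
  colSums(states * wts) / sum(wts)
}
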