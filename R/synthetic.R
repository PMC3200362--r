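## Synthetic structure generators: model compounds (truncated side-chain
## fragments), multi-site toys with analytic expectations, and a
## miniature reaction-center-like bundle (an ionizable phenol between a
## cofactor pair carrying a 2:1 cation hole, with hydroxyl and imidazole
## hydrogen-bond partners).  All fixtures are plain PDB structures so the
## full pipeline, not a shortcut path, is exercised.

.new_structure <- function(atoms) {
  atoms$serial <- seq_len(nrow(atoms))
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, conformer_label = NA_character_,
                 waters_kept = .water_ids(atoms)),
            class = "pdb_structure")
}

.atom_rows <- function(names, elements, xyz, resname, chain, resseq,
                       het = FALSE, altloc = "") {
  xyz <- matrix(xyz, ncol = 3, byrow = TRUE)
  data.frame(serial = NA_integer_, name = names, element = elements,
             resname = resname, chain = chain, resseq = resseq,
             altloc = altloc, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             occupancy = if (nzchar(altloc[1])) 0.5 else 1.0,
             het = het, radius = NA_real_, charge = 0,
             stringsAsFactors = FALSE)
}

# hexagonal ring coordinates in the xy-plane
.ring_xy <- function(n, radius, phase = 0) {
  ang <- phase + 2 * pi * (seq_len(n) - 1) / n
  cbind(radius * cos(ang), radius * sin(ang), 0)
}

# side-chain fragment geometries in local coordinates.  Chemistry-grade
# ideality is not required: charges, not bond lengths, drive the model.
.fragment_geometry <- function(resname) {
  switch(resname,
    ASP = {
      cb <- c(0, 0, 0); cg <- c(1.52, 0, 0)
      list(names = c("CB", "HB1", "HB2", "CG", "OD1", "OD2"),
           elements = c("C", "H", "H", "C", "O", "O"),
           xyz = rbind(cb, c(-0.36, 0.51, 0.89), c(-0.36, 0.51, -0.89),
                       cg, cg + c(0.59, 1.10, 0), cg + c(0.59, -1.10, 0)))
    },
    ASN = {
      cb <- c(0, 0, 0); cg <- c(1.52, 0, 0)
      list(names = c("CB", "HB1", "HB2", "CG", "OD1", "ND2"),
           elements = c("C", "H", "H", "C", "O", "N"),
           xyz = rbind(cb, c(-0.36, 0.51, 0.89), c(-0.36, 0.51, -0.89),
                       cg, cg + c(0.59, 1.10, 0), cg + c(0.62, -1.16, 0)))
    },
    GLU = {
      cb <- c(0, 0, 0); cg <- c(1.26, 0.86, 0); cd <- c(2.52, 0, 0)
      list(names = c("CB", "HB1", "HB2", "CG", "HG1", "HG2", "CD",
                     "OE1", "OE2"),
           elements = c("C", "H", "H", "C", "H", "H", "C", "O", "O"),
           xyz = rbind(cb, c(-0.51, -0.51, 0.76), c(-0.51, -0.51, -0.76),
                       cg, cg + c(0, 0.62, 0.89), cg + c(0, 0.62, -0.89),
                       cd, cd + c(0.59, -1.10, 0), cd + c(1.24, 0.15, 0)))
    },
    SER = {
      cb <- c(0, 0, 0)
      list(names = c("CB", "HB1", "HB2", "OG"),
           elements = c("C", "H", "H", "O"),
           xyz = rbind(cb, c(-0.36, 0.51, 0.89), c(-0.36, 0.51, -0.89),
                       c(1.42, 0, 0)))
    },
    THR = {
      cb <- c(0, 0, 0)
      list(names = c("CB", "HB", "OG1", "CG2", "HG21", "HG22", "HG23"),
           elements = c("C", "H", "O", "C", "H", "H", "H"),
           xyz = rbind(cb, c(-0.36, -1.0, 0.2), c(1.42, 0, 0),
                       c(-0.70, 0.9, -1.0),
                       c(-1.78, 0.9, -1.0), c(-0.35, 1.9, -1.0),
                       c(-0.35, 0.45, -1.93)))
    },
    CYS = {
      cb <- c(0, 0, 0)
      list(names = c("CB", "HB1", "HB2", "SG"),
           elements = c("C", "H", "H", "S"),
           xyz = rbind(cb, c(-0.36, 0.51, 0.89), c(-0.36, 0.51, -0.89),
                       c(1.81, 0, 0)))
    },
    LYS = {
      ch <- rbind(c(0, 0, 0), c(1.26, 0.86, 0), c(2.52, 0, 0),
                  c(3.78, 0.86, 0), c(5.00, 0.05, 0))
      hs <- function(p, up) rbind(p + c(0, up * 0.62, 0.89),
                                  p + c(0, up * 0.62, -0.89))
      list(names = c("CB", "CG", "CD", "CE", "NZ",
                     "HB1", "HB2", "HG1", "HG2", "HD1", "HD2",
                     "HE1", "HE2"),
           elements = c("C", "C", "C", "C", "N", rep("H", 8)),
           xyz = rbind(ch, hs(ch[1, ], -1), hs(ch[2, ], 1),
                       hs(ch[3, ], -1), hs(ch[4, ], 1)))
    },
    ARG = {
      cb <- c(0, 0, 0); cg <- c(1.26, 0.86, 0); cd <- c(2.52, 0, 0)
      ne <- c(3.72, 0.80, 0); cz <- c(4.98, 0.28, 0)
      nh1 <- place_internal(cd, ne, cz, 1.33, 120, 0)
      nh2 <- place_internal(cd, ne, cz, 1.33, 120, 180)
      hs <- function(p, up) rbind(p + c(0, up * 0.62, 0.89),
                                  p + c(0, up * 0.62, -0.89))
      list(names = c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2",
                     "HB1", "HB2", "HG1", "HG2", "HD1", "HD2"),
           elements = c("C", "C", "C", "N", "C", "N", "N", rep("H", 6)),
           xyz = rbind(cb, cg, cd, ne, cz, nh1, nh2,
                       hs(cb, -1), hs(cg, 1), hs(cd, -1)))
    },
    TYR = {
      ring <- .ring_xy(6, 1.39)           # CG CD1 CE1 CZ CE2 CD2
      hr <- .ring_xy(6, 2.47)
      cb <- c(2.90, 0, 0)
      oh <- c(-2.75, 0, 0)
      list(names = c("CG", "CD1", "CE1", "CZ", "CE2", "CD2",
                     "HD1", "HE1", "HE2", "HD2", "CB", "HB1", "HB2",
                     "OH"),
           elements = c(rep("C", 6), rep("H", 4), "C", "H", "H", "O"),
           xyz = rbind(ring, hr[2, ], hr[3, ], hr[5, ], hr[6, ],
                       cb, cb + c(0.51, 0.51, 0.89),
                       cb + c(0.51, -0.51, 0.89), oh))
    },
    HIS = {
      ring <- .ring_xy(5, 1.17, phase = pi / 2)  # CG ND1 CE1 NE2 CD2
      out <- .ring_xy(5, 2.25, phase = pi / 2)
      cb <- ring[1, ] + c(ring[1, 1:2], 0) / sqrt(sum(ring[1, 1:2]^2)) *
        1.50
      list(names = c("CG", "ND1", "CE1", "NE2", "CD2", "HE1", "HD2",
                     "CB", "HB1", "HB2"),
           elements = c("C", "N", "C", "N", "C", "H", "H", "C", "H",
                        "H"),
           xyz = rbind(ring, out[3, ], out[5, ], cb,
                       cb + c(0.51, 0.51, 0.89),
                       cb + c(0.51, -0.51, 0.89)))
    },
    CFR = list(names = paste0("C", 1:12), elements = rep("C", 12),
               xyz = .ring_xy(12, 3.0)),
    RDX = list(names = "X1", elements = "X", xyz = rbind(c(0, 0, 0))),
    HOH = list(names = "O", elements = "O", xyz = rbind(c(0, 0, 0))),
    stop("unsupported fragment kind: ", resname)
  )
}

.make_fragment <- function(resname, chain = "A", resseq = 1,
                           origin = c(0, 0, 0), rot = diag(3),
                           het = FALSE, altloc = "") {
  geo <- .fragment_geometry(resname)
  xyz <- t(rot %*% t(matrix(geo$xyz, ncol = 3)))
  xyz <- sweep(xyz, 2, origin, "+")
  .atom_rows(geo$names, geo$elements, t(xyz), resname, chain, resseq,
             het = het || resname %in% c("HOH", "RDX"), altloc = altloc)
}

#' Build a model compound for a titratable residue type
#'
#' Truncated side-chain fragment (capped at the beta carbon) whose two
#' charge states are resolvable by the shipped library.  Running
#' \code{\link{pka_system}} on a model compound alone in water recovers
#' the reference pKa exactly by construction (the protein and model
#' contexts coincide, so every electrostatic term cancels).
#'
#' @param kind residue type: Asp, Glu, Lys, Arg, Cys, Tyr, His (also Ser,
#'   Thr, Asn, HOH for non-titratable fragments)
#' @param chain,resseq placement identifiers
#' @param hydrogens place polar hydrogens
#' @return a \code{pdb_structure}
#' @export
make_model_compound <- function(kind, chain = "A", resseq = 1,
                                hydrogens = TRUE) {
  resname <- toupper(kind)
  supported <- c("ASP", "GLU", "LYS", "ARG", "CYS", "TYR", "HIS", "SER",
                 "THR", "ASN", "HOH", "RDX")
  if (!resname %in% supported) {
    stop("unsupported model-compound kind: ", kind)
  }
  s <- .new_structure(.make_fragment(resname, chain, resseq))
  if (hydrogens) s <- place_polar_hydrogens(s)
  s$conformer_label <- paste0(resname, "_model")
  s
}

#' Build a multi-site toy system with analytic expectations
#'
#' Places side-chain fragments at controlled separations along a line
#' (with seeded random orientations) and records closed-form Coulomb
#' expectations for the site-site couplings, for use as test oracles.
#'
#' @param spec list with elements: \code{site_kinds} (character vector of
#'   residue types), \code{distances} (separations between consecutive
#'   sites, Angstrom, all >= 3; scalar recycled), \code{eps_context}
#'   \code{"uniform"} (solvent dielectric everywhere) or \code{"sphere"}
#'   (a filler shell creates a low-dielectric interior), \code{seed}
#'   (mandatory)
#' @return list: \code{structure} (a \code{pdb_structure}),
#'   \code{expectations} (data frame of pairwise closed-form couplings,
#'   filled in against the realized geometry by
#'   \code{\link{toy_expectations}}), \code{spec}
#' @export
make_toy_multisite <- function(spec) {
  stopifnot(!is.null(spec$site_kinds), !is.null(spec$seed))
  kinds <- toupper(spec$site_kinds)
  n <- length(kinds)
  d <- spec$distances
  if (is.null(d)) d <- 10
  d <- rep_len(d, max(n - 1, 1))
  if (any(d < 3)) stop("inter-site distances must be >= 3 Angstrom")
  eps_context <- if (is.null(spec$eps_context)) "uniform" else
    spec$eps_context
  set.seed(spec$seed)
  xs <- c(0, cumsum(d))[seq_len(n)]
  rows <- list()
  for (i in seq_len(n)) {
    rot <- rot_matrix(runif(1, 0, 2 * pi), runif(1, 0, 2 * pi),
                      runif(1, 0, 2 * pi))
    rows[[i]] <- .make_fragment(kinds[i], chain = "A", resseq = i,
                                origin = c(xs[i], 0, 0), rot = rot)
  }
  if (eps_context == "sphere") {
    center <- c(mean(range(xs)), 0, 0)
    rad <- diff(range(xs)) / 2 + 6
    sh <- .filler_shell(center, rad, n_atoms = 80, seed = spec$seed + 1,
                        avoid = do.call(rbind, rows), resseq0 = n + 1)
    rows <- c(rows, list(sh))
  }
  s <- .new_structure(do.call(rbind, rows))
  s <- place_polar_hydrogens(s)
  s$conformer_label <- "toy"
  list(structure = s, spec = spec,
       expectations = toy_expectations(s, eps_context))
}

#' Closed-form coupling expectations for a toy structure
#'
#' Point-charge Coulomb couplings between the charge-difference centroids
#' of every site pair, in pK units, in a uniform dielectric.  Recomputed
#' from the realized geometry so the record can never drift from the
#' structure.
#'
#' @param s toy \code{pdb_structure}
#' @param eps_context "uniform" or "sphere" (expectations only for
#'   uniform)
#' @param env environment for temperature/dielectric
#' @return data frame site_i, site_j, r (A), W_coulomb (pK)
#' @export
toy_expectations <- function(s, eps_context = "uniform",
                             env = pka_env()) {
  s2 <- assign_state_charges(s)
  sites <- detect_titratable_sites(s2)
  cm <- .site_charge_model(s2, sites, default_charge_library())
  pos <- lapply(cm$D, function(Di) {
    p <- as.matrix(s2$atoms[Di$idx, c("x", "y", "z")])
    colSums(p * abs(Di$dq)) / sum(abs(Di$dq))
  })
  out <- list()
  C <- coulomb_kT(env$temperature)
  kap <- debye_kappa(env$ionic_strength, env$temperature, env$eps_water)
  for (i in seq_len(nrow(sites))) for (j in seq_len(nrow(sites))) {
    if (j <= i || sites$key[i] == sites$key[j]) next
    r <- sqrt(sum((pos[[i]] - pos[[j]])^2))
    neti <- sum(cm$D[[i]]$dq); netj <- sum(cm$D[[j]]$dq)
    W <- if (eps_context == "uniform") {
      C * neti * netj * exp(-kap * r) / (env$eps_water * r * log(10))
    } else NA_real_
    out[[length(out) + 1]] <- data.frame(
      site_i = sites$site_id[i], site_j = sites$site_id[j], r = r,
      W_coulomb = W, stringsAsFactors = FALSE)
  }
  if (length(out) == 0) return(data.frame(site_i = character(),
                                          site_j = character(),
                                          r = numeric(),
                                          W_coulomb = numeric()))
  do.call(rbind, out)
}

# solid block of neutral packing carbons creating a low-dielectric
# interior: a cubic lattice (spacing 1.9 A, fully overlapping van der
# Waals spheres) clipped to a ball, with clearance around the core atoms
# and a small seeded jitter so no two fixtures are crystallographically
# identical
.filler_shell <- function(center, radius, n_atoms = Inf, seed,
                          avoid = NULL, resseq0 = 100, chain = "Z",
                          spacing = 1.9, clearance = 2.5) {
  set.seed(seed)
  ax <- seq(-radius, radius, by = spacing)
  pts <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  pts <- pts[rowSums(pts^2) <= radius^2, , drop = FALSE]
  pts <- sweep(pts, 2, center, "+")
  pts <- pts + matrix(stats::runif(length(pts), -0.15, 0.15),
                      nrow(pts), 3)
  if (!is.null(avoid) && nrow(avoid) > 0) {
    keep <- vapply(seq_len(nrow(pts)), function(i) {
      min((avoid$x - pts[i, 1])^2 + (avoid$y - pts[i, 2])^2 +
            (avoid$z - pts[i, 3])^2) > clearance^2
    }, logical(1))
    pts <- pts[keep, , drop = FALSE]
  }
  if (nrow(pts) > n_atoms) pts <- pts[seq_len(n_atoms), , drop = FALSE]
  .atom_rows(paste0("C", seq_len(nrow(pts))), rep("C", nrow(pts)),
             t(pts), "CFR", chain, resseq0, het = TRUE)
}

#' Build the miniature reaction-center-like bundle
#'
#' A ~200-atom synthetic structure emulating the studied motif: an
#' ionizable phenol (Tyr analog) with two side-chain conformers (A =
#' "dark", farther from the hydroxyl partner; B = "light", closer), a
#' threonine-like hydroxyl and a histidine-like imidazole forming a
#' hydrogen-bond chain, a crystal water, an acidic residue, and two rigid
#' neutral cofactor rings at unequal distances that can carry a +1 hole
#' split 2:1 (\code{\link{apply_special_pair_hole}}).  A shell of neutral
#' packing atoms creates the low-dielectric interior.
#'
#' @param seed integer; the same seed regenerates a bit-identical
#'   structure
#' @return list: \code{structure} (unresolved altlocs A/B),
#'   \code{expectations} (closed-form Coulomb estimate of the hole-induced
#'   phenol pKa shift and geometry facts), \code{cofactors} (residue keys
#'   of the two rings)
#' @export
make_mini_rc <- function(seed = 1) {
  set.seed(seed)
  rows <- list()
  # phenol: conformer A with hydroxyl O at the origin and the ring toward
  # +x; conformer B shifted toward the hydroxyl partner (-x)
  tyrA <- .make_fragment("TYR", "A", 1, origin = c(2.75, 0, 0),
                         altloc = "A")
  shift <- c(-1.1, 0.15, 0)
  tyrB <- tyrA
  tyrB$altloc <- "B"
  tyrB[, c("x", "y", "z")] <- tyrB[, c("x", "y", "z")] +
    rep(shift, each = nrow(tyrB))
  rows$tyrA <- tyrA; rows$tyrB <- tyrB
  # threonine-like hydroxyl: OG1 at 4.4 A from the conformer-A hydroxyl O
  # (3.3 A from the conformer-B position).  The CB-OG1 axis is tilted so
  # that both H-bond partners (phenol O and imidazole ND1) lie on the
  # hydroxyl hydrogen's rotation cone: the dihedral scan can then select
  # either partner depending on the protonation state.
  og1 <- c(-4.4, 0, 0)
  axis <- c(0.327, -0.206, 0.922)
  axis <- axis / sqrt(sum(axis^2))
  b0 <- pracma_cross(axis, c(0, 0, 1))
  b0 <- b0 / sqrt(sum(b0^2))
  c0 <- pracma_cross(axis, b0)
  rot_thr <- cbind(axis, b0, c0)
  rows$thr <- .make_fragment("THR", "A", 2, origin = og1 - 1.42 * axis,
                             rot = rot_thr)
  # imidazole: ND1 at H-bond range (~2.8 A) of the threonine hydroxyl,
  # placed off the CB-OG1 axis so the hydroxyl's rotation cone can reach
  # either the imidazole nitrogen or the phenolate oxygen (mirrored ring
  # keeps the CB stub pointing away from the phenol)
  theta <- -85 * pi / 180
  his_rot <- rot_matrix(0, 0, theta) %*% diag(c(1, -1, 1))
  rows$his <- .make_fragment("HIS", "A", 3, origin = c(-2.84, -3.68, 0),
                             rot = his_rot)
  # crystal water near the phenol oxygen
  rows$wat <- .make_fragment("HOH", "W", 2001, origin = c(-0.4, 2.9, 0.4))
  # acidic residue ~7 A from the phenol oxygen
  rows$asp <- .make_fragment("ASP", "A", 4, origin = c(-0.6, -6.8, 3.2),
                             rot = rot_matrix(0.4, 0.3, 1.2))
  # cofactor rings at unequal distances from the phenol oxygen
  pa_c <- c(3.4, 5.6, 3.4); pb_c <- c(2.0, -7.5, -6.5)
  rows$pa <- .make_fragment("CFR", "P", 10, origin = pa_c,
                            rot = rot_matrix(0.3, 0.8, 0.1), het = TRUE)
  rows$pb <- .make_fragment("CFR", "P", 11, origin = pb_c,
                            rot = rot_matrix(1.1, 0.2, 0.7), het = TRUE)
  core <- do.call(rbind, rows)
  shell <- .filler_shell(c(-0.5, 0, 0), 12.0, seed = seed + 7,
                         avoid = core, resseq0 = 500)
  s <- .new_structure(rbind(core, shell))
  # geometry facts + closed-form estimate of the hole effect
  oA <- c(0, 0, 0)
  dA <- sqrt(sum((pa_c - oA)^2))
  dB <- sqrt(sum((pb_c - oA)^2))
  env <- pka_env()
  C <- coulomb_kT(env$temperature)
  dpk_hole <- -C / log(10) / env$eps_protein *
    (2 / 3 / dA + 1 / 3 / dB)
  list(structure = s,
       cofactors = c(PA = "P:10", PB = "P:11"),
       expectations = list(
         d_OO_A = 4.4, d_OO_B = 4.4 + shift[1],
         d_hole_A = dA, d_hole_B = dB,
         dpk_hole_coulomb_eps_protein = dpk_hole,
         note = paste("dpk estimate assumes uniform protein dielectric;",
                      "use as a sign/band oracle only")))
}

#' Apply the photo-oxidized special-pair hole to a structure
#'
#' Adds +1 distributed over two cofactor groups with the given ratio
#' (default 2:1), spread uniformly over each group's atoms.
#'
#' @param s charged \code{pdb_structure}
#' @param key_a,key_b residue keys of the two groups
#' @param ratio weight pair
#' @return list: structure with modified charges, idx/dq of the
#'   perturbation (for \code{\link{apply_background}})
#' @export
apply_special_pair_hole <- function(s, key_a, key_b, ratio = c(2, 1)) {
  rk <- .residue_key(s$atoms)
  ia <- which(rk == key_a); ib <- which(rk == key_b)
  if (length(ia) == 0 || length(ib) == 0) {
    stop("cofactor group(s) not found: ", key_a, " / ", key_b)
  }
  csa <- charge_state("PA", setNames(s$atoms$charge[ia], s$atoms$name[ia]))
  csb <- charge_state("PB", setNames(s$atoms$charge[ib], s$atoms$name[ib]))
  out <- special_pair_cation(csa, csb, ratio)
  dq <- c(out[[1]]$atom_charges - csa$atom_charges,
          out[[2]]$atom_charges - csb$atom_charges)
  idx <- c(ia, ib)
  s$atoms$charge[idx] <- s$atoms$charge[idx] + dq
  list(structure = s, idx = idx, dq = unname(dq))
}
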