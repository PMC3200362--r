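## Deterministic ideal-geometry placement of polar hydrogens.
##
## The positions of non-rotatable polar hydrogens (backbone amide, Arg
## guanidinium, His ring, Asn amide) follow fixed ideal internal
## coordinates.  Rotatable polar hydrogens (Ser/Thr/Tyr/Cys hydroxyl-type,
## Lys ammonium, water) are oriented by an exhaustive dihedral grid search
## (15 degree steps by default) scored by a Coulomb term against
## provisional charges plus a distance-weighted hydrogen-bond bonus toward
## strong acceptors.  Heavy-atom coordinates are never modified.

# hydrogen topology: which polar hydrogens each residue needs.
# type "fixed": full internal coordinates; "scan": dihedral searched;
# "scan3": three protons sharing one scanned dihedral (staggered).
.H_TOPOLOGY <- list(
  SER = list(list(name = "HG1", heavy = "OG", b = "CB",
                  a = c("CA", "HB1"),
                  len = 0.96, ang = 108.5, type = "scan")),
  THR = list(list(name = "HG1", heavy = "OG1", b = "CB",
                  a = c("CA", "HB"),
                  len = 0.96, ang = 108.5, type = "scan")),
  TYR = list(list(name = "HH", heavy = "OH", b = "CZ", a = "CE1",
                  len = 0.96, ang = 108.0, type = "scan")),
  CYS = list(list(name = "HG1", heavy = "SG", b = "CB",
                  a = c("CA", "HB1"),
                  len = 1.34, ang = 96.0, type = "scan")),
  LYS = list(list(name = c("HZ1", "HZ2", "HZ3"), heavy = "NZ", b = "CE",
                  a = "CD", len = 1.04, ang = 109.5, type = "scan3")),
  ARG = list(
    list(name = "HE", heavy = "NE", b = "CZ", a = "NH1", len = 1.00,
         ang = 119.0, dih = 180, type = "fixed"),
    list(name = "HH11", heavy = "NH1", b = "CZ", a = "NE", len = 1.00,
         ang = 120.0, dih = 0, type = "fixed"),
    list(name = "HH12", heavy = "NH1", b = "CZ", a = "NE", len = 1.00,
         ang = 120.0, dih = 180, type = "fixed"),
    list(name = "HH21", heavy = "NH2", b = "CZ", a = "NE", len = 1.00,
         ang = 120.0, dih = 0, type = "fixed"),
    list(name = "HH22", heavy = "NH2", b = "CZ", a = "NE", len = 1.00,
         ang = 120.0, dih = 180, type = "fixed")),
  HIS = list(
    list(name = "HD1", heavy = "ND1", b = "CE1", a = "NE2", len = 1.00,
         ang = 125.5, dih = 180, type = "fixed"),
    list(name = "HE2", heavy = "NE2", b = "CE1", a = "ND1", len = 1.00,
         ang = 125.5, dih = 180, type = "fixed")),
  ASN = list(
    list(name = "HD21", heavy = "ND2", b = "CG", a = "OD1", len = 1.00,
         ang = 120.0, dih = 180, type = "fixed"),
    list(name = "HD22", heavy = "ND2", b = "CG", a = "OD1", len = 1.00,
         ang = 120.0, dih = 0, type = "fixed"))
)

.KNOWN_TOPOLOGY <- c(names(.H_TOPOLOGY), "HOH", "WAT", "TIP3", "TIP",
                     "GLY", "ALA", "ASP", "GLU", "ACE", "NME", "CFR",
                     "RDX", "PHE", "BNZ")

#' Place polar hydrogens at ideal geometry
#'
#' Adds missing polar hydrogens to every residue with a known topology.
#' Rotatable hydroxyl/ammonium/water hydrogens are oriented by a
#' deterministic dihedral grid search; see the package vignette for the
#' scoring model.  Non-hydrogen coordinates are returned bit-identical.
#'
#' @param s a resolved \code{pdb_structure}
#' @param mode placement policy; only \code{"ideal"} is implemented
#' @param assignment protonation-state assignment used for the provisional
#'   scoring charges (same format as \code{\link{assign_state_charges}});
#'   pass e.g. the deprotonated-tyrosine assignment so donors orient toward
#'   the anion
#' @param lib charge library for scoring charges
#' @param scan_step dihedral grid step in degrees
#' @param refine number of additional re-scan passes over rotatable
#'   hydrogens (network self-consistency)
#' @return \code{pdb_structure} with hydrogens appended after each
#'   residue's atoms
#' @export
place_polar_hydrogens <- function(s, mode = "ideal", assignment = list(),
                                  lib = default_charge_library(),
                                  scan_step = 15, refine = 1) {
  stopifnot(identical(mode, "ideal"))
  at <- s$atoms
  rk <- .residue_key(at)
  unknown <- setdiff(unique(at$resname), .KNOWN_TOPOLOGY)
  if (length(unknown) > 0) {
    stop("unknown residue topology for hydrogen placement: ",
         paste(unknown, collapse = ", "))
  }

  # provisional scoring charges (zero where assignment is impossible)
  qprov <- .provisional_charges(s, lib, assignment)

  newrows <- list()
  resorder <- unique(rk)
  get_xyz <- function(i) as.numeric(at[i, c("x", "y", "z")])

  for (key in resorder) {
    idx <- which(rk == key)
    resname <- at$resname[idx[1]]
    have <- at$name[idx]
    mkrow <- function(name, pos) {
      r <- at[idx[1], , drop = FALSE]
      r$serial <- NA_integer_; r$name <- name; r$element <- "H"
      r$x <- pos[1]; r$y <- pos[2]; r$z <- pos[3]
      r$occupancy <- 1; r$altloc <- ""; r$charge <- 0; r$radius <- NA_real_
      r
    }
    res_at <- function(nm) {
      # nm may list fallback frame atoms; first present wins
      for (cand in nm) {
        i <- idx[at$name[idx] == cand]
        if (length(i) == 1) return(get_xyz(i))
      }
      NULL
    }
    if (resname %in% c("HOH", "WAT", "TIP3", "TIP")) {
      if (!any(c("H1", "H2") %in% have)) {
        o <- res_at("OH2"); if (is.null(o)) o <- res_at("O")
        if (is.null(o)) stop("water ", key, " lacks an oxygen atom")
        hh <- .orient_water(o, at, qprov, idx, scan_step)
        newrows[[length(newrows) + 1]] <- mkrow("H1", hh$h1)
        newrows[[length(newrows) + 1]] <- mkrow("H2", hh$h2)
      }
      next
    }
    # backbone amide H
    if (resname %in% .AMINO && !any(c("HN", "H") %in% have) &&
        "N" %in% have && "CA" %in% have) {
      prev <- .previous_C(at, rk, key, idx)
      if (!is.null(prev)) {
        n <- res_at("N"); ca <- res_at("CA")
        d1 <- n - prev; d1 <- d1 / sqrt(sum(d1^2))
        d2 <- n - ca; d2 <- d2 / sqrt(sum(d2^2))
        dir <- d1 + d2; dir <- dir / sqrt(sum(dir^2))
        newrows[[length(newrows) + 1]] <- mkrow("HN", n + 1.0 * dir)
      }
    }
    defs <- .H_TOPOLOGY[[resname]]
    if (is.null(defs)) next
    for (d in defs) {
      if (all(d$name %in% have)) next
      heavy <- res_at(d$heavy); b <- res_at(d$b); a <- res_at(d$a)
      if (is.null(heavy) || is.null(b) || is.null(a)) {
        stop("residue ", resname, " ", key, " misses frame atoms for ",
             paste(d$name, collapse = "/"))
      }
      if (d$type == "fixed") {
        pos <- place_internal(a, b, heavy, d$len, d$ang, d$dih)
        newrows[[length(newrows) + 1]] <- mkrow(d$name, pos)
      } else {
        ndi <- if (d$type == "scan3") 3 else 1
        dih0 <- .scan_dihedral(a, b, heavy, d, at, qprov, idx, scan_step)
        for (m in seq_len(ndi)) {
          pos <- place_internal(a, b, heavy, d$len, d$ang,
                                dih0 + (m - 1) * 120)
          newrows[[length(newrows) + 1]] <- mkrow(d$name[m], pos)
        }
      }
    }
  }

  if (length(newrows) > 0) {
    nr <- do.call(rbind, newrows)
    at2 <- rbind(at, nr)
    rk2 <- .residue_key(at2)
    # keep residues contiguous in original order, hydrogens after heavies
    ord <- order(match(rk2, resorder),
                 c(rep(0, nrow(at)), rep(1, nrow(nr))),
                 c(seq_len(nrow(at)), seq_len(nrow(nr))))
    at2 <- at2[ord, , drop = FALSE]
    at2$serial <- seq_len(nrow(at2))
    rownames(at2) <- NULL
    s$atoms <- at2
  }
  # refinement passes: re-scan rotatable hydrogens against the completed
  # hydrogen network
  if (refine > 0 && length(newrows) > 0) {
    for (pass in seq_len(refine)) s <- .rescan_rotatable(s, assignment, lib,
                                                         scan_step)
  }
  s
}

.previous_C <- function(at, rk, key, idx) {
  chain <- at$chain[idx[1]]; resseq <- at$resseq[idx[1]]
  i <- which(at$chain == chain & at$resseq == resseq - 1 & at$name == "C")
  if (length(i) == 1) as.numeric(at[i, c("x", "y", "z")]) else NULL
}

.provisional_charges <- function(s, lib, assignment) {
  q <- rep(0, nrow(s$atoms))
  at <- s$atoms
  rk <- .residue_key(at)
  assignment <- unlist(assignment)
  for (key in unique(rk)) {
    idx <- which(rk == key)
    resname <- at$resname[idx[1]]
    if (resname %in% c("WAT", "TIP3", "TIP")) resname <- "HOH"
    state <- if (key %in% names(assignment)) assignment[[key]] else
      .DEFAULT_STATE[resname]
    if (is.null(state) || is.na(state)) next
    anames <- at$name[idx]
    if (resname == "HOH") anames[anames == "O"] <- "OH2"
    qq <- .residue_state_charges(lib, resname, state, anames)
    qq[is.na(qq)] <- 0
    q[idx] <- qq
  }
  q
}

# Coulomb + H-bond score of candidate hydrogen positions (rows of `pos`)
# against all atoms outside `self_idx`.  Lower is better.
.score_h <- function(pos, qh, at, qprov, self_idx) {
  other <- setdiff(seq_len(nrow(at)), self_idx)
  if (length(other) == 0) return(rep(0, nrow(pos)))
  ox <- at$x[other]; oy <- at$y[other]; oz <- at$z[other]
  qo <- qprov[other]
  acc <- qo <= -0.4
  vapply(seq_len(nrow(pos)), function(i) {
    dx <- ox - pos[i, 1]; dy <- oy - pos[i, 2]; dz <- oz - pos[i, 3]
    r <- sqrt(dx * dx + dy * dy + dz * dz)
    near <- r < 8
    r <- pmax(r, 0.8)
    elec <- sum(qh * qo[near] / r[near])
    hb <- -sum(acc[near] / pmax(r[near], 1.5)^2) * 0.15
    elec + hb
  }, numeric(1))
}

.scan_dihedral <- function(a, b, heavy, d, at, qprov, idx, step) {
  qh <- 0.40
  dihs <- seq(0, 360 - step, by = step)
  npos <- if (d$type == "scan3") 3 else 1
  best <- Inf; best_d <- 0
  for (dd in dihs) {
    sc <- 0
    for (m in seq_len(npos)) {
      pos <- matrix(place_internal(a, b, heavy, d$len, d$ang,
                                   dd + (m - 1) * 120), 1)
      sc <- sc + .score_h(pos, qh, at, qprov, idx)
    }
    if (sc < best - 1e-12) { best <- sc; best_d <- dd }
  }
  best_d
}

.orient_water <- function(o, at, qprov, self_idx, step) {
  # candidate H1 directions: toward each strong acceptor within 3.6 A,
  # plus axis fallbacks; H2 by dihedral scan at the ideal water angle
  len <- 0.9572; ang <- 104.52
  other <- setdiff(seq_len(nrow(at)), self_idx)
  dx <- at$x[other] - o[1]; dy <- at$y[other] - o[2]; dz <- at$z[other] - o[3]
  r <- sqrt(dx^2 + dy^2 + dz^2)
  cand <- which(qprov[other] <= -0.3 & r > 0.5 & r < 3.8)
  dirs <- rbind(
    if (length(cand) > 0)
      cbind(dx[cand], dy[cand], dz[cand]) / r[cand] else NULL,
    diag(3), -diag(3))
  best <- Inf; bh1 <- o + c(len, 0, 0); bh2 <- o + c(0, len, 0)
  for (i in seq_len(nrow(dirs))) {
    u <- dirs[i, ]
    h1 <- o + len * u
    # reference frame atom for the dihedral about the O-H1 axis
    refp <- h1 + if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    for (dd in seq(0, 360 - step, by = step)) {
      h2 <- place_internal(refp, h1, o, len, ang, dd)
      sc <- sum(.score_h(rbind(h1, h2), 0.417, at, qprov, self_idx))
      if (sc < best - 1e-12) { best <- sc; bh1 <- h1; bh2 <- h2 }
    }
  }
  list(h1 = bh1, h2 = bh2)
}

.rescan_rotatable <- function(s, assignment, lib, step) {
  at <- s$atoms
  rk <- .residue_key(at)
  qprov <- .provisional_charges(s, lib, assignment)
  for (key in unique(rk)) {
    idx <- which(rk == key)
    resname <- at$resname[idx[1]]
    if (resname %in% c("HOH", "WAT", "TIP3", "TIP")) {
      hi <- idx[at$name[idx] %in% c("H1", "H2")]
      oi <- idx[at$name[idx] %in% c("OH2", "O")]
      if (length(hi) == 2 && length(oi) == 1) {
        o <- as.numeric(at[oi, c("x", "y", "z")])
        hh <- .orient_water(o, at, qprov, idx, step)
        at[hi[1], c("x", "y", "z")] <- as.list(hh$h1)
        at[hi[2], c("x", "y", "z")] <- as.list(hh$h2)
      }
      next
    }
    defs <- .H_TOPOLOGY[[resname]]
    if (is.null(defs)) next
    for (d in defs) {
      if (!d$type %in% c("scan", "scan3")) next
      hi <- idx[match(d$name, at$name[idx])]
      if (anyNA(hi)) next
      res_xyz <- function(nm) {
        for (cand in nm) {
          i <- idx[at$name[idx] == cand]
          if (length(i) == 1)
            return(as.numeric(at[i, c("x", "y", "z")]))
        }
        NULL
      }
      heavy <- res_xyz(d$heavy); b <- res_xyz(d$b); a <- res_xyz(d$a)
      if (is.null(heavy) || is.null(b) || is.null(a)) next
      dih0 <- .scan_dihedral(a, b, heavy, d, at, qprov, idx, step)
      for (m in seq_along(d$name)) {
        pos <- place_internal(a, b, heavy, d$len, d$ang, dih0 + (m - 1) * 120)
        at[hi[m], c("x", "y", "z")] <- as.list(pos)
      }
    }
  }
  s$atoms <- at
  s
}
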