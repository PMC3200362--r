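## Decomposition of pKa shifts into per-residue contributions (side chain
## vs backbone), hydrogen-bond network analysis, and state-to-state
## comparison reports.

#' Intrinsic pKa of a site
#' @param sys a \code{pka_system}
#' @param target site id, residue key, or index (default: all sites)
#' @return named numeric vector of intrinsic pKa values (pK units)
#' @export
intrinsic_pka <- function(sys, target = NULL) {
  if (is.null(target)) {
    return(setNames(sys$pkintr, sys$sites$site_id))
  }
  i <- .site_index(sys, target)
  setNames(sys$pkintr[i], sys$sites$site_id[i])
}

#' Site-site interaction matrix in pK units
#'
#' Symmetric, zero-diagonal couplings between the protonation-state
#' changes of all sites; entry (i, j) is the electrostatic interaction of
#' site i's charging distribution with site j's, in pK units, positive
#' when simultaneous deviation from the neutral reference is penalized
#' (e.g. two neighboring acids).
#' @param sys a \code{pka_system}
#' @return matrix with dimnames = site ids
#' @export
interaction_matrix <- function(sys) {
  W <- sys$W
  dimnames(W) <- list(sys$sites$site_id, sys$sites$site_id)
  W
}

# equilibrium-averaged charge on every atom given site means
.equilibrium_charges <- function(sys, mean_x) {
  q <- sys$qbase
  for (j in seq_along(sys$D)) {
    q[sys$D[[j]]$idx] <- q[sys$D[[j]]$idx] + mean_x[j] * sys$D[[j]]$dq
  }
  q
}

#' Contribution of one residue/group to a target site's pKa
#'
#' Interaction energy of the group's (equilibrium-averaged) charges with
#' the target's protonation charge difference, in pK units, split into
#' side-chain and backbone parts.  Positive values stabilize the
#' protonated target, i.e. raise its pKa.  For groups without a defined
#' backbone partition (cofactors, waters) only the total is reported.
#'
#' @param sys a \code{pka_system}
#' @param target target site (id, key or index)
#' @param group residue key \code{"chain:resseq"} of the contributing group
#' @param mean_x per-site mean protonation used for the group's charges
#'   (default: the sites' neutral reference states); see
#'   \code{\link{exact_populations}}
#' @return named numeric c(side_chain, backbone, total) in pK units;
#'   side_chain/backbone are NA for partition-less groups
#' @export
residue_contribution <- function(sys, target, group, mean_x = NULL) {
  i <- .site_index(sys, target)
  if (is.null(mean_x)) mean_x <- sys$sites$xref
  rk <- .residue_key(sys$atoms)
  gidx <- which(rk == group)
  if (length(gidx) == 0) stop("no atoms for group ", group)
  if (group == sys$sites$key[i]) {
    stop("group is the target's own residue; its effect is part of the ",
         "intrinsic (desolvation/model) term")
  }
  q <- .equilibrium_charges(sys, mean_x)[gidx]
  contrib <- -(q * sys$pot_atoms[i, gidx]) / log(10)
  resname <- sys$atoms$resname[gidx[1]]
  total <- sum(contrib)
  if (resname %in% .AMINO) {
    bb <- sys$atoms$name[gidx] %in% .BACKBONE_ATOMS
    c(side_chain = sum(contrib[!bb]), backbone = sum(contrib[bb]),
      total = total)
  } else {
    c(side_chain = NA_real_, backbone = NA_real_, total = total)
  }
}

#' Per-residue contribution table for a target site
#'
#' One row per residue/group carrying charge, sorted by |total|; the
#' paper-style side-chain/backbone/total layout.  Sign convention:
#' positive = stabilizes the protonated target = raises its pKa.
#'
#' @param sys a \code{pka_system}
#' @param target target site
#' @param mean_x per-site mean protonation defining the group charges
#'   (default: equilibrium populations at the environment pH, with the
#'   target site excluded from averaging by freezing it at its reference
#'   state)
#' @param state_label label stored on the table
#' @param top_n keep the strongest n rows (Inf = all)
#' @return data frame of class \code{"contribution_table"} with columns
#'   group, resname, side_chain, backbone, total
#' @export
contribution_table <- function(sys, target, mean_x = NULL,
                               state_label = NA_character_, top_n = Inf) {
  i <- .site_index(sys, target)
  n <- nrow(sys$sites)
  if (is.null(mean_x)) {
    frozen <- rep(FALSE, n); xfix <- rep(0L, n)
    frozen[i] <- TRUE; xfix[i] <- sys$sites$xref[i]
    sib <- which(sys$sites$key == sys$sites$key[i])
    frozen[sib] <- TRUE; xfix[sib] <- sys$sites$xref[sib]
    mean_x <- if (sum(!frozen) <= 16) {
      exact_populations(sys, frozen = frozen, xfix = xfix)
    } else {
      mc_sample(sys, seed = 1, frozen = frozen, xfix = xfix)$mean
    }
  }
  rk <- .residue_key(sys$atoms)
  q <- .equilibrium_charges(sys, mean_x)
  groups <- setdiff(unique(rk), sys$sites$key[i])
  rows <- lapply(groups, function(g) {
    gidx <- which(rk == g)
    if (max(abs(q[gidx])) < 1e-12) return(NULL)  # zero-charge group
    v <- residue_contribution(sys, i, g, mean_x)
    data.frame(group = g, resname = sys$atoms$resname[gidx[1]],
               side_chain = v[["side_chain"]], backbone = v[["backbone"]],
               total = v[["total"]], stringsAsFactors = FALSE)
  })
  tb <- do.call(rbind, rows)
  if (is.null(tb)) {
    tb <- data.frame(group = character(), resname = character(),
                     side_chain = numeric(), backbone = numeric(),
                     total = numeric())
  }
  tb <- tb[order(-abs(tb$total)), , drop = FALSE]
  if (is.finite(top_n)) tb <- head(tb, top_n)
  rownames(tb) <- NULL
  structure(tb, class = c("contribution_table", "data.frame"),
            target = sys$sites$site_id[i], state_label = state_label,
            mean_x = mean_x,
            sign_convention = "positive = raises target pKa (stabilizes protonated form)")
}

#' @export
print.contribution_table <- function(x, ...) {
  cat("Contributions to pKa(", attr(x, "target"), ")",
      if (!is.na(attr(x, "state_label")))
        paste0(" [", attr(x, "state_label"), "]"), "\n", sep = "")
  cat("# ", attr(x, "sign_convention"), "\n", sep = "")
  print.data.frame(cbind(x[, 1:2], round(x[, 3:5], 2)), row.names = FALSE)
  invisible(x)
}

#' Hydrogen-bond network of a structure
#'
#' Directed donor-to-acceptor edges: an edge exists when the
#' hydrogen...acceptor distance is at most \code{dmax} and the
#' donor-H...acceptor angle is at least \code{angle_min}.  The heavy-atom
#' donor-acceptor distance is also reported for comparison with
#' crystallographic distances.
#'
#' @param s a \code{pdb_structure} with hydrogens present
#' @param dmax maximum H...acceptor distance (Angstrom)
#' @param angle_min minimum donor-H...acceptor angle (degrees)
#' @param donor_elements,acceptor_elements element sets defining donors
#'   (heavy atom bonded to H) and acceptors
#' @param min_h_charge when the structure carries assigned charges,
#'   hydrogens with |charge| below this are treated as chemically absent
#'   (the implicit-proton convention keeps deprotonated protons as
#'   zero-charge atoms)
#' @return data frame of class \code{"hbond_graph"}: donor, donor_atom,
#'   acceptor, acceptor_atom, d_HA, d_DA, angle
#' @export
hbond_network <- function(s, dmax = 2.5, angle_min = 120,
                          donor_elements = c("N", "O", "S"),
                          acceptor_elements = c("N", "O", "S"),
                          min_h_charge = 0.05) {
  at <- s$atoms
  hy <- which(toupper(at$element) == "H")
  if (length(hy) == 0) {
    stop("structure has no hydrogens; run place_polar_hydrogens() first")
  }
  if (any(at$charge != 0)) {
    hy <- hy[abs(at$charge[hy]) >= min_h_charge]
  }
  rk <- .residue_key(at)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  heavy <- which(toupper(at$element) %in% donor_elements)
  edges <- list()
  for (h in hy) {
    d2 <- colSums((t(xyz[heavy, , drop = FALSE]) - xyz[h, ])^2)
    cand <- heavy[d2 < 1.6^2]
    if (length(cand) == 0) next
    don <- cand[which.min(colSums((t(xyz[cand, , drop = FALSE]) -
                                     xyz[h, ])^2))]
    acc_cand <- which(toupper(at$element) %in% acceptor_elements &
                      rk != rk[h])
    if (length(acc_cand) == 0) next
    dHA <- sqrt(colSums((t(xyz[acc_cand, , drop = FALSE]) - xyz[h, ])^2))
    ok <- which(dHA <= dmax)
    for (m in ok) {
      a <- acc_cand[m]
      ang <- vec_angle(xyz[don, ], xyz[h, ], xyz[a, ])
      if (ang >= angle_min) {
        edges[[length(edges) + 1]] <- data.frame(
          donor = rk[don], donor_atom = at$name[don],
          donor_res = at$resname[don],
          acceptor = rk[a], acceptor_atom = at$name[a],
          acceptor_res = at$resname[a],
          d_HA = dHA[m],
          d_DA = sqrt(sum((xyz[don, ] - xyz[a, ])^2)),
          angle = ang, stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(edges) > 0) do.call(rbind, edges) else
    data.frame(donor = character(), donor_atom = character(),
               donor_res = character(), acceptor = character(),
               acceptor_atom = character(), acceptor_res = character(),
               d_HA = numeric(), d_DA = numeric(), angle = numeric())
  rownames(out) <- NULL
  structure(out, class = c("hbond_graph", "data.frame"),
            dmax = dmax, angle_min = angle_min)
}

#' Compare titration/decomposition results across states
#'
#' @param results named list: state label -> named numeric vector of pKa
#'   values (site -> pKa), e.g. collected from \code{\link{titrate_pka}}
#' @param tables optional named list of \code{contribution_table}s
#' @param networks optional named list of \code{hbond_graph}s
#' @param threshold report residues whose |contribution change| exceeds
#'   this (pK units)
#' @return list of class \code{"state_comparison"}: \code{dpka} (site x
#'   state matrix of pKa minus reference-state pKa), \code{changed_groups},
#'   \code{edges_gained}, \code{edges_lost}
#' @export
compare_states <- function(results, tables = NULL, networks = NULL,
                           threshold = 0.5) {
  if (length(results) < 2) stop("need at least 2 states to compare")
  common <- Reduce(intersect, lapply(results, names))
  if (length(common) == 0) stop("states share no sites")
  pka <- vapply(results, function(r) r[common],
                numeric(length(common)))
  if (length(common) == 1) pka <- matrix(pka, 1,
                                         dimnames = list(common,
                                                         names(results)))
  dpka <- pka - pka[, 1]
  changed <- NULL
  if (!is.null(tables) && length(tables) >= 2) {
    ref <- tables[[1]]
    for (s in names(tables)[-1]) {
      tb <- tables[[s]]
      g <- union(ref$group, tb$group)
      t0 <- setNames(rep(0, length(g)), g)
      t1 <- t0
      t0[ref$group] <- ref$total
      t1[tb$group] <- tb$total
      d <- t1 - t0
      big <- which(abs(d) >= threshold)
      if (length(big) > 0) {
        changed <- rbind(changed, data.frame(
          state = s, group = names(d)[big], ref_total = t0[big],
          state_total = t1[big], delta = d[big],
          stringsAsFactors = FALSE))
      }
    }
    if (!is.null(changed)) rownames(changed) <- NULL
  }
  gained <- lost <- NULL
  if (!is.null(networks) && length(networks) >= 2) {
    ekey <- function(nw) paste(nw$donor, nw$donor_atom, "->",
                               nw$acceptor, nw$acceptor_atom)
    ref <- ekey(networks[[1]])
    for (s in names(networks)[-1]) {
      cur <- ekey(networks[[s]])
      if (length(setdiff(cur, ref)) > 0) {
        gained <- rbind(gained, data.frame(state = s,
                                           edge = setdiff(cur, ref)))
      }
      if (length(setdiff(ref, cur)) > 0) {
        lost <- rbind(lost, data.frame(state = s,
                                       edge = setdiff(ref, cur)))
      }
    }
  }
  structure(list(pka = pka, dpka = dpka, changed_groups = changed,
                 edges_gained = gained, edges_lost = lost,
                 reference_state = names(results)[1]),
            class = "state_comparison")
}

#' @export
print.state_comparison <- function(x, ...) {
  cat("State comparison (reference:", x$reference_state, ")\n")
  cat("pKa by state:\n")
  print(round(x$pka, 2))
  if (!is.null(x$changed_groups)) {
    cat("groups with large contribution changes:\n")
    print(cbind(x$changed_groups[, 1:2],
                round(x$changed_groups[, 3:5], 2)), row.names = FALSE)
  }
  if (!is.null(x$edges_gained)) {
    cat("H-bond edges gained:\n"); print(x$edges_gained, row.names = FALSE)
  }
  if (!is.null(x$edges_lost)) {
    cat("H-bond edges lost:\n"); print(x$edges_lost, row.names = FALSE)
  }
  invisible(x)
}
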