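## Titration engine: titratable-site detection, intrinsic pKa values,
## site-site interaction matrix, microstate energies, Metropolis Monte
## Carlo and exact enumeration, bias-potential titration, and Nernst
## treatment of redox-active groups.

# reference pKa values of the model compounds (pH units)
.PKA_REF <- c(ARG = 12.0, ASP = 4.0, CYS = 9.5, GLU = 4.4, LYS = 10.4,
              TYR = 9.6)
.PKA_REF_HIS <- c(NE2 = 7.0, ND1 = 6.6)

# x = 1 means protonated (electron bound, for redox sites).  xref is the
# neutral reference state used for intrinsic-pKa backgrounds and for the
# charge deviations entering the interaction term.
.SITE_DEFS <- list(
  ASP = list(kind = "acid", xref = 1, states = c("prot", "deprot")),
  GLU = list(kind = "acid", xref = 1, states = c("prot", "deprot")),
  TYR = list(kind = "acid", xref = 1, states = c("prot", "deprot")),
  CYS = list(kind = "acid", xref = 1, states = c("prot", "deprot")),
  LYS = list(kind = "base", xref = 0, states = c("prot", "deprot")),
  ARG = list(kind = "base", xref = 0, states = c("prot", "deprot")),
  RDX = list(kind = "redox", xref = 0, states = c("red", "ox"))
)

# energy penalty (pK units) excluding the doubly-deprotonated His
# microstate
.HIS_EXCLUSION_PK <- 30

#' Detect titratable sites in a structure
#'
#' @param s a resolved \code{pdb_structure}
#' @param redox_ref named numeric: reference midpoint potentials (mV) for
#'   redox groups, by residue key \code{"chain:resseq"}
#' @return data frame with one row per site (His contributes two subsites,
#'   N-epsilon and N-delta)
#' @export
detect_titratable_sites <- function(s, redox_ref = c()) {
  at <- s$atoms
  rk <- .residue_key(at)
  out <- list()
  for (key in unique(rk)) {
    idx <- which(rk == key)
    resname <- at$resname[idx[1]]
    if (resname == "HIS") {
      out[[length(out) + 1]] <- data.frame(
        site_id = paste(key, "HIS", c("NE2", "ND1"), sep = ":"),
        key = key, resname = "HIS", subsite = c("NE2", "ND1"),
        kind = "base", pka_ref = .PKA_REF_HIS[c("NE2", "ND1")],
        xref = c(0, 1), stringsAsFactors = FALSE)
    } else if (!is.null(.SITE_DEFS[[resname]])) {
      def <- .SITE_DEFS[[resname]]
      ref <- if (resname == "RDX") {
        if (key %in% names(redox_ref)) redox_ref[[key]] / mv_per_pk(300)
        else 0
      } else .PKA_REF[[resname]]
      out[[length(out) + 1]] <- data.frame(
        site_id = paste(key, resname, sep = ":"), key = key,
        resname = resname, subsite = NA_character_, kind = def$kind,
        pka_ref = ref, xref = def$xref, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(site_id = character(), key = character(),
                      resname = character(), subsite = character(),
                      kind = character(), pka_ref = numeric(),
                      xref = integer()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# per-site protonation charge-difference distribution D (q(x=1)-q(x=0))
# and the global base charge vector (all sites at x=0)
.site_charge_model <- function(s, sites, lib) {
  at <- s$atoms
  rk <- .residue_key(at)
  qbase <- at$charge
  D <- vector("list", nrow(sites))
  state_q <- function(idx, resname, state) {
    anames <- at$name[idx]
    if (resname == "HOH") anames[anames == "O"] <- "OH2"
    q <- .residue_state_charges(lib, resname, state, anames)
    q[is.na(q)] <- 0
    q
  }
  for (key in unique(sites$key)) {
    srows <- which(sites$key == key)
    idx <- which(rk == key)
    resname <- sites$resname[srows[1]]
    if (resname == "HIS") {
      qd <- state_q(idx, "HIS", "HSD")
      qe <- state_q(idx, "HIS", "HSE")
      qp <- state_q(idx, "HIS", "HSP")
      q00 <- qd + qe - qp          # linear tautomer decomposition
      qbase[idx] <- q00
      for (r in srows) {
        dq <- if (sites$subsite[r] == "ND1") qp - qe else qp - qd
        nz <- which(abs(dq) > 1e-12)
        D[[r]] <- list(idx = idx[nz], dq = dq[nz])
      }
    } else {
      def <- .SITE_DEFS[[resname]]
      q1 <- state_q(idx, resname, def$states[1])
      q0 <- state_q(idx, resname, def$states[2])
      qbase[idx] <- q0
      dq <- q1 - q0
      nz <- which(abs(dq) > 1e-12)
      D[[srows]] <- list(idx = idx[nz], dq = dq[nz])
    }
  }
  list(D = D, qbase = qbase)
}

#' Build a pKa system: electrostatics for all titratable sites
#'
#' Runs the focused LPB solver for every site's protonation charge
#' difference in the protein context and in the model-compound context
#' (the site's own residue alone, at identical coordinates on identical
#' grids, so grid self-energies cancel), producing intrinsic pKa values
#' and the site-site interaction matrix in pK units.
#'
#' @param s a resolved, charged \code{pdb_structure} (hydrogens placed);
#'   if charges are absent, standard states are assigned
#' @param env a \code{\link{pka_env}}
#' @param sites site table from \code{\link{detect_titratable_sites}}
#'   (default: detect)
#' @param levels focusing grid spacings, coarse to fine
#' @param uniform_eps if non-NULL, replace the dielectric boundary by this
#'   uniform dielectric (used by closed-form validation)
#' @param cap_n maximum grid nodes per axis
#' @param tol,maxit solver controls
#' @param lib charge library
#' @param redox_ref reference midpoints (mV) by residue key for redox sites
#' @param verbose print per-site progress
#' @return object of class \code{"pka_system"}
#' @export
pka_system <- function(s, env = pka_env(), sites = NULL,
                       levels = c(2.5, 1.0, 0.3), uniform_eps = NULL,
                       cap_n = 97, tol = 1e-6, maxit = 10000,
                       lib = default_charge_library(), redox_ref = c(),
                       verbose = FALSE) {
  if (all(s$atoms$charge == 0) || anyNA(s$atoms$radius)) {
    s <- assign_state_charges(s, lib)
  }
  if (is.null(sites)) sites <- detect_titratable_sites(s, redox_ref)
  if (nrow(sites) == 0) stop("no titratable sites in structure")
  at <- s$atoms
  rk <- .residue_key(at)
  cm <- .site_charge_model(s, sites, lib)
  n <- nrow(sites)
  lnkT <- log(10)  # energies handled in pK units (kT ln10)
  allpos <- as.matrix(at[, c("x", "y", "z")])

  pot_atoms <- matrix(0, n, nrow(at))   # protein-context phi(D_i) at atoms
  self_prot <- self_model <- numeric(n)
  pot_model <- vector("list", n)        # model-context phi at own residue
  for (i in seq_len(n)) {
    Di <- cm$D[[i]]
    dpos <- allpos[Di$idx, , drop = FALSE]
    fc <- colSums(dpos * abs(Di$dq)) / sum(abs(Di$dq))
    grids <- .focus_grids(dpos, at, fc, levels, 20, 10, cap_n)
    fp <- focus_solve(dpos, Di$dq, at, env, fc, levels,
                      uniform_eps = uniform_eps, grids = grids,
                      cap_n = cap_n, tol = tol, maxit = maxit)
    res_idx <- which(rk == sites$key[i])
    model_atoms <- at[res_idx, , drop = FALSE]
    fm <- focus_solve(dpos, Di$dq, model_atoms, env, fc, levels,
                      uniform_eps = uniform_eps, grids = grids,
                      cap_n = cap_n, tol = tol, maxit = maxit)
    pot_atoms[i, ] <- eval_potential(fp, allpos)
    pm <- eval_potential(fm, allpos[res_idx, , drop = FALSE])
    pot_model[[i]] <- list(idx = res_idx, phi = pm)
    self_prot[i] <- 0.5 * sum(Di$dq * pot_atoms[i, Di$idx])
    self_model[i] <- 0.5 * sum(Di$dq * pm[match(Di$idx, res_idx)])
    if (verbose) message("site ", sites$site_id[i], ": solved (",
                         length(Di$idx), " difference charges)")
  }

  # interaction matrix (pK units); same-residue subsite coupling is
  # embodied in the reference constants and excluded
  W <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || sites$key[i] == sites$key[j]) next
    Dj <- cm$D[[j]]
    W[i, j] <- sum(Dj$dq * pot_atoms[i, Dj$idx]) / lnkT
  }
  W_asym <- max(abs(W - t(W)))
  W <- (W + t(W)) / 2

  # intrinsic pKa: other sites at their neutral reference states
  pkintr <- numeric(n)
  for (i in seq_len(n)) {
    b <- cm$qbase
    for (j in seq_len(n)) {
      if (j != i && sites$xref[j] == 1) {
        b[cm$D[[j]]$idx] <- b[cm$D[[j]]$idx] + cm$D[[j]]$dq
      }
    }
    res_idx <- pot_model[[i]]$idx
    back_prot <- sum(b * pot_atoms[i, ])
    bm <- b[res_idx]
    back_model <- sum(bm * pot_model[[i]]$phi)
    dG_prot <- self_prot[i] + back_prot      # kT, protonation in protein
    dG_model <- self_model[i] + back_model   # kT, protonation in model
    pkintr[i] <- sites$pka_ref[i] - (dG_prot - dG_model) / lnkT
  }

  excl <- which(sites$resname == "HIS" & sites$subsite == "NE2")
  excl_pairs <- do.call(rbind, lapply(excl, function(i) {
    j <- which(sites$key == sites$key[i] & sites$subsite == "ND1")
    c(i, j)
  }))
  if (is.null(excl_pairs)) excl_pairs <- matrix(integer(), 0, 2)

  structure(list(atoms = at, sites = sites, D = cm$D, qbase = cm$qbase,
                 pkintr = pkintr, W = W, W_asymmetry = W_asym,
                 pot_atoms = pot_atoms, pot_model = pot_model,
                 self_prot = self_prot, self_model = self_model,
                 excl_pairs = excl_pairs,
                 excl_pen = rep(.HIS_EXCLUSION_PK, nrow(excl_pairs)),
                 env = env, levels = levels,
                 uniform_eps = uniform_eps,
                 charge_set = s$charge_set,
                 conformer_label = s$conformer_label),
            class = "pka_system")
}

#' @export
print.pka_system <- function(x, ...) {
  cat("pKa system:", nrow(x$sites), "titratable sites,",
      nrow(x$atoms), "atoms\n")
  df <- data.frame(site = x$sites$site_id, kind = x$sites$kind,
                   pka_ref = x$sites$pka_ref,
                   pka_intr = round(x$pkintr, 2))
  print(df, row.names = FALSE)
  cat("max |W| =", round(max(abs(x$W)), 2), "pK;",
      "pre-symmetrization asymmetry", signif(x$W_asymmetry, 2), "pK\n")
  invisible(x)
}

#' Shift the static background charge of a system
#'
#' Adds a fixed charge perturbation (e.g. the photo-oxidized special-pair
#' hole) and updates every intrinsic pKa through the precomputed site
#' potentials; the interaction matrix is unchanged (the perturbation is
#' not titratable).
#'
#' @param sys a \code{pka_system}
#' @param idx atom row indices of the perturbed atoms
#' @param dq charge changes (e) at those atoms
#' @param label optional label recorded on the system
#' @return updated \code{pka_system}
#' @export
apply_background <- function(sys, idx, dq, label = NULL) {
  stopifnot(length(idx) == length(dq))
  shift <- as.numeric(sys$pot_atoms[, idx, drop = FALSE] %*% dq) / log(10)
  sys$pkintr <- sys$pkintr - shift
  sys$qbase[idx] <- sys$qbase[idx] + dq
  sys$atoms$charge[idx] <- sys$atoms$charge[idx] + dq
  if (!is.null(label)) sys$background_label <- label
  sys
}

# per-site chemical potential in pK units (pH for proton sites, solution
# redox potential for electron sites)
.site_mu <- function(sys, pH, Eh_mV = 0) {
  ifelse(sys$sites$kind == "redox",
         Eh_mV / mv_per_pk(sys$env$temperature), pH)
}

#' Microstate energy
#'
#' Energy of one full protonation microstate in kT:
#' \code{ln10 * [sum_i x_i (mu_i - pka_intr_i - bias_i)
#'   + 0.5 sum_{i != j} W_ij P_i P_j + exclusion penalties]},
#' with \code{P_i = x_i - xref_i} the deviation from the neutral reference.
#'
#' @param sys a \code{pka_system}
#' @param x 0/1 vector of protonation indicators
#' @param pH solution pH
#' @param bias per-site bias in pK units (positive favors protonation)
#' @param Eh_mV solution redox potential for redox sites
#' @return energy in kT
#' @export
microstate_energy <- function(sys, x, pH = sys$env$pH, bias = 0,
                              Eh_mV = 0) {
  n <- nrow(sys$sites)
  bias <- rep_len(bias, n)
  mu <- .site_mu(sys, pH, Eh_mV)
  P <- x - sys$sites$xref
  e <- sum(x * (mu - sys$pkintr - bias)) +
    0.5 * sum((P %o% P) * sys$W) +
    sum(apply(sys$excl_pairs, 1, function(pr)
      (1 - x[pr[1]]) * (1 - x[pr[2]])) * sys$excl_pen)
  log(10) * e
}

#' Exact Boltzmann populations by enumeration
#'
#' Enumerates all microstates of the non-frozen sites (at most 20) and
#' returns the exact mean protonation of every site.
#'
#' @param sys a \code{pka_system}
#' @param pH solution pH
#' @param bias per-site bias (pK units)
#' @param Eh_mV solution redox potential (mV) applied to redox sites
#' @param frozen logical vector: sites held fixed at \code{xfix}
#' @param xfix 0/1 values for frozen sites
#' @return named numeric vector of mean protonation per site
#' @export
exact_populations <- function(sys, pH = sys$env$pH, bias = 0, Eh_mV = 0,
                              frozen = NULL, xfix = NULL) {
  n <- nrow(sys$sites)
  bias <- rep_len(bias, n)
  mu <- .site_mu(sys, pH, Eh_mV)
  if (is.null(frozen)) frozen <- rep(FALSE, n)
  if (is.null(xfix)) xfix <- rep(0L, n)
  free <- which(!frozen)
  m <- length(free)
  if (m > 20) stop("exact enumeration limited to 20 free sites (got ",
                   m, ")")
  nst <- 2^m
  X <- matrix(rep(xfix, each = nst), nst, n)
  if (m > 0) {
    bits <- vapply(seq_len(m), function(b)
      bitwAnd(0:(nst - 1), bitwShiftL(1L, b - 1L)) > 0, logical(nst))
    X[, free] <- bits + 0
  }
  P <- sweep(X, 2, sys$sites$xref)
  E <- as.numeric(X %*% (mu - sys$pkintr - bias)) +
    0.5 * rowSums((P %*% sys$W) * P)
  if (nrow(sys$excl_pairs) > 0) {
    for (e in seq_len(nrow(sys$excl_pairs))) {
      pr <- sys$excl_pairs[e, ]
      E <- E + sys$excl_pen[e] * (1 - X[, pr[1]]) * (1 - X[, pr[2]])
    }
  }
  w <- exp(-log(10) * (E - min(E)))
  mx <- as.numeric(colSums(X * w) / sum(w))
  names(mx) <- sys$sites$site_id
  mx
}

#' Metropolis Monte Carlo sampling of protonation microstates
#'
#' Single-site flips plus joint flips for strongly coupled pairs
#' (\code{|W| > pair_threshold}).  Reproducible: the sampler draws from R's
#' RNG, so \code{set.seed(seed)} fixes the trajectory bit-for-bit.
#'
#' @inheritParams exact_populations
#' @param n_sweeps sampling sweeps
#' @param burn_in discarded equilibration sweeps
#' @param seed RNG seed (mandatory)
#' @param pair_threshold coupling threshold (pK) for paired moves
#' @return list: mean (per-site mean protonation), acceptance, n_sweeps,
#'   seed, final state
#' @export
mc_sample <- function(sys, pH = sys$env$pH, bias = 0, Eh_mV = 0,
                      n_sweeps = 10000, burn_in = 100, seed,
                      frozen = NULL, xfix = NULL, pair_threshold = 2) {
  if (missing(seed)) stop("an explicit seed is required")
  n <- nrow(sys$sites)
  bias <- rep_len(bias, n)
  mu <- .site_mu(sys, pH, Eh_mV)
  if (is.null(frozen)) frozen <- rep(FALSE, n)
  if (is.null(xfix)) xfix <- rep(0L, n)
  x0 <- ifelse(frozen, xfix, sys$sites$xref)
  strong <- which(abs(sys$W) > pair_threshold & upper.tri(sys$W),
                  arr.ind = TRUE)
  set.seed(seed)
  res <- cpp_mc_titrate(as.integer(x0), mu, sys$pkintr + bias, sys$W,
                        as.integer(sys$sites$xref), as.integer(frozen),
                        matrix(as.integer(sys$excl_pairs - 1), ncol = 2),
                        sys$excl_pen,
                        matrix(as.integer(strong - 1), ncol = 2),
                        as.integer(burn_in), as.integer(n_sweeps))
  mean <- res$mean
  mean[frozen] <- xfix[frozen]
  names(mean) <- sys$sites$site_id
  if (res$acceptance == 0 && n > 0) {
    warning("Monte Carlo acceptance rate was 0")
  }
  list(mean = mean, acceptance = res$acceptance, n_sweeps = n_sweeps,
       burn_in = burn_in, seed = seed, final = res$final)
}

# resolve a target site given by id, index, or residue key
.site_index <- function(sys, target) {
  if (is.numeric(target)) return(as.integer(target))
  i <- which(sys$sites$site_id == target)
  if (length(i) == 0) i <- which(sys$sites$key == target)
  if (length(i) != 1) stop("target '", target, "' matches ", length(i),
                           " sites")
  i
}

#' Bias-potential titration of one site
#'
#' Applies a bias to the target site and locates, by bisection, the bias at
#' which its two protonation states are equally populated, with all other
#' sites fully equilibrated at every step.  The pKa is \code{pH - bias} at
#' the root (for an isolated site this recovers the intrinsic pKa
#' exactly).  For a His subsite the sibling nitrogen is held protonated
#' (microscopic pKa; the reference constants embody the tautomer
#' equilibrium).
#'
#' @param sys a \code{pka_system}
#' @param target site id, residue key, or site index
#' @param pH solution pH (default from env)
#' @param Eh_mV solution redox potential for any redox sites present
#' @param method "exact" enumerates microstates, "mc" uses Monte Carlo,
#'   "auto" picks exact when at most \code{exact_limit} free sites
#' @param exact_limit site-count limit for the exact method under "auto"
#' @param bias_tol bisection tolerance on the bias (pK)
#' @param bracket half-width of the bias search interval (pK)
#' @param n_sweeps,burn_in,seed Monte Carlo controls (a fresh seed is
#'   derived for every bias evaluation)
#' @param freeze_pattern optional list(frozen =, xfix =) to titrate against
#'   a frozen protonation pattern
#' @return object of class \code{"titration_result"}
#' @export
titrate_pka <- function(sys, target, pH = sys$env$pH, Eh_mV = 0,
                        method = c("auto", "exact", "mc"),
                        exact_limit = 14, bias_tol = 0.01, bracket = 30,
                        n_sweeps = 10000, burn_in = 100, seed = 1,
                        freeze_pattern = NULL) {
  method <- match.arg(method)
  i <- .site_index(sys, target)
  n <- nrow(sys$sites)
  frozen <- rep(FALSE, n)
  xfix <- rep(0L, n)
  if (!is.null(freeze_pattern)) {
    frozen <- freeze_pattern$frozen
    xfix <- as.integer(freeze_pattern$xfix)
    frozen[i] <- FALSE
  }
  sib <- which(sys$sites$key == sys$sites$key[i] & seq_len(n) != i)
  if (length(sib) > 0) { frozen[sib] <- TRUE; xfix[sib] <- 1L }
  nfree <- sum(!frozen)
  if (method == "auto") {
    method <- if (nfree <= exact_limit) "exact" else "mc"
  }
  evals <- 0
  fmean <- function(bias_i) {
    evals <<- evals + 1
    b <- rep(0, n); b[i] <- bias_i
    if (method == "exact") {
      exact_populations(sys, pH, b, Eh_mV, frozen, xfix)[i]
    } else {
      mc_sample(sys, pH, b, Eh_mV, n_sweeps, burn_in,
                seed = seed + evals, frozen = frozen, xfix = xfix)$mean[i]
    }
  }
  lo <- -bracket; hi <- bracket
  flo <- fmean(lo); fhi <- fmean(hi)
  if (flo > 0.5 || fhi < 0.5) {
    stop("titration root not bracketed in +/-", bracket, " pK for site ",
         sys$sites$site_id[i])
  }
  curve <- data.frame(bias = c(lo, hi), mean = c(flo, fhi))
  while (hi - lo > bias_tol) {
    mid <- (lo + hi) / 2
    fm <- fmean(mid)
    curve <- rbind(curve, data.frame(bias = mid, mean = fm))
    if (fm < 0.5) lo <- mid else hi <- mid
  }
  bias_root <- (lo + hi) / 2
  mu_i <- .site_mu(sys, pH, Eh_mV)[i]
  pka <- mu_i - bias_root
  structure(list(site_id = sys$sites$site_id[i], pka = pka,
                 bias = bias_root, pH = pH, Eh_mV = Eh_mV,
                 method = method,
                 curve = curve[order(curve$bias), ],
                 diagnostics = list(evaluations = evals, seed = seed,
                                    n_sweeps = n_sweeps,
                                    burn_in = burn_in,
                                    n_free_sites = nfree)),
            class = "titration_result")
}

#' @export
print.titration_result <- function(x, ...) {
  lab <- if (grepl("RDX", x$site_id)) {
    paste0("midpoint = ", round(x$pka * mv_per_pk(300), 1), " mV")
  } else paste0("pKa = ", round(x$pka, 2))
  cat("Titration of", x$site_id, "(", x$method, "):", lab, "\n")
  invisible(x)
}

#' Redox midpoint potential of a redox-active site
#'
#' Bias search on the electron chemical potential until the oxidized and
#' reduced populations are equal; the midpoint is returned in mV through
#' the Nernst constant at the environment temperature.
#'
#' @inheritParams titrate_pka
#' @param Eh_mV solution redox potential at which the other sites
#'   equilibrate
#' @return list with \code{midpoint_mV} and the underlying
#'   \code{titration_result}
#' @export
redox_midpoint <- function(sys, target, Eh_mV = 0, ...) {
  i <- .site_index(sys, target)
  if (sys$sites$kind[i] != "redox") stop("site ", sys$sites$site_id[i],
                                         " is not redox-active")
  tr <- titrate_pka(sys, i, Eh_mV = Eh_mV, ...)
  list(midpoint_mV = tr$pka * mv_per_pk(sys$env$temperature),
       titration = tr)
}

#' Mean protonation of every site across a pH range
#' @param sys a \code{pka_system}
#' @param pH_range numeric vector of pH values
#' @param ... passed to \code{\link{exact_populations}}
#' @return matrix (length(pH_range) x n_sites)
#' @export
titration_curves <- function(sys, pH_range = seq(0, 14, by = 0.5), ...) {
  n <- nrow(sys$sites)
  out <- matrix(NA_real_, length(pH_range), n,
                dimnames = list(pH_range, sys$sites$site_id))
  for (k in seq_along(pH_range)) {
    out[k, ] <- exact_populations(sys, pH = pH_range[k], ...)
  }
  out
}
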