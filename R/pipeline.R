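## End-to-end orchestration: run configuration validation, single-state
## runs (structure -> states -> pKa -> decomposition -> report), and the
## fitted-model interface with the usual S3 methods.

#' Validate and normalize a run configuration
#'
#' Fills defaults matching the standard computational conditions
#' (eps_protein 4, eps_water 80, 100 mM, 300 K, pH 7, focusing levels
#' 2.5/1.0/0.3 Angstrom), checks units and ranges, and aggregates every
#' error rather than stopping at the first.
#'
#' @param config a named list; recognized fields: structure (path or
#'   \code{pdb_structure}), conformer, water_keep, site_states (named
#'   state overrides by residue key), special_pair (list with a, b,
#'   ratio), redox_ref, eps_protein, eps_water, ionic_strength,
#'   temperature, pH, ion_exclusion, levels, cap_n, n_sweeps, burn_in,
#'   seed (mandatory), targets, outdir, waiver
#' @param collect if TRUE, return \code{list(config, errors)} instead of
#'   stopping on errors
#' @return normalized config of class \code{"pka_config"} (attribute
#'   \code{defaulted} lists every field that received a default)
#' @export
validate_config <- function(config = list(), collect = FALSE) {
  errors <- character()
  defaults <- list(conformer = NULL, water_keep = character(),
                   site_states = list(), special_pair = NULL,
                   redox_ref = c(),
                   eps_protein = 4, eps_water = 80, ionic_strength = 0.1,
                   temperature = 300, pH = 7.0, ion_exclusion = 2.0,
                   levels = c(2.5, 1.0, 0.3), cap_n = 97,
                   n_sweeps = 10000, burn_in = 100,
                   targets = NULL, outdir = NULL, waiver = character())
  defaulted <- setdiff(names(defaults), names(config))
  for (nm in defaulted) config[[nm]] <- defaults[[nm]]
  unknown <- setdiff(names(config), c(names(defaults), "structure",
                                      "seed"))
  if (length(unknown) > 0) {
    errors <- c(errors, paste("unknown config field(s):",
                              paste(unknown, collapse = ", ")))
  }
  if (is.null(config$structure)) {
    errors <- c(errors, "structure is required (path or pdb_structure)")
  } else if (is.character(config$structure) &&
             !file.exists(config$structure)) {
    errors <- c(errors, paste("structure file not found:",
                              config$structure))
  }
  if (is.null(config$seed)) {
    errors <- c(errors, "seed is required")
  } else if (!is.numeric(config$seed) || length(config$seed) != 1) {
    errors <- c(errors, "seed must be a single integer")
  }
  if (config$ionic_strength < 0) {
    errors <- c(errors, "ionic_strength must be >= 0")
  }
  if (config$eps_protein < 1 || config$eps_water < 1) {
    errors <- c(errors, "dielectric constants must be >= 1")
  }
  if (config$temperature <= 0) {
    errors <- c(errors, "temperature must be positive")
  }
  if (length(config$levels) < 1 || any(diff(config$levels) >= 0) ||
      any(config$levels <= 0)) {
    errors <- c(errors, "levels must be positive and strictly decreasing")
  }
  if (config$n_sweeps < config$burn_in) {
    errors <- c(errors, "n_sweeps must be >= burn_in")
  }
  config <- structure(config, class = "pka_config",
                      defaulted = defaulted)
  if (collect) return(list(config = config, errors = errors))
  if (length(errors) > 0) {
    stop("invalid configuration:\n  - ",
         paste(errors, collapse = "\n  - "))
  }
  config
}

#' Run one conformational/redox state end to end
#'
#' Structure preparation (conformer resolution, water policy, hydrogen
#' placement), charge assignment, LPB electrostatics, bias-potential
#' titration of the target sites, per-residue decomposition, hydrogen-bond
#' network, and a manifest sufficient for bit-reproduction.
#'
#' @param config a config list or \code{pka_config}
#' @param state_label label for this state (e.g. \code{"P0_Ydark"})
#' @param verbose print progress
#' @return object of class \code{"pka_fit"}
#' @export
run_state <- function(config, state_label = "state", verbose = FALSE) {
  if (!inherits(config, "pka_config")) config <- validate_config(config)
  s <- config$structure
  if (is.character(s)) s <- read_structure(s)
  if (!is.null(config$conformer)) {
    s <- resolve_conformer(s, config$conformer, state_label)
  } else if (any(nzchar(s$atoms$altloc))) {
    stop("structure has unresolved altlocs; set config$conformer")
  }
  s <- apply_water_policy(s, config$water_keep)
  s <- place_polar_hydrogens(s, assignment = config$site_states)
  s <- assign_state_charges(s, assignment = config$site_states,
                            waiver = config$waiver)
  env <- pka_env(config$eps_protein, config$eps_water,
                 config$ionic_strength, config$temperature, config$pH,
                 config$ion_exclusion)
  sys <- pka_system(s, env, levels = config$levels, cap_n = config$cap_n,
                    redox_ref = config$redox_ref, verbose = verbose)
  hole <- NULL
  if (!is.null(config$special_pair)) {
    sp <- config$special_pair
    ratio <- if (is.null(sp$ratio)) c(2, 1) else sp$ratio
    h <- apply_special_pair_hole(.structure_of(sys), sp$a, sp$b, ratio)
    sys <- apply_background(sys, h$idx, h$dq,
                            label = paste0("special_pair_hole_",
                                           paste(ratio, collapse = ":")))
    hole <- list(idx = h$idx, dq = h$dq, ratio = ratio)
  }
  targets <- config$targets
  if (is.null(targets)) targets <- sys$sites$site_id
  titr <- list()
  for (tg in targets) {
    titr[[tg]] <- titrate_pka(sys, tg, n_sweeps = config$n_sweeps,
                              burn_in = config$burn_in,
                              seed = config$seed)
    if (verbose) print(titr[[tg]])
  }
  pka <- vapply(titr, function(t) t$pka, numeric(1))
  tables <- lapply(targets, function(tg)
    contribution_table(sys, tg, state_label = state_label))
  names(tables) <- targets
  hb <- hbond_network(s)
  manifest <- list(
    state_label = state_label,
    parameters = config[setdiff(names(config), "structure")],
    structure_atoms = nrow(s$atoms),
    conformer_label = s$conformer_label,
    waters_kept = s$waters_kept,
    charge_set = s$charge_set,
    seeds = list(titration = config$seed),
    package_version = as.character(utils::packageVersion("contpka")))
  fit <- structure(list(state_label = state_label, structure = s,
                        system = sys, titrations = titr, pka = pka,
                        tables = tables, hbonds = hb, hole = hole,
                        manifest = manifest, config = config),
                   class = "pka_fit")
  if (!is.null(config$outdir)) write_fit(fit, config$outdir)
  fit
}

.structure_of <- function(sys) {
  structure(list(atoms = sys$atoms, conformer_label = sys$conformer_label,
                 waters_kept = character()), class = "pdb_structure")
}

#' Write all outputs of a fitted state to a directory
#' @param fit a \code{pka_fit}
#' @param outdir output directory (created if absent)
#' @return outdir, invisibly
#' @export
write_fit <- function(fit, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  pk <- data.frame(site = names(fit$pka), pka = fit$pka)
  write.table(pk, file.path(outdir, "pka.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  for (tg in names(fit$tables)) {
    tb <- fit$tables[[tg]]
    fn <- paste0("contributions_", gsub("[^A-Za-z0-9]", "_", tg), ".tsv")
    con <- file(file.path(outdir, fn), "w")
    writeLines(paste("#", attr(tb, "sign_convention")), con)
    write.table(as.data.frame(tb), con, sep = "\t", row.names = FALSE,
                quote = FALSE)
    close(con)
  }
  write.table(as.data.frame(fit$hbonds),
              file.path(outdir, "hbonds.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  jsonlite::write_json(fit$manifest,
                       file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(outdir)
}

#' Fit state-dependent pKa values of a structure
#'
#' The package's central fitting function: takes a structure and run
#' options, executes the full continuum-electrostatics titration
#' pipeline, and returns a fitted object with \code{print},
#' \code{summary}, \code{coef} and \code{plot} methods.
#'
#' @param structure path to a PDB file or a \code{pdb_structure}
#' @param seed RNG seed (mandatory)
#' @param state_label label for the state
#' @param ... further configuration fields (see
#'   \code{\link{validate_config}})
#' @return a \code{pka_fit}
#' @export
#' @examples
#' \donttest{
#' mc <- make_model_compound("Asp")
#' fit <- fit_pka(mc, seed = 1, levels = c(2.0, 1.0))
#' coef(fit)  # recovers the Asp reference pKa of 4.0
#' }
fit_pka <- function(structure, seed, state_label = "state", ...) {
  config <- c(list(structure = structure, seed = seed), list(...))
  run_state(config, state_label = state_label)
}

#' @export
print.pka_fit <- function(x, ...) {
  cat("Continuum-electrostatics pKa fit [", x$state_label, "]\n",
      sep = "")
  cat(nrow(x$system$sites), "titratable sites;",
      nrow(x$structure$atoms), "atoms\n")
  cat("pKa (bias-potential titration at pH ", x$config$pH, "):\n",
      sep = "")
  print(round(x$pka, 2))
  invisible(x)
}

#' @export
summary.pka_fit <- function(object, ...) {
  df <- data.frame(site = object$system$sites$site_id,
                   kind = object$system$sites$kind,
                   pka_ref = object$system$sites$pka_ref,
                   pka_intr = object$system$pkintr)
  df$pka <- object$pka[match(df$site, names(object$pka))]
  out <- list(state_label = object$state_label, sites = df,
              W = interaction_matrix(object$system),
              n_hbonds = nrow(object$hbonds),
              hole = object$hole,
              charge_set = object$system$charge_set)
  class(out) <- "summary.pka_fit"
  out
}

#' @export
print.summary.pka_fit <- function(x, ...) {
  cat("State:", x$state_label, "  (charge set ", x$charge_set, ")\n",
      sep = "")
  print(transform(x$sites, pka_ref = round(pka_ref, 2),
                  pka_intr = round(pka_intr, 2),
                  pka = round(pka, 2)), row.names = FALSE)
  cat("strongest coupling |W| =", round(max(abs(x$W)), 2), "pK\n")
  cat("H-bond edges:", x$n_hbonds, "\n")
  if (!is.null(x$hole)) cat("special-pair hole applied, ratio ",
                            paste(x$hole$ratio, collapse = ":"), "\n")
  invisible(x)
}

#' @export
coef.pka_fit <- function(object, ...) object$pka

#' Titration curves of the fitted sites
#'
#' Mean protonation against pH from the exact partition function of the
#' fitted system (Monte Carlo means for large systems).
#' @param x a \code{pka_fit}
#' @param pH_range pH grid
#' @param ... ignored
#' @export
plot.pka_fit <- function(x, pH_range = seq(0, 14, 0.25), ...) {
  cur <- titration_curves(x$system, pH_range)
  graphics::matplot(pH_range, cur, type = "l", lty = 1,
                    xlab = "pH", ylab = "mean protonation",
                    main = paste("Titration curves:", x$state_label))
  graphics::legend("bottomleft", legend = colnames(cur) %||%
                     x$system$sites$site_id,
                   col = seq_len(ncol(cur)), lty = 1, cex = 0.7)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
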