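## Charge model: per-atom partial charges and radii for every
## protonation/redox state, and the conventions for acidic protonation,
## basic deprotonation and the special-pair cation hole.

.AMINO <- c("ALA", "GLY", "SER", "THR", "ASN", "ASP", "GLU", "LYS", "ARG",
            "TYR", "CYS", "HIS")
.BACKBONE_ATOMS <- c("N", "HN", "H", "CA", "HA", "HA1", "HA2", "C", "O",
                     "OXT")

# default (standard) protonation state at neutral pH: acids deprotonated,
# bases protonated
.DEFAULT_STATE <- c(ASP = "deprot", GLU = "deprot", LYS = "prot",
                    ARG = "prot", TYR = "prot", CYS = "prot", HIS = "HSP",
                    SER = "std", THR = "std", ASN = "std", ALA = "std",
                    GLY = "std", HOH = "std", CFR = "neutral", RDX = "ox")

# neutral reference state used for intrinsic-pKa backgrounds
.NEUTRAL_STATE <- c(ASP = "prot", GLU = "prot", LYS = "deprot",
                    ARG = "deprot", TYR = "prot", CYS = "prot", HIS = "HSD")

#' Load the shipped charge/radius library
#'
#' The library is a flat text table (resname, state, atom, charge) of
#' CHARMM22-derived partial charges for every protonation state of every
#' supported group, plus PARSE-style element radii.
#'
#' @param charges_path,radii_path optional alternative table paths
#' @return object of class \code{"charge_library"}: list with
#'   \code{entries} (named list \code{"RES|state"} of named charge vectors),
#'   \code{radii} (named numeric by element) and \code{version}
#' @export
load_charge_library <- function(charges_path = NULL, radii_path = NULL) {
  if (is.null(charges_path)) {
    charges_path <- system.file("extdata", "charge_states.tsv",
                                package = "contpka")
  }
  if (is.null(radii_path)) {
    radii_path <- system.file("extdata", "radii.tsv", package = "contpka")
  }
  tb <- read.table(charges_path, header = TRUE, sep = "\t",
                   comment.char = "#", stringsAsFactors = FALSE)
  entries <- list()
  for (k in split(seq_len(nrow(tb)), paste(tb$resname, tb$state, sep = "|"))) {
    key <- paste(tb$resname[k[1]], tb$state[k[1]], sep = "|")
    v <- tb$charge[k]
    names(v) <- tb$atom[k]
    v <- v[names(v) != "."]  # "." marks an intentionally empty atom set
    entries[[key]] <- v
  }
  rt <- read.table(radii_path, header = TRUE, sep = "\t",
                   comment.char = "#", stringsAsFactors = FALSE)
  radii <- setNames(rt$radius, rt$element)
  structure(list(entries = entries, radii = radii, version = "contpka-1"),
            class = "charge_library")
}

# cached library accessor
.lib_cache <- new.env(parent = emptyenv())
default_charge_library <- function() {
  if (is.null(.lib_cache$lib)) .lib_cache$lib <- load_charge_library()
  .lib_cache$lib
}

#' Construct a charge state
#'
#' @param state_id identifier, e.g. \code{"ASP_prot"}
#' @param atom_charges named numeric vector (atom name -> elementary charge)
#' @return object of class \code{"charge_state"} with a \code{net_charge}
#'   field equal to the charge sum
#' @export
charge_state <- function(state_id, atom_charges) {
  stopifnot(is.numeric(atom_charges), !is.null(names(atom_charges)))
  structure(list(state_id = state_id, atom_charges = atom_charges,
                 net_charge = sum(atom_charges)),
            class = "charge_state")
}

#' Library lookup as a charge state
#' @param lib a \code{charge_library}
#' @param resname residue code
#' @param state state id within the residue
#' @export
library_state <- function(lib, resname, state) {
  key <- paste(resname, state, sep = "|")
  v <- lib$entries[[key]]
  if (is.null(v)) stop("no charge-library entry for ", key)
  charge_state(paste(resname, state, sep = "_"), v)
}

#' Protonate a carboxylic acid state
#'
#' Implements the implicit-proton convention for Asp/Glu: the charges of the
#' two carboxylate oxygens are each increased by +0.5, all other atoms are
#' untouched, raising the net charge by exactly +1.
#'
#' @param base \code{charge_state} of the deprotonated acid; must contain
#'   exactly two carboxylate oxygens (OD1/OD2 or OE1/OE2)
#' @return protonated \code{charge_state}
#' @export
protonate_acidic <- function(base) {
  q <- base$atom_charges
  ox <- grep("^O[DE][12]$", names(q))
  if (length(ox) != 2) {
    stop("cannot identify exactly two carboxylate oxygens in state ",
         base$state_id, " (found ", length(ox), ")")
  }
  q[ox] <- q[ox] + 0.5
  charge_state(sub("_deprot$", "_prot", base$state_id), q)
}

#' Deprotonate a basic group state
#'
#' Implements the implicit-deprotonation convention for Arg/Lys: the charges
#' of all titratable protons are reduced symmetrically by a total unit
#' charge (1/n per proton); heavy atoms are untouched.
#'
#' @param base \code{charge_state} of the protonated base
#' @param protons atom names of the titratable protons; by default the Lys
#'   ammonium protons (HZ*) or the Arg guanidinium protons
#'   (HE, HH11, HH12, HH21, HH22) are detected
#' @return deprotonated \code{charge_state}
#' @export
deprotonate_basic <- function(base, protons = NULL) {
  q <- base$atom_charges
  if (is.null(protons)) {
    hz <- grep("^HZ[0-9]$", names(q), value = TRUE)
    gu <- intersect(c("HE", "HH11", "HH12", "HH21", "HH22"), names(q))
    protons <- if (length(hz) > 0) hz else gu
  }
  protons <- intersect(protons, names(q))
  if (length(protons) == 0) {
    stop("no titratable protons identified in state ", base$state_id)
  }
  q[protons] <- q[protons] - 1 / length(protons)
  charge_state(sub("_prot$", "_deprot", base$state_id), q)
}

#' Distribute the special-pair cation hole over two macrocycles
#'
#' Adds a unit positive charge split between the two halves of a cofactor
#' dimer with the given weight ratio (default 2:1), each half's share
#' spread over its atoms in proportion to \code{weights}.
#'
#' @param pa,pb \code{charge_state}s of the two neutral macrocycles
#' @param ratio two positive weights, e.g. \code{c(2, 1)}
#' @param weights_a,weights_b optional per-atom spreading weights (default
#'   uniform over each macrocycle's atoms)
#' @return list of two \code{charge_state}s carrying the +1 hole
#' @export
special_pair_cation <- function(pa, pb, ratio = c(2, 1),
                                weights_a = NULL, weights_b = NULL) {
  if (length(ratio) != 2 || any(ratio < 0) || sum(ratio) <= 0) {
    stop("ratio must be two non-negative weights with a positive sum")
  }
  share <- ratio / sum(ratio)
  spread <- function(cs, extra, w) {
    if (is.null(w)) w <- rep(1, length(cs$atom_charges))
    if (any(w < 0) || sum(w) <= 0) stop("non-positive spreading weights")
    q <- cs$atom_charges + extra * w / sum(w)
    charge_state(paste0(cs$state_id, "_cation"), q)
  }
  list(spread(pa, share[1], weights_a), spread(pb, share[2], weights_b))
}

# internal: charges for one residue's atoms under a given state id.
# Returns numeric vector aligned with `anames`; atoms not covered get NA.
.residue_state_charges <- function(lib, resname, state, anames) {
  out <- rep(NA_real_, length(anames))
  if (resname %in% .AMINO) {
    bbkey <- if (resname == "GLY") "BBGLY|std" else "BB|std"
    bb <- lib$entries[[bbkey]]
    hit <- match(anames, names(bb))
    out[!is.na(hit)] <- bb[hit[!is.na(hit)]]
    # HN may be recorded as H in PDB files
    out[anames == "H"] <- bb[["HN"]]
  }
  key <- paste(resname, state, sep = "|")
  sc <- lib$entries[[key]]
  if (!is.null(sc)) {
    if (length(sc) == 0) {
      # "." marker: the whole group is uncharged by definition
      out[] <- 0
    } else {
      hit <- match(anames, names(sc))
      out[!is.na(hit)] <- sc[hit[!is.na(hit)]]
    }
  }
  out
}

#' Assign per-atom charges and radii for a full structure
#'
#' Every atom receives a partial charge for its residue's assigned
#' protonation/redox state and a radius from the element table.  Sites
#' without an explicit assignment get their standard state (acids
#' deprotonated, bases protonated); fixed-state groups are set through
#' \code{assignment}.
#'
#' @param s a resolved \code{pdb_structure} with hydrogens placed
#' @param lib a \code{charge_library}
#' @param assignment named list/character: residue key \code{"chain:resseq"}
#'   -> state id (e.g. \code{"deprot"}, \code{"HSE"})
#' @param waiver residue names to be given all-zero charges without a
#'   library entry
#' @return \code{pdb_structure} with \code{charge} and \code{radius} filled
#' @export
assign_state_charges <- function(s, lib = default_charge_library(),
                                 assignment = list(), waiver = character()) {
  at <- s$atoms
  rk <- .residue_key(at)
  assignment <- unlist(assignment)
  for (key in unique(rk)) {
    idx <- which(rk == key)
    resname <- at$resname[idx[1]]
    if (resname %in% c("WAT", "TIP3", "TIP")) resname <- "HOH"
    if (resname %in% waiver) { at$charge[idx] <- 0; next }
    state <- if (key %in% names(assignment)) assignment[[key]] else
      .DEFAULT_STATE[resname]
    if (is.null(state) || is.na(state)) {
      stop("no charge-library entry for residue ", resname, " (", key,
           ") and no waiver given")
    }
    anames <- at$name[idx]
    if (resname == "HOH") anames[anames == "O"] <- "OH2"
    q <- .residue_state_charges(lib, resname, state, anames)
    if (anyNA(q)) {
      stop("atoms of residue ", resname, " ", key,
           " missing from charge entry '", state, "': ",
           paste(at$name[idx][is.na(q)], collapse = ", "))
    }
    at$charge[idx] <- q
  }
  rad <- lib$radii[toupper(at$element)]
  rad[is.na(rad)] <- lib$radii[["X"]]
  at$radius <- unname(rad)
  s$atoms <- at
  s$charge_set <- lib$version
  s
}
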