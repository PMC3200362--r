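## Structure input/output: PDB reading and writing (via bio3d), alternate
## conformer resolution, the crystal-water policy, and geometric queries.

#' Read a PDB structure
#'
#' Parses ATOM/HETATM records into an atom table.  All alternate-location
#' records are retained; resolve them with \code{\link{resolve_conformer}}
#' before any electrostatic calculation.  Cofactors (HETATM) and waters are
#' kept and flagged.
#'
#' @param pdb_source path to a PDB file, or a character vector of PDB lines
#' @param model_index which MODEL to read from a multi-model file (1-based)
#' @return an object of class \code{"pdb_structure"}: a list with elements
#'   \code{atoms} (data frame with one row per atom: serial, name, element,
#'   resname, chain, resseq, altloc, x, y, z, occupancy, het, radius,
#'   charge), \code{conformer_label} and \code{waters_kept}
#' @export
read_structure <- function(pdb_source, model_index = 1) {
  if (length(pdb_source) == 1 && !grepl("\n", pdb_source) &&
      file.exists(pdb_source)) {
    lines <- readLines(pdb_source, warn = FALSE)
  } else {
    lines <- unlist(strsplit(paste(pdb_source, collapse = "\n"), "\n"))
  }
  .validate_pdb_lines(lines)
  lines <- .select_model(lines, model_index)
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  writeLines(lines, tf)
  pdb <- bio3d::read.pdb(tf, verbose = FALSE, rm.alt = FALSE)
  at <- pdb$atom
  element <- at$elesy
  bad <- is.na(element) | !nzchar(trimws(element))
  if (any(bad)) element[bad] <- .element_from_name(at$elety[bad])
  atoms <- data.frame(
    serial = at$eleno,
    name = trimws(at$elety),
    element = trimws(element),
    resname = trimws(at$resid),
    chain = ifelse(is.na(at$chain), "", at$chain),
    resseq = at$resno,
    altloc = ifelse(is.na(at$alt), "", at$alt),
    x = at$x, y = at$y, z = at$z,
    occupancy = ifelse(is.na(at$o), 1, at$o),
    het = at$type == "HETATM",
    radius = NA_real_,
    charge = 0,
    stringsAsFactors = FALSE
  )
  structure(list(atoms = atoms, conformer_label = NA_character_,
                 waters_kept = .water_ids(atoms)),
            class = "pdb_structure")
}

.validate_pdb_lines <- function(lines) {
  rec <- substr(lines, 1, 6)
  atom_lines <- which(rec %in% c("ATOM  ", "HETATM"))
  for (i in atom_lines) {
    ln <- lines[i]
    ok <- nchar(ln) >= 54 &&
      !anyNA(suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                           substr(ln, 39, 46),
                                           substr(ln, 47, 54)))))
    if (!ok) stop("malformed ATOM/HETATM record at line ", i, ": ", ln)
  }
  invisible(TRUE)
}

.select_model <- function(lines, model_index) {
  starts <- grep("^MODEL", lines)
  if (length(starts) == 0) {
    if (model_index != 1) stop("model index ", model_index,
                               " not present (single-model file)")
    return(lines)
  }
  if (model_index > length(starts)) {
    stop("model index ", model_index, " not present (file has ",
         length(starts), " models)")
  }
  ends <- grep("^ENDMDL", lines)
  if (length(ends) < length(starts)) ends <- c(ends, length(lines))
  lines[(starts[model_index] + 1):(ends[model_index] - 1)]
}

.element_from_name <- function(name) {
  nm <- gsub("[0-9']", "", trimws(name))
  first2 <- toupper(substr(nm, 1, 2))
  ifelse(first2 %in% c("FE", "MG", "ZN", "MN", "CA_", "CL", "NA_", "BR"),
         substr(nm, 1, 2), substr(toupper(nm), 1, 1))
}

.water_ids <- function(atoms) {
  w <- atoms$resname %in% c("HOH", "WAT", "TIP3", "TIP")
  unique(paste(atoms$resname[w], atoms$chain[w], atoms$resseq[w]))
}

.residue_key <- function(atoms) paste(atoms$chain, atoms$resseq, sep = ":")

#' Write a structure to PDB format
#'
#' @param s a \code{pdb_structure}
#' @param file output path
#' @return the file path, invisibly
#' @export
write_structure <- function(s, file) {
  at <- s$atoms
  bio3d::write.pdb(
    file = file,
    xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
    type = ifelse(at$het, "HETATM", "ATOM"),
    resno = at$resseq, resid = at$resname, eleno = at$serial,
    elety = at$name, chain = at$chain,
    alt = ifelse(nzchar(at$altloc), at$altloc, NA),
    o = at$occupancy, b = rep(0, nrow(at)), elesy = at$element,
    end = TRUE
  )
  invisible(file)
}

#' Resolve alternate conformers into a single named state
#'
#' For every atom recorded with more than one alternate-location indicator,
#' keeps only the requested label; atoms with a blank altloc are kept as
#' they are.  After resolution no two atoms share (chain, resseq, name) and
#' every altloc is blank.
#'
#' @param s a \code{pdb_structure}
#' @param label single-character altloc to keep (e.g. "A")
#' @param state_name name for the resolved state (e.g. "Y_dark")
#' @return resolved \code{pdb_structure} with \code{conformer_label} set
#' @export
resolve_conformer <- function(s, label, state_name = label) {
  at <- s$atoms
  key <- paste(at$chain, at$resseq, at$name)
  has_alt <- nzchar(at$altloc)
  groups <- unique(key[has_alt])
  missing <- vapply(groups, function(g) {
    !label %in% at$altloc[key == g]
  }, logical(1))
  if (any(missing)) {
    stop("alternate-conformer group(s) lacking label '", label, "': ",
         paste(groups[missing], collapse = ", "))
  }
  keep <- !has_alt | at$altloc == label
  at <- at[keep, , drop = FALSE]
  at$altloc <- ""
  dup <- duplicated(paste(at$chain, at$resseq, at$name))
  at <- at[!dup, , drop = FALSE]
  rownames(at) <- NULL
  s$atoms <- at
  s$conformer_label <- state_name
  s
}

#' Apply the crystal-water policy
#'
#' Removes all crystal waters except those listed.  Cavities left by removed
#' waters are implicitly filled with the solvent dielectric by the
#' dielectric-map builder (no cavity patching).
#'
#' @param s a \code{pdb_structure}
#' @param keep character vector of water identifiers, either
#'   \code{"HOH M 2001"} (resname chain resseq) or \code{"M:2001"}; empty
#'   vector removes every water
#' @return \code{pdb_structure} without the discarded waters
#' @export
apply_water_policy <- function(s, keep = character()) {
  at <- s$atoms
  isw <- at$resname %in% c("HOH", "WAT", "TIP3", "TIP")
  wid <- paste(at$resname, at$chain, at$resseq)
  wid2 <- paste(at$chain, at$resseq, sep = ":")
  keep_norm <- vapply(keep, function(k) {
    k <- trimws(k)
    if (grepl(":", k)) k else {
      p <- strsplit(k, "\\s+")[[1]]
      if (length(p) == 3) paste(p[2], p[3], sep = ":") else k
    }
  }, character(1))
  present <- unique(wid2[isw])
  absent <- setdiff(keep_norm, present)
  if (length(absent) > 0) {
    stop("water id(s) not found: ", paste(absent, collapse = ", "))
  }
  drop <- isw & !(wid2 %in% keep_norm)
  s$atoms <- at[!drop, , drop = FALSE]
  rownames(s$atoms) <- NULL
  s$waters_kept <- .water_ids(s$atoms)
  s
}

#' Select atoms by "chain:resseq:atomname" selector
#'
#' @param s a \code{pdb_structure}
#' @param sel selector string; fields may be left empty to match anything,
#'   e.g. \code{":162:OH"}
#' @return integer vector of atom row indices
#' @export
select_atoms <- function(s, sel) {
  p <- strsplit(sel, ":")[[1]]
  p <- c(p, rep("", 3 - length(p)))
  at <- s$atoms
  idx <- rep(TRUE, nrow(at))
  if (nzchar(p[1])) idx <- idx & at$chain == p[1]
  if (nzchar(p[2])) idx <- idx & at$resseq == as.integer(p[2])
  if (nzchar(p[3])) idx <- idx & at$name == trimws(p[3])
  which(idx)
}

#' Distance between two uniquely selected atoms
#'
#' @param s a \code{pdb_structure}
#' @param sel1,sel2 selectors (see \code{\link{select_atoms}})
#' @return Euclidean distance in Angstrom
#' @export
measure_distance <- function(s, sel1, sel2) {
  i <- select_atoms(s, sel1)
  j <- select_atoms(s, sel2)
  if (length(i) != 1) stop("selector '", sel1, "' matches ", length(i),
                           " atoms (must be exactly 1)")
  if (length(j) != 1) stop("selector '", sel2, "' matches ", length(j),
                           " atoms (must be exactly 1)")
  a <- s$atoms[i, c("x", "y", "z")]
  b <- s$atoms[j, c("x", "y", "z")]
  sqrt(sum((as.numeric(a) - as.numeric(b))^2))
}

#' @export
print.pdb_structure <- function(x, ...) {
  at <- x$atoms
  cat("PDB structure:", nrow(at), "atoms,",
      length(unique(.residue_key(at))), "residues\n")
  if (!is.na(x$conformer_label))
    cat("  conformer state:", x$conformer_label, "\n")
  nalt <- sum(nzchar(at$altloc))
  if (nalt > 0) cat("  unresolved altloc records:", nalt, "\n")
  if (length(x$waters_kept) > 0)
    cat("  waters:", length(x$waters_kept), "\n")
  invisible(x)
}

# coordinates of one uniquely identified atom (chain, resseq, name)
.atom_xyz <- function(s, chain, resseq, name) {
  at <- s$atoms
  i <- which(at$chain == chain & at$resseq == resseq & at$name == name)
  if (length(i) != 1) stop("atom ", chain, ":", resseq, ":", name,
                           " matches ", length(i), " atoms")
  as.numeric(at[i, c("x", "y", "z")])
}
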