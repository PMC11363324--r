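#' Structural frames and residue-role tagging
#'
#' A frame set is a long data frame of atoms across one or more structural
#' snapshots, with columns `frame`, `eleno` (atom serial), `elety` (atom
#' name), `resname`, `chain`, `resno`, `element`, `x`, `y`, `z` (Angstrom).
#' Analyses never hard-code author residue numbering: atoms are located
#' through a *roles* configuration mapping a functional role (e.g. the
#' sodium-site carboxylate, Ballesteros-Weinstein D2.50) to residue
#' name/number/atom names, so the same detectors run on any receptor
#' numbering scheme.
#'
#' @name frames
NULL

FRAME_COLS <- c("frame", "eleno", "elety", "resname", "chain", "resno",
                "element", "x", "y", "z")

#' Default residue-role configuration
#'
#' Roles used throughout the pipeline, preconfigured for a mu-opioid
#' receptor system: the ligand hydroxyl oxygen (`ligand_hydroxyl`), the
#' sodium-site aspartate carboxylate oxygens at residue 114 (D2.50,
#' `carboxylate`), water oxygens (`water`), the tyrosine-7.43 phenol ring
#' and hydroxyl (`tyr_ring`, `tyr_oh`), the glutamine-2.60 amide
#' (`gln_amide`), and the ligand's amide-phenyl ring (`ligand_ring`).
#'
#' @param lig_resname residue name of the ligand (default `"LIG"`)
#' @param asp_resno residue number of the sodium-site aspartate
#' @param tyr_resno residue number of the TM7 tyrosine
#' @param gln_resno residue number of the TM2 glutamine
#' @return named list of role selectors; each selector is a list with any
#'   of `resname`, `resno`, `chain`, `elety` used as equality filters.
#' @export
default_roles <- function(lig_resname = "LIG", asp_resno = 114L,
                          tyr_resno = 326L, gln_resno = 124L) {
  list(
    ligand_hydroxyl = list(resname = lig_resname, elety = "O1"),
    carboxylate = list(resname = "ASP", resno = asp_resno,
                       elety = c("OD1", "OD2")),
    water = list(resname = "HOH", elety = "O"),
    tyr_oh = list(resname = "TYR", resno = tyr_resno, elety = "OH"),
    tyr_ring = list(resname = "TYR", resno = tyr_resno,
                    elety = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
    gln_amide = list(resname = "GLN", resno = gln_resno,
                     elety = c("NE2", "OE1")),
    ligand_ring = list(resname = lig_resname,
                       elety = c("C1", "C2", "C3", "C4", "C5", "C6"))
  )
}

#' Select atoms matching a role
#'
#' @param atoms data frame of atoms (one frame)
#' @param role a role selector list (see [default_roles()])
#' @param role_name name used in error messages
#' @param required if `TRUE`, fail when no atom matches
#' @return the matching rows of `atoms`
#' @export
select_role <- function(atoms, role, role_name = "role", required = TRUE) {
  keep <- rep(TRUE, nrow(atoms))
  for (field in intersect(names(role), c("resname", "resno", "chain", "elety"))) {
    keep <- keep & atoms[[field]] %in% role[[field]]
  }
  out <- atoms[keep, , drop = FALSE]
  if (required && nrow(out) == 0L) {
    stop("no atoms match role '", role_name, "'", call. = FALSE)
  }
  out
}

#' Validate a single-frame atom table
#'
#' Checks column presence, finite coordinates, and that singular roles
#' (the ligand hydroxyl) resolve to exactly one atom when a roles config
#' is supplied.
#'
#' @param atoms data frame of atoms
#' @param roles optional roles list to check against
#' @return `atoms`, invisibly
#' @export
validate_frame <- function(atoms, roles = NULL) {
  miss <- setdiff(setdiff(FRAME_COLS, "frame"), names(atoms))
  if (length(miss)) stop("frame is missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite coordinates in frame", call. = FALSE)
  if (anyDuplicated(atoms$eleno)) stop("duplicate atom serials", call. = FALSE)
  if (!is.null(roles)) {
    lig <- select_role(atoms, roles$ligand_hydroxyl, "ligand_hydroxyl")
    if (nrow(lig) != 1L) stop("role 'ligand_hydroxyl' must be unique", call. = FALSE)
    select_role(atoms, roles$carboxylate, "carboxylate")
  }
  invisible(atoms)
}

#' Split a frame set into per-frame atom tables
#' @param frames frame-set data frame with a `frame` column
#' @return named list of single-frame data frames, in frame order
#' @export
split_frames <- function(frames) {
  ids <- sort(unique(frames$frame))
  split(frames, factor(frames$frame, levels = ids))
}

# ---- multi-model PDB I/O ----------------------------------------------------

pdb_atom_line <- function(rec, eleno, elety, resname, chain, resno, x, y, z,
                          element) {
  # PDB columns: name left-padded so 1-2 character names start in column 14
  name4 <- if (nchar(elety) < 4L) sprintf(" %-3s", elety) else elety
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, eleno, name4, "", resname, chain, resno, "", x, y, z,
          1.00, 0.00, element)
}

#' Write a frame set as a multi-model PDB file
#'
#' One MODEL/ENDMDL block per frame. Waters (resname `HOH`) and the ligand
#' (non-standard residue names) are written as `HETATM`, receptor residues
#' as `ATOM`. Coordinates are printed with 3 decimals, the PDB fixed-column
#' convention.
#'
#' @param frames frame-set data frame
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_frames_pdb <- function(frames, path) {
  std_res <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
               "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
               "TYR", "VAL")
  con <- file(path, "w")
  on.exit(close(con))
  ids <- sort(unique(frames$frame))
  for (k in seq_along(ids)) {
    fr <- frames[frames$frame == ids[k], , drop = FALSE]
    writeLines(sprintf("MODEL     %4d", k), con)
    rec <- ifelse(fr$resname %in% std_res, "ATOM", "HETATM")
    lines <- mapply(pdb_atom_line, rec, fr$eleno, fr$elety, fr$resname,
                    fr$chain, fr$resno, fr$x, fr$y, fr$z, fr$element)
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a multi-model PDB file into a frame set
#'
#' Parsing is delegated to [bio3d::read.pdb()] with `multi = TRUE`; the
#' per-model coordinate matrix is unrolled into the long frame-set layout.
#'
#' @param path PDB file path
#' @return frame-set data frame
#' @export
read_frames_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  xyz <- pdb$xyz                       # nmodel x (3*natom)
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  at$chain[is.na(at$chain)] <- ""
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == "")) {
    elem <- substr(trimws(at$elety), 1L, 1L)
  }
  out <- lapply(seq_len(nrow(xyz)), function(m) {
    co <- matrix(xyz[m, ], ncol = 3L, byrow = TRUE)
    data.frame(frame = m, eleno = at$eleno, elety = trimws(at$elety),
               resname = trimws(at$resid), chain = at$chain,
               resno = at$resno, element = trimws(elem),
               x = co[, 1], y = co[, 2], z = co[, 3],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
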