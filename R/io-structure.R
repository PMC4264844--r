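#' Read a PDB structure
#'
#' Parses a PDB file into a [topology()] plus the single frame of
#' coordinates it carries. Where a residue carries alternate locations,
#' only the highest-occupancy altloc of each atom is retained (first on
#' ties). Parsing is delegated to \pkg{bio3d} after a light per-line
#' validation pass so that malformed records are reported by line number.
#'
#' @param path PDB file path.
#' @param solvent_resnames residue names treated as solvent.
#' @return list with elements `topology` (a [topology()]) and `coords`
#'   (N x 3 matrix, Angstrom).
#' @export
read_structure <- function(path, solvent_resnames = SOLVENT_RESNAMES) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(rec))
    stop("no ATOM/HETATM records in '", path, "' (empty or not a PDB file)")
  for (ln in which(rec)) {
    l <- lines[ln]
    if (nchar(l) < 54)
      stop("malformed PDB record at line ", ln, ": too short")
    xyz <- substring(l, c(31, 39, 47), c(38, 46, 54))
    if (anyNA(suppressWarnings(as.numeric(xyz))))
      stop("malformed PDB record at line ", ln,
           ": non-numeric coordinate field")
  }
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE, multi = FALSE,
                                  rm.alt = FALSE),
                  error = function(e)
                    stop("PDB parse error in '", path, "': ",
                         conditionMessage(e)))
  at <- pdb$atom

  # altloc handling: keep the highest-occupancy location of each atom
  key <- paste(at$chain, at$resno, at$insert, at$elety)
  occ <- ifelse(is.finite(at$o), at$o, 1)
  keep <- rep(TRUE, nrow(at))
  alt <- !is.na(at$alt) & at$alt != "" & at$alt != " "
  for (k in unique(key[alt])) {
    rows <- which(key == k)
    if (length(rows) > 1) {
      best <- rows[which.max(occ[rows])]
      keep[setdiff(rows, best)] <- FALSE
    }
  }
  at <- at[keep, , drop = FALSE]

  elem <- at$elesy
  if (is.null(elem)) elem <- rep(NA_character_, nrow(at))
  blank <- is.na(elem) | trimws(elem) == ""
  elem[blank] <- substr(trimws(at$elety[blank]), 1, 1)
  elem <- trimws(elem)

  chain <- at$chain
  chain[is.na(chain)] <- " "
  atoms <- data.frame(
    serial = at$eleno, name = trimws(at$elety), element = elem,
    mass = element_mass(elem), resno = at$resno, resid = trimws(at$resid),
    chain = chain, type = at$type, stringsAsFactors = FALSE)

  groups <- list()
  is_solv <- atoms$resid %in% solvent_resnames
  is_prot <- atoms$type == "ATOM" & !is_solv
  is_lig <- atoms$type == "HETATM" & !is_solv
  if (any(is_prot)) groups$protein <- which(is_prot)
  if (any(is_lig)) groups$ligand <- which(is_lig)
  ca <- which(is_prot & atoms$name == "CA")
  if (length(ca)) groups$calpha <- ca

  top <- topology(atoms, groups, solvent_resnames = solvent_resnames)
  coords <- cbind(at$x, at$y, at$z)
  dimnames(coords) <- NULL
  list(topology = top, coords = coords)
}

#' Write a PDB structure
#'
#' @param path output file path.
#' @param top a [topology()].
#' @param coords N x 3 coordinate matrix (Angstrom).
#' @return `path`, invisibly.
#' @export
write_structure <- function(path, top, coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) != n_atoms(top) || ncol(coords) != 3)
    stop("coords must be an N x 3 matrix matching the topology")
  a <- top$atoms
  type <- if (!is.null(a$type)) a$type else rep("ATOM", nrow(a))
  bio3d::write.pdb(file = path, xyz = as.vector(t(coords)),
                   type = type, eleno = a$serial, elety = a$name,
                   resid = a$resid, resno = a$resno, chain = a$chain,
                   elesy = a$element, o = rep(1, nrow(a)),
                   b = rep(0, nrow(a)))
  invisible(path)
}
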