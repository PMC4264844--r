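#' Build a molecular topology
#'
#' A topology holds the per-atom bookkeeping (serial, name, element, mass,
#' residue, chain) plus named atom groups: ligand moieties (e.g. core, iBu,
#' Tol, Ethe), protein regions (binding pocket, mobile loop, loop tip) and
#' the solvent. Coordinates live in a separate [trajectory()] or plain
#' matrix so the same topology can serve many frames.
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`, `mass`,
#'   `resno`, `resid`, `chain`. `mass` may be omitted and is then filled
#'   from the element.
#' @param groups named list of integer atom-index vectors. Moiety groups
#'   must be pairwise disjoint.
#' @param moieties character vector naming which entries of `groups` are
#'   ligand moieties.
#' @param solvent_resnames residue names identifying solvent molecules.
#' @return an object of class `topology`.
#' @export
topology <- function(atoms, groups = list(), moieties = character(),
                     solvent_resnames = SOLVENT_RESNAMES) {
  req <- c("serial", "name", "element", "resno", "resid", "chain")
  miss <- setdiff(req, names(atoms))
  if (length(miss))
    stop("atoms data.frame lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(atoms$serial))
    stop("atom serial numbers must be unique within a topology")
  if (is.null(atoms$mass)) atoms$mass <- element_mass(atoms$element)
  if (any(!is.finite(atoms$mass)) || any(atoms$mass <= 0))
    stop("all atom masses must be positive")
  n <- nrow(atoms)
  for (g in names(groups)) {
    idx <- groups[[g]]
    if (length(idx) == 0 || any(idx < 1L | idx > n))
      stop("group '", g, "' is empty or indexes atoms outside the topology")
    groups[[g]] <- as.integer(idx)
  }
  moieties <- intersect(moieties, names(groups))
  if (length(moieties) > 1) {
    all_m <- unlist(groups[moieties])
    if (anyDuplicated(all_m))
      stop("moiety groups must be pairwise disjoint")
  }
  is_solvent <- atoms$resid %in% solvent_resnames
  structure(
    list(atoms = atoms, groups = groups, moieties = moieties,
         solvent = which(is_solvent),
         solvent_resnames = solvent_resnames),
    class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  cat("topology:", nrow(x$atoms), "atoms,",
      length(unique(paste(x$atoms$chain, x$atoms$resno))), "residues\n")
  if (length(x$groups))
    cat("  groups:",
        paste(sprintf("%s[%d]", names(x$groups), lengths(x$groups)),
              collapse = " "), "\n")
  if (length(x$solvent))
    cat("  solvent atoms:", length(x$solvent), "\n")
  invisible(x)
}

#' Number of atoms in a topology
#' @param top a [topology()].
#' @return integer atom count.
#' @export
n_atoms <- function(top) nrow(top$atoms)

#' Atom indices of a named group
#' @param top a [topology()].
#' @param name group name.
#' @return integer vector of atom indices.
#' @export
group_atoms <- function(top, name) {
  if (!name %in% names(top$groups))
    stop("topology has no group named '", name, "'")
  top$groups[[name]]
}

#' Build a trajectory
#'
#' Time-ordered coordinate frames tied to a topology.
#'
#' @param top a [topology()].
#' @param coords numeric array of dimension (atoms, 3, frames), or an
#'   N x 3 matrix for a single frame. Angstrom.
#' @param dt time per frame, ps.
#' @return an object of class `trajectory`.
#' @export
trajectory <- function(top, coords, dt) {
  if (is.matrix(coords)) coords <- array(coords, c(nrow(coords), 3, 1))
  d <- dim(coords)
  if (length(d) != 3 || d[2] != 3)
    stop("coords must be an (atoms, 3, frames) array")
  if (d[1] != n_atoms(top))
    stop("frame atom count (", d[1], ") does not match topology (",
         n_atoms(top), ")")
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0)
    stop("dt must be a single positive number (ps per frame)")
  structure(list(topology = top, coords = coords, dt = dt),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("trajectory:", n_frames(x), "frames x", n_atoms(x$topology),
      "atoms, dt =", x$dt, "ps\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a [trajectory()].
#' @return integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Coordinates of one frame
#' @param traj a [trajectory()].
#' @param i frame index (1-based).
#' @return N x 3 coordinate matrix (Angstrom).
#' @export
frame_coords <- function(traj, i) {
  if (i < 1 || i > n_frames(traj))
    stop("frame index ", i, " out of range 1..", n_frames(traj))
  traj$coords[, , i, drop = TRUE]
}

#' Restrict a trajectory to a frame interval
#' @param traj a [trajectory()].
#' @param from,to first and last frame index (inclusive).
#' @return a [trajectory()] over the sub-interval.
#' @export
subset_frames <- function(traj, from, to) {
  if (from < 1 || to > n_frames(traj) || from > to)
    stop("invalid frame interval [", from, ", ", to, "]")
  trajectory(traj$topology, traj$coords[, , from:to, drop = FALSE], traj$dt)
}

#' Per-frame distance between two atoms
#' @param traj a [trajectory()].
#' @param i,j atom indices.
#' @return numeric vector, one distance (Angstrom) per frame.
#' @export
pair_distance_series <- function(traj, i, j) {
  dx <- traj$coords[i, , , drop = FALSE] - traj$coords[j, , , drop = FALSE]
  sqrt(colSums(matrix(dx, nrow = 3)^2))
}
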