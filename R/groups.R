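#' Read a group-definition config
#'
#' The config is a YAML document naming the reaction-coordinate atom pair,
#' the binding-pocket residues, the ligand moiety definitions, and optional
#' named flat-bottom (NOE-style) restraint sets:
#'
#' ```yaml
#' reaction_coordinate: ["LIG 100 N7", "GLU 5 CA"]
#' pocket_residues: [26, 36, 46, 53, 54, 55, 56, 59, 82, 87, 90, 91]
#' moieties:
#'   core: ["LIG 100 C2", "LIG 100 N7"]
#'   Tol:  ["LIG 100 C17"]
#' restraints:
#'   C3:
#'     - {pair: ["LIG 100 N7", "GLU 5 CA"], rmin: 2.5, rmax: 3.5, k: 10}
#' ```
#'
#' Selectors are `"RESNAME RESNO ATOMNAME"`, `"RESNO ATOMNAME"` (any residue
#' name) or `"RESNAME RESNO"` (all atoms of the residue). Residue numbers
#' follow the input file verbatim.
#'
#' @param path YAML file path.
#' @return an object of class `group_config`.
#' @export
read_group_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  cfg <- yaml::read_yaml(path)
  group_config(reaction_coordinate = cfg$reaction_coordinate,
               pocket_residues = cfg$pocket_residues,
               moieties = cfg$moieties,
               restraints = cfg$restraints)
}

#' Construct a group config in code
#'
#' @param reaction_coordinate character vector of two atom selectors
#'   (ligand anchor, protein anchor).
#' @param pocket_residues integer vector of binding-pocket residue numbers.
#' @param moieties named list of selector vectors, one entry per ligand
#'   moiety.
#' @param restraints named list of restraint sets; each set is a list of
#'   `list(pair = c(sel, sel), rmin =, rmax =, k =)` entries with `rmin <=
#'   rmax` (Angstrom) and `k >= 0` (kcal/mol/A^2).
#' @return an object of class `group_config`.
#' @export
group_config <- function(reaction_coordinate = NULL, pocket_residues = NULL,
                         moieties = NULL, restraints = NULL) {
  if (!is.null(reaction_coordinate) && length(reaction_coordinate) != 2)
    stop("reaction_coordinate must name exactly two atoms")
  for (set in names(restraints)) {
    for (r in restraints[[set]]) {
      if (is.null(r$pair) || length(r$pair) != 2)
        stop("restraint in set '", set, "' lacks a two-atom pair")
      if (r$rmin > r$rmax)
        stop("restraint in set '", set, "' has rmin > rmax")
      if (r$k < 0)
        stop("restraint in set '", set, "' has negative force constant")
    }
  }
  structure(list(reaction_coordinate = reaction_coordinate,
                 pocket_residues = pocket_residues,
                 moieties = moieties, restraints = restraints),
            class = "group_config")
}

parse_selector <- function(sel) {
  tok <- strsplit(trimws(sel), "\\s+")[[1]]
  if (length(tok) == 3)
    list(resid = tok[1], resno = as.integer(tok[2]), name = tok[3])
  else if (length(tok) == 2) {
    if (grepl("^[0-9]+$", tok[1]))
      list(resid = NA, resno = as.integer(tok[1]), name = tok[2])
    else
      list(resid = tok[1], resno = as.integer(tok[2]), name = NA)
  } else stop("cannot parse atom selector '", sel, "'")
}

match_selector <- function(sel, top) {
  p <- parse_selector(sel)
  if (is.na(p$resno)) stop("selector '", sel, "' has no residue number")
  a <- top$atoms
  hit <- a$resno == p$resno
  if (!is.na(p$resid)) hit <- hit & a$resid == p$resid
  if (!is.na(p$name)) hit <- hit & a$name == p$name
  which(hit)
}

resolve_one <- function(sel, top) {
  idx <- match_selector(sel, top)
  if (length(idx) == 0)
    stop("selector '", sel, "' matches no atom in the topology")
  if (length(idx) > 1)
    stop("selector '", sel, "' is ambiguous: matches ", length(idx),
         " atoms where one was expected")
  idx
}

#' Resolve a group config against a topology
#'
#' Every selector must resolve; an unresolved or ambiguous selector is an
#' error, never a silently empty group. Moiety groups are checked for
#' pairwise disjointness.
#'
#' @param config a [group_config()].
#' @param top a [topology()].
#' @return list with `rc_atoms` (length-2 integer vector or NULL), `pocket`
#'   (atom indices of the pocket residues, protein atoms only), `moieties`
#'   (named list of index vectors) and `restraints` (named list of resolved
#'   restraint data.frames with columns i, j, rmin, rmax, k).
#' @export
resolve_groups <- function(config, top) {
  out <- list(rc_atoms = NULL, pocket = NULL, moieties = list(),
              restraints = list())
  if (!is.null(config$reaction_coordinate))
    out$rc_atoms <- vapply(config$reaction_coordinate, resolve_one,
                           integer(1), top = top, USE.NAMES = FALSE)
  if (!is.null(config$pocket_residues)) {
    a <- top$atoms
    solv <- seq_len(nrow(a)) %in% top$solvent
    idx <- which(a$resno %in% config$pocket_residues & !solv)
    if (!is.null(top$groups$protein)) idx <- intersect(idx, top$groups$protein)
    missing <- setdiff(config$pocket_residues, a$resno[idx])
    if (length(missing))
      stop("pocket residue(s) absent from topology: ",
           paste(missing, collapse = ", "))
    out$pocket <- idx
  }
  for (m in names(config$moieties)) {
    idx <- unique(unlist(lapply(config$moieties[[m]], function(s) {
      hit <- match_selector(s, top)
      if (!length(hit))
        stop("moiety '", m, "': selector '", s, "' matches no atom")
      hit
    })))
    out$moieties[[m]] <- sort(idx)
  }
  if (length(out$moieties) > 1) {
    all_m <- unlist(out$moieties)
    if (anyDuplicated(all_m))
      stop("moiety groups overlap after resolution")
  }
  for (set in names(config$restraints)) {
    rs <- config$restraints[[set]]
    out$restraints[[set]] <- data.frame(
      i = vapply(rs, function(r) resolve_one(r$pair[1], top), integer(1)),
      j = vapply(rs, function(r) resolve_one(r$pair[2], top), integer(1)),
      rmin = vapply(rs, function(r) as.numeric(r$rmin), numeric(1)),
      rmax = vapply(rs, function(r) as.numeric(r$rmax), numeric(1)),
      k = vapply(rs, function(r) as.numeric(r$k), numeric(1)))
  }
  out
}
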