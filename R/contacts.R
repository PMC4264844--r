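#' Contact census over an ensemble of trajectories
#'
#' A ligand-protein atom pair is a contact candidate when its distance is
#' strictly below `cutoff` in strictly more than `min_freq` of the frames
#' of at least one simulation. Distance statistics are pooled over all
#' frames of all simulations; heavy atoms only (hydrogens are excluded
#' from the census, as is conventional for contact counting).
#'
#' @param trajs a [trajectory()] or list of trajectories sharing one
#'   topology (one entry per independent simulation).
#' @param ligand_atoms,protein_atoms atom index vectors; default the
#'   topology's `ligand` and `protein` groups.
#' @param cutoff contact cutoff, A (strict `<`).
#' @param min_freq frequency filter (strict `>`).
#' @param heavy_only drop hydrogens from both sets.
#' @return data.frame of class `contact_records`, one row per retained
#'   pair: `i`, `j` (atom indices), `lig_name`, `prot_name`, `prot_resid`,
#'   `prot_resno`, `freq_max` (largest per-simulation frequency),
#'   `pooled_mean`, `pooled_sd` (A), `class` ("permanent"/"transient"),
#'   plus attributes `freq` (pairs x simulations matrix) and `cutoff`.
#' @export
candidate_contacts <- function(trajs, ligand_atoms = NULL,
                               protein_atoms = NULL, cutoff = 4,
                               min_freq = 0.5, heavy_only = TRUE) {
  if (inherits(trajs, "trajectory")) trajs <- list(trajs)
  if (!length(trajs)) stop("at least one trajectory is required")
  top <- trajs[[1]]$topology
  if (is.null(ligand_atoms)) ligand_atoms <- group_atoms(top, "ligand")
  if (is.null(protein_atoms)) protein_atoms <- group_atoms(top, "protein")
  if (heavy_only) {
    h <- toupper(top$atoms$element) == "H"
    ligand_atoms <- ligand_atoms[!h[ligand_atoms]]
    protein_atoms <- protein_atoms[!h[protein_atoms]]
  }
  if (!length(ligand_atoms) || !length(protein_atoms))
    stop("empty ligand or protein atom set")

  pairs <- expand.grid(i = ligand_atoms, j = protein_atoms,
                       KEEP.OUT.ATTRS = FALSE)
  np <- nrow(pairs)
  nsim <- length(trajs)
  freq <- matrix(NA_real_, np, nsim)
  sums <- numeric(np); sums2 <- numeric(np); ntot <- 0L
  all_below <- rep(TRUE, np)
  for (s in seq_len(nsim)) {
    D <- pair_distance_matrix(trajs[[s]], pairs$i, pairs$j)
    freq[, s] <- rowMeans(D < cutoff)
    sums <- sums + rowSums(D)
    sums2 <- sums2 + rowSums(D^2)
    all_below <- all_below & apply(D < cutoff, 1, all)
    ntot <- ntot + ncol(D)
  }
  keep <- apply(freq > min_freq, 1, any)
  pairs <- pairs[keep, , drop = FALSE]
  freq <- freq[keep, , drop = FALSE]
  mu <- sums[keep] / ntot
  v <- (sums2[keep] - ntot * mu^2) / max(ntot - 1, 1)
  sdd <- sqrt(pmax(v, 0))
  a <- top$atoms
  rec <- data.frame(
    i = pairs$i, j = pairs$j,
    lig_name = a$name[pairs$i], prot_name = a$name[pairs$j],
    prot_resid = a$resid[pairs$j], prot_resno = a$resno[pairs$j],
    freq_max = if (nrow(freq)) apply(freq, 1, max) else numeric(0),
    pooled_mean = mu, pooled_sd = sdd,
    class = ifelse(all_below[keep] & sdd < 0.25, "permanent", "transient"),
    stringsAsFactors = FALSE)
  rownames(rec) <- NULL
  attr(rec, "freq") <- freq
  attr(rec, "cutoff") <- cutoff
  class(rec) <- c("contact_records", "data.frame")
  rec
}

# distances of given atom pairs for every frame: (pairs x frames)
pair_distance_matrix <- function(traj, i, j) {
  nf <- n_frames(traj)
  D <- matrix(NA_real_, length(i), nf)
  for (f in seq_len(nf)) {
    x <- frame_coords(traj, f)
    D[, f] <- sqrt(rowSums((x[i, , drop = FALSE] -
                            x[j, , drop = FALSE])^2))
  }
  D
}

#' Classify a contact as permanent or transient
#'
#' Permanent iff the pair distance is strictly below the cutoff in every
#' frame of every simulation *and* the pooled distance SD is below
#' `sd_max`; every other retained contact is transient.
#'
#' @param record one row of a `contact_records` data.frame.
#' @param trajs the trajectories the census was computed over.
#' @param cutoff contact cutoff, A.
#' @param sd_max pooled-SD bound for permanence, A (default 0.25).
#' @return "permanent" or "transient".
#' @export
classify_contact <- function(record, trajs, cutoff = 4, sd_max = 0.25) {
  if (inherits(trajs, "trajectory")) trajs <- list(trajs)
  d <- unlist(lapply(trajs, function(tr)
    pair_distance_series(tr, record$i, record$j)))
  if (all(d < cutoff) && stats::sd(d) < sd_max) "permanent" else "transient"
}

#' Moiety-by-residue contact map
#'
#' For every (ligand group, protein residue) cell, counts the atom pairs
#' within the cutoff per frame, averages over the frames of each
#' simulation, then averages those time averages across simulations.
#'
#' @param trajs a [trajectory()] or list of trajectories.
#' @param ligand_groups named list of ligand atom index vectors (rows);
#'   default the topology's moiety groups.
#' @param residues protein residue numbers (columns); default all protein
#'   residues.
#' @param cutoff contact cutoff, A (strict `<`).
#' @param heavy_only drop hydrogens.
#' @return object of class `contact_map`: `map` (ensemble-average matrix,
#'   groups x residues), `per_sim` (list of per-simulation time-average
#'   matrices), `residues`, `cutoff`. The bridging-water layer is added by
#'   [bridging_waters()].
#' @export
contact_map <- function(trajs, ligand_groups = NULL, residues = NULL,
                        cutoff = 4, heavy_only = TRUE) {
  if (inherits(trajs, "trajectory")) trajs <- list(trajs)
  top <- trajs[[1]]$topology
  if (is.null(ligand_groups)) {
    ligand_groups <- top$groups[top$moieties]
    if (!length(ligand_groups))
      stop("topology has no moiety groups; supply ligand_groups")
  }
  a <- top$atoms
  prot <- group_atoms(top, "protein")
  if (heavy_only) {
    h <- toupper(a$element) == "H"
    prot <- prot[!h[prot]]
    ligand_groups <- lapply(ligand_groups, function(g) g[!h[g]])
  }
  if (is.null(residues)) residues <- sort(unique(a$resno[prot]))
  res_atoms <- lapply(residues, function(r) prot[a$resno[prot] == r])

  per_sim <- lapply(trajs, function(tr) {
    acc <- matrix(0, length(ligand_groups), length(residues),
                  dimnames = list(names(ligand_groups), residues))
    nf <- n_frames(tr)
    for (f in seq_len(nf)) {
      x <- frame_coords(tr, f)
      for (g in seq_along(ligand_groups)) {
        gx <- x[ligand_groups[[g]], , drop = FALSE]
        for (r in seq_along(residues)) {
          rx <- x[res_atoms[[r]], , drop = FALSE]
          d2 <- outer(rowSums(gx^2), rowSums(rx^2), "+") -
            2 * gx %*% t(rx)
          acc[g, r] <- acc[g, r] + sum(d2 < cutoff^2)
        }
      }
    }
    acc / nf
  })
  map <- Reduce("+", per_sim) / length(per_sim)
  structure(list(map = map, per_sim = per_sim, residues = residues,
                 cutoff = cutoff, waters = NULL),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat("contact_map:", nrow(x$map), "ligand groups x", ncol(x$map),
      "residues (cutoff", x$cutoff, "A)\n")
  print(round(x$map, 2))
  if (!is.null(x$waters)) {
    cat("bridging waters:\n")
    print(round(x$waters, 2))
  }
  invisible(x)
}

#' Bridging-water layer of a contact map
#'
#' Per frame and (ligand group, residue) cell, counts the distinct water
#' molecules having at least one atom within the cutoff of the group AND
#' at least one atom within the cutoff of the residue; averaged per
#' simulation, then across simulations.
#'
#' @inheritParams contact_map
#' @param oxygen_only use water oxygens only instead of any water atom.
#' @return the ensemble-average bridging-water matrix (groups x residues);
#'   all-zero with a warning when the topology has no solvent.
#' @export
bridging_waters <- function(trajs, ligand_groups = NULL, residues = NULL,
                            cutoff = 4, oxygen_only = FALSE) {
  if (inherits(trajs, "trajectory")) trajs <- list(trajs)
  top <- trajs[[1]]$topology
  a <- top$atoms
  if (is.null(ligand_groups)) ligand_groups <- top$groups[top$moieties]
  prot <- group_atoms(top, "protein")
  if (is.null(residues)) residues <- sort(unique(a$resno[prot]))
  res_atoms <- lapply(residues, function(r) prot[a$resno[prot] == r])
  empty <- matrix(0, length(ligand_groups), length(residues),
                  dimnames = list(names(ligand_groups), residues))
  solv <- top$solvent
  if (oxygen_only) solv <- solv[toupper(a$element[solv]) == "O"]
  if (!length(solv)) {
    warning("topology has no solvent atoms; bridging-water layer is zero")
    return(empty)
  }
  wat_mols <- split(solv, paste(a$chain[solv], a$resno[solv]))

  per_sim <- lapply(trajs, function(tr) {
    acc <- empty
    nf <- n_frames(tr)
    for (f in seq_len(nf)) {
      x <- frame_coords(tr, f)
      near <- function(idx_a, idx_b) {
        xa <- x[idx_a, , drop = FALSE]; xb <- x[idx_b, , drop = FALSE]
        d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
        any(d2 < cutoff^2)
      }
      for (g in seq_along(ligand_groups)) {
        gmatch <- vapply(wat_mols, near, logical(1),
                         idx_b = ligand_groups[[g]])
        if (!any(gmatch)) next
        for (r in seq_along(residues)) {
          n <- sum(vapply(wat_mols[gmatch], near, logical(1),
                          idx_b = res_atoms[[r]]))
          acc[g, r] <- acc[g, r] + n
        }
      }
    }
    acc / nf
  })
  Reduce("+", per_sim) / length(per_sim)
}

#' Display bin of a bridging-water count
#'
#' The map legend bins average bridging-water counts into the left-open,
#' right-closed intervals (0.5, 1], (1, 1.5], (1.5, 2]; values at or below
#' 0.5 are unbinned.
#'
#' @param x average water count(s). Vectorized.
#' @return character vector: "]0.5;1]", "]1;1.5]", "]1.5;2]", ">2" or ""
#'   (unbinned).
#' @export
water_bin <- function(x) {
  ifelse(x > 2, ">2",
  ifelse(x > 1.5, "]1.5;2]",
  ifelse(x > 1, "]1;1.5]",
  ifelse(x > 0.5, "]0.5;1]", ""))))
}

#' Hydrogen-bond geometry statistics
#'
#' Per-frame hydrogen-acceptor distance and donor-hydrogen-acceptor angle
#' (at the hydrogen), pooled over all frames of all simulations. The bond
#' is flagged as formed when the mean distance is at most `dist_max` and
#' the mean angle at least `angle_min`; the defaults are chosen so that a
#' long, bent geometry classifies as a van der Waals contact rather than a
#' hydrogen bond.
#'
#' @param trajs a [trajectory()] or list of trajectories.
#' @param donor,hydrogen,acceptor atom indices (three distinct atoms).
#' @param dist_max H...A distance threshold, A.
#' @param angle_min D-H...A angle threshold, degrees.
#' @return object of class `hbond_geometry`: `mean_dist`, `sd_dist` (A),
#'   `mean_angle`, `sd_angle` (degrees), `formed`, `n_frames`.
#' @export
hbond_stats <- function(trajs, donor, hydrogen, acceptor, dist_max = 2.5,
                        angle_min = 135) {
  if (inherits(trajs, "trajectory")) trajs <- list(trajs)
  if (length(unique(c(donor, hydrogen, acceptor))) != 3)
    stop("donor, hydrogen and acceptor must be three distinct atoms")
  dist <- c(); ang <- c()
  for (tr in trajs) {
    for (f in seq_len(n_frames(tr))) {
      x <- frame_coords(tr, f)
      hd <- x[donor, ] - x[hydrogen, ]
      ha <- x[acceptor, ] - x[hydrogen, ]
      dist <- c(dist, sqrt(sum(ha^2)))
      cosang <- sum(hd * ha) / sqrt(sum(hd^2) * sum(ha^2))
      ang <- c(ang, acos(pmin(pmax(cosang, -1), 1)) * 180 / pi)
    }
  }
  md <- mean(dist); ma <- mean(ang)
  structure(list(
    mean_dist = md, sd_dist = if (length(dist) > 1) stats::sd(dist) else 0,
    mean_angle = ma, sd_angle = if (length(ang) > 1) stats::sd(ang) else 0,
    formed = md <= dist_max && ma >= angle_min,
    n_frames = length(dist)), class = "hbond_geometry")
}

#' @export
print.hbond_geometry <- function(x, ...) {
  cat(sprintf(
    "hbond_geometry: H...A %.2f +- %.2f A, D-H...A %.0f +- %.0f deg -> %s\n",
    x$mean_dist, x$sd_dist, x$mean_angle, x$sd_angle,
    if (x$formed) "formed" else "not formed (van der Waals contact)"))
  invisible(x)
}
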