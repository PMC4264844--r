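#' Synthetic trajectory with planted atom-pair contacts
#'
#' Generates a trajectory in which each planned ligand-protein atom pair
#' shows a contact (distance < 4 A) in a prescribed fraction of frames,
#' with prescribed in-contact mean distance and distance SD. Pairs are laid
#' out along x, 20 A apart, so no unplanned cross-pair contact can occur
#' even on non-contact frames (which sit around `far_mean`).
#'
#' @param plan data.frame with columns `freq` (target contact frequency in
#'   `[0, 1]`), `mean` (in-contact mean distance, A), `sd` (in-contact
#'   distance SD, A) and optionally `moiety` (ligand group name, default
#'   "core") and `resno` (protein residue number, default consecutive).
#' @param n_frames number of frames.
#' @param dt ps per frame.
#' @param seed RNG seed.
#' @param far_mean,far_sd distance distribution used on non-contact frames.
#' @return a [trajectory()] whose topology has one ligand atom and one
#'   protein atom per planned pair, moiety groups taken from the plan, and
#'   attribute `plan` recording the input.
#' @export
synth_contact_trajectory <- function(plan, n_frames = 100, dt = 1,
                                     seed = 1L, far_mean = 6, far_sd = 0.3) {
  plan <- as.data.frame(plan)
  stopifnot(all(c("freq", "mean", "sd") %in% names(plan)))
  if (any(plan$freq < 0 | plan$freq > 1))
    stop("contact frequencies must lie in [0, 1]")
  for (p in seq_len(nrow(plan))) {
    if (plan$freq[p] > 0 && stats::pnorm(4, plan$mean[p], plan$sd[p]) < 0.1)
      stop("infeasible plan row ", p, ": mean distance ", plan$mean[p],
           " A with SD ", plan$sd[p],
           " cannot realize contacts below the 4 A cutoff")
  }
  if (is.null(plan$moiety)) plan$moiety <- "core"
  if (is.null(plan$resno)) plan$resno <- seq_len(nrow(plan))

  np <- nrow(plan)
  set.seed(seed)
  coords <- array(0, c(2 * np, 3, n_frames))
  for (p in seq_len(np)) {
    x0 <- (p - 1) * 20
    contact <- stats::runif(n_frames) < plan$freq[p]
    d <- numeric(n_frames)
    nc <- sum(contact)
    if (nc) {
      di <- stats::rnorm(nc, plan$mean[p], plan$sd[p])
      # resample the rare draws crossing the cutoff so planted
      # frequency-1 pairs are in contact in every frame
      bad <- which(di >= 4 | di <= 0)
      while (length(bad)) {
        di[bad] <- stats::rnorm(length(bad), plan$mean[p], plan$sd[p])
        bad <- bad[di[bad] >= 4 | di[bad] <= 0]
      }
      d[contact] <- di
    }
    if (any(!contact)) {
      do <- stats::rnorm(sum(!contact), max(far_mean, 4.6), far_sd)
      do[do < 4.2] <- 4.2 + (4.2 - do[do < 4.2])
      d[!contact] <- do
    }
    coords[p, 1, ] <- x0              # protein atom, fixed
    coords[np + p, 1, ] <- x0 + d     # ligand atom along +x
  }

  atoms <- data.frame(
    serial = seq_len(2 * np),
    name = c(rep("CA", np), sprintf("C%d", seq_len(np))),
    element = c(rep("C", np), rep(c("C", "N", "O"), length.out = np)),
    mass = 12.011,
    resno = c(plan$resno, rep(500L, np)),
    resid = c(rep("ALA", np), rep("LIG", np)),
    chain = c(rep("A", np), rep("L", np)),
    type = c(rep("ATOM", np), rep("HETATM", np)),
    stringsAsFactors = FALSE)
  groups <- list(protein = seq_len(np), ligand = np + seq_len(np))
  moieties <- character()
  for (m in unique(plan$moiety)) {
    groups[[m]] <- np + which(plan$moiety == m)
    moieties <- c(moieties, m)
  }
  top <- topology(atoms, groups, moieties = moieties)
  traj <- trajectory(top, coords, dt)
  attr(traj, "plan") <- plan
  traj
}

#' Synthetic multi-channel time series with planted plateaus
#'
#' Emulates the monitored unbinding traces (reaction-coordinate distance,
#' center-of-mass distances, RMSDs): within each planted interval the
#' series holds a constant level plus Gaussian noise; between plateaus it
#' ramps linearly between the neighboring levels; before the first (after
#' the last) plateau it ramps from (to) a level offset by `approach`.
#'
#' Plateau boundaries are sharp, as barrier crossings are fast compared to
#' the metastable residence times: the trace leaves a plateau at
#' `edge_slope` for the first `edge_ps` of a gap, then drifts at
#' `far_slope` across the rest of the gap toward the next level's
#' shoulder.
#'
#' @param plateaus data.frame with columns `start`, `end` (ps, inclusive),
#'   `level` and `sd` (noise SD), and optionally `channel` (default 1).
#'   Intervals must not overlap within a channel.
#' @param total_ps total series length, ps.
#' @param dt ps per sample.
#' @param seed RNG seed.
#' @param edge_slope drift rate (A/ps) immediately outside a plateau.
#' @param edge_ps duration of the steep shoulder, ps.
#' @param far_slope drift rate far from any plateau, A/ps.
#' @return numeric matrix (samples x channels) with attributes `time`
#'   (ps) and `dt`.
#' @export
synth_series <- function(plateaus, total_ps, dt = 1, seed = 1L,
                         edge_slope = 1, edge_ps = 10,
                         far_slope = 0.02) {
  plateaus <- as.data.frame(plateaus)
  stopifnot(all(c("start", "end", "level", "sd") %in% names(plateaus)))
  if (is.null(plateaus$channel)) plateaus$channel <- 1L
  if (any(plateaus$end > total_ps) || any(plateaus$start < 0))
    stop("plateau intervals exceed the series length")
  if (any(plateaus$end <= plateaus$start))
    stop("plateau intervals must have end > start")
  tvec <- seq(0, total_ps, by = dt)
  nchan <- max(plateaus$channel)
  out <- matrix(NA_real_, length(tvec), nchan)
  set.seed(seed)
  for (ch in seq_len(nchan)) {
    pl <- plateaus[plateaus$channel == ch, , drop = FALSE]
    pl <- pl[order(pl$start), , drop = FALSE]
    if (nrow(pl) > 1 && any(pl$start[-1] <= pl$end[-nrow(pl)]))
      stop("plateau intervals overlap in channel ", ch)
    base <- rep(NA_real_, length(tvec))
    noise_sd <- rep(0, length(tvec))
    for (p in seq_len(nrow(pl))) {
      in_p <- tvec >= pl$start[p] & tvec <= pl$end[p]
      base[in_p] <- pl$level[p]
      noise_sd[in_p] <- pl$sd[p]
    }
    # drifting traces across the gaps: steep shoulder, then slow drift
    offset <- function(u) {
      edge_slope * pmin(u, edge_ps) + far_slope * pmax(u - edge_ps, 0)
    }
    if (nrow(pl)) {
      first <- pl$start[1]; last <- pl$end[nrow(pl)]
      pre <- tvec < first
      base[pre] <- pl$level[1] - offset(first - tvec[pre])
      post <- tvec > last
      base[post] <- pl$level[nrow(pl)] + offset(tvec[post] - last)
      if (nrow(pl) > 1) {
        for (p in seq_len(nrow(pl) - 1)) {
          e <- pl$end[p]; s2 <- pl$start[p + 1]
          mid <- (e + s2) / 2
          dir <- if (pl$level[p + 1] >= pl$level[p]) 1 else -1
          left <- tvec > e & tvec <= mid
          base[left] <- pl$level[p] + dir * offset(tvec[left] - e)
          right <- tvec > mid & tvec < s2
          base[right] <- pl$level[p + 1] - dir * offset(s2 - tvec[right])
          gap <- tvec > e & tvec < s2
          noise_sd[gap] <- (pl$sd[p] + pl$sd[p + 1]) / 2
        }
      }
    } else base[] <- 0
    out[, ch] <- base + stats::rnorm(length(tvec), 0, noise_sd)
  }
  attr(out, "time") <- tvec
  attr(out, "dt") <- dt
  out
}
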