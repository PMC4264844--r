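#' Least-squares superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD of the
#' fit atoms of `mobile` onto `reference`, by the standard SVD closed form
#' with reflection corrected to a proper rotation (det = +1).
#'
#' @param mobile,reference N x 3 coordinate matrices.
#' @param fit_atoms indices of the atoms used for the fit (>= 3,
#'   non-collinear). Default: all atoms.
#' @return list with `R` (3 x 3 rotation), `t` (translation), `rmsd` (fit
#'   RMSD, A). The fitted mobile coordinates are `mobile %*% R + t`
#'   (rowwise).
#' @export
superpose <- function(mobile, reference, fit_atoms = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (is.null(fit_atoms)) fit_atoms <- seq_len(nrow(mobile))
  if (length(fit_atoms) < 3)
    stop("superposition needs at least 3 fit atoms")
  P <- mobile[fit_atoms, , drop = FALSE]
  Q <- reference[fit_atoms, , drop = FALSE]
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  sv <- svd(crossprod(Pc, Qc))  # 3x3: t(Pc) %*% Qc
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1))
    stop("degenerate (collinear) fit atom set: rotation is not determined")
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)
  t <- cq - as.vector(cp %*% R)
  fitted <- sweep(Pc %*% R, 2, cq, "+")
  list(R = R, t = t, rmsd = sqrt(mean(rowSums((fitted - Q)^2))))
}

#' Apply a superposition transform
#'
#' @param x N x 3 coordinates.
#' @param fit a transform from [superpose()].
#' @return transformed N x 3 coordinates.
#' @export
apply_transform <- function(x, fit) {
  sweep(as.matrix(x) %*% fit$R, 2, fit$t, "+")
}

#' Alignment specification (A1 / A2)
#'
#' Under alignment A1 all C-alpha (fit) atoms are superposed on their
#' reference positions; under A2 all except an excluded group G, so that
#' the RMSD of G then measures its displacement relative to the rest of
#' the protein.
#'
#' @param mode "A1" or "A2".
#' @param measure_group name of the group whose RMSD is reported.
#' @param excluded_group group excluded from the fit (A2 only; must be
#'   non-empty and is removed from the fit set).
#' @param fit_group name of the group providing fit atoms (default
#'   "calpha", falling back to "protein").
#' @return object of class `alignment_spec`.
#' @export
alignment_spec <- function(mode = c("A1", "A2"), measure_group,
                           excluded_group = NULL, fit_group = NULL) {
  mode <- match.arg(mode)
  if (mode == "A2" && is.null(excluded_group))
    stop("alignment A2 requires an excluded group")
  if (mode == "A1" && !is.null(excluded_group))
    stop("alignment A1 does not take an excluded group")
  structure(list(mode = mode, measure_group = measure_group,
                 excluded_group = excluded_group, fit_group = fit_group),
            class = "alignment_spec")
}

alignment_indices <- function(spec, top) {
  fg <- spec$fit_group
  if (is.null(fg))
    fg <- if ("calpha" %in% names(top$groups)) "calpha" else "protein"
  fit <- group_atoms(top, fg)
  if (spec$mode == "A2") {
    excl <- group_atoms(top, spec$excluded_group)
    fit <- setdiff(fit, excl)
    if (!length(fit))
      stop("A2 fit set is empty after excluding group '",
           spec$excluded_group, "'")
  }
  measure <- group_atoms(top, spec$measure_group)
  if (!length(measure)) stop("empty measure group")
  list(fit = fit, measure = measure)
}

#' RMSD of a group after superposition
#'
#' Superposes the frame on the reference over the alignment's fit atoms,
#' then reports the RMSD of the measure group.
#'
#' @param frame,reference N x 3 coordinate matrices.
#' @param spec an [alignment_spec()].
#' @param top the [topology()] resolving the group names.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(frame, reference, spec, top) {
  idx <- alignment_indices(spec, top)
  fit <- superpose(frame, reference, idx$fit)
  moved <- apply_transform(frame, fit)
  sqrt(mean(rowSums((moved[idx$measure, , drop = FALSE] -
                     as.matrix(reference)[idx$measure, , drop = FALSE])^2)))
}

#' Per-frame RMSD series over a trajectory
#'
#' @param traj a [trajectory()].
#' @param reference reference coordinates (N x 3).
#' @param spec an [alignment_spec()].
#' @return numeric vector of per-frame RMSDs (A).
#' @export
rmsd_series <- function(traj, reference, spec) {
  idx <- alignment_indices(spec, traj$topology)
  ref <- as.matrix(reference)
  vapply(seq_len(n_frames(traj)), function(f) {
    x <- frame_coords(traj, f)
    fit <- superpose(x, ref, idx$fit)
    moved <- apply_transform(x, fit)
    sqrt(mean(rowSums((moved[idx$measure, , drop = FALSE] -
                       ref[idx$measure, , drop = FALSE])^2)))
  }, numeric(1))
}

#' Distance between two group centers of mass
#'
#' @param frame N x 3 coordinates.
#' @param group_a,group_b atom index vectors.
#' @param masses per-atom masses (amu); geometric centroids if `NULL`.
#' @return Euclidean distance between the mass-weighted centroids, A.
#' @export
com_distance <- function(frame, group_a, group_b, masses = NULL) {
  frame <- as.matrix(frame)
  if (!length(group_a) || !length(group_b))
    stop("center-of-mass groups must be non-empty")
  if (is.null(masses)) masses <- rep(1, nrow(frame))
  com <- function(idx) {
    m <- masses[idx]
    if (sum(m) <= 0) stop("zero total mass in center-of-mass group")
    colSums(frame[idx, , drop = FALSE] * m) / sum(m)
  }
  sqrt(sum((com(group_a) - com(group_b))^2))
}

#' Per-frame center-of-mass distance series
#'
#' @param traj a [trajectory()].
#' @param group_a,group_b atom index vectors.
#' @param mass_weighted use topology masses (default) or geometric
#'   centroids.
#' @return numeric vector of distances (A) per frame.
#' @export
com_distance_series <- function(traj, group_a, group_b,
                                mass_weighted = TRUE) {
  m <- if (mass_weighted) traj$topology$atoms$mass else NULL
  vapply(seq_len(n_frames(traj)), function(f)
    com_distance(frame_coords(traj, f), group_a, group_b, m), numeric(1))
}

#' Root-mean-square fluctuation per atom
#'
#' Each frame is superposed on the reference over the alignment's fit
#' atoms; the RMSF of each selected atom is then the root mean square of
#' its displacement from its time-average position.
#'
#' @param traj a [trajectory()] with at least 2 frames.
#' @param selection atom indices to report (default: all).
#' @param spec an [alignment_spec()] providing the fit atoms, or `NULL`
#'   for no alignment (raw fluctuations).
#' @param reference reference coordinates for the fit; default frame 1.
#' @return named numeric vector of per-atom RMSF (A).
#' @export
rmsf <- function(traj, selection = NULL, spec = NULL, reference = NULL) {
  nf <- n_frames(traj)
  if (nf < 2) stop("RMSF needs at least 2 frames")
  na <- n_atoms(traj$topology)
  if (is.null(selection)) selection <- seq_len(na)
  if (is.null(reference)) reference <- frame_coords(traj, 1)
  fit_idx <- if (is.null(spec)) NULL
             else alignment_indices(spec, traj$topology)$fit
  aligned <- array(NA_real_, c(na, 3, nf))
  for (f in seq_len(nf)) {
    x <- frame_coords(traj, f)
    if (!is.null(fit_idx)) {
      tr <- superpose(x, reference, fit_idx)
      x <- apply_transform(x, tr)
    }
    aligned[, , f] <- x
  }
  mean_pos <- apply(aligned, c(1, 2), mean)
  out <- vapply(selection, function(i) {
    disp <- sweep(t(aligned[i, , ]), 2, mean_pos[i, ])
    sqrt(mean(rowSums(disp^2)))
  }, numeric(1))
  names(out) <- traj$topology$atoms$name[selection]
  out
}

#' Summary statistics of a monitored series across simulations
#'
#' `fluctuation` is the (mean) within-simulation sample SD; `ensemble_sd`
#' is the sample SD of the per-simulation means, the consistency statistic
#' used to judge whether independent simulations report the same state.
#' Sample (n-1) SDs throughout, appropriate to small ensembles; with a
#' single simulation `ensemble_sd` is 0.
#'
#' @param series a numeric vector (one simulation) or list of numeric
#'   vectors (one per simulation).
#' @return object of class `series_summary`: list with `mean`, `sd`,
#'   `fluctuation`, `ensemble_sd`, `per_sim_means`, `n_sim`.
#' @export
summarize_series <- function(series) {
  if (!is.list(series)) series <- list(series)
  per_means <- vapply(series, mean, numeric(1))
  per_sds <- vapply(series, function(s)
    if (length(s) > 1) stats::sd(s) else 0, numeric(1))
  pooled <- unlist(series)
  structure(list(
    mean = mean(per_means),
    sd = if (length(pooled) > 1) stats::sd(pooled) else 0,
    fluctuation = mean(per_sds),
    ensemble_sd = if (length(per_means) > 1) stats::sd(per_means) else 0,
    per_sim_means = per_means,
    n_sim = length(series)), class = "series_summary")
}

#' @export
print.series_summary <- function(x, ...) {
  cat(sprintf(
    "series_summary: mean %.3f, fluctuation %.3f, ensemble SD %.3f (%d sim)\n",
    x$mean, x$fluctuation, x$ensemble_sd, x$n_sim))
  invisible(x)
}
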