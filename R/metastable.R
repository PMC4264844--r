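#' Detect metastable plateaus in multi-channel series
#'
#' Scans the monitored series (reaction-coordinate distance, center-of-mass
#' distances, RMSDs) for maximal contiguous segments on which *every*
#' channel is simultaneously stable, and keeps those whose lifetime reaches
#' `min_lifetime` (boundary inclusive). A segment qualifies when, in every
#' channel:
#'
#' * the drift — the difference between the mean of the segment's leading
#'   window and that of its trailing window — stays within `drift_tol`;
#' * the within-segment SD stays within `fluct_tol`;
#' * no single sample departs from the running segment mean by more than
#'   `2 * fluct_tol` (so a level step terminates the segment at the step,
#'   not a window later).
#'
#' Adjacent qualifying segments separated by less than one window are
#' fused when the fused span itself still qualifies (so a noise glitch does
#' not split a plateau, while a genuine level change does).
#'
#' @param series numeric vector or (samples x channels) matrix.
#' @param dt ps per sample (taken from the series attribute if present).
#' @param window stability window, ps.
#' @param drift_tol maximal running-mean drift across a segment, A.
#' @param fluct_tol maximal within-segment SD, A.
#' @param min_lifetime minimal plateau lifetime, ps (> 0). Default 150 ps,
#'   the lifetime rule separating candidate intermediates from transients.
#' @return list of `metastable_segment` objects ordered by start time;
#'   each has `start`, `end`, `lifetime` (ps), `start_idx`, `end_idx`,
#'   `last_frame_index` (the restart point), `means` and `sds` per channel.
#' @export
detect_plateaus <- function(series, dt = NULL, window = 50,
                            drift_tol = 0.5, fluct_tol = 1.0,
                            min_lifetime = 150) {
  if (min_lifetime <= 0) stop("min_lifetime must be > 0")
  if (is.null(dt)) dt <- attr(series, "dt")
  if (is.null(dt) || !is.finite(dt) || dt <= 0)
    stop("dt must be supplied (ps per sample)")
  if (drift_tol <= 0 || fluct_tol <= 0)
    stop("drift_tol and fluct_tol must be > 0")
  M <- as.matrix(series)
  n <- nrow(M); nc <- ncol(M)
  w <- max(2L, as.integer(round(window / dt)))
  if (w >= n) stop("window must be shorter than the series")

  # prefix sums for O(1) interval means / SDs
  cs <- apply(M, 2, cumsum)
  cs2 <- apply(M^2, 2, cumsum)
  int_sum <- function(a, b) {
    if (a == 1) cs[b, ] else cs[b, ] - cs[a - 1, ]
  }
  int_sum2 <- function(a, b) {
    if (a == 1) cs2[b, ] else cs2[b, ] - cs2[a - 1, ]
  }
  seg_ok <- function(a, b) {
    len <- b - a + 1
    mu <- int_sum(a, b) / len
    if (len > 1) {
      v <- (int_sum2(a, b) - len * mu^2) / (len - 1)
      if (any(sqrt(pmax(v, 0)) > fluct_tol)) return(FALSE)
    }
    wl <- min(w, len)
    head_mu <- int_sum(a, a + wl - 1) / wl
    tail_mu <- int_sum(b - wl + 1, b) / wl
    all(abs(tail_mu - head_mu) <= drift_tol)
  }

  runs <- list()
  s <- 1L
  e <- 1L
  while (s <= n) {
    e <- s
    mu <- M[s, ]
    while (e < n) {
      len <- e - s + 1
      # sample-level gate against the running mean
      if (any(abs(M[e + 1, ] - mu) > 2 * fluct_tol)) break
      if (!seg_ok(s, e + 1)) break
      e <- e + 1L
      mu <- int_sum(s, e) / (e - s + 1)
    }
    runs[[length(runs) + 1L]] <- c(s, e)
    s <- e + 1L
  }

  # fuse near-adjacent runs when the fused span still qualifies,
  # including the sample-level gate against the fused mean
  fuse_ok <- function(a, b) {
    if (!seg_ok(a, b)) return(FALSE)
    mu <- int_sum(a, b) / (b - a + 1)
    dev <- sweep(M[a:b, , drop = FALSE], 2, mu, "-")
    max(abs(dev)) <= 2 * fluct_tol
  }
  fused <- list()
  for (r in runs) {
    if (length(fused)) {
      prev <- fused[[length(fused)]]
      gap <- r[1] - prev[2] - 1
      if (gap < w && fuse_ok(prev[1], r[2])) {
        fused[[length(fused)]] <- c(prev[1], r[2])
        next
      }
    }
    fused[[length(fused) + 1L]] <- r
  }

  out <- list()
  for (r in fused) {
    lifetime <- (r[2] - r[1]) * dt
    if (lifetime < min_lifetime) next
    a <- r[1]; b <- r[2]; len <- b - a + 1
    mu <- int_sum(a, b) / len
    v <- if (len > 1) (int_sum2(a, b) - len * mu^2) / (len - 1) else mu * 0
    seg <- structure(list(
      start = (a - 1) * dt, end = (b - 1) * dt, lifetime = lifetime,
      start_idx = a, end_idx = b, last_frame_index = b,
      means = mu, sds = sqrt(pmax(v, 0))), class = "metastable_segment")
    out[[length(out) + 1L]] <- seg
  }
  out
}

#' @export
print.metastable_segment <- function(x, ...) {
  cat(sprintf("metastable_segment: %.1f-%.1f ps (lifetime %.1f ps)\n",
              x$start, x$end, x$lifetime))
  m <- x$means
  if (!is.null(names(m)) && length(m) <= 12)
    cat("  means:", paste(sprintf("%s=%.2f", names(m), m), collapse = " "),
        "\n")
  invisible(x)
}

#' Restart structure of a metastable segment
#'
#' The last structure of the stable portion of a run, used to restart the
#' simulation with a lower ratchet force constant.
#'
#' @param segment a `metastable_segment` from [detect_plateaus()].
#' @param traj the [trajectory()] the segment indexes into.
#' @return N x 3 coordinates of the segment's final frame.
#' @export
segment_restart_structure <- function(segment, traj) {
  idx <- segment$last_frame_index
  if (idx < 1 || idx > n_frames(traj))
    stop("segment restart frame ", idx, " outside trajectory (",
         n_frames(traj), " frames)")
  frame_coords(traj, idx)
}
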