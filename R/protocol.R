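#' Monitored channels of an unbinding run
#'
#' Computes, per saved frame, the quantities whose joint stability defines
#' a metastable state: the reaction-coordinate distance, the center-of-mass
#' distance from the binding pocket to each ligand moiety, the RMSD of
#' each moiety under alignment A1 (all protein C-alpha fit), and the
#' non-loop protein RMSD.
#'
#' @param traj a [trajectory()] whose topology defines groups `pocket`,
#'   `nonloop` and the moiety groups.
#' @param rc_atoms integer pair (ligand anchor, protein anchor).
#' @param reference reference (bound-state) coordinates for the RMSDs.
#' @return numeric matrix (frames x channels) with channel names
#'   `d_RC`, `dCM_<moiety>`, `RMSD_<moiety>`, `RMSD_protein`, and
#'   attribute `dt`.
#' @export
monitor_series <- function(traj, rc_atoms, reference) {
  top <- traj$topology
  moieties <- top$moieties
  pocket <- group_atoms(top, "pocket")
  prot_group <- if ("nonloop" %in% names(top$groups)) "nonloop" else "protein"
  rmsd_groups <- c(lapply(moieties, group_atoms, top = top),
                   list(group_atoms(top, prot_group)))
  names(rmsd_groups) <- c(paste0("RMSD_", moieties), "RMSD_protein")
  fit_idx <- if ("calpha" %in% names(top$groups))
    group_atoms(top, "calpha") else group_atoms(top, "protein")
  cm_groups <- lapply(moieties, group_atoms, top = top)
  names(cm_groups) <- paste0("dCM_", moieties)
  mass <- top$atoms$mass
  ref <- as.matrix(reference)
  nf <- n_frames(traj)

  M <- matrix(NA_real_, nf,
              1 + length(cm_groups) + length(rmsd_groups),
              dimnames = list(NULL, c("d_RC", names(cm_groups),
                                      names(rmsd_groups))))
  pocket_m <- mass[pocket]
  for (f in seq_len(nf)) {
    x <- traj$coords[, , f]
    M[f, 1] <- sqrt(sum((x[rc_atoms[1], ] - x[rc_atoms[2], ])^2))
    pc <- colSums(x[pocket, , drop = FALSE] * pocket_m) / sum(pocket_m)
    for (g in seq_along(cm_groups)) {
      idx <- cm_groups[[g]]
      gm <- mass[idx]
      gc <- colSums(x[idx, , drop = FALSE] * gm) / sum(gm)
      M[f, 1 + g] <- sqrt(sum((pc - gc)^2))
    }
    # one superposition per frame, shared by all RMSD channels
    fit <- superpose(x, ref, fit_idx)
    moved <- apply_transform(x, fit)
    for (g in seq_along(rmsd_groups)) {
      idx <- rmsd_groups[[g]]
      M[f, 1 + length(cm_groups) + g] <-
        sqrt(mean(rowSums((moved[idx, , drop = FALSE] -
                           ref[idx, , drop = FALSE])^2)))
    }
  }
  attr(M, "dt") <- traj$dt
  M
}

#' Detector parameter block
#'
#' @param window stability window, ps.
#' @param drift_tol running-mean drift tolerance, A.
#' @param fluct_tol within-segment SD tolerance, A.
#' @param min_lifetime pooling lifetime threshold, ps.
#' @param stub_lifetime minimal lifetime of a "short stable stretch" that
#'   still provides a restart structure for the lifetime-extension step.
#' @return list of detector parameters.
#' @export
detector_params <- function(window = 50, drift_tol = 0.5, fluct_tol = 1.0,
                            min_lifetime = 150, stub_lifetime = 10) {
  list(window = window, drift_tol = drift_tol, fluct_tol = fluct_tol,
       min_lifetime = min_lifetime, stub_lifetime = stub_lifetime)
}

# segments of one run, split into pooled candidates (> min_lifetime, away
# from the bound state) and restart stubs
analyze_run <- function(run, cx, detector, rebound_tol = 1) {
  traj <- bmd_trajectory(run, cx$topology)
  M <- monitor_series(traj, cx$rc_atoms, cx$coords)
  # a run shorter than the stability window cannot hold a plateau
  if ((nrow(M) - 1) * traj$dt <= max(detector$window,
                                     detector$stub_lifetime))
    return(list(pooled = list(), stubs = list()))
  segs <- detect_plateaus(M, dt = traj$dt, window = detector$window,
                          drift_tol = detector$drift_tol,
                          fluct_tol = detector$fluct_tol,
                          min_lifetime = detector$stub_lifetime)
  pooled <- list(); stubs <- list()
  for (s in segs) {
    mean_rho <- mean(run$rho[s$start_idx:s$end_idx])
    s$mean_rho <- mean_rho
    # the initial bound-state residence is not an unbinding intermediate
    if (abs(mean_rho - cx$bound_rho) <= rebound_tol) next
    if (s$lifetime > detector$min_lifetime) {
      s$traj <- subset_frames(traj, s$start_idx, s$end_idx)
      pooled[[length(pooled) + 1L]] <- s
    } else {
      # restart from the last frame that is one stability window inside
      # the stretch: the segment end is only window-accurate and may
      # already be on the escape path
      w <- as.integer(round(detector$window / traj$dt))
      s_inner <- s
      s_inner$last_frame_index <- max(s$start_idx, s$end_idx - w)
      s$restart <- segment_restart_structure(s_inner, traj)
      stubs[[length(stubs) + 1L]] <- s
    }
  }
  list(pooled = pooled, stubs = stubs)
}

# has the ligand rebound (rho within rebound_tol of the bound well for at
# least rebound_ps)?
detect_rebound <- function(run, bound_rho, rebound_tol = 1,
                           rebound_ps = 50) {
  near <- abs(run$rho - bound_rho) <= rebound_tol
  need <- max(1L, as.integer(round(rebound_ps / run$dt)))
  r <- rle(near)
  any(r$values & r$lengths >= need)
}

#' Step 1: biased unbinding from an ensemble of bound-state structures
#'
#' Runs one BMD unbinding simulation per start structure at the initial
#' (fast-unbinding) force constant. Metastable segments with lifetime
#' above the pooling threshold enter the candidate pool; shorter stable
#' stretches contribute restart structures for [step2_extend()]. Segments
#' parked at the bound well are skipped. Failed runs are logged, not
#' fatal.
#'
#' @param cx a [make_toy_complex()] system (or a compatible list with
#'   `topology`, `potential`, `coords`, `rc_atoms`, `bound_rho`).
#' @param starts list of N x 3 start coordinate matrices.
#' @param alpha1 step-1 force constant, pN/A (default 300, the value that
#'   unbinds within the 5 ns time limit).
#' @param time_limit per-run time limit, ps.
#' @param params a [langevin_params()]; its seed seeds run 1, subsequent
#'   runs use consecutive seeds.
#' @param detector a [detector_params()].
#' @param unbound_rho unbound threshold, A; default `bound_rho + 8`.
#' @param save_every engine steps per saved frame.
#' @return list of class `candidate_pool`: `segments` (pooled segments,
#'   each annotated with `run`, `alpha`, `mean_rho`, `traj`), `restarts`
#'   (stub segments with `$restart` coordinates), `log` (one record per
#'   run).
#' @export
step1_unbind <- function(cx, starts, alpha1 = 300, time_limit = 5000,
                         params = langevin_params(), detector =
                           detector_params(),
                         unbound_rho = NULL, save_every = 100L) {
  if (alpha1 < 0) stop("alpha1 must be >= 0")
  if (is.null(unbound_rho)) unbound_rho <- cx$bound_rho + 8
  pool <- list(); restarts <- list(); log <- list()
  for (i in seq_along(starts)) {
    pr <- params; pr$seed <- params$seed + i - 1L
    run <- tryCatch(
      run_bmd(starts[[i]], cx$potential, pr, cx$topology$atoms$mass,
              bias_state(cx$rc_atoms, alpha1), time_limit, unbound_rho,
              save_every),
      error = function(e) e)
    if (inherits(run, "error")) {
      log[[i]] <- list(run = i, status = "failed",
                       message = conditionMessage(run))
      next
    }
    an <- analyze_run(run, cx, detector)
    for (s in an$pooled) {
      s$run <- i; s$alpha <- alpha1
      pool[[length(pool) + 1L]] <- s
    }
    for (s in an$stubs) {
      s$run <- i; s$alpha <- alpha1
      restarts[[length(restarts) + 1L]] <- s
    }
    log[[i]] <- list(run = i, status = run$stopped,
                     n_pooled = length(an$pooled),
                     n_stubs = length(an$stubs))
  }
  structure(list(segments = pool, restarts = restarts, log = log),
            class = "candidate_pool")
}

#' @export
print.candidate_pool <- function(x, ...) {
  cat("candidate_pool:", length(x$segments), "pooled segments,",
      length(x$restarts), "restart stubs\n")
  invisible(x)
}

#' Step 2: lifetime extension with a lowered force constant
#'
#' Restarts a run from a short-lived stable stretch, walking the force
#' constant down the schedule until a plateau above the pooling lifetime
#' forms (pooled), the ligand rebinds (discarded: rebound), or the
#' schedule is exhausted (discarded).
#'
#' @param cx the system, as in [step1_unbind()].
#' @param restart N x 3 restart coordinates.
#' @param alpha_start first force constant tried, pN/A (the schedule entry
#'   point below the step-1 value).
#' @param params a [langevin_params()]; consecutive retries use
#'   consecutive seeds.
#' @param detector a [detector_params()].
#' @param time_limit per-attempt time limit, ps.
#' @param unbound_rho unbound threshold, A.
#' @param rebound_tol,rebound_ps rebound criterion: reaction coordinate
#'   within `rebound_tol` A of the bound well for at least `rebound_ps`.
#' @param save_every engine steps per saved frame.
#' @return list with `outcome` ("pooled", "rebound", "exhausted"),
#'   `segments` (pooled segments, possibly empty), `alpha` (last force
#'   constant tried), `attempts` (log of per-alpha branch decisions).
#' @export
step2_extend <- function(cx, restart, alpha_start = 250,
                         params = langevin_params(),
                         detector = detector_params(), time_limit = 5000,
                         unbound_rho = NULL, rebound_tol = 1,
                         rebound_ps = 50, save_every = 100L) {
  if (is.null(unbound_rho)) unbound_rho <- cx$bound_rho + 8
  alpha <- alpha_start
  attempt <- 0L
  attempts <- list()
  repeat {
    attempt <- attempt + 1L
    pr <- params; pr$seed <- params$seed + attempt - 1L
    run <- run_bmd(restart, cx$potential, pr, cx$topology$atoms$mass,
                   bias_state(cx$rc_atoms, alpha), time_limit, unbound_rho,
                   save_every)
    an <- analyze_run(run, cx, detector, rebound_tol)
    if (length(an$pooled)) {
      for (k in seq_along(an$pooled)) an$pooled[[k]]$alpha <- alpha
      attempts[[attempt]] <- list(alpha = alpha, branch = "2b: pooled")
      return(list(outcome = "pooled", segments = an$pooled, alpha = alpha,
                  attempts = attempts))
    }
    if (detect_rebound(run, cx$bound_rho, rebound_tol, rebound_ps)) {
      attempts[[attempt]] <- list(alpha = alpha,
                                  branch = "2c: rebound, discarded")
      return(list(outcome = "rebound", segments = list(), alpha = alpha,
                  attempts = attempts))
    }
    attempts[[attempt]] <- list(alpha = alpha,
                                branch = "2c: fast unbinding, retry lower")
    nxt <- tryCatch(next_alpha(alpha), error = function(e) NULL)
    if (is.null(nxt))
      return(list(outcome = "exhausted", segments = list(), alpha = alpha,
                  attempts = attempts))
    alpha <- nxt
  }
}

#' Step 3: clustering and acceptance of pooled metastable states
#'
#' Groups the pooled segments by average-linkage agglomerative clustering
#' on the feature vector (per-moiety center-of-mass distance means,
#' per-moiety RMSD means) and applies the four acceptance criteria:
#'
#' 1. every member's within-segment fluctuations pass the detector
#'    tolerance (stability);
#' 2. the members' mean non-loop protein RMSD stays below
#'    `integrity_threshold` (protein not significantly altered);
#' 3. every feature's ensemble SD (SD of per-member means) stays below
#'    `tight_threshold` (tight cluster);
#' 4. the cluster-mean core center-of-mass distance lies within
#'    `proximity_offset` of the bound-state value (close to the bound
#'    state).
#'
#' @param pool a `candidate_pool` with at least one segment.
#' @param bound_dcm_core bound-state core-pocket center-of-mass distance,
#'   A.
#' @param tight_threshold ensemble-SD threshold, A. Default 1.0: accepted
#'   ensembles in this kind of analysis show ensemble SDs well below 1 A
#'   while inconsistent ones exceed 2 A.
#' @param integrity_threshold mean non-loop protein RMSD bound, A.
#' @param proximity_offset allowed outward displacement of the core from
#'   its bound-state distance, A.
#' @param fluct_tol per-member fluctuation bound (criterion 1), A.
#' @param cutoff clustering height; default
#'   `tight_threshold * sqrt(n_features)`.
#' @return object of class `cluster_report`: `membership`, `features`,
#'   `clusters` (per-cluster stats and criteria flags), `accepted`
#'   (accepted cluster ids), `accepted_id` (the accepted cluster, or NA).
#' @export
step3_cluster <- function(pool, bound_dcm_core, tight_threshold = 1.0,
                          integrity_threshold = 2.0, proximity_offset = 5.0,
                          fluct_tol = 1.0, cutoff = NULL) {
  segs <- pool$segments
  if (!length(segs)) stop("empty candidate pool")
  chan <- names(segs[[1]]$means)
  feat_names <- chan[grepl("^dCM_|^RMSD_", chan) & chan != "RMSD_protein"]
  features <- t(vapply(segs, function(s) s$means[feat_names],
                       numeric(length(feat_names))))
  rownames(features) <- sprintf("seg%02d", seq_along(segs))
  if (is.null(cutoff)) cutoff <- tight_threshold * sqrt(ncol(features))

  membership <- if (nrow(features) == 1) 1L else {
    hc <- stats::hclust(stats::dist(features), method = "average")
    stats::cutree(hc, h = cutoff)
  }

  clusters <- list()
  for (cl in sort(unique(membership))) {
    idx <- which(membership == cl)
    fm <- features[idx, , drop = FALSE]
    ens_sd <- apply(fm, 2, function(v) if (length(v) > 1) stats::sd(v) else 0)
    stable <- all(vapply(segs[idx], function(s)
      all(s$sds <= fluct_tol), logical(1)))
    integrity <- mean(vapply(segs[idx], function(s)
      s$means[["RMSD_protein"]], numeric(1)))
    dcm_core <- mean(fm[, "dCM_core"])
    crit <- c(
      stable = stable,
      integrity = integrity <= integrity_threshold,
      tight = all(ens_sd <= tight_threshold),
      proximity = dcm_core <= bound_dcm_core + proximity_offset)
    clusters[[as.character(cl)]] <- list(
      id = cl, members = idx, n = length(idx),
      feature_means = colMeans(fm), ensemble_sd = ens_sd,
      mean_rho = mean(vapply(segs[idx], function(s) s$mean_rho,
                             numeric(1))),
      protein_rmsd = integrity, dcm_core = dcm_core,
      criteria = crit, accepted = all(crit))
  }
  accepted <- vapply(clusters, function(c) c$accepted, logical(1))
  acc_ids <- vapply(clusters[accepted], function(c) c$id, integer(1))
  acc_ids <- unname(acc_ids)
  acc_id <- if (length(acc_ids) == 0) NA_integer_ else {
    sizes <- unname(vapply(clusters[accepted], function(c) c$n, integer(1)))
    acc_ids[which.max(sizes)]
  }
  structure(list(membership = membership, features = features,
                 clusters = clusters, accepted = acc_ids,
                 accepted_id = acc_id,
                 thresholds = list(tight = tight_threshold,
                                   integrity = integrity_threshold,
                                   proximity = proximity_offset,
                                   cutoff = cutoff)),
            class = "cluster_report")
}

#' @export
print.cluster_report <- function(x, ...) {
  cat("cluster_report:", length(x$clusters), "cluster(s) over",
      nrow(x$features), "segments\n")
  for (c in x$clusters) {
    cat(sprintf(
      "  cluster %d: n=%d, mean rho %.2f A, criteria [%s]%s\n",
      c$id, c$n, c$mean_rho,
      paste(names(c$criteria)[c$criteria], collapse = ","),
      if (c$accepted) " ACCEPTED" else ""))
  }
  invisible(x)
}

#' Full three-step intermediate search on a toy complex
#'
#' Samples bound-state start structures by unbiased Langevin dynamics,
#' runs the step-1 biased unbinding on each, extends short-lived stable
#' stretches in step 2 down the force-constant schedule, and clusters and
#' judges the pooled metastable states in step 3.
#'
#' @param cx a [make_toy_complex()] system.
#' @param n_starts number of unbinding start structures.
#' @param seed master seed; all run seeds derive from it, so identical
#'   seeds give identical reports.
#' @param alpha1 step-1 force constant, pN/A.
#' @param alpha2_start entry value of the step-2 schedule, pN/A.
#' @param time_limit step-1 per-run time limit, ps (default 5000, the
#'   fast-unbinding limit).
#' @param time_limit2 per-attempt time limit in step 2, ps; long enough
#'   for plateaus far beyond the 150 ps pooling rule.
#' @param params a [langevin_params()] providing temperature/friction/dt.
#' @param detector a [detector_params()].
#' @param bound_sampling_ps length of the bound-state sampling run, ps.
#' @param max_restarts cap on the number of step-2 restart stubs pursued.
#' @param save_every engine steps per saved frame.
#' @param ... thresholds passed to [step3_cluster()].
#' @return list of class `protocol_result`: `found` (logical), `pool`,
#'   `report` (a `cluster_report` or NULL), `accepted_segments`, `log`.
#' @export
run_protocol <- function(cx, n_starts = 5, seed = 1L, alpha1 = 300,
                         alpha2_start = 250, time_limit = 5000,
                         time_limit2 = 2500,
                         params = langevin_params(),
                         detector = detector_params(),
                         bound_sampling_ps = 60, max_restarts = 6L,
                         save_every = 250L, ...) {
  set.seed(seed)
  seeds <- sample.int(2^30, 3)
  log <- list()

  # bound-state sampling for start structures
  pb <- params; pb$seed <- seeds[1]
  nsteps <- ceiling(bound_sampling_ps / params$dt)
  bound <- run_langevin(cx$coords, cx$potential, pb,
                        cx$topology$atoms$mass, nsteps,
                        save_every = max(1L, nsteps %/% (10 * n_starts)))
  nf <- dim(bound$coords)[3]
  pick <- round(seq(nf / n_starts, nf, length.out = n_starts))
  starts <- lapply(pick, function(f) bound$coords[, , f])
  log$starts <- sprintf("sampled %d start structures from %.0f ps of bound-state LD",
                        n_starts, bound_sampling_ps)

  p1 <- params; p1$seed <- seeds[2]
  pool <- step1_unbind(cx, starts, alpha1, time_limit, p1, detector,
                       save_every = save_every)
  log$step1 <- sprintf("step 1: %d runs, %d pooled, %d stubs",
                       n_starts, length(pool$segments),
                       length(pool$restarts))

  stubs <- pool$restarts
  if (length(stubs) > max_restarts) stubs <- stubs[seq_len(max_restarts)]
  for (k in seq_along(stubs)) {
    p2 <- params; p2$seed <- seeds[3] + 17L * k
    ext <- step2_extend(cx, stubs[[k]]$restart, alpha2_start, p2, detector,
                        time_limit2, save_every = save_every)
    log[[paste0("step2_", k)]] <-
      sprintf("step 2 stub %d: %s at alpha %d", k, ext$outcome, ext$alpha)
    for (s in ext$segments) {
      s$run <- paste0("restart", k)
      pool$segments[[length(pool$segments) + 1L]] <- s
    }
  }

  if (!length(pool$segments)) {
    log$step3 <- "step 3: empty pool, no intermediate found"
    return(structure(list(found = FALSE, pool = pool, report = NULL,
                          accepted_segments = list(), log = log),
                     class = "protocol_result"))
  }
  bound_dcm <- com_distance(cx$coords, group_atoms(cx$topology, "pocket"),
                            group_atoms(cx$topology, "core"),
                            cx$topology$atoms$mass)
  report <- step3_cluster(pool, bound_dcm, fluct_tol = detector$fluct_tol,
                          ...)
  found <- !is.na(report$accepted_id)
  acc <- if (found)
    pool$segments[report$clusters[[as.character(report$accepted_id)]]$members]
  else list()
  log$step3 <- sprintf(
    "step 3: %d segments, %d cluster(s), accepted: %s",
    length(pool$segments), length(report$clusters),
    if (found) as.character(report$accepted_id) else "none")
  structure(list(found = found, pool = pool, report = report,
                 accepted_segments = acc, log = log),
            class = "protocol_result")
}

#' @export
print.protocol_result <- function(x, ...) {
  cat("protocol_result:",
      if (x$found) "intermediate found" else "no intermediate found", "\n")
  for (l in x$log) cat(" ", l, "\n")
  if (!is.null(x$report)) print(x$report)
  invisible(x)
}
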