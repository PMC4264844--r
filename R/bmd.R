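#' Ratchet bias state
#'
#' State of the BMD ratchet: the reaction-coordinate atom pair, the largest
#' reaction-coordinate value reached so far (the watermark `rho_max`), and
#' the force constant `alpha` in pN/A.
#'
#' @param rc_atoms integer vector of two atom indices (ligand anchor,
#'   protein anchor).
#' @param alpha ratchet force constant, pN/A (>= 0).
#' @param rho_max current watermark, A; `NA` means "initialize from the
#'   starting frame's reaction-coordinate distance", the convention that
#'   makes the bias zero at t = 0.
#' @return object of class `bias_state`.
#' @export
bias_state <- function(rc_atoms, alpha, rho_max = NA_real_) {
  if (length(rc_atoms) != 2 || rc_atoms[1] == rc_atoms[2])
    stop("rc_atoms must be two distinct atom indices")
  if (alpha < 0) stop("bias force constant alpha must be >= 0")
  structure(list(rc_atoms = as.integer(rc_atoms), alpha = alpha,
                 rho_max = rho_max),
            class = "bias_state")
}

#' @export
print.bias_state <- function(x, ...) {
  cat("bias_state: rc atoms (", x$rc_atoms[1], ",", x$rc_atoms[2],
      "), alpha =", x$alpha, "pN/A, rho_max =", x$rho_max, "A\n")
  invisible(x)
}

#' Ratchet bias energy
#'
#' Half-quadratic penalty applied only when the reaction coordinate lies
#' below its running maximum: `0.5 alpha (rho_max - rho)^2` for
#' `rho < rho_max`, exactly zero otherwise (the ratchet advances instead of
#' pushing).
#'
#' @param rho current reaction-coordinate value, A. Vectorized.
#' @param rho_max watermark, A.
#' @param alpha force constant, pN/A.
#' @return energy in kcal/mol.
#' @examples
#' bias_energy(9, 10, 300)  # 0.5 * 300 pN/A * 1 A^2 = 2.159 kcal/mol
#' bias_energy(11, 10, 300) # 0: rho is above the watermark
#' @export
bias_energy <- function(rho, rho_max, alpha) {
  if (alpha < 0) stop("bias force constant alpha must be >= 0")
  k <- pn_per_A_to_kcal(alpha)
  ifelse(rho < rho_max, 0.5 * k * (rho_max - rho)^2, 0)
}

#' Advance the ratchet watermark
#'
#' @param rho observed reaction-coordinate value, A.
#' @param state a [bias_state()].
#' @return the state with `rho_max` replaced by `max(rho_max, rho)`; all
#'   other fields unchanged.
#' @export
update_rho_max <- function(rho, state) {
  state$rho_max <- max(state$rho_max, rho, na.rm = TRUE)
  state
}

#' Next force constant in the adaptive schedule
#'
#' The schedule lowers `alpha` by steps of 25 pN/A within the range
#' 50-250 pN/A; from the initial unbinding value of 300 pN/A the first
#' retry value is 250.
#'
#' @param alpha current force constant, pN/A (> 0).
#' @return the next force constant, pN/A.
#' @export
next_alpha <- function(alpha) {
  if (alpha <= 0) stop("alpha must be > 0")
  if (alpha <= 50)
    stop("alpha schedule exhausted: already at the 50 pN/A lower bound",
         call. = FALSE)
  max(min(alpha - 25, 250), 50)
}

#' Run a biased (BMD) simulation
#'
#' Langevin dynamics with the ratchet bias applied along the separation
#' vector of the two reaction-coordinate atoms (equal and opposite on the
#' pair). With `alpha = 0` the run is bit-identical to an unbiased
#' [run_langevin()] at the same seed. The run stops at the time limit or as
#' soon as the reaction coordinate reaches `unbound_rho`.
#'
#' @param x0 N x 3 starting coordinates (Angstrom).
#' @param potential a [toy_potential()].
#' @param params a [langevin_params()].
#' @param masses per-atom masses, amu.
#' @param bias a [bias_state()].
#' @param time_limit run length, ps.
#' @param unbound_rho stop threshold on the reaction coordinate, A
#'   (`Inf` to disable).
#' @param save_every save a frame every this many steps.
#' @param v0 optional initial velocities.
#' @return list of class `bmd_run`: `trajectory` (a [trajectory()] with
#'   `dt = save_every * params$dt`), `times`, `rho`, `rho_max`,
#'   `bias_energy` (per saved frame), `bias_work` (accumulated, kcal/mol),
#'   `stopped` ("time_limit" or "unbound"), `x_final`, `v_final`, `alpha`.
#' @export
run_bmd <- function(x0, potential, params, masses, bias,
                    time_limit = 5000, unbound_rho = Inf,
                    save_every = 100L, v0 = NULL) {
  x0 <- as.matrix(x0)
  if (is.null(v0)) v0 <- matrix(0, nrow(x0), 3)
  if (length(masses) == 1) masses <- rep(masses, nrow(x0))
  nsteps <- ceiling(time_limit / params$dt)
  set.seed(params$seed)
  res <- engine_run(x0, as.matrix(v0), as.numeric(masses), potential,
                    params$dt, params$friction, params$temperature,
                    as.integer(nsteps), as.integer(save_every),
                    list(enabled = TRUE, i = bias$rc_atoms[1],
                         j = bias$rc_atoms[2],
                         alpha = pn_per_A_to_kcal(bias$alpha),
                         rho_max0 = as.numeric(bias$rho_max)),
                    unbound_rho)
  coords <- aperm(res$frames, c(2, 1, 3))
  structure(list(coords = coords, times = res$times, rho = res$rho,
                 rho_max = res$rho_max, bias_energy = res$bias_energy,
                 bias_work = res$bias_work, stopped = res$stopped,
                 x_final = res$x_final, v_final = res$v_final,
                 alpha = bias$alpha, dt = params$dt * save_every),
            class = "bmd_run")
}

#' @export
print.bmd_run <- function(x, ...) {
  cat("bmd_run: alpha =", x$alpha, "pN/A,", length(x$times),
      "saved frames over", round(max(x$times), 1), "ps; stopped:",
      x$stopped, "\n")
  cat("  rho:", round(x$rho[1], 2), "->", round(x$rho[length(x$rho)], 2),
      "A (watermark", round(max(x$rho_max), 2), "A)\n")
  invisible(x)
}

#' Trajectory of a BMD run
#'
#' @param run a `bmd_run` (see [run_bmd()]).
#' @param top the system [topology()].
#' @return a [trajectory()] of the saved frames.
#' @export
bmd_trajectory <- function(run, top) trajectory(top, run$coords, run$dt)
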