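#' Langevin dynamics parameters
#'
#' @param temperature bath temperature, Kelvin (>= 0).
#' @param friction friction coefficient, ps^-1 (> 0). Default 60, the
#'   high-friction regime typical of implicit-solvent protein simulations.
#' @param dt integration time step, ps (> 0). Default 0.002 ps, a standard
#'   step for unconstrained bead dynamics.
#' @param seed integer RNG seed; every simulation is bit-reproducible given
#'   the seed.
#' @return object of class `langevin_params`.
#' @export
langevin_params <- function(temperature = 300, friction = 60, dt = 0.002,
                            seed = 1L) {
  if (temperature < 0) stop("temperature must be >= 0")
  if (friction <= 0) stop("friction must be > 0")
  if (dt <= 0) stop("dt must be > 0")
  structure(list(temperature = temperature, friction = friction,
                 dt = dt, seed = as.integer(seed)),
            class = "langevin_params")
}

#' Run unbiased Langevin dynamics
#'
#' BAOAB-split Langevin integration of a [toy_potential()]. Deterministic
#' given `params$seed`; with friction effectively zero and temperature 0
#' the scheme reduces to velocity Verlet.
#'
#' @param x0 N x 3 initial coordinates (Angstrom).
#' @param potential a [toy_potential()].
#' @param params a [langevin_params()].
#' @param masses per-atom masses, amu.
#' @param nsteps number of integration steps.
#' @param save_every save a frame every this many steps.
#' @param v0 optional N x 3 initial velocities (A/ps); default zero.
#' @return list with `coords` (atoms x 3 x frames array), `times` (ps),
#'   `x_final`, `v_final`.
#' @export
run_langevin <- function(x0, potential, params, masses, nsteps,
                         save_every = 1L, v0 = NULL) {
  x0 <- as.matrix(x0)
  if (is.null(v0)) v0 <- matrix(0, nrow(x0), 3)
  if (length(masses) == 1) masses <- rep(masses, nrow(x0))
  set.seed(params$seed)
  res <- engine_run(x0, as.matrix(v0), as.numeric(masses), potential,
                    params$dt, params$friction, params$temperature,
                    as.integer(nsteps), as.integer(save_every),
                    list(enabled = FALSE), Inf)
  coords <- aperm(res$frames, c(2, 1, 3))
  list(coords = coords, times = res$times,
       x_final = res$x_final, v_final = res$v_final)
}
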