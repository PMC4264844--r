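test_that("flat-bottom restraint matches its closed form and is C1", {
  expect_equal(flat_bottom_energy(3.0, 2.5, 3.5, 7), 0)
  expect_equal(flat_bottom_energy(4.5, 2.5, 3.5, 2), 1.0)
  expect_equal(flat_bottom_energy(2.0, 2.5, 3.5, 2), 0.25)
  expect_error(flat_bottom_energy(3, 2.5, 3.5, -1), ">= 0")
  expect_error(flat_bottom_energy(3, 3.5, 2.5, 1), "rmin <= rmax")

  # energy equals minus the integral of the force (trapezoid quadrature)
  d <- seq(1.0, 6.0, by = 1e-4)
  f <- flat_bottom_force(d, 2.5, 3.5, 3)
  e <- flat_bottom_energy(d, 2.5, 3.5, 3)
  w <- -cumsum((f[-1] + f[-length(f)]) / 2) * 1e-4
  expect_lt(max(abs((e[-1] - e[1]) - w)), 1e-6)
})

test_that("every potential term has an exact analytic gradient", {
  set.seed(3)
  pots <- list(
    toy_potential(list(harmonic_well(1L, c(1, -2, 0.5), 3))),
    toy_potential(list(harmonic_well(2L, c(0, 0, 0), c(0, 1, 2)))),
    toy_potential(list(flat_bottom_pair(1L, 2L, 2, 3, 4))),
    toy_potential(list(funnel_radial(1L, 2L,
                                     rbind(c(5, 6, 0.9), c(9, 3.5, 0.5)),
                                     wall_r = 3, wall_k = 50))),
    toy_potential(list(double_well_1d(1L, 1L, 1, 1.2))),
    toy_potential(list(vector_bond(1L, 2L, c(1, 0.5, -0.3), 8))))
  h <- 1e-5
  for (pot in pots) {
    for (rep in 1:5) {
      x <- matrix(rnorm(6, sd = 3), 2, 3)
      x[2, ] <- x[1, ] + rnorm(3, sd = 4) # keep pair distances generic
      f <- toy_forces(pot, x)
      scale <- max(abs(f), 1)
      for (i in 1:2) for (d in 1:3) {
        xp <- x; xp[i, d] <- xp[i, d] + h
        xm <- x; xm[i, d] <- xm[i, d] - h
        num <- -(toy_energy(pot, xp) - toy_energy(pot, xm)) / (2 * h)
        expect_lt(abs(f[i, d] - num) / scale, 1e-5)
      }
    }
  }
})

test_that("a particle at the minimum at T = 0 is a fixed point", {
  pot <- toy_potential(list(harmonic_well(1L, c(2, 1, 0), 5)))
  p <- langevin_params(temperature = 0, friction = 60, dt = 0.002, seed = 1)
  r <- run_langevin(matrix(c(2, 1, 0), 1, 3), pot, p, 12, 1000)
  expect_lt(max(abs(r$x_final - c(2, 1, 0))), 1e-12)
})

test_that("identical seeds give bit-identical trajectories", {
  cx <- make_toy_complex()
  p <- langevin_params(seed = 99)
  r1 <- run_langevin(cx$coords, cx$potential, p, cx$topology$atoms$mass,
                     2000, save_every = 50L)
  r2 <- run_langevin(cx$coords, cx$potential, p, cx$topology$atoms$mass,
                     2000, save_every = 50L)
  expect_identical(r1$coords, r2$coords)
  p2 <- langevin_params(seed = 100)
  r3 <- run_langevin(cx$coords, cx$potential, p2, cx$topology$atoms$mass,
                     2000, save_every = 50L)
  expect_false(identical(r1$coords, r3$coords))
})

test_that("harmonic sampling reproduces the equipartition variance", {
  pot <- toy_potential(list(harmonic_well(1L, c(0, 0, 0), 1)))
  p <- langevin_params(300, 60, 0.002, seed = 7)
  r <- run_langevin(matrix(0, 1, 3), pot, p, 12.011, 1e6, save_every = 10L)
  v <- var(r$coords[1, 1, ])
  expect_lt(abs(v - 0.5962) / 0.5962, 0.05)
})

test_that("the sampled double-well marginal matches Boltzmann", {
  # quartic double well a (x^2 - b^2)^2, barrier 1 kcal/mol
  pot <- toy_potential(list(
    double_well_1d(1L, 1L, 1, 1),
    harmonic_well(1L, c(0, 0, 0), c(0, 5, 5))))
  p <- langevin_params(300, 60, 0.002, seed = 13)
  r <- run_langevin(matrix(c(1, 0, 0), 1, 3), pot, p, 12, 1e6,
                    save_every = 5L)
  x <- r$coords[1, 1, ]
  kT <- 1.987204e-3 * 300
  breaks <- seq(-2.5, 2.5, by = 0.1)
  x <- x[x > -2.5 & x < 2.5]
  obs <- hist(x, breaks = breaks, plot = FALSE)$counts
  obs <- obs / sum(obs)
  dens <- function(q) exp(-((q^2 - 1)^2) / kT)
  expc <- vapply(seq_len(length(breaks) - 1), function(i)
    integrate(dens, breaks[i], breaks[i + 1])$value, numeric(1))
  expc <- expc / sum(expc)
  keep <- obs > 0 & expc > 0
  kl <- sum(obs[keep] * log(obs[keep] / expc[keep]))
  expect_lt(kl, 0.05)
})

test_that("toy-complex landscape minima sit where specified", {
  cx <- make_toy_complex(bound_rho = 5, inter_rho = 9)
  # independent re-minimization, bracketing each well
  for (target in c(5, 9)) {
    m <- optimize(function(r) funnel_energy(cx$landscape, r),
                  c(target - 1.5, target + 1.5), tol = 1e-9)
    expect_lt(abs(m$minimum - target), 1e-3)
  }
  # barrier top between the wells lies above both well energies
  prof <- funnel_energy(cx$landscape, seq(5, 9, by = 0.01))
  expect_gt(max(prof), funnel_energy(cx$landscape, 5))
  expect_gt(max(prof), funnel_energy(cx$landscape, 9))
})

test_that("a zero-depth intermediate leaves a single minimum", {
  cx <- make_toy_complex(inter_depth = 0)
  rho <- seq(3.2, 14, by = 0.01)
  prof <- funnel_energy(cx$landscape, rho)
  dps <- diff(sign(diff(prof)))
  expect_equal(sum(dps == 2), 1) # exactly one local minimum
})

test_that("overlapping wells are rejected", {
  expect_error(make_toy_complex(bound_rho = 5, inter_rho = 6.2,
                                bound_width = 0.9, inter_width = 0.7),
               "overlap")
  expect_error(make_toy_complex(bound_rho = 9, inter_rho = 5), "ordered")
})

test_that("planted contacts are realized at the planned rates", {
  plan <- data.frame(freq = c(1, 0, 0.55), mean = c(3.2, 8, 3.4),
                     sd = c(0.15, 0.3, 0.2))
  traj <- synth_contact_trajectory(plan, n_frames = 1000, seed = 5)
  d1 <- pair_distance_series(traj, 4, 1)
  d2 <- pair_distance_series(traj, 5, 2)
  d3 <- pair_distance_series(traj, 6, 3)
  expect_true(all(d1 < 4))           # frequency 1: every frame in contact
  expect_true(all(d2 >= 4))          # frequency 0: no contacts
  f3 <- mean(d3 < 4)
  expect_lt(abs(f3 - 0.55), 3 * sqrt(0.55 * 0.45 / 1000))
  expect_lt(abs(sd(d1) - 0.15) / 0.15, 0.15)
  expect_lt(abs(mean(d1) - 3.2), 0.05)
})

test_that("contact generator seeds differ in noise, agree in statistics", {
  plan <- data.frame(freq = 1, mean = 3.2, sd = 0.15)
  t1 <- synth_contact_trajectory(plan, 1000, seed = 1)
  t2 <- synth_contact_trajectory(plan, 1000, seed = 2)
  expect_false(identical(t1$coords, t2$coords))
  d1 <- pair_distance_series(t1, 2, 1)
  d2 <- pair_distance_series(t2, 2, 1)
  expect_lt(abs(mean(d1) - mean(d2)), 0.03)
  expect_lt(abs(sd(d1) - sd(d2)), 0.03)
  expect_identical(synth_contact_trajectory(plan, 100, seed = 9)$coords,
                   synth_contact_trajectory(plan, 100, seed = 9)$coords)
})

test_that("infeasible contact plans are rejected", {
  expect_error(synth_contact_trajectory(
    data.frame(freq = 1, mean = 8, sd = 0.2)), "infeasible")
  expect_error(synth_contact_trajectory(
    data.frame(freq = 1.4, mean = 3, sd = 0.2)), "\\[0, 1\\]")
})

test_that("planted plateaus in synthetic series hold their levels", {
  # noiseless single plateau spanning the series: constant
  s <- synth_series(data.frame(start = 0, end = 500, level = 5, sd = 0),
                    total_ps = 500, dt = 1)
  expect_true(all(s[, 1] == 5))

  # noiseless two-level series: exact step function
  s2 <- synth_series(data.frame(start = c(0, 250), end = c(249, 500),
                                level = c(5, 9), sd = c(0, 0)),
                     total_ps = 500, dt = 1)
  tv <- attr(s2, "time")
  expect_true(all(s2[tv <= 249, 1] == 5))
  expect_true(all(s2[tv >= 250, 1] == 9))
  expect_true(all(s2[, 1] %in% c(5, 9)))

  # planted (100-400 ps, level 7, SD 0.2): sample mean within 0.03
  s3 <- synth_series(data.frame(start = 100, end = 400, level = 7,
                                sd = 0.2), total_ps = 600, dt = 1,
                     seed = 11)
  tv <- attr(s3, "time")
  expect_lt(abs(mean(s3[tv >= 100 & tv <= 400, 1]) - 7), 0.03)

  expect_error(synth_series(data.frame(start = 0, end = 700, level = 1,
                                       sd = 0), total_ps = 500), "exceed")
  expect_error(synth_series(data.frame(start = c(0, 100),
                                       end = c(150, 300),
                                       level = c(1, 2), sd = c(0, 0)),
                            total_ps = 500), "overlap")
})
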