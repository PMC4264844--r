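test_that("self-superposition is the identity with zero RMSD", {
  x <- fixture_coords()
  fit <- superpose(x, x)
  expect_equal(fit$rmsd, 0, tolerance = 1e-12)
  expect_equal(fit$R, diag(3), tolerance = 1e-9)
  expect_equal(as.numeric(fit$t), c(0, 0, 0), tolerance = 1e-9)
})

test_that("a known rigid transform is recovered exactly", {
  x <- fixture_coords()
  R0 <- euler_rot(0.4, 1.1, -0.7)
  t0 <- c(3, -2, 8)
  y <- sweep(x %*% t(R0), 2, t0, "+")
  fit <- superpose(x, y)
  expect_lt(fit$rmsd, 1e-9)
  expect_lt(max(abs(apply_transform(x, fit) - y)), 1e-9)
  expect_equal(det(fit$R), 1, tolerance = 1e-9)        # proper rotation
  expect_equal(crossprod(fit$R), diag(3), tolerance = 1e-9)
})

test_that("Kabsch attains the brute-force rotational minimum", {
  set.seed(8)
  for (rep in 1:5) {
    P <- matrix(rnorm(30, sd = 2), 10, 3)
    Q <- matrix(rnorm(30, sd = 2), 10, 3)
    fit <- superpose(P, Q)
    oracle <- grid_min_rmsd(P, Q)
    expect_lt(abs(fit$rmsd - oracle), 1e-3)
    expect_lte(fit$rmsd, oracle + 1e-9)  # never worse than the oracle
  }
})

test_that("superposition agrees with the bio3d reference implementation", {
  set.seed(12)
  P <- matrix(rnorm(30, sd = 2), 10, 3)
  Q <- matrix(rnorm(30, sd = 2), 10, 3)
  fit <- superpose(P, Q)
  xyz <- bio3d::fit.xyz(fixed = as.vector(t(Q)), mobile = as.vector(t(P)),
                        fixed.inds = 1:30, mobile.inds = 1:30)
  ref_rmsd <- sqrt(mean(rowSums((matrix(xyz, ncol = 3, byrow = TRUE) -
                                 Q)^2)))
  expect_equal(fit$rmsd, ref_rmsd, tolerance = 1e-8)
})

test_that("degenerate fit sets are rejected", {
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(superpose(line, line + 1), "collinear|degenerate")
  expect_error(superpose(matrix(0, 2, 3), matrix(0, 2, 3)), "at least 3")
})

test_that("superposition is invariant to pre-rotation of the mobile frame", {
  set.seed(9)
  P <- matrix(rnorm(30, sd = 2), 10, 3)
  Q <- matrix(rnorm(30, sd = 2), 10, 3)
  r1 <- superpose(P, Q)$rmsd
  r2 <- superpose(P %*% t(euler_rot(1, 0.5, 2)), Q)$rmsd
  expect_equal(r1, r2, tolerance = 1e-9)
  # superposed RMSD never exceeds the unfitted RMSD
  raw <- sqrt(mean(rowSums((P - Q)^2)))
  expect_lte(r1, raw + 1e-12)
})

test_that("group RMSD under A1/A2 behaves on a displaced-loop fixture", {
  top <- fixture_topology()
  ref <- fixture_coords()
  expect_equal(rmsd(ref, ref, alignment_spec("A1", "ligand"), top), 0,
               tolerance = 1e-9)
  # rigidly translate the loop group (atoms 5:6) by 3 A
  moved <- ref
  moved[5:6, 1] <- moved[5:6, 1] + 3
  a2 <- rmsd(moved, ref, alignment_spec("A2", "loop", "loop"), top)
  a1 <- rmsd(moved, ref, alignment_spec("A1", "loop"), top)
  expect_equal(a2, 3, tolerance = 1e-9)   # A2 fit untouched by the shift
  expect_gte(a2, a1 - 1e-9)               # A1 fit absorbs part of it
  expect_error(rmsd(ref, ref, alignment_spec("A1", "nosuch"), top),
               "no group")
  expect_error(alignment_spec("A2", "loop"), "excluded")
})

test_that("center-of-mass distances match the explicit formula", {
  x <- rbind(c(0, 0, 0), c(3, 4, 0))
  expect_equal(com_distance(x, 1, 2), 5)
  expect_equal(com_distance(x, 1:2, 1:2), 0)
  set.seed(14)
  y <- matrix(rnorm(30), 10, 3)
  m <- runif(10, 1, 16)
  ga <- c(1, 4, 7); gb <- c(2, 3, 9, 10)
  coma <- colSums(y[ga, ] * m[ga]) / sum(m[ga])
  comb <- colSums(y[gb, ] * m[gb]) / sum(m[gb])
  expect_equal(com_distance(y, ga, gb, m),
               sqrt(sum((coma - comb)^2)), tolerance = 1e-12)
  expect_error(com_distance(y, integer(0), gb), "non-empty")
  expect_error(com_distance(y, ga, gb, rep(0, 10)), "zero total mass")
})

test_that("RMSF vanishes for static and rigidly tumbling trajectories", {
  top <- fixture_topology()
  x <- fixture_coords()
  static <- trajectory(top, array(rep(x, 4), c(10, 3, 4)), 1)
  expect_true(all(rmsf(static) < 1e-12))
  expect_error(rmsf(trajectory(top, array(x, c(10, 3, 1)), 1)),
               "at least 2")
  # rigid-body tumbling: alignment on all atoms removes all motion
  coords <- array(NA_real_, c(10, 3, 6))
  set.seed(15)
  for (f in 1:6) {
    R0 <- euler_rot(runif(1, 0, 2 * pi), runif(1, 0, pi),
                    runif(1, 0, 2 * pi))
    coords[, , f] <- sweep(x %*% t(R0), 2, rnorm(3, sd = 5), "+")
  }
  tumb <- trajectory(top, coords, 1)
  spec <- alignment_spec("A1", "protein", fit_group = "protein")
  expect_true(all(rmsf(tumb, spec = spec) < 1e-3))
})

test_that("a tethered bead's RMSF matches the equipartition closed form", {
  pot <- toy_potential(list(harmonic_well(1L, c(0, 0, 0), 1)))
  p <- langevin_params(300, 60, 0.002, seed = 23)
  r <- run_langevin(matrix(0, 1, 3), pot, p, 12.011, 1e6, save_every = 10L)
  atoms <- data.frame(serial = 1L, name = "C1", element = "C",
                      mass = 12.011, resno = 1L, resid = "LIG",
                      chain = "L")
  traj <- trajectory(topology(atoms, list(bead = 1L)), r$coords, 0.02)
  # sqrt(3 kB T / k) = 1.337 A at 300 K, k = 1 kcal/mol/A^2
  expect_lt(abs(rmsf(traj)[[1]] - 1.337) / 1.337, 0.05)
})

test_that("series summaries split within- and between-simulation spread", {
  s <- summarize_series(list(rep(2, 10), rep(2, 10), rep(2, 10)))
  expect_equal(s$fluctuation, 0)
  expect_equal(s$ensemble_sd, 0)
  # per-simulation means {5, 6, 7}: sample SD is 1
  s2 <- summarize_series(list(rep(5, 4), rep(6, 4), rep(7, 4)))
  expect_equal(s2$ensemble_sd, 1)
  expect_equal(s2$mean, 6)
  set.seed(16)
  s3 <- summarize_series(lapply(1:4, function(i) rnorm(20000, 3, 0.8)))
  expect_lt(abs(s3$fluctuation - 0.8) / 0.8, 0.05)
  # single simulation: ensemble SD defined as 0
  expect_equal(summarize_series(rnorm(10))$ensemble_sd, 0)
})
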