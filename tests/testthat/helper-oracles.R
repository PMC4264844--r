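# Independent oracles used across the suite. These deliberately avoid the
# code paths they check.

# rotation matrix from z-y-z Euler angles
euler_rot <- function(a, b, g) {
  rz <- function(t) matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0,
                             0, 0, 1), 3, 3, byrow = TRUE)
  ry <- function(t) matrix(c(cos(t), 0, sin(t), 0, 1, 0,
                             -sin(t), 0, cos(t)), 3, 3, byrow = TRUE)
  rz(a) %*% ry(b) %*% rz(g)
}

# translation-optimal RMSD for a fixed rotation (centroids matched)
rot_rmsd <- function(ang, P, Q) {
  R <- euler_rot(ang[1], ang[2], ang[3])
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  sqrt(mean(rowSums((Pc %*% t(R) - Qc)^2)))
}

# brute-force minimal RMSD over rotations: coarse Euler grid then local
# polish from the best grid points
grid_min_rmsd <- function(P, Q, coarse = 12) {
  ga <- seq(0, 2 * pi, length.out = coarse + 1)[-1]
  gb <- seq(0, pi, length.out = ceiling(coarse / 2))
  vals <- expand.grid(a = ga, b = gb, g = ga)
  r <- apply(vals, 1, rot_rmsd, P = P, Q = Q)
  best <- order(r)[1:3]
  min(vapply(best, function(i) {
    stats::optim(as.numeric(vals[i, ]), rot_rmsd, P = P, Q = Q,
                 method = "Nelder-Mead",
                 control = list(reltol = 1e-14, maxit = 4000))$value
  }, numeric(1)))
}

# literal per-frame all-pairs contact recount (triple loop, no reuse of
# package internals)
brute_contact_census <- function(traj, lig, prot, cutoff = 4) {
  nf <- n_frames(traj)
  freq <- matrix(0, length(lig), length(prot))
  dsum <- dsum2 <- matrix(0, length(lig), length(prot))
  for (f in seq_len(nf)) {
    x <- frame_coords(traj, f)
    for (a in seq_along(lig)) {
      for (b in seq_along(prot)) {
        d <- sqrt(sum((x[lig[a], ] - x[prot[b], ])^2))
        if (d < cutoff) freq[a, b] <- freq[a, b] + 1
        dsum[a, b] <- dsum[a, b] + d
        dsum2[a, b] <- dsum2[a, b] + d^2
      }
    }
  }
  list(freq = freq / nf, mean = dsum / nf,
       sd = sqrt(pmax((dsum2 - dsum^2 / nf) / (nf - 1), 0)))
}

# small fixed topology used by io/geometry fixtures: 6 protein CA + 4
# ligand atoms
fixture_topology <- function() {
  atoms <- data.frame(
    serial = 1:10,
    name = c(rep("CA", 6), "C1", "C2", "N7", "O1"),
    element = c(rep("C", 6), "C", "C", "N", "O"),
    mass = c(rep(12.011, 6), 12.011, 12.011, 14.007, 15.999),
    resno = c(1:6, rep(100L, 4)),
    resid = c("MET", "VAL", "GLY", "ALA", "GLU", "ILE", rep("LIG", 4)),
    chain = c(rep("A", 6), rep("L", 4)),
    type = c(rep("ATOM", 6), rep("HETATM", 4)),
    stringsAsFactors = FALSE)
  topology(atoms,
           groups = list(protein = 1:6, calpha = 1:6, ligand = 7:10,
                         pocket = 1:4, loop = 5:6,
                         core = 7:8, N7g = 9L, O1g = 10L),
           moieties = c("core", "N7g", "O1g"))
}

fixture_coords <- function() {
  set.seed(42)
  matrix(rnorm(30, sd = 3), 10, 3)
}
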