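make_pair_traj <- function(distances) {
  # two atoms whose separation follows `distances`, one value per frame
  atoms <- data.frame(serial = 1:2, name = c("CA", "C1"),
                      element = "C", mass = 12.011,
                      resno = c(5L, 100L), resid = c("GLU", "LIG"),
                      chain = c("A", "L"), type = c("ATOM", "HETATM"))
  top <- topology(atoms, list(protein = 1L, ligand = 2L, core = 2L),
                  moieties = "core")
  coords <- array(0, c(2, 3, length(distances)))
  coords[2, 1, ] <- distances
  trajectory(top, coords, 1)
}

test_that("the census applies strict cutoff and frequency rules", {
  # hand count: {3.5, 3.9, 4.2} -> 2/3 frames < 4 A -> frequency 2/3 > 0.5
  tr <- make_pair_traj(c(3.5, 3.9, 4.2))
  rec <- candidate_contacts(tr)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$freq_max, 2 / 3)
  # exactly 4.000 A in every frame: strict '<' means zero contacts
  tr4 <- make_pair_traj(c(4, 4, 4))
  expect_equal(nrow(candidate_contacts(tr4)), 0)
  # frequency exactly 0.5 is NOT retained (strict '>')
  tr50 <- make_pair_traj(c(3.5, 3.5, 4.5, 4.5))
  expect_equal(nrow(candidate_contacts(tr50)), 0)
  expect_error(candidate_contacts(tr, ligand_atoms = integer(0)), "empty")
})

test_that("planted frequencies select exactly the planned pairs", {
  plan <- data.frame(freq = c(0.2, 0.55, 1.0), mean = c(3.4, 3.4, 3.2),
                     sd = c(0.2, 0.2, 0.15), resno = c(1L, 2L, 3L))
  traj <- synth_contact_trajectory(plan, n_frames = 400, seed = 7)
  rec <- candidate_contacts(traj)
  expect_equal(sort(rec$prot_resno), c(2L, 3L))
})

test_that("permanent/transient labels follow the all-frames and SD rules", {
  plan <- data.frame(freq = c(1.0, 1.0, 0.99, 0.6, 0.2),
                     mean = c(3.2, 3.2, 3.2, 3.4, 3.4),
                     sd = c(0.15, 0.45, 0.10, 0.2, 0.2),
                     resno = 1:5)
  traj <- synth_contact_trajectory(plan, n_frames = 600, seed = 9)
  rec <- candidate_contacts(traj)
  lab <- setNames(rec$class, rec$prot_resno)
  expect_equal(unname(lab["1"]), "permanent")  # every frame, low SD
  expect_equal(unname(lab["2"]), "transient")  # every frame but SD >= 0.25
  expect_equal(unname(lab["3"]), "transient")  # one missed frame suffices
  expect_equal(unname(lab["4"]), "transient")
  expect_false("5" %in% names(lab))            # below the frequency filter
  # classify_contact agrees with the census labels
  for (r in seq_len(nrow(rec)))
    expect_equal(classify_contact(rec[r, ], traj), rec$class[r])
})

test_that("census statistics equal a brute-force per-frame recount", {
  plan <- data.frame(freq = c(1, 0.7, 0.4), mean = c(3.3, 3.5, 3.6),
                     sd = c(0.2, 0.25, 0.2), resno = 1:3)
  traj <- synth_contact_trajectory(plan, n_frames = 100, seed = 21)
  top <- traj$topology
  lig <- group_atoms(top, "ligand")
  prot <- group_atoms(top, "protein")
  b <- brute_contact_census(traj, lig, prot)
  rec <- candidate_contacts(traj)
  for (r in seq_len(nrow(rec))) {
    a <- match(rec$i[r], lig); p <- match(rec$j[r], prot)
    expect_identical(rec$freq_max[r], b$freq[a, p])
    expect_equal(rec$pooled_mean[r], b$mean[a, p], tolerance = 1e-12)
    expect_equal(rec$pooled_sd[r], b$sd[a, p], tolerance = 1e-12)
  }
  # permanent set is a subset of the retained candidates
  expect_true(all(rec$class %in% c("permanent", "transient")))
})

test_that("contact-map cells count pairs and are frame-order invariant", {
  # single frame: one Tol-His87 pair within the cutoff
  atoms <- data.frame(serial = 1:4, name = c("CA", "CB", "C1", "C2"),
                      element = "C", mass = 12.011,
                      resno = c(87L, 54L, 200L, 200L),
                      resid = c("HIS", "GLU", "LIG", "LIG"),
                      chain = c("A", "A", "L", "L"),
                      type = c("ATOM", "ATOM", "HETATM", "HETATM"))
  top <- topology(atoms, list(protein = 1:2, ligand = 3:4,
                              Tol = 3L, core = 4L),
                  moieties = c("Tol", "core"))
  x <- rbind(c(0, 0, 0), c(20, 0, 0), c(3, 0, 0), c(40, 0, 0))
  cm <- contact_map(trajectory(top, x, 1))
  expect_equal(cm$map["Tol", "87"], 1)
  expect_equal(sum(cm$map), 1)

  # conservation: cell total equals the total cross-pair contact count
  plan <- data.frame(freq = c(1, 1, 0.5), mean = c(3.2, 3.4, 3.5),
                     sd = c(0.15, 0.2, 0.2), resno = 1:3,
                     moiety = c("core", "Tol", "Tol"))
  traj <- synth_contact_trajectory(plan, n_frames = 60, seed = 10)
  cm2 <- contact_map(traj)
  total <- 0
  for (f in seq_len(n_frames(traj))) {
    xx <- frame_coords(traj, f)
    for (i in group_atoms(traj$topology, "ligand"))
      for (j in group_atoms(traj$topology, "protein"))
        total <- total + (sqrt(sum((xx[i, ] - xx[j, ])^2)) < 4)
  }
  expect_equal(sum(cm2$map) * n_frames(traj), total)

  # permuting the frames leaves the time-averaged map unchanged
  perm <- traj
  perm$coords <- perm$coords[, , sample(n_frames(traj))]
  expect_equal(contact_map(perm)$map, cm2$map, tolerance = 1e-12)
})

test_that("planted contact maps are recovered within sampling error", {
  plan <- data.frame(freq = c(1, 0.8, 0.6), mean = c(3.2, 3.4, 3.4),
                     sd = c(0.15, 0.2, 0.2), resno = 1:3,
                     moiety = c("core", "iBu", "Tol"))
  traj <- synth_contact_trajectory(plan, n_frames = 500, seed = 12)
  cm <- contact_map(traj)
  for (r in seq_len(nrow(plan))) {
    se <- sqrt(plan$freq[r] * (1 - plan$freq[r]) / 500)
    expect_lt(abs(cm$map[plan$moiety[r], as.character(plan$resno[r])] -
                  plan$freq[r]), 3 * se + 1e-9)
  }
})

test_that("bridging waters require contact with both partners", {
  atoms <- data.frame(
    serial = 1:5,
    name = c("CA", "C1", "O", "H1", "O"),
    element = c("C", "C", "O", "H", "O"),
    mass = c(12.011, 12.011, 15.999, 1.008, 15.999),
    resno = c(5L, 100L, 300L, 300L, 301L),
    resid = c("GLU", "LIG", "HOH", "HOH", "HOH"),
    chain = c("A", "L", "W", "W", "W"),
    type = c("ATOM", "HETATM", "HETATM", "HETATM", "HETATM"))
  top <- topology(atoms, list(protein = 1L, ligand = 2L, core = 2L),
                  moieties = "core")
  # water 300 bridges (3.5 A from each); water 301 touches the ligand only
  x <- rbind(c(0, 0, 0), c(7, 0, 0), c(3.5, 0, 0), c(3.5, 0.9, 0),
             c(9, 0, 0))
  w <- bridging_waters(trajectory(top, x, 1))
  expect_equal(w["core", "5"], 1)
  # move the bridging water out of range of the protein: count drops to 0
  x2 <- x; x2[3:4, 1] <- c(5.5, 5.5)
  w2 <- bridging_waters(trajectory(top, x2, 1))
  expect_equal(w2["core", "5"], 0)
  # no solvent at all: zero layer with a warning
  dry <- fixture_topology()
  xd <- fixture_coords()
  expect_warning(bridging_waters(trajectory(dry, xd, 1)), "no solvent")
})

test_that("water-count display bins are left-open right-closed", {
  expect_equal(water_bin(0.5), "")
  expect_equal(water_bin(0.51), "]0.5;1]")
  expect_equal(water_bin(1.0), "]0.5;1]")
  expect_equal(water_bin(1.01), "]1;1.5]")
  expect_equal(water_bin(1.5), "]1;1.5]")
  expect_equal(water_bin(2.0), "]1.5;2]")
})

test_that("hydrogen-bond geometry is measured at the hydrogen", {
  atoms <- data.frame(serial = 1:3, name = c("N", "H", "O"),
                      element = c("N", "H", "O"),
                      mass = c(14.007, 1.008, 15.999),
                      resno = c(56L, 56L, 100L),
                      resid = c("ILE", "ILE", "LIG"),
                      chain = c("A", "A", "L"),
                      type = c("ATOM", "ATOM", "HETATM"))
  top <- topology(atoms, list(protein = 1:2, ligand = 3L))
  # collinear D-H...A with H...A = 1.9 A
  xc <- rbind(c(0, 0, 0), c(1, 0, 0), c(2.9, 0, 0))
  hb <- hbond_stats(trajectory(top, xc, 1), 1, 2, 3)
  expect_equal(hb$mean_angle, 180)
  expect_equal(hb$mean_dist, 1.9)
  expect_true(hb$formed)
  # right-angle construction
  xr <- rbind(c(-1, 0, 0), c(0, 0, 0), c(0, 2, 0))
  hb90 <- hbond_stats(trajectory(top, xr, 1), 1, 2, 3)
  expect_equal(hb90$mean_angle, 90)
  expect_false(hb90$formed)
  expect_error(hbond_stats(trajectory(top, xc, 1), 1, 1, 3), "distinct")
})

test_that("a long bent geometry classifies as a van der Waals contact", {
  # frames built to average to H...A 2.78 A and angle ~123 degrees: under
  # the defaults (2.5 A, 135 deg) the bond is not formed
  atoms <- data.frame(serial = 1:3, name = c("N", "H", "O1"),
                      element = c("N", "H", "O"),
                      mass = c(14.007, 1.008, 15.999),
                      resno = c(56L, 56L, 100L),
                      resid = c("ILE", "ILE", "LIG"),
                      chain = c("A", "A", "L"),
                      type = c("ATOM", "ATOM", "HETATM"))
  top <- topology(atoms, list(protein = 1:2, ligand = 3L))
  ang <- 123 * pi / 180
  mk <- function(d) rbind(c(-1, 0, 0), c(0, 0, 0),
                          d * c(cos(pi - ang), sin(pi - ang), 0))
  coords <- array(NA_real_, c(3, 3, 2))
  coords[, , 1] <- mk(2.78 - 0.3)
  coords[, , 2] <- mk(2.78 + 0.3)
  hb <- hbond_stats(trajectory(top, coords, 1), 1, 2, 3)
  expect_equal(hb$mean_dist, 2.78, tolerance = 1e-9)
  expect_equal(hb$mean_angle, 123, tolerance = 1e-6)
  expect_false(hb$formed)
})
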