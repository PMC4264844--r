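#' Toy protein-ligand complex on a model unbinding landscape
#'
#' Builds a minimal bead model of a protein-ligand complex whose unbinding
#' coordinate (distance between the ligand core bead and a protein anchor
#' bead) moves on a prescribed radial energy landscape: a bound well, an
#' optional metastable intermediate well, and a flat unbound region.
#'
#' The "protein" is five beads: four pocket anchors harmonically tethered
#' to fixed sites (stiff springs) and one weakly tethered mobile bead that
#' plays the role of the flexible loop. The "ligand" is a core bead plus
#' three peripheral beads (iBu/Tol/Ethe analogues) held at fixed offsets
#' from the core by vector bonds, so the ligand translates along the
#' unbinding channel without free tumbling. A transverse harmonic guide on
#' the core bead confines the exit path to a channel, standing in for the
#' pocket walls.
#'
#' @param bound_rho,bound_depth,bound_width bound-well position (A), depth
#'   (kcal/mol) and Gaussian width (A).
#' @param inter_rho,inter_depth,inter_width intermediate-well parameters;
#'   `inter_depth = 0` removes the intermediate (single-minimum landscape).
#' @param wall_rho,wall_k inner repulsive wall radius and stiffness.
#' @param guide_k transverse confinement stiffness on the ligand core
#'   (kcal/mol/A^2).
#' @param anchor_k,loop_k tether stiffness of the pocket anchors and of the
#'   mobile loop bead.
#' @return object of class `toy_complex`: list with `topology`,
#'   `potential`, `coords` (bound-state coordinates), `rc_atoms` (ligand
#'   core, protein anchor), `landscape` (the funnel term), and the
#'   well positions.
#' @export
make_toy_complex <- function(bound_rho = 5, bound_depth = 6,
                             bound_width = 0.9, inter_rho = 9,
                             inter_depth = 3.5, inter_width = 0.5,
                             wall_rho = 3, wall_k = 50, guide_k = 1,
                             anchor_k = 50, loop_k = 2) {
  if (bound_rho >= inter_rho)
    stop("wells must be ordered bound < intermediate along the coordinate")
  if (inter_depth > 0 &&
      (inter_rho - bound_rho) < 2 * (bound_width + inter_width))
    stop("overlapping wells: separation must exceed twice the summed widths")

  prot_sites <- rbind(c(0, 0, 0),        # RC anchor ("Glu5 CA" analogue)
                      c(1.5, 2.5, 0),
                      c(1.5, -2.5, 0),
                      c(-1.0, 0, 1.5),
                      c(2.0, 4.0, 0))    # mobile loop bead
  lig_offsets <- rbind(c(0, 0, 0),       # core
                       c(0, 1.5, 0),     # iBu
                       c(0, -1.05, 1.05),# Tol
                       c(0.5, 0, -1.45)) # Ethe
  core0 <- c(bound_rho, 0, 0)
  coords <- rbind(prot_sites, sweep(lig_offsets, 2, core0, "+"))

  atoms <- data.frame(
    serial = 1:9,
    name = c(rep("CA", 5), "C1", "C2", "C3", "C4"),
    element = "C",
    mass = 12.011,
    resno = c(1:5, rep(100L, 4)),
    resid = c(rep("ALA", 5), rep("LIG", 4)),
    chain = c(rep("A", 5), rep("L", 4)),
    type = c(rep("ATOM", 5), rep("HETATM", 4)),
    stringsAsFactors = FALSE)
  groups <- list(protein = 1:5, calpha = 1:5, ligand = 6:9,
                 pocket = 1:4, nonloop = 1:4, `80s_loop` = 5L,
                 loop_tip = 5L, core = 6L, iBu = 7L, Tol = 8L, Ethe = 9L)
  top <- topology(atoms, groups,
                  moieties = c("core", "iBu", "Tol", "Ethe"))

  wells <- rbind(c(bound_rho, bound_depth, bound_width))
  if (inter_depth > 0)
    wells <- rbind(wells, c(inter_rho, inter_depth, inter_width))
  landscape <- funnel_radial(6L, 1L, wells, wall_r = wall_rho,
                             wall_k = wall_k)

  terms <- list(landscape)
  for (i in 1:4)
    terms <- c(terms, list(harmonic_well(i, prot_sites[i, ], anchor_k)))
  terms <- c(terms, list(harmonic_well(5L, prot_sites[5, ], loop_k)))
  # transverse channel guide on the core bead (free along x)
  terms <- c(terms, list(harmonic_well(6L, c(0, 0, 0),
                                       c(0, guide_k, guide_k))))
  for (i in 2:4)
    terms <- c(terms, list(vector_bond(5L + i, 6L, lig_offsets[i, ], 10)))

  pot <- toy_potential(terms)

  # confirm by local minimization that the landscape minima sit where
  # specified
  minima <- c(stats::optimize(function(r) funnel_energy(landscape, r),
                              c(wall_rho, (bound_rho + inter_rho) / 2))$minimum)
  if (inter_depth > 0) {
    m2 <- stats::optimize(function(r) funnel_energy(landscape, r),
                          c((bound_rho + inter_rho) / 2,
                            inter_rho + 3 * inter_width))$minimum
    minima <- c(minima, m2)
  }

  structure(list(topology = top, potential = pot, coords = coords,
                 rc_atoms = c(6L, 1L), landscape = landscape,
                 bound_rho = bound_rho, inter_rho = inter_rho,
                 inter_depth = inter_depth, minima = minima),
            class = "toy_complex")
}

#' @export
print.toy_complex <- function(x, ...) {
  cat("toy_complex: 9 beads; bound well at", x$bound_rho, "A",
      if (x$inter_depth > 0)
        paste(", intermediate well at", x$inter_rho, "A")
      else ", no intermediate well", "\n")
  invisible(x)
}

#' Radial landscape energy of a funnel term
#'
#' Evaluates the radial profile (Gaussian wells + inner wall) of a
#' `funnel_radial` term at given reaction-coordinate values.
#'
#' @param term a `funnel_radial` term (e.g. `complex$landscape`).
#' @param rho distance value(s), Angstrom. Vectorized.
#' @return energy in kcal/mol.
#' @export
funnel_energy <- function(term, rho) {
  stopifnot(term$kind == "funnel_radial")
  e <- numeric(length(rho))
  for (w in seq_len(nrow(term$wells))) {
    pos <- term$wells[w, 1]; depth <- term$wells[w, 2]
    width <- term$wells[w, 3]
    e <- e - depth * exp(-0.5 * (rho - pos)^2 / width^2)
  }
  wall <- rho < term$wall_r
  e[wall] <- e[wall] + 0.5 * term$wall_k * (term$wall_r - rho[wall])^2
  e
}
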