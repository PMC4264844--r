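#' Model potentials for the toy simulator
#'
#' A toy potential is a list of additive terms evaluated by the compiled
#' engine. Available terms:
#'
#' * `harmonic_well(atom, ref, k)` — isotropic or per-dimension harmonic
#'   tether of one atom to a fixed point, `0.5 k |r - ref|^2`.
#' * `flat_bottom_pair(i, j, rmin, rmax, k)` — NOE-style flat-bottom
#'   distance restraint between two atoms: zero inside `[rmin, rmax]`,
#'   half-harmonic outside. With `rmin == rmax` this is an ordinary
#'   harmonic bond.
#' * `funnel_radial(i, j, wells, wall_r, wall_k)` — radial energy profile
#'   on the distance between two atoms: a sum of Gaussian wells
#'   (`wells` is a matrix with columns position, depth, width; kcal/mol,
#'   Angstrom) plus a half-harmonic repulsive wall below `wall_r`. Flat
#'   (zero) far from the wells, which models the unbound region.
#' * `double_well_1d(atom, dim, a, b)` — quartic double well
#'   `a (q^2 - b^2)^2` on one Cartesian coordinate of one atom.
#' * `vector_bond(i, j, d0, k)` — harmonic restraint of the *vector*
#'   between two atoms to `d0`, fixing their relative geometry.
#'
#' @param terms list of term lists as built by the constructors below.
#' @return object of class `toy_potential`.
#' @export
toy_potential <- function(terms) {
  stopifnot(is.list(terms))
  structure(list(terms = terms), class = "toy_potential")
}

#' @export
print.toy_potential <- function(x, ...) {
  kinds <- vapply(x$terms, function(t) t$kind, character(1))
  cat("toy_potential:", length(x$terms), "terms (",
      paste(sprintf("%s x%d", names(table(kinds)), table(kinds)),
            collapse = ", "), ")\n")
  invisible(x)
}

#' @rdname toy_potential
#' @param atom,i,j 1-based atom indices.
#' @param ref,d0 length-3 numeric vectors (Angstrom).
#' @param k force constant, kcal/mol/A^2 (length 1, or length 3 for a
#'   per-dimension `harmonic_well`).
#' @export
harmonic_well <- function(atom, ref, k) {
  stopifnot(length(ref) == 3, all(k >= 0), length(k) %in% c(1, 3))
  list(kind = "harmonic_well", atom = as.integer(atom),
       ref = as.numeric(ref), k = as.numeric(k))
}

#' @rdname toy_potential
#' @param rmin,rmax flat-bottom edges, Angstrom (`rmin <= rmax`).
#' @export
flat_bottom_pair <- function(i, j, rmin, rmax, k) {
  if (k < 0) stop("flat-bottom restraint force constant must be >= 0")
  if (rmin > rmax) stop("flat-bottom restraint requires rmin <= rmax")
  list(kind = "flat_bottom_pair", i = as.integer(i), j = as.integer(j),
       rmin = as.numeric(rmin), rmax = as.numeric(rmax), k = as.numeric(k))
}

#' @rdname toy_potential
#' @param wells numeric matrix, columns (position, depth, width).
#' @param wall_r,wall_k inner repulsive wall radius (A) and stiffness.
#' @export
funnel_radial <- function(i, j, wells, wall_r = 0, wall_k = 0) {
  wells <- matrix(as.numeric(wells), ncol = 3)
  if (any(wells[, 3] <= 0)) stop("funnel well widths must be positive")
  if (any(wells[, 2] < 0)) stop("funnel well depths must be >= 0")
  list(kind = "funnel_radial", i = as.integer(i), j = as.integer(j),
       wells = wells, wall_r = as.numeric(wall_r),
       wall_k = as.numeric(wall_k))
}

#' @rdname toy_potential
#' @param dim Cartesian dimension (1, 2 or 3) for `double_well_1d`.
#' @param a,b quartic double-well parameters: minima at `q = +-b`,
#'   barrier height `a b^4`.
#' @export
double_well_1d <- function(atom, dim, a, b) {
  list(kind = "double_well_1d", atom = as.integer(atom),
       dim = as.integer(dim), a = as.numeric(a), b = as.numeric(b))
}

#' @rdname toy_potential
#' @export
vector_bond <- function(i, j, d0, k) {
  stopifnot(length(d0) == 3, k >= 0)
  list(kind = "vector_bond", i = as.integer(i), j = as.integer(j),
       d0 = as.numeric(d0), k = as.numeric(k))
}

#' Potential energy of a configuration
#'
#' @param potential a [toy_potential()].
#' @param x N x 3 coordinate matrix (Angstrom).
#' @return energy in kcal/mol.
#' @export
toy_energy <- function(potential, x) {
  engine_energy_forces(as.matrix(x), potential)$energy
}

#' Forces (minus energy gradient) of a configuration
#'
#' @inheritParams toy_energy
#' @return N x 3 force matrix, kcal/mol/A.
#' @export
toy_forces <- function(potential, x) {
  engine_energy_forces(as.matrix(x), potential)$forces
}

#' Flat-bottom restraint energy
#'
#' Zero inside `[rmin, rmax]`, `0.5 k (d - rmax)^2` above and
#' `0.5 k (rmin - d)^2` below; continuous with continuous first derivative
#' at both edges. This is the functional form used for NOE-style distance
#' restraints centered on an experimentally measured distance.
#'
#' @param d distance(s), Angstrom. Vectorized.
#' @param rmin,rmax flat-bottom edges (`rmin <= rmax`), Angstrom.
#' @param k force constant, kcal/mol/A^2.
#' @return energy in kcal/mol, same length as `d`.
#' @examples
#' flat_bottom_energy(3.0, 2.5, 3.5, 5)   # 0
#' flat_bottom_energy(4.5, 2.5, 3.5, 2)   # 1
#' @export
flat_bottom_energy <- function(d, rmin, rmax, k) {
  if (k < 0) stop("flat-bottom restraint force constant must be >= 0")
  if (rmin > rmax) stop("flat-bottom restraint requires rmin <= rmax")
  ifelse(d > rmax, 0.5 * k * (d - rmax)^2,
         ifelse(d < rmin, 0.5 * k * (rmin - d)^2, 0))
}

#' Flat-bottom restraint force along the distance
#'
#' Minus the derivative of [flat_bottom_energy()] with respect to `d`.
#'
#' @inheritParams flat_bottom_energy
#' @return force in kcal/mol/A (negative above `rmax`, positive below
#'   `rmin`, zero inside).
#' @export
flat_bottom_force <- function(d, rmin, rmax, k) {
  if (k < 0) stop("flat-bottom restraint force constant must be >= 0")
  if (rmin > rmax) stop("flat-bottom restraint requires rmin <= rmax")
  ifelse(d > rmax, -k * (d - rmax), ifelse(d < rmin, k * (rmin - d), 0))
}

#' Convert a restraint set to flat-bottom potential terms
#'
#' @param restraints data.frame with columns i, j, rmin, rmax, k (as
#'   produced by [resolve_groups()]).
#' @return list of `flat_bottom_pair` terms.
#' @export
restraint_terms <- function(restraints) {
  lapply(seq_len(nrow(restraints)), function(r)
    flat_bottom_pair(restraints$i[r], restraints$j[r],
                     restraints$rmin[r], restraints$rmax[r],
                     restraints$k[r]))
}
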