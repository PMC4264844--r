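#' Physical constants and unit conversions
#'
#' Internal unit system: lengths in Angstrom, time in ps, masses in amu,
#' energies in kcal/mol. Bias force constants are quoted in pN/A (the unit
#' used for the ratchet force constant in the BMD literature) and converted
#' with [pn_per_A_to_kcal()].
#'
#' @name units
NULL

# Boltzmann constant, kcal mol^-1 K^-1
KB_KCAL <- 1.987204e-3

# 1 pN/A = 1.439e-2 kcal mol^-1 A^-2  (1 pN.A = 1e-22 J = 0.01439 kcal/mol)
PN_A_TO_KCAL <- 1.439e-2

# kcal/mol -> amu A^2 ps^-2 (the AKMA dynamical unit conversion)
KCAL_TO_AKMA <- 418.4

#' Convert a force constant from pN/A to kcal mol^-1 A^-2
#'
#' @param alpha force constant in pN/A.
#' @return force constant in kcal mol^-1 A^-2.
#' @examples
#' pn_per_A_to_kcal(300) # 4.317
#' @export
pn_per_A_to_kcal <- function(alpha) alpha * PN_A_TO_KCAL

# atomic masses (amu) used when a structure file carries no masses
ELEMENT_MASSES <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, F = 18.998, CL = 35.45, BR = 79.904, I = 126.904,
  NA. = 22.99, MG = 24.305, K = 39.098, CA = 40.078, ZN = 65.38,
  FE = 55.845, SE = 78.971
)

element_mass <- function(element) {
  el <- toupper(element)
  el[el == "NA"] <- "NA."
  m <- ELEMENT_MASSES[el]
  unname(ifelse(is.na(m), 12.011, m))
}

# default residue names treated as solvent
SOLVENT_RESNAMES <- c("HOH", "TIP3", "WAT", "SOL")
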