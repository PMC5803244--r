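## Physical constants (CODATA) and atomic data used throughout.
## Units are fixed project-wide: depth cm, energy MeV, time s, sigma mbarn.

.const <- list(
  me_c2    = 0.51099895,     # electron rest energy, MeV
  mp_c2    = 938.27208816,   # proton rest energy, MeV
  K        = 0.307075,       # 4 pi NA re^2 me c^2, MeV cm^2 / mol
  Nav      = 6.02214076e23,  # Avogadro, 1/mol
  e_charge = 1.602176634e-19,# C
  alpha    = 7.2973525693e-3,# fine-structure constant
  barn     = 1e-24,          # cm^2
  mbarn    = 1e-27,          # cm^2
  # Bohr energy-straggling constant 4 pi NA re^2 (me c^2)^2, MeV^2 cm^2 / mol
  bohr     = 0.307075 * 0.51099895
)

## Z and standard atomic weight for the elements that appear in the targets.
.elements <- data.frame(
  symbol = c("H", "C", "N", "O", "Si"),
  Z      = c(1, 6, 7, 8, 14),
  A      = c(1.008, 12.011, 14.007, 15.999, 28.085),
  stringsAsFactors = FALSE
)

.elementZ <- function(sym) {
  i <- match(sym, .elements$symbol)
  if (anyNA(i)) stop("unknown element(s): ", paste(sym[is.na(i)], collapse = ", "))
  .elements$Z[i]
}
.elementA <- function(sym) {
  i <- match(sym, .elements$symbol)
  if (anyNA(i)) stop("unknown element(s): ", paste(sym[is.na(i)], collapse = ", "))
  .elements$A[i]
}

## Nuclear data for the beta+ emitters produced from oxygen (and 14O as an
## optional fast nuisance component).  Half-lives in s, endpoint kinetic
## energies in MeV, beta+ branching fractions.  Endpoints and branchings are
## standard evaluated nuclear data.
.isotopeData <- data.frame(
  isotope   = c("O15", "N13", "C11", "O14"),
  half_life = c(122.2, 597.9, 1222, 70.62),
  endpoint  = c(1.732, 1.199, 0.960, 1.808),
  branching = c(0.999, 0.998, 0.998, 0.994),
  stringsAsFactors = FALSE
)

#' Relativistic kinematics of a proton
#'
#' @param energy Proton kinetic energy in MeV.
#' @return List with `gamma`, `beta2` (\eqn{\beta^2}) and `beta2gamma2`.
#' @keywords internal
.protonKinematics <- function(energy) {
  gamma <- 1 + energy / .const$mp_c2
  beta2 <- 1 - 1 / gamma^2
  list(gamma = gamma, beta2 = beta2, beta2gamma2 = gamma^2 - 1)
}
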