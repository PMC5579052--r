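## Physical constants (CODATA 2018, exact where the SI redefinition makes them so)
## shared by the partition-function and kinetics code. Canonical internal units:
## kJ/mol (energy), cm^-1 (frequency), GHz (rotational constants), Angstrom^3
## (cluster volume), amu (mass), K (temperature), Pa (pressure).

.const <- list(
  h        = 6.62607015e-34,     # Planck, J s (exact)
  kB       = 1.380649e-23,       # Boltzmann, J/K (exact)
  N_A      = 6.02214076e23,      # Avogadro, 1/mol (exact)
  R        = 8.314462618,        # molar gas constant, J/(mol K)
  c_cm     = 2.99792458e10,      # speed of light, cm/s (exact)
  amu      = 1.66053906660e-27,  # atomic mass unit, kg
  hartree_kJ   = 2625.4996,      # kJ/mol per hartree
  hartree_kcal = 627.5095,       # kcal/mol per hartree
  kcal_kJ  = 4.184,              # kJ per kcal (thermochemical)
  atm_Pa   = 101325,             # Pa per atm (exact)
  bar_Pa   = 1e5,                # Pa per bar (exact)
  A3_L     = 1e-27               # litres per Angstrom^3
)

#' Physical constants used throughout the package
#'
#' Returns the CODATA 2018 constants and unit-conversion factors pinned by the
#' package (Planck and Boltzmann constants, Avogadro number, molar gas
#' constant, speed of light, atomic mass unit, hartree/kcal/kJ conversion
#' factors, pressure conversions). All thermodynamic and kinetic routines draw
#' from this single table.
#'
#' @return A named list of numeric constants (SI units unless the name says
#'   otherwise).
#' @examples
#' qce_constants()$R  # 8.314462618 J/(mol K)
#' @export
qce_constants <- function() .const

## log(sum(exp(x))) without overflow; -Inf-safe
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
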