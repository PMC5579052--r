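## Per-cluster partition functions in the rigid-rotor / harmonic-oscillator /
## electronic factorization. Everything is carried in log space: over the
## 150-700 K range a large cluster's q spans hundreds of orders of magnitude
## and the raw product would overflow immediately.

#' Thermal de Broglie wavelength
#'
#' Lambda = h / sqrt(2 pi m kB T).
#'
#' @param mass Particle mass in amu.
#' @param T Temperature in K.
#' @return Wavelength in Angstrom.
#' @examples
#' thermal_wavelength(18.0153, 298.15)  # 0.2382 A for water
#' @export
thermal_wavelength <- function(mass, T) {
  stopifnot(mass > 0, T > 0)
  m <- mass * .const$amu
  1e10 * .const$h / sqrt(2 * pi * m * .const$kB * T)
}

#' Translational partition function (log)
#'
#' ln q_trans = ln[(2 pi m kB T / h^2)^(3/2) V_free] = ln(V_free / Lambda^3).
#' The free volume is the exclusion-corrected system volume supplied by the
#' QCE solver.
#'
#' @param mass Cluster mass in amu.
#' @param T Temperature in K.
#' @param free_volume Free volume available to translation, litres per
#'   system.
#' @return ln q (dimensionless).
#' @export
q_translational <- function(mass, T, free_volume) {
  stopifnot(free_volume > 0)
  lambda_m <- thermal_wavelength(mass, T) * 1e-10
  log(free_volume * 1e-3) - 3 * log(lambda_m)   # V in m^3
}

#' Rigid-rotor rotational partition function (log)
#'
#' Classical nonlinear-top formula
#' ln q_rot = ln[(sqrt(pi)/sigma) sqrt(T^3 / (Theta_A Theta_B Theta_C))]
#' with Theta_X = h B_X / kB.
#'
#' @param rot_constants Three rotational constants in GHz.
#' @param sigma Rotational symmetry number (integer >= 1).
#' @param T Temperature in K.
#' @return ln q.
#' @examples
#' exp(q_rotational(c(835.8, 435.1, 278.4), 2, 298.15))  # ~ 43
#' @export
q_rotational <- function(rot_constants, sigma, T) {
  stopifnot(length(rot_constants) == 3L, all(rot_constants > 0),
            sigma >= 1, T > 0)
  theta <- .const$h * rot_constants * 1e9 / .const$kB   # K
  0.5 * log(pi) - log(sigma) + 0.5 * (3 * log(T) - sum(log(theta)))
}

#' Harmonic vibrational partition function (log)
#'
#' Product over modes of exp(-x_j/2) / (1 - exp(-x_j)) with
#' x_j = h c nu_j / kB T; the zero-point factor exp(-x_j/2) is included when
#' \code{include_zpe} is \code{TRUE} (the default, matching interaction
#' energies that are pure electronic, i.e. ZPE-exclusive).
#'
#' @param frequencies Harmonic wavenumbers in cm^-1, all > 0.
#' @param T Temperature in K.
#' @param include_zpe Include the zero-point-energy factor? Default
#'   \code{TRUE}.
#' @param scale Optional uniform frequency scaling factor (default 1).
#' @return ln q.
#' @export
q_vibrational <- function(frequencies, T, include_zpe = TRUE, scale = 1) {
  stopifnot(T > 0)
  if (!length(frequencies)) return(0)
  if (any(frequencies <= 0))
    stop("nonpositive frequency: vibrational partition function needs real minima")
  x <- .const$h * .const$c_cm * frequencies * scale / (.const$kB * T)
  lnq <- -log1p(-exp(-x))
  if (include_zpe) lnq <- lnq - x / 2
  sum(lnq)
}

#' Electronic partition function with mean-field correction (log)
#'
#' ln q_elec = -(dE_i - a_mf n_i / V_m) / (R T): the adiabatic interaction
#' energy of the cluster, lowered by the van der Waals mean-field attraction
#' a_mf per monomer at molar volume V_m.
#'
#' @param interaction_energy Adiabatic interaction energy dE_i, kJ/mol.
#' @param n_monomers Monomer count n_i of the cluster.
#' @param a_mf Mean-field attraction parameter, J L / mol^2 (>= 0).
#' @param molar_volume Molar volume of the system, L per mole of monomers.
#' @param T Temperature in K.
#' @return ln q.
#' @export
q_electronic <- function(interaction_energy, n_monomers, a_mf,
                         molar_volume, T) {
  stopifnot(molar_volume > 0, T > 0)
  e <- interaction_energy * 1e3 - a_mf * n_monomers / molar_volume  # J/mol
  -e / (.const$R * T)
}

#' Full partition function of one cluster (log terms)
#'
#' Assembles the translational, rotational, vibrational and electronic log
#' partition functions of a cluster; the total is their sum.
#'
#' @param cluster A \code{"qce_cluster"}.
#' @param monomer_mass Monomer mass in amu (cluster mass =
#'   \code{n_monomers * monomer_mass}).
#' @param T Temperature in K.
#' @param free_volume Free volume, litres per system.
#' @param molar_volume Molar volume, L per mole of monomers.
#' @param a_mf Mean-field attraction, J L / mol^2.
#' @param include_zpe,scale Passed to [q_vibrational()].
#' @return List of class \code{"qce_partition_terms"} with \code{ln_q_trans},
#'   \code{ln_q_rot}, \code{ln_q_vib}, \code{ln_q_elec} and their sum
#'   \code{ln_q_total}.
#' @export
ln_cluster_partition <- function(cluster, monomer_mass, T, free_volume,
                                 molar_volume, a_mf,
                                 include_zpe = TRUE, scale = 1) {
  lt <- q_translational(cluster$n_monomers * monomer_mass, T, free_volume)
  lr <- q_rotational(cluster$rotational_constants, cluster$symmetry_number, T)
  lv <- q_vibrational(cluster$frequencies, T, include_zpe = include_zpe,
                      scale = scale)
  le <- q_electronic(cluster$interaction_energy, cluster$n_monomers, a_mf,
                     molar_volume, T)
  structure(list(ln_q_trans = lt, ln_q_rot = lr, ln_q_vib = lv,
                 ln_q_elec = le, ln_q_total = lt + lr + lv + le),
            class = "qce_partition_terms")
}

#' @export
print.qce_partition_terms <- function(x, ...) {
  cat(sprintf(
    "ln q: trans %.4f + rot %.4f + vib %.4f + elec %.4f = %.4f\n",
    x$ln_q_trans, x$ln_q_rot, x$ln_q_vib, x$ln_q_elec, x$ln_q_total))
  invisible(x)
}
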