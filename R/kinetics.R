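## Standalone thermochemistry / kinetics utilities: energy-unit conversion,
## dG -> K, Eyring rates, and free-energy profiles over stationary points of
## a cluster reaction sequence. Everything that could overflow (K values of
## order 1e-285) is carried in log10 space.

.unit_to_kJ <- c("hartree" = 2625.4996, "kcal/mol" = 4.184, "kJ/mol" = 1)

#' Convert energies between hartree, kcal/mol and kJ/mol
#'
#' CODATA factors: 1 hartree = 627.5095 kcal/mol = 2625.4996 kJ/mol.
#'
#' @param value Numeric energy value(s).
#' @param from,to Units, each one of \code{"hartree"}, \code{"kcal/mol"},
#'   \code{"kJ/mol"}.
#' @return Converted value(s).
#' @examples
#' convert_energy(1, "hartree", "kcal/mol")  # 627.5095
#' @export
convert_energy <- function(value, from, to) {
  if (!from %in% names(.unit_to_kJ)) stop("unknown energy unit '", from, "'")
  if (!to %in% names(.unit_to_kJ)) stop("unknown energy unit '", to, "'")
  value * .unit_to_kJ[[from]] / .unit_to_kJ[[to]]
}

#' Equilibrium constant from a reaction free energy
#'
#' K = exp(-dG / RT), computed in log space: \code{pK = dG / (RT ln 10)} is
#' evaluated first so that reaction free energies of hundreds of kcal/mol
#' (pK of order 300) survive without underflow.
#'
#' @param dG Standard-state reaction free energy, kcal/mol (or \code{unit}).
#' @param T Temperature, K.
#' @param unit Unit of \code{dG} (default \code{"kcal/mol"}).
#' @return List with \code{K} (0 when it underflows a double) and \code{pK}
#'   (= -log10 K, always finite).
#' @examples
#' equilibrium_constant(389, 298.15)$pK  # 285.1: gas-phase water splitting
#' @export
equilibrium_constant <- function(dG, T, unit = "kcal/mol") {
  stopifnot(T > 0)
  dG_J <- convert_energy(dG, unit, "kJ/mol") * 1e3
  pK <- dG_J / (.const$R * T * log(10))
  list(K = 10^(-pK), pK = pK)
}

#' Eyring rate constant from an activation free energy
#'
#' k = (kB T / h) exp(-dG‡ / RT), transmission coefficient fixed at 1.
#'
#' @param dG_activation Activation free energy, kcal/mol (or \code{unit}).
#' @param T Temperature, K.
#' @param unit Unit of the barrier (default \code{"kcal/mol"}).
#' @return Rate constant in 1/s.
#' @examples
#' eyring_rate(0, 298.15)  # kB T / h = 6.2124e12 1/s
#' @export
eyring_rate <- function(dG_activation, T, unit = "kcal/mol") {
  stopifnot(T > 0)
  .const$kB * T / .const$h * equilibrium_constant(dG_activation, T, unit)$K
}

#' Enhancement between two equilibrium constants in orders of magnitude
#'
#' log10(K_num / K_den). With \code{log_space = TRUE} the inputs are taken
#' as pK values (negative decadic logs) and the result is
#' \code{pK_den - pK_num}, immune to underflow.
#'
#' @param K_num,K_den Equilibrium constants (> 0), or pK values when
#'   \code{log_space} is \code{TRUE}.
#' @param log_space Interpret inputs as pK values? Default \code{FALSE}.
#' @return Orders of magnitude, log10(K_num/K_den).
#' @examples
#' enhancement_orders(1e-14, 1e-285)        # 271
#' enhancement_orders(14, 285, log_space = TRUE)
#' @export
enhancement_orders <- function(K_num, K_den, log_space = FALSE) {
  if (log_space) return(K_den - K_num)
  if (K_num <= 0 || K_den <= 0)
    stop("equilibrium constants must be positive; use log_space = TRUE for pK inputs")
  log10(K_num) - log10(K_den)
}

#' Build a reaction free-energy profile from stationary points
#'
#' An ordered sequence of stationary points (minima and transition states)
#' along a cluster reaction pathway, each with electronic energy E and
#' standard-state Gibbs energy G0 in hartree.
#'
#' @param label Character vector of point labels, in pathway order.
#' @param E Electronic energies, hartree.
#' @param G0 Standard-state Gibbs energies, hartree.
#' @param kind \code{"minimum"} or \code{"transition_state"} per point
#'   (default all minima).
#' @return Object of class \code{"reaction_profile"}.
#' @seealso [reaction_barriers()], [read_reaction_profile()]
#' @export
reaction_profile <- function(label, E, G0,
                             kind = rep("minimum", length(label))) {
  stopifnot(length(label) >= 1L, length(E) == length(label),
            length(G0) == length(label), length(kind) == length(label),
            all(kind %in% c("minimum", "transition_state")))
  structure(data.frame(label = as.character(label), E = as.numeric(E),
                       G0 = as.numeric(G0), kind = as.character(kind)),
            class = c("reaction_profile", "data.frame"))
}

#' Read a reaction profile from CSV
#'
#' Expects columns \code{label}, \code{E_hartree}, \code{G0_hartree},
#' \code{kind}. The packaged file \code{w5_ionization_profile.csv} holds
#' the water-pentamer ionization pathway: the cyclic pentamer W5c, the
#' propellane-like bridged pentamer W5p, and the double-proton-transfer
#' transition state W5x leading to the ion-pair pentamer.
#'
#' @param path CSV path; default: the packaged pentamer profile.
#' @return A \code{"reaction_profile"}.
#' @export
read_reaction_profile <- function(path = system.file(
  "extdata", "w5_ionization_profile.csv", package = "qcewater")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "E_hartree", "G0_hartree", "kind")
  if (!all(need %in% names(df)))
    stop("profile CSV must have columns: ", paste(need, collapse = ", "))
  reaction_profile(df$label, df$E_hartree, df$G0_hartree, df$kind)
}

#' Step energetics of a reaction profile
#'
#' Successive differences of E and G0 along the pathway, converted to
#' kcal/mol, each step referenced to the preceding point; steps ending in a
#' transition state are activation barriers (dE‡, dG‡). Translation-
#' invariant: adding a constant to all energies changes nothing.
#'
#' @param profile A \code{"reaction_profile"} with at least two points.
#' @return Data frame with one row per step: \code{from}, \code{to},
#'   \code{dE_kcal}, \code{dG0_kcal}, \code{is_barrier}.
#' @examples
#' p <- read_reaction_profile()
#' reaction_barriers(p)  # the W5p -> W5x step is the ~19 kcal/mol barrier
#' @export
reaction_barriers <- function(profile) {
  stopifnot(inherits(profile, "reaction_profile"), nrow(profile) >= 2L)
  i <- seq_len(nrow(profile) - 1L)
  data.frame(
    from = profile$label[i], to = profile$label[i + 1L],
    dE_kcal = convert_energy(diff(profile$E), "hartree", "kcal/mol"),
    dG0_kcal = convert_energy(diff(profile$G0), "hartree", "kcal/mol"),
    is_barrier = profile$kind[i + 1L] == "transition_state")
}

#' @export
print.reaction_profile <- function(x, ...) {
  cat(sprintf("Reaction profile with %d stationary points:\n", nrow(x)))
  print.data.frame(x, row.names = FALSE)
  if (nrow(x) >= 2L) {
    cat("steps (kcal/mol):\n")
    print.data.frame(reaction_barriers(x), row.names = FALSE, digits = 4)
  }
  invisible(x)
}
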