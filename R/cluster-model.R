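## Cluster-set data model: the monomer, individual clusters, and validated
## collections of clusters sharing one monomer definition. These objects are
## the complete input of a QCE calculation.

#' Define the monomer a cluster set is built from
#'
#' @param label Short text label, e.g. \code{"H2O"}.
#' @param mass Molecular mass in amu (must be > 0).
#' @param molar_mass Molar mass in g/mol; defaults to the same number as
#'   \code{mass} (identical numerical value, different unit role).
#' @return An object of class \code{"qce_monomer"}.
#' @examples
#' water_monomer()
#' @export
monomer <- function(label, mass, molar_mass = mass) {
  stopifnot(is.character(label), length(label) == 1L)
  if (!is.numeric(mass) || length(mass) != 1L || mass <= 0)
    stop("monomer mass must be a single positive number (amu)")
  if (!is.numeric(molar_mass) || molar_mass <= 0)
    stop("molar_mass must be positive (g/mol)")
  structure(list(label = label, mass = as.numeric(mass),
                 molar_mass = as.numeric(molar_mass)),
            class = "qce_monomer")
}

#' The water monomer
#'
#' Convenience constructor for H2O (18.0153 amu).
#' @return A \code{"qce_monomer"}.
#' @export
water_monomer <- function() monomer("H2O", 18.0153)

#' Define one cluster record
#'
#' A cluster is the unit of all QCE input: its composition, adiabatic
#' interaction energy relative to separated monomers, harmonic frequencies,
#' rotational constants, symmetry number and volume. Net-neutral ion-pair
#' clusters carry equal hydronium and hydroxide counts.
#'
#' @param label Unique text label (e.g. \code{"W5c"}, \code{"W8ip"}).
#' @param n_monomers Number of monomer units (>= 1); for an ion-pair cluster
#'   this counts total water equivalents (H3O+ plus OH- count as two).
#' @param interaction_energy Adiabatic interaction energy in kJ/mol relative
#'   to \code{n_monomers} separated monomers; <= 0 for bound neutral clusters,
#'   may be > 0 for destabilized ion-pair isomers.
#' @param frequencies Harmonic wavenumbers in cm^-1, all > 0; a nonlinear
#'   cluster of n monomers (3n atoms each... for water, 3n atoms) must supply
#'   9n - 6 modes.
#' @param rotational_constants Three rotational constants in GHz, all > 0.
#' @param volume Cluster volume in Angstrom^3 (> 0).
#' @param n_hydronium,n_hydroxide Hydronium / hydroxide counts (>= 0; must be
#'   equal for net neutrality).
#' @param symmetry_number Rotational symmetry number sigma (integer >= 1,
#'   default 1).
#' @param geometry Optional data frame with columns \code{element}, \code{x},
#'   \code{y}, \code{z} (Angstrom).
#' @return An object of class \code{"qce_cluster"}.
#' @seealso [cluster_set()], [validate_cluster_set()]
#' @export
cluster <- function(label, n_monomers, interaction_energy, frequencies,
                    rotational_constants, volume,
                    n_hydronium = 0L, n_hydroxide = 0L,
                    symmetry_number = 1L, geometry = NULL) {
  structure(list(label = as.character(label),
                 n_monomers = as.integer(n_monomers),
                 n_hydronium = as.integer(n_hydronium),
                 n_hydroxide = as.integer(n_hydroxide),
                 interaction_energy = as.numeric(interaction_energy),
                 frequencies = as.numeric(frequencies),
                 rotational_constants = as.numeric(rotational_constants),
                 symmetry_number = as.integer(symmetry_number),
                 volume = as.numeric(volume),
                 geometry = geometry),
            class = "qce_cluster")
}

#' Assemble a validated cluster set
#'
#' @param monomer A \code{"qce_monomer"}.
#' @param clusters List of \code{"qce_cluster"} records. Exactly one must have
#'   \code{n_monomers == 1} and zero interaction energy; it is moved to the
#'   front.
#' @param name Name of the set.
#' @param check If \code{TRUE} (default), stop on any validation diagnostic.
#' @return An object of class \code{"qce_cluster_set"}.
#' @examples
#' cs <- toy_water_set()
#' validate_cluster_set(cs)
#' @export
cluster_set <- function(monomer, clusters, name = "cluster_set", check = TRUE) {
  stopifnot(inherits(monomer, "qce_monomer"), is.list(clusters))
  is1 <- vapply(clusters, function(cl) cl$n_monomers == 1L, logical(1))
  if (sum(is1) == 1L)  # monomer cluster first
    clusters <- c(clusters[is1], clusters[!is1])
  cs <- structure(list(monomer = monomer, clusters = clusters,
                       name = as.character(name)),
                  class = "qce_cluster_set")
  if (check) {
    d <- validate_cluster_set(cs)
    if (length(d)) stop("invalid cluster set:\n  ", paste(d, collapse = "\n  "))
  }
  cs
}

#' @export
print.qce_monomer <- function(x, ...) {
  cat(sprintf("QCE monomer '%s': %.4f amu\n", x$label, x$mass))
  invisible(x)
}

#' @export
print.qce_cluster <- function(x, ...) {
  ip <- if (x$n_hydronium > 0) sprintf(" [ion pair: %d H3O+ / %d OH-]",
                                       x$n_hydronium, x$n_hydroxide) else ""
  cat(sprintf("QCE cluster '%s': n = %d%s, dE = %.3f kJ/mol, %d modes, v = %.2f A^3\n",
              x$label, x$n_monomers, ip, x$interaction_energy,
              length(x$frequencies), x$volume))
  invisible(x)
}

#' @export
print.qce_cluster_set <- function(x, ...) {
  n_ip <- sum(vapply(x$clusters, function(cl) cl$n_hydronium > 0, logical(1)))
  cat(sprintf("QCE cluster set '%s': %d clusters (%d ion-pair), monomer %s\n",
              x$name, length(x$clusters), n_ip, x$monomer$label))
  df <- as.data.frame(x)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.qce_cluster_set <- function(x, ...) {
  data.frame(
    label = vapply(x$clusters, `[[`, character(1), "label"),
    n = vapply(x$clusters, `[[`, integer(1), "n_monomers"),
    n_h3o = vapply(x$clusters, `[[`, integer(1), "n_hydronium"),
    n_oh = vapply(x$clusters, `[[`, integer(1), "n_hydroxide"),
    energy_kJmol = vapply(x$clusters, `[[`, numeric(1), "interaction_energy"),
    modes = vapply(x$clusters, function(cl) length(cl$frequencies), integer(1)),
    sigma = vapply(x$clusters, `[[`, integer(1), "symmetry_number"),
    volume_A3 = vapply(x$clusters, `[[`, numeric(1), "volume"))
}

#' Validate a cluster set
#'
#' Checks every type invariant and returns diagnostics instead of raising:
#' monomer presence and uniqueness (exactly one cluster with one monomer and
#' zero interaction energy), unique labels, charge balance
#' (\code{n_hydronium == n_hydroxide}), positive frequencies (a negative value
#' signals a transition state supplied where a minimum is required), the
#' nonlinear mode count 9n - 6, three positive rotational constants, positive
#' volume and a symmetry number of at least 1.
#'
#' @param cs A \code{"qce_cluster_set"} (or a bare list with the same fields).
#' @return Character vector of diagnostics; empty iff the set is valid. Each
#'   entry names the offending cluster label and the violated invariant.
#' @export
validate_cluster_set <- function(cs) {
  out <- character(0)
  say <- function(...) out <<- c(out, sprintf(...))
  if (!is.list(cs$clusters) || !length(cs$clusters)) {
    return("cluster set has no clusters")
  }
  if (!is.numeric(cs$monomer$mass) || cs$monomer$mass <= 0)
    say("monomer: mass must be > 0 amu")
  labels <- vapply(cs$clusters, `[[`, character(1), "label")
  if (anyDuplicated(labels))
    say("duplicate labels: %s", paste(unique(labels[duplicated(labels)]), collapse = ", "))
  is1 <- vapply(cs$clusters, function(cl) cl$n_monomers == 1L, logical(1))
  if (sum(is1) != 1L) {
    say("expected exactly one monomer cluster (n_monomers == 1), found %d", sum(is1))
  } else if (abs(cs$clusters[[which(is1)]]$interaction_energy) > 1e-12) {
    say("%s: monomer cluster must have interaction_energy == 0", labels[which(is1)])
  }
  for (cl in cs$clusters) {
    lb <- cl$label
    if (cl$n_monomers < 1L) say("%s: n_monomers must be >= 1", lb)
    if (cl$n_hydronium < 0L || cl$n_hydroxide < 0L)
      say("%s: ion counts must be >= 0", lb)
    if (cl$n_hydronium != cl$n_hydroxide)
      say("%s: charge imbalance (n_hydronium %d != n_hydroxide %d); ion-pair clusters must be net neutral",
          lb, cl$n_hydronium, cl$n_hydroxide)
    if (any(cl$frequencies <= 0))
      say("%s: imaginary mode (frequency %.1f cm^-1 <= 0); minima only", lb,
          min(cl$frequencies))
    nexp <- 9L * cl$n_monomers - 6L
    if (length(cl$frequencies) != nexp)
      say("%s: expected %d modes (9n - 6 for a nonlinear cluster of %d waters), got %d",
          lb, nexp, cl$n_monomers, length(cl$frequencies))
    if (length(cl$rotational_constants) != 3L || any(cl$rotational_constants <= 0))
      say("%s: need three positive rotational constants (GHz); atomic or linear species are not supported",
          lb)
    if (!is.finite(cl$volume) || cl$volume <= 0) say("%s: volume must be > 0 A^3", lb)
    if (cl$symmetry_number < 1L) say("%s: symmetry number must be >= 1", lb)
  }
  out
}
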