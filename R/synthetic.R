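## Synthetic cluster sets. These emulate the shape of a real quantum-chemistry
## cluster set for water -- Grotthus-ordered neutral rings/chains of 1..N
## monomers plus net-neutral hydronium/hydroxide ion-pair isomers that are
## energetically destabilized relative to the neutral cluster of the same
## size -- without claiming to equal any published dataset.

## run expr with a private RNG stream; leaves the caller's RNG state untouched
with_local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

.water_rot_ghz <- c(835.8, 435.1, 278.4)    # water monomer A, B, C
.water_intra_cm <- c(1595, 3657, 3756)      # bend, sym stretch, asym stretch

## plausible 9n - 6 harmonic wavenumbers for a cluster of n waters:
## 6(n-1) low intermolecular modes + 3n intramolecular modes, jittered
.draw_frequencies <- function(n, ionic = FALSE) {
  inter <- if (n > 1L) sort(stats::runif(6L * (n - 1L), 35, 750)) else numeric(0)
  bends <- .water_intra_cm[1] + stats::rnorm(n, 20, 10)
  ## H-bonded OH stretches red-shift; ionic clusters shift further
  shift <- if (ionic) 280 else 150
  str1 <- .water_intra_cm[2] - shift + stats::rnorm(n, 0, 40)
  str2 <- .water_intra_cm[3] - shift / 2 + stats::rnorm(n, 0, 30)
  pmin(pmax(c(inter, bends, str1, str2), 30), 3800)
}

.draw_cluster <- function(label, n, energy, n_ion = 0L, ionic = FALSE) {
  rot <- .water_rot_ghz / n^(5 / 3) * (1 + stats::runif(3, -0.05, 0.05))
  cluster(label = label, n_monomers = n,
          n_hydronium = n_ion, n_hydroxide = n_ion,
          interaction_energy = energy,
          frequencies = .draw_frequencies(n, ionic = ionic),
          rotational_constants = rot,
          volume = n * 20 * (1 + stats::runif(1, -0.03, 0.03)))
}

#' Generate a synthetic water-like cluster set
#'
#' Produces a deterministic, seeded cluster set emulating a hydrogen-bonded
#' liquid: neutral clusters of 1..\code{max_size} monomers (chains for the
#' dimer, rings of n hydrogen bonds for n >= 3) with interaction energies of
#' about -25 kJ/mol per hydrogen bond, plausible harmonic frequencies (9n - 6
#' modes between 30 and 3800 cm^-1, with low-frequency intermolecular modes),
#' rotational constants decreasing with size, and volumes of about
#' 20 Angstrom^3 per monomer. For every size n >= 5 one net-neutral ion-pair
#' isomer (one hydronium, one hydroxide) is added whose interaction energy is
#' exactly the neutral isomer's plus \code{ip_destabilization}; sizes listed
#' in \code{extra_ip_sizes} receive a second ion-pair isomer (same energy
#' rule, independent spectroscopy), mirroring the coexistence of several
#' ion-pair motifs at the larger sizes in real water cluster sets.
#'
#' The generator is a pure function of its arguments: the same call always
#' returns the identical set and the caller's RNG state is left untouched.
#'
#' @param seed Integer seed.
#' @param max_size Largest neutral cluster (>= 2).
#' @param ip_destabilization Energy penalty of an ion-pair isomer relative to
#'   the neutral isomer of the same size, kJ/mol (>= 0). Default 80.
#' @param extra_ip_sizes Integer sizes receiving a second ion-pair isomer
#'   (default none).
#' @return A validated \code{"qce_cluster_set"}.
#' @seealso [synthetic_water_set()] for the packaged 18-cluster default,
#'   [toy_water_set()] for a minimal hand-curated fixture.
#' @export
synthetic_cluster_set <- function(seed, max_size, ip_destabilization = 80,
                                  extra_ip_sizes = integer(0)) {
  stopifnot(max_size >= 2, ip_destabilization >= 0)
  with_local_seed(seed, {
    clusters <- list()
    e_neutral <- numeric(max_size)
    for (n in seq_len(max_size)) {
      n_hb <- if (n == 1L) 0L else if (n == 2L) 1L else n
      e_hb <- 25 + stats::rnorm(1, 0, 1)
      e_neutral[n] <- if (n == 1L) 0 else -n_hb * e_hb
      clusters[[length(clusters) + 1L]] <-
        .draw_cluster(paste0("W", n), n, e_neutral[n])
    }
    for (n in seq_len(max_size)) {
      if (n < 5L) next
      clusters[[length(clusters) + 1L]] <-
        .draw_cluster(paste0("W", n, "ip"), n,
                      e_neutral[n] + ip_destabilization, n_ion = 1L, ionic = TRUE)
      if (n %in% extra_ip_sizes)
        clusters[[length(clusters) + 1L]] <-
          .draw_cluster(paste0("W", n, "ip2"), n,
                        e_neutral[n] + ip_destabilization, n_ion = 1L, ionic = TRUE)
    }
    cluster_set(water_monomer(), clusters,
                name = sprintf("synthetic_water_seed%d", seed))
  })
}

#' The packaged synthetic 18-cluster water fixture
#'
#' Neutral clusters of 1..10 waters, one ion-pair isomer per size 5..10, and
#' a second ion-pair isomer at sizes 8 and 10: 18 clusters, the composition
#' mix of a realistic ion-pair-extended QCE water set.
#'
#' @param seed Integer seed (default 1).
#' @param ip_destabilization Ion-pair energy penalty, kJ/mol (default 80).
#' @return A \code{"qce_cluster_set"} of 18 clusters.
#' @export
synthetic_water_set <- function(seed = 1, ip_destabilization = 80) {
  synthetic_cluster_set(seed, max_size = 10,
                        ip_destabilization = ip_destabilization,
                        extra_ip_sizes = c(8L, 10L))
}

#' Reference vdW parameters of the packaged synthetic fixture
#'
#' The (a_mf, b_xv) pair at which the default 18-cluster synthetic set
#' ([synthetic_water_set()] with seed 1) reproduces ambient liquid water to
#' within about 1 per cent in density (0.997 g/cm^3 at 298.15 K) and shows
#' its boiling transition at 1 atm within about 10 K of 373.15 K. Used as
#' the documented operating point for isobar examples and property checks.
#'
#' @return A \code{"qce_parameters"} with a_mf = 500 J L/mol^2 and
#'   b_xv = 1.43.
#' @export
synthetic_reference_parameters <- function() qce_parameters(500, 1.43)

#' A minimal hand-curated water cluster set
#'
#' Four clusters -- the monomer, a cyclic trimer, a cyclic pentamer and one
#' ion-pair pentamer -- with physically plausible hand-picked energies,
#' frequencies, rotational constants and volumes. Illustrative synthetic
#' values for examples and tests, not any published cluster data.
#'
#' @return A validated \code{"qce_cluster_set"} of 4 clusters.
#' @examples
#' cs <- toy_water_set()
#' validate_cluster_set(cs)  # character(0)
#' @export
toy_water_set <- function() {
  w1_geom <- data.frame(element = c("O", "H", "H"),
                        x = c(0, 0, 0),
                        y = c(0, 0.7572, -0.7572),
                        z = c(0.1173, -0.4692, -0.4692))
  w1 <- cluster("W1", 1L, 0,
                frequencies = .water_intra_cm,
                rotational_constants = .water_rot_ghz,
                symmetry_number = 2L, volume = 19.6, geometry = w1_geom)
  w3 <- cluster("W3c", 3L, -66.0,
                frequencies = c(168, 184, 201, 214, 332, 346, 421, 446,
                                519, 562, 621, 679,
                                1609, 1615, 1622, 3519, 3544, 3561,
                                3714, 3722, 3731),
                rotational_constants = c(6.72, 6.58, 3.41), volume = 58.4)
  w5 <- cluster("W5c", 5L, -151.0,
                frequencies = c(44, 58, 73, 92, 108, 126, 151, 178, 204, 228,
                                252, 279, 334, 362, 398, 437, 476, 512, 558,
                                604, 662, 721, 784, 842,
                                1611, 1618, 1627, 1638, 1652,
                                3302, 3348, 3397, 3441, 3488,
                                3694, 3701, 3709, 3716, 3724),
                rotational_constants = c(1.82, 1.71, 0.94), volume = 96.5)
  w5ip <- cluster("W5ip", 5L, -71.0, n_hydronium = 1L, n_hydroxide = 1L,
                  frequencies = c(51, 66, 84, 101, 119, 142, 167, 193, 221,
                                  247, 274, 309, 351, 389, 428, 472, 521, 574,
                                  633, 701, 778, 861, 952, 1049,
                                  1604, 1621, 1645, 1672, 1703,
                                  2855, 2988, 3124, 3266, 3371,
                                  3582, 3617, 3655, 3686, 3712),
                  rotational_constants = c(1.88, 1.76, 0.98), volume = 94.8)
  cluster_set(water_monomer(), list(w1, w3, w5, w5ip), name = "toy_water")
}
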