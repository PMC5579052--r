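## Temperature sweeps (isobars), phase-transition detection, monomer-
## normalized populations and the ionic product Kw. qce() is the central
## model-fitting-style entry point: it converges both phase branches at every
## grid temperature (warm-started along the grid), selects the minimum-Gibbs
## branch, and returns a classed object with the usual accessor methods.

#' Compute a QCE isobar
#'
#' Converges the cluster equilibria at every temperature of an ascending
#' grid at fixed pressure. Both initial branches (gas-like and liquid-like)
#' are attempted at every point, warm-started from the previous grid point
#' of the same branch; the converged branch of minimal Gibbs energy is
#' selected (ties go to the denser liquid-like branch). Branches that fail
#' to converge are dropped with a warning; a grid point where no branch
#' converges is an error naming the offending temperature.
#'
#' @param cluster_set A \code{"qce_cluster_set"}.
#' @param params A \code{"qce_parameters"}, or \code{NULL} to pass
#'   \code{a_mf}/\code{b_xv} directly.
#' @param T Ascending temperature grid, K (default 274 to 400 in 1 K steps).
#' @param p Pressure, Pa (default 1 atm).
#' @param a_mf,b_xv Parameter shortcut used when \code{params} is
#'   \code{NULL}.
#' @param include_zpe,scale Vibrational conventions, see [q_vibrational()].
#' @return Object of class \code{"qce"}: the per-temperature selected
#'   \code{"qce_state"} objects (\code{$states}), both branch states
#'   (\code{$branches}), the inputs, and the detected boiling temperature
#'   (see [transition_temperature()]). Methods: \code{print}, \code{summary},
#'   \code{coef}, \code{predict}, \code{plot}, \code{as.data.frame}.
#' @examples
#' \donttest{
#' cs <- synthetic_water_set(seed = 1)
#' iso <- qce(cs, a_mf = 1.3, b_xv = 1.2, T = seq(290, 310, 5))
#' summary(iso)
#' }
#' @export
qce <- function(cluster_set, params = NULL, T = seq(274, 400, by = 1),
                p = 101325, a_mf = NULL, b_xv = NULL,
                include_zpe = TRUE, scale = 1) {
  stopifnot(inherits(cluster_set, "qce_cluster_set"))
  if (is.null(params)) {
    if (is.null(a_mf) || is.null(b_xv))
      stop("supply either params or both a_mf and b_xv")
    params <- qce_parameters(a_mf, b_xv)
  }
  if (is.unsorted(T, strictly = TRUE)) stop("T grid must be strictly ascending")
  states <- vector("list", length(T))
  branches <- vector("list", length(T))
  warm_g <- NULL; warm_l <- NULL
  for (i in seq_along(T)) {
    br <- tryCatch(
      .solve_branches(cluster_set, params, T[i], p,
                      warm_gas = warm_g, warm_liquid = warm_l,
                      include_zpe = include_zpe, scale = scale),
      error = function(e)
        stop(sprintf("isobar failed at T = %.2f K: %s", T[i],
                     conditionMessage(e)), call. = FALSE))
    states[[i]] <- br$state
    branches[[i]] <- br
    if (!is.null(br$gas) && br$gas$converged) warm_g <- br$gas
    if (!is.null(br$liquid) && br$liquid$converged) warm_l <- br$liquid
  }
  out <- structure(list(cluster_set = cluster_set, params = params,
                        T = T, p = p, states = states, branches = branches,
                        include_zpe = include_zpe, scale = scale,
                        transition_temperature = NA_real_,
                        call = match.call()),
                   class = "qce")
  out$transition_temperature <- transition_temperature(out)
  out
}

#' Boiling (phase-transition) temperature of an isobar
#'
#' Finds the largest relative jump in molar volume between adjacent grid
#' points; if it exceeds \code{min_jump} (default 50\%), the transition
#' temperature is refined by bisection on the gas/liquid Gibbs-energy
#' crossing between the bracketing grid points until the bracket is at most
#' \code{tol} K wide. Returns \code{NA} when no jump qualifies (a valid
#' result for a supercritical or single-phase sweep). If two jumps of equal
#' size occur, the lower-temperature one is taken with a warning.
#'
#' @param isobar A \code{"qce"} object with at least two grid points.
#' @param min_jump Minimal relative volume jump to count as a transition
#'   (default 0.5).
#' @param tol Bracket width for the bisection refinement, K (default 0.01).
#' @return Transition temperature in K, or \code{NA_real_}.
#' @export
transition_temperature <- function(isobar, min_jump = 0.5, tol = 0.01) {
  stopifnot(inherits(isobar, "qce"))
  Tg <- isobar$T
  if (length(Tg) < 2L) return(NA_real_)
  V <- vapply(isobar$states, `[[`, numeric(1), "molar_volume")
  jump <- abs(diff(V)) / pmin(V[-length(V)], V[-1])
  if (max(jump) < min_jump) return(NA_real_)
  best <- which(jump == max(jump))
  if (length(best) > 1L) {
    warning("two equal volume jumps; taking the lower-temperature one")
    best <- best[1L]
  }
  lo <- Tg[best]; hi <- Tg[best + 1L]
  st_lo <- isobar$branches[[best]]
  st_hi <- isobar$branches[[best + 1L]]
  warm_l <- if (!is.null(st_lo$liquid) && st_lo$liquid$converged)
    st_lo$liquid else st_lo$state
  warm_g <- if (!is.null(st_hi$gas) && st_hi$gas$converged)
    st_hi$gas else st_hi$state
  ## gas G - liquid G: positive while the liquid is stable, negative above
  sgn <- function(Tm) {
    br <- tryCatch(
      .solve_branches(isobar$cluster_set, isobar$params, Tm, isobar$p,
                      warm_gas = warm_g, warm_liquid = warm_l,
                      include_zpe = isobar$include_zpe, scale = isobar$scale),
      error = function(e) NULL)
    if (is.null(br)) return(NA_real_)
    gg <- if (!is.null(br$gas) && br$gas$converged) br$gas$gibbs_energy else Inf
    gl <- if (!is.null(br$liquid) && br$liquid$converged)
      br$liquid$gibbs_energy else Inf
    if (!is.finite(gg) && !is.finite(gl)) return(NA_real_)
    ## branches merged onto one fixed point: no distinct liquid phase here
    if (is.finite(gg) && is.finite(gl) &&
        abs(br$gas$molar_volume - br$liquid$molar_volume) /
          min(br$gas$molar_volume, br$liquid$molar_volume) < 0.01)
      return(-1e-12)
    gg - gl
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    s <- sgn(mid)
    if (is.na(s)) break
    if (s > 0) lo <- mid else hi <- mid    # liquid still stable -> move up
  }
  (lo + hi) / 2
}

#' Monomer-normalized cluster populations
#'
#' The fraction of all monomer units bound in each cluster,
#' pop_i = n_i N_i / sum_j n_j N_j; sums to one and is invariant under
#' rescaling of the total monomer amount.
#'
#' @param state A \code{"qce_state"}.
#' @return Named numeric vector summing to 1.
#' @export
monomer_normalized_populations <- function(state) {
  stopifnot(inherits(state, "qce_state"))
  w <- state$n_monomers * state$populations
  w / sum(w)
}

#' Ionic product of one converged state
#'
#' Implements the diagonal ionic-cluster sum
#' \code{Kw = sum_i n_i(H3O+) n_i(OH-) N_i^2 / V^2} with N_i in moles of
#' cluster per mole of monomer and V the molar volume in L per mole of
#' monomer, yielding mol^2/L^2 directly; pKw = -log10(Kw). The sum runs in
#' log space, so ion-pair populations far below 1e-154 (whose square would
#' underflow) still give finite pKw. With \code{mode = "product"} the
#' physically conventional concentration product
#' \code{(sum_i n_i(H3O+) N_i / V) (sum_i n_i(OH-) N_i / V)} is returned
#' instead; with exactly one populated ion-pair cluster the two coincide.
#'
#' @param state A \code{"qce_state"}.
#' @param mode \code{"diagonal"} (default) or \code{"product"}.
#' @return List of class \code{"qce_kw"} with \code{T} (K), \code{Kw}
#'   (mol^2/L^2; 0 if the set has no ion-pair clusters) and \code{pKw}
#'   (\code{Inf} when Kw is 0).
#' @export
ion_product <- function(state, mode = c("diagonal", "product")) {
  mode <- match.arg(mode)
  stopifnot(inherits(state, "qce_state"))
  nh <- state$n_hydronium; noh <- state$n_hydroxide
  ip <- nh > 0 & noh > 0
  lnV <- log(state$molar_volume)
  if (!any(ip)) {
    ln_kw <- -Inf
  } else if (mode == "diagonal") {
    ln_kw <- logsumexp(log(nh[ip] * noh[ip]) +
                         2 * state$ln_populations[ip]) - 2 * lnV
  } else {
    ln_kw <- logsumexp(log(nh[ip]) + state$ln_populations[ip]) +
      logsumexp(log(noh[ip]) + state$ln_populations[ip]) - 2 * lnV
  }
  structure(list(T = state$T, Kw = exp(ln_kw),
                 pKw = if (is.finite(ln_kw)) -ln_kw / log(10) else Inf),
            class = "qce_kw")
}

#' @export
print.qce_kw <- function(x, ...) {
  cat(sprintf("Kw(%.2f K) = %.4g mol^2/L^2  (pKw = %.4f)\n",
              x$T, x$Kw, x$pKw))
  invisible(x)
}

#' Ionic-product curve along an isobar
#'
#' One [ion_product()] evaluation per grid temperature.
#'
#' @param isobar A \code{"qce"} object.
#' @param mode Passed to [ion_product()].
#' @return Data frame with columns \code{T}, \code{Kw}, \code{pKw}.
#' @seealso [pkw_experimental_reference()] for the packaged experimental
#'   comparison points.
#' @export
kw_curve <- function(isobar, mode = c("diagonal", "product")) {
  mode <- match.arg(mode)
  stopifnot(inherits(isobar, "qce"))
  pts <- lapply(isobar$states, ion_product, mode = mode)
  data.frame(T = vapply(pts, `[[`, numeric(1), "T"),
             Kw = vapply(pts, `[[`, numeric(1), "Kw"),
             pKw = vapply(pts, `[[`, numeric(1), "pKw"))
}

#' Experimental pKw reference points
#'
#' The two experimental ionic-product reference values packaged for
#' comparison plots: pKw = 14.93 at 274 K and 11.98 at 373 K.
#'
#' @return Data frame with columns \code{T} and \code{pKw}.
#' @export
pkw_experimental_reference <- function() {
  data.frame(T = c(274, 373), pKw = c(14.93, 11.98))
}
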