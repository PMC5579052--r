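## Self-consistent solution of the simultaneous cluster equilibria at fixed
## (T, p, total monomer amount). The system basis is one mole of monomer:
## V is the molar volume in litres, cluster amounts N_i are in moles of
## cluster per mole of monomer (particle counts N_i * N_Avogadro enter the
## Stirling terms). All population algebra is done in log space.

#' Empirical van der Waals parameters of the QCE model
#'
#' @param a_mf Mean-field attraction per monomer, J L / mol^2 (>= 0).
#' @param b_xv Exclusion-volume scale, dimensionless (> 0); the fraction of
#'   the summed cluster volumes removed from the translational free volume.
#' @return Object of class \code{"qce_parameters"}.
#' @examples
#' qce_parameters(1.5, 1.2)
#' @export
qce_parameters <- function(a_mf, b_xv) {
  stopifnot(is.numeric(a_mf), length(a_mf) == 1L, a_mf >= 0,
            is.numeric(b_xv), length(b_xv) == 1L, b_xv > 0)
  structure(list(a_mf = as.numeric(a_mf), b_xv = as.numeric(b_xv)),
            class = "qce_parameters")
}

#' @export
print.qce_parameters <- function(x, ...) {
  cat(sprintf("QCE parameters: a_mf = %.6g J L/mol^2, b_xv = %.6g\n",
              x$a_mf, x$b_xv))
  invisible(x)
}

#' Solve the cluster mass-action equations for the populations
#'
#' Given log partition functions ln q_i and monomer counts n_i (the monomer
#' itself must be present with n = 1), finds the unique populations
#' satisfying the simultaneous equilibria
#' \code{ln N_i = ln q_i + n_i (ln N_1 - ln q_1)} under the mass constraint
#' \code{sum(n_i N_i) = N_total}. The constraint is strictly increasing in
#' N_1, so the root in ln N_1 is unique; it is located by bracketing plus
#' safeguarded Newton iteration entirely in log space.
#'
#' @param ln_q Numeric vector of log partition functions.
#' @param n Integer vector of monomer counts (same length; must contain a 1).
#' @param N_total Total monomer amount (same unit as the returned N_i).
#' @return List with \code{populations} (N_i), \code{ln_populations} and
#'   \code{ln_N1}; the mass-constraint residual is at most 1e-12 relative.
#' @export
solve_populations <- function(ln_q, n, N_total) {
  stopifnot(length(ln_q) == length(n), N_total > 0, all(n >= 1))
  i1 <- match(1L, n)
  if (is.na(i1)) stop("monomer (n = 1) missing from the cluster set")
  a <- log(n) + ln_q - n * ln_q[i1]       # term_i(x) = a_i + n_i x
  lnNt <- log(N_total)
  g <- function(x) logsumexp(a + n * x) - lnNt
  hi <- lnNt                               # monomer term alone reaches N_total
  lo <- hi - 50
  it <- 0L
  while (g(lo) > 0) {
    lo <- lo - 100
    it <- it + 1L
    if (it > 1000L) stop("no bracket found for ln N_1; pathological q values")
  }
  x <- (lo + hi) / 2
  for (k in 1:200) {
    t <- a + n * x
    m <- max(t)
    w <- exp(t - m)
    fx <- m + log(sum(w)) - lnNt
    if (fx > 0) hi <- x else lo <- x
    dx <- fx / (sum(w * n) / sum(w))       # Newton step; f' = <n>_weighted
    xn <- x - dx
    if (!is.finite(xn) || xn <= lo || xn >= hi) xn <- (lo + hi) / 2
    if (abs(xn - x) < 1e-15 * max(1, abs(x)) && abs(fx) < 1e-13) {
      x <- xn; break
    }
    x <- xn
  }
  ln_N <- ln_q + n * (x - ln_q[i1])
  ln_N[i1] <- x                            # exact identity for the monomer
  list(populations = exp(ln_N), ln_populations = ln_N, ln_N1 = x)
}

## exclusion volume in litres for populations in moles of cluster
.v_excl <- function(populations, volumes_A3, b_xv) {
  b_xv * sum(populations * volumes_A3) * .const$N_A * .const$A3_L
}

#' Admissible volume roots of the QCE equation of state
#'
#' Solves the cubic
#' \code{p V^2 (V - V_ex) - R T (sum N_i) V^2 + a_mf N_mono V
#'  - a_mf N_mono V_ex = 0}
#' (pressure converted to J/L, volumes in litres) where
#' \code{V_ex = b_xv sum(N_i v_i)} is the exclusion volume and
#' \code{N_mono = sum(n_i N_i)}; this is the vdW-type isotherm
#' \code{p = R T sum(N_i)/(V - V_ex) - a_mf N_mono / V^2}. Real positive
#' roots with \code{V > V_ex} are returned in increasing order.
#'
#' @param populations Cluster amounts N_i, moles per mole of monomer.
#' @param clusters List of \code{"qce_cluster"} records (for n_i and v_i),
#'   or a list with elements \code{n} and \code{volume_A3}.
#' @param params A \code{"qce_parameters"}.
#' @param T Temperature, K.
#' @param p Pressure, Pa.
#' @return Numeric vector of admissible volumes (L per mole of monomer).
#' @export
volume_roots <- function(populations, clusters, params, T, p) {
  stopifnot(T > 0, p > 0)
  if (!is.null(clusters$n)) {
    n <- clusters$n; v <- clusters$volume_A3
  } else {
    n <- vapply(clusters, `[[`, integer(1), "n_monomers")
    v <- vapply(clusters, `[[`, numeric(1), "volume")
  }
  v_ex <- .v_excl(populations, v, params$b_xv)
  n_c <- sum(populations)
  n_mono <- sum(n * populations)
  p_jl <- p * 1e-3                         # Pa -> J/L
  rt <- .const$R * T
  ## coefficients, ascending powers of V
  co <- c(-params$a_mf * n_mono * v_ex,
          params$a_mf * n_mono,
          -(p_jl * v_ex + rt * n_c),
          p_jl)
  z <- polyroot(co)
  re <- Re(z)
  ok <- abs(Im(z)) < 1e-8 * pmax(1, abs(re)) & re > v_ex & re > 0
  roots <- sort(re[ok])
  if (!length(roots))
    stop(sprintf("no admissible volume root (T = %.2f K, V_ex = %.4g L)",
                 T, v_ex))
  roots
}

## Helmholtz and Gibbs energy (kJ per mole of monomer) of a population/volume
## state; Stirling approximation with particle counts N_i * N_A.
.state_energies <- function(ln_q, ln_N_mol, T, p, V) {
  ln_N_part <- ln_N_mol + log(.const$N_A)
  terms <- exp(ln_N_mol) * (ln_q - ln_N_part + 1)
  A <- -.const$R * T * sum(terms) * 1e-3           # kJ
  G <- A + p * 1e-3 * V * 1e-3                     # p[J/L] * V[L] -> kJ
  c(helmholtz = A, gibbs = G)
}

#' Converge one QCE state at fixed temperature and pressure
#'
#' Fixed-point iteration between populations and volume: given a volume,
#' build the partition functions (free volume V - V_ex, mean-field term
#' a_mf/V), solve the mass-action system with [solve_populations()],
#' re-solve the equation-of-state cubic with [volume_roots()] (taking the
#' admissible root closest to the current volume), and update the volume
#' with damping until the relative changes in V and ln N_1 fall below
#' \code{tol} or \code{max_iter} is reached.
#'
#' @param cs A \code{"qce_cluster_set"}.
#' @param params A \code{"qce_parameters"}.
#' @param T Temperature, K.
#' @param p Pressure, Pa.
#' @param init Initial branch: \code{"gas"} (V = RT/p), \code{"liquid"}
#'   (1.1 x the b_xv-scaled packed volume of one mole of monomers), a
#'   numeric volume in L, or a previously converged \code{"qce_state"}
#'   (warm start; also reuses its populations and phase label).
#' @param damping Damping factor on volume updates in (0, 1]; default 0.5.
#' @param tol Relative convergence threshold; default 1e-10.
#' @param max_iter Iteration cap; default 500.
#' @param include_zpe,scale Vibrational conventions, see [q_vibrational()].
#' @return Object of class \code{"qce_state"}: temperature, pressure, molar
#'   volume (L per mole monomer), populations and their logs (moles of
#'   cluster per mole of monomer), exclusion volume, per-cluster ln q,
#'   phase label, Helmholtz and Gibbs energies (kJ per mole monomer),
#'   convergence flag, iteration count and final residuals. Non-convergence
#'   is reported with a warning carrying the last residuals, never silently.
#' @export
converge_state <- function(cs, params, T, p, init = "gas",
                           damping = 0.5, tol = 1e-10, max_iter = 500L,
                           include_zpe = TRUE, scale = 1) {
  stopifnot(inherits(params, "qce_parameters"), T > 0, p > 0,
            damping > 0, damping <= 1)
  cl <- cs$clusters
  labels <- vapply(cl, `[[`, character(1), "label")
  n <- vapply(cl, `[[`, integer(1), "n_monomers")
  v <- vapply(cl, `[[`, numeric(1), "volume")
  mass_mono <- cs$monomer$mass
  i1 <- match(1L, n)
  ## V-independent log-q pieces, computed once per (T, conventions)
  ln_q_rv <- vapply(cl, function(ci)
    q_rotational(ci$rotational_constants, ci$symmetry_number, T) +
      q_vibrational(ci$frequencies, T, include_zpe = include_zpe,
                    scale = scale),
    numeric(1))
  dE <- vapply(cl, `[[`, numeric(1), "interaction_energy")
  ## 3/2 ln(2 pi m kB T / h^2) per cluster, so trans = this + ln(V_free m^3)
  ln_trans0 <- vapply(n * mass_mono, function(m)
    -3 * log(thermal_wavelength(m, T) * 1e-10), numeric(1))

  N <- rep(0, length(cl)); N[i1] <- 1              # start: all monomer
  phase <- NULL
  if (inherits(init, "qce_state")) {
    V <- init$molar_volume
    N <- init$populations
    phase <- init$phase
  } else if (identical(init, "gas")) {
    V <- .const$R * T / (p * 1e-3)                 # RT/p in litres
    phase <- "gas-like"
  } else if (identical(init, "liquid")) {
    V <- 1.1 * max(params$b_xv, 1) * v[i1] * .const$N_A * .const$A3_L
    phase <- "liquid-like"
  } else if (is.numeric(init) && init > 0) {
    V <- as.numeric(init)
    phase <- "custom"
  } else stop("init must be 'gas', 'liquid', a positive volume, or a qce_state")

  ln_N <- log(N)
  ln_q <- NULL
  conv <- FALSE; iters <- 0L
  dV_rel <- NA_real_; dN1 <- NA_real_
  for (k in seq_len(max_iter)) {
    iters <- k
    v_ex <- .v_excl(N, v, params$b_xv)
    v_free <- V - v_ex
    if (v_free <= 0) v_free <- 1e-6 * V            # recoverable mid-iteration
    ln_q <- ln_trans0 + log(v_free * 1e-3) + ln_q_rv +
      vapply(seq_along(cl), function(i)
        q_electronic(dE[i], n[i], params$a_mf, V, T), numeric(1))
    sol <- solve_populations(ln_q, n, .const$N_A)
    ln_N_new <- sol$ln_populations - log(.const$N_A)  # particles -> mol
    N_new <- exp(ln_N_new)
    roots <- volume_roots(N_new, list(n = n, volume_A3 = v), params, T, p)
    V_root <- roots[which.min(abs(roots - V))]
    V_new <- (1 - damping) * V + damping * V_root
    dV_rel <- abs(V_new - V) / V
    dN1 <- abs(ln_N_new[i1] - ln_N[i1]) / max(1, abs(ln_N_new[i1]))
    V <- V_new; N <- N_new; ln_N <- ln_N_new
    if (dV_rel <= tol && dN1 <= tol) { conv <- TRUE; break }
  }
  if (!conv)
    warning(sprintf(
      "QCE state not converged at T = %.2f K (branch %s): |dV|/V = %.2e, |d lnN1| = %.2e after %d iterations",
      T, phase, dV_rel, dN1, iters))
  en <- .state_energies(ln_q, ln_N, T, p, V)
  structure(list(T = T, p = p, molar_volume = V,
                 populations = stats::setNames(N, labels),
                 ln_populations = stats::setNames(ln_N, labels),
                 n_monomers = stats::setNames(n, labels),
                 n_hydronium = stats::setNames(
                   vapply(cl, `[[`, integer(1), "n_hydronium"), labels),
                 n_hydroxide = stats::setNames(
                   vapply(cl, `[[`, integer(1), "n_hydroxide"), labels),
                 exclusion_volume = .v_excl(N, v, params$b_xv),
                 ln_q = stats::setNames(ln_q, labels),
                 phase = phase,
                 helmholtz_energy = unname(en["helmholtz"]),
                 gibbs_energy = unname(en["gibbs"]),
                 converged = conv, iterations = iters,
                 residuals = c(dV_rel = dV_rel, d_lnN1 = dN1)),
            class = "qce_state")
}

#' Helmholtz and Gibbs energy of a converged state
#'
#' Accessors for the energies stored on a \code{"qce_state"}:
#' A = -RT sum_i N_i (ln q_i - ln(N_i N_A) + 1) by Stirling's approximation
#' (amounts as particle counts), G = A + pV, both per mole of monomer.
#'
#' @param state A \code{"qce_state"}.
#' @return Energy in kJ per mole of monomer.
#' @export
gibbs_energy <- function(state) {
  stopifnot(inherits(state, "qce_state"))
  state$gibbs_energy
}

#' @rdname gibbs_energy
#' @export
helmholtz_energy <- function(state) {
  stopifnot(inherits(state, "qce_state"))
  state$helmholtz_energy
}

#' @export
print.qce_state <- function(x, ...) {
  cat(sprintf("QCE state at T = %.2f K, p = %.4g Pa [%s]%s\n",
              x$T, x$p, x$phase,
              if (x$converged) "" else "  ** NOT CONVERGED **"))
  cat(sprintf("  molar volume %.6g L/mol (V_ex %.4g L), G = %.4f kJ/mol, A = %.4f kJ/mol\n",
              x$molar_volume, x$exclusion_volume, x$gibbs_energy,
              x$helmholtz_energy))
  cat(sprintf("  mass balance: sum n_i N_i = %.12f; %d iterations\n",
              sum(x$n_monomers * x$populations), x$iterations))
  invisible(x)
}

## run both initial branches; returns list(gas=, liquid=) of states (possibly
## unconverged), plus the min-G converged selection (ties -> liquid, logged)
.solve_branches <- function(cs, params, T, p, warm_gas = NULL,
                            warm_liquid = NULL, ...) {
  run <- function(init, fallback) {
    st <- withCallingHandlers(
      tryCatch(converge_state(cs, params, T, p, init = init, ...),
               error = function(e) NULL),
      warning = function(w) invokeRestart("muffleWarning"))
    if ((is.null(st) || !st$converged) && !identical(init, fallback))
      st <- tryCatch(suppressWarnings(
        converge_state(cs, params, T, p, init = fallback, ...)),
        error = function(e) st)
    st
  }
  gas <- run(if (!is.null(warm_gas)) warm_gas else "gas", "gas")
  liq <- run(if (!is.null(warm_liquid)) warm_liquid else "liquid", "liquid")
  if (!is.null(gas)) gas$phase <- "gas-like"
  if (!is.null(liq)) liq$phase <- "liquid-like"
  gv <- if (!is.null(gas) && gas$converged) gas$gibbs_energy else Inf
  lv <- if (!is.null(liq) && liq$converged) liq$gibbs_energy else Inf
  if (!is.finite(gv) && !is.finite(lv))
    stop(sprintf("no branch converged at T = %.2f K", T))
  ## tie-break at equal G (within the solver's convergence resolution):
  ## the denser liquid-like branch
  sel <- if (lv <= gv + 1e-9 * max(1, abs(lv))) liq else gas
  list(gas = gas, liquid = liq, state = sel)
}
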