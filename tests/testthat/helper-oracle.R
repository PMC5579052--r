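# Independent brute-force oracle for the cluster population equations:
# dense scan over ln N_1 with successive grid refinement (no Newton steps,
# no shared code with solve_populations).
oracle_populations <- function(ln_q, n, N_total) {
  i1 <- match(1, n)
  f <- function(x) sum(n * exp(ln_q + n * (x - ln_q[i1]))) - N_total
  lo <- log(N_total) - 300
  hi <- log(N_total)
  while (hi - lo > 1e-12) {
    xs <- seq(lo, hi, length.out = 1001L)
    fs <- vapply(xs, f, numeric(1))
    k <- which(fs > 0)[1L]
    if (is.na(k) || k == 1L) break
    lo <- xs[k - 1L]
    hi <- xs[k]
  }
  x <- (lo + hi) / 2
  N <- exp(ln_q + n * (x - ln_q[i1]))
  N[i1] <- exp(x)
  N
}

# monomer-only cluster set (ideal-gas reference system)
monomer_only_set <- function() {
  cluster_set(water_monomer(),
              list(cluster("W1", 1L, 0,
                           frequencies = c(1595, 3657, 3756),
                           rotational_constants = c(835.8, 435.1, 278.4),
                           symmetry_number = 2L, volume = 19.6)),
              name = "monomer_only")
}

# near-zero exclusion volume: the ideal-gas limit of the vdW parameters
# (the b_xv > 0 invariant forbids exactly zero)
ideal_params <- function() qce_parameters(0, 1e-12)
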