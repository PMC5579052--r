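test_that("population solver: closed-form and brute-force agreement", {
  ## monomer only
  s <- solve_populations(ln_q = 5, n = 1L, N_total = 3.7)
  expect_equal(s$populations, 3.7, tolerance = 1e-12)

  ## monomer + dimer with K = q2/q1^2 = 1, N_total = 1:
  ## N1 + 2 N1^2 = 1  =>  N1 = 1/2, N2 = N1^2 = 1/4
  s <- solve_populations(ln_q = c(0, 0), n = c(1L, 2L), N_total = 1)
  expect_equal(s$populations, c(0.5, 0.25), tolerance = 1e-11)
  expect_equal(oracle_populations(c(0, 0), c(1L, 2L), 1), c(0.5, 0.25),
               tolerance = 1e-9)

  ## random 2- and 3-cluster systems against the dense-scan oracle
  set.seed(42)
  for (k in 1:10) {
    m <- sample(2:3, 1)
    n <- c(1L, sort(sample(2:8, m - 1L)))
    ln_q <- c(0, rnorm(m - 1L, 0, 5))
    Nt <- runif(1, 0.5, 2)
    got <- solve_populations(ln_q, n, Nt)$populations
    want <- oracle_populations(ln_q, n, Nt)
    expect_equal(got, want, tolerance = 1e-9)
    expect_equal(sum(n * got), Nt, tolerance = 1e-12)
  }
})

test_that("volume cubic: ideal-gas and excluded-volume limits, residuals", {
  mono <- list(n = 1L, volume_A3 = 19.6)
  ## a_mf = 0, b_xv -> 0: V = RT/p = 24.4654 L/mol at 298.15 K, 1 atm
  r <- volume_roots(1, mono, ideal_params(), 298.15, 101325)
  expect_equal(r, 24.4654, tolerance = 1e-5)

  ## a_mf = 0, b_xv > 0: V = RT sum(N)/p + V_ex exactly
  co <- qce_constants()
  pars <- qce_parameters(0, 1.3)
  N <- c(0.4, 0.1)
  sys <- list(n = c(1L, 3L), volume_A3 = c(19.6, 61))
  v_ex <- 1.3 * sum(N * sys$volume_A3) * co$N_A * 1e-27
  r <- volume_roots(N, sys, pars, 310, 101325)
  expect_equal(max(r), co$R * 310 * sum(N) / (101325e-3) + v_ex,
               tolerance = 1e-10)

  ## generic parameters: every root satisfies the cubic
  pars <- qce_parameters(300, 1.2)
  N <- c(0.05, 0.03, 0.02)
  sys <- list(n = c(1L, 4L, 9L), volume_A3 = c(19.6, 80, 180))
  v_ex <- 1.2 * sum(N * sys$volume_A3) * co$N_A * 1e-27
  roots <- volume_roots(N, sys, pars, 298.15, 101325)
  p_jl <- 101325e-3
  n_mono <- sum(sys$n * N)
  for (V in roots) {
    res <- p_jl * V^2 * (V - v_ex) - co$R * 298.15 * sum(N) * V^2 +
      pars$a_mf * n_mono * V - pars$a_mf * n_mono * v_ex
    expect_lt(abs(res), 1e-8 * p_jl * V^3)
    expect_gt(V, v_ex)
  }
})

test_that("converged monomer-only state is an exact ideal gas", {
  cs <- monomer_only_set()
  co <- qce_constants()
  for (T in c(200, 298.15, 500)) {
    st <- converge_state(cs, ideal_params(), T, 101325, init = "gas")
    expect_true(st$converged)
    expect_lt(abs(101325e-3 * st$molar_volume / (co$R * T) - 1), 1e-10)
  }
})

test_that("fixed points re-enter in at most two iterations and conserve mass", {
  cs <- synthetic_cluster_set(seed = 2, max_size = 6, ip_destabilization = 70)
  pars <- synthetic_reference_parameters()
  st <- converge_state(cs, pars, 298, 101325, init = "liquid")
  expect_true(st$converged)
  expect_lt(abs(sum(st$n_monomers * st$populations) - 1), 1e-10)
  expect_true(all(st$populations > 0))
  st2 <- converge_state(cs, pars, 298, 101325, init = st)
  expect_lte(st2$iterations, 2)
  expect_equal(st2$molar_volume, st$molar_volume, tolerance = 1e-10)

  ## warm start from a neighbouring temperature lands on the same fixed point
  st_303_cold <- converge_state(cs, pars, 303, 101325, init = "liquid")
  st_303_warm <- converge_state(cs, pars, 303, 101325, init = st)
  expect_equal(st_303_warm$molar_volume, st_303_cold$molar_volume,
               tolerance = 1e-8)
  expect_equal(st_303_warm$ln_populations, st_303_cold$ln_populations,
               tolerance = 1e-8)
})

test_that("Gibbs energy obeys dG/dp = V and drives branch selection", {
  cs <- monomer_only_set()
  p0 <- 101325
  st <- converge_state(cs, ideal_params(), 298.15, p0, init = "gas")
  dp <- 100  # Pa, central difference
  stm <- converge_state(cs, ideal_params(), 298.15, p0 - dp, init = "gas")
  stp <- converge_state(cs, ideal_params(), 298.15, p0 + dp, init = "gas")
  dGdp <- (stp$gibbs_energy - stm$gibbs_energy) / (2 * dp)   # kJ/Pa
  expect_equal(dGdp, st$molar_volume * 1e-6, tolerance = 1e-6)
  expect_equal(gibbs_energy(st), st$helmholtz_energy + p0 * 1e-6 * st$molar_volume)

  ## equal-G degenerate case (both branches reach the same ideal-gas state):
  ## the documented tie-break selects the liquid-like label
  br <- qcewater:::.solve_branches(cs, ideal_params(), 298.15, p0)
  expect_equal(br$gas$gibbs_energy, br$liquid$gibbs_energy, tolerance = 1e-9)
  expect_identical(br$state$phase, "liquid-like")

  ## distinct branches on the liquid-forming fixture: min G wins
  syn <- synthetic_water_set(seed = 1)
  br <- qcewater:::.solve_branches(syn, synthetic_reference_parameters(),
                                  298.15, p0)
  expect_lt(br$liquid$gibbs_energy, br$gas$gibbs_energy)
  expect_identical(br$state$phase, "liquid-like")
})
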