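test_that("energy conversions use the pinned CODATA factors", {
  expect_equal(convert_energy(1, "hartree", "kcal/mol"), 627.5095,
               tolerance = 1e-7)
  expect_equal(convert_energy(1, "hartree", "kJ/mol"), 2625.4996)
  expect_equal(convert_energy(0.030453, "hartree", "kcal/mol"), 19.109,
               tolerance = 1e-4)
  for (u in c("hartree", "kcal/mol", "kJ/mol"))
    expect_equal(convert_energy(convert_energy(1.234, u, "kJ/mol"),
                                "kJ/mol", u), 1.234, tolerance = 1e-12)
  expect_error(convert_energy(1, "eV", "kJ/mol"), "unknown")
})

test_that("equilibrium constants survive huge free energies in log space", {
  ek <- equilibrium_constant(389, 298.15)
  expect_equal(ek$pK, 285.1, tolerance = 2e-4)   # gas-phase water splitting
  expect_equal(equilibrium_constant(0, 300)$K, 1)
  ## additivity in log space
  a <- equilibrium_constant(123.4, 298.15)$pK
  b <- equilibrium_constant(271.6, 298.15)$pK
  expect_equal(equilibrium_constant(123.4 + 271.6, 298.15)$pK, a + b,
               tolerance = 1e-12)
  ## |dG| up to 1000 kcal/mol: pK finite both ways
  expect_true(is.finite(equilibrium_constant(1000, 298.15)$pK))
  expect_true(is.finite(equilibrium_constant(-1000, 298.15)$pK))
})

test_that("Eyring rates: prefactor value, linearity, and barrier composition", {
  expect_equal(eyring_rate(0, 298.15), 6.2124e12, tolerance = 1e-4)
  expect_equal(eyring_rate(0, 2 * 298.15) / eyring_rate(0, 298.15), 2)
  k <- eyring_rate(19.11, 298.15)
  pref <- qce_constants()$kB * 298.15 / qce_constants()$h
  expect_equal(log10(k / pref),
               -equilibrium_constant(19.11, 298.15)$pK, tolerance = 1e-12)
  expect_equal(log10(k / pref), -14.01, tolerance = 1e-3)
})

test_that("enhancement orders compare equilibrium constants across regimes", {
  expect_equal(enhancement_orders(1e-14, 1e-285), 271)
  expect_equal(enhancement_orders(3e-7, 3e-7), 0)
  expect_equal(enhancement_orders(14, 285, log_space = TRUE), 271)
  expect_error(enhancement_orders(-1, 1), "positive")
})

test_that("pentamer ionization profile reproduces the printed step energetics", {
  prof <- read_reaction_profile()
  expect_s3_class(prof, "reaction_profile")
  tab <- reaction_barriers(prof)
  expect_equal(nrow(tab), 2L)
  ## bridging step W5c -> W5p, then the double-proton-transfer barrier
  expect_equal(tab$dG0_kcal[tab$to == "W5p"], 4.887, tolerance = 1e-3)
  barrier <- tab$dG0_kcal[tab$is_barrier]
  expect_equal(barrier, 19.11, tolerance = 1e-3)
  expect_lt(abs(barrier - 20), 1)   # "ca. 20 kcal/mol"
  expect_equal(tab$dE_kcal[tab$is_barrier], 18.255, tolerance = 1e-3)
})

test_that("reaction_barriers is translation invariant and handles flat steps", {
  prof <- read_reaction_profile()
  shifted <- reaction_profile(prof$label, prof$E + 100, prof$G0 + 100,
                              prof$kind)
  expect_equal(reaction_barriers(shifted)[, c("dE_kcal", "dG0_kcal")],
               reaction_barriers(prof)[, c("dE_kcal", "dG0_kcal")],
               tolerance = 1e-7)
  flat <- reaction_profile(c("a", "b"), c(-1, -1), c(-1, -1))
  expect_equal(reaction_barriers(flat)$dE_kcal, 0)
  expect_equal(reaction_barriers(flat)$dG0_kcal, 0)
  expect_error(reaction_barriers(reaction_profile("x", -1, -1)))
})
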