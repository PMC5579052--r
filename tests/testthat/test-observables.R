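# hand-built converged-state stub for the ionic-product algebra tests
fake_state <- function(N, nh, noh, V, n = rep(2L, length(N)), T = 298.15) {
  labels <- paste0("c", seq_along(N))
  structure(list(T = T, p = 101325, molar_volume = V,
                 populations = setNames(N, labels),
                 ln_populations = setNames(log(N), labels),
                 n_monomers = setNames(as.integer(n), labels),
                 n_hydronium = setNames(as.integer(nh), labels),
                 n_hydroxide = setNames(as.integer(noh), labels),
                 phase = "liquid-like", converged = TRUE),
            class = "qce_state")
}

test_that("ionic product implements the diagonal ionic-cluster sum", {
  ## one IP cluster at N/V = 1e-7 mol/L: Kw = 1e-14, pKw = 14
  kw <- ion_product(fake_state(N = 1e-7, nh = 1, noh = 1, V = 1))
  expect_equal(kw$Kw, 1e-14, tolerance = 1e-12)
  expect_equal(kw$pKw, 14, tolerance = 1e-12)

  ## no IP clusters: Kw = 0 with the +Inf pKw sentinel
  kw0 <- ion_product(fake_state(N = 0.3, nh = 0, noh = 0, V = 1))
  expect_identical(kw0$Kw, 0)
  expect_identical(kw0$pKw, Inf)

  ## two IP clusters at 1e-7 each: diagonal sum gives 2e-14 ...
  st2 <- fake_state(N = c(1e-7, 1e-7), nh = c(1, 1), noh = c(1, 1), V = 1)
  expect_equal(ion_product(st2)$Kw, 2e-14, tolerance = 1e-12)
  ## ... while the conventional concentration product gives 4e-14
  expect_equal(ion_product(st2, mode = "product")$Kw, 4e-14,
               tolerance = 1e-12)
  ## single dominant IP cluster: the two modes coincide
  st1 <- fake_state(N = c(2e-7, 0.4), nh = c(1, 0), noh = c(1, 0), V = 0.5)
  expect_equal(ion_product(st1)$Kw, ion_product(st1, mode = "product")$Kw)

  ## regression against the hand-summed formula on a generic state
  st <- fake_state(N = c(0.2, 3e-8, 5e-9), nh = c(0, 1, 1),
                   noh = c(0, 1, 1), V = 0.018, n = c(1, 5, 8))
  hand <- sum(c(0, 1, 1) * c(0, 1, 1) * c(0.2, 3e-8, 5e-9)^2) / 0.018^2
  expect_equal(ion_product(st)$Kw, hand, tolerance = 1e-12)

  ## log-space evaluation survives populations whose square underflows
  tiny <- fake_state(N = 1e-200, nh = 1, noh = 1, V = 0.018)
  expect_equal(ion_product(tiny)$pKw, -log10(1e-200 / 0.018) * 2,
               tolerance = 1e-9)
})

test_that("monomer-normalized populations are a proper distribution", {
  cs <- monomer_only_set()
  st <- converge_state(cs, ideal_params(), 300, 101325)
  expect_equal(monomer_normalized_populations(st),
               c(W1 = 1), tolerance = 1e-12)

  syn <- synthetic_cluster_set(seed = 4, max_size = 6, ip_destabilization = 70)
  st <- converge_state(syn, synthetic_reference_parameters(), 298, 101325,
                       init = "liquid")
  pops <- monomer_normalized_populations(st)
  expect_equal(sum(pops), 1, tolerance = 1e-12)
  expect_true(all(pops > 0))

  ## invariant under intensive rescaling of the system: doubling the total
  ## monomer amount and the volume (ln q_i + ln 2 via the translational term)
  ln_q <- c(0, 2, -1)
  n <- c(1L, 2L, 3L)
  p1 <- solve_populations(ln_q, n, 1)$populations
  p2 <- solve_populations(ln_q + log(2), n, 2)$populations
  expect_equal(n * p1 / sum(n * p1), n * p2 / sum(n * p2), tolerance = 1e-9)
  expect_equal(p2, 2 * p1, tolerance = 1e-9)
})

test_that("ideal-gas isobar has density proportional to 1/T and no transition", {
  iso <- qce(monomer_only_set(), ideal_params(), T = seq(300, 310, 2))
  df <- as.data.frame(iso)
  expect_true(all(df$converged))
  rhoT <- df$density * df$T
  expect_equal(max(rhoT) / min(rhoT), 1, tolerance = 1e-10)
  expect_true(is.na(iso$transition_temperature))

  ## single grid point: one entry, no transition
  iso1 <- qce(monomer_only_set(), ideal_params(), T = 298.15)
  expect_equal(nrow(as.data.frame(iso1)), 1L)
  expect_true(is.na(iso1$transition_temperature))
})

test_that("isobar of the liquid-forming fixture shows one boiling jump", {
  cs <- synthetic_water_set(seed = 1)
  iso <- qce(cs, synthetic_reference_parameters(), T = seq(353, 399, 2))
  df <- as.data.frame(iso, populations = FALSE)
  V <- df$molar_volume
  jumps <- which(abs(diff(V)) / pmin(V[-1], V[-length(V)]) > 0.5)
  expect_length(jumps, 1L)
  tt <- iso$transition_temperature
  expect_false(is.na(tt))
  expect_gte(tt, df$T[jumps])
  expect_lte(tt, df$T[jumps + 1L])
  ## liquid below the transition, gas above
  expect_identical(df$phase[1L], "liquid-like")
  expect_identical(df$phase[nrow(df)], "gas-like")
  ## pKw falls with T on the liquid branch (the experimental trend)
  liq <- df$phase == "liquid-like"
  expect_true(all(diff(df$pKw[liq]) < 0))
})

test_that("kw_curve tracks the isobar and reacts to IP destabilization", {
  ## IP-free set: all Kw identically zero
  neutral <- synthetic_cluster_set(seed = 3, max_size = 4,
                                   ip_destabilization = 50)
  iso <- qce(neutral, synthetic_reference_parameters(), T = c(290, 300, 310))
  kw <- kw_curve(iso)
  expect_identical(kw$Kw, rep(0, 3))
  expect_identical(kw$pKw, rep(Inf, 3))

  ## +10 kJ/mol IP destabilization raises pKw at each of a few temperatures
  cs80 <- synthetic_water_set(seed = 1, ip_destabilization = 80)
  cs90 <- synthetic_water_set(seed = 1, ip_destabilization = 90)
  Ts <- c(280, 320, 360)
  k80 <- kw_curve(qce(cs80, synthetic_reference_parameters(), T = Ts))
  k90 <- kw_curve(qce(cs90, synthetic_reference_parameters(), T = Ts))
  expect_true(all(k90$pKw > k80$pKw))

  ref <- pkw_experimental_reference()
  expect_equal(ref$pKw[ref$T == 274], 14.93)
  expect_equal(ref$pKw[ref$T == 373], 11.98)
})

test_that("qce object methods behave like a fitted-model object", {
  cs <- synthetic_water_set(seed = 1)
  iso <- qce(cs, synthetic_reference_parameters(), T = c(296, 298, 300))
  expect_s3_class(iso, "qce")
  expect_equal(unname(coef(iso)), c(500, 1.43))
  expect_output(print(iso), "QCE isobar")
  expect_output(print(summary(iso)), "density")
  pr <- predict(iso, T = 298)
  expect_equal(pr$molar_volume,
               as.data.frame(iso)$molar_volume[2], tolerance = 1e-9)
  df <- as.data.frame(iso)
  expect_true(all(c("T", "molar_volume", "density", "phase", "pKw",
                    "N_W1", "N_W10ip2") %in% names(df)))
  pdf_file <- withr::local_tempfile(fileext = ".pdf")
  grDevices::pdf(pdf_file)
  expect_invisible(plot(iso))
  grDevices::dev.off()
  expect_true(file.size(pdf_file) > 0)
})
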