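test_that("cluster-set write/load round-trips every field to full precision", {
  cs <- toy_water_set()
  d <- withr::local_tempdir()
  write_cluster_set(cs, d)
  cs2 <- load_cluster_set(d)
  expect_equal(cs2$monomer, cs$monomer, tolerance = 0)
  expect_equal(length(cs2$clusters), length(cs$clusters))
  for (i in seq_along(cs$clusters)) {
    a <- cs$clusters[[i]]; b <- cs2$clusters[[i]]
    expect_identical(b$label, a$label)
    expect_identical(b$n_monomers, a$n_monomers)
    expect_identical(b$n_hydronium, a$n_hydronium)
    expect_equal(b$interaction_energy, a$interaction_energy, tolerance = 0)
    expect_equal(b$frequencies, a$frequencies, tolerance = 0)
    expect_equal(b$rotational_constants, a$rotational_constants, tolerance = 0)
    expect_equal(b$volume, a$volume, tolerance = 0)
    expect_identical(b$symmetry_number, a$symmetry_number)
  }
  ## geometry survives through XYZ (text, not full double precision)
  expect_equal(cs2$clusters[[1]]$geometry, cs$clusters[[1]]$geometry,
               tolerance = 1e-9)
})

test_that("loader converts tagged energy units and rejects bad input", {
  cs <- toy_water_set()
  d <- withr::local_tempdir()
  write_cluster_set(cs, d)
  mpath <- file.path(d, "cluster_set.yaml")
  m <- yaml::read_yaml(mpath)

  ## hartree tag: -0.010 Eh = -26.254996 kJ/mol
  m2 <- m
  m2$clusters[[2]]$energy <- -0.010
  m2$clusters[[2]]$energy_unit <- "hartree"
  yaml::write_yaml(m2, mpath)
  cs2 <- load_cluster_set(d)
  expect_equal(cs2$clusters[[2]]$interaction_energy, -26.254996,
               tolerance = 1e-12)

  ## kcal/mol tag
  m2$clusters[[2]]$energy <- -10
  m2$clusters[[2]]$energy_unit <- "kcal/mol"
  yaml::write_yaml(m2, mpath)
  expect_equal(load_cluster_set(d)$clusters[[2]]$interaction_energy, -41.84)

  ## unknown unit tag
  m2$clusters[[2]]$energy_unit <- "eV"
  yaml::write_yaml(m2, mpath)
  expect_error(load_cluster_set(d), "unknown energy unit")

  ## imaginary frequency
  yaml::write_yaml(m, mpath)
  writeLines(c("-150", "3657", "3756"), file.path(d, "W1.freq"))
  expect_error(load_cluster_set(d), "imaginary mode")

  ## missing monomer entry
  m3 <- m
  m3$monomer <- NULL
  yaml::write_yaml(m3, mpath)
  expect_error(load_cluster_set(d), "monomer")

  ## duplicate labels
  m4 <- m
  m4$clusters[[3]]$label <- m4$clusters[[2]]$label
  yaml::write_yaml(m4, mpath)
  writeLines(c("1595", "3657", "3756"), file.path(d, "W1.freq"))
  expect_error(load_cluster_set(d), "duplicate")
})

test_that("validate_cluster_set reports each violated invariant by label", {
  expect_length(validate_cluster_set(toy_water_set()), 0)
  expect_length(validate_cluster_set(synthetic_water_set(seed = 3)), 0)

  cs <- toy_water_set()
  ## charge imbalance: lone hydronium
  cs$clusters[[4]]$n_hydroxide <- 0L
  d <- validate_cluster_set(cs)
  expect_match(d, "charge imbalance", all = FALSE)
  expect_match(d, "W5ip", all = FALSE)

  ## wrong mode count: pentamer with 38 of its 39 modes
  cs <- toy_water_set()
  cs$clusters[[3]]$frequencies <- cs$clusters[[3]]$frequencies[-1]
  expect_match(validate_cluster_set(cs), "expected 39", all = FALSE)

  ## nonpositive volume and missing monomer
  cs <- toy_water_set()
  cs$clusters[[2]]$volume <- -1
  cs$clusters[[1]]$n_monomers <- 2L
  d <- validate_cluster_set(cs)
  expect_match(d, "volume", all = FALSE)
  expect_match(d, "exactly one monomer", all = FALSE)
})

test_that("synthetic generator is deterministic, pure, and valid", {
  a <- synthetic_cluster_set(seed = 1, max_size = 5, ip_destabilization = 80)
  b <- synthetic_cluster_set(seed = 1, max_size = 5, ip_destabilization = 80)
  expect_identical(a, b)
  expect_false(identical(
    a, synthetic_cluster_set(seed = 2, max_size = 5, ip_destabilization = 80)))

  ## pure: caller's RNG stream is untouched
  set.seed(99)
  r1 <- runif(3)
  set.seed(99)
  invisible(synthetic_cluster_set(seed = 7, max_size = 4, 50))
  expect_identical(runif(3), r1)

  ## every generated set passes validation; mode counts follow 9n - 6
  for (seed in 1:4) {
    cs <- synthetic_cluster_set(seed, max_size = 6, ip_destabilization = 60)
    expect_length(validate_cluster_set(cs), 0)
    for (cl in cs$clusters) {
      expect_length(cl$frequencies, 9 * cl$n_monomers - 6)
      expect_true(all(cl$frequencies > 0))
      expect_true(all(cl$frequencies >= 30 & cl$frequencies <= 3800))
    }
  }

  ## generated pentamer: 39 modes
  pent <- a$clusters[[which(vapply(a$clusters, function(cl)
    cl$n_monomers == 5L && cl$n_hydronium == 0L, logical(1)))]]
  expect_length(pent$frequencies, 39)
})

test_that("ion-pair isomers sit exactly ip_destabilization above the neutrals", {
  cs0 <- synthetic_cluster_set(seed = 5, max_size = 8, ip_destabilization = 0,
                               extra_ip_sizes = 8L)
  e <- vapply(cs0$clusters, `[[`, numeric(1), "interaction_energy")
  n <- vapply(cs0$clusters, `[[`, integer(1), "n_monomers")
  ip <- vapply(cs0$clusters, function(cl) cl$n_hydronium > 0L, logical(1))
  for (i in which(ip))
    expect_equal(e[i], e[which(!ip & n == n[i])], tolerance = 0)

  cs1 <- synthetic_cluster_set(seed = 5, max_size = 8, ip_destabilization = 42.5)
  e1 <- vapply(cs1$clusters, `[[`, numeric(1), "interaction_energy")
  n1 <- vapply(cs1$clusters, `[[`, integer(1), "n_monomers")
  ip1 <- vapply(cs1$clusters, function(cl) cl$n_hydronium > 0L, logical(1))
  for (i in which(ip1))
    expect_equal(e1[i] - e1[which(!ip1 & n1 == n1[i])], 42.5)
})

test_that("the packaged example set loads and matches toy_water_set()", {
  d <- system.file("extdata", "toy_water_set", package = "qcewater")
  cs <- load_cluster_set(d)
  ref <- toy_water_set()
  expect_equal(length(cs$clusters), length(ref$clusters))
  expect_equal(vapply(cs$clusters, `[[`, numeric(1), "interaction_energy"),
               vapply(ref$clusters, `[[`, numeric(1), "interaction_energy"))
  expect_length(validate_cluster_set(cs), 0)
})

test_that("packaged fixtures have the documented composition", {
  toy <- toy_water_set()
  expect_length(toy$clusters, 4)
  expect_equal(sum(vapply(toy$clusters, `[[`, integer(1), "n_hydronium")), 1L)
  expect_equal(toy$clusters[[1]]$n_monomers, 1L)
  expect_equal(toy$clusters[[1]]$interaction_energy, 0)

  syn <- synthetic_water_set(seed = 1)
  expect_length(syn$clusters, 18)
  expect_equal(sum(vapply(syn$clusters, function(cl) cl$n_hydronium > 0L,
                          logical(1))), 8L)  # ip at 5..10 plus ip2 at 8, 10
  expect_length(validate_cluster_set(syn), 0)
})
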