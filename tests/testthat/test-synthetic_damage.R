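test_that("generator contracts: dose zero, determinism, multiplicity", {
  cfg <- generator_config(seed = 11)
  expect_equal(generate_clusters(cfg, dose = 0, genome_size = 6), list())
  a <- generate_clusters(cfg, dose = 0.5, genome_size = 6)
  b <- generate_clusters(cfg, dose = 0.5, genome_size = 6)
  expect_identical(a, b)
  # a different seed changes the draw
  c2 <- generate_clusters(cfg, dose = 0.5, genome_size = 6, seed = 12)
  expect_false(identical(a, c2))
  expect_error(generate_clusters(cfg, dose = -1, genome_size = 6),
               "non-negative")
  expect_error(generate_clusters(cfg, dose = 1, genome_size = 0), "> 0")
  expect_error(generate_clusters(cfg, 1, 6, oxygen_pct = 7), "oxygen")
  # Poisson(0) extra lesions: every cluster is a single lesion
  solo <- generate_clusters(generator_config(cluster_density = 0, seed = 3),
                            dose = 1, genome_size = 2)
  expect_true(all(vapply(solo, cluster_multiplicity, 0L) == 1L))
})

test_that("generator_config validates its fields", {
  expect_error(generator_config(lesion_yield = -1), "lesion_yield")
  expect_error(generator_config(break_fraction = 1.2), "break_fraction")
  expect_error(generator_config(cluster_density = -0.1), "cluster_density")
  expect_error(generator_config(oxygen_scaling = c(1, 0.5)), "named")
  expect_error(generator_config(oxygen_scaling = c("21" = 1.5)), "factors")
})

test_that("estimate_spectrum converts counts to per-Gy-per-Gbp yields", {
  dsb <- damage_cluster(c(100, 104), strand = c(1, 2))
  sp <- estimate_spectrum(rep(list(dsb), 60), dose = 1, genome_size = 6)
  expect_equal(unname(sp$yields["DSB"]), 10)
  expect_equal(sp$multiplicity_yields$multiplicity, 2L)
  expect_equal(sp$multiplicity_yields$yield, 10)
  empty <- estimate_spectrum(list(), dose = 1, genome_size = 6)
  expect_equal(unname(empty$yields), numeric(7))
  expect_error(estimate_spectrum(list(dsb), dose = 0, genome_size = 6),
               "dose")
})

test_that("yields are dose-linear within Monte Carlo error", {
  cfg <- generator_config(seed = 5)
  genome <- 40
  totals <- vapply(c(0.5, 1, 2), function(d) {
    cl <- generate_clusters(cfg, dose = d, genome_size = genome,
                            seed = 17 + round(10 * d))
    aggregate_totals(estimate_spectrum(cl, d, genome))[["total_damage"]]
  }, 0)
  # expected cluster yield and its 3-sigma Monte Carlo band per dose
  rate <- cfg$lesion_yield / (1 + cfg$cluster_density)
  for (i in seq_along(totals)) {
    d <- c(0.5, 1, 2)[i]
    se <- sqrt(rate / (d * genome))
    expect_lt(abs(totals[i] - rate), 3 * se)
  }
})

test_that("total yield is monotone non-increasing as oxygen drops", {
  cfg <- generator_config(seed = 9)
  tot <- vapply(c(21, 2, 0.1), function(o2) {
    cl <- generate_clusters(cfg, dose = 1, genome_size = 30, oxygen_pct = o2,
                            seed = 100 + round(o2 * 10))
    aggregate_totals(estimate_spectrum(cl, 1, 30))[["total_damage"]]
  }, 0)
  expect_true(all(diff(tot) < 0))
  # and the scaling matches the configured factors within MC error
  expect_equal(tot[2] / tot[1], 0.85, tolerance = 0.05)
  expect_equal(tot[3] / tot[1], 0.43, tolerance = 0.05)
})

test_that("higher cluster density produces more complex damage", {
  genome <- 50   # ~3e4 clusters per run
  share <- function(density, seed) {
    cfg <- generator_config(cluster_density = density, seed = seed)
    sp <- estimate_spectrum(generate_clusters(cfg, 1, genome), 1, genome)
    tot <- sum(sp$yields)
    complex <- sum(sp$yields[c("SSBp", "SSB2", "DSBp", "DSBpp")])
    c(complex = complex / tot, bd = unname(sp$yields["BD"]) / tot,
      dsbp_dsb = unname(sp$yields["DSBp"] / sp$yields["DSB"]))
  }
  lo <- share(0.2, seed = 21)
  hi <- share(1.5, seed = 22)
  expect_gt(hi[["complex"]], lo[["complex"]])
  expect_lt(hi[["bd"]], lo[["bd"]])
  expect_gt(hi[["dsbp_dsb"]], lo[["dsbp_dsb"]])
})

test_that("default calibration lands near the entrance-position total", {
  cfg <- generator_config(seed = 31)
  genome <- 170   # ~1e5 clusters at 1 Gy
  cl <- generate_clusters(cfg, dose = 1, genome_size = genome)
  expect_gt(length(cl), 9e4)
  tot <- aggregate_totals(estimate_spectrum(cl, 1, genome))
  expect_lt(abs(tot[["total_damage"]] - 616) / 616, 0.10)
  # base-damage share near the packaged 68%
  sp <- estimate_spectrum(cl, 1, genome)
  expect_equal(unname(sp$yields["BD"]) / tot[["total_damage"]], 0.68,
               tolerance = 0.05)
})
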