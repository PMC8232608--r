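test_that("enzymatic-DSB conversion is a weighted sum over multiplicities", {
  y <- c("2" = 100, "3" = 50, "4" = 10)
  # uniform conversion probability factors out of the sum
  expect_equal(enzymatic_dsb_yield(y, 0.019), 0.019 * sum(y))
  expect_equal(enzymatic_dsb_yield(y, c("2" = 0, "3" = 0, "4" = 0)), 0)
  expect_equal(enzymatic_dsb_yield(numeric(0), 0.5), 0)
  # linearity and permutation invariance
  p <- c("2" = 0.01, "3" = 0.02, "4" = 0.05)
  expect_equal(enzymatic_dsb_yield(2 * y, p), 2 * enzymatic_dsb_yield(y, p))
  perm <- c("4" = 10, "2" = 100, "3" = 50)
  expect_equal(enzymatic_dsb_yield(perm, p), enzymatic_dsb_yield(y, p))
  expect_error(enzymatic_dsb_yield(y, 1.2), "\\[0, 1\\]")
  expect_error(enzymatic_dsb_yield(y, c("2" = 0.1)), "cover")
  # distal-position bookkeeping: total non-DSB damage times the long-patch
  # BER conversion probability; 9.47 from the printed totals, 9.48 from the
  # per-category sums (which round slightly differently)
  expect_equal(signif((511 - 12.4) * 0.019, 3), 9.47)
  expect_equal(signif(max_dsb_conversion(fixture_spectrum("P6"), 0.019), 3),
               9.48)
})

test_that("enzymatic share reproduces the endpoint percentages", {
  expect_equal(round(max_enzymatic_share(5.72, 8.28), 1), 69.1)
  expect_equal(round(max_enzymatic_share(9.66, 12.4), 1), 77.9)
  expect_equal(max_enzymatic_share(0, 5), 0)
  expect_error(max_enzymatic_share(1, 0), "> 0")
})

test_that("single-cluster repair follows the decision tree deterministically", {
  # lone damaged base with no polymerase error: always correct
  p0 <- repair_sim_parameters(polymerase_error_sp = 0,
                              polymerase_error_lp_ner = 0)
  bd <- damage_cluster(100, 1, "base_damage")
  for (s in 1:5)
    expect_equal(simulate_repair(bd, p0, "LP_BER", seed = s), "correct")
  # excision opposite a break within the inhibition distance: enzymatic DSB
  forced <- damage_cluster(c(100, 103), strand = c(1, 2),
                           kind = c("strand_break", "abasic_site"))
  for (s in 1:5)
    expect_equal(simulate_repair(forced, repair_sim_parameters(), "LP_BER",
                                 seed = s), "enzymatic_dsb")
  # DSB-class clusters are not excision-repair substrates
  dsb <- damage_cluster(c(100, 104), strand = c(1, 2))
  expect_error(simulate_repair(dsb), "not excision-repair substrates")
  # determinism at a fixed seed
  cl <- damage_cluster(c(100, 104), strand = c(1, 2),
                       kind = c("base_damage", "strand_break"))
  expect_equal(simulate_repair(cl, seed = 42), simulate_repair(cl, seed = 42))
})

test_that("one-strand clusters can never convert to an enzymatic DSB", {
  withr::with_seed(77, {
    for (rep in 1:60) {
      n <- sample(1:4, 1)
      cl <- damage_cluster(100 + sample.int(20, n, replace = TRUE),
                           strand = 1L,
                           kind = sample(lesion_kinds(), n, replace = TRUE))
      out <- simulate_repair(cl, repair_sim_parameters(), "LP_BER_NER")
      expect_true(out %in% c("correct", "mutation"))
    }
  })
})

test_that("ensemble outcome frequencies are normalised and reproducible", {
  p0 <- repair_sim_parameters(polymerase_error_sp = 0,
                              polymerase_error_lp_ner = 0)
  bd_only <- list(damage_cluster(100, 1, "base_damage"),
                  damage_cluster(200, 2, "base_damage"))
  op <- outcome_probabilities(bd_only, p0, "LP_BER", n_reps = 50, seed = 1)
  expect_equal(c(op$p_correct, op$p_mutation, op$p_dsb), c(1, 0, 0))
  mixed <- list(
    damage_cluster(c(100, 104), strand = c(1, 2),
                   kind = c("base_damage", "strand_break")),
    damage_cluster(c(100, 102), strand = c(1, 2),
                   kind = c("base_damage", "base_damage")))
  op2 <- outcome_probabilities(mixed, n_reps = 500, seed = 2)
  expect_equal(op2$p_correct + op2$p_mutation + op2$p_dsb, 1)
  expect_equal(op2$n, 1000)
  op3 <- outcome_probabilities(mixed, n_reps = 500, seed = 2)
  expect_equal(op2, op3)
  expect_error(outcome_probabilities(list()), "non-empty")
})

test_that("sampled frequencies match the exact decision-tree enumeration", {
  params <- repair_sim_parameters()
  n <- 2e4
  cases <- list(
    damage_cluster(c(100, 104), strand = c(1, 2),
                   kind = c("base_damage", "strand_break")),
    damage_cluster(c(100, 112), strand = c(1, 2),
                   kind = c("abasic_site", "strand_break")),
    damage_cluster(c(100, 103), strand = c(1, 2),
                   kind = c("base_damage", "abasic_site")),
    damage_cluster(c(100, 101, 109), strand = c(1, 2, 1),
                   kind = c("base_damage", "strand_break", "base_damage")))
  for (i in seq_along(cases)) {
    for (pw in c("SP_BER", "LP_BER_NER")) {
      exact <- oracle_repair_probs(cases[[i]], params, pw)
      got <- outcome_probabilities(cases[i], params, pw, n_reps = n,
                                   seed = 300 + i)
      est <- c(got$p_correct, got$p_mutation, got$p_dsb)
      for (j in 1:3) {
        band <- binom_band(n, exact[j])
        expect_gte(est[j] * n, band["lo"])
        expect_lte(est[j] * n, band["hi"])
      }
    }
  }
})

test_that("widening the inhibition distance never lowers p_dsb", {
  withr::with_seed(55, {
    clusters <- replicate(40, {
      repeat {
        cl <- random_cluster(sample(2:4, 1), span = 25)
        if (!is_dsb_class(classify_cluster(cl))) return(cl)
      }
    }, simplify = FALSE)
  })
  p_at <- function(d) {
    outcome_probabilities(
      clusters, repair_sim_parameters(inhibition_distance = d),
      "LP_BER", n_reps = 200, seed = 91)$p_dsb
  }
  p <- vapply(c(2, 5, 8, 12, 16), p_at, 0)
  expect_true(all(diff(p) >= 0))
})

test_that("NER-containing pathways convert at least as often as SP BER", {
  withr::with_seed(66, {
    clusters <- replicate(60, {
      repeat {
        cl <- random_cluster(sample(2:3, 1), span = 25)
        if (!is_dsb_class(classify_cluster(cl))) return(cl)
      }
    }, simplify = FALSE)
  })
  params <- repair_sim_parameters()
  p_sp <- outcome_probabilities(clusters, params, "SP_BER",
                                n_reps = 400, seed = 7)$p_dsb
  p_ner <- outcome_probabilities(clusters, params, "SP_BER_NER",
                                 n_reps = 400, seed = 7)$p_dsb
  expect_lte(p_sp, p_ner)
})
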