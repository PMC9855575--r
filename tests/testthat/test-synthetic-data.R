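test_that("scenario config validates its structure", {
  expect_error(scenario_config(source_pop = "Nope"), "source_pop")
  expect_error(scenario_config(f_values = c(NativeA = 0.05),
                               source_pop = "NativeA"),
               "exactly one")
  cfg <- scenario_config()
  expect_equal(unname(cfg$n_per_pop), c(24, 14, 18, 18))
  expect_equal(cfg$introduced_pop, "Introduced")
})

test_that("fixed seed makes the generators bit-identical", {
  s1 <- simulate_unlinked(scenario_config(n_sites = 300, seed = 5))
  s2 <- simulate_unlinked(scenario_config(n_sites = 300, seed = 5))
  expect_identical(s1$genotypes, s2$genotypes)
  expect_identical(s1$truth$p_pop, s2$truth$p_pop)
  g1 <- simulate_linked(wf_config(pop_size = 20, chrom_length_bp = 5e3,
                                  burn_in_generations = 50,
                                  sample_size = 10, seed = 5))
  g2 <- simulate_linked(wf_config(pop_size = 20, chrom_length_bp = 5e3,
                                  burn_in_generations = 50,
                                  sample_size = 10, seed = 5))
  expect_identical(g1, g2)
})

test_that("F = 0 is the zero-drift limit and fixation is absorbing", {
  cfg <- scenario_config(n_per_pop = c(P1 = 5, Intro = 5),
                         f_values = c(P1 = 0), source_pop = "P1",
                         n_sites = 100, seed = 3)
  sim <- simulate_unlinked(cfg)
  expect_equal(sim$truth$p_pop["P1", ], sim$truth$p0)
  # force fixation in the source: introduced frequency must be 1
  cfg2 <- scenario_config(n_per_pop = c(P1 = 5, Intro = 5),
                          f_values = c(P1 = 0.9999), source_pop = "P1",
                          founder_size = 2, post_founding_generations = 3,
                          n_sites = 200, seed = 9)
  sim2 <- simulate_unlinked(cfg2)
  fixed <- sim2$truth$p_pop["P1", ] == 1
  expect_gt(sum(fixed), 0)
  expect_true(all(sim2$truth$p_pop["Intro", fixed] == 1))
})

test_that("one-generation founder drift shrinks heterozygosity by 1 - 1/(2Nf)", {
  set.seed(101)
  ratio <- replicate(50, {
    cfg <- scenario_config(n_per_pop = c(Src = 5, Intro = 5),
                           f_values = c(Src = 0.05), source_pop = "Src",
                           founder_size = 10, post_founding_generations = 0,
                           n_sites = 2000, missing_rate = 0)
    sim <- simulate_unlinked(cfg)
    p_src <- sim$truth$p_pop["Src", ]
    p_int <- sim$truth$p_pop["Intro", ]
    mean(2 * p_int * (1 - p_int)) / mean(2 * p_src * (1 - p_src))
  })
  expect_equal(mean(ratio), 1 - 1 / 20, tolerance = 0.01)
})

test_that("FST between equal-F populations approximates F", {
  set.seed(103)
  f <- replicate(5, {
    cfg <- scenario_config(n_per_pop = c(P1 = 50, P2 = 50, Intro = 5),
                           f_values = c(P1 = 0.05, P2 = 0.05),
                           source_pop = "P1", n_sites = 4000,
                           missing_rate = 0)
    sim <- simulate_unlinked(cfg)
    fst_pair(sim$genotypes, sim$popmap, "P1", "P2",
             estimator = "hudson")$global_fst
  })
  expect_lt(abs(mean(f) - 0.05), 0.015)
  # FST increases with F
  f_hi <- {
    cfg <- scenario_config(n_per_pop = c(P1 = 50, P2 = 50, Intro = 5),
                           f_values = c(P1 = 0.2, P2 = 0.2),
                           source_pop = "P1", n_sites = 4000,
                           missing_rate = 0)
    sim <- simulate_unlinked(cfg)
    fst_pair(sim$genotypes, sim$popmap, "P1", "P2",
             estimator = "hudson")$global_fst
  }
  expect_gt(f_hi, mean(f))
})

test_that("introduced diversity sits below the source's over replicates", {
  set.seed(107)
  deltas <- replicate(20, {
    sim <- simulate_unlinked(scenario_config(n_sites = 1000))
    w <- make_windows(c(chr1 = 1e6))
    wd <- window_diversity(sim$genotypes, sim$popmap, w,
                           populations = c("Introduced", "NativeB"))
    pi_i <- mean(wd$theta_pi[wd$population == "Introduced"], na.rm = TRUE)
    pi_s <- mean(wd$theta_pi[wd$population == "NativeB"], na.rm = TRUE)
    pi_s - pi_i
  })
  expect_gt(mean(deltas), 0)
  expect_lt(stats::t.test(deltas, alternative = "greater")$p.value, 0.05)
})

test_that("WF simulator edge cases: no mutation, no recombination", {
  expect_warning(
    g0 <- simulate_linked(wf_config(pop_size = 20, chrom_length_bp = 1e4,
                                    mu = 0, rec = 1e-5,
                                    burn_in_generations = 100,
                                    sample_size = 10, seed = 1)),
    "no segregating")
  expect_equal(n_sites(g0), 0)
  # rec = 0: fully linked derived sites on identical backgrounds have r2 = 1
  set.seed(5)
  g <- simulate_linked(wf_config(pop_size = 30, chrom_length_bp = 1e4,
                                 mu = 4e-5, rec = 0,
                                 burn_in_generations = 300,
                                 sample_size = 15, seed = 5))
  ac <- colSums(g$dosages)
  # find two sites with identical genotype columns (same haplotype background)
  found <- FALSE
  for (i in seq_len(n_sites(g) - 1)) {
    for (j in (i + 1):n_sites(g)) {
      if (identical(g$dosages[, i], g$dosages[, j]) &&
          var(g$dosages[, i]) > 0) {
        expect_equal(pair_r2(g$dosages[, i], g$dosages[, j]), 1)
        found <- TRUE
        break
      }
    }
    if (found) break
  }
  expect_true(found)
})
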