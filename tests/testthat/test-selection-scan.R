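test_that("ROD arithmetic and guards", {
  expect_equal(rod(0.004, 0.004), 0)                 # equal diversities
  expect_equal(rod(0, 0.004), 1)                     # total loss
  expect_equal(rod(0.0034, 0.0045), 0.244444, tolerance = 1e-5)
  expect_true(is.na(rod(0.001, 0)))                  # undefined source
  expect_error(rod(-0.1, 0.2), "non-negative")
  expect_equal(rod(c(0.002, 0.004), c(0.004, 0.004)), c(0.5, 0))
})

test_that("quantile outlier flags follow the rank rule with ties included", {
  v <- sample(1:100)                                  # 100 distinct values
  top <- flag_outliers(v, "top", 0.05)
  expect_equal(sum(top), 5)
  expect_setequal(v[top], 96:100)
  # all values equal: everything tied at the boundary, all flagged
  expect_true(all(flag_outliers(rep(3, 10), "top", 0.05)))
  # bottom tail matches a sort oracle on negative sequences
  set.seed(5)
  for (rep in 1:10) {
    x <- rnorm(57)
    x[sample(57, 5)] <- NA
    fl <- flag_outliers(x, "bottom", 0.1)
    n <- sum(!is.na(x))
    thr <- sort(x)[ceiling(0.1 * n)]
    expect_identical(fl, !is.na(x) & x <= thr)
    expect_false(any(fl & is.na(x)))
  }
  expect_warning(flag_outliers(c(NA_real_, NA), "top", 0.05), "all values")
})

test_that("candidate set on a toy statistics table equals hand enumeration", {
  # 10 windows with hand-chosen statistics; fraction 0.2 -> 2 flagged per tail
  fst <- c(9, 8, 1, 1, 1, 1, 1, 1, 1, 1)
  rodv <- c(1, 1, 9, 8, 1, 1, 1, 1, 1, 1) / 10
  tajd <- c(-3, 1, -4, 1, 1, 1, 1, 1, 1, 1)
  ft <- flag_outliers(fst, "top", 0.2)
  rt <- flag_outliers(rodv, "top", 0.2)
  tb <- flag_outliers(tajd, "bottom", 0.2)
  cand <- (ft | rt) & tb & tajd < 0
  expect_equal(which(cand), c(1, 3))     # fst-top & D=-3; rod-top & D=-4
  expect_false(cand[2])                  # fst-top but D positive
  expect_false(cand[4])                  # rod-top but D not in bottom tail
})

test_that("scan output respects the flag structure and subset invariants", {
  set.seed(11)
  sim <- simulate_unlinked(scenario_config(n_sites = 3000, seed = 11))
  w <- make_windows(c(chr1 = 1e6))
  sc <- selection_scan(sim$genotypes, sim$popmap, "Introduced", "NativeB", w)
  expect_s3_class(sc, "selection_scan")
  expect_true(all(sc$candidate == ((sc$fst_top | sc$rod_top) & sc$tajd_bottom &
                                     !is.na(sc$tajima_d) & sc$tajima_d < 0)))
  # candidates are a subset of the Tajima bottom tail
  expect_true(all(sc$tajd_bottom[sc$candidate]))
  expect_true(all(sc$rod[!is.na(sc$rod)] <= 1))
  # dropping the ROD flag can only shrink the candidate set
  cand_no_rod <- sc$fst_top & sc$tajd_bottom & !is.na(sc$tajima_d) &
    sc$tajima_d < 0
  expect_true(all(cand_no_rod <= sc$candidate))
  expect_error(selection_scan(sim$genotypes, sim$popmap, "NativeB",
                              "NativeB", w), "must differ")
})

test_that("a constructed diversity-loss block is recovered as candidate", {
  set.seed(13)
  hits <- replicate(10, {
    sim <- simulate_unlinked(scenario_config(n_sites = 3000))
    sim <- inject_sweep(sim, 5e5, 5.2e5)
    w <- make_windows(c(chr1 = 1e6))
    sc <- selection_scan(sim$genotypes, sim$popmap, "Introduced", "NativeB", w)
    any(sc$candidate & sc$start >= 4.95e5 & sc$end <= 5.25e5)
  })
  expect_gte(sum(hits), 9)
})

test_that("neutral equal-history data yields few candidate windows", {
  set.seed(17)
  frac <- replicate(5, {
    cfg <- scenario_config(n_per_pop = c(P1 = 20, P2 = 20, Intro = 4),
                           f_values = c(P1 = 0.07, P2 = 0.07),
                           source_pop = "P1", n_sites = 3000)
    sim <- simulate_unlinked(cfg)
    w <- make_windows(c(chr1 = 1e6))
    sc <- selection_scan(sim$genotypes, sim$popmap, "P2", "P1", w)
    mean(sc$candidate)
  })
  expect_lt(mean(frac), 0.02)
})

test_that("candidate windows merge into regions and overlap genes", {
  # hand-built scan table: windows [0,10k), [5k,15k), [20k,30k) are candidates
  sc <- data.frame(chrom = "c", start = c(0, 5000, 10000, 20000, 40000),
                   end = c(10000, 15000, 20000, 30000, 50000),
                   n_sites = 5L, fst = 0.5, rod = 0.5, tajima_d = -2,
                   fst_top = TRUE, rod_top = TRUE, tajd_bottom = TRUE,
                   candidate = c(TRUE, TRUE, FALSE, TRUE, FALSE))
  class(sc) <- c("selection_scan", "data.frame")
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               paste("c", "src", "gene", "12001", "14000", ".", "+", ".",
                     "ID=geneA", sep = "\t"),
               paste("c", "src", "gene", "16000", "19000", ".", "+", ".",
                     "ID=geneB", sep = "\t"),
               paste("c", "src", "mRNA", "12001", "13000", ".", "+", ".",
                     "ID=mrna1;Parent=geneA", sep = "\t"),
               paste("cX", "src", "gene", "100", "200", ".", "+", ".",
                     "ID=geneC", sep = "\t")), gff)
  expect_warning(res <- merge_candidates(sc, gff), "absent from the scan")
  expect_equal(res$regions$start, c(0, 20000))
  expect_equal(res$regions$end, c(15000, 30000))
  expect_equal(res$regions$n_windows, c(2L, 1L))
  # gene at 12,001-14,000 (1-based) overlaps region [0, 15000); geneB and the
  # unknown-chromosome geneC do not contribute
  expect_equal(res$genes, "geneA")
  expect_equal(res$regions$gene_ids, c("geneA", ""))
  # no candidates -> no regions, no genes
  sc0 <- sc; sc0$candidate <- FALSE
  res0 <- merge_candidates(sc0)
  expect_equal(nrow(res0$regions), 0)
  expect_length(res0$genes, 0)
})

test_that("region bookkeeping invariants hold on simulated scans", {
  set.seed(19)
  sim <- simulate_unlinked(scenario_config(n_sites = 3000, seed = 19))
  sim <- inject_sweep(sim, 2e5, 2.2e5)
  w <- make_windows(c(chr1 = 1e6))
  sc <- selection_scan(sim$genotypes, sim$popmap, "Introduced", "NativeB", w)
  res <- merge_candidates(sc)
  expect_lte(nrow(res$regions), sum(sc$candidate))
  expect_lte(sum(res$regions$end - res$regions$start),
             sum(sc$end[sc$candidate] - sc$start[sc$candidate]))
  expect_gte(min(res$regions$n_windows), 1)
})
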