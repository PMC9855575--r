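test_that("PCA basics: duplicated samples coincide, 2 samples load on PC1", {
  set.seed(3)
  d <- matrix(sample(0:2, 6 * 30, replace = TRUE), 6, 30)
  d[6, ] <- d[5, ]                       # duplicate
  g <- genotypes(d, chrom = rep("c", 30), pos = 1:30)
  p <- pca_genotypes(g)
  expect_equal(p$coordinates[5, ], p$coordinates[6, ], tolerance = 1e-8)
  expect_true(all(diff(p$variance_explained) <= 1e-8))
  expect_lte(sum(p$variance_explained), 1 + 1e-8)
  # two samples: all variance on PC1
  g2 <- genotypes(matrix(c(0L, 2L, 0L, 2L, 1L, 0L), 2, 3),
                  chrom = rep("c", 3), pos = 1:3)
  p2 <- pca_genotypes(g2)
  expect_equal(p2$variance_explained[1], 1, tolerance = 1e-8)
  # all-monomorphic input is an error
  g3 <- genotypes(matrix(1L, 4, 3), chrom = rep("c", 3), pos = 1:3)
  expect_error(pca_genotypes(g3), "monomorphic")
})

test_that("PCA coordinates are sample-order invariant up to sign", {
  set.seed(19)
  g <- random_genotypes(12, 60, miss = 0.05)
  p1 <- pca_genotypes(g)
  perm <- sample(n_samples(g))
  g2 <- g[perm, ]
  p2 <- pca_genotypes(g2)
  back <- p2$coordinates[match(g$sample_ids, g2$sample_ids), ]
  for (k in 1:3) {
    expect_true(isTRUE(all.equal(back[, k], p1$coordinates[, k],
                                 tolerance = 1e-6)) ||
                isTRUE(all.equal(back[, k], -p1$coordinates[, k],
                                 tolerance = 1e-6)))
  }
  expect_equal(p2$variance_explained, p1$variance_explained,
               tolerance = 1e-8)
})

test_that("PCA separates two drifted populations", {
  set.seed(29)
  hits <- replicate(10, {
    cfg <- scenario_config(n_per_pop = c(P1 = 40, P2 = 40, Intro = 5),
                           f_values = c(P1 = 0.1, P2 = 0.1),
                           source_pop = "P1", n_sites = 2000)
    sim <- simulate_unlinked(cfg)
    keep <- names(sim$popmap)[sim$popmap != "Intro"]
    p <- pca_genotypes(sim$genotypes[keep, ])
    pc1 <- p$coordinates[, 1]
    grp <- sim$popmap[keep]
    max(pc1[grp == "P1"]) < min(pc1[grp == "P2"]) ||
      max(pc1[grp == "P2"]) < min(pc1[grp == "P1"])
  })
  expect_gte(sum(hits), 9)
})

test_that("p-distance follows its definition and is a semimetric", {
  # identical, opposite-homozygote and het cases
  g <- genotypes(rbind(c(0L, 0L), c(2L, 2L), c(1L, 0L)),
                 chrom = c("c", "c"), pos = 1:2)
  d <- p_distance(g)
  expect_equal(d[1, 2], 1)                    # all 0 vs all 2
  expect_equal(d[1, 3], 0.25)                 # one het over two sites
  expect_equal(unname(diag(d)), rep(0, 3))
  # single site 0 vs 1 is 0.5
  g1 <- genotypes(matrix(c(0L, 1L, 0L), 3, 1), chrom = "c", pos = 1L)
  expect_equal(p_distance(g1)[1, 2], 0.5)
  # brute force with missing data, plus symmetry/triangle checks
  set.seed(37)
  for (rep in 1:5) {
    gr <- random_genotypes(6, 25, miss = 0.2)
    dr <- p_distance(gr)
    expect_equal(dr, t(dr))
    for (i in 1:5) for (j in (i + 1):6) {
      both <- !is.na(gr$dosages[i, ]) & !is.na(gr$dosages[j, ])
      expect_equal(dr[i, j],
                   sum(abs(gr$dosages[i, both] - gr$dosages[j, both])) /
                     (2 * sum(both)))
    }
    tri <- TRUE
    for (i in 1:6) for (j in 1:6) for (k in 1:6)
      tri <- tri && dr[i, j] <= dr[i, k] + dr[k, j] + 1e-9
    expect_true(tri)
  }
})

test_that("NJ recovers the additive 4-taxon tree exactly", {
  d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d["A", "B"] <- 3; d["A", "C"] <- 5; d["A", "D"] <- 6
  d["B", "C"] <- 6; d["B", "D"] <- 7; d["C", "D"] <- 7
  d <- d + t(d)
  tr <- nj_tree(d)
  # topology: (A,B) | (C,D)
  expect_true(ape::is.monophyletic(ape::root(tr, "D"), c("A", "B")))
  # path lengths reproduce the additive input exactly
  pd <- ape::cophenetic.phylo(tr)[rownames(d), colnames(d)]
  expect_equal(pd, d, tolerance = 1e-9)
  # leaf branches 1,2,3,4 and internal branch 1
  el <- sort(tr$edge.length)
  expect_equal(el, c(1, 1, 2, 3, 4), tolerance = 1e-9)
})

test_that("NJ clamps negative branch lengths and validates input", {
  set.seed(41)
  g <- random_genotypes(8, 60)
  d <- p_distance(g)
  tr <- nj_tree(d)
  expect_true(all(tr$edge.length >= 0))
  expect_setequal(tr$tip.label, g$sample_ids)
  bad <- d; bad[1, 2] <- bad[1, 2] + 1
  expect_error(nj_tree(bad), "symmetric")
})

test_that("introduced samples cluster with the source clade in the NJ tree", {
  set.seed(53)
  hits <- replicate(10, {
    sim <- simulate_unlinked(scenario_config(n_sites = 2000))
    tr <- nj_tree(p_distance(sim$genotypes))
    td <- ape::cophenetic.phylo(tr)
    intro <- sim$truth$config$introduced_pop
    src <- sim$truth$config$source_pop
    # nearest foreign population on the tree, averaged over introduced tips
    ii <- names(sim$popmap)[sim$popmap == intro]
    others <- setdiff(unique(sim$popmap), intro)
    mean_d <- vapply(others, function(p)
      mean(td[ii, names(sim$popmap)[sim$popmap == p]]), 0)
    names(which.min(mean_d)) == src
  })
  expect_gte(sum(hits), 8)
})

test_that("PHYLIP distance writer emits a readable square matrix", {
  g <- random_genotypes(4, 10)
  d <- p_distance(g)
  f <- withr::local_tempfile(fileext = ".phy")
  write_phylip_dist(d, f)
  lines <- readLines(f)
  expect_equal(as.integer(trimws(lines[1])), 4)
  row2 <- as.numeric(strsplit(trimws(substring(lines[3], 11)),
                              "[[:space:]]+")[[1]])
  expect_equal(row2, unname(d[2, ]), tolerance = 1e-6)
})
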