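# Small programmatic fixtures shared across test files.

# Random genotype matrix with optional missingness; positions spread over
# `span` bp of one chromosome.
random_genotypes <- function(n_samples = 10, n_sites = 50, miss = 0.1,
                             span = 10 * n_sites, chrom = "chr1") {
  d <- matrix(sample(0:2, n_samples * n_sites, replace = TRUE),
              nrow = n_samples)
  if (miss > 0) d[runif(length(d)) < miss] <- NA
  genotypes(d, chrom = rep(chrom, n_sites),
            pos = sort(sample.int(span, n_sites)))
}

two_pop_map <- function(g, n_a) {
  stats::setNames(rep(c("A", "B"), c(n_a, n_samples(g) - n_a)), g$sample_ids)
}

# Brute-force per-site pi: mean difference over all unordered pairs of
# non-missing alleles, enumerated explicitly.
brute_site_pi <- function(dosages_at_site) {
  d <- dosages_at_site[!is.na(dosages_at_site)]
  alleles <- unlist(lapply(d, function(x) c(rep(1, x), rep(0, 2 - x))))
  if (length(alleles) < 2) return(NA_real_)
  pr <- utils::combn(length(alleles), 2)
  mean(alleles[pr[1, ]] != alleles[pr[2, ]])
}

# Inject a hard-sweep signature into the introduced population over
# [block_start, block_end): fix every block site to dosage 0, then restore a
# few singleton variants so Tajima's D is defined and strongly negative.
inject_sweep <- function(sim, block_start, block_end, n_singletons = 4) {
  g <- sim$genotypes
  intro <- names(sim$popmap)[sim$popmap == sim$truth$config$introduced_pop]
  rows <- match(intro, g$sample_ids)
  in_block <- g$pos > block_start & g$pos <= block_end
  g$dosages[rows, in_block] <- 0L
  sites <- which(in_block)
  if (length(sites)) {
    at <- sites[unique(round(seq(1, length(sites),
                                 length.out = min(n_singletons,
                                                  length(sites)))))]
    for (s in at) g$dosages[rows[1], s] <- 1L
  }
  sim$genotypes <- g
  sim
}
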