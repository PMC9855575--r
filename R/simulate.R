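#' Founder-event scenario configuration
#'
#' Describes the synthetic study design the package is exercised against:
#' several native populations drifted from a common ancestral gene pool under
#' the Balding-Nichols model, plus one introduced population founded from a
#' single native source through a small-founder bottleneck. Defaults mirror a
#' four-site pearl-oyster survey: three natives of 24, 14 and 18 samples and
#' an introduced population of 18, with native differentiation parameters F
#' of 0.05, 0.07 and 0.10 (giving pairwise FST on the 0.04-0.12 scale) and a
#' 10-founder introduction from the second native followed by two generations
#' of growth-phase drift.
#'
#' @param n_per_pop named integer vector: samples per population. Names of
#'   the native populations must match `names(f_values)`; the remaining name
#'   is the introduced population.
#' @param n_sites number of unlinked SNP sites.
#' @param f_values named numeric vector of Balding-Nichols F for each native
#'   population, each in `[0, 1)`. `F = 0` is the zero-drift limit (the
#'   population keeps the ancestral frequencies exactly).
#' @param source_pop name of the native population seeding the introduction.
#' @param founder_size number of diploid founders of the introduced
#'   population.
#' @param post_founding_generations generations of binomial drift at size
#'   `n_intro` after founding.
#' @param n_intro diploid population size during the post-founding phase.
#' @param missing_rate per-genotype probability of a missing call.
#' @param genome_length chromosome length in bp over which site positions are
#'   scattered (single chromosome `chr1`).
#' @param seed RNG seed; fixed seed gives bit-identical output.
#' @return a list of class `"scenario_config"`.
#' @export
scenario_config <- function(n_per_pop = c(NativeA = 24, NativeB = 14,
                                          NativeC = 18, Introduced = 18),
                            n_sites = 5000,
                            f_values = c(NativeA = 0.05, NativeB = 0.07,
                                         NativeC = 0.10),
                            source_pop = "NativeB",
                            founder_size = 10,
                            post_founding_generations = 2,
                            n_intro = 200,
                            missing_rate = 0.05,
                            genome_length = 1e6,
                            seed = NULL) {
  stopifnot(n_sites >= 1, founder_size >= 1, post_founding_generations >= 0,
            missing_rate >= 0, missing_rate <= 1,
            all(f_values >= 0), all(f_values < 1),
            genome_length >= n_sites)
  natives <- names(f_values)
  if (is.null(names(n_per_pop)) || is.null(natives))
    stop("n_per_pop and f_values must be named")
  if (!source_pop %in% natives)
    stop("source_pop must be one of the native populations: ",
         paste(natives, collapse = ", "))
  introduced <- setdiff(names(n_per_pop), natives)
  if (length(introduced) != 1L)
    stop("exactly one population in n_per_pop must be the introduced one ",
         "(i.e. absent from f_values)")
  structure(list(n_per_pop = n_per_pop, n_sites = as.integer(n_sites),
                 f_values = f_values, source_pop = source_pop,
                 introduced_pop = introduced,
                 founder_size = as.integer(founder_size),
                 post_founding_generations = as.integer(post_founding_generations),
                 n_intro = as.integer(n_intro),
                 missing_rate = missing_rate,
                 genome_length = as.integer(genome_length), seed = seed),
            class = "scenario_config")
}

#' Simulate unlinked SNP genotypes under the founder-event scenario
#'
#' Per site: an ancestral frequency `p0 ~ Uniform(0.05, 0.95)`; each native
#' population's frequency is Beta-distributed around `p0` with the
#' Balding-Nichols parameterisation `Beta(p0(1-F)/F, (1-p0)(1-F)/F)`; the
#' introduced population's frequency is obtained by binomial sampling of
#' `2 * founder_size` founder alleles from the source population followed by
#' `post_founding_generations` rounds of binomial drift at size `n_intro`.
#' Genotypes are drawn per sample as `Binomial(2, p)` (Hardy-Weinberg), then
#' masked missing i.i.d. at `missing_rate`.
#'
#' @param cfg a [scenario_config()].
#' @return a list of class `"founder_sim"` with elements `genotypes` (a
#'   [genotypes()] object), `popmap` (named character vector) and `truth`
#'   (list with `p0` and the per-population latent frequency matrix
#'   `p_pop`, populations x sites).
#' @export
simulate_unlinked <- function(cfg = scenario_config()) {
  stopifnot(inherits(cfg, "scenario_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  ns <- cfg$n_sites
  p0 <- stats::runif(ns, 0.05, 0.95)
  pops <- names(cfg$n_per_pop)
  p_pop <- matrix(NA_real_, nrow = length(pops), ncol = ns,
                  dimnames = list(pops, NULL))
  for (pop in names(cfg$f_values)) {
    f <- cfg$f_values[[pop]]
    if (f == 0) {
      p_pop[pop, ] <- p0            # degenerate Beta: zero-drift limit
    } else {
      p_pop[pop, ] <- stats::rbeta(ns, p0 * (1 - f) / f,
                                   (1 - p0) * (1 - f) / f)
    }
  }
  # founder bottleneck from the source population, then growth-phase drift
  p <- stats::rbinom(ns, 2L * cfg$founder_size, p_pop[cfg$source_pop, ]) /
    (2 * cfg$founder_size)
  if (cfg$post_founding_generations > 0L) {
    for (i in seq_len(cfg$post_founding_generations))
      p <- stats::rbinom(ns, 2L * cfg$n_intro, p) / (2 * cfg$n_intro)
  }
  p_pop[cfg$introduced_pop, ] <- p

  n_tot <- sum(cfg$n_per_pop)
  dos <- matrix(NA_integer_, nrow = n_tot, ncol = ns)
  popmap <- character(n_tot)
  ids <- character(n_tot)
  row <- 0L
  for (pop in pops) {
    n <- cfg$n_per_pop[[pop]]
    rows <- row + seq_len(n)
    dos[rows, ] <- matrix(stats::rbinom(n * ns, 2L,
                                        rep(p_pop[pop, ], each = n)),
                          nrow = n)
    popmap[rows] <- pop
    ids[rows] <- paste0(pop, "_", seq_len(n))
    row <- row + n
  }
  if (cfg$missing_rate > 0)
    dos[stats::runif(length(dos)) < cfg$missing_rate] <- NA_integer_
  pos <- sort(sample.int(cfg$genome_length, ns))
  g <- genotypes(dos, chrom = rep("chr1", ns), pos = pos, sample_ids = ids)
  structure(list(genotypes = g,
                 popmap = stats::setNames(popmap, ids),
                 truth = list(p0 = p0, p_pop = p_pop, config = cfg)),
            class = "founder_sim")
}

#' @export
print.founder_sim <- function(x, ...) {
  cat("Founder-event simulation:\n")
  print(x$genotypes)
  cat("Populations:",
      paste(sprintf("%s (n=%d)", names(x$truth$config$n_per_pop),
                    x$truth$config$n_per_pop), collapse = ", "), "\n")
  cat("Introduced:", x$truth$config$introduced_pop, "founded from",
      x$truth$config$source_pop, "with", x$truth$config$founder_size,
      "founders\n")
  invisible(x)
}

#' Forward Wright-Fisher configuration
#'
#' Desk-scale forward diploid simulator used to generate linked haplotypes
#' for LD analyses. Mutation is finite-sites with at most one segregating
#' allele per position (a repeat mutation flips the allele back), which
#' biases diversity slightly downward at high mutation rates.
#'
#' @param pop_size diploid population size N.
#' @param chrom_length_bp chromosome length L in bp.
#' @param mu per-bp per-generation mutation rate.
#' @param rec per-bp per-generation recombination rate (crossover count per
#'   gamete is `Poisson(rec * L)` with uniform breakpoints).
#' @param burn_in_generations generations simulated before sampling
#'   (default `10 * pop_size`, enough to approach mutation-drift
#'   equilibrium for diversity statistics).
#' @param sample_size diploids sampled at the end.
#' @param chrom chromosome label for the output.
#' @param seed RNG seed.
#' @return a list of class `"wf_config"`.
#' @export
wf_config <- function(pop_size = 100, chrom_length_bp = 1e5,
                      mu = 1.25e-5, rec = 1.25e-5,
                      burn_in_generations = 10 * pop_size,
                      sample_size = 25, chrom = "chr1", seed = NULL) {
  stopifnot(pop_size >= 2, chrom_length_bp >= 1, mu >= 0, rec >= 0,
            burn_in_generations >= 0, sample_size >= 1,
            sample_size <= pop_size)
  structure(list(pop_size = as.integer(pop_size),
                 chrom_length_bp = as.integer(chrom_length_bp),
                 mu = mu, rec = rec,
                 burn_in_generations = as.integer(burn_in_generations),
                 sample_size = as.integer(sample_size),
                 chrom = chrom, seed = seed),
            class = "wf_config")
}

#' Simulate linked haplotypes with a forward Wright-Fisher model
#'
#' Simulates a diploid panmictic population of constant size forward in time
#' from a monomorphic start: each offspring haplotype is a recombinant of one
#' random parent's two haplotypes, and `Poisson(mu * L)` mutations per gamete
#' flip the allele at uniform positions. After the burn-in, `sample_size`
#' diploids are emitted at the sites still segregating among them. At
#' equilibrium the per-site nucleotide diversity approaches
#' `theta = 4 * N * mu`.
#'
#' @param cfg a [wf_config()].
#' @return a [genotypes()] object (zero sites, with a warning, if no site
#'   segregates in the sample).
#' @export
simulate_linked <- function(cfg = wf_config()) {
  stopifnot(inherits(cfg, "wf_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  N <- cfg$pop_size; L <- cfg$chrom_length_bp
  mu_tot <- cfg$mu * L; rec_tot <- cfg$rec * L
  n_hap <- 2L * N
  pos <- integer(0)                      # segregating positions, sorted
  H <- matrix(0L, nrow = 0L, ncol = n_hap)   # sites x haplotypes
  for (gen in seq_len(cfg$burn_in_generations)) {
    S <- length(pos)
    parents <- sample.int(N, n_hap, replace = TRUE)
    start <- sample.int(2L, n_hap, replace = TRUE)
    n_mut <- stats::rpois(n_hap, mu_tot)
    n_cross <- stats::rpois(n_hap, rec_tot)
    # non-recombinant gametes copy one parental haplotype wholesale
    G <- H[, 2L * parents - 2L + start, drop = FALSE]
    for (i in which(n_cross > 0L)) {
      bp <- sort(stats::runif(n_cross[i], 0, L))
      seg <- findInterval(pos, bp) %% 2L == 1L
      gam <- H[, 2L * parents[i] - 2L + start[i]]
      gam[seg] <- H[, 2L * parents[i] - 1L + (start[i] == 1L)][seg]
      G[, i] <- gam
    }
    new_pos <- vector("list", n_hap)
    for (i in which(n_mut > 0L)) {
      mp <- sample.int(L, n_mut[i])
      j <- match(mp, pos)
      hit <- !is.na(j)
      if (any(hit)) G[j[hit], i] <- 1L - G[j[hit], i]
      if (any(!hit)) new_pos[[i]] <- mp[!hit]
    }
    np <- unique(unlist(new_pos))
    if (length(np)) {
      add <- matrix(0L, nrow = length(np), ncol = n_hap)
      for (i in seq_len(n_hap)) {
        if (length(new_pos[[i]]))
          add[match(new_pos[[i]], np), i] <- 1L
      }
      G <- rbind(G, add)
      pos <- c(pos, np)
      ord <- order(pos)
      pos <- pos[ord]
      G <- G[ord, , drop = FALSE]
    }
    # drop fixed and lost sites
    cs <- rowSums(G)
    seg <- cs > 0L & cs < n_hap
    if (!all(seg)) {
      G <- G[seg, , drop = FALSE]
      pos <- pos[seg]
    }
    H <- G
  }
  take <- sort(sample.int(N, cfg$sample_size))
  cols <- as.vector(rbind(2L * take - 1L, 2L * take))
  Hs <- t(H[, cols, drop = FALSE])
  cs <- colSums(Hs)
  seg <- cs > 0L & cs < nrow(Hs)
  if (!any(seg)) {
    warning("no segregating sites in the sampled individuals")
    return(genotypes(matrix(integer(0), nrow = cfg$sample_size, ncol = 0),
                     chrom = character(0), pos = integer(0),
                     sample_ids = paste0("WF_", seq_len(cfg$sample_size))))
  }
  Hs <- Hs[, seg, drop = FALSE]
  dos <- Hs[seq(1L, nrow(Hs), by = 2L), , drop = FALSE] +
    Hs[seq(2L, nrow(Hs), by = 2L), , drop = FALSE]
  genotypes(dos, chrom = rep(cfg$chrom, sum(seg)), pos = pos[seg],
            sample_ids = paste0("WF_", seq_len(cfg$sample_size)))
}
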