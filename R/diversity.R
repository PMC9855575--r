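#' Sliding windows over chromosomes
#'
#' Builds the window grid used by all windowed statistics: windows of
#' `window_size` bp starting at 0 and every `step` bp thereafter, in 0-based
#' half-open coordinates, fully contained in the chromosome. A trailing
#' region shorter than `window_size` produces no window, so a chromosome
#' shorter than one window contributes none.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths in bp.
#' @param window_size window size in bp (default 10 kb).
#' @param step step between window starts in bp (default 5 kb).
#' @return a data.frame (class `"windows"`) with columns `chrom`, `start`,
#'   `end`, ordered by chromosome then start.
#' @export
#' @examples
#' make_windows(c(chr1 = 25000))          # starts 0, 5000, 10000, 15000
make_windows <- function(chrom_lengths, window_size = 10000, step = 5000) {
  stopifnot(window_size >= step, step >= 1)
  if (is.null(names(chrom_lengths))) stop("chrom_lengths must be named")
  out <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    if (len < window_size) return(NULL)
    starts <- seq(0, len - window_size, by = step)
    data.frame(chrom = ch, start = starts, end = starts + window_size)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0))
  class(out) <- c("windows", "data.frame")
  out
}

#' Per-site nucleotide diversity
#'
#' Unbiased per-site heterozygosity: with `c` ALT alleles among `n2`
#' non-missing alleles, `pi = 2 c (n2 - c) / (n2 (n2 - 1))` — the probability
#' that two alleles drawn without replacement differ.
#'
#' @param ac ALT allele count(s).
#' @param an non-missing allele number(s) (2 x genotyped samples).
#' @return numeric vector; `NA` where `an < 2`.
#' @export
#' @examples
#' site_pi(2, 4)   # 8/12
site_pi <- function(ac, an) {
  out <- 2 * ac * (an - ac) / (an * (an - 1))
  out[an < 2] <- NA_real_
  out
}

# Tajima (1989) normalising constants for sample size n (alleles), vectorised.
tajima_constants <- function(n) {
  n <- as.integer(n)
  maxn <- max(n, 2L)
  h1 <- cumsum(1 / seq_len(maxn))        # harmonic numbers
  h2 <- cumsum(1 / seq_len(maxn)^2)
  a1 <- h1[pmax(n - 1L, 1L)]
  a2 <- h2[pmax(n - 1L, 1L)]
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  bad <- n < 2L
  if (any(bad)) {
    a1[bad] <- NA; e1[bad] <- NA; e2[bad] <- NA
  }
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = e1, e2 = e2)
}

# Tajima's D from the summed per-site pi, segregating-site count and sample
# size n (alleles). NA when S = 0 or n < 2.
tajima_d_stat <- function(pi_sum, S, n) {
  k <- tajima_constants(n)
  d <- (pi_sum - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
  d[S == 0 | n < 2] <- NA_real_
  d
}

#' Sliding-window diversity statistics per population
#'
#' For every window and population: the number of segregating sites `S`
#' (polymorphic within the population, at least two non-missing alleles),
#' Watterson's estimator `theta_w = S / (a1 * L)`, nucleotide diversity
#' `theta_pi = sum(site_pi) / L`, and Tajima's D, where `a1` is the harmonic
#' number for the window's sample size `n` (the rounded mean non-missing
#' allele count over the window's sites with data — robust to scattered
#' missingness) and `L` is the window length in bp. With
#' `mode = "per_variant"` the denominator `L` is the segregating-site count
#' instead, for data whose callable-site fraction is unknown. Windows with no
#' segregating sites report `theta = 0` and Tajima's D as `NA` (undefined).
#'
#' @param g a [genotypes()] object.
#' @param popmap named character vector from [read_popmap()].
#' @param windows a window grid from [make_windows()].
#' @param mode denominator convention, `"per_bp"` (default) or
#'   `"per_variant"`.
#' @param populations optional subset of populations to compute.
#' @return a data.frame with columns `chrom`, `start`, `end`, `population`,
#'   `n_sites`, `theta_w`, `theta_pi`, `tajima_d`, ordered by window then
#'   population.
#' @export
window_diversity <- function(g, popmap, windows,
                             mode = c("per_bp", "per_variant"),
                             populations = NULL) {
  mode <- match.arg(mode)
  pm <- check_popmap(g, popmap)
  if (is.null(populations)) populations <- unique(unname(pm))
  if (!all(populations %in% pm))
    stop("population absent from map: ",
         paste(setdiff(populations, pm), collapse = ", "))
  res <- vector("list", length(populations))
  for (k in seq_along(populations)) {
    pop <- populations[k]
    idx <- which(pm == pop)
    a <- alt_counts(g, idx)
    has_data <- a$an >= 2L
    seg <- has_data & a$ac > 0L & a$ac < a$an
    spi <- site_pi(a$ac, a$an)
    spi[!seg] <- 0
    spi[!has_data] <- 0
    stats <- window_sums(g, windows,
                         cbind(S = as.numeric(seg), pi = spi,
                               an = ifelse(has_data, a$an, 0),
                               nd = as.numeric(has_data)))
    S <- stats[, "S"]
    pi_sum <- stats[, "pi"]
    n_alleles <- round(ifelse(stats[, "nd"] > 0,
                              stats[, "an"] / stats[, "nd"], 0))
    L <- if (mode == "per_bp") windows$end - windows$start else pmax(S, 1)
    k1 <- tajima_constants(pmax(n_alleles, 2))
    theta_w <- ifelse(n_alleles >= 2, S / (k1$a1 * L), NA_real_)
    theta_pi <- ifelse(stats[, "nd"] > 0, pi_sum / L, NA_real_)
    tajd <- tajima_d_stat(pi_sum, S, n_alleles)
    res[[k]] <- data.frame(chrom = windows$chrom, start = windows$start,
                           end = windows$end, population = pop,
                           n_sites = as.integer(S), theta_w = theta_w,
                           theta_pi = theta_pi, tajima_d = tajd)
  }
  out <- do.call(rbind, res)
  ord <- order(match(out$chrom, unique(windows$chrom)), out$start,
               match(out$population, populations))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Sum per-site values over windows. `values` is a matrix with one row per
# site of g; returns one row per window. Uses cumulative sums per chromosome,
# so overlapping windows cost O(1) each.
window_sums <- function(g, windows, values) {
  values <- as.matrix(values)
  out <- matrix(0, nrow = nrow(windows), ncol = ncol(values),
                dimnames = list(NULL, colnames(values)))
  for (ch in unique(windows$chrom)) {
    sidx <- which(g$chrom == ch)
    widx <- which(windows$chrom == ch)
    if (!length(widx)) next
    if (!length(sidx)) next
    pos <- g$pos[sidx]
    cs <- apply(values[sidx, , drop = FALSE], 2, cumsum)
    cs <- rbind(0, cs)
    # window [start, end) covers 1-based positions start+1 .. end
    lo <- findInterval(windows$start[widx], pos)        # sites with pos <= start
    hi <- findInterval(windows$end[widx], pos)          # sites with pos <= end
    out[widx, ] <- cs[hi + 1L, , drop = FALSE] - cs[lo + 1L, , drop = FALSE]
  }
  out
}

#' Expected and observed heterozygosity per population
#'
#' Per site within a population: `He = 2 p (1 - p)` with `p` the ALT
#' frequency among non-missing alleles, and `Ho` the fraction of heterozygous
#' genotypes among non-missing ones. The population value is the mean over
#' sites polymorphic in the whole dataset; sites with no data in a population
#' are skipped for that population.
#'
#' @inheritParams window_diversity
#' @return a data.frame with columns `population`, `He`, `Ho`, `n_sites`.
#' @export
heterozygosity <- function(g, popmap) {
  pm <- check_popmap(g, popmap)
  if (n_sites(g) < 1L) stop("no sites")
  all_a <- alt_counts(g)
  poly <- all_a$ac > 0L & all_a$ac < all_a$an
  pops <- unique(unname(pm))
  out <- data.frame(population = pops, He = NA_real_, Ho = NA_real_,
                    n_sites = NA_integer_)
  for (k in seq_along(pops)) {
    idx <- which(pm == pops[k])
    d <- g$dosages[idx, , drop = FALSE]
    n_geno <- colSums(!is.na(d))
    use <- poly & n_geno >= 1L
    p <- colSums(d, na.rm = TRUE)[use] / (2 * n_geno[use])
    he <- 2 * p * (1 - p)
    ho <- colSums(d[, use, drop = FALSE] == 1L, na.rm = TRUE) / n_geno[use]
    out$He[k] <- mean(he)
    out$Ho[k] <- mean(ho)
    out$n_sites[k] <- sum(use)
  }
  out
}

#' Genome-wide diversity summary table
#'
#' One row per population with `He`, `Ho`, genome-wide `theta_w`, `theta_pi`
#' and Tajima's D. The windowed statistics are aggregated as the unweighted
#' mean over windows (windows with undefined values excluded).
#'
#' @inheritParams window_diversity
#' @return a data.frame with columns `population`, `He`, `Ho`, `theta_w`,
#'   `theta_pi`, `tajima_d`.
#' @export
diversity_summary <- function(g, popmap, windows,
                              mode = c("per_bp", "per_variant")) {
  het <- heterozygosity(g, popmap)
  wd <- window_diversity(g, popmap, windows, mode = mode)
  agg <- function(v, pop) mean(v[wd$population == pop], na.rm = TRUE)
  het$theta_w <- vapply(het$population, function(p) agg(wd$theta_w, p), 0)
  het$theta_pi <- vapply(het$population, function(p) agg(wd$theta_pi, p), 0)
  het$tajima_d <- vapply(het$population, function(p) agg(wd$tajima_d, p), 0)
  het[, c("population", "He", "Ho", "theta_w", "theta_pi", "tajima_d")]
}
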