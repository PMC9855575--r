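#' Squared correlation between two dosage vectors
#'
#' Composite (genotype) linkage disequilibrium: the squared Pearson
#' correlation of ALT-allele dosages over the samples genotyped at both
#' sites. Phase is not used. Invariant to allele relabelling
#' (`dosage -> 2 - dosage`) at either site.
#'
#' @param g_i,g_j numeric dosage vectors of equal length (`NA` = missing).
#' @return r-squared, or `NA` if fewer than two shared samples or either
#'   site is monomorphic among them.
#' @export
#' @examples
#' pair_r2(c(2, 0, 1), c(2, 0, 1))   # 1
pair_r2 <- function(g_i, g_j) {
  ok <- !is.na(g_i) & !is.na(g_j)
  if (sum(ok) < 2L) return(NA_real_)
  x <- g_i[ok]; y <- g_j[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

#' Linkage-disequilibrium decay curve for one population
#'
#' Computes r-squared for intra-chromosome site pairs up to `max_dist` bp
#' apart within one population's samples, and averages it in half-open
#' distance bins `[lo, hi)` of width `bin_width`. When the number of
#' eligible pairs exceeds `max_pairs`, a seeded random subsample of pairs is
#' used. Monomorphic sites (within the population) are excluded; pairs with
#' undefined r-squared are excluded from the bins.
#'
#' @param g a [genotypes()] object.
#' @param popmap named character vector mapping sample to population.
#' @param population population label to analyse.
#' @param max_dist maximum pair distance in bp (default 300 kb).
#' @param bin_width distance bin width in bp (default 5 kb).
#' @param max_pairs cap on the number of site pairs (default 1e6).
#' @param seed RNG seed for pair subsampling.
#' @return a data.frame of class `"ld_decay"` with columns `population`,
#'   `bin_lo`, `bin_hi`, `mean_r2`, `n_pairs`.
#' @export
ld_decay <- function(g, popmap, population, max_dist = 3e5, bin_width = 5e3,
                     max_pairs = 1e6, seed = NULL) {
  stopifnot(max_dist >= 1, bin_width >= 1, max_pairs >= 1)
  idx <- pop_index(g, popmap, population)
  d <- g$dosages[idx, , drop = FALSE]
  if (nrow(d) < 2L) stop("population has fewer than 2 samples")
  nm <- colSums(!is.na(d))
  p <- colSums(d, na.rm = TRUE) / (2 * nm)
  poly <- nm >= 2L & p > 0 & p < 1
  pi_idx <- pj_idx <- integer(0)
  for (ch in unique(g$chrom)) {
    s <- which(poly & g$chrom == ch)
    if (length(s) < 2L) next
    pos <- g$pos[s]
    hi <- findInterval(pos + max_dist, pos)
    n_each <- hi - seq_along(s)
    use <- n_each > 0L
    if (!any(use)) next
    ii <- rep(seq_along(s)[use], n_each[use])
    jj <- sequence(n_each[use]) + ii
    pi_idx <- c(pi_idx, s[ii])
    pj_idx <- c(pj_idx, s[jj])
  }
  bins <- data.frame(population = population,
                     bin_lo = seq(0, max_dist - bin_width, by = bin_width),
                     bin_hi = seq(bin_width, max_dist, by = bin_width),
                     mean_r2 = NA_real_, n_pairs = 0L)
  class(bins) <- c("ld_decay", "data.frame")
  if (!length(pi_idx)) {
    warning("no eligible site pairs for population ", population)
    return(bins)
  }
  if (length(pi_idx) > max_pairs) {
    if (!is.null(seed)) set.seed(seed)
    take <- sample.int(length(pi_idx), max_pairs)
    pi_idx <- pi_idx[take]; pj_idx <- pj_idx[take]
  }
  dist <- abs(g$pos[pj_idx] - g$pos[pi_idx])
  A <- d; A[is.na(A)] <- 0
  M <- (!is.na(d)) + 0
  r2 <- numeric(length(pi_idx))
  chunk <- 20000L
  for (lo in seq(1L, length(pi_idx), by = chunk)) {
    hi2 <- min(lo + chunk - 1L, length(pi_idx))
    I <- pi_idx[lo:hi2]; J <- pj_idx[lo:hi2]
    MM <- M[, I, drop = FALSE] * M[, J, drop = FALSE]
    XI <- A[, I, drop = FALSE] * MM
    XJ <- A[, J, drop = FALSE] * MM
    n <- colSums(MM)
    sx <- colSums(XI); sy <- colSums(XJ)
    sxx <- colSums(XI * XI); syy <- colSums(XJ * XJ)
    sxy <- colSums(XI * XJ)
    vx <- n * sxx - sx^2
    vy <- n * syy - sy^2
    num <- (n * sxy - sx * sy)^2
    r <- ifelse(n >= 2 & vx > 0 & vy > 0, num / (vx * vy), NA_real_)
    r2[lo:hi2] <- r
  }
  bin <- findInterval(dist, bins$bin_lo)     # half-open [lo, hi)
  ok <- !is.na(r2) & bin >= 1 & bin <= nrow(bins) & dist < max_dist
  if (any(ok)) {
    sums <- tapply(r2[ok], bin[ok], sum)
    cnts <- tapply(r2[ok], bin[ok], length)
    b <- as.integer(names(sums))
    bins$mean_r2[b] <- sums / cnts
    bins$n_pairs[b] <- as.integer(cnts)
  }
  bins
}
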