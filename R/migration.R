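#' Differentiation between a population and the migrant pool
#'
#' Core arithmetic of the directional relative-migration method: for a
#' population pair the hypothetical migrant pool has per-site allele
#' frequency `(p_a + p_b) / 2`; each population is then compared against the
#' pool. For units x and y (a population and the pool), per site
#' `Hs = (2 p_x (1 - p_x) + 2 p_y (1 - p_y)) / 2` and `Ht = 2 pbar (1 - pbar)`
#' with `pbar = (p_x + p_y) / 2`; sums are taken over sites before ratios:
#' `Gst = (sum Ht - sum Hs) / sum Ht` and Jost's
#' `D = 2 (sum Ht - sum Hs) / sum(1 - Hs)` (the factor 2 is
#' `n_units / (n_units - 1)` for two units).
#'
#' @param freq_a,freq_b per-site allele frequencies of the two populations
#'   over their shared non-missing sites.
#' @return a list with elements `gst` and `jost_d`, each a named vector with
#'   entries `a` and `b`: the differentiation of that population from the
#'   pair's migrant pool. `NA` when there is no variation (`sum Ht = 0`).
#' @export
pooled_stats <- function(freq_a, freq_b) {
  stopifnot(length(freq_a) == length(freq_b))
  pool <- (freq_a + freq_b) / 2
  one <- function(px) {
    hs <- (2 * px * (1 - px) + 2 * pool * (1 - pool)) / 2
    pbar <- (px + pool) / 2
    ht <- 2 * pbar * (1 - pbar)
    sht <- sum(ht); shs <- sum(hs)
    if (sht == 0) return(c(gst = NA_real_, jost_d = NA_real_))
    c(gst = (sht - shs) / sht,
      jost_d = 2 * (sht - shs) / sum(1 - hs))
  }
  a <- one(freq_a); b <- one(freq_b)
  list(gst = c(a = unname(a["gst"]), b = unname(b["gst"])),
       jost_d = c(a = unname(a["jost_d"]), b = unname(b["jost_d"])))
}

# Directed relative-migration matrix for a fixed sample assignment.
# m[a, b] = migration from a INTO b: lower differentiation between the pair's
# migrant pool and recipient b means more immigration into b.
raw_migration_matrix <- function(g, pm, pops, statistic) {
  n <- length(pops)
  m <- matrix(NA_real_, n, n, dimnames = list(pops, pops))
  freqs <- lapply(pops, function(p) {
    idx <- which(pm == p)
    a <- alt_counts(g, idx)
    list(p = a$ac / a$an, has = a$an >= 1L)
  })
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      shared <- freqs[[i]]$has & freqs[[j]]$has
      if (!any(shared)) next
      ps <- pooled_stats(freqs[[i]]$p[shared], freqs[[j]]$p[shared])
      d <- if (statistic == "jost_d") ps$jost_d else ps$gst
      rate <- function(dx) {
        if (is.na(dx)) return(NA_real_)
        if (dx <= 0) return(Inf)          # capped to max finite rate later
        if (statistic == "nm") (1 / dx - 1) / 4 else (1 - dx) / dx
      }
      m[j, i] <- rate(d[["a"]])           # into pop i (pool vs i)
      m[i, j] <- rate(d[["b"]])           # into pop j
    }
  }
  fin <- m[is.finite(m)]
  cap <- if (length(fin)) max(fin) else 1
  m[is.infinite(m)] <- cap
  mx <- max(m, na.rm = TRUE)
  if (is.finite(mx) && mx > 0) m <- m / mx
  m
}

#' Directional relative-migration network
#'
#' divMigrate-style analysis: for every ordered population pair, a
#' hypothetical migrant pool is formed (mean allele frequencies) and the
#' differentiation between the pool and the recipient population is turned
#' into a relative migration rate `(1 - d) / d` (or the Nm transform
#' `(1/d - 1) / 4` for `statistic = "nm"`). The full directed matrix is
#' divided by its maximum, so rates are relative with the strongest edge
#' equal to 1. Edges below `filter_threshold` are flagged hidden (never
#' deleted). Bootstrap resamples individuals with replacement within
#' populations and reports percentile confidence intervals per edge.
#'
#' @param g a [genotypes()] object.
#' @param popmap named character vector mapping sample to population.
#' @param statistic `"gst"` (default), `"jost_d"` or `"nm"`.
#' @param bootstraps number of bootstrap replicates (default 1000; 0 skips
#'   the bootstrap).
#' @param filter_threshold relative rate below which an edge is flagged
#'   hidden (default 0.2).
#' @param seed optional RNG seed for the bootstrap.
#' @return a list of class `"migration_network"`: `labels`, `statistic`,
#'   `m` (directed relative-rate matrix, `m[a, b]` = a into b, diagonal NA),
#'   `hidden` (logical matrix), `filter_threshold` and, when bootstrapped,
#'   `boot_mean`, `boot_ci_low`, `boot_ci_high`.
#' @export
directional_network <- function(g, popmap, statistic = c("gst", "jost_d", "nm"),
                                bootstraps = 1000, filter_threshold = 0.2,
                                seed = NULL) {
  statistic <- match.arg(statistic)
  stopifnot(bootstraps >= 0, filter_threshold >= 0, filter_threshold <= 1)
  pm <- check_popmap(g, popmap)
  pops <- unique(unname(pm))
  if (length(pops) < 2L) stop("need at least two populations")
  if (!is.null(seed)) set.seed(seed)
  m <- raw_migration_matrix(g, pm, pops, statistic)
  out <- list(labels = pops, statistic = statistic, m = m,
              hidden = !is.na(m) & m < filter_threshold,
              filter_threshold = filter_threshold)
  if (bootstraps > 0) {
    idx_by_pop <- lapply(pops, function(p) which(pm == p))
    boots <- array(NA_real_, c(length(pops), length(pops), bootstraps),
                   dimnames = list(pops, pops, NULL))
    for (b in seq_len(bootstraps)) {
      take <- unlist(lapply(idx_by_pop, function(ix)
        ix[sample.int(length(ix), length(ix), replace = TRUE)]))
      gb <- g$dosages[take, , drop = FALSE]
      gboot <- g
      gboot$dosages <- gb
      boots[, , b] <- raw_migration_matrix(gboot, pm[take], pops, statistic)
    }
    out$boot_mean <- apply(boots, c(1, 2), mean, na.rm = TRUE)
    out$boot_ci_low <- apply(boots, c(1, 2), stats::quantile, probs = 0.025,
                             na.rm = TRUE, names = FALSE)
    out$boot_ci_high <- apply(boots, c(1, 2), stats::quantile, probs = 0.975,
                              na.rm = TRUE, names = FALSE)
    dimnames(out$boot_mean) <- dimnames(out$boot_ci_low) <-
      dimnames(out$boot_ci_high) <- dimnames(m)
    out$boot <- boots
  }
  class(out) <- "migration_network"
  out
}

#' @export
print.migration_network <- function(x, digits = 3, ...) {
  cat("Directional relative-migration network (", x$statistic, ")\n", sep = "")
  print(round(x$m, digits), na.print = ".")
  n_hidden <- sum(x$hidden, na.rm = TRUE)
  cat(n_hidden, "edge(s) below filter threshold", x$filter_threshold, "\n")
  invisible(x)
}

#' Edge list of a migration network
#'
#' @param net a [directional_network()] result.
#' @return a data.frame with columns `from`, `to`, `statistic`,
#'   `relative_rate`, `boot_ci_low`, `boot_ci_high`, `hidden`.
#' @export
migration_edges <- function(net) {
  stopifnot(inherits(net, "migration_network"))
  n <- length(net$labels)
  ij <- which(row(net$m) != col(net$m), arr.ind = TRUE)
  ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE]
  data.frame(from = net$labels[ij[, 1]], to = net$labels[ij[, 2]],
             statistic = net$statistic,
             relative_rate = net$m[ij],
             boot_ci_low = if (!is.null(net$boot_ci_low))
               net$boot_ci_low[ij] else NA_real_,
             boot_ci_high = if (!is.null(net$boot_ci_high))
               net$boot_ci_high[ij] else NA_real_,
             hidden = net$hidden[ij])
}
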