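# Per-site FST components for one population pair.
# Returns a matrix with columns `num` and `den` whose ratio-of-sums is the
# estimate, plus a `valid` flag; invalid sites contribute nothing.
fst_site_components <- function(g, idx_a, idx_b,
                                estimator = c("weir_cockerham", "hudson")) {
  estimator <- match.arg(estimator)
  da <- g$dosages[idx_a, , drop = FALSE]
  db <- g$dosages[idx_b, , drop = FALSE]
  na_i <- colSums(!is.na(da))            # genotyped individuals
  nb_i <- colSums(!is.na(db))
  pa <- colSums(da, na.rm = TRUE) / (2 * na_i)
  pb <- colSums(db, na.rm = TRUE) / (2 * nb_i)
  if (estimator == "hudson") {
    # Bhatia et al. (2013) form with within-population correction terms
    valid <- na_i >= 1L & nb_i >= 1L & (2 * na_i) >= 2L & (2 * nb_i) >= 2L
    n1 <- 2 * na_i; n2 <- 2 * nb_i
    num <- (pa - pb)^2 - pa * (1 - pa) / (n1 - 1) - pb * (1 - pb) / (n2 - 1)
    den <- pa * (1 - pb) + pb * (1 - pa)
  } else {
    # Weir & Cockerham (1984) variance components a, b, c for r = 2
    ha <- colSums(da == 1L, na.rm = TRUE) / na_i   # observed het freq
    hb <- colSums(db == 1L, na.rm = TRUE) / nb_i
    r <- 2
    nbar <- (na_i + nb_i) / r
    valid <- na_i >= 1L & nb_i >= 1L & nbar > 1
    nc <- (r * nbar - (na_i^2 + nb_i^2) / (r * nbar)) / (r - 1)
    pbar <- (na_i * pa + nb_i * pb) / (r * nbar)
    s2 <- (na_i * (pa - pbar)^2 + nb_i * (pb - pbar)^2) / ((r - 1) * nbar)
    hbar <- (na_i * ha + nb_i * hb) / (r * nbar)
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
    cc <- hbar / 2
    num <- a
    den <- a + b + cc
  }
  num[!valid] <- 0
  den[!valid] <- 0
  cbind(num = num, den = den, valid = as.numeric(valid))
}

#' Pairwise FST between two populations
#'
#' Ratio-of-sums FST for one population pair, genome-wide and (optionally) in
#' sliding windows. Two estimators are provided: `"weir_cockerham"` — the
#' Weir & Cockerham (1984) variance components `a / (a + b + c)` — and
#' `"hudson"` — the Hudson estimator in the Bhatia et al. form, numerator
#' `(p1 - p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)`, denominator
#' `p1(1-p2) + p2(1-p1)` with `n` the non-missing allele counts. Components
#' are summed over sites before taking the ratio (never a mean of per-site
#' ratios); sites lacking data in either population are skipped. Negative
#' window estimates are reported as computed.
#'
#' @param g a [genotypes()] object.
#' @param popmap named character vector mapping sample to population.
#' @param pop_a,pop_b population labels.
#' @param windows optional window grid from [make_windows()].
#' @param estimator `"weir_cockerham"` (default) or `"hudson"`.
#' @return a list of class `"fst_result"` with `pop_a`, `pop_b`, `estimator`,
#'   `global_fst`, `n_sites` (sites used) and, when `windows` is given,
#'   `window_fst`: a data.frame `chrom`, `start`, `end`, `n_sites`, `fst`.
#' @export
fst_pair <- function(g, popmap, pop_a, pop_b, windows = NULL,
                     estimator = c("weir_cockerham", "hudson")) {
  estimator <- match.arg(estimator)
  idx_a <- pop_index(g, popmap, pop_a)
  idx_b <- pop_index(g, popmap, pop_b)
  comp <- fst_site_components(g, idx_a, idx_b, estimator)
  if (sum(comp[, "valid"]) == 0) {
    warning("no usable sites for pair ", pop_a, " / ", pop_b)
    global <- NA_real_
  } else {
    den <- sum(comp[, "den"])
    global <- if (den > 0) sum(comp[, "num"]) / den else NA_real_
  }
  out <- list(pop_a = pop_a, pop_b = pop_b, estimator = estimator,
              global_fst = global, n_sites = sum(comp[, "valid"]))
  if (!is.null(windows)) {
    ws <- window_sums(g, windows, comp)
    wfst <- ifelse(ws[, "den"] > 0, ws[, "num"] / ws[, "den"], NA_real_)
    out$window_fst <- data.frame(chrom = windows$chrom,
                                 start = windows$start, end = windows$end,
                                 n_sites = as.integer(ws[, "valid"]),
                                 fst = wfst)
  }
  class(out) <- "fst_result"
  out
}

#' @export
print.fst_result <- function(x, ...) {
  cat(sprintf("FST (%s) %s vs %s: %.4f over %d sites\n", x$estimator,
              x$pop_a, x$pop_b, x$global_fst, x$n_sites))
  if (!is.null(x$window_fst))
    cat("  windowed over", nrow(x$window_fst), "windows\n")
  invisible(x)
}

#' Pairwise FST matrix over all populations
#'
#' Computes [fst_pair()] for every unordered pair and assembles a symmetric
#' matrix (diagonal 0). Printed and written in lower-triangular layout.
#'
#' @inheritParams fst_pair
#' @return a symmetric numeric matrix of class `"fst_matrix"` with
#'   populations as dimnames; the per-pair [fst_pair()] results are attached
#'   as attribute `"pairs"`.
#' @export
fst_matrix <- function(g, popmap, windows = NULL,
                       estimator = c("weir_cockerham", "hudson")) {
  estimator <- match.arg(estimator)
  pm <- check_popmap(g, popmap)
  pops <- unique(unname(pm))
  if (length(pops) < 2L) stop("need at least two populations")
  m <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  pairs <- list()
  for (i in seq_along(pops)[-1]) {
    for (j in seq_len(i - 1L)) {
      fr <- fst_pair(g, popmap, pops[i], pops[j], windows, estimator)
      m[i, j] <- m[j, i] <- fr$global_fst
      pairs[[paste(pops[i], pops[j], sep = "~")]] <- fr
    }
  }
  attr(m, "pairs") <- pairs
  class(m) <- "fst_matrix"
  m
}

#' @export
print.fst_matrix <- function(x, digits = 4, ...) {
  m <- unclass(x)
  attr(m, "pairs") <- NULL
  m[upper.tri(m, diag = TRUE)] <- NA
  cat("Pairwise FST (lower triangle):\n")
  print(round(m[-1, -ncol(m), drop = FALSE], digits), na.print = "")
  invisible(x)
}
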