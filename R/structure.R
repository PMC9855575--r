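#' PCA on a genotype matrix
#'
#' Principal component analysis of the sample-by-site dosage matrix. Missing
#' dosages are imputed to the per-site mean; monomorphic sites are dropped;
#' each site is centred and, with the default `"patterson"` scaling, divided
#' by `sqrt(2 * p * (1 - p))` with `p` the mean dosage / 2 — the
#' population-genetics normalisation that equalises the drift variance of
#' sites across allele frequencies. Eigendecomposition of the sample
#' covariance yields scores and the fraction of total variance per component.
#'
#' @param g a [genotypes()] object (>= 2 samples, >= 2 sites).
#' @param scaling `"patterson"` (default) or `"center_only"`.
#' @param k number of components to return (default `min(n - 1, 10)`).
#' @return a list of class `"genotype_pca"`: `coordinates` (samples x k),
#'   `variance_explained` (length k, fractions of total variance),
#'   `n_sites_used`.
#' @export
pca_genotypes <- function(g, scaling = c("patterson", "center_only"),
                          k = NULL) {
  scaling <- match.arg(scaling)
  if (n_samples(g) < 2L || n_sites(g) < 2L)
    stop("PCA needs at least 2 samples and 2 sites")
  X <- g$dosages
  mu <- colMeans(X, na.rm = TRUE)
  miss <- which(is.na(X))
  if (length(miss))
    X[miss] <- mu[(miss - 1L) %/% nrow(X) + 1L]
  p <- mu / 2
  keep <- p > 0 & p < 1 & apply(X, 2, stats::var) > 0
  if (!any(keep)) stop("all sites monomorphic; PCA undefined")
  X <- X[, keep, drop = FALSE]
  p <- p[keep]
  X <- sweep(X, 2L, mu[keep])
  if (scaling == "patterson")
    X <- sweep(X, 2L, sqrt(2 * p * (1 - p)), "/")
  C <- tcrossprod(X) / ncol(X)
  e <- eigen(C, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  if (is.null(k)) k <- min(n_samples(g) - 1L, 10L)
  k <- min(k, length(ev))
  coords <- e$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(ev[seq_len(k)]), k)
  dimnames(coords) <- list(g$sample_ids, paste0("PC", seq_len(k)))
  structure(list(coordinates = coords,
                 variance_explained = ev[seq_len(k)] / sum(ev),
                 n_sites_used = ncol(X)),
            class = "genotype_pca")
}

#' @export
print.genotype_pca <- function(x, ...) {
  cat("Genotype PCA over", nrow(x$coordinates), "samples,",
      x$n_sites_used, "sites\n")
  ve <- utils::head(100 * x$variance_explained, 3)
  cat("Top PCs explain:", paste(sprintf("%.2f%%", ve), collapse = ", "), "\n")
  invisible(x)
}

#' Pairwise p-distance between individuals
#'
#' `d(i, j) = sum |g_i - g_j| / (2 * m_ij)` over the `m_ij` sites where both
#' individuals are genotyped: the proportion of allele differences between
#' the two diploid genotypes, in `[0, 1]`.
#'
#' @param g a [genotypes()] object.
#' @return a symmetric matrix with zero diagonal and the sample ids as
#'   dimnames; `NA` (with a warning) for pairs sharing no genotyped site.
#' @export
p_distance <- function(g) {
  d <- g$dosages
  M <- !is.na(d)
  I0 <- (!is.na(d) & d == 0L) + 0
  I1 <- (!is.na(d) & d == 1L) + 0
  I2 <- (!is.na(d) & d == 2L) + 0
  # sum over sites of |a - b|: 1 for {0,1} and {1,2}, 2 for {0,2}
  diff_sum <- tcrossprod(I0, I1) + tcrossprod(I1, I0) +
    tcrossprod(I1, I2) + tcrossprod(I2, I1) +
    2 * (tcrossprod(I0, I2) + tcrossprod(I2, I0))
  m_ij <- tcrossprod(M + 0)
  out <- diff_sum / (2 * m_ij)
  if (any(m_ij == 0 & upper.tri(m_ij))) {
    warning("sample pair(s) share no genotyped site; distance set to NA")
  }
  out[m_ij == 0] <- NA_real_
  diag(out) <- 0
  dimnames(out) <- list(g$sample_ids, g$sample_ids)
  out
}

#' Neighbour-joining tree from a distance matrix
#'
#' Saitou-Nei neighbour joining (via \pkg{ape}) on an individual-level
#' distance matrix, with negative branch lengths clamped to zero afterwards
#' (the deficit is not redistributed). On an additive distance matrix the
#' tree's path lengths reproduce the input exactly.
#'
#' @param d symmetric numeric distance matrix with labelled dimnames (e.g.
#'   from [p_distance()]); no `NA` entries.
#' @return an unrooted `phylo` tree (\pkg{ape}).
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8))
    stop("distance matrix must be symmetric")
  if (anyNA(d)) stop("distance matrix contains NA entries")
  if (nrow(d) < 3L) stop("need at least 3 taxa")
  tr <- ape::nj(stats::as.dist(d))
  tr$edge.length <- pmax(tr$edge.length, 0)
  tr
}

#' Write a square PHYLIP distance matrix
#'
#' @param d symmetric matrix with dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phylip_dist <- function(d, path) {
  d <- as.matrix(d)
  n <- nrow(d)
  lab <- substr(rownames(d), 1, 10)
  lines <- c(sprintf("%5d", n),
             vapply(seq_len(n), function(i) {
               paste0(formatC(lab[i], width = -10),
                      paste(sprintf("%.6f", d[i, ]), collapse = "  "))
             }, ""))
  writeLines(lines, path)
  invisible(path)
}
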