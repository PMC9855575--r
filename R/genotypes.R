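#' Genotype matrix container
#'
#' Builds the central data structure of the package: a diploid dosage matrix
#' (samples in rows, biallelic SNP sites in columns) together with per-site
#' chromosome labels and 1-based bp positions. Dosage is the count of ALT
#' alleles, so values are 0, 1, 2 or `NA` for a missing genotype.
#'
#' Sites must be sorted by chromosome and strictly increasing position within
#' each chromosome; the constructor enforces this ordering (reordering if
#' needed) so that windowed statistics can assume it.
#'
#' @param dosages integer matrix, samples x sites, values in `{0, 1, 2, NA}`.
#' @param chrom character vector of chromosome labels, one per site.
#' @param pos integer vector of 1-based bp positions, one per site.
#' @param sample_ids character vector of sample names; defaults to the
#'   rownames of `dosages` or `S1..Sn`.
#' @param site_ids character vector of site names; defaults to
#'   `chrom_pos`.
#' @param ref,alt optional per-site REF/ALT alleles (single bases); kept so
#'   a matrix read from a VCF round-trips through [write_vcf()].
#'
#' @return An object of class `"genotypes"`: a list with elements `dosages`,
#'   `chrom`, `pos`, `sample_ids`, `site_ids`, `ref`, `alt`.
#' @seealso [read_vcf()], [filter_sites()]
#' @export
#' @examples
#' g <- genotypes(matrix(c(0L, 1L, 2L, NA), 2, 2), chrom = c("c1", "c1"),
#'                pos = c(100L, 200L))
#' g
genotypes <- function(dosages, chrom, pos, sample_ids = NULL, site_ids = NULL,
                      ref = NULL, alt = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  n_sites <- ncol(dosages)
  if (length(chrom) != n_sites || length(pos) != n_sites)
    stop("chrom and pos must have one entry per site (column of dosages)")
  bad <- dosages[!is.na(dosages)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L)))
    stop("dosages must be 0, 1, 2 or NA")
  if (nrow(dosages) < 1L)
    stop("at least one sample required")
  if (is.null(sample_ids)) {
    sample_ids <- rownames(dosages)
    if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(dosages)))
  }
  chrom <- as.character(chrom)
  pos <- as.integer(pos)
  if (is.null(site_ids)) site_ids <- paste(chrom, pos, sep = "_")
  if (is.null(ref)) ref <- rep("A", n_sites)
  if (is.null(alt)) alt <- rep("T", n_sites)
  # canonical site order: by chromosome (first-appearance order), then position
  ord <- order(match(chrom, unique(chrom)), pos)
  if (is.unsorted(ord)) {
    dosages <- dosages[, ord, drop = FALSE]
    chrom <- chrom[ord]; pos <- pos[ord]
    site_ids <- site_ids[ord]; ref <- ref[ord]; alt <- alt[ord]
  }
  if (n_sites > 1L) {
    same <- chrom[-1L] == chrom[-n_sites]
    if (any(same & pos[-1L] <= pos[-n_sites]))
      stop("positions must be strictly increasing within a chromosome ",
           "(duplicate site?)")
  }
  dimnames(dosages) <- list(sample_ids, site_ids)
  structure(list(dosages = dosages, chrom = chrom, pos = pos,
                 sample_ids = sample_ids, site_ids = site_ids,
                 ref = as.character(ref), alt = as.character(alt)),
            class = "genotypes")
}

#' @export
print.genotypes <- function(x, ...) {
  cat("Genotype matrix:", nrow(x$dosages), "samples x", ncol(x$dosages),
      "biallelic sites\n")
  cat("Chromosomes:", paste(utils::head(unique(x$chrom), 5), collapse = ", "),
      if (length(unique(x$chrom)) > 5) "..." else "", "\n")
  miss <- mean(is.na(x$dosages))
  cat(sprintf("Missing genotypes: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotypes <- function(x) dim(x$dosages)

#' Number of samples / sites
#' @param g a [genotypes()] object.
#' @return integer count.
#' @export
n_samples <- function(g) nrow(g$dosages)

#' @rdname n_samples
#' @export
n_sites <- function(g) ncol(g$dosages)

#' Subset a genotype matrix
#'
#' @param x a [genotypes()] object.
#' @param i sample index (logical, integer or names).
#' @param j site index.
#' @param ... ignored.
#' @return a [genotypes()] object.
#' @export
`[.genotypes` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$dosages))
  if (missing(j)) j <- seq_len(ncol(x$dosages))
  if (is.character(i)) i <- match(i, x$sample_ids)
  d <- x$dosages[i, j, drop = FALSE]
  genotypes(d, chrom = x$chrom[j], pos = x$pos[j],
            sample_ids = x$sample_ids[i], site_ids = x$site_ids[j],
            ref = x$ref[j], alt = x$alt[j])
}

#' Per-site allele counts and frequencies
#'
#' `alt_counts()` returns per-site ALT allele counts and non-missing allele
#' totals; `allele_freq()` the ALT allele frequency; `maf()` the minor-allele
#' frequency; `site_missing_rate()` the fraction of samples with a missing
#' genotype. All are computed on non-missing genotypes only.
#'
#' @param g a [genotypes()] object.
#' @param samples optional subset of sample ids / indices.
#' @return `alt_counts()`: a list with integer vectors `ac` (ALT allele count)
#'   and `an` (non-missing allele number); the others a numeric vector with
#'   one entry per site (NaN where no data).
#' @export
alt_counts <- function(g, samples = NULL) {
  d <- g$dosages
  if (!is.null(samples)) d <- d[samples, , drop = FALSE]
  list(ac = colSums(d, na.rm = TRUE), an = 2L * colSums(!is.na(d)))
}

#' @rdname alt_counts
#' @export
allele_freq <- function(g, samples = NULL) {
  a <- alt_counts(g, samples)
  a$ac / a$an
}

#' @rdname alt_counts
#' @export
maf <- function(g, samples = NULL) {
  p <- allele_freq(g, samples)
  pmin(p, 1 - p)
}

#' @rdname alt_counts
#' @export
site_missing_rate <- function(g) colMeans(is.na(g$dosages))

#' Site filtering by missing rate and minor-allele frequency
#'
#' Keeps a site iff its fraction of missing genotypes is strictly less than
#' `max_missing_rate` AND its minor-allele frequency (computed on non-missing
#' alleles) is strictly greater than `min_maf`. The strict inequalities match
#' the usual "missing rate less than 50% and MAF greater than 0.01"
#' convention, so boundary sites are removed. Monomorphic sites (MAF 0) are
#' always removed when `min_maf >= 0`.
#'
#' @param g a [genotypes()] object.
#' @param max_missing_rate maximum tolerated missing fraction (default 0.5).
#' @param min_maf minimum minor-allele frequency (default 0.01).
#' @return the filtered [genotypes()] object, with a `filter_report`
#'   attribute: a list with `n_in`, `n_fail_missing`, `n_fail_maf`, `n_out`.
#'   Sites failing both criteria are counted under both.
#' @export
filter_sites <- function(g, max_missing_rate = 0.5, min_maf = 0.01) {
  stopifnot(max_missing_rate >= 0, max_missing_rate <= 1,
            min_maf >= 0, min_maf <= 0.5)
  miss <- site_missing_rate(g)
  m <- maf(g)
  m[is.nan(m)] <- 0            # all-missing site: no observable polymorphism
  keep <- miss < max_missing_rate & m > min_maf
  report <- list(n_in = n_sites(g),
                 n_fail_missing = sum(miss >= max_missing_rate),
                 n_fail_maf = sum(m <= min_maf),
                 n_out = sum(keep))
  if (!any(keep)) {
    warning("all sites removed by filters")
    out <- g[, 0]
  } else {
    out <- g[, keep]
  }
  attr(out, "filter_report") <- report
  out
}
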