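#' Read a multi-sample VCF into a genotype matrix
#'
#' Parses a VCF 4.x file (via \pkg{vcfR}) and converts GT fields to ALT-allele
#' dosages. Only biallelic SNP records are used: multiallelic records and
#' records whose REF or ALT is not a single base are skipped, with a message
#' reporting the count. Missing genotypes (`./.`) and half-calls (`./1`) are
#' stored as `NA`. Phase separators (`|` vs `/`) are ignored.
#'
#' @param path path to a VCF file (plain text or gzipped).
#' @param region optional region string `"chrom"` or `"chrom:start-end"`
#'   (1-based, inclusive) restricting the sites returned.
#' @return a [genotypes()] object.
#' @export
read_vcf <- function(path, region = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  if (nrow(fix) == 0L) stop("VCF contains no variant records: ", path)
  if (ncol(v@gt) < 2L)
    stop("VCF has no sample columns: ", path)
  format_col <- v@gt[, 1L]
  if (any(!grepl("(^|:)GT(:|$)", format_col))) {
    bad <- which(!grepl("(^|:)GT(:|$)", format_col))[1L]
    stop("record ", fix[bad, "CHROM"], ":", fix[bad, "POS"],
         " has no GT field in FORMAT")
  }
  alt <- fix[, "ALT"]
  ref <- fix[, "REF"]
  snp <- !is.na(alt) & !grepl(",", alt, fixed = TRUE) &
    nchar(ref) == 1L & nchar(alt) == 1L
  n_skip <- sum(!snp)
  if (n_skip > 0L)
    message("read_vcf: skipped ", n_skip, " multiallelic/non-SNP record(s)")
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[snp, , drop = FALSE]
  fix <- fix[snp, , drop = FALSE]
  # GT strings -> dosage via lookup over the handful of diploid codes
  codes <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  norm <- gsub("|", "/", gt, fixed = TRUE)
  dos <- codes[norm]                       # anything unlisted (./., ./1) -> NA
  dos <- matrix(as.integer(dos), nrow = nrow(gt), ncol = ncol(gt))
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste(fix[, "CHROM"], fix[, "POS"],
                                        sep = "_")[is.na(ids) | ids == "."]
  g <- genotypes(t(dos), chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                 sample_ids = colnames(gt), site_ids = ids,
                 ref = ref[snp], alt = alt[snp])
  if (!is.null(region)) {
    m <- regmatches(region, regexec("^([^:]+)(:([0-9]+)-([0-9]+))?$", region))[[1]]
    if (length(m) == 0L) stop("malformed region: ", region)
    keep <- g$chrom == m[2]
    if (m[3] != "")
      keep <- keep & g$pos >= as.integer(m[4]) & g$pos <= as.integer(m[5])
    g <- g[, keep]
  }
  g
}

#' Write a genotype matrix as a minimal VCF 4.2
#'
#' Emits a GT-only VCF (CHROM, POS, ID, REF, ALT, QUAL=., FILTER=PASS,
#' INFO=., FORMAT=GT). REF/ALT default to the placeholder A/T when the matrix
#' was not read from a VCF. `read_vcf(write_vcf(g))` reproduces `g` exactly.
#'
#' @param g a [genotypes()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(g, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"),
             con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", g$sample_ids), collapse = "\t"), con)
  if (n_sites(g) > 0L) {
    code <- c("0/0", "0/1", "1/1")
    gt <- matrix("./.", nrow = n_sites(g), ncol = n_samples(g))
    d <- t(g$dosages)
    ok <- !is.na(d)
    gt[ok] <- code[d[ok] + 1L]
    body <- paste(g$chrom, g$pos, g$site_ids, g$ref, g$alt, ".", "PASS", ".",
                  "GT", sep = "\t")
    body <- paste(body, apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
    writeLines(body, con)
  }
  invisible(path)
}

#' Read / write a sample-to-population map
#'
#' Two-column whitespace- or tab-separated text: sample id, population label.
#' Lines starting with `#` are comments.
#'
#' @param path file path.
#' @return `read_popmap()`: a named character vector mapping sample id to
#'   population label.
#' @export
read_popmap <- function(path) {
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE,
                           col.names = c("sample", "population"))
  if (anyDuplicated(tab$sample))
    stop("duplicate sample id in population map: ",
         tab$sample[duplicated(tab$sample)][1])
  stats::setNames(as.character(tab$population), tab$sample)
}

#' @rdname read_popmap
#' @param popmap named character vector (names = sample ids, values =
#'   population labels).
#' @export
write_popmap <- function(popmap, path) {
  utils::write.table(data.frame(sample = names(popmap),
                                population = unname(popmap)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Validate that every sample of g has a population label; returns the map
# restricted to g's samples, in sample order.
check_popmap <- function(g, popmap) {
  missing <- setdiff(g$sample_ids, names(popmap))
  if (length(missing))
    stop("samples without a population label: ",
         paste(utils::head(missing, 5), collapse = ", "))
  popmap[g$sample_ids]
}

# Indices of the samples belonging to one population.
pop_index <- function(g, popmap, population) {
  pm <- check_popmap(g, popmap)
  idx <- which(pm == population)
  if (!length(idx)) stop("population not present in map: ", population)
  idx
}
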