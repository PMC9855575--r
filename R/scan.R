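#' Reduction of diversity (ROD)
#'
#' `ROD = 1 - theta_pi_introduced / theta_pi_source`: values near 1 indicate
#' near-total diversity loss in the introduced (derived) population relative
#' to the source, the footprint of a selective sweep or extreme bottleneck.
#'
#' @param theta_pi_intro per-site nucleotide diversity of the introduced
#'   population (scalar or vector).
#' @param theta_pi_source per-site nucleotide diversity of the source
#'   population.
#' @return `1 - theta_pi_intro / theta_pi_source`; `NA` where the source
#'   value is 0 or missing.
#' @export
#' @examples
#' rod(0.0034, 0.0045)   # 0.2444
rod <- function(theta_pi_intro, theta_pi_source) {
  if (any(theta_pi_intro < 0, na.rm = TRUE) ||
      any(theta_pi_source < 0, na.rm = TRUE))
    stop("diversities must be non-negative")
  out <- 1 - theta_pi_intro / theta_pi_source
  out[!is.na(theta_pi_source) & theta_pi_source == 0] <- NA_real_
  out
}

#' Flag empirical-quantile outliers
#'
#' Rank-based tail flagging used by the selection scan: with `n` non-missing
#' values and tail fraction `f`, the `ceiling(f * n)` most extreme values are
#' flagged; values tied with the boundary value are all flagged (conservative
#' toward more outliers). Missing values are never flagged.
#'
#' @param values numeric vector (may contain `NA`).
#' @param tail `"top"` (largest values) or `"bottom"` (smallest).
#' @param fraction tail fraction in (0, 1), e.g. 0.05.
#' @return logical vector the length of `values`.
#' @export
flag_outliers <- function(values, tail = c("top", "bottom"), fraction = 0.05) {
  tail <- match.arg(tail)
  stopifnot(fraction > 0, fraction < 1)
  ok <- !is.na(values)
  if (!any(ok)) {
    warning("all values missing; nothing flagged")
    return(rep(FALSE, length(values)))
  }
  n <- sum(ok)
  k <- ceiling(fraction * n)
  sorted <- sort(values[ok], decreasing = (tail == "top"))
  thr <- sorted[k]
  if (tail == "top") ok & values >= thr else ok & values <= thr
}

#' Selection scan of an introduced population against its source
#'
#' Windowed scan for selected regions in a recently introduced population:
#' per window it computes the introduced-vs-source FST, the reduction of
#' diversity `ROD = 1 - theta_pi_intro / theta_pi_source` from the window
#' diversities, and the introduced population's Tajima's D. Outlier windows
#' are flagged by empirical quantiles ([flag_outliers()], tail fraction
#' `fraction`): top FST, top ROD, bottom Tajima's D. A window is a candidate
#' when it is in the FST or ROD top tail AND in the Tajima's-D bottom tail
#' with a negative D (`require_tajima = FALSE` drops the Tajima's-D
#' condition entirely).
#'
#' @param g a [genotypes()] object.
#' @param popmap named character vector mapping sample to population.
#' @param introduced,source population labels (must differ).
#' @param windows window grid from [make_windows()].
#' @param fraction empirical tail fraction (default 0.05).
#' @param estimator FST estimator, see [fst_pair()].
#' @param mode diversity denominator, see [window_diversity()].
#' @param require_tajima apply the Tajima's-D condition (default `TRUE`).
#' @return a data.frame of class `"selection_scan"`: `chrom`, `start`, `end`,
#'   `n_sites`, `fst`, `rod`, `tajima_d`, `fst_top`, `rod_top`,
#'   `tajd_bottom`, `candidate`.
#' @export
selection_scan <- function(g, popmap, introduced, source, windows,
                           fraction = 0.05,
                           estimator = c("weir_cockerham", "hudson"),
                           mode = c("per_bp", "per_variant"),
                           require_tajima = TRUE) {
  if (identical(introduced, source))
    stop("introduced and source populations must differ")
  estimator <- match.arg(estimator)
  mode <- match.arg(mode)
  wd <- window_diversity(g, popmap, windows, mode = mode,
                         populations = c(introduced, source))
  wi <- wd[wd$population == introduced, ]
  ws <- wd[wd$population == source, ]
  fr <- fst_pair(g, popmap, introduced, source, windows, estimator)
  out <- data.frame(chrom = windows$chrom, start = windows$start,
                    end = windows$end, n_sites = wi$n_sites,
                    fst = fr$window_fst$fst,
                    rod = rod(wi$theta_pi, ws$theta_pi),
                    tajima_d = wi$tajima_d)
  out$fst_top <- flag_outliers(out$fst, "top", fraction)
  out$rod_top <- flag_outliers(out$rod, "top", fraction)
  out$tajd_bottom <- flag_outliers(out$tajima_d, "bottom", fraction)
  out$candidate <- (out$fst_top | out$rod_top)
  if (require_tajima)
    out$candidate <- out$candidate & out$tajd_bottom &
      !is.na(out$tajima_d) & out$tajima_d < 0
  class(out) <- c("selection_scan", "data.frame")
  out
}

#' Read gene features from a GFF3 file
#'
#' Parses a GFF3 annotation (via [ape::read.gff()]) and keeps `gene`
#' features. The gene identifier is taken from the `ID=` attribute (falling
#' back to `gene_id` or a positional label).
#'
#' @param path GFF3 file path.
#' @return a data.frame with columns `chrom`, `start`, `end` (1-based
#'   inclusive, as in GFF) and `gene_id`.
#' @export
read_gene_annotation <- function(path) {
  gff <- ape::read.gff(path, GFF3 = TRUE)
  genes <- gff[gff$type == "gene", , drop = FALSE]
  get_id <- function(attr) {
    m <- regmatches(attr, regexec("(^|;)ID=([^;]+)", attr))
    id <- vapply(m, function(x) if (length(x) >= 3) x[3] else NA_character_, "")
    alt <- regmatches(attr, regexec("(^|;)gene_id[= ]\"?([^;\"]+)", attr))
    id2 <- vapply(alt, function(x) if (length(x) >= 3) x[3] else NA_character_, "")
    id[is.na(id)] <- id2[is.na(id)]
    id
  }
  ids <- get_id(as.character(genes$attributes))
  ids[is.na(ids)] <- paste0("gene", seq_len(nrow(genes)))[is.na(ids)]
  data.frame(chrom = as.character(genes$seqid), start = genes$start,
             end = genes$end, gene_id = ids)
}

#' Merge candidate windows into regions and overlap genes
#'
#' Overlapping or book-ended candidate windows on the same chromosome are
#' merged into maximal regions. When a gene annotation is supplied, a gene
#' overlaps a region if their intervals intersect by at least 1 bp (GFF
#' 1-based inclusive coordinates are converted to 0-based half-open); each
#' gene is listed once per region and counted once globally. Genes on
#' chromosomes absent from the scan are skipped with a warning.
#'
#' @param scan a [selection_scan()] result.
#' @param annotation optional gene table from [read_gene_annotation()], or a
#'   GFF3 file path.
#' @return a list of class `"candidate_regions"` with `regions` (data.frame
#'   `chrom`, `start`, `end`, `n_windows`, `gene_ids`) and `genes` (unique
#'   gene ids over all regions).
#' @export
merge_candidates <- function(scan, annotation = NULL) {
  stopifnot(inherits(scan, "selection_scan"))
  cand <- scan[scan$candidate, , drop = FALSE]
  regions <- data.frame(chrom = character(0), start = numeric(0),
                        end = numeric(0), n_windows = integer(0),
                        gene_ids = character(0))
  if (nrow(cand)) {
    parts <- lapply(split(cand, cand$chrom), function(cw) {
      cw <- cw[order(cw$start), , drop = FALSE]
      reg_start <- cw$start[1]; reg_end <- cw$end[1]; n <- 1L
      rows <- list()
      if (nrow(cw) > 1) {
        for (i in 2:nrow(cw)) {
          if (cw$start[i] <= reg_end) {        # overlap or book-ended
            reg_end <- max(reg_end, cw$end[i]); n <- n + 1L
          } else {
            rows[[length(rows) + 1L]] <- data.frame(
              chrom = cw$chrom[1], start = reg_start, end = reg_end,
              n_windows = n)
            reg_start <- cw$start[i]; reg_end <- cw$end[i]; n <- 1L
          }
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(chrom = cw$chrom[1],
                                              start = reg_start,
                                              end = reg_end, n_windows = n)
      do.call(rbind, rows)
    })
    regions <- do.call(rbind, parts)
    regions <- regions[order(match(regions$chrom, unique(scan$chrom)),
                             regions$start), , drop = FALSE]
    rownames(regions) <- NULL
    regions$gene_ids <- ""
  }
  genes_all <- character(0)
  if (!is.null(annotation) && nrow(regions)) {
    if (is.character(annotation)) annotation <- read_gene_annotation(annotation)
    unknown <- !annotation$chrom %in% unique(scan$chrom)
    if (any(unknown)) {
      warning(sum(unknown), " gene(s) on chromosome(s) absent from the scan; ",
              "skipped")
      annotation <- annotation[!unknown, , drop = FALSE]
    }
    g0 <- annotation$start - 1           # to 0-based half-open
    g1 <- annotation$end
    for (r in seq_len(nrow(regions))) {
      hit <- annotation$chrom == regions$chrom[r] &
        g0 < regions$end[r] & g1 > regions$start[r]
      ids <- unique(annotation$gene_id[hit])
      regions$gene_ids[r] <- paste(ids, collapse = ",")
      genes_all <- c(genes_all, ids)
    }
  }
  structure(list(regions = regions, genes = unique(genes_all)),
            class = "candidate_regions")
}

#' @export
print.candidate_regions <- function(x, ...) {
  cat("Candidate selected regions:", nrow(x$regions), "region(s),",
      length(x$genes), "gene(s)\n")
  if (nrow(x$regions))
    print(utils::head(x$regions, 10))
  invisible(x)
}
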