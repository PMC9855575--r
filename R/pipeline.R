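#' Pipeline configuration
#'
#' Assembles all stage parameters with defaults matching the standard
#' analysis settings: 10 kb windows with a 5 kb step, site filters of
#' missing rate < 0.5 and MAF > 0.01, Weir-Cockerham FST, migration networks
#' with 1000 bootstraps and a 0.2 filter threshold, and a 5% empirical tail
#' for the selection scan. Provide either a VCF + population map (real-data
#' mode) or a [scenario_config()] (simulation mode). Unknown arguments are
#' errors.
#'
#' @param vcf,popmap,gff input file paths (real-data mode; `gff` optional).
#' @param scenario a [scenario_config()] (simulation mode).
#' @param window_size,step window grid in bp.
#' @param max_missing,min_maf site filters, see [filter_sites()].
#' @param fst_estimator `"weir_cockerham"` or `"hudson"`.
#' @param diversity_mode `"per_bp"` or `"per_variant"`.
#' @param ld_max_dist,ld_bin_width,ld_max_pairs LD-decay parameters.
#' @param migration_statistic `"gst"`, `"jost_d"` or `"nm"`.
#' @param bootstraps migration bootstrap replicates.
#' @param filter_threshold migration edge filter threshold.
#' @param scan_fraction empirical tail fraction for the selection scan.
#' @param introduced,source population labels for the scan (defaulted from
#'   the scenario in simulation mode).
#' @param chrom_lengths optional named vector; defaults to the largest
#'   observed position per chromosome.
#' @param seed seed driving every stochastic stage; fixed seed gives
#'   byte-identical outputs.
#' @return a list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(vcf = NULL, popmap = NULL, gff = NULL,
                            scenario = NULL,
                            window_size = 10000, step = 5000,
                            max_missing = 0.5, min_maf = 0.01,
                            fst_estimator = "weir_cockerham",
                            diversity_mode = "per_bp",
                            ld_max_dist = 3e5, ld_bin_width = 5e3,
                            ld_max_pairs = 1e6,
                            migration_statistic = "gst",
                            bootstraps = 1000, filter_threshold = 0.2,
                            scan_fraction = 0.05,
                            introduced = NULL, source = NULL,
                            chrom_lengths = NULL, seed = 1L) {
  if (is.null(scenario) && (is.null(vcf) || is.null(popmap)))
    stop("provide either `scenario` or both `vcf` and `popmap`")
  if (!is.null(scenario)) {
    stopifnot(inherits(scenario, "scenario_config"))
    if (is.null(introduced)) introduced <- scenario$introduced_pop
    if (is.null(source)) source <- scenario$source_pop
  }
  structure(list(vcf = vcf, popmap = popmap, gff = gff, scenario = scenario,
                 window_size = window_size, step = step,
                 max_missing = max_missing, min_maf = min_maf,
                 fst_estimator = fst_estimator,
                 diversity_mode = diversity_mode,
                 ld_max_dist = ld_max_dist, ld_bin_width = ld_bin_width,
                 ld_max_pairs = ld_max_pairs,
                 migration_statistic = migration_statistic,
                 bootstraps = bootstraps, filter_threshold = filter_threshold,
                 scan_fraction = scan_fraction,
                 introduced = introduced, source = source,
                 chrom_lengths = chrom_lengths, seed = seed),
            class = "pipeline_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes filter, diversity, FST, PCA, NJ, migration, LD and selection
#' scan in order, writing one TSV/Newick/BED report per stage into
#' `out_dir`, including a per-population diversity summary (He, Ho, theta_w,
#' theta_pi, Tajima's D) and a lower-triangular pairwise-FST matrix. All
#' randomness derives from `cfg$seed`, so a rerun with the same config and
#' inputs reproduces the output directory byte for byte.
#'
#' @param cfg a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return a list of class `"poptrace_run"` with all stage results and
#'   `out_dir`.
#' @export
run_pipeline <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  set.seed(cfg$seed)
  if (!is.null(cfg$scenario)) {
    sim <- stage("simulate", {
      sc <- cfg$scenario
      sc$seed <- NULL                 # RNG already seeded by the pipeline
      simulate_unlinked(sc)
    })
    g <- sim$genotypes
    popmap <- sim$popmap
  } else {
    g <- stage("input", read_vcf(cfg$vcf))
    popmap <- stage("input", read_popmap(cfg$popmap))
  }
  g <- stage("filter", filter_sites(g, cfg$max_missing, cfg$min_maf))
  rep_f <- attr(g, "filter_report")
  message(sprintf(
    "filter: %d sites in, %d failed missing-rate, %d failed MAF, %d kept",
    rep_f$n_in, rep_f$n_fail_missing, rep_f$n_fail_maf, rep_f$n_out))
  chrom_lengths <- cfg$chrom_lengths
  if (is.null(chrom_lengths))
    chrom_lengths <- tapply(g$pos, g$chrom, max)[unique(g$chrom)]
  windows <- make_windows(chrom_lengths, cfg$window_size, cfg$step)

  wd <- stage("diversity",
              window_diversity(g, popmap, windows, mode = cfg$diversity_mode))
  summ <- stage("diversity",
                diversity_summary(g, popmap, windows,
                                  mode = cfg$diversity_mode))
  fstm <- stage("fst", fst_matrix(g, popmap, windows, cfg$fst_estimator))
  pca <- stage("pca", pca_genotypes(g))
  pd <- stage("nj", p_distance(g))
  tree <- stage("nj", nj_tree(pd))
  mig <- stage("migration",
               directional_network(g, popmap, cfg$migration_statistic,
                                   cfg$bootstraps, cfg$filter_threshold))
  pops <- unique(unname(popmap[g$sample_ids]))
  ld <- stage("ld", do.call(rbind, lapply(pops, function(p)
    ld_decay(g, popmap, p, cfg$ld_max_dist, cfg$ld_bin_width,
             cfg$ld_max_pairs))))
  scan <- regions <- NULL
  if (!is.null(cfg$introduced) && !is.null(cfg$source)) {
    scan <- stage("scan",
                  selection_scan(g, popmap, cfg$introduced, cfg$source,
                                 windows, cfg$scan_fraction,
                                 cfg$fst_estimator, cfg$diversity_mode))
    regions <- stage("scan", merge_candidates(scan, cfg$gff))
  }

  # ---- reports -------------------------------------------------------------
  write_tsv(summ, file.path(out_dir, "diversity_summary.tsv"))
  write_tsv(wd, file.path(out_dir, "window_diversity.tsv"))
  fm <- unclass(fstm); attr(fm, "pairs") <- NULL
  fm[upper.tri(fm, diag = TRUE)] <- NA
  fst_tab <- data.frame(population = rownames(fm), round(fm, 6),
                        check.names = FALSE)[-1, -ncol(fm) - 1]
  write_tsv(fst_tab, file.path(out_dir, "fst_matrix.tsv"))
  wtab <- do.call(rbind, lapply(attr(fstm, "pairs"), function(fr) {
    wf <- fr$window_fst
    wf$pair <- paste(fr$pop_a, fr$pop_b, sep = "~")
    wf$fst <- pmin(pmax(wf$fst, -1), 1)        # report range clip
    wf
  }))
  write_tsv(wtab, file.path(out_dir, "window_fst.tsv"))
  write_tsv(data.frame(sample = rownames(pca$coordinates),
                       round(pca$coordinates, 6),
                       check.names = FALSE),
            file.path(out_dir, "pca_scores.tsv"))
  write_tsv(data.frame(component = seq_along(pca$variance_explained),
                       variance_explained = round(pca$variance_explained, 6)),
            file.path(out_dir, "pca_variance.tsv"))
  write_phylip_dist(pd, file.path(out_dir, "p_distance.phy"))
  ape::write.tree(tree, file.path(out_dir, "nj_tree.nwk"))
  write_tsv(migration_edges(mig), file.path(out_dir, "migration_edges.tsv"))
  write_tsv(ld, file.path(out_dir, "ld_decay.tsv"))
  if (!is.null(scan)) {
    write_tsv(scan, file.path(out_dir, "scan_windows.tsv"))
    if (nrow(regions$regions))
      write_tsv(data.frame(chrom = regions$regions$chrom,
                           start = regions$regions$start,
                           end = regions$regions$end),
                file.path(out_dir, "candidate_regions.bed"))
    else
      writeLines(character(0), file.path(out_dir, "candidate_regions.bed"))
    writeLines(regions$genes, file.path(out_dir, "candidate_genes.txt"))
  }
  cfg_lines <- vapply(names(cfg), function(k) {
    v <- cfg[[k]]
    if (is.null(v)) v <- "NULL"
    if (inherits(v, "scenario_config")) v <- "<scenario_config>"
    paste0(k, " = ", paste(format(v), collapse = ","))
  }, "")
  writeLines(cfg_lines, file.path(out_dir, "config.txt"))

  structure(list(config = cfg, genotypes = g, popmap = popmap,
                 filter_report = rep_f, windows = windows,
                 diversity = wd, summary = summ, fst = fstm, pca = pca,
                 distance = pd, tree = tree, migration = mig, ld = ld,
                 scan = scan, regions = regions, out_dir = out_dir),
            class = "poptrace_run")
}

#' @export
print.poptrace_run <- function(x, ...) {
  cat("poptrace pipeline run\n")
  cat("  samples:", n_samples(x$genotypes),
      " sites after filtering:", n_sites(x$genotypes), "\n")
  cat("  populations:", paste(x$summary$population, collapse = ", "), "\n")
  cat("  windows:", nrow(x$windows), "\n")
  if (!is.null(x$regions))
    cat("  candidate regions:", nrow(x$regions$regions),
        " genes:", length(x$regions$genes), "\n")
  cat("  reports in:", x$out_dir, "\n")
  invisible(x)
}
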