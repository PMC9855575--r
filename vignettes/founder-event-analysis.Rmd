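---
title: "Tracing introduced populations: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing introduced populations: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poptrace)
```

## The problem

A recently introduced population — a pearl oyster colonising a reef outside
its native range, say — carries a genomic record of its origin. Three
signals identify the source among candidate native populations: the
introduction is *least differentiated* (lowest FST) from its source, its
individuals *cluster with* the source in PCA and in individual-level trees,
and gene flow inferred between it and the source is strongest. A fourth
signal records the founding itself: a founder bottleneck *reduces
diversity* genome-wide, and loci under post-introduction selection lose
diversity locally far beyond the genome-wide reduction.

`poptrace` implements this entire post-variant-calling analysis on a
diploid dosage matrix (samples × biallelic SNPs, 0/1/2/`NA`), plus a
synthetic-data generator that produces data with exactly this structure so
that every estimator is testable against known truth.

## Statistics and their conventions

### Windowed diversity

Windows are 0-based half-open `[start, start + window_size)`, placed every
`step` bp from 0 and fully contained in the chromosome (a trailing partial
window is dropped — its statistics would not be comparable at a different
effective length). Defaults are 10 kb windows with a 5 kb step, the common
choice for dense SNP data.

Per window and population, with `S` segregating sites and per-site
unbiased heterozygosity `site_pi = 2c(2n − c) / (2n(2n − 1))`:

- `theta_w = S / (a1 · L)` with `a1 = sum(1/i, i < n)`,
- `theta_pi = sum(site_pi) / L`,
- Tajima's `D = (sum(site_pi) − S/a1) / sqrt(e1·S + e2·S(S−1))` with the
  Tajima (1989) constants.

Two denominator conventions are provided because a VCF alone cannot tell
which monomorphic sites were callable. The default `per_bp` mode uses the
full window length `L` in bp — comparable across windows, downward-biased
in absolute level when callability is incomplete. `per_variant` mode uses
the segregating-site count instead, which is the right scale for
reduced-representation data. Ratio and outlier statistics (ROD, tail
flags) are invariant to this choice.

Missing genotypes make the sample size vary site to site; the Tajima
constants use the rounded mean non-missing allele count over the window's
sites with data. Per-site constants would be the alternative; at the
missingness levels the generator emulates (~5%) the difference is far below
sampling noise. Windows with `S = 0` report `theta = 0` but `D = NA` — the
statistic is undefined there, and `NA` windows are excluded from empirical
quantiles rather than counted as extreme.

The genome-wide per-population value reported in the summary table is the
unweighted mean over windows, for all of `theta_w`, `theta_pi` and `D`.

### FST

Both pairwise estimators are ratio-of-sums: per-site variance components
are summed over the window (or genome) before dividing, which is the
stable aggregation for sparse windows; a mean of per-site ratios would be
dominated by low-information sites. Weir–Cockerham is the default
(the estimator population-genomic studies most often cite); Hudson is used
for all analytic checks because its expectation under the Balding–Nichols
model equals `F` with no sample-size correction subtleties. On balanced
designs the two agree to well within 0.02. Negative per-window estimates
are legitimate sampling outcomes and are kept as computed; only rendered
reports clip to `[−1, 1]`.

### Structure

PCA imputes missing dosages to the site mean (the standard neutral choice),
drops monomorphic sites, centres, and by default applies Patterson scaling
`1/sqrt(2p̂(1 − p̂))`; `center_only` is available for comparability with
generic PCA. p-distance between individuals is
`sum|g_i − g_j| / (2 · m_ij)` over the `m_ij` jointly genotyped sites.
Neighbour joining is the classical Saitou–Nei agglomeration; negative
branch lengths, which NJ can produce on noisy distances, are clamped to
zero without redistributing the deficit. On an additive matrix the tree
reproduces the input path lengths exactly.

### Directional migration networks

The divMigrate construction: for each ordered pair, a hypothetical migrant
pool with the mean of the two allele-frequency vectors; the differentiation
between the pool and the *recipient* population (Nei Gst, Jost's D, or the
Nm transform `(1/Gst − 1)/4`) is converted to a relative rate
`(1 − d)/d`, and the directed matrix is normalised by its maximum. The
orientation convention — lower pool-vs-recipient differentiation means more
migration *into* that recipient — follows the published method description;
it is the one genuinely under-documented point of the method, so it is
stated here explicitly. Degenerate `d ≤ 0` edges are capped at the largest
finite rate before normalisation. Edges below the filter threshold
(default 0.2) are flagged hidden but never removed from the emitted matrix.
Bootstrap resamples individuals within populations; intervals are
percentile 2.5/97.5. The Nei–Chesser small-sample corrections are omitted:
plug-in estimators keep the pool construction exactly symmetric, which is
what the no-directionality null test relies on.

### LD decay

r² is the squared Pearson correlation of dosages (composite LD) — the
genotype-level quantity appropriate for unphased data. Pairs are binned by
half-open distance intervals; above `max_pairs` (default 10⁶) a seeded
subsample of pairs is used. A founder event does *not* guarantee elevated
LD — with many founders or rapid expansion LD can even drop — so the
package tests only the controllable properties: curves are reproducible
under a fixed seed and decay faster at higher recombination rates.

### Selection scan

Per window (introduced vs source): FST, `ROD = 1 − θπ_intro/θπ_source`, and
the introduced population's Tajima's D. Tail flagging is rank-based: the
`ceiling(f·n)` most extreme non-missing values, boundary ties all included
(conservative toward more candidates). A window is a candidate when
`(FST top 5% OR ROD top 5%) AND (D bottom 5% AND D < 0)` — the reading of
the combined criterion that requires an excess of rare variants *and* a
differentiation or diversity-loss signal; `require_tajima = FALSE` exposes
the OR-only alternative. Candidate windows that overlap or book-end merge
into regions; genes (GFF3 `gene` features, 1-based inclusive, converted to
0-based half-open) overlap a region at ≥ 1 bp.

One subtlety: a region with *zero* diversity in the introduced population
has no segregating sites, hence no defined Tajima's D, and can never
satisfy the D condition. A real hard sweep is not like that — it leaves a
few recent rare variants, which is exactly what drives D strongly negative.
The positive-control fixture therefore fixes a 20 kb block to the major
allele and restores a handful of singletons: ROD ≈ 1, D ≪ 0, and the block
is detected reliably.

## The synthetic-data generator

`simulate_unlinked()` draws, per site, an ancestral frequency
`p0 ~ U(0.05, 0.95)`, then per native population a Balding–Nichols
frequency `Beta(p0(1−F)/F, (1−p0)(1−F)/F)`; the introduced population's
frequency is a binomial founder sample of `2·N_f` alleles from the source
followed by binomial drift during expansion. Genotypes are
Hardy–Weinberg draws; missingness is i.i.d. The defaults are the study
design the package targets: four populations of 24/14/18/18 samples, native
`F` of 0.05/0.07/0.10 (chosen once to place pairwise FST on the 0.04–0.12
scale reported for real pearl-oyster populations — a stylistic target, not
a fit), a 10-founder introduction from the 14-sample native, two
generations of post-founding drift at size 200 (an abundant, rapidly
expanding introduction), and 5% missingness. Balding–Nichols was chosen
over coalescent machinery because its analytic expectations
(`E[FST] ≈ F`; one founder generation shrinks heterozygosity by exactly
`1 − 1/(2N_f)`) make parameter-recovery tests sharp. The truth record
(ancestral and per-population frequencies) is a first-class output, so
downstream tests are parameter-recovery tests rather than golden-file
comparisons.

What the generator does *not* emulate: linkage (in the unlinked flavour),
ascertainment of the SNP panel, inbreeding and HWE departures, clustered
RAD-style missingness, and migration after founding. Passing tests
therefore demonstrate estimator correctness and the detectability of
founder structure under idealised sampling — not robustness to those
real-data complications.

`simulate_linked()` is a forward diploid Wright–Fisher simulator for the LD
analyses: offspring haplotypes recombine (`Poisson(rec·L)` crossovers,
uniform breakpoints) and mutate (`Poisson(mu·L)` flips at uniform
positions; finite sites, re-mutation overwrites — a small downward bias on
diversity at high `mu`). After a burn-in of `10N` generations the sampled
diversity is within a few percent of the equilibrium `theta = 4·N·mu`. The
default configuration (`N = 100`, `L = 50 kb`, `mu = rec = 1.25e-5`, so
`theta = rho = 0.005`) keeps a replicate under ~20 s while giving ~1000
segregating sites — the size used throughout the test suite; diversity
expectations are means over 10 replicates.

## Numerical and degenerate-input choices

- `F = 0` natives use `p = p0` exactly (the Beta degenerates).
- Sites with all genotypes missing have undefined MAF; the filter treats
  them as MAF 0 and removes them.
- Filters are strict inequalities (`missing < 0.5`, `MAF > 0.01`); boundary
  sites are removed.
- Pairs of samples sharing no genotyped site get `NA` distance with a
  warning; NJ refuses `NA` matrices rather than guessing.
- Empirical-quantile ties are all flagged; with all values equal, every
  window is flagged (degenerate but documented).
- All stochastic functions take a `seed`; the pipeline derives every
  stage's randomness from one seed and writes byte-identical reports on
  reruns.

## Known limitations

Single-reference biallelic SNPs only (no BCF, no genotype likelihoods); the
migration network is relative (no absolute rates, no significance test of
asymmetry beyond bootstrap CIs); the scan's 5% empirical threshold is a
screening rule, not a false-discovery control; and the pipeline's
`per_bp` diversity levels depend on callability assumptions as discussed
above. Model-based clustering (ADMIXTURE-style) and functional annotation
of candidate genes are out of scope.
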