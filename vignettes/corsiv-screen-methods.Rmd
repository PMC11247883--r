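---
title: "Methods: screening for systemic interindividual methylation variation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening for systemic interindividual methylation variation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Most interindividual DNA methylation differences are tissue-specific.
A small class of loci, however, shows *systemic* interindividual
variation: individual A is more methylated than individual B at the
locus in every tissue, across all three embryonic germ layers. Such
correlated regions of systemic interindividual variation (CoRSIVs)
behave like metastable epialleles — their methylation state is set in
the early embryo, is sensitive to the periconceptional environment, and
can be read out from accessible tissue such as blood as a proxy for the
whole body. `corsivr` implements a two-step whole-genome bisulfite
sequencing (WGBS) screen for these regions in a two-subject,
three-tissue design, together with the downstream analyses such a
screen needs: matched control regions, genomic-context annotation, and
a two-group comparison for assisted-reproduction style cohorts.

## The screen model

**First step — bins and residuals.** The genome is tiled into 100-bp
bins; only bins containing at least one CpG participate. For a bin with
`n` CpGs in one library, coverage is *adequate* when all CpGs have at
least `min_depth = 5` reads (if `n <= 2`), or at least `ceiling(n/2)`
CpGs do (if `n > 2`). A bin enters the screen when adequately covered
in at least two tissues in each subject (the strict all-six-libraries
policy is also available and is what the genome-wide clustering check
uses). The bin's *individual-level residual* is the mean, over tissues
adequate in **both** subjects, of the percentage-point difference in
bin methylation (subject B minus subject A); bin methylation itself is
read-weighted (`100 * sum(meth) / sum(meth + unmeth)`).

**Second step — blocks and SIVI.** Maximal runs of at least two
genomically consecutive bins whose residuals all exceed 10 percentage
points in absolute value, with the same sign, become blocks. For each
block, the block-level per-tissue residuals `x`, `y`, `z` (one per germ
layer) feed the systemic interindividual variation index:

    SIVI = A + B,   A = cubeRoot(|x * y * z|),   B = -sd(x, y, z)

`A` rewards large interindividual differences; `B` penalizes
inconsistency across tissues. A historical third term rewarding similar
absolute methylation across tissues is deliberately absent: systemic
variation can be strongly correlated across tissues even when the
tissues differ in mean methylation. Blocks with `SIVI >= 20` are
candidates; candidates with at least 5 CpGs are the reported CoRSIVs.
SIVI is symmetric in `(x, y, z)` and positively homogeneous
(`sivi(kx, ky, kz) = k * sivi(x, y, z)` for `k > 0`), and is bounded by
`max(|x|, |y|, |z|)` with equality exactly at `x = y = z`.

**CpG-SNP masking.** A C-to-T (or G-to-A) variant destroys a CpG and
reads as unmethylated, so genetic variation can masquerade as
epigenetic variation. Before binning, any CpG whose C or G position is
covered by a variant with quality at least 30 at which the two
subjects' genotypes are discordant (unequal, both non-missing) is
removed from all libraries. Indels overlap a position when their
reference span covers it. One subtlety is documented in the test suite:
because masking lowers `n` as well as the covered count, removing an
*uncovered* CpG can legitimately flip a bin from inadequate to adequate
(e.g. depths `(5,5,0,0,0)` to `(5,5,0,0)`); the rule is implemented
exactly as stated rather than patched to avoid this.

**Permutation null.** For each block, the six block-level library
methylation values are reassigned uniformly at random to the six
(subject, tissue) labels, 1000 times, and SIVI is recomputed. This
breaks the subject pairing while keeping the block's value
distribution, giving a per-block empirical p and a genome-wide chance
rate: the fraction of (block, iteration) events at or above the SIVI
threshold.

## Matched controls and annotation

Each CoRSIV is paired with a random control region from the same
chromosome with exactly the same CpG count and the same genomic size,
drawn from screen-adequate bins outside CoRSIVs. If 1000 draws fail to
match the CpG count at the current size, the target size grows by
100 bp and the draw repeats; the relaxation count is reported. Controls
may not overlap CoRSIVs or each other; a chromosome can be exhausted,
in which case the CoRSIV is reported unmatched rather than given a
fabricated control. Each CoRSIV draws from its own RNG stream keyed by
`(seed, id)`, so matching is deterministic and order-invariant.

Annotation follows the conventions of the field: a region is a TSS/TES
region when any transcription start/end site lies within 2.5 kb
(minimal distance from any base of the region, inclusive), a gene-body
region when it overlaps a gene span; categories are not exclusive, and
regions matching none are intergenic. Genetic-variant concordance is
counted in 1-kb windows centered on region midpoints (start inclusive,
end exclusive): discordant = the two subjects' genotypes differ (both
called), concordant = equal with at least one non-reference allele — a
shared homozygous-reference genotype carries no variant. Repeat context
is profiled in ±50-kb flanks at 5-kb increments, with a separate
direct-overlap stratum; a repeat overlapping the region itself counts
only there, and both sides are pooled.

## Two-group (IVP/MOET-style) comparison

Group differences are assessed two ways, both relative to matched
controls so that miscalibration cancels between the sets. (1) DMR
overlap: an externally called differentially-methylated-region list per
tissue is intersected with CoRSIVs and controls; an overlap is valid
when the intersection covers at least half the smaller of the two
intervals, and the hit counts are compared by a Yates-corrected 2x2
chi-square. (2) Read-level: per region, methylated/unmethylated reads
summed over all region CpGs, by group, tested with the same Yates
chi-square; p-values are Benjamini–Hochberg adjusted jointly across
CoRSIVs and controls within each tissue (Bonferroni available — the
choice of adjustment is deliberately pluggable since only "adjusted for
multiple testing" is specified upstream). Counts of significant regions
are then compared between sets per tissue and pooled (the pooled table
is the cellwise sum). Degenerate 2x2 margins yield p = 1 with a flag in
per-region sweeps, and an explicit NA for the set-level comparisons, so
genome-scale runs never abort. Direction bias uses an exact two-sided
sign test.

## The synthetic world

The generator states one fixed world rather than exposing tuning dials:

* **Genome.** Background CpGs as a Poisson process at 0.02/bp plus
  CpG-island-like patches (400–700 bp, 0.06/bp, one per ~20 kb), with
  CpG dinucleotides non-overlapping and at most 10 CpGs per 100-bp
  tile. This reproduces the low median CpGs-per-bin of a mammalian
  genome while providing the CpG-dense pool that both CoRSIVs and their
  CpG-matched controls need.
* **Baseline methylation.** Bimodal: mostly methylated bulk, a
  hypomethylated island fraction, a minority of intermediate CpGs.
  Planted epivariable loci are intermediately methylated (0.32–0.45),
  as metastable-epiallele-like loci are, which also keeps offsets of
  either sign inside [0, 1] without clipping.
* **Tissue structure.** Per-CpG, per-tissue offsets (sd 0.06) shared by
  all subjects, so genome-wide libraries cluster by tissue while only
  planted systemic loci cluster by individual.
* **Noise.** Read depth Poisson (default 18x, the coverage regime the
  screen design targets); methylated counts beta-binomial with
  `rho = 0.01`. The mild default reflects that the screen consumes
  read-level-imputed coverage, which is close to binomial; `rho = 0`
  recovers pure binomial and the value is a parameter, not a constant.
* **Planted truth.** Systemic variants sit on islands with at least 25
  CpGs and apply one subject offset (|effect| 0.25–0.30, random sign)
  in *all* tissues; tissue-DMRs apply a same-sized offset in exactly
  one tissue; null regions record untouched intervals. All truth
  intervals are mutually disjoint with a 1-kb guard. The island
  placement is deliberate: the sampling variance of a block-level
  tissue residual shrinks with the number of reads in the block, so at
  20x depth a +25–30-point effect clears SIVI >= 20 reliably at
  island-scale CpG counts (the acceptance suite verifies >= 0.9
  sensitivity in exactly this world), while sparse blocks of a few
  CpGs would sit at the detection boundary.
* **CpG-SNPs.** Planted at rate 5e-4 per CpG as homozygous-alternate
  genotypes at the C or G (10% below the masking quality threshold, 30%
  concordant between subjects, exercising both negative branches of
  the masking rule); a destroyed site reads 0% methylated in the
  carrier. Background SNPs/indels avoid CpG dinucleotides so that
  `cpg_snp_rate = 0` guarantees a CpG-clean variant list.

What a green test does *not* establish: the generator has no bisulfite
conversion error, no mappability structure, no read-level correlation
beyond the per-site beta-binomial, no linkage between planted variants
and methylation (mQTL), and tissue effects are independent across CpGs
rather than regionally smooth. Results on real WGBS should be expected
to be noisier than the synthetic benchmarks.

## Numerical and design choices

* Coordinates are 0-based half-open internally; Bismark coverage and
  VCF convert at the file boundary only. `data.table::foverlaps` is
  closed-interval, so all overlap queries go through one helper that
  subtracts 1 bp from interval ends; boundary behavior is pinned by
  tests (window starts inclusive, ends exclusive; TSS distance
  inclusive at exactly 2.5 kb).
* The SIVI standard deviation uses the sample convention (n−1), the
  default of the analysis environments the formula originates from;
  the population convention is available (`sd_denom`) for sensitivity
  analysis.
* Block-level tissue methylation is read-weighted over all member-bin
  CpGs by default (`block_meth = "bin_averaged"` is the alternative);
  read-weighting is robust at low depth.
* The permutation scrambles labels uniformly over all 720 assignments
  with replacement across iterations, seeded; per-block empirical p is
  the fraction of permuted SIVI at or above the observed value.
* Thresholds are inclusive everywhere the upstream wording says "at
  least"/">=" (quality 30, MAF 0.05, valid genotypes 200, residual 10,
  SIVI 20, 5 CpGs, r 0.71). The validation comparison applies a 1e-9
  guard so that a correlation constructed to be exactly 0.71 validates
  despite floating-point representation.
* The pipeline config is JSON (no YAML parser is part of this stack);
  the run manifest records seeds, thresholds and output checksums, and
  identical configs reproduce byte-identical outputs.

## Limitations

The screen is defined for exactly two subjects and three tissues, as
in the design it implements; generalizing the residual to more subjects
would change the statistic itself. DMR calling is consumed, not
computed — the synthetic truth channel emits DMR intervals directly.
The per-region read-pooling chi-square ignores within-group biological
variability (pseudoreplication); its miscalibration under
overdispersion is absorbed by the CoRSIV-vs-control design rather than
corrected, which is why all headline comparisons are relative to
matched controls.
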