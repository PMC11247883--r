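# First-step screen machinery: 100-bp bins, CpG coverage adequacy,
# CpG-SNP masking, per-bin methylation and individual-level residuals.

#' Tile CpG-containing 100-bp bins over a set of CpG sites
#'
#' Bins are aligned to multiples of `bin_size` from the chromosome start;
#' only bins containing at least one CpG are returned.
#'
#' @param cpg a `data.table(chrom, pos)` of CpG C positions (0-based), or a
#'   `corsiv_genome`.
#' @param params a [screen_params()] object.
#' @return `data.table` with `chrom, start, end, n_cpg`, sorted.
#' @export
make_bins <- function(cpg, params = screen_params()) {
  if (inherits(cpg, "corsiv_genome")) cpg <- cpg_sites(cpg)
  cpg <- as.data.table(cpg)
  bs <- params$bin_size
  bins <- cpg[, .(n_cpg = .N), by = .(chrom, start = (pos %/% bs) * bs)]
  bins[, end := start + bs]
  setcolorder(bins, c("chrom", "start", "end", "n_cpg"))
  setorder(bins, chrom, start)
  bins[]
}

#' CpG coverage adequacy of one bin in one library
#'
#' For a bin with `n` CpGs: if `n <= 2` every CpG must reach `min_depth`
#' reads; if `n > 2`, at least `ceiling(n / 2)` CpGs must.
#'
#' @param depths read depths of the bin's CpGs in one library (length `n`;
#'   absent sites count as depth 0).
#' @param min_depth read threshold (default 5).
#' @return logical flag.
#' @export
adequacy <- function(depths, min_depth = 5) {
  n <- length(depths)
  if (n == 0L) abort_data("adequacy() needs at least one CpG")
  covered <- sum(depths >= min_depth)
  if (n <= 2L) covered == n else covered >= ceiling(n / 2)
}

#' Read-weighted percent methylation of a set of counts
#'
#' `100 * sum(n_meth) / sum(n_meth + n_unmeth)` over CpGs with depth > 0;
#' `NA` (undefined, distinct from 0%) when total depth is zero.
#'
#' @param n_meth,n_unmeth count vectors.
#' @return percent in `[0, 100]` or `NA`.
#' @export
bin_methylation <- function(n_meth, n_unmeth) {
  tot <- sum(n_meth) + sum(n_unmeth)
  if (tot == 0) return(NA_real_)
  100 * sum(n_meth) / tot
}

#' Mask CpG-SNPs: CpG sites destroyed by discordant genetic variants
#'
#' A CpG site is removed from all libraries when a variant with quality
#' `>= snp_min_qual` overlaps its C or its G position (indels overlap a
#' position when their reference span covers it) and the two screen
#' subjects' genotypes at that variant are discordant — unequal and both
#' non-missing. A genetically destroyed cytosine would otherwise read as
#' unmethylated and masquerade as epigenetic variation.
#'
#' @param cpg `data.table(chrom, pos)` of CpG sites.
#' @param variants variant table with genotype columns (see
#'   [read_variants()]).
#' @param subjects the two screen subjects (genotype column names).
#' @param params [screen_params()] (supplies `snp_min_qual`).
#' @return list with `cpg` (unmasked sites), `masked` (removed sites) and
#'   `n_masked`.
#' @export
mask_cpg_snps <- function(cpg, variants, subjects,
                          params = screen_params()) {
  cpg <- as.data.table(cpg)
  variants <- as.data.table(variants)
  if (length(subjects) != 2L)
    abort_config("CpG-SNP masking is defined for exactly two subjects")
  if (!all(subjects %in% names(variants)))
    abort_config("subject(s) %s absent from the genotype table",
                 paste(setdiff(subjects, names(variants)), collapse = ", "))
  v <- variants[qual >= params$snp_min_qual]
  g1 <- v[[subjects[1]]]; g2 <- v[[subjects[2]]]
  v <- v[g1 != g2 & g1 != "missing" & g2 != "missing"]
  if (nrow(v) == 0L)
    return(list(cpg = cpg, masked = cpg[0], n_masked = 0L))
  v <- copy(v)[, `:=`(start = pos, end = pos + nchar(ref))]
  # CpG dinucleotide spans [pos, pos + 2)
  site <- cpg[, .(chrom, start = pos, end = pos + 2L)]
  hits <- overlap_pairs(site, v[, .(chrom, start, end)])
  masked_idx <- sort(unique(hits$xid))
  masked <- cpg[masked_idx]
  list(cpg = cpg[!masked_idx], masked = masked,
       n_masked = length(masked_idx))
}

#' Remove masked CpG sites from a cohort count table
#'
#' @param cohort long count table.
#' @param masked `data.table(chrom, pos)` of sites to drop.
#' @return filtered cohort.
#' @export
apply_mask <- function(cohort, masked) {
  cohort <- as.data.table(cohort)
  if (!nrow(masked)) return(cohort)
  cohort[!as.data.table(masked)[, .(chrom, pos)], on = .(chrom, pos)]
}

#' Per-bin library statistics, adequacy and individual-level residuals
#'
#' The first screen step. For every CpG-containing bin and every
#' (subject, tissue) library: CpGs covered at `min_depth`, read-weighted
#' percent methylation and the adequacy flag. For the two screen subjects:
#' the average individual-level residual — the mean over tissues adequate
#' in *both* subjects of (%meth subject B − %meth subject A), in
#' percentage points. A bin enters the screen when adequately covered in
#' at least two tissues in each subject (`two_per_animal` policy) or in
#' all libraries (`all_libraries`).
#'
#' @param cohort long count table (`chrom, pos, subject, tissue, n_meth,
#'   n_unmeth`).
#' @param cpg CpG census (`chrom, pos`), post-masking; bins and their CpG
#'   counts derive from this, so sites with no coverage still count.
#' @param params [screen_params()].
#' @param subjects character vector of the two subjects, residual oriented
#'   as `subjects[2] - subjects[1]`.
#' @param tissues tissues to use (default: all in the cohort).
#' @return `data.table`, one row per bin: `chrom, start, end, n_cpg`,
#'   per-library `pct_<subject>.<tissue>` and `adq_<subject>.<tissue>`
#'   columns, `enters_screen`, `residual`.
#' @export
screen_bins <- function(cohort, cpg, params = screen_params(),
                        subjects = NULL, tissues = NULL) {
  cohort <- as.data.table(cohort)
  if (is.null(subjects)) subjects <- sort(unique(cohort$subject))
  if (length(subjects) != 2L)
    abort_config("the screen is defined for exactly two subjects")
  if (is.null(tissues)) tissues <- sort(unique(cohort$tissue))
  bs <- params$bin_size
  bins <- make_bins(cpg, params)
  co <- cohort[subject %in% subjects & tissue %in% tissues]
  co <- co[as.data.table(cpg)[, .(chrom, pos)], on = .(chrom, pos),
           nomatch = 0L]
  co[, `:=`(bin_start = (pos %/% bs) * bs, depth = n_meth + n_unmeth)]
  st <- co[, .(n_cov = sum(depth >= params$min_depth),
               meth_sum = sum(n_meth), depth_sum = sum(depth)),
           by = .(chrom, bin_start, subject, tissue)]
  st <- st[bins[, .(chrom, bin_start = start, n_cpg)],
           on = .(chrom, bin_start)]
  # libraries with no rows in a bin have zero covered CpGs
  libs <- lib_id(rep(subjects, each = length(tissues)),
                 rep(tissues, length(subjects)))
  st[, lib := lib_id(subject, tissue)]
  st[, adequate := fifelse(n_cpg <= 2L, n_cov == n_cpg,
                           n_cov >= ceiling(n_cpg / 2))]
  st[, pct := fifelse(depth_sum > 0, 100 * meth_sum / depth_sum, NA_real_)]
  wide_p <- dcast(st, chrom + bin_start + n_cpg ~ lib, value.var = "pct")
  wide_a <- dcast(st, chrom + bin_start + n_cpg ~ lib,
                  value.var = "adequate")
  for (l in setdiff(libs, names(wide_p))) {
    wide_p[[l]] <- NA_real_
    wide_a[[l]] <- NA
  }
  amat <- as.matrix(wide_a[, ..libs])
  amat[is.na(amat)] <- FALSE
  pmat <- as.matrix(wide_p[, ..libs])
  l1 <- lib_id(subjects[1], tissues)
  l2 <- lib_id(subjects[2], tissues)
  adq1 <- amat[, l1, drop = FALSE]
  adq2 <- amat[, l2, drop = FALSE]
  enters <- if (params$adequacy_policy == "two_per_animal") {
    rowSums(adq1) >= 2L & rowSums(adq2) >= 2L
  } else rowSums(amat[, c(l1, l2), drop = FALSE]) == 2L * length(tissues)
  both <- adq1 & adq2
  diffs <- pmat[, l2, drop = FALSE] - pmat[, l1, drop = FALSE]
  diffs[!both] <- NA
  residual <- rowMeans(diffs, na.rm = TRUE)
  residual[!is.finite(residual)] <- NA_real_
  cols <- list(chrom = wide_p$chrom, start = wide_p$bin_start,
               end = wide_p$bin_start + bs, n_cpg = wide_p$n_cpg)
  for (l in libs) {
    cols[[paste0("pct_", l)]] <- pmat[, l]
    cols[[paste0("adq_", l)]] <- amat[, l]
  }
  cols$enters_screen <- enters
  # residual: mean over tissues adequate in both subjects
  cols$residual <- residual
  out <- as.data.table(cols)
  setorder(out, chrom, start)
  out[]
}
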