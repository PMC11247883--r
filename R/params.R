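#' Parameters for the synthetic multi-tissue methylome generator
#'
#' The defaults describe the world the screen was designed for: two subjects,
#' one tissue per embryonic germ layer, ~18x mean CpG depth, mildly
#' overdispersed (beta-binomial) read counts, a mostly-methylated genome with
#' CpG-island-like dense patches, and planted truth regions of three kinds —
#' systemic interindividual variants (same subject offset in every tissue),
#' tissue-specific DMRs (subject offset in a strict subset of tissues), and
#' null regions (book-keeping only).
#'
#' @param n_subjects number of subjects (screen design uses 2).
#' @param tissues character vector of tissue names, one per germ layer.
#' @param chrom_sizes named numeric vector of chromosome lengths (bp).
#' @param cpg_density background CpG rate per bp (Poisson process).
#' @param island_spacing mean bp between CpG-island-like patches.
#' @param island_size length-2 range of island widths (bp).
#' @param island_density CpG rate per bp inside islands.
#' @param depth_mean mean reads per CpG per library (Poisson).
#' @param beta_binomial_rho intra-site correlation of the beta-binomial read
#'   noise; 0 gives pure binomial counts.
#' @param baseline_meth_profile optional per-CpG baseline methylation means
#'   in `[0,1]` (named list per chromosome); `NULL` draws a bimodal profile
#'   (mostly methylated, islands hypomethylated).
#' @param tissue_profile_sd sd of per-CpG, per-tissue offsets shared by all
#'   subjects; drives genome-wide clustering by tissue.
#' @param n_planted_systemic,n_planted_dmr,n_planted_null numbers of planted
#'   truth regions of each kind.
#' @param systemic_effect length-2 range of systemic methylation-fraction
#'   offsets (absolute value; sign is drawn per region).
#' @param dmr_effect length-2 range of tissue-DMR offsets.
#' @param systemic_min_cpg minimum CpGs in a planted systemic region.
#' @param cpg_snp_rate per-CpG probability of a discordant CpG-SNP.
#' @param variant_rate per-bp rate of background genetic variants.
#' @param seed integer master seed; fixes every output bit-for-bit.
#' @return an object of class `sim_params` (a validated list).
#' @export
sim_params <- function(n_subjects = 2,
                       tissues = c("cortex", "lung", "blood"),
                       chrom_sizes = c(chr1 = 2e6, chr2 = 2e6),
                       cpg_density = 0.02,
                       island_spacing = 2e4,
                       island_size = c(400, 700),
                       island_density = 0.06,
                       depth_mean = 18,
                       beta_binomial_rho = 0.01,
                       baseline_meth_profile = NULL,
                       tissue_profile_sd = 0.06,
                       n_planted_systemic = 20,
                       n_planted_dmr = 40,
                       n_planted_null = 40,
                       systemic_effect = c(0.25, 0.30),
                       dmr_effect = c(0.25, 0.30),
                       systemic_min_cpg = 25,
                       cpg_snp_rate = 5e-4,
                       variant_rate = 2e-4,
                       seed = 1L) {
  p <- as.list(environment())
  stopifnot_param(is_count(n_subjects) && n_subjects >= 1, "n_subjects")
  stopifnot_param(length(tissues) >= 1 && !anyDuplicated(tissues), "tissues")
  stopifnot_param(length(chrom_sizes) >= 1 && all(chrom_sizes > 0) &&
                  !is.null(names(chrom_sizes)), "chrom_sizes")
  stopifnot_param(cpg_density > 0 && cpg_density <= 0.11, "cpg_density")
  stopifnot_param(island_density >= 0 && island_density <= 0.11,
                  "island_density")
  stopifnot_param(depth_mean > 0, "depth_mean")
  stopifnot_param(beta_binomial_rho >= 0 && beta_binomial_rho < 1,
                  "beta_binomial_rho")
  stopifnot_param(tissue_profile_sd >= 0, "tissue_profile_sd")
  for (nm in c("n_planted_systemic", "n_planted_dmr", "n_planted_null"))
    stopifnot_param(is_count(p[[nm]]), nm)
  for (nm in c("systemic_effect", "dmr_effect"))
    stopifnot_param(all(p[[nm]] >= 0 & p[[nm]] <= 1) &&
                    length(p[[nm]]) %in% 1:2, nm)
  stopifnot_param(cpg_snp_rate >= 0 && cpg_snp_rate <= 1, "cpg_snp_rate")
  stopifnot_param(variant_rate >= 0 && variant_rate <= 1, "variant_rate")
  stopifnot_param(is_count(abs(seed)), "seed")
  p$systemic_effect <- rep(p$systemic_effect, length.out = 2)
  p$dmr_effect <- rep(p$dmr_effect, length.out = 2)
  p$seed <- as.integer(seed)
  structure(p, class = "sim_params")
}

stopifnot_param <- function(ok, name) {
  if (!isTRUE(ok)) abort_config("invalid simulation/screen parameter '%s'",
                                name)
}

#' Parameters of the CoRSIV screen
#'
#' Houses the screen constants: 100-bp bins, the 5-read CpG coverage rule,
#' the 10-percentage-point residual threshold for block building, the
#' SIVI >= 20 call threshold, the 5-CpG minimum for reported CoRSIVs, and
#' the quality floor for CpG-SNP masking.
#'
#' @param bin_size genomic tile width (bp).
#' @param min_depth reads required for a CpG to count as covered.
#' @param delta_threshold minimum absolute bin residual (percentage points)
#'   for block membership.
#' @param sivi_threshold SIVI call threshold.
#' @param min_cpg_corsiv minimum CpGs for a reported CoRSIV.
#' @param min_bins_per_block minimum consecutive qualifying bins per block.
#' @param snp_min_qual minimum phred quality for a masking variant.
#' @param adequacy_policy `"two_per_animal"` (screen entry: adequate in at
#'   least two tissues in each subject) or `"all_libraries"` (strict rule
#'   used for genome-wide clustering).
#' @param sd_denom standard-deviation convention in the SIVI B term:
#'   `"sample"` (n-1, default) or `"population"` (n).
#' @param block_meth block-level tissue methylation: `"read_weighted"`
#'   (default) or `"bin_averaged"`.
#' @return an object of class `screen_params`.
#' @export
screen_params <- function(bin_size = 100,
                          min_depth = 5,
                          delta_threshold = 10,
                          sivi_threshold = 20,
                          min_cpg_corsiv = 5,
                          min_bins_per_block = 2,
                          snp_min_qual = 30,
                          adequacy_policy = c("two_per_animal",
                                              "all_libraries"),
                          sd_denom = c("sample", "population"),
                          block_meth = c("read_weighted", "bin_averaged")) {
  for (nm in c("bin_size", "min_depth", "delta_threshold", "sivi_threshold",
               "min_cpg_corsiv", "min_bins_per_block", "snp_min_qual")) {
    v <- get(nm)
    stopifnot_param(length(v) == 1L && is.numeric(v) && v > 0, nm)
  }
  structure(list(bin_size = as.integer(bin_size),
                 min_depth = as.integer(min_depth),
                 delta_threshold = delta_threshold,
                 sivi_threshold = sivi_threshold,
                 min_cpg_corsiv = as.integer(min_cpg_corsiv),
                 min_bins_per_block = as.integer(min_bins_per_block),
                 snp_min_qual = snp_min_qual,
                 adequacy_policy = match.arg(adequacy_policy),
                 sd_denom = match.arg(sd_denom),
                 block_meth = match.arg(block_meth)),
            class = "screen_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Synthetic cohort parameters\n")
  cat(sprintf("  %d subject(s) x tissues: %s\n", x$n_subjects,
              paste(x$tissues, collapse = ", ")))
  cat(sprintf("  genome: %s (%.1f Mb total)\n",
              paste(names(x$chrom_sizes), collapse = ","),
              sum(x$chrom_sizes) / 1e6))
  cat(sprintf("  depth %gx, beta-binomial rho %g, seed %d\n",
              x$depth_mean, x$beta_binomial_rho, x$seed))
  cat(sprintf("  planted: %d systemic, %d tissue-DMR, %d null\n",
              x$n_planted_systemic, x$n_planted_dmr, x$n_planted_null))
  invisible(x)
}

#' @export
print.screen_params <- function(x, ...) {
  cat(sprintf(paste0("CoRSIV screen parameters: %d bp bins, depth >= %d, ",
                     "|residual| >= %g%%, SIVI >= %g, >= %d CpGs, ",
                     "qual >= %g, policy %s\n"),
              x$bin_size, x$min_depth, x$delta_threshold, x$sivi_threshold,
              x$min_cpg_corsiv, x$snp_min_qual, x$adequacy_policy))
  invisible(x)
}
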