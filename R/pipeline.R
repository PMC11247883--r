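# Orchestration: simulate -> bins -> call -> controls -> annotate ->
# group-test, driven by a JSON config, with a run manifest recording
# seeds, thresholds and output checksums.

#' Default pipeline configuration
#'
#' @return the default config list consumed by [run_pipeline()].
#' @export
default_pipeline_config <- function() {
  list(
    out_dir = "corsiv_run",
    seed = 1L,
    sim = list(),      # overrides for sim_params()
    screen = list(),   # overrides for screen_params()
    permutation = list(n_iter = 1000L),
    group = list(enabled = TRUE, group_sizes = c(4L, 4L),
                 group_effect = 0.2, effect_at = "corsivs",
                 alpha = 0.05, adjust = "BH"),
    annotate = list(enabled = TRUE)
  )
}

#' Read a pipeline configuration (JSON)
#'
#' Unknown keys are rejected; missing keys fall back to defaults.
#'
#' @param path JSON file path.
#' @return a config list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort_config("config file not found: %s", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- default_pipeline_config()
  unknown <- setdiff(names(cfg), names(base))
  if (length(unknown))
    abort_config("unknown config key(s): %s", paste(unknown, collapse = ", "))
  utils::modifyList(base, cfg)
}

log_msg <- function(fmt, ...) {
  message(sprintf("[corsivr %s] %s", format(Sys.time(), "%H:%M:%S"),
                  sprintf(fmt, ...)))
}

manifest_entry <- function(stage, paths, seed = NULL, params = NULL) {
  list(stage = stage,
       outputs = lapply(paths, function(p)
         list(path = p, md5 = unname(tools::md5sum(p)))),
       seed = seed, params = params)
}

#' Run the full synthetic-to-results pipeline
#'
#' Stages in dependency order: simulate (genome, cohort, coverage files,
#' VCF, truth BEDs, annotation tracks), screen (bins, blocks, CoRSIV
#' call), permutation null, control matching, genomic-context annotation,
#' and the two-group comparison. Every stage seed derives from the master
#' seed, so reruns with an identical config are byte-identical. A
#' manifest (JSON) records outputs, checksums, seeds and the thresholds
#' applied.
#'
#' @param config a config list (see [read_pipeline_config()]) or a path
#'   to a JSON config.
#' @return the manifest, invisibly; files under `config$out_dir`.
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  cfg <- utils::modifyList(default_pipeline_config(), config)
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  sp <- do.call(sim_params, c(cfg$sim, list(seed = as.integer(cfg$seed))))
  scp <- do.call(screen_params, cfg$screen)

  log_msg("simulate: %d subjects x %s at %gx",
          sp$n_subjects, paste(sp$tissues, collapse = "/"), sp$depth_mean)
  genome <- generate_genome(sp)
  sim <- generate_cohort(genome, sp)
  cov_paths <- write_cohort_coverage(sim$cohort, file.path(out, "coverage"))
  vcf_path <- file.path(out, "genotypes.vcf")
  write_variants(sim$variants, vcf_path)
  truth_path <- file.path(out, "truth.bed")
  write_bed(copy(sim$truth)[, name := paste(kind, id, sep = ";")],
            truth_path)
  ann <- generate_annotation(genome, seed = derive_seed(sp$seed, "ann"))
  genes_path <- file.path(out, "genes.tsv")
  fwrite(ann$genes, genes_path, sep = "\t")
  repeats_path <- file.path(out, "repeats.tsv")
  fwrite(ann$repeats, repeats_path, sep = "\t")
  manifest$simulate <- manifest_entry(
    "simulate", c(cov_paths, vcf_path, truth_path, genes_path,
                  repeats_path),
    seed = sp$seed, params = unclass(sp)[c("depth_mean",
                                           "beta_binomial_rho",
                                           "n_planted_systemic",
                                           "n_planted_dmr",
                                           "n_planted_null")])

  # read inputs back through the file layer (exercises the I/O contract)
  cohort <- rbindlist(lapply(names(cov_paths), function(l) {
    st <- strsplit(l, ".", fixed = TRUE)[[1]]
    read_coverage(cov_paths[[l]], subject = st[1], tissue = st[2])
  }))
  variants <- read_variants(vcf_path)
  if (!all(file.exists(c(cov_paths, vcf_path))))
    abort_config("missing pipeline inputs")

  log_msg("screen: bins + blocks + SIVI (policy %s)", scp$adequacy_policy)
  scr <- run_screen(cohort, genome, variants, scp,
                    subjects = subject_names(sp$n_subjects)[1:2],
                    tissues = sp$tissues)
  bins_path <- file.path(out, "bins.tsv")
  fwrite(scr$bins, bins_path, sep = "\t")
  corsivs_path <- file.path(out, "corsivs.bed")
  write_bed(scr$corsivs, corsivs_path)
  log_msg("screen: %d bins, %d blocks, %d candidates, %d CoRSIVs (%d CpG-SNP sites masked)",
          nrow(scr$bins), nrow(scr$blocks), nrow(scr$candidates),
          nrow(scr$corsivs), scr$n_masked)
  manifest$screen <- manifest_entry(
    "screen", c(bins_path, corsivs_path), seed = NULL,
    params = unclass(scp))

  perm <- permutation_null(scr$blocks, scp,
                           n_iter = as.integer(cfg$permutation$n_iter),
                           seed = derive_seed(sp$seed, "perm"))
  perm_path <- file.path(out, "permutation.tsv")
  fwrite(perm$p, perm_path, sep = "\t")
  manifest$permutation <- manifest_entry(
    "permutation", perm_path, seed = derive_seed(sp$seed, "perm"),
    params = list(n_iter = cfg$permutation$n_iter,
                  genomewide_rate = perm$genomewide_rate))

  controls <- if (nrow(scr$corsivs)) {
    cpg_post <- cpg_sites(genome)[!scr$masked, on = .(chrom, pos)]
    match_controls(scr$corsivs, scr$bins, cpg_post, genome$chrom_sizes,
                   seed = derive_seed(sp$seed, "controls"), params = scp)
  } else data.table()
  controls_path <- file.path(out, "controls.bed")
  if (nrow(controls)) write_bed(controls[!is.na(start)], controls_path)
  else writeLines(character(), controls_path)
  manifest$controls <- manifest_entry(
    "controls", controls_path, seed = derive_seed(sp$seed, "controls"))

  if (isTRUE(cfg$annotate$enabled) && nrow(scr$corsivs)) {
    genes <- read_gene_models(genes_path)
    reps <- read_repeats(repeats_path)
    ann_c <- genic_annotation(scr$corsivs, genes)
    annot_path <- file.path(out, "corsivs_annotated.tsv")
    fwrite(ann_c, annot_path, sep = "\t")
    ctrl_ok <- controls[!is.na(start)]
    ctx <- list(
      tss = if (nrow(ctrl_ok)) tss_enrichment_test(
        ann_c$tss, genic_annotation(ctrl_ok, genes)$tss),
      variants = if (nrow(ctrl_ok)) variant_concordance(
        scr$corsivs, variants, subject_names(sp$n_subjects)[1:2],
        regions2 = ctrl_ok),
      repeats = repeat_flank_profile(scr$corsivs, reps))
    manifest$annotate <- manifest_entry(
      "annotate", annot_path,
      params = list(tss_p = ctx$tss$p, variant_p = ctx$variants$p))
  }

  if (isTRUE(cfg$group$enabled) && nrow(scr$corsivs)) {
    log_msg("group-test: %s effect %.2f at %s",
            paste(cfg$group$group_sizes, collapse = "+"),
            cfg$group$group_effect, cfg$group$effect_at)
    eff_at <- if (identical(cfg$group$effect_at, "corsivs"))
      scr$corsivs[, .(chrom, start, end)] else
        data.table(chrom = character(), start = integer(),
                   end = integer())
    two <- generate_two_group_cohort(genome, sp, eff_at,
                                     group_sizes = cfg$group$group_sizes,
                                     group_effect = cfg$group$group_effect)
    ctrl_ok <- if (nrow(controls)) controls[!is.na(start)] else controls
    res <- rbindlist(lapply(sp$tissues, function(t) {
      rc <- region_group_test(two$cohort, scr$corsivs, tissue = t,
                              adjust = "none")
      rk <- if (nrow(ctrl_ok))
        region_group_test(two$cohort, ctrl_ok, tissue = t,
                          adjust = "none") else NULL
      both <- rbind(cbind(rc, set = "corsiv"),
                    if (!is.null(rk)) cbind(rk, set = "control"))
      both[, p_adj := adjust_pvalues(p, cfg$group$adjust)]
      both[, tissue := t]
      both
    }))
    results_path <- file.path(out, "group_results.tsv")
    fwrite(res, results_path, sep = "\t")
    enr <- significant_region_enrichment(res[set == "corsiv"],
                                         res[set == "control"],
                                         alpha = cfg$group$alpha)
    enr_path <- file.path(out, "group_enrichment.tsv")
    fwrite(enr, enr_path, sep = "\t")
    manifest$group <- manifest_entry(
      "group", c(results_path, enr_path),
      seed = sp$seed,
      params = cfg$group[c("group_sizes", "group_effect", "alpha",
                           "adjust")])
  }

  manifest$thresholds <- unclass(scp)
  manifest_path <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  log_msg("done: %s", out)
  invisible(manifest)
}
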