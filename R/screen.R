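# Second-step: block building over qualifying consecutive bins, the
# systemic interindividual variation index (SIVI), CoRSIV classification,
# and the library-scrambling permutation null.

#' Systemic interindividual variation index
#'
#' `SIVI = A + B` with `A = cubeRoot(|x * y * z|)` (rewards large
#' interindividual differences) and `B = -sd(x, y, z)` (rewards
#' direction-consistent differences across the three tissues). `x`, `y`,
#' `z` are the block-level per-tissue residuals (subject B − subject A, in
#' percentage points). Vectorized over blocks.
#'
#' @param x,y,z per-tissue block residuals.
#' @param sd_denom `"sample"` (n−1, default) or `"population"` (n).
#' @return numeric SIVI values; `NA` where any tissue residual is `NA`.
#' @export
sivi <- function(x, y, z, sd_denom = c("sample", "population")) {
  sd_denom <- match.arg(sd_denom)
  a <- abs(x * y * z)^(1 / 3)
  m <- (x + y + z) / 3
  ss <- (x - m)^2 + (y - m)^2 + (z - m)^2
  b <- -sqrt(ss / if (sd_denom == "sample") 2 else 3)
  a + b
}

#' Build blocks of consecutive qualifying bins
#'
#' Maximal runs of genomically adjacent bins (start offsets differing by
#' exactly `bin_size`) that entered the screen, with defined residuals of
#' absolute value at least `delta_threshold`, all in the same direction.
#' Runs shorter than `min_bins_per_block` are discarded; a bin with an
#' undefined residual — or any genomic gap — breaks a run.
#'
#' @param bins output of [screen_bins()] (needs `chrom, start, end, n_cpg,
#'   enters_screen, residual`).
#' @param params [screen_params()].
#' @return `data.table`, one row per block: `block_id, chrom, start, end,
#'   n_bins, n_cpg, direction, mean_residual`.
#' @export
build_blocks <- function(bins, params = screen_params()) {
  bins <- as.data.table(bins)
  setorder(bins, chrom, start)
  bs <- params$bin_size
  ok <- bins$enters_screen & !is.na(bins$residual) &
    abs(bins$residual) >= params$delta_threshold
  sgn <- sign(bins$residual)
  newrun <- ok & (
    c(TRUE, diff(bins$start) != bs) |
      c(TRUE, bins$chrom[-1] != bins$chrom[-nrow(bins)]) |
      c(TRUE, sgn[-1] != sgn[-nrow(bins)]) |
      c(TRUE, !ok[-nrow(bins)])
  )
  run <- cumsum(newrun)
  run[!ok] <- NA
  b <- bins[ok]
  if (nrow(b) == 0L)
    return(data.table(block_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      n_bins = integer(), n_cpg = integer(),
                      direction = numeric(), mean_residual = numeric()))
  b[, run_id := run[ok]]
  blocks <- b[, .(chrom = chrom[1], start = min(start), end = max(end),
                  n_bins = .N, n_cpg = sum(n_cpg),
                  direction = sign(residual[1]),
                  mean_residual = mean(residual)),
              by = run_id]
  blocks <- blocks[n_bins >= params$min_bins_per_block]
  setorder(blocks, chrom, start)
  blocks[, block_id := sprintf("block_%05d", .I)]
  blocks[, run_id := NULL]
  setcolorder(blocks, c("block_id", "chrom", "start", "end", "n_bins",
                        "n_cpg", "direction", "mean_residual"))
  blocks[]
}

#' Block-level library methylation, tissue residuals and SIVI
#'
#' For each block and each of the six (subject, tissue) libraries, the
#' block-level percent methylation: read-weighted over all member-bin CpGs
#' by default, or the mean of per-bin percentages (`block_meth =
#' "bin_averaged"`). Tissue residuals `x, y, z` are block-level subject
#' differences for `tissues[1]`, `tissues[2]`, `tissues[3]`; the
#' tissue-to-role mapping is configuration since SIVI is symmetric.
#'
#' @param blocks output of [build_blocks()].
#' @param cohort long count table (post-masking).
#' @param params [screen_params()].
#' @param subjects two subjects, residuals oriented `subjects[2] -
#'   subjects[1]`.
#' @param tissues three tissues playing the x, y, z roles.
#' @return `blocks` with added per-library `meth_<subject>.<tissue>`
#'   columns, `x, y, z`, and `sivi` (`NA` when any tissue lacks reads in
#'   either subject; such blocks are excluded from calling and counted).
#' @export
block_values <- function(blocks, cohort, params = screen_params(),
                         subjects = NULL, tissues = NULL) {
  blocks <- as.data.table(blocks)
  cohort <- as.data.table(cohort)
  if (is.null(subjects)) subjects <- sort(unique(cohort$subject))
  if (is.null(tissues)) tissues <- sort(unique(cohort$tissue))
  if (length(tissues) != 3L)
    abort_config("SIVI requires exactly three tissue roles")
  if (nrow(blocks) == 0L) {
    blocks[, `:=`(x = numeric(), y = numeric(), z = numeric(),
                  sivi = numeric())]
    return(blocks[])
  }
  co <- cohort[subject %in% subjects & tissue %in% tissues]
  site <- co[, .(chrom, start = pos, end = pos + 1L, subject, tissue,
                 n_meth, n_unmeth)]
  reg <- blocks[, .(block_id, chrom, start, end)]
  pairs <- overlap_pairs(site, reg, type = "within")
  hits <- cbind(site[pairs$xid,
                     .(pos = start, subject, tissue, n_meth, n_unmeth)],
                block_id = reg$block_id[pairs$yid])
  if (params$block_meth == "read_weighted") {
    bm <- hits[, .(pct = bin_methylation(n_meth, n_unmeth)),
               by = .(block_id, subject, tissue)]
  } else {
    bs <- params$bin_size
    per_bin <- hits[, .(pct = bin_methylation(n_meth, n_unmeth)),
                    by = .(block_id, subject, tissue,
                           bin = (pos %/% bs) * bs)]
    bm <- per_bin[, .(pct = mean(pct, na.rm = TRUE)),
                  by = .(block_id, subject, tissue)]
  }
  bm[, lib := paste0("meth_", lib_id(subject, tissue))]
  wide <- dcast(bm, block_id ~ lib, value.var = "pct")
  out <- wide[blocks, on = "block_id"]
  for (l in paste0("meth_", lib_id(rep(subjects, each = 3), tissues)))
    if (!l %in% names(out)) out[[l]] <- NA_real_
  res <- sapply(tissues, function(t)
    out[[paste0("meth_", lib_id(subjects[2], t))]] -
      out[[paste0("meth_", lib_id(subjects[1], t))]])
  res <- matrix(res, ncol = 3)
  out[, `:=`(x = res[, 1], y = res[, 2], z = res[, 3])]
  out[, sivi := sivi(x, y, z, params$sd_denom)]
  setcolorder(out, c("block_id", "chrom", "start", "end"))
  setorder(out, chrom, start)
  out[]
}

#' Classify CoRSIVs from scored blocks
#'
#' @param blocks output of [block_values()] (needs `sivi`, `n_cpg`).
#' @param params [screen_params()].
#' @return list: `candidates` (blocks with `sivi >= sivi_threshold`),
#'   `corsivs` (candidates with `n_cpg >= min_cpg_corsiv`), and
#'   `n_undefined` (blocks whose SIVI was undefined), all sorted by
#'   (chrom, start).
#' @export
classify_corsivs <- function(blocks, params = screen_params()) {
  blocks <- as.data.table(blocks)
  cand <- blocks[!is.na(sivi) & sivi >= params$sivi_threshold]
  setorder(cand, chrom, start)
  cors <- cand[n_cpg >= params$min_cpg_corsiv]
  if (nrow(cors)) cors <- copy(cors)[, id := sprintf("corsiv_%04d", .I)]
  list(candidates = cand[], corsivs = cors,
       n_undefined = sum(is.na(blocks$sivi)))
}

#' Permutation null for block SIVI
#'
#' For each block, the six block-level library methylation values are
#' reassigned uniformly at random to the six (subject, tissue) labels for
#' `n_iter` iterations; SIVI is recomputed each time. Returns the
#' per-block empirical p (fraction of iterations with permuted SIVI at
#' least the observed SIVI) and the genome-wide chance rate: the fraction
#' of (block, iteration) events with permuted SIVI at or above
#' `sivi_threshold`.
#'
#' @param blocks output of [block_values()]; blocks with any missing
#'   library value are skipped (reported in `n_skipped`).
#' @param params [screen_params()].
#' @param subjects,tissues as in [block_values()].
#' @param n_iter iterations (default 1000).
#' @param seed integer seed; fixes the permutation stream.
#' @return list: `p` (`data.table` of block_id, observed sivi, perm_p),
#'   `genomewide_rate`, `n_iter`, `n_skipped`.
#' @export
permutation_null <- function(blocks, params = screen_params(),
                             subjects = NULL, tissues = NULL,
                             n_iter = 1000, seed = 1L) {
  blocks <- as.data.table(blocks)
  libcols <- grep("^meth_", names(blocks), value = TRUE)
  if (length(libcols) != 6L)
    abort_config("permutation_null needs the six meth_* library columns")
  if (is.null(subjects)) {
    st <- strsplit(sub("^meth_", "", libcols), ".", fixed = TRUE)
    subjects <- sort(unique(vapply(st, `[`, "", 1L)))
    tissues <- unique(vapply(st, `[`, "", 2L))
  }
  vals <- as.matrix(blocks[, ..libcols])
  ok <- stats::complete.cases(vals)
  v <- vals[ok, , drop = FALSE]
  B <- nrow(v)
  if (B == 0L)
    return(list(p = data.table(block_id = character(), sivi = numeric(),
                               perm_p = numeric()),
                genomewide_rate = NA_real_, n_iter = n_iter,
                n_skipped = sum(!ok)))
  # role of each column position after permutation
  col_of <- function(s, t) match(paste0("meth_", lib_id(s, t)), libcols)
  ax <- col_of(subjects[1], tissues[1]); bx <- col_of(subjects[2], tissues[1])
  ay <- col_of(subjects[1], tissues[2]); by <- col_of(subjects[2], tissues[2])
  az <- col_of(subjects[1], tissues[3]); bz <- col_of(subjects[2], tissues[3])
  perms <- as.matrix(expand.grid(rep(list(1:6), 6)))
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == 6L), ,
                 drop = FALSE]                      # all 720 permutations
  obs <- sivi(v[, bx] - v[, ax], v[, by] - v[, ay], v[, bz] - v[, az],
              params$sd_denom)
  ge_obs <- integer(B)
  n_ge_thr <- 0
  with_seed(seed, {
    for (i in seq_len(n_iter)) {
      pidx <- sample.int(nrow(perms), B, replace = TRUE)
      pick <- function(role) v[cbind(seq_len(B), perms[pidx, role])]
      s <- sivi(pick(bx) - pick(ax), pick(by) - pick(ay),
                pick(bz) - pick(az), params$sd_denom)
      ge_obs <- ge_obs + (s >= obs)
      n_ge_thr <- n_ge_thr + sum(s >= params$sivi_threshold)
    }
  })
  list(p = data.table(block_id = blocks$block_id[ok], sivi = obs,
                      perm_p = ge_obs / n_iter),
       genomewide_rate = n_ge_thr / (as.numeric(B) * n_iter),
       n_iter = n_iter, n_skipped = sum(!ok))
}

#' Run the whole two-step CoRSIV screen on a cohort
#'
#' Masks CpG-SNPs (when variants are supplied), computes bin statistics
#' and residuals, builds blocks, scores SIVI and classifies CoRSIVs.
#'
#' @param cohort long count table.
#' @param cpg CpG census (`chrom, pos`) or a `corsiv_genome`.
#' @param variants optional genotype table for CpG-SNP masking.
#' @param params [screen_params()].
#' @param subjects,tissues see [screen_bins()] / [block_values()].
#' @return list: `bins`, `blocks`, `candidates`, `corsivs`, `masked`,
#'   `n_masked`, `n_undefined`, `params`.
#' @export
run_screen <- function(cohort, cpg, variants = NULL,
                       params = screen_params(), subjects = NULL,
                       tissues = NULL) {
  if (inherits(cpg, "corsiv_genome")) cpg <- cpg_sites(cpg)
  cpg <- as.data.table(cpg)
  cohort <- as.data.table(cohort)
  if (is.null(subjects)) subjects <- sort(unique(cohort$subject))
  if (is.null(tissues)) tissues <- sort(unique(cohort$tissue))
  masked <- cpg[0]
  n_masked <- 0L
  if (!is.null(variants) && nrow(variants)) {
    mk <- mask_cpg_snps(cpg, variants, subjects, params)
    cpg <- mk$cpg
    masked <- mk$masked
    n_masked <- mk$n_masked
    cohort <- apply_mask(cohort, masked)
  }
  bins <- screen_bins(cohort, cpg, params, subjects, tissues)
  blocks <- build_blocks(bins, params)
  blocks <- block_values(blocks, cohort, params, subjects, tissues)
  cls <- classify_corsivs(blocks, params)
  list(bins = bins, blocks = blocks, candidates = cls$candidates,
       corsivs = cls$corsivs, masked = masked, n_masked = n_masked,
       n_undefined = cls$n_undefined, params = params)
}
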