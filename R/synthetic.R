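# Synthetic multi-tissue WGBS generator with a planted truth channel.
#
# The generator states a world: a mostly-methylated genome with
# CpG-island-like dense patches, per-tissue methylation profiles shared by
# all subjects (so genome-wide libraries cluster by tissue), beta-binomial
# read noise, and three kinds of planted truth regions. Systemic variants
# mimic metastable-epiallele-like loci: CpG-dense, intermediately
# methylated, with the same subject offset in every tissue.

#' Beta-binomial random counts
#'
#' `rho` is the intra-site correlation; `rho = 0` degenerates to binomial.
#' Sites with `p <= 0` or `p >= 1` are deterministic.
#'
#' @param n number of draws.
#' @param size integer vector of trial counts (recycled).
#' @param prob per-draw success means (recycled).
#' @param rho overdispersion in `[0, 1)`.
#' @return integer vector of methylated-read counts.
#' @export
rbetabinom <- function(n, size, prob, rho = 0) {
  size <- rep_len(size, n)
  prob <- rep_len(prob, n)
  out <- integer(n)
  hi <- prob >= 1
  mid <- !(prob <= 0 | hi)
  if (any(mid)) {
    pp <- if (rho > 0) {
      rbeta(sum(mid), prob[mid] * (1 - rho) / rho,
            (1 - prob[mid]) * (1 - rho) / rho)
    } else prob[mid]
    out[mid] <- rbinom(sum(mid), size[mid], pp)
  }
  out[hi] <- size[hi]
  out
}

#' Generate a synthetic genome (chromosome sizes + CpG landscape)
#'
#' CpGs are laid down as a background Poisson process plus CpG-island-like
#' patches of elevated density, so 100-bp tiles carry 0-10 CpGs with a
#' low median, as in real mammalian genomes. Each chromosome is generated
#' from its own RNG stream keyed by `(seed, chrom)`, so output is
#' independent of chromosome processing order.
#'
#' @param params a [sim_params()] object.
#' @return an object of class `corsiv_genome`: a list with `chrom_sizes`,
#'   `cpg` (sorted 0-based positions of each CpG's C, per chromosome) and
#'   `islands` (a `data.table` of island intervals).
#' @export
generate_genome <- function(params) {
  if (!inherits(params, "sim_params"))
    abort_config("params must be created by sim_params()")
  chroms <- names(params$chrom_sizes)
  cpg <- vector("list", length(chroms))
  names(cpg) <- chroms
  isl_list <- vector("list", length(chroms))
  for (ch in chroms) {
    len <- params$chrom_sizes[[ch]]
    res <- with_seed(derive_seed(params$seed, "genome", ch), {
      n_isl <- rpois(1, len / params$island_spacing)
      isl <- data.table(
        start = floor(runif(n_isl, 0, max(len - params$island_size[2], 1))))
      isl[, end := start + floor(runif(.N, params$island_size[1],
                                       params$island_size[2] + 1))]
      setorder(isl, start)
      # islands are disjoint features; merge any closer than 200 bp so
      # bin-aligned island windows stay non-overlapping too
      if (nrow(isl) > 1) {
        keep_s <- integer(); keep_e <- integer()
        cs <- isl$start[1]; ce <- isl$end[1]
        for (i in 2:nrow(isl)) {
          if (isl$start[i] <= ce + 200L) ce <- max(ce, isl$end[i])
          else { keep_s <- c(keep_s, cs); keep_e <- c(keep_e, ce)
                 cs <- isl$start[i]; ce <- isl$end[i] }
        }
        isl <- data.table(start = c(keep_s, cs), end = c(keep_e, ce))
      }
      n_bg <- rpois(1, len * params$cpg_density)
      pos <- floor(runif(n_bg, 0, len - 1))
      extra_rate <- max(params$island_density - params$cpg_density, 0)
      if (nrow(isl)) {
        n_ex <- rpois(nrow(isl), (isl$end - isl$start) * extra_rate)
        ex <- floor(runif(sum(n_ex),
                          rep(isl$start, n_ex), rep(isl$end, n_ex)))
        pos <- c(pos, ex)
      }
      pos <- sort(unique(pos))
      pos <- pos[pos < len - 1]
      # a CpG occupies 2 bp; enforce non-overlapping dinucleotides
      if (length(pos) > 1) pos <- pos[c(TRUE, diff(pos) >= 2)]
      # contract: a 100-bp tile carries at most 10 CpGs
      if (length(pos)) {
        tile <- pos %/% 100L
        keep <- unlist(lapply(split(seq_along(pos), tile), function(ix) {
          if (length(ix) <= 10L) ix else
            ix[unique(round(seq(1, length(ix), length.out = 10L)))]
        }), use.names = FALSE)
        pos <- pos[sort(keep)]
      }
      list(pos = as.integer(pos), isl = isl)
    })
    cpg[[ch]] <- res$pos
    isl_list[[ch]] <- if (nrow(res$isl)) data.table(chrom = ch, res$isl)
  }
  if (any(vapply(cpg, length, 1L) == 0L))
    abort_data("a chromosome received zero CpGs; enlarge it or cpg_density")
  structure(list(chrom_sizes = params$chrom_sizes, cpg = cpg,
                 islands = rbindlist(isl_list)),
            class = "corsiv_genome")
}

#' @export
print.corsiv_genome <- function(x, ...) {
  cat(sprintf("Synthetic genome: %d chromosome(s), %.2f Mb, %d CpGs\n",
              length(x$chrom_sizes), sum(x$chrom_sizes) / 1e6,
              sum(vapply(x$cpg, length, 1L))))
  invisible(x)
}

#' CpG sites of a genome as a keyed data.table
#' @param genome a `corsiv_genome`.
#' @return `data.table` with columns `chrom`, `pos` (0-based C position).
#' @export
cpg_sites <- function(genome) {
  dt <- rbindlist(lapply(names(genome$cpg), function(ch)
    data.table(chrom = ch, pos = genome$cpg[[ch]])))
  setkey(dt, chrom, pos)
  dt[]
}

# ---- truth-region planting -------------------------------------------------

# pick non-overlapping bin-aligned windows; systemic regions sit on CpG
# islands with >= systemic_min_cpg CpGs, DMR/null regions on background.
plant_truth <- function(genome, params, bin_size = 100L) {
  taken <- data.table(chrom = character(), start = integer(),
                      end = integer())
  gap <- 1000L
  overlaps_taken <- function(ch, s, e) {
    tt <- taken[chrom == ch]
    nrow(tt) && any(tt$start < e + gap & tt$end > s - gap)
  }
  rows <- list()
  with_seed(derive_seed(params$seed, "truth"), {
    # systemic candidates: islands, bin-aligned, enough CpGs
    isl <- copy(genome$islands)
    if (nrow(isl)) {
      isl[, start := (start %/% bin_size) * bin_size]
      isl[, end := ((end + bin_size - 1L) %/% bin_size) * bin_size]
      isl[, n_cpg := count_in_window(genome$cpg[[chrom]], start, end),
          by = seq_len(nrow(isl))]
      isl <- isl[n_cpg >= params$systemic_min_cpg]
    }
    if (params$n_planted_systemic > 0) {
      if (nrow(isl) < params$n_planted_systemic)
        abort_data(paste0("only %d CpG-island windows with >= %d CpGs ",
                          "available for %d planted systemic regions"),
                   nrow(isl), params$systemic_min_cpg,
                   params$n_planted_systemic)
      ord <- sample.int(nrow(isl))
      k <- 0L
      for (i in ord) {
        if (k == params$n_planted_systemic) break
        if (overlaps_taken(isl$chrom[i], isl$start[i], isl$end[i])) next
        k <- k + 1L
        eff <- runif(1, params$systemic_effect[1], params$systemic_effect[2]) *
          sample(c(-1, 1), 1)
        rows[[length(rows) + 1L]] <- data.table(
          chrom = isl$chrom[i], start = isl$start[i], end = isl$end[i],
          kind = "systemic_variant", effect = eff, tissues_affected = "*")
        taken <- rbind(taken, data.table(chrom = isl$chrom[i],
                                         start = isl$start[i],
                                         end = isl$end[i]))
      }
      if (k < params$n_planted_systemic)
        abort_data("could not place %d non-overlapping systemic regions",
                   params$n_planted_systemic)
    }
    # background windows for tissue-DMR and null regions
    place_bg <- function(n, kind) {
      placed <- 0L
      attempts <- 0L
      while (placed < n && attempts < n * 200L) {
        attempts <- attempts + 1L
        ch <- sample(names(genome$chrom_sizes), 1)
        nb <- sample(3:5, 1)
        w <- nb * bin_size
        s <- (floor(runif(1, 0, genome$chrom_sizes[[ch]] - w)) %/%
                bin_size) * bin_size
        e <- s + w
        if (count_in_window(genome$cpg[[ch]], s, e) < 3L) next
        if (overlaps_taken(ch, s, e)) next
        eff <- if (kind == "tissue_dmr") {
          runif(1, params$dmr_effect[1], params$dmr_effect[2]) *
            sample(c(-1, 1), 1)
        } else 0
        tis <- if (kind == "tissue_dmr") sample(params$tissues, 1) else ""
        rows[[length(rows) + 1L]] <<- data.table(
          chrom = ch, start = as.integer(s), end = as.integer(e),
          kind = kind, effect = eff, tissues_affected = tis)
        taken <<- rbind(taken, data.table(chrom = ch, start = as.integer(s),
                                          end = as.integer(e)))
        placed <- placed + 1L
      }
      if (placed < n)
        abort_data("could not place %d non-overlapping %s regions", n, kind)
    }
    place_bg(params$n_planted_dmr, "tissue_dmr")
    place_bg(params$n_planted_null, "null")
  })
  truth <- rbindlist(rows)
  if (!nrow(truth))
    return(data.table(id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      kind = character(), effect = numeric(),
                      tissues_affected = character()))
  truth[, id := sprintf("%s_%03d", kind, seq_len(.N)), by = kind]
  setcolorder(truth, c("id", "chrom", "start", "end", "kind", "effect",
                       "tissues_affected"))
  setorder(truth, chrom, start)
  truth[]
}

# ---- cohort generation -----------------------------------------------------

subject_names <- function(n) sprintf("s%d", seq_len(n))

# per-chrom baseline means: background bimodal (mostly methylated),
# islands hypomethylated, planted epivariable regions intermediate
baseline_for_chrom <- function(genome, params, ch, truth) {
  pos <- genome$cpg[[ch]]
  if (!is.null(params$baseline_meth_profile)) {
    u <- params$baseline_meth_profile[[ch]]
    if (length(u) != length(pos) || any(u < 0 | u > 1))
      abort_config("baseline_meth_profile[[%s]] must hold %d values in [0,1]",
                   ch, length(pos))
    return(u)
  }
  u <- with_seed(derive_seed(params$seed, "baseline", ch), {
    grp <- sample(1:3, length(pos), replace = TRUE,
                  prob = c(0.75, 0.15, 0.10))
    u <- numeric(length(pos))
    u[grp == 1] <- rbeta(sum(grp == 1), 7, 2)    # methylated bulk
    u[grp == 2] <- rbeta(sum(grp == 2), 2, 2)    # intermediate
    u[grp == 3] <- rbeta(sum(grp == 3), 2, 8)    # hypomethylated
    isl <- genome$islands[chrom == ch]
    if (nrow(isl)) {
      in_isl <- rep(FALSE, length(pos))
      for (i in seq_len(nrow(isl)))
        in_isl <- in_isl | (pos >= isl$start[i] & pos < isl$end[i])
      u[in_isl] <- rbeta(sum(in_isl), 2, 9)      # islands mostly unmethylated
    }
    # planted epivariable loci are intermediately methylated so offsets of
    # either sign stay within [0, 1]
    tt <- truth[chrom == ch & kind %in% c("systemic_variant", "tissue_dmr")]
    if (nrow(tt)) {
      for (i in seq_len(nrow(tt))) {
        sel <- pos >= tt$start[i] & pos < tt$end[i]
        u[sel] <- runif(sum(sel), 0.32, 0.45)
      }
    }
    u
  })
  u
}

tissue_offsets_for_chrom <- function(genome, params, ch) {
  n <- length(genome$cpg[[ch]])
  off <- sapply(params$tissues, function(t)
    with_seed(derive_seed(params$seed, "tissue", ch, t),
              stats::rnorm(n, 0, params$tissue_profile_sd)))
  matrix(off, nrow = n, dimnames = list(NULL, params$tissues))
}

# CpG-SNPs: destroyed CpG dinucleotides. Returns variant records plus the
# per-(site, subject) forcing table.
plant_cpg_snps <- function(genome, params, subjects, ch) {
  pos <- genome$cpg[[ch]]
  with_seed(derive_seed(params$seed, "cpgsnp", ch), {
    hit <- which(runif(length(pos)) < params$cpg_snp_rate)
    if (!length(hit)) return(NULL)
    n <- length(hit)
    on_g <- runif(n) < 0.5                       # variant at the G of the CpG
    vpos <- ifelse(on_g, pos[hit] + 1L, pos[hit])
    ref <- ifelse(on_g, "G", "C")
    alt <- ifelse(on_g, "A", "T")
    concordant <- runif(n) < 0.3
    lowq <- runif(n) < 0.1
    qual <- ifelse(lowq, runif(n, 10, 29.9), runif(n, 30, 60))
    carrier <- sample(subjects, n, replace = TRUE)
    gt <- matrix("hom_ref", n, length(subjects),
                 dimnames = list(NULL, subjects))
    for (s in subjects) gt[concordant | carrier == s, s] <- "hom_alt"
    v <- data.table(chrom = ch, pos = as.integer(vpos), ref = ref,
                    alt = alt, qual = round(qual, 1), is_indel = FALSE)
    v <- cbind(v, as.data.table(gt))
    # forcing: any hom_alt genotype destroys that subject's CpG readout
    frc <- rbindlist(lapply(subjects, function(s) {
      w <- which(gt[, s] == "hom_alt")
      if (!length(w)) return(NULL)
      data.table(chrom = ch, pos = pos[hit][w], subject = s)
    }))
    list(variants = v, force = frc)
  })
}

plant_background_variants <- function(genome, params, subjects, ch) {
  len <- genome$chrom_sizes[[ch]]
  pos <- genome$cpg[[ch]]
  with_seed(derive_seed(params$seed, "variants", ch), {
    n <- rpois(1, len * params$variant_rate)
    if (!n) return(NULL)
    vpos <- floor(runif(n, 0, len - 5))
    is_indel <- runif(n) < 0.1
    reflen <- ifelse(is_indel, sample(2:4, n, replace = TRUE), 1L)
    bases <- c("A", "C", "G", "T")
    ref <- vapply(reflen, function(k)
      paste(sample(bases, k, replace = TRUE), collapse = ""), "")
    alt <- vapply(substr(ref, 1, 1), function(b)
      sample(setdiff(bases, b), 1), "")
    alt <- ifelse(is_indel, substr(ref, 1, 1), alt)  # indel: deletion-style
    qual <- round(runif(n, 10, 60), 1)
    gt <- matrix(sample(c("hom_ref", "het", "hom_alt", "missing"),
                        n * length(subjects), replace = TRUE,
                        prob = c(0.5, 0.3, 0.15, 0.05)),
                 n, length(subjects), dimnames = list(NULL, subjects))
    v <- data.table(chrom = ch, pos = as.integer(vpos), ref = ref, alt = alt,
                    qual = qual, is_indel = is_indel)
    v <- cbind(v, as.data.table(gt))
    # background variants must not touch CpG dinucleotides
    cpg_bp <- c(pos, pos + 1L)
    span_hits <- vapply(seq_len(n), function(i) {
      any(cpg_bp >= v$pos[i] & cpg_bp < v$pos[i] + reflen[i])
    }, TRUE)
    v[!span_hits]
  })
}

#' Generate a synthetic screen cohort (subjects x tissues methylomes)
#'
#' Draws per-CpG read counts for every (subject, tissue) library around the
#' baseline profile plus planted offsets. Systemic-variant regions apply the
#' same subject offset in all tissues; tissue-DMR regions apply a subject
#' offset in a strict subset of tissues; CpG-SNPs are planted as
#' homozygous-alternate genotypes that force apparent 0% methylation at
#' the destroyed site in carrier subjects.
#'
#' @param genome a `corsiv_genome` from [generate_genome()].
#' @param params the [sim_params()] used for the genome.
#' @return a list with `cohort` (a `data.table` of per-CpG counts with
#'   columns `chrom, pos, subject, tissue, n_meth, n_unmeth`), `truth`
#'   (planted regions), and `variants` (genotype records for all subjects).
#' @export
generate_cohort <- function(genome, params) {
  if (!inherits(genome, "corsiv_genome"))
    abort_config("genome must come from generate_genome()")
  subjects <- subject_names(params$n_subjects)
  truth <- plant_truth(genome, params)
  cohort_parts <- list()
  var_parts <- list()
  for (ch in names(genome$chrom_sizes)) {
    pos <- genome$cpg[[ch]]
    u <- baseline_for_chrom(genome, params, ch, truth)
    toff <- tissue_offsets_for_chrom(genome, params, ch)
    snps <- plant_cpg_snps(genome, params, subjects, ch)
    bg <- plant_background_variants(genome, params, subjects, ch)
    var_parts[[length(var_parts) + 1L]] <- rbind(snps$variants, bg)
    # per-subject offsets from planted regions (subject 1 is the reference)
    sub_off <- array(0, dim = c(length(pos), length(params$tissues),
                                length(subjects)),
                     dimnames = list(NULL, params$tissues, subjects))
    tch <- truth[chrom == ch & kind != "null"]
    if (nrow(tch) && length(subjects) > 1) {
      for (i in seq_len(nrow(tch))) {
        sel <- pos >= tch$start[i] & pos < tch$end[i]
        tis <- if (tch$tissues_affected[i] == "*") params$tissues else
          strsplit(tch$tissues_affected[i], ",")[[1]]
        for (s in subjects[-1]) sub_off[sel, tis, s] <-
            sub_off[sel, tis, s] + tch$effect[i]
      }
    }
    for (s in subjects) {
      for (t in params$tissues) {
        p <- pmin(pmax(u + toff[, t] + sub_off[, t, s], 0), 1)
        counts <- with_seed(derive_seed(params$seed, "reads", ch, s, t), {
          dpt <- rpois(length(pos), params$depth_mean)
          nm <- rbetabinom(length(pos), dpt, p, params$beta_binomial_rho)
          list(dpt = dpt, nm = nm)
        })
        dt <- data.table(chrom = ch, pos = pos, subject = s, tissue = t,
                         n_meth = counts$nm,
                         n_unmeth = counts$dpt - counts$nm)
        cohort_parts[[length(cohort_parts) + 1L]] <- dt
      }
    }
    # CpG-SNP forcing: destroyed site reads as fully unmethylated
    if (!is.null(snps) && nrow(snps$force)) {
      last_n <- length(cohort_parts)
      idx <- (last_n - length(subjects) * length(params$tissues) + 1L):last_n
      for (k in idx) {
        dtk <- cohort_parts[[k]]
        f <- snps$force[subject == dtk$subject[1]]
        if (nrow(f)) {
          m <- dtk$pos %in% f$pos
          dtk[m, `:=`(n_unmeth = n_meth + n_unmeth, n_meth = 0L)]
        }
      }
    }
  }
  cohort <- rbindlist(cohort_parts)
  setkey(cohort, chrom, pos)
  variants <- rbindlist(var_parts)
  if (nrow(variants)) setorder(variants, chrom, pos)
  list(cohort = cohort, truth = truth, variants = variants)
}

#' Generate a two-group cohort with planted group-level effects
#'
#' Emulates an assisted-reproduction comparison: `group_sizes[1]` exposed
#' subjects and `group_sizes[2]` controls, each with one methylome per
#' tissue. Group 1 receives a methylation offset at the given intervals —
#' in all tissues by default (systemic, the behaviour observed at
#' CoRSIV-overlapping group differences) or in a named subset.
#'
#' @param genome a `corsiv_genome`.
#' @param params [sim_params()]; `tissues` and noise settings are reused.
#' @param group_effect_at `data.table` of intervals (`chrom, start, end`)
#'   receiving the group offset; empty for a null cohort.
#' @param group_sizes integer vector of two group sizes (each >= 2).
#' @param group_effect methylation-fraction offset added to group 1.
#' @param affected_tissues tissues receiving the offset; `NULL` = all.
#' @param group_labels labels for the two groups.
#' @return list with `cohort` (counts with `subject`, `group`, `tissue`)
#'   and `truth` (per-tissue DMR-style records of the planted intervals).
#' @export
generate_two_group_cohort <- function(genome, params, group_effect_at,
                                      group_sizes = c(4, 4),
                                      group_effect = 0.20,
                                      affected_tissues = NULL,
                                      group_labels = c("g1", "g2")) {
  if (any(group_sizes < 2)) abort_config("group sizes must be >= 2")
  group_effect_at <- as.data.table(group_effect_at)
  if (nrow(group_effect_at)) check_intervals(group_effect_at, "group_effect_at")
  if (is.null(affected_tissues)) affected_tissues <- params$tissues
  subjects <- c(sprintf("%s_%d", group_labels[1], seq_len(group_sizes[1])),
                sprintf("%s_%d", group_labels[2], seq_len(group_sizes[2])))
  grp <- rep(group_labels, group_sizes)
  parts <- list()
  for (ch in names(genome$chrom_sizes)) {
    pos <- genome$cpg[[ch]]
    # intermediate baseline at effect intervals keeps offsets unclipped
    u <- with_seed(derive_seed(params$seed, "baseline2", ch), {
      u <- rbeta(length(pos), 5, 2)
      gch <- group_effect_at[chrom == ch]
      if (nrow(gch)) for (i in seq_len(nrow(gch))) {
        sel <- pos >= gch$start[i] & pos < gch$end[i]
        u[sel] <- runif(sum(sel), 0.30, 0.55)
      }
      u
    })
    toff <- tissue_offsets_for_chrom(genome, params, ch)
    eff <- rep(0, length(pos))
    gch <- group_effect_at[chrom == ch]
    if (nrow(gch)) for (i in seq_len(nrow(gch)))
      eff[pos >= gch$start[i] & pos < gch$end[i]] <- group_effect
    for (k in seq_along(subjects)) {
      s <- subjects[k]
      for (t in params$tissues) {
        p <- u + toff[, t]
        if (grp[k] == group_labels[1] && t %in% affected_tissues)
          p <- p + eff
        p <- pmin(pmax(p, 0), 1)
        counts <- with_seed(derive_seed(params$seed, "reads2", ch, s, t), {
          dpt <- rpois(length(pos), params$depth_mean)
          nm <- rbetabinom(length(pos), dpt, p, params$beta_binomial_rho)
          list(dpt = dpt, nm = nm)
        })
        parts[[length(parts) + 1L]] <- data.table(
          chrom = ch, pos = pos, subject = s, group = grp[k], tissue = t,
          n_meth = counts$nm, n_unmeth = counts$dpt - counts$nm)
      }
    }
  }
  cohort <- rbindlist(parts)
  setkey(cohort, chrom, pos)
  truth <- if (nrow(group_effect_at)) {
    rbindlist(lapply(affected_tissues, function(t)
      data.table(group_effect_at[, .(chrom, start, end)], tissue = t,
                 direction = sign(group_effect), mean_diff = group_effect)))
  } else data.table(chrom = character(), start = integer(), end = integer(),
                    tissue = character(), direction = numeric(),
                    mean_diff = numeric())
  list(cohort = cohort, truth = truth)
}

#' Generate synthetic annotation tracks for a genome
#'
#' Gene models (for TSS/TES/gene-body annotation), repeat features
#' (LINE/SINE/LTR classes) and the genome's CpG islands, for exercising the
#' genomic-context stages without external tracks.
#'
#' @param genome a `corsiv_genome`.
#' @param seed integer seed.
#' @param gene_spacing,repeat_spacing mean bp between features.
#' @return list of `data.table`s: `genes`, `repeats`, `cpg_islands`.
#' @export
generate_annotation <- function(genome, seed = 1L, gene_spacing = 5e4,
                                repeat_spacing = 4e3) {
  genes <- list(); reps <- list()
  classes <- c("LINE", "SINE", "LTR")
  families <- list(LINE = c("L1", "L2"), SINE = c("BovA", "MIR"),
                   LTR = c("ERVK", "ERVL"))
  for (ch in names(genome$chrom_sizes)) {
    len <- genome$chrom_sizes[[ch]]
    g <- with_seed(derive_seed(seed, "genes", ch), {
      n <- rpois(1, len / gene_spacing)
      s <- sort(floor(runif(n, 0, max(len - 3e4, 1))))
      w <- floor(runif(n, 5e3, 3e4))
      data.table(chrom = ch, strand = sample(c("+", "-"), n, TRUE),
                 txStart = as.integer(s),
                 txEnd = as.integer(pmin(s + w, len)),
                 name = sprintf("%s_g%03d", ch, seq_len(n)))
    })
    r <- with_seed(derive_seed(seed, "repeats", ch), {
      n <- rpois(1, len / repeat_spacing)
      s <- floor(runif(n, 0, max(len - 6e3, 1)))
      w <- floor(runif(n, 200, 6e3))
      cls <- sample(classes, n, TRUE, prob = c(0.45, 0.35, 0.2))
      fam <- vapply(cls, function(k) sample(families[[k]], 1), "")
      data.table(chrom = ch, start = as.integer(s),
                 end = as.integer(pmin(s + w, len)),
                 repeat_class = cls, repeat_family = fam)
    })
    genes[[ch]] <- g; reps[[ch]] <- r
  }
  list(genes = rbindlist(genes), repeats = rbindlist(reps),
       cpg_islands = copy(genome$islands))
}
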