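# Genomic-context annotation of CoRSIVs and control regions: genic
# features (TSS/TES/gene body/intergenic), genetic-variant concordance in
# 1-kb windows, and repeat-class profiles in +/- 50 kb flanks.

#' Yates-corrected 2x2 chi-square (closed form)
#'
#' `chi2 = N * (max(0, |ad - bc| - N/2))^2 / ((a+b)(c+d)(a+c)(b+d))`.
#' Degenerate tables (a zero margin) get `chi2 = 0`, `p = 1` and a
#' `degenerate` flag — genome-scale sweeps never abort. Vectorized.
#'
#' @param a,b,c,d cell counts (row-major: `[[a, b], [c, d]]`).
#' @return `data.table` with `chi2, p, degenerate, odds_ratio`.
#' @export
yates_chisq <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  den <- (a + b) * (c + d) * (a + c) * (b + d)
  num <- n * pmax(0, abs(a * d - b * c) - n / 2)^2
  chi2 <- fifelse(den > 0, num / den, 0)
  data.table(chi2 = chi2,
             p = fifelse(den > 0, pchisq(chi2, 1, lower.tail = FALSE), 1),
             degenerate = den <= 0,
             odds_ratio = fifelse(b * c > 0, (a * d) / (b * c), NA_real_))
}

#' Annotate regions with genic categories
#'
#' A region is a TSS region when any transcription start site lies within
#' `window` bp of it (minimal distance between any point of the region and
#' the TSS coordinate, inclusive), a TES region likewise for transcription
#' end sites, a gene-body region when it overlaps any gene span, and
#' intergenic when none of the above. Categories are not exclusive.
#'
#' @param regions interval table (`chrom, start, end`, optional `id`).
#' @param genes gene models from [read_gene_models()] (or any table with
#'   `chrom, strand, txStart, txEnd`).
#' @param window distance threshold in bp (default 2500).
#' @return `regions` with logical columns `tss, tes, gene_body,
#'   intergenic`.
#' @export
genic_annotation <- function(regions, genes, window = 2500) {
  regions <- as.data.table(regions)
  check_intervals(regions, "regions")
  genes <- add_tss_tes(genes)
  out <- copy(regions)
  flag_points <- function(pts) {
    # point p is within `window` of [s, e) iff p in [s - window, e + window)
    q <- data.table(chrom = genes$chrom, start = pts, end = pts + 1L)
    r <- out[, .(chrom, start = start - as.integer(window),
                 end = end + as.integer(window))]
    hit <- overlap_pairs(r, q)
    seq_len(nrow(out)) %in% hit$xid
  }
  out[, tss := flag_points(genes$tss)]
  out[, tes := flag_points(genes$tes)]
  body <- data.table(chrom = genes$chrom, start = genes$txStart,
                     end = genes$txEnd)
  hb <- overlap_pairs(out[, .(chrom, start, end)], body)
  out[, gene_body := seq_len(nrow(out)) %in% hb$xid]
  out[, intergenic := !(tss | tes | gene_body)]
  out[]
}

#' Compare TSS-category rates between CoRSIVs and controls
#'
#' Two-sided Yates-corrected chi-square on the 2x2 table of region set by
#' TSS flag, with the odds ratio.
#'
#' @param corsiv_flags,control_flags logical vectors (TSS flags).
#' @return list with `table`, `odds_ratio`, `chi2`, `p` (`NA` when a
#'   margin is zero).
#' @export
tss_enrichment_test <- function(corsiv_flags, control_flags) {
  a <- sum(corsiv_flags); b <- sum(!corsiv_flags)
  c <- sum(control_flags); d <- sum(!control_flags)
  y <- yates_chisq(a, b, c, d)
  list(table = matrix(c(a, b, c, d), 2, byrow = TRUE,
                      dimnames = list(c("corsiv", "control"),
                                      c("tss", "not_tss"))),
       odds_ratio = y$odds_ratio,
       chi2 = y$chi2, p = if (y$degenerate) NA_real_ else y$p)
}

classify_concordance <- function(variants, subjects) {
  g1 <- variants[[subjects[1]]]
  g2 <- variants[[subjects[2]]]
  ifelse(g1 == "missing" | g2 == "missing", "uninformative",
         ifelse(g1 != g2, "discordant",
                ifelse(g1 == "hom_ref", "uninformative", "concordant")))
}

#' Concordant vs discordant variants in windows centered on regions
#'
#' Counts genetic variants (SNPs and indels; an indel overlaps a position
#' when its reference span covers it) inside `window`-bp windows centered
#' on each region's midpoint. A variant is discordant when the two
#' subjects' genotypes differ (both non-missing) and concordant when they
#' are equal with at least one non-reference allele. When two region sets
#' are supplied the 2x2 comparison (concordant/discordant x set) is
#' tested with a Yates chi-square.
#'
#' @param regions interval table (e.g. CoRSIVs).
#' @param variants genotype table.
#' @param subjects the two subjects.
#' @param window total window width in bp (default 1000), start inclusive,
#'   end exclusive.
#' @param regions2 optional second region set (e.g. controls).
#' @return list: `counts` (per set), and with `regions2` also `chi2`, `p`.
#' @export
variant_concordance <- function(regions, variants, subjects, window = 1000,
                                regions2 = NULL) {
  count_set <- function(reg) {
    reg <- as.data.table(reg)
    check_intervals(reg, "regions")
    v <- copy(as.data.table(variants))
    v[, concordance := classify_concordance(v, subjects)]
    v <- v[concordance != "uninformative"]
    v[, `:=`(start = pos, end = pos + nchar(ref))]
    half <- as.integer(window %/% 2)
    win <- reg[, .(chrom, start = (start + end) %/% 2L - half)]
    win[, end := start + as.integer(window)]
    hits <- overlap_pairs(win, v[, .(chrom, start, end)])
    cls <- v$concordance[hits$yid]
    c(concordant = sum(cls == "concordant"),
      discordant = sum(cls == "discordant"))
  }
  c1 <- count_set(regions)
  if (is.null(regions2))
    return(list(counts = rbind(set1 = c1)))
  c2 <- count_set(regions2)
  y <- yates_chisq(c1["concordant"], c1["discordant"],
                   c2["concordant"], c2["discordant"])
  list(counts = rbind(set1 = c1, set2 = c2),
       chi2 = y$chi2, p = if (y$degenerate) NA_real_ else y$p,
       ratio = c(set1 = unname(c1["concordant"] /
                                 max(c1["discordant"], 1)),
                 set2 = unname(c2["concordant"] /
                                 max(c2["discordant"], 1))))
}

#' Repeat-class overlap profile in region flanks
#'
#' For each region and repeat feature within `flank` bp, the repeat is
#' assigned to the direct-overlap stratum when it intersects the region
#' itself, otherwise to the distance stratum of its gap to the nearest
#' region edge (`0-5kb`, `5-10kb`, ... at `step` increments; both sides
#' pooled). Reported per repeat class and stratum as the number of
#' regions with at least one such repeat.
#'
#' @param regions interval table.
#' @param repeats repeat track from [read_repeats()].
#' @param flank flank width in bp (default 50000).
#' @param step stratum width in bp (default 5000).
#' @return `data.table`: `repeat_class, stratum` (ordered factor,
#'   `"overlap"` first), `n_regions`.
#' @export
repeat_flank_profile <- function(regions, repeats, flank = 50000,
                                 step = 5000) {
  regions <- as.data.table(regions)
  check_intervals(regions, "regions")
  repeats <- as.data.table(repeats)
  ext <- regions[, .(chrom, start = pmax(start - as.integer(flank), 0L),
                     end = end + as.integer(flank))]
  rp <- repeats[, .(chrom, start, end, repeat_class)]
  pairs <- overlap_pairs(ext, rp)
  if (nrow(pairs) == 0L)
    return(data.table(repeat_class = character(), stratum = character(),
                      n_regions = integer()))
  hits <- data.table(xid = pairs$xid,
                     rs = regions$start[pairs$xid],
                     re = regions$end[pairs$xid],
                     start = rp$start[pairs$yid],
                     end = rp$end[pairs$yid],
                     repeat_class = rp$repeat_class[pairs$yid])
  # gap between repeat [start, end) and region [rs, re); 0 if overlapping
  hits[, d := pmax(rs - end, start - re, 0L)]
  hits[, stratum := fifelse(start < re & end > rs, "overlap",
                            paste0(pmin(d %/% as.integer(step),
                                        flank %/% step - 1L) * step / 1000,
                                   "-",
                                   (pmin(d %/% as.integer(step),
                                         flank %/% step - 1L) + 1L) *
                                     step / 1000, "kb"))]
  out <- hits[, .(n_regions = uniqueN(xid)), by = .(repeat_class, stratum)]
  lev <- c("overlap", paste0(seq(0, flank - step, step) / 1000, "-",
                             seq(step, flank, step) / 1000, "kb"))
  out[, stratum := factor(stratum, levels = lev)]
  setorder(out, repeat_class, stratum)
  out[]
}
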