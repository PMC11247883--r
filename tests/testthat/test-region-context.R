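# matched controls, genic annotation, variant concordance, repeat flanks

make_pool <- function(seed = 1, size = 5e5) {
  p <- sim_params(chrom_sizes = c(chr1 = size), seed = seed)
  g <- generate_genome(p)
  cpg <- cpg_sites(g)
  list(genome = g, cpg = cpg, bins = make_bins(cpg))
}

test_that("controls match chromosome, CpG count and size exactly", {
  w <- make_pool(seed = 4)
  # pretend-CoRSIVs: three island windows
  isl <- w$genome$islands[1:3]
  corsivs <- data.table::data.table(
    id = sprintf("c%d", 1:3), chrom = isl$chrom,
    start = (isl$start %/% 100L) * 100L,
    end = ((isl$end + 99L) %/% 100L) * 100L)
  corsivs[, n_cpg := count_in_window(w$genome$cpg$chr1, start, end),
          by = id]
  ctl <- match_controls(corsivs, w$bins, w$cpg,
                        w$genome$chrom_sizes, seed = 9)
  expect_equal(nrow(ctl), 3)
  ok <- !is.na(ctl$start)
  expect_true(any(ok))
  for (i in which(ok)) {
    expect_equal(ctl$chrom[i], corsivs$chrom[i])
    expect_equal(count_in_window(w$genome$cpg$chr1, ctl$start[i],
                                 ctl$end[i]), ctl$n_cpg[i])
    expect_equal(ctl$n_cpg[i], corsivs$n_cpg[i])
    expect_equal(ctl$size[i], (corsivs$end[i] - corsivs$start[i]) +
                   100L * ctl$relaxation[i])
  }
  # no control overlaps a CoRSIV or another control
  iv <- rbind(corsivs[, .(chrom, start, end)], ctl[ok, .(chrom, start, end)])
  data.table::setorder(iv, chrom, start)
  expect_true(all(iv[, start[-1] >= head(end, -1)]))
  # deterministic under seed
  ctl2 <- match_controls(corsivs, w$bins, w$cpg,
                         w$genome$chrom_sizes, seed = 9)
  expect_identical(ctl, ctl2)
  # order-invariant up to relabeling (per-CoRSIV streams keyed by id)
  ctl3 <- match_controls(corsivs[c(3, 1, 2)], w$bins, w$cpg,
                         w$genome$chrom_sizes, seed = 9)
  expect_identical(ctl[order(matched_corsiv), !"id"],
                   ctl3[order(matched_corsiv), !"id"])
})

test_that("size relaxation is forced when no exact-size match exists", {
  # constructed pool: CpG pattern offers a 6-CpG window only at 400 bp
  cpg <- data.table::data.table(
    chrom = "chr1",
    pos = c(
      seq(100L, 350L, 50L),              # "CoRSIV": 6 CpGs in [100, 400)
      c(5000L, 5150L, 5250L, 5320L, 5380L, 5390L)))  # 6 CpGs over 390 bp
  corsiv <- data.table::data.table(id = "c1", chrom = "chr1", start = 100L,
                                   end = 400L, n_cpg = 6L)
  pool <- data.table::data.table(chrom = "chr1", start = c(5000L),
                                 end = c(5100L))
  ctl <- match_controls(corsiv, pool, cpg, c(chr1 = 10000L), seed = 1,
                        max_attempts = 50)
  expect_equal(ctl$n_cpg, 6L)
  expect_equal(ctl$relaxation, 1L)     # 300 -> 400 bp
  expect_equal(ctl$size, 400L)
  # an impossible request is reported unmatched, not fabricated
  corsiv9 <- data.table::copy(corsiv)[, n_cpg := 9L]
  expect_warning(
    ctl9 <- match_controls(corsiv9, pool, cpg, c(chr1 = 2000L), seed = 1,
                           max_attempts = 10),
    "no control")
  expect_true(is.na(ctl9$start))
})

test_that("controls stay disjoint from CoRSIVs across many random worlds", {
  for (seed in c(11, 22, 33)) {
    w <- make_pool(seed = seed, size = 4e5)
    isl <- w$genome$islands[1:2]
    corsivs <- data.table::data.table(
      id = sprintf("c%d", 1:2), chrom = isl$chrom,
      start = (isl$start %/% 100L) * 100L,
      end = ((isl$end + 99L) %/% 100L) * 100L)
    corsivs[, n_cpg := count_in_window(w$genome$cpg$chr1, start, end),
            by = id]
    ctl <- suppressWarnings(match_controls(corsivs, w$bins, w$cpg,
                                           w$genome$chrom_sizes,
                                           seed = seed))
    ok <- ctl[!is.na(start)]
    if (nrow(ok)) {
      both <- rbind(corsivs[, .(chrom, start, end)],
                    ok[, .(chrom, start, end)])
      data.table::setorder(both, chrom, start)
      expect_true(all(both[, start[-1] >= head(end, -1)]))
    }
  }
})

test_that("genic annotation flags TSS/TES/gene body/intergenic", {
  genes <- data.table::data.table(
    chrom = "chr1", strand = c("+", "-"),
    txStart = c(10000L, 50000L), txEnd = c(30000L, 70000L),
    name = c("gPlus", "gMinus"))
  regions <- data.table::data.table(
    id = c("tss_prox", "intron", "far", "tes_minus"),
    chrom = "chr1",
    start = c(8000L, 15000L, 200000L, 48000L),
    end = c(8200L, 15200L, 200200L, 48200L))
  ann <- genic_annotation(regions, genes)
  expect_true(ann[id == "tss_prox"]$tss)        # 1800 bp from TSS
  expect_false(ann[id == "tss_prox"]$gene_body)
  expect_true(ann[id == "intron"]$gene_body)    # inside, > 2.5 kb from ends
  expect_false(ann[id == "intron"]$tss)
  expect_true(ann[id == "far"]$intergenic)
  # minus-strand gene: TES at txStart = 50000; region within 2.5 kb
  expect_true(ann[id == "tes_minus"]$tes)
  expect_false(ann[id == "tes_minus"]$tss)
  # inclusive distance boundary: last region base 7500, TSS 10000 -> 2500
  edge <- data.table::data.table(chrom = "chr1", start = 7400L,
                                 end = 7501L)
  expect_true(genic_annotation(edge, genes)$tss)
  # last base 7499 -> distance 2501 -> excluded
  edge2 <- data.table::data.table(chrom = "chr1", start = 7400L,
                                  end = 7500L)
  expect_false(genic_annotation(edge2, genes)$tss)
  # flags stable under gene-list permutation
  ann_perm <- genic_annotation(regions, genes[c(2, 1)])
  expect_equal(ann, ann_perm)
})

test_that("tss_enrichment_test matches the closed-form Yates chi-square", {
  same <- c(rep(TRUE, 30), rep(FALSE, 70))
  r0 <- tss_enrichment_test(same, same)
  expect_equal(r0$odds_ratio, 1)
  expect_gt(r0$p, 0.95)
  cf <- c(rep(TRUE, 60), rep(FALSE, 157))
  kf <- c(rep(TRUE, 30), rep(FALSE, 187))
  r <- tss_enrichment_test(cf, kf)
  o <- oracle_yates(60, 157, 30, 187)
  expect_equal(r$chi2, unname(o$statistic), tolerance = 1e-9)
  expect_equal(r$p, o$p.value, tolerance = 1e-9)
  # degenerate margin reported as undefined
  expect_true(is.na(tss_enrichment_test(rep(FALSE, 5), rep(FALSE, 5))$p))
})

test_that("variant concordance counts use half-open centered windows", {
  regions <- data.table::data.table(chrom = "chr1", start = 1000L,
                                    end = 1200L)   # midpoint 1100
  mkv <- function(pos, g1, g2, ref = "A")
    data.table::data.table(chrom = "chr1", pos = pos, ref = ref, alt = "T",
                           qual = 50, is_indel = nchar(ref) > 1,
                           s1 = g1, s2 = g2)
  v <- rbind(
    mkv(600L, "het", "het"),          # window start, inclusive
    mkv(1599L, "hom_alt", "hom_ref"), # last in-window base
    mkv(1600L, "het", "hom_ref"),     # end exclusive -> out
    mkv(599L, "het", "hom_ref"),      # before start -> out
    mkv(800L, "missing", "het"),      # uninformative
    mkv(900L, "hom_ref", "hom_ref"),  # shared hom_ref: no variant
    mkv(597L, "het", "het", ref = "AAAA"))  # indel spans into window
  r <- variant_concordance(regions, v, c("s1", "s2"))
  expect_equal(unname(r$counts[1, "concordant"]), 2)  # 600 + indel
  expect_equal(unname(r$counts[1, "discordant"]), 1)  # 1599
  # two-set comparison is a Yates chi-square
  r2 <- variant_concordance(regions, v, c("s1", "s2"), regions2 = regions)
  expect_equal(r2$counts[1, ], r2$counts[2, ])
  expect_gt(r2$p, 0.9)
})

test_that("repeat flank strata follow the 5-kb increments", {
  regions <- data.table::data.table(chrom = "chr1", start = 100000L,
                                    end = 100500L)
  reps <- data.table::data.table(
    chrom = "chr1",
    start = c(97000L, 100200L, 88000L, 140000L, 160000L),
    end = c(98000L, 100300L, 89000L, 141000L, 161000L),
    repeat_class = c("LINE", "LINE", "SINE", "LTR", "LTR"),
    repeat_family = "x")
  prof <- repeat_flank_profile(regions, reps)
  g <- function(cl, s) prof[repeat_class == cl & stratum == s]$n_regions
  expect_equal(g("LINE", "0-5kb"), 1)      # gap 2000 upstream
  expect_equal(g("LINE", "overlap"), 1)    # direct overlap only
  expect_equal(g("SINE", "10-15kb"), 1)    # gap 11000
  expect_equal(g("LTR", "35-40kb"), 1)     # gap 39500 downstream
  expect_equal(nrow(prof[repeat_class == "LTR" & stratum != "35-40kb" &
                           n_regions > 0]), 0)  # 160 kb repeat out of range
})

test_that("repeat profile agrees with brute-force interval math", {
  set.seed(55)
  for (i in 1:20) {
    regions <- data.table::data.table(
      chrom = "chr1", start = sort(sample.int(5e5, 3)) )
    regions[, end := start + sample(c(200L, 400L), 3, replace = TRUE)]
    reps <- data.table::data.table(
      chrom = "chr1", start = sample.int(6e5, 40))
    reps[, end := start + sample.int(3000L, 40)]
    reps[, repeat_class := sample(c("LINE", "SINE"), 40, replace = TRUE)]
    prof <- repeat_flank_profile(regions, reps, flank = 20000, step = 5000)
    # oracle: nested loops over regions x repeats
    want <- list()
    for (r in seq_len(nrow(regions))) {
      for (q in seq_len(nrow(reps))) {
        rs <- regions$start[r]; re <- regions$end[r]
        qs <- reps$start[q]; qe <- reps$end[q]
        if (qs < re && qe > rs) {
          str <- "overlap"
        } else {
          d <- max(rs - qe, qs - re, 0)
          if (d >= 20000) next
          k <- d %/% 5000
          str <- paste0(k * 5, "-", (k + 1) * 5, "kb")
        }
        want[[length(want) + 1]] <-
          data.frame(cl = reps$repeat_class[q], str = str, region = r)
      }
    }
    want <- unique(do.call(rbind, want))
    agg <- stats::aggregate(region ~ cl + str, want, length)
    for (j in seq_len(nrow(agg))) {
      got <- prof[repeat_class == agg$cl[j] &
                    as.character(stratum) == agg$str[j]]$n_regions
      expect_equal(got, agg$region[j])
    }
    expect_equal(sum(prof$n_regions), sum(agg$region))
  }
})
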