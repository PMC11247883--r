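# two-group analysis: overlap validity, read-level chi-square, adjustment,
# enrichment, direction bias, clustering, validation criterion

test_that("overlap validity uses half the smaller interval", {
  region <- data.table::data.table(chrom = "chr1", start = 0L, end = 200L)
  dmr <- data.table::data.table(chrom = "chr1", start = 80L, end = 1080L)
  expect_true(overlap_is_valid(region, dmr))    # 120 >= 100
  dmr2 <- data.table::data.table(chrom = "chr1", start = 120L, end = 1120L)
  expect_false(overlap_is_valid(region, dmr2))  # 80 < 100
  # region contained in DMR: always valid
  dmr3 <- data.table::data.table(chrom = "chr1", start = 0L, end = 5000L)
  expect_true(overlap_is_valid(region, dmr3))
  # different chromosome: never valid
  dmr4 <- data.table::data.table(chrom = "chr2", start = 0L, end = 200L)
  expect_false(overlap_is_valid(region, dmr4))
})

test_that("yates_chisq reproduces hand and textbook values", {
  y <- yates_chisq(10, 20, 20, 10)
  expect_equal(y$chi2, 5.4)                     # N(|ad-bc|-N/2)^2 / prod
  o <- oracle_yates(10, 20, 20, 10)
  expect_equal(y$chi2, unname(o$statistic))
  expect_equal(y$p, o$p.value)
  # identical rows: chi2 = 0, p = 1
  y0 <- yates_chisq(15, 5, 15, 5)
  expect_equal(y0$chi2, 0)
  expect_equal(y0$p, 1)
  # degenerate margin: p = 1 flagged, no error
  yd <- yates_chisq(0, 0, 5, 5)
  expect_true(yd$degenerate)
  expect_equal(yd$p, 1)
})

test_that("yates_chisq matches stats::chisq.test on 1000 random tables", {
  set.seed(77)
  n <- 1000
  a <- rpois(n, 20); b <- rpois(n, 15); cc <- rpois(n, 10); d <- rpois(n, 25)
  keep <- (a + b) > 0 & (cc + d) > 0 & (a + cc) > 0 & (b + d) > 0
  y <- yates_chisq(a[keep], b[keep], cc[keep], d[keep])
  for (i in seq_len(sum(keep))) {
    o <- oracle_yates(a[keep][i], b[keep][i], cc[keep][i], d[keep][i])
    expect_equal(y$chi2[i], unname(o$statistic), tolerance = 1e-9)
    expect_equal(y$p[i], o$p.value, tolerance = 1e-9)
  }
  # doubling all counts increases chi2 at fixed proportions
  y1 <- yates_chisq(10, 20, 20, 10)
  y2 <- yates_chisq(20, 40, 40, 20)
  expect_gt(y2$chi2, y1$chi2)
})

test_that("BH adjustment reproduces the step-up hand example", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_pvalues(0.2), 0.2)
  expect_equal(adjust_pvalues(numeric()), numeric())
  p <- c(0.001, 0.5, 0.04, 0.9)
  perm <- c(3, 1, 4, 2)
  expect_equal(adjust_pvalues(p)[perm], adjust_pvalues(p[perm]))
  expect_true(all(adjust_pvalues(p) >= p))
  expect_equal(adjust_pvalues(p, "bonferroni"), pmin(p * 4, 1))
  expect_error(adjust_pvalues(c(0.5, 1.2)), class = "corsivr_data_error")
})

test_that("region_group_test sums reads per region and flags degenerates", {
  regions <- data.table::data.table(id = c("r1", "r2"), chrom = "chr1",
                                    start = c(0L, 1000L),
                                    end = c(500L, 1500L))
  co <- data.table::rbindlist(list(
    data.table::data.table(chrom = "chr1", pos = c(10L, 20L), subject = "a1",
                           group = "g1", tissue = "t",
                           n_meth = c(5L, 5L), n_unmeth = c(10L, 10L)),
    data.table::data.table(chrom = "chr1", pos = c(10L, 20L), subject = "b1",
                           group = "g2", tissue = "t",
                           n_meth = c(10L, 10L), n_unmeth = c(5L, 5L))))
  r <- region_group_test(co, regions, groups = c("g1", "g2"))
  r1 <- r[id == "r1"]
  expect_equal(c(r1$meth1, r1$unmeth1, r1$meth2, r1$unmeth2),
               c(10, 20, 20, 10))
  expect_equal(r1$chi2, 5.4)
  expect_equal(r1$direction, -1)
  # r2 has no CpGs: degenerate, p = 1
  expect_true(r[id == "r2"]$degenerate)
  expect_equal(r[id == "r2"]$p, 1)
})

test_that("dmr_enrichment counts valid overlaps per tissue", {
  corsivs <- data.table::data.table(chrom = "chr1",
                                    start = c(0L, 1000L, 2000L),
                                    end = c(200L, 1200L, 2200L))
  controls <- data.table::data.table(chrom = "chr1",
                                     start = c(5000L, 6000L, 7000L),
                                     end = c(5200L, 6200L, 7200L))
  dmrs <- list(
    liver = data.table::data.table(chrom = "chr1", start = c(0L, 1000L),
                                   end = c(200L, 1150L)),
    muscle = data.table::data.table(chrom = "chr1", start = 9000L,
                                    end = 9100L))
  e <- dmr_enrichment(corsivs, controls, dmrs)
  expect_equal(e[tissue == "liver"]$corsiv_hit, 2)
  expect_equal(e[tissue == "liver"]$control_hit, 0)
  expect_true(is.na(e[tissue == "muscle"]$p))     # zero overlaps both sets
  # swapping the sets leaves p unchanged (test symmetry)
  e2 <- dmr_enrichment(controls, corsivs, dmrs)
  expect_equal(e2[tissue == "liver"]$p, e[tissue == "liver"]$p)
})

test_that("significant_region_enrichment pools per-tissue tables", {
  mk <- function(tissue, sig, ns, set) data.table::data.table(
    id = sprintf("%s_%s_%d", set, tissue, seq_len(sig + ns)),
    tissue = tissue, p_adj = c(rep(0.01, sig), rep(0.5, ns)))
  ct <- rbind(mk("liver", 8, 2, "c"), mk("muscle", 6, 4, "c"))
  kt <- rbind(mk("liver", 1, 9, "k"), mk("muscle", 2, 8, "k"))
  enr <- significant_region_enrichment(ct, kt)
  comb <- enr[tissue == "combined"]
  expect_equal(comb$corsiv_sig,
               sum(enr[tissue != "combined"]$corsiv_sig))
  expect_equal(comb$control_sig,
               sum(enr[tissue != "combined"]$control_sig))
  expect_lt(comb$p, 0.05)
  # equal significance rates: p ~ 1
  same <- significant_region_enrichment(mk("liver", 5, 5, "c"),
                                        mk("liver", 5, 5, "k"))
  expect_gt(same[tissue == "combined"]$p, 0.9)
})

test_that("direction bias test is an exact two-sided sign test", {
  expect_equal(direction_bias_test(c(rep(1, 10), rep(-1, 10)))$p, 1)
  r <- direction_bias_test(rep(2.5, 15))
  expect_equal(r$n_pos, 15L)
  expect_equal(r$p, 2 * 0.5^15)                 # ~6.1e-5
  expect_equal(direction_bias_test(rep(-2.5, 15))$p, r$p)  # sign symmetry
  set.seed(1)
  v <- rnorm(31)
  expect_equal(direction_bias_test(v)$p, direction_bias_test(-v)$p)
  expect_true(is.na(direction_bias_test(c(0, 0))$p))
})

test_that("clustering calls by_tissue vs by_individual correctly", {
  set.seed(9)
  n <- 150
  tissue <- rep(c("cortex", "lung", "blood"), 2)
  subject <- rep(c("s1", "s2"), each = 3)
  t_eff <- matrix(rnorm(n * 3, sd = 10), n)[, match(tissue,
                                                    unique(tissue))]
  s_eff <- matrix(rnorm(n * 2, sd = 10), n)[, match(subject,
                                                    unique(subject))]
  noise <- function() matrix(rnorm(n * 6, sd = 1), n)
  base <- matrix(rep(runif(n, 20, 80), 6), n)
  by_t <- cluster_libraries(base + t_eff + noise(), tissue, subject)
  expect_equal(by_t$grouping, "by_tissue")
  by_s <- cluster_libraries(base + s_eff + noise(), tissue, subject)
  expect_equal(by_s$grouping, "by_individual")
  for (link in c("average", "complete")) {
    expect_equal(cluster_libraries(base + t_eff, tissue, subject,
                                   linkage = link)$grouping, "by_tissue")
  }
  # identical columns: degenerate, mixed
  deg <- cluster_libraries(base, tissue, subject)
  expect_equal(deg$grouping, "mixed")
  expect_true(deg$degenerate)
  expect_error(cluster_libraries(base[, 1, drop = FALSE], "a", "b"),
               class = "corsivr_config_error")
})

test_that("validation criterion is inclusive at r = 0.71", {
  mk <- function(vals_by_tissue, region = "r1") {
    data.table::rbindlist(lapply(names(vals_by_tissue), function(t)
      data.table::data.table(region = region,
                             animal = seq_along(vals_by_tissue[[t]]),
                             tissue = t, meth = vals_by_tissue[[t]])))
  }
  v <- seq(10, 90, length.out = 20)
  # identical vectors: r = 1, validated
  d1 <- mk(list(liver = v, kidney = v, cortex = rnorm(20)))
  r1 <- validate_regions(d1)
  expect_true(r1$validated)
  expect_equal(r1$r_max, 1)
  # exactly r = 0.71 via constructed vectors
  set.seed(4)
  x <- rnorm(20)
  e <- rnorm(20); e <- residuals(lm(e ~ x))
  target <- 0.71
  y <- target * sd(e) * x + e * sd(x) * sqrt(1 - target^2)
  expect_equal(cor(x, y), target, tolerance = 1e-12)
  d2 <- mk(list(liver = x, kidney = y, cortex = rnorm(20)))
  expect_true(validate_regions(d2)$validated)
  # zero variance pair excluded, not validated on noise
  d3 <- mk(list(liver = rep(5, 20), kidney = rnorm(20),
                cortex = rnorm(20)))
  r3 <- validate_regions(d3)
  expect_true(is.na(r3$r_liver_kidney) || is.na(r3$r_cortex_liver))
  # blood proxy correlations are reported when asked
  d4 <- mk(list(liver = v, kidney = v, cortex = v, blood = v))
  r4 <- validate_regions(d4, blood = "blood")
  expect_true(all(abs(unlist(r4[, grep("r_blood", names(r4)),
                                with = FALSE]) - 1) < 1e-12))
})
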