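# Two-group (exposed vs control cohort) analysis: DMR-overlap enrichment
# at CoRSIVs vs matched controls, read-level per-region chi-square tests,
# direction-bias tests, clustering sanity checks, and the inter-tissue
# correlation validation criterion.

#' Is a region/DMR overlap valid?
#'
#' Valid when the intersection is at least half the size of the smaller of
#' the two intervals.
#'
#' @param region,dmr interval tables (`chrom, start, end`), recycled
#'   row-wise.
#' @return logical vector.
#' @export
overlap_is_valid <- function(region, dmr) {
  region <- as.data.table(region)
  dmr <- as.data.table(dmr)
  n <- max(nrow(region), nrow(dmr))
  ri <- rep_len(seq_len(nrow(region)), n)
  di <- rep_len(seq_len(nrow(dmr)), n)
  inter <- pmax(0, pmin(region$end[ri], dmr$end[di]) -
                  pmax(region$start[ri], dmr$start[di]))
  inter <- inter * (region$chrom[ri] == dmr$chrom[di])
  w_min <- pmin(region$end[ri] - region$start[ri],
                dmr$end[di] - dmr$start[di])
  inter >= 0.5 * w_min
}

count_valid_overlaps <- function(regions, dmrs) {
  regions <- as.data.table(regions)
  dmrs <- as.data.table(dmrs)
  if (nrow(regions) == 0L || nrow(dmrs) == 0L)
    return(rep(FALSE, nrow(regions)))
  pairs <- overlap_pairs(regions[, .(chrom, start, end)],
                         dmrs[, .(chrom, start, end)])
  if (nrow(pairs) == 0L) return(rep(FALSE, nrow(regions)))
  rs <- regions$start[pairs$xid]; re <- regions$end[pairs$xid]
  ds <- dmrs$start[pairs$yid]; de <- dmrs$end[pairs$yid]
  inter <- pmin(re, de) - pmax(rs, ds)
  valid <- inter >= 0.5 * pmin(re - rs, de - ds)
  seq_len(nrow(regions)) %in% pairs$xid[valid]
}

#' DMR-overlap enrichment at CoRSIVs vs control regions
#'
#' Per tissue: how many CoRSIVs and how many controls carry at least one
#' valid DMR overlap (see [overlap_is_valid()]), compared by Yates
#' chi-square. With no DMRs the counts are zero and the test undefined.
#'
#' @param corsivs,controls interval tables.
#' @param dmrs_by_tissue named list of DMR interval tables, or one table
#'   with a `tissue` column.
#' @return `data.table`: `tissue, corsiv_hit, corsiv_miss, control_hit,
#'   control_miss, chi2, p` (`p = NA` when undefined).
#' @export
dmr_enrichment <- function(corsivs, controls, dmrs_by_tissue) {
  if (is.data.frame(dmrs_by_tissue)) {
    dd <- as.data.table(dmrs_by_tissue)
    dmrs_by_tissue <- split(dd, dd$tissue)
  }
  rows <- lapply(names(dmrs_by_tissue), function(t) {
    hit_c <- count_valid_overlaps(corsivs, dmrs_by_tissue[[t]])
    hit_k <- count_valid_overlaps(controls, dmrs_by_tissue[[t]])
    a <- sum(hit_c); b <- sum(!hit_c)
    cc <- sum(hit_k); d <- sum(!hit_k)
    y <- yates_chisq(a, b, cc, d)
    data.table(tissue = t, corsiv_hit = a, corsiv_miss = b,
               control_hit = cc, control_miss = d, chi2 = y$chi2,
               p = if (y$degenerate || (a + cc) == 0) NA_real_ else y$p)
  })
  rbindlist(rows)
}

#' Read-level two-group contingency test per region
#'
#' For each region, a 2x2 table of methylated/unmethylated read counts
#' summed over all region CpGs, by group; Yates-corrected chi-square,
#' two-sided. Degenerate margins yield `p = 1` and a flag. Direction is
#' the sign of (group-1 methylation fraction − group-2 fraction).
#'
#' @param cohort long count table with a `group` column (see
#'   [generate_two_group_cohort()]); may contain several tissues — pass
#'   one tissue at a time or use the `tissue` argument.
#' @param regions interval table with `id`.
#' @param groups the two group labels, in order.
#' @param tissue optional tissue filter.
#' @param adjust multiplicity adjustment method passed to
#'   [adjust_pvalues()] (`"BH"` default; `"none"` to skip).
#' @return `data.table`: `id, meth1, unmeth1, meth2, unmeth2, chi2, p,
#'   p_adj, direction, degenerate`.
#' @export
region_group_test <- function(cohort, regions, groups = NULL,
                              tissue = NULL, adjust = "BH") {
  cohort <- as.data.table(cohort)
  regions <- as.data.table(regions)
  check_intervals(regions, "regions")
  if (!"group" %in% names(cohort))
    abort_config("cohort lacks a 'group' column")
  if (!is.null(tissue)) {
    tt <- tissue
    cohort <- cohort[cohort$tissue == tt]
  }
  if (is.null(groups)) groups <- sort(unique(cohort$group))
  if (length(groups) != 2L) abort_config("exactly two groups required")
  if (!"id" %in% names(regions))
    regions <- copy(regions)[, id := sprintf("region_%04d", .I)]
  reg <- regions[, .(id, chrom, start, end)]
  site <- cohort[, .(chrom, start = pos, end = pos + 1L, group, n_meth,
                     n_unmeth)]
  pairs <- overlap_pairs(site, reg, type = "within")
  hits <- cbind(site[pairs$xid, .(group, n_meth, n_unmeth)],
                id = reg$id[pairs$yid])
  agg <- hits[, .(meth = sum(n_meth), unmeth = sum(n_unmeth)),
              by = .(id, group)]
  wide <- dcast(agg, id ~ group, value.var = c("meth", "unmeth"), fill = 0)
  for (cn in c(paste0("meth_", groups), paste0("unmeth_", groups)))
    if (!cn %in% names(wide)) wide[[cn]] <- 0
  out <- wide[regions[, .(id)], on = "id"]
  for (cn in setdiff(names(out), "id")) out[is.na(out[[cn]]), (cn) := 0]
  m1 <- out[[paste0("meth_", groups[1])]]
  u1 <- out[[paste0("unmeth_", groups[1])]]
  m2 <- out[[paste0("meth_", groups[2])]]
  u2 <- out[[paste0("unmeth_", groups[2])]]
  y <- yates_chisq(m1, u1, m2, u2)
  res <- data.table(id = out$id, meth1 = m1, unmeth1 = u1, meth2 = m2,
                    unmeth2 = u2, chi2 = y$chi2, p = y$p,
                    degenerate = y$degenerate)
  res[, direction := sign(meth1 / pmax(meth1 + unmeth1, 1) -
                            meth2 / pmax(meth2 + unmeth2, 1))]
  res[, p_adj := if (identical(adjust, "none")) p else
    adjust_pvalues(p, adjust)]
  res[]
}

#' Adjust p-values for multiple testing
#'
#' Thin, validated wrapper over [stats::p.adjust()]; Benjamini-Hochberg by
#' default, Bonferroni available.
#'
#' @param pvals numeric p-values in `[0, 1]`.
#' @param method `"BH"` or `"bonferroni"`.
#' @return adjusted p-values, same order.
#' @export
adjust_pvalues <- function(pvals, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  if (!length(pvals)) return(numeric())
  if (any(!is.na(pvals) & (pvals < 0 | pvals > 1)))
    abort_data("p-values outside [0, 1]")
  p.adjust(pvals, method = method)
}

#' Do significant two-group regions concentrate in CoRSIVs?
#'
#' Counts CoRSIVs and controls with adjusted p below `alpha`, per tissue
#' and pooled across tissues, each compared by Yates chi-square. The
#' pooled table is the cellwise sum of the per-tissue tables.
#'
#' @param corsiv_tests,control_tests outputs of [region_group_test()],
#'   with a `tissue` column (added by the caller when testing per tissue).
#' @param alpha significance threshold on `p_adj` (default 0.05).
#' @return `data.table` with one row per tissue plus `"combined"`:
#'   significant / non-significant counts for both sets, `chi2`, `p`
#'   (`NA` when a margin is zero).
#' @export
significant_region_enrichment <- function(corsiv_tests, control_tests,
                                          alpha = 0.05) {
  ct <- as.data.table(corsiv_tests)
  kt <- as.data.table(control_tests)
  if (!"tissue" %in% names(ct)) ct <- copy(ct)[, tissue := "all"]
  if (!"tissue" %in% names(kt)) kt <- copy(kt)[, tissue := "all"]
  tissues <- union(unique(ct$tissue), unique(kt$tissue))
  one <- function(tsel, label) {
    a <- ct[tissue %in% tsel, sum(p_adj < alpha, na.rm = TRUE)]
    b <- ct[tissue %in% tsel, sum(!(p_adj < alpha), na.rm = TRUE)]
    cc <- kt[tissue %in% tsel, sum(p_adj < alpha, na.rm = TRUE)]
    d <- kt[tissue %in% tsel, sum(!(p_adj < alpha), na.rm = TRUE)]
    y <- yates_chisq(a, b, cc, d)
    data.table(tissue = label, corsiv_sig = a, corsiv_ns = b,
               control_sig = cc, control_ns = d, chi2 = y$chi2,
               p = if (y$degenerate) NA_real_ else y$p)
  }
  rbindlist(c(lapply(tissues, function(t) one(t, t)),
              list(one(tissues, "combined"))))
}

#' Exact sign test for direction bias
#'
#' Two-sided exact binomial test of positive vs negative signed values
#' against p0 = 0.5; zeros are dropped.
#'
#' @param signed_values numeric vector (e.g. methylation differences).
#' @return list: `n_pos`, `n_neg`, `p` (`NA` when all values are zero).
#' @export
direction_bias_test <- function(signed_values) {
  n_pos <- sum(signed_values > 0)
  n_neg <- sum(signed_values < 0)
  if (n_pos + n_neg == 0)
    return(list(n_pos = 0L, n_neg = 0L, p = NA_real_))
  list(n_pos = n_pos, n_neg = n_neg,
       p = binom.test(n_pos, n_pos + n_neg, 0.5)$p.value)
}

#' Hierarchical clustering of libraries with a tissue/individual call
#'
#' Agglomerative clustering (Euclidean distance on percent methylation,
#' average linkage by default) of the library columns of a regions x
#' libraries matrix. The grouping label reports whether cutting the tree
#' at k = number of tissues reproduces the tissue partition
#' (`"by_tissue"`), at k = number of subjects the subject partition
#' (`"by_individual"`), or neither/both (`"mixed"`).
#'
#' @param mat numeric matrix, rows = regions, columns = libraries;
#'   rows with missing values are dropped (complete-case).
#' @param tissue,subject factors labelling the columns.
#' @param linkage linkage method for [stats::hclust()].
#' @return list: `hclust`, `grouping`, `tissue_clean`, `subject_clean`.
#' @export
cluster_libraries <- function(mat, tissue, subject, linkage = "average") {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2L) abort_config("need at least two libraries")
  mat <- mat[stats::complete.cases(mat), , drop = FALSE]
  if (nrow(mat) == 0L) abort_data("no complete-case regions to cluster")
  dd <- dist(t(mat))
  hc <- hclust(dd, method = linkage)
  if (all(dd == 0))
    return(list(hclust = hc, grouping = "mixed", tissue_clean = FALSE,
                subject_clean = FALSE, degenerate = TRUE))
  clean_cut <- function(lab) {
    k <- length(unique(lab))
    if (k < 2L || k >= ncol(mat)) return(FALSE)
    ct <- cutree(hc, k = k)
    all(rowSums(table(ct, lab) > 0) == 1L) &&
      all(colSums(table(ct, lab) > 0) == 1L)
  }
  t_clean <- clean_cut(tissue)
  s_clean <- clean_cut(subject)
  grouping <- if (t_clean && !s_clean) "by_tissue" else
    if (s_clean && !t_clean) "by_individual" else "mixed"
  list(hclust = hc, grouping = grouping, tissue_clean = t_clean,
       subject_clean = s_clean, degenerate = FALSE)
}

#' Validate regions by inter-tissue correlation
#'
#' A region is validated when at least one inter-tissue Pearson
#' correlation of methylation across animals reaches `r_threshold`
#' (inclusive; 0.71 corresponds to r^2 = 0.5). Pairs with zero variance
#' in either tissue have undefined r and are excluded from the maximum.
#' When a `blood` tissue is given, its correlations with each tissue are
#' reported too (blood as a proxy for systemic regulation) but do not
#' enter the validation criterion.
#'
#' @param meth long table: `region, animal, tissue, meth`.
#' @param r_threshold validation threshold (default 0.71).
#' @param blood optional name of the blood/proxy tissue.
#' @return `data.table`: one row per region with `r_<t1>_<t2>` columns,
#'   `r_max`, `validated`, and `r_blood_<tissue>` columns when requested.
#' @export
validate_regions <- function(meth, r_threshold = 0.71, blood = NULL) {
  meth <- as.data.table(meth)
  need <- c("region", "animal", "tissue", "meth")
  if (!all(need %in% names(meth)))
    abort_config("meth needs columns %s", paste(need, collapse = ", "))
  tissues <- setdiff(unique(meth$tissue), blood)
  if (length(tissues) < 2L) abort_config("need >= 2 non-blood tissues")
  if (uniqueN(meth$animal) < 3L)
    abort_config("need >= 3 animals with paired measurements")
  pairs <- utils::combn(sort(tissues), 2, simplify = FALSE)
  wide <- dcast(meth, region + animal ~ tissue, value.var = "meth")
  safe_r <- function(a, b) {
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) < 3L || sd(a[ok]) == 0 || sd(b[ok]) == 0) return(NA_real_)
    cor(a[ok], b[ok])
  }
  pair_cols <- vapply(pairs, function(pr)
    paste("r", pr[1], pr[2], sep = "_"), "")
  rows <- lapply(split(wide, by = "region"), function(w) {
    rs <- lapply(pairs, function(pr) safe_r(w[[pr[1]]], w[[pr[2]]]))
    names(rs) <- pair_cols
    if (!is.null(blood) && blood %in% names(w)) {
      for (t in tissues)
        rs[[paste0("r_blood_", t)]] <- safe_r(w[[blood]], w[[t]])
    }
    as.data.table(c(list(region = w$region[1]), rs))
  })
  out <- rbindlist(rows)
  rmax <- apply(as.matrix(out[, ..pair_cols]), 1, function(r)
    if (all(is.na(r))) NA_real_ else max(r, na.rm = TRUE))
  out[, r_max := rmax]
  # inclusive threshold with a small numeric guard for exact-boundary r
  out[, validated := !is.na(r_max) & r_max >= r_threshold - 1e-9]
  out[]
}
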