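# Matched control regions: for each CoRSIV, a random same-chromosome,
# same-CpG-count region of the same size, drawn from the screen-adequate
# bin pool with CoRSIV bins removed; size is relaxed in +100 bp steps when
# an exact CpG match cannot be found.

#' Sample control regions matched to CoRSIVs
#'
#' For each CoRSIV (processed in (chrom, start) order, each with its own
#' RNG stream keyed by `(seed, id)` so matching is deterministic and
#' order-invariant up to relabeling): draw candidate windows anchored on
#' pool bins of the same chromosome and the current target size; accept
#' the first whose CpG count equals the CoRSIV's exactly and which
#' overlaps neither a CoRSIV nor a previously accepted control. After
#' `max_attempts` failures the target size grows by `bin_size` and the
#' draw repeats. A CoRSIV whose chromosome is exhausted is reported
#' unmatched, not fabricated.
#'
#' @param corsivs `data.table` with `id, chrom, start, end, n_cpg`.
#' @param bins screen bin table ([screen_bins()] output or any
#'   `chrom, start, end` table); the pool is its screen-adequate rows
#'   minus bins overlapping CoRSIVs.
#' @param cpg CpG census used for counting (`chrom, pos`), post-masking.
#' @param chrom_sizes named vector of chromosome lengths.
#' @param seed integer seed.
#' @param max_attempts draws per size before relaxing (default 1000).
#' @param params [screen_params()] (supplies `bin_size`).
#' @return `data.table`: `id, matched_corsiv, chrom, start, end, n_cpg,
#'   size, relaxation` (number of +`bin_size` increments); unmatched
#'   CoRSIVs appear with `NA` coordinates.
#' @export
match_controls <- function(corsivs, bins, cpg, chrom_sizes, seed = 1L,
                           max_attempts = 1000,
                           params = screen_params()) {
  corsivs <- as.data.table(corsivs)
  check_intervals(corsivs, "corsivs")
  bins <- as.data.table(bins)
  if ("enters_screen" %in% names(bins)) bins <- bins[enters_screen == TRUE]
  cpg <- as.data.table(cpg)
  bs <- params$bin_size
  if (!"id" %in% names(corsivs))
    corsivs <- copy(corsivs)[, id := sprintf("corsiv_%04d", .I)]
  setorder(corsivs, chrom, start)
  # pool: adequate bins not overlapping any CoRSIV
  bb <- bins[, .(chrom, start, end)]
  ov <- overlap_pairs(bb, corsivs[, .(chrom, start, end)])
  pool <- if (nrow(ov)) bb[-unique(ov$xid)] else bb
  pool_starts <- split(pool$start, pool$chrom)
  cpg_by_chrom <- split(cpg$pos, cpg$chrom)
  accepted <- list()   # per chrom matrices of (start, end)
  overlaps_any <- function(ch, s, e, tbl) {
    if (is.null(tbl[[ch]])) return(rep(FALSE, length(s)))
    m <- tbl[[ch]]
    vapply(seq_along(s), function(i)
      any(m[, 1] < e[i] & m[, 2] > s[i]), TRUE)
  }
  corsiv_iv <- split(corsivs[, .(start, end)], corsivs$chrom)
  corsiv_iv <- lapply(corsiv_iv, as.matrix)
  out <- vector("list", nrow(corsivs))
  for (i in seq_len(nrow(corsivs))) {
    ci <- corsivs[i]
    ch <- ci$chrom
    target_n <- ci$n_cpg
    size0 <- ci$end - ci$start
    starts <- pool_starts[[ch]]
    pos_sorted <- cpg_by_chrom[[ch]]
    found <- NULL
    relax <- 0L
    if (!is.null(starts) && length(starts)) {
      with_seed(derive_seed(seed, "control", ci$id), {
        repeat {
          size <- size0 + relax * bs
          if (size > chrom_sizes[[ch]]) break
          s <- starts[sample.int(length(starts), max_attempts,
                                 replace = TRUE)]
          e <- s + size
          okwin <- e <= chrom_sizes[[ch]]
          ncp <- count_in_window(pos_sorted, s, e)
          cand <- which(okwin & ncp == target_n)
          if (length(cand)) {
            bad <- overlaps_any(ch, s[cand], e[cand], corsiv_iv) |
              overlaps_any(ch, s[cand], e[cand], accepted)
            cand <- cand[!bad]
          }
          if (length(cand)) {
            k <- cand[1]
            found <- c(s[k], e[k])
            break
          }
          relax <- relax + 1L
        }
      })
    }
    if (is.null(found)) {
      out[[i]] <- data.table(matched_corsiv = ci$id, chrom = ch,
                             start = NA_integer_, end = NA_integer_,
                             n_cpg = target_n, size = NA_integer_,
                             relaxation = NA_integer_)
      warning(sprintf("no control region found for %s on %s", ci$id, ch))
    } else {
      accepted[[ch]] <- rbind(accepted[[ch]], found)
      out[[i]] <- data.table(matched_corsiv = ci$id, chrom = ch,
                             start = as.integer(found[1]),
                             end = as.integer(found[2]), n_cpg = target_n,
                             size = as.integer(found[2] - found[1]),
                             relaxation = relax)
    }
  }
  res <- rbindlist(out)
  res[, id := sprintf("control_%04d", .I)]
  setcolorder(res, c("id", "matched_corsiv", "chrom", "start", "end",
                     "n_cpg", "size", "relaxation"))
  res[]
}
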