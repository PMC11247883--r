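# Independent oracles and small fixture builders. These deliberately use
# plain loops / base R so they share no code path with the package.

# brute-force block segmentation: scan qualifying bins one by one
oracle_segments <- function(starts, residuals, bin_size = 100, delta = 10,
                            min_bins = 2) {
  ok <- !is.na(residuals) & abs(residuals) >= delta
  blocks <- list()
  cur <- NULL
  flush <- function() {
    if (!is.null(cur) && length(cur$idx) >= min_bins)
      blocks[[length(blocks) + 1]] <<- cur
    cur <<- NULL
  }
  for (i in seq_along(starts)) {
    if (!ok[i]) { flush(); next }
    s <- sign(residuals[i])
    if (is.null(cur)) {
      cur <- list(idx = i, sign = s)
    } else {
      prev <- cur$idx[length(cur$idx)]
      if (starts[i] - starts[prev] == bin_size && s == cur$sign) {
        cur$idx <- c(cur$idx, i)
      } else {
        flush()
        cur <- list(idx = i, sign = s)
      }
    }
  }
  flush()
  if (!length(blocks)) {
    return(data.frame(start = numeric(), end = numeric(),
                      n_bins = integer(), direction = numeric()))
  }
  do.call(rbind, lapply(blocks, function(b)
    data.frame(start = starts[b$idx[1]],
               end = starts[b$idx[length(b$idx)]] + bin_size,
               n_bins = length(b$idx), direction = b$sign)))
}

# adequacy rule restated independently
oracle_adequacy <- function(depths, min_depth = 5) {
  n <- length(depths)
  hit <- 0
  for (d in depths) if (d >= min_depth) hit <- hit + 1
  if (n <= 2) hit == n else hit >= ceiling(n / 2)
}

# textbook Yates chi-square via stats::chisq.test
oracle_yates <- function(a, b, c, d) {
  suppressWarnings(stats::chisq.test(matrix(c(a, c, b, d), 2),
                                     correct = TRUE))
}

# a cohort with exact per-CpG counts for hand-specified bin methylation:
# spec is a data.frame(chrom, pos, subject, tissue, n_meth, n_unmeth)
tiny_cohort <- function(spec) data.table::as.data.table(spec)

# count table giving one library pct p (in %) at every listed CpG, depth d
lib_counts <- function(chrom, pos, subject, tissue, pct, depth = 10) {
  nm <- round(depth * pct / 100)
  data.table::data.table(chrom = chrom, pos = pos, subject = subject,
                         tissue = tissue, n_meth = nm,
                         n_unmeth = depth - nm)
}

# build a 2-subject x 3-tissue cohort from a matrix of bin-level pct:
# rows = bins (consecutive starts), one CpG per bin at start + 1
grid_cohort <- function(pct_by_lib, starts, chrom = "chr1", depth = 20) {
  libs <- colnames(pct_by_lib)
  out <- list()
  for (l in libs) {
    st <- strsplit(l, ".", fixed = TRUE)[[1]]
    out[[l]] <- lib_counts(chrom, starts + 1L, st[1], st[2],
                           pct_by_lib[, l], depth)
  }
  data.table::rbindlist(out)
}

default_libs <- c("s1.cortex", "s1.lung", "s1.blood",
                  "s2.cortex", "s2.lung", "s2.blood")

small_sim <- function(seed = 1, size = 1e6, n_sys = 5, n_dmr = 8,
                      n_null = 8, depth = 20, ...) {
  p <- sim_params(chrom_sizes = c(chr1 = size), depth_mean = depth,
                  n_planted_systemic = n_sys, n_planted_dmr = n_dmr,
                  n_planted_null = n_null, seed = seed, ...)
  g <- generate_genome(p)
  c(list(params = p, genome = g), generate_cohort(g, p))
}
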