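# Internal helpers: classed errors, seed derivation, interval checks.

abort_config <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("corsivr_config_error", "corsivr_error")))
}

abort_data <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("corsivr_data_error", "corsivr_error")))
}

#' Derive a reproducible child seed from a master seed and string salts
#'
#' Small multiplicative hash kept below 2^31 so the result is a valid R
#' integer seed. Used to key independent RNG streams (per chromosome, per
#' region, per pipeline stage) off a single master seed.
#'
#' @param seed integer master seed.
#' @param ... character or integer salts.
#' @return a single integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  salts <- paste(vapply(list(...), as.character, ""), collapse = "\r")
  h <- as.numeric(seed) %% 2147483647
  for (code in utf8ToInt(salts)) {
    h <- (h * 48271 + code) %% 2147483647
  }
  as.integer(h %% 2147483645 + 1)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# validate a (chrom, start, end) table; 0-based half-open
check_intervals <- function(x, what = "interval table") {
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(x)))
    abort_data("%s must have columns chrom, start, end", what)
  if (nrow(x) && any(x$start < 0 | x$start >= x$end))
    abort_data("%s has rows with start < 0 or start >= end", what)
  invisible(x)
}

# number of sorted positions p with s <= p < e (vectorized over s, e)
count_in_window <- function(pos_sorted, s, e) {
  findInterval(e - 0.5, pos_sorted) - findInterval(s - 0.5, pos_sorted)
}

# index pairs (xid, yid) of overlapping intervals, 0-based HALF-OPEN
# semantics (data.table::foverlaps itself is closed-interval); both inputs
# need chrom/start/end columns. Points are [pos, pos + 1).
overlap_pairs <- function(x, y, type = "any") {
  xx <- as.data.table(x)[, .(chrom, start, end = end - 1L)]
  yy <- as.data.table(y)[, .(chrom, start, end = end - 1L)]
  yy[, yid := .I]
  setkey(yy, chrom, start, end)   # reorders yy; map indices back via yid
  hits <- foverlaps(xx, yy, by.x = c("chrom", "start", "end"),
                    type = type, which = TRUE, nomatch = 0L)
  hits[, yid := yy$yid[yid]]
  hits[]
}

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x == as.integer(x) && x >= 0

lib_id <- function(subject, tissue) paste(subject, tissue, sep = ".")
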