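# Readers/writers for the external formats the pipeline touches.
# Internal convention: 0-based half-open coordinates everywhere; Bismark
# coverage and VCF are 1-based on disk, converted only here.

GT_LEVELS <- c("hom_ref", "het", "hom_alt", "missing")

#' Read a Bismark-style CpG coverage file
#'
#' Expected columns: chrom, start, end (1-based, start == end for a CpG),
#' percent methylation, methylated count, unmethylated count. The percent
#' column is ignored and recomputed from counts downstream.
#'
#' @param path file path (tab-delimited, no header).
#' @param subject,tissue library labels attached to the result.
#' @param merge_g_positions optional sorted `data.table(chrom, pos)` of CpG C
#'   positions (0-based); rows at a C position + 1 (the G of the same CpG)
#'   are folded into the C's counts, the common WGBS convention.
#' @return a `data.table` with columns `chrom, pos, subject, tissue,
#'   n_meth, n_unmeth`, `pos` 0-based, sorted by (chrom, pos).
#' @export
read_coverage <- function(path, subject = "s1", tissue = "t1",
                          merge_g_positions = NULL) {
  if (!file.exists(path)) abort_config("coverage file not found: %s", path)
  dt <- tryCatch(
    suppressWarnings(fread(path, header = FALSE, sep = "\t", fill = TRUE,
                           colClasses = list(character = 1))),
    error = function(e) abort_data("cannot parse %s: %s", path,
                                   conditionMessage(e)))
  if (nrow(dt) == 0L) {
    warning(sprintf("empty coverage file: %s", path))
    return(data.table(chrom = character(), pos = integer(),
                      subject = character(), tissue = character(),
                      n_meth = integer(), n_unmeth = integer()))
  }
  if (ncol(dt) < 6L)
    abort_data("%s: expected 6 tab-delimited columns, found %d",
               path, ncol(dt))
  setnames(dt, 1:6, c("chrom", "start1", "end1", "pct", "n_meth",
                      "n_unmeth"))
  bad <- which(!is.finite(dt$start1) | !is.finite(suppressWarnings(
    as.numeric(dt$n_meth))) | !is.finite(suppressWarnings(
    as.numeric(dt$n_unmeth))) |
    dt$n_meth < 0 | dt$n_unmeth < 0 | dt$start1 < 1)
  if (length(bad))
    abort_data("%s: malformed coverage line(s): %s", path,
               paste(head(bad, 5), collapse = ", "))
  out <- dt[, .(chrom = chrom, pos = as.integer(start1) - 1L,
                subject = subject, tissue = tissue,
                n_meth = as.integer(n_meth),
                n_unmeth = as.integer(n_unmeth))]
  if (!is.null(merge_g_positions)) {
    cp <- as.data.table(merge_g_positions)[, .(chrom, pos)]
    g <- copy(cp)[, pos := pos + 1L]
    is_g <- out[g, on = .(chrom, pos), which = TRUE, nomatch = 0L]
    if (length(is_g)) out[is_g, pos := pos - 1L]
    out <- out[, .(n_meth = sum(n_meth), n_unmeth = sum(n_unmeth)),
               by = .(chrom, pos, subject, tissue)]
  }
  setorder(out, chrom, pos)
  out[]
}

#' Write per-CpG counts as a Bismark-style coverage file
#'
#' @param counts a `data.table` with `chrom, pos, n_meth, n_unmeth`
#'   (0-based positions); one library.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_coverage <- function(counts, path) {
  counts <- as.data.table(counts)
  depth <- counts$n_meth + counts$n_unmeth
  out <- data.table(counts$chrom, counts$pos + 1L, counts$pos + 1L,
                    ifelse(depth > 0, round(100 * counts$n_meth / depth, 6),
                           0),
                    counts$n_meth, counts$n_unmeth)
  fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Write every library of a cohort as coverage files
#'
#' Files are named `<subject>_<tissue>.cov` under `dir`.
#'
#' @param cohort long count table from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return named character vector of paths.
#' @export
write_cohort_coverage <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  libs <- unique(as.data.table(cohort)[, .(subject, tissue)])
  paths <- character(nrow(libs))
  for (i in seq_len(nrow(libs))) {
    sel <- cohort[subject == libs$subject[i] & tissue == libs$tissue[i]]
    paths[i] <- file.path(dir, sprintf("%s_%s.cov", libs$subject[i],
                                       libs$tissue[i]))
    write_coverage(sel, paths[i])
  }
  names(paths) <- lib_id(libs$subject, libs$tissue)
  paths
}

# ---- VCF-lite --------------------------------------------------------------

parse_gt <- function(x) {
  a <- sub(":.*", "", x)
  out <- rep("missing", length(a))
  out[a %in% c("0/0", "0|0")] <- "hom_ref"
  out[a %in% c("0/1", "1/0", "0|1", "1|0")] <- "het"
  out[a %in% c("1/1", "1|1")] <- "hom_alt"
  out
}

format_gt <- function(x) {
  c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1", missing = "./.")[x]
}

#' Read a minimal VCF (CHROM POS ID REF ALT QUAL FILTER INFO FORMAT GT...)
#'
#' Multi-allelic records are split into one biallelic record per ALT allele
#' (genotypes carrying another allele become `missing` for that record).
#' Records with `QUAL < min_quality` are dropped; the threshold is
#' inclusive.
#'
#' @param path VCF file path (uncompressed).
#' @param min_quality phred quality floor (records with qual >= kept).
#' @return a `data.table` with columns `chrom, pos` (0-based), `ref, alt,
#'   qual, is_indel` plus one genotype column per sample, values in
#'   `hom_ref / het / hom_alt / missing`.
#' @export
read_variants <- function(path, min_quality = 0) {
  if (!file.exists(path)) abort_config("VCF file not found: %s", path)
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (!length(hdr)) abort_data("%s: no #CHROM header line", path)
  cols <- strsplit(sub("^#", "", lines[hdr[1]]), "\t")[[1]]
  samples <- if (length(cols) > 9) cols[10:length(cols)] else character()
  body <- lines[seq_along(lines) > hdr[1] & !startsWith(lines, "#")]
  body <- body[nzchar(body)]
  empty <- data.table(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      qual = numeric(), is_indel = logical())
  for (s in samples) empty[[s]] <- character()
  if (!length(body)) return(empty)
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  need <- if (length(samples)) 9L + length(samples) else 8L
  if (any(nf < need))
    abort_data("%s: line(s) %s lack the declared sample columns", path,
               paste(head(which(nf < need) + hdr[1], 5), collapse = ", "))
  m <- do.call(rbind, fields)
  pos1 <- suppressWarnings(as.integer(m[, 2]))
  qual <- suppressWarnings(as.numeric(m[, 6]))
  if (anyNA(pos1))
    abort_data("%s: non-numeric POS at line(s) %s", path,
               paste(head(which(is.na(pos1)) + hdr[1], 5), collapse = ", "))
  qual[is.na(qual)] <- 0   # '.' quality treated as 0
  alts <- strsplit(m[, 5], ",", fixed = TRUE)
  n_alt <- lengths(alts)
  rec_idx <- rep(seq_len(nrow(m)), n_alt)
  alt_k <- sequence(n_alt)
  out <- data.table(chrom = m[rec_idx, 1], pos = pos1[rec_idx] - 1L,
                    ref = m[rec_idx, 4], alt = unlist(alts),
                    qual = qual[rec_idx])
  out[, is_indel := nchar(ref) != 1L | nchar(alt) != 1L]
  for (j in seq_along(samples)) {
    raw <- sub(":.*", "", m[rec_idx, 9L + j])
    k <- as.character(alt_k)
    a1 <- sub("[/|].*", "", raw); a2 <- sub(".*[/|]", "", raw)
    gt <- rep("missing", length(raw))
    known <- a1 %in% c("0", k) & a2 %in% c("0", k) |
      (a1 == "0" & a2 == "0")
    # alleles other than REF or this record's ALT -> missing for this split
    both0 <- a1 == "0" & a2 == "0"
    bothk <- a1 == k & a2 == k
    onek <- (a1 == "0" & a2 == k) | (a1 == k & a2 == "0")
    gt[known & both0] <- "hom_ref"
    gt[known & onek] <- "het"
    gt[known & bothk] <- "hom_alt"
    out[[samples[j]]] <- gt
  }
  out <- out[qual >= min_quality]
  setorder(out, chrom, pos)
  out[]
}

#' Write variant records as a minimal VCF
#'
#' @param variants a `data.table` as returned by [read_variants()] or
#'   [generate_cohort()]; genotype columns are all columns after `is_indel`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_variants <- function(variants, path) {
  variants <- as.data.table(variants)
  fixed <- c("chrom", "pos", "ref", "alt", "qual", "is_indel")
  samples <- setdiff(names(variants), fixed)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", samples),
                     collapse = "\t")), con)
  if (nrow(variants)) {
    gt <- vapply(samples, function(s) format_gt(variants[[s]]),
                 character(nrow(variants)))
    if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(variants))
    body <- cbind(variants$chrom, variants$pos + 1L, ".", variants$ref,
                  variants$alt, variants$qual, "PASS", ".", "GT", gt)
    writeLines(apply(body, 1, paste, collapse = "\t"), con)
  }
  invisible(path)
}

#' Keep variants common and well-genotyped in a population panel
#'
#' Generic record filter for population panels: a record is retained when
#' it has a valid (non-missing) genotype in at least `min_valid_gt` samples
#' and a minor allele frequency of at least `min_maf` among valid
#' genotypes. Both thresholds are inclusive.
#'
#' @param variants variant table; genotype columns as in [read_variants()].
#' @param min_valid_gt minimum number of non-missing genotypes.
#' @param min_maf minimum minor allele frequency.
#' @return the filtered table.
#' @export
filter_population_variants <- function(variants, min_valid_gt = 200,
                                       min_maf = 0.05) {
  variants <- as.data.table(variants)
  fixed <- c("chrom", "pos", "ref", "alt", "qual", "is_indel")
  samples <- setdiff(names(variants), fixed)
  if (!length(samples)) abort_config("variants carry no genotype columns")
  gt <- as.matrix(variants[, ..samples])
  valid <- gt != "missing"
  n_valid <- rowSums(valid)
  alt_dose <- (gt == "het") + 2 * (gt == "hom_alt")
  alt_dose[!valid] <- 0
  af <- rowSums(alt_dose) / pmax(2 * n_valid, 1)
  maf <- pmin(af, 1 - af)
  variants[n_valid >= min_valid_gt & maf >= min_maf]
}

# ---- BED and annotation tables --------------------------------------------

#' Read / write BED intervals (0-based half-open)
#'
#' @param path file path.
#' @return `data.table` with `chrom, start, end` and, if present, `name`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) abort_config("BED file not found: %s", path)
  dt <- fread(path, header = FALSE, sep = "\t", fill = TRUE)
  if (nrow(dt) == 0L)
    return(data.table(chrom = character(), start = integer(),
                      end = integer()))
  setnames(dt, 1:3, c("chrom", "start", "end"))
  if (ncol(dt) >= 4) setnames(dt, 4, "name")
  bad <- which(!is.finite(dt$start) | !is.finite(dt$end) |
                 dt$start < 0 | dt$start >= dt$end)
  if (length(bad))
    abort_data("%s: invalid BED interval at line(s) %s", path,
               paste(head(bad, 5), collapse = ", "))
  dt[, `:=`(start = as.integer(start), end = as.integer(end))]
  dt[]
}

#' @rdname read_bed
#' @param intervals interval table with `chrom, start, end` (+ extras).
#' @export
write_bed <- function(intervals, path) {
  intervals <- as.data.table(intervals)
  check_intervals(intervals)
  cols <- intersect(c("chrom", "start", "end", "name", "id", "sivi",
                      "n_cpg"), names(intervals))
  fwrite(intervals[, ..cols], path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read refGene-style gene models
#'
#' Tab-delimited with header: chrom, strand, txStart, txEnd, name. Derived
#' TSS is txStart on `+` genes and txEnd - 1 on `-` genes; TES the
#' opposite.
#'
#' @param path file path.
#' @return `data.table` with the five columns plus `tss`, `tes`.
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) abort_config("gene model file not found: %s", path)
  dt <- fread(path, header = TRUE, sep = "\t")
  need <- c("chrom", "strand", "txStart", "txEnd", "name")
  if (!all(need %in% names(dt)))
    abort_data("%s: gene models need columns %s", path,
               paste(need, collapse = ", "))
  if (nrow(dt) && (any(dt$txStart >= dt$txEnd) ||
                   !all(dt$strand %in% c("+", "-"))))
    abort_data("%s: invalid gene model rows", path)
  add_tss_tes(dt)
}

add_tss_tes <- function(genes) {
  genes <- as.data.table(genes)
  genes[, tss := ifelse(strand == "+", txStart, txEnd - 1L)]
  genes[, tes := ifelse(strand == "+", txEnd - 1L, txStart)]
  genes[]
}

#' Read a RepeatMasker-derived repeat table
#'
#' Tab-delimited with header: chrom, start, end, repeat_class,
#' repeat_family (0-based half-open).
#'
#' @param path file path.
#' @return `data.table` of repeat features.
#' @export
read_repeats <- function(path) {
  if (!file.exists(path)) abort_config("repeat file not found: %s", path)
  dt <- fread(path, header = TRUE, sep = "\t")
  need <- c("chrom", "start", "end", "repeat_class")
  if (!all(need %in% names(dt)))
    abort_data("%s: repeat track needs columns %s", path,
               paste(need, collapse = ", "))
  check_intervals(dt, path)
  if (nrow(dt) && any(!nzchar(dt$repeat_class)))
    abort_data("%s: empty repeat_class", path)
  dt[]
}
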