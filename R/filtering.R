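#' Read a small RNA FASTQ library
#'
#' Plain or gzipped FASTQ, Phred+33 qualities.
#'
#' @param path FASTQ path.
#' @return data.frame with columns `sequence` and `quality`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  x <- readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.frame(sequence = as.character(x),
             quality = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Quality filtering of raw reads (extraction step 1)
#'
#' Discards reads containing uncalled bases (N) and low-quality reads. The
#' quality criterion is a single Phred threshold applied, by default, to the
#' read's mean base quality; `mode = "min"` instead requires every base to
#' reach the threshold.
#'
#' @param reads data.frame with `sequence` and `quality` (Phred+33).
#' @param min_quality Phred threshold (default 20); reads strictly below it
#'   are rejected.
#' @param mode `"mean"` (default) or `"min"` per-read summary.
#' @return list with `passed` (data.frame of surviving reads) and `tally`
#'   (named counts: input, contains_n, low_quality, passed).
#' @export
quality_filter <- function(reads, min_quality = 20, mode = c("mean", "min")) {
  mode <- match.arg(mode)
  bad_len <- nchar(reads$sequence) != nchar(reads$quality)
  if (any(bad_len)) {
    stop("sequence/quality length mismatch at read ", which(bad_len)[1])
  }
  has_n <- grepl("N", reads$sequence, fixed = TRUE)
  q <- vapply(reads$quality, function(s) {
    v <- as.integer(charToRaw(s)) - 33L
    if (mode == "mean") mean(v) else min(v)
  }, numeric(1), USE.NAMES = FALSE)
  low_q <- !has_n & q < min_quality
  keep <- !has_n & !low_q
  list(passed = reads[keep, , drop = FALSE],
       tally = c(input = nrow(reads), contains_n = sum(has_n),
                 low_quality = sum(low_q), passed = sum(keep)))
}

#' Collapse stage libraries into unique reads with per-stage counts
#'
#' @param stage_reads named list (one element per stage, in stage order) of
#'   character vectors of read sequences after quality filtering.
#' @return data.frame of unique reads: `sequence`, one integer count column
#'   per stage, and `pooled_count` (their sum), ordered by sequence.
#' @export
deduplicate <- function(stage_reads) {
  stages <- names(stage_reads)
  stopifnot(!is.null(stages), !anyDuplicated(stages))
  all_seq <- sort(unique(unlist(stage_reads, use.names = FALSE)))
  counts <- vapply(stage_reads, function(v) {
    tab <- table(factor(v, levels = all_seq))
    as.integer(tab)
  }, integer(length(all_seq)))
  if (length(all_seq) == 0L) {
    counts <- matrix(integer(0), nrow = 0, ncol = length(stages),
                     dimnames = list(NULL, stages))
  }
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1,
                                             dimnames = list(NULL, stages))
  out <- data.frame(sequence = all_seq, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(counts))
  out$pooled_count <- as.integer(rowSums(counts))
  rownames(out) <- NULL
  out
}

stage_cols <- function(unique_reads) {
  setdiff(colnames(unique_reads), c("sequence", "pooled_count"))
}

#' Abundance filter on unique reads (extraction step 1)
#'
#' Reads sequenced fewer than `min_count` times are removed. By default the
#' count is pooled across all stage libraries; `per_stage = TRUE` keeps a
#' read if any single stage reaches the threshold.
#'
#' @param unique_reads data.frame from [deduplicate()].
#' @param min_count minimum retained count (default 5).
#' @param per_stage apply the threshold per stage instead of pooled.
#' @return list with `passed` and `tally` (input, below_threshold, passed).
#' @export
abundance_filter <- function(unique_reads, min_count = 5L, per_stage = FALSE) {
  if (per_stage) {
    cm <- as.matrix(unique_reads[, stage_cols(unique_reads), drop = FALSE])
    keep <- apply(cm, 1, max) >= min_count
  } else {
    keep <- unique_reads$pooled_count >= min_count
  }
  list(passed = unique_reads[keep, , drop = FALSE],
       tally = c(input = nrow(unique_reads), below_threshold = sum(!keep),
                 passed = sum(keep)))
}

#' Length filter on unique reads (extraction step 2)
#'
#' Retains reads of `min_len`-`max_len` nucleotides (default 25-45 nt, the
#' window in which fragments map uniquely enough to be called).
#'
#' @param unique_reads data.frame from [deduplicate()].
#' @param min_len,max_len inclusive length bounds.
#' @return list with `passed` and `tally` (input, too_short, too_long,
#'   passed).
#' @export
length_filter <- function(unique_reads, min_len = 25L, max_len = 45L) {
  if (min_len > max_len) stop("min_len > max_len")
  len <- nchar(unique_reads$sequence)
  short <- len < min_len
  long <- len > max_len
  keep <- !short & !long
  list(passed = unique_reads[keep, , drop = FALSE],
       tally = c(input = nrow(unique_reads), too_short = sum(short),
                 too_long = sum(long), passed = sum(keep)))
}

#' Run the full read-filtering stage over six FASTQ libraries
#'
#' Applies [quality_filter()] per library, [deduplicate()] across libraries,
#' then [abundance_filter()] and [length_filter()], and assembles a
#' per-filter accounting report.
#'
#' @param fastq_paths named character vector of FASTQ paths, one per stage,
#'   in stage order.
#' @param min_quality,quality_mode see [quality_filter()].
#' @param min_count,per_stage see [abundance_filter()].
#' @param min_len,max_len see [length_filter()].
#' @return list with `unique_reads` (surviving reads), `report` (data.frame
#'   of per-filter tallies), and `all_unique` (deduplicated reads before the
#'   abundance/length filters, used for spike-in counting).
#' @export
filter_reads <- function(fastq_paths, min_quality = 20,
                         quality_mode = c("mean", "min"), min_count = 5L,
                         per_stage = FALSE, min_len = 25L, max_len = 45L) {
  quality_mode <- match.arg(quality_mode)
  stages <- names(fastq_paths)
  qres <- lapply(fastq_paths, function(p) {
    quality_filter(read_fastq(p), min_quality, quality_mode)
  })
  qtally <- Reduce(`+`, lapply(qres, `[[`, "tally"))
  uniq <- deduplicate(lapply(setNames(qres, stages),
                             function(r) r$passed$sequence))
  ab <- abundance_filter(uniq, min_count, per_stage)
  ln <- length_filter(ab$passed, min_len, max_len)
  # read-level rejection counts (pooled) alongside unique-sequence counts
  ab_reads <- sum(uniq$pooled_count) - sum(ab$passed$pooled_count)
  len <- nchar(ab$passed$sequence)
  short_reads <- sum(ab$passed$pooled_count[len < min_len])
  long_reads <- sum(ab$passed$pooled_count[len > max_len])
  report <- data.frame(
    filter = c("quality", "quality", "abundance", "length", "length"),
    reason = c("contains_n", "low_quality", "below_threshold", "too_short",
               "too_long"),
    rejected_unique = c(NA_integer_, NA_integer_,
                        ab$tally[["below_threshold"]],
                        ln$tally[["too_short"]], ln$tally[["too_long"]]),
    rejected_reads = c(qtally[["contains_n"]], qtally[["low_quality"]],
                       ab_reads, short_reads, long_reads),
    stringsAsFactors = FALSE
  )
  list(unique_reads = ln$passed, report = report, all_unique = uniq)
}
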