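#' Spike-in normalization factors across stage libraries
#'
#' Two synthetic spike RNAs are added to each library at controlled amounts;
#' their per-stage read sums anchor cross-library scaling. The factor for
#' stage s is `K / spike_sum_s`, where `K` is the geometric mean of the
#' per-stage spike sums, so factors are scale-free and multiply to 1 across
#' stages. Normalized count = raw count x factor.
#'
#' @param spike_counts matrix (2 spikes x stages) or vector of per-stage
#'   spike read sums; every stage sum must be positive.
#' @param anchor `"geometric"` (default), `"constant"` (K = 1e6), or
#'   `"first"` (K = first stage's sum).
#' @return named numeric vector of per-stage factors.
#' @export
normalization_factors <- function(spike_counts,
                                  anchor = c("geometric", "constant", "first")) {
  anchor <- match.arg(anchor)
  sums <- if (is.matrix(spike_counts)) colSums(spike_counts) else spike_counts
  if (any(sums <= 0)) {
    stop("zero spike-in count in stage(s): ",
         paste(names(sums)[sums <= 0], collapse = ", "))
  }
  K <- switch(anchor, geometric = geometric_mean(sums), constant = 1e6,
              first = sums[[1L]])
  K / sums
}

#' Count spike-in reads per stage
#'
#' @param unique_reads deduplicated read table (before the abundance/length
#'   filters; spikes are tallied from everything that passed quality
#'   filtering).
#' @param spikes character vector of the two spike sequences.
#' @return matrix (spikes x stages) of raw counts.
#' @export
count_spikes <- function(unique_reads, spikes) {
  scols <- stage_cols(unique_reads)
  m <- matrix(0L, nrow = length(spikes), ncol = length(scols),
              dimnames = list(spikes, scols))
  idx <- match(spikes, unique_reads$sequence)
  found <- !is.na(idx)
  m[found, ] <- as.matrix(unique_reads[idx[found], scols, drop = FALSE])
  m
}

#' Per-position normalized coverage of one parental tRNA
#'
#' For each stage, the coverage at mature position p is the sum of
#' normalized counts of the fragments whose span covers p (CCA positions
#' included).
#'
#' @param trfs fragment table rows sharing one reference parent (spans on
#'   that parent).
#' @param length_ mature length of the parent.
#' @param factors named per-stage normalization factors.
#' @return matrix (positions x stages) of normalized coverage.
#' @export
positional_coverage <- function(trfs, length_, factors) {
  stages <- names(factors)
  cov <- matrix(0, nrow = length_, ncol = length(stages),
                dimnames = list(NULL, stages))
  for (i in seq_len(nrow(trfs))) {
    pos <- trfs$span_start[i]:trfs$span_end[i]
    for (s in stages) {
      cov[pos, s] <- cov[pos, s] + trfs[[s]][i] * factors[[s]]
    }
  }
  cov
}

#' Relative-abundance heatmap matrix of top fragment variants
#'
#' One row per variant: normalized per-stage counts divided by the row
#' maximum, so every non-zero row peaks at 1. All-zero rows stay zero and
#' are flagged in the `"zero_rows"` attribute.
#'
#' @param variants fragment table (e.g. top variants per anticodon) with
#'   per-stage raw counts.
#' @param factors named per-stage normalization factors.
#' @param row_names optional row labels (default: fragment sequences).
#' @return numeric matrix (variants x stages) with values in \[0, 1\].
#' @export
heatmap_matrix <- function(variants, factors, row_names = NULL) {
  stages <- names(factors)
  raw <- as.matrix(variants[, stages, drop = FALSE])
  norm <- sweep(raw, 2L, unlist(factors), `*`)
  mx <- apply(norm, 1L, max)
  rel <- norm / ifelse(mx == 0, 1, mx)
  rownames(rel) <- if (is.null(row_names)) variants$sequence else row_names
  attr(rel, "zero_rows") <- which(mx == 0)
  rel
}

#' Hierarchically cluster heatmap rows
#'
#' Agglomerative clustering with average linkage on distance
#' 1 - uncentered correlation (the default similarity of the Cluster 3.0
#' program). Leaf order is the deterministic hclust ordering of the input.
#'
#' @param mat numeric matrix (rows = variants, columns = stages).
#' @return list with `order` (row indices, leaf order), `hclust` (the tree,
#'   `NULL` for fewer than 2 rows), and `newick` (Newick string for the
#'   dendrogram, `NULL` for fewer than 2 rows).
#' @export
cluster_rows <- function(mat) {
  if (nrow(mat) < 2L) {
    return(list(order = seq_len(nrow(mat)), hclust = NULL, newick = NULL))
  }
  if (is.null(rownames(mat))) rownames(mat) <- paste0("row", seq_len(nrow(mat)))
  d <- as.dist(1 - uncentered_correlation(mat))
  hc <- hclust(d, method = "average")
  phy <- ape::as.phylo(hc)
  list(order = hc$order, hclust = hc,
       newick = ape::write.tree(phy))
}

#' Developmental expression trend of one fragment variant
#'
#' Operationalizes three qualitative patterns over the six ordered stages.
#' Egg enrichment is evaluated first: the egg library holds more than
#' `egg_share` of the variant's total signal. A series that declines
#' smoothly across stages is not egg-enriched even when the egg holds the
#' majority (any clean stage-halving series does): egg enrichment yields
#' to a decline that is both strongly ordered (Spearman rank correlation
#' with stage index at or below -`rho`) and graded rather than collapsing
#' right after the egg (some later stage still holds at least `collapse`
#' of the egg signal). Otherwise increasing / decreasing are called by
#' rank correlation at +/-`rho`, and everything else is "other".
#'
#' @param counts numeric vector of per-stage normalized counts, in stage
#'   order starting at the egg.
#' @param rho rank-correlation threshold (default 0.8).
#' @param egg_share egg-enrichment share threshold (default 0.5).
#' @param collapse post-egg collapse ratio (default 0.25): below it, a
#'   majority-egg series counts as egg-enriched even if rank-decreasing.
#' @return one of `"increasing"`, `"decreasing"`, `"egg-enriched"`,
#'   `"other"`.
#' @export
expression_trend <- function(counts, rho = 0.8, egg_share = 0.5,
                             collapse = 0.25) {
  stopifnot(length(counts) >= 3L)
  if (sum(counts) == 0) return("other")
  r <- suppressWarnings(cor(counts, seq_along(counts), method = "spearman"))
  if (is.na(r)) r <- 0
  smooth_decline <- r <= -rho && max(counts[-1L]) >= collapse * counts[1L]
  if (counts[1L] > egg_share * sum(counts) && !smooth_decline) {
    return("egg-enriched")
  }
  if (r >= rho) return("increasing")
  if (r <= -rho) return("decreasing")
  "other"
}
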