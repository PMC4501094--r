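#' Classify a fragment span into a structural region category
#'
#' Fragments are categorized by where they sit on the mature tRNA relative
#' to the anticodon loop. Halves are fragments cleaved in the anticodon loop
#' and anchored at a terminus; end fragments are shorter than halves,
#' anchored at a terminus but stopping short of the loop; anticodon
#' stem-loop fragments are unanchored and contained in the stem-loop window.
#' The decision order is:
#'
#' 1. 5' half: 5'-anchored (`start <= 1 + t5`) and 3' terminus inside the
#'    anticodon loop;
#' 2. 3' half: 3'-anchored (`end >= L - t3`, CCA included) and 5' terminus
#'    inside the loop;
#' 3. 5' end: 5'-anchored, 3' terminus strictly before the loop;
#' 4. 3' end: 3'-anchored, 5' terminus strictly after the loop;
#' 5. AC stem-loop: unanchored at both termini and contained in the
#'    stem-loop window widened by `w` on each side;
#' 6. other.
#'
#' @param span_start,span_end 1-based inclusive span on the mature tRNA.
#' @param map region map from [region_map()] (or a row of a mature table
#'   with `length`, `loop_start`, `loop_end`, `sl_start`, `sl_end`).
#' @param t5,t3 anchoring tolerances at the 5'/3' terminus (default 2 nt).
#' @param w stem-loop window slack (default 5 nt; the smallest slack that
#'   admits fragments of the 25-45 nt calling range under the default
#'   loop/stem geometry).
#' @return list with `category` (one of "5' half", "5' end", "3' half",
#'   "3' end", "AC stem-loop", "other") and flags `anchored_5p`,
#'   `anchored_3p`, `loop_overlap`.
#' @export
classify_region <- function(span_start, span_end, map, t5 = 2L, t3 = 2L,
                            w = 5L) {
  L <- map$length
  if (span_start < 1L || span_end > L || span_start > span_end) {
    stop("span ", span_start, "-", span_end, " outside mature tRNA [1, ", L, "]")
  }
  a5 <- span_start <= 1L + t5
  a3 <- span_end >= L - t3
  in_loop <- function(p) p >= map$loop_start & p <= map$loop_end
  category <- if (a5 && in_loop(span_end)) {
    "5' half"
  } else if (a3 && in_loop(span_start)) {
    "3' half"
  } else if (a5 && span_end < map$loop_start) {
    "5' end"
  } else if (a3 && span_start > map$loop_end) {
    "3' end"
  } else if (!a5 && !a3 && span_start >= map$sl_start - w &&
             span_end <= map$sl_end + w) {
    "AC stem-loop"
  } else {
    "other"
  }
  list(category = category, anchored_5p = a5, anchored_3p = a3,
       loop_overlap = span_start <= map$loop_end & span_end >= map$loop_start)
}

#' Add region categories to a called-fragment table
#'
#' Classifies each fragment's span on its reference parent.
#'
#' @param trfs fragment table from [call_trfs()].
#' @param matures mature-tRNA table with region-map columns (reference
#'   parents are looked up by the first gene in `parents`).
#' @param t5,t3,w see [classify_region()].
#' @return `trfs` with a `region` column added.
#' @export
classify_trfs <- function(trfs, matures, t5 = 2L, t3 = 2L, w = 5L) {
  if (nrow(trfs) == 0L) {
    trfs$region <- character(0)
    return(trfs)
  }
  ref_gene <- vapply(strsplit(trfs$parents, ",", fixed = TRUE), `[`, "", 1L)
  idx <- match(ref_gene, matures$gene_id)
  trfs$region <- vapply(seq_len(nrow(trfs)), function(i) {
    classify_region(trfs$span_start[i], trfs$span_end[i],
                    matures[idx[i], , drop = FALSE], t5, t3, w)$category
  }, character(1))
  trfs
}

#' Main fragment region(s) of one anticodon group
#'
#' Sums pooled read counts per region category and reports every category
#' holding at least a fraction `f` of the group total, most abundant first,
#' joined by `" and "` (the style of mixed labels such as
#' "5' end and 3' half"). Ties are broken by the fixed category order
#' 5' half, 5' end, 3' half, 3' end, AC stem-loop, other.
#'
#' @param regions character vector of per-fragment region categories.
#' @param counts pooled read counts, parallel to `regions`.
#' @param f minimum fraction of the group total for a category to be
#'   reported (default 0.25).
#' @return single label string.
#' @export
main_region <- function(regions, counts, f = 0.25) {
  if (length(regions) == 0L) stop("empty fragment group")
  by_cat <- tapply(counts, factor(regions, levels = REGION_LEVELS), sum,
                   default = 0)
  by_cat[is.na(by_cat)] <- 0
  share <- by_cat / sum(by_cat)
  keep <- which(share >= f)
  # order: descending share, then fixed category order (factor level order)
  keep <- keep[order(-share[keep], keep)]
  paste(names(by_cat)[keep], collapse = " and ")
}

#' Most abundant fragment variants of one anticodon group
#'
#' @param trfs fragment table rows for one anticodon.
#' @param k number of variants to return (default 3).
#' @return the `min(k, nrow)` most abundant rows, sorted by pooled count
#'   descending, ties broken by sequence (lexicographic).
#' @export
top_variants <- function(trfs, k = 3L) {
  if (nrow(trfs) == 0L) stop("empty fragment group")
  ord <- order(-trfs$pooled_count, trfs$sequence)
  out <- trfs[ord[seq_len(min(k, nrow(trfs)))], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Stacked gapless alignment of fragments on their parent tRNA
#'
#' Renders each fragment at its offset on the CCA-terminated mature
#' sequence, one row per variant with its pooled read count, sorted by
#' count descending (ties by sequence).
#'
#' @param trfs fragment table rows (must all be exact substrings of the
#'   parent at their recorded spans).
#' @param parent one-row mature-tRNA data.frame.
#' @param min_count only show variants with pooled count at or above this
#'   threshold (default 0 = all).
#' @return data.frame with `text` (space-padded aligned sequence),
#'   `sequence`, `span_start`, `span_end`, `pooled_count`; the parent
#'   sequence is in attribute `"parent"`.
#' @export
variant_alignment <- function(trfs, parent, min_count = 0) {
  trfs <- trfs[trfs$pooled_count >= min_count, , drop = FALSE]
  trfs <- trfs[order(-trfs$pooled_count, trfs$sequence), , drop = FALSE]
  ok <- substr(rep(parent$sequence, nrow(trfs)), trfs$span_start,
               trfs$span_end) == trfs$sequence
  if (!all(ok)) {
    stop("fragment not a substring of parent at its span: ",
         trfs$sequence[which(!ok)[1]])
  }
  pad <- vapply(trfs$span_start - 1L, function(n) {
    paste(rep(" ", n), collapse = "")
  }, character(1))
  out <- data.frame(text = paste0(pad, trfs$sequence),
                    sequence = trfs$sequence, span_start = trfs$span_start,
                    span_end = trfs$span_end,
                    pooled_count = trfs$pooled_count,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "parent") <- parent$sequence
  out
}
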