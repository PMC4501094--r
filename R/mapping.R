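#' Exact, CCA-aware matching of a read against one mature tRNA
#'
#' Reports every exact-substring occurrence (no mismatches, no gaps) of the
#' read in the mature sequence. Occurrences are split by how they relate to
#' the post-transcriptional CCA tail, which the genome does not encode: a hit
#' ending at the mature 3' end means the read carries the full CCA tail and
#' maps to the gene only after the tail is masked (`cca_masked = TRUE`); a
#' hit ending at or before the last genomic base is an ordinary genomic hit.
#' Hits ending inside the CCA tail (read carries a partial "C"/"CC" tail)
#' are reported only when `cca_partial = TRUE`.
#'
#' @param read read sequence (character).
#' @param trna_sequence mature tRNA sequence; must end in "CCA".
#' @param cca_partial also accept partial CCA tails (default FALSE).
#' @return data.frame with columns `start`, `end` (1-based span on the
#'   mature sequence) and `cca_masked`.
#' @export
match_to_trna <- function(read, trna_sequence, cca_partial = FALSE) {
  L <- nchar(trna_sequence)
  stopifnot(substr(trna_sequence, L - 2L, L) == "CCA")
  m <- gregexpr(read, trna_sequence, fixed = TRUE)[[1]]
  empty <- data.frame(start = integer(), end = integer(),
                      cca_masked = logical())
  if (m[1] == -1L) return(empty)
  start <- as.integer(m)
  end <- start + nchar(read) - 1L
  masked <- end > L - 3L
  keep <- end <= L - 3L | end == L | (cca_partial & masked)
  data.frame(start = start[keep], end = end[keep],
             cca_masked = masked[keep], row.names = NULL)
}

#' Genome-wide exact occurrences of a read
#'
#' Scans both strands of a contig set for exact occurrences of the read as
#' sequenced. Minus-strand occurrences are located by searching the plus
#' strand for the read's reverse complement; their coordinates are reported
#' on the plus strand.
#'
#' @param read read sequence.
#' @param contigs named character vector of contig sequences.
#' @param rc_contigs optional precomputed reverse complements of `contigs`
#'   (same names/order); computed when `NULL`.
#' @return data.frame with `subject`, `start`, `end`, `strand`.
#' @export
find_genomic_occurrences <- function(read, contigs, rc_contigs = NULL) {
  fwd <- find_occurrences(read, contigs)
  fwd$strand <- rep("+", nrow(fwd))
  if (is.null(rc_contigs)) rc_contigs <- setNames(revcomp(contigs), names(contigs))
  rev_hits <- find_occurrences(read, rc_contigs)
  if (nrow(rev_hits) > 0L) {
    len <- nchar(contigs[rev_hits$subject])
    s <- len - rev_hits$end + 1L
    e <- len - rev_hits$start + 1L
    rev_hits$start <- as.integer(s)
    rev_hits$end <- as.integer(e)
    rev_hits$strand <- "-"
  } else {
    rev_hits$strand <- character(0)
  }
  rbind(fwd, rev_hits)
}

# classify genomic occurrences: within any annotated tRNA gene interval on
# the matching strand -> tRNA-locus occurrence; anything else is a non-tRNA
# occurrence (this includes reads antisense to a tRNA gene)
occ_in_trna_locus <- function(occ, genes) {
  if (nrow(occ) == 0L) return(logical(0))
  vapply(seq_len(nrow(occ)), function(i) {
    any(genes$contig_id == occ$subject[i] & genes$strand == occ$strand[i] &
          genes$start <= occ$start[i] & genes$end >= occ$end[i])
  }, logical(1))
}

#' Assemble a calling catalog for one genome compartment
#'
#' Bundles the annotated gene set, the curated genes' mature sequences, and
#' the contig sequences into the object [call_trfs()] consumes. Mature
#' sequences are also derived for polymorphic-flagged genes (removed from
#' the curated set) so that reads matching them can be dropped with an
#' explicit "polymorphic" reason rather than silently.
#'
#' @param all_genes full annotated gene table (including pseudo, contig-end
#'   and polymorphic genes); used to recognize tRNA loci genome-wide.
#' @param curated curated gene table from [curate_genes()].
#' @param contigs named character vector of contig sequences.
#' @param anticodon_center,stem_width see [mature_sequence()],
#'   [region_map()].
#' @return list with elements `all_genes`, `matures` (with region-map
#'   columns and a `polymorphic` flag), `contigs`, `rc_contigs`.
#' @export
build_catalog <- function(all_genes, curated, contigs, anticodon_center = 34L,
                          stem_width = 5L) {
  removed <- attr(curated, "removed")
  poly <- if (!is.null(removed)) {
    removed[removed$reason == "polymorphic", , drop = FALSE]
  } else {
    curated[0, , drop = FALSE]
  }
  matures <- add_region_map(
    mature_sequences(curated, contigs, anticodon_center), stem_width)
  matures$polymorphic <- rep(FALSE, nrow(matures))
  if (nrow(poly) > 0L) {
    pm <- add_region_map(
      mature_sequences(poly[, colnames(curated), drop = FALSE], contigs,
                       anticodon_center), stem_width)
    pm$polymorphic <- rep(TRUE, nrow(pm))
    matures <- rbind(matures, pm)
  }
  matures <- matures[order(matures$gene_id), , drop = FALSE]
  rownames(matures) <- NULL
  list(all_genes = all_genes, matures = matures, contigs = contigs,
       rc_contigs = setNames(revcomp(contigs), names(contigs)))
}

# mature-tRNA matches of one read across a catalog; one row per (gene, hit)
mature_hits <- function(read, matures, cca_partial = FALSE) {
  if (nrow(matures) == 0L) {
    return(data.frame(gene_id = character(), anticodon = character(),
                      isotype = character(), polymorphic = logical(),
                      start = integer(), end = integer(),
                      cca_masked = logical()))
  }
  out <- lapply(seq_len(nrow(matures)), function(i) {
    h <- match_to_trna(read, matures$sequence[i], cca_partial)
    if (nrow(h) == 0L) return(NULL)
    cbind(data.frame(gene_id = matures$gene_id[i],
                     anticodon = matures$anticodon[i],
                     isotype = matures$isotype[i],
                     polymorphic = matures$polymorphic[i],
                     stringsAsFactors = FALSE)[rep(1L, nrow(h)), , drop = FALSE],
          h)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) {
    return(data.frame(gene_id = character(), anticodon = character(),
                      isotype = character(), polymorphic = logical(),
                      start = integer(), end = integer(),
                      cca_masked = logical()))
  }
  h <- do.call(rbind, out)
  rownames(h) <- NULL
  h
}

#' Multi-mapping ambiguity filters on one candidate fragment
#'
#' Applies the three removal rules used when tallying fragments: (a) reads
#' that also occur at a non-tRNA genomic locus are removed; (b) reads
#' mappable to a tRNA gene carrying polymorphic site(s) are removed (by
#' default any polymorphic parent disqualifies the read; with
#' `poly_mode = "only"` polymorphic parents are discarded and the read is
#' removed only if no parent remains); (c) reads mappable to tRNA genes of
#' two or more distinct anticodons are removed. Reads hitting several
#' same-anticodon subtypes (isodecoders) are kept with all parents.
#'
#' @param hits data.frame of mature-tRNA hits for one read (columns
#'   `gene_id`, `anticodon`, `polymorphic`, ...).
#' @param has_non_trna_occurrence does the read also occur at a non-tRNA
#'   genomic locus?
#' @param apply_a,apply_c toggles for rules (a) and (c).
#' @param poly_mode `"any"` or `"only"`, see above.
#' @return list with `keep` (logical), `reason` (`NA` when kept), and
#'   `hits` (surviving parent hits).
#' @export
ambiguity_filter <- function(hits, has_non_trna_occurrence, apply_a = TRUE,
                             apply_c = TRUE, poly_mode = c("any", "only")) {
  poly_mode <- match.arg(poly_mode)
  drop <- function(reason) list(keep = FALSE, reason = reason, hits = hits[0, ])
  if (apply_a && has_non_trna_occurrence) return(drop("ambiguous_genomic"))
  if (poly_mode == "any") {
    if (any(hits$polymorphic)) return(drop("polymorphic"))
  } else {
    hits <- hits[!hits$polymorphic, , drop = FALSE]
    if (nrow(hits) == 0L) return(drop("polymorphic"))
  }
  if (apply_c && length(unique(hits$anticodon)) > 1L) {
    return(drop("multi_anticodon"))
  }
  list(keep = TRUE, reason = NA_character_, hits = hits)
}

#' Call tRNA-derived fragments from unique reads
#'
#' Implements the mapping steps of the extraction procedure: each unique
#' read is first confronted with the mitochondrial compartment (mature
#' mitochondrial tRNAs, CCA-tail aware, plus both strands of the
#' mitochondrial genome). Any mitochondrial occurrence claims the read:
#' a mature-tRNA match makes it a mitochondrial fragment candidate, while a
#' genomic-only occurrence consumes it without forwarding it to the nuclear
#' search. Remaining reads are confronted with the nuclear compartment the
#' same way, and nuclear candidates pass through the three ambiguity
#' filters (see [ambiguity_filter()]). Every kept read is counted once per
#' anticodon regardless of how many same-anticodon subtypes it matches.
#'
#' @param unique_reads data.frame from [deduplicate()]/[filter_reads()]
#'   (columns `sequence`, per-stage counts, `pooled_count`).
#' @param mito_catalog,nuclear_catalog catalogs from [build_catalog()];
#'   either may be `NULL` to skip that compartment.
#' @param cca_partial accept partial CCA tails (default FALSE).
#' @param footnote_a_mito,footnote_c_mito apply the non-tRNA-occurrence and
#'   multi-anticodon filters to mitochondrial candidates. The cross-genome
#'   rule (a) is a nuclear-side rule by default; within-compartment
#'   multi-anticodon hits are dropped in both compartments.
#' @param poly_mode see [ambiguity_filter()].
#' @return list with `trfs` (one row per called fragment: sequence,
#'   compartment, anticodon, isotype, parents, span on the reference parent,
#'   `cca_masked`, per-stage counts, `pooled_count`), `hits` (long table of
#'   every surviving read-parent hit), `dropped` (read, compartment, reason),
#'   and `summary` (per-compartment, per-anticodon read-count totals).
#' @export
call_trfs <- function(unique_reads, mito_catalog, nuclear_catalog,
                      cca_partial = FALSE, footnote_a_mito = FALSE,
                      footnote_c_mito = TRUE, poly_mode = c("any", "only")) {
  poly_mode <- match.arg(poly_mode)
  scols <- stage_cols(unique_reads)
  trf_rows <- list(); hit_rows <- list(); drop_rows <- list()
  seqs <- unique_reads$sequence
  for (i in seq_along(seqs)) {
    read <- seqs[i]
    assigned <- FALSE
    for (comp in c("mitochondrial", "nuclear")) {
      cat_ <- if (comp == "mitochondrial") mito_catalog else nuclear_catalog
      if (is.null(cat_)) next
      hits <- mature_hits(read, cat_$matures, cca_partial)
      occ <- find_genomic_occurrences(read, cat_$contigs, cat_$rc_contigs)
      if (nrow(hits) == 0L && nrow(occ) == 0L) next
      assigned <- TRUE
      if (nrow(hits) == 0L) {
        drop_rows[[length(drop_rows) + 1L]] <-
          data.frame(sequence = read, compartment = comp,
                     reason = "non_trna_locus", stringsAsFactors = FALSE)
        break
      }
      in_trna <- occ_in_trna_locus(occ, cat_$all_genes)
      apply_a <- if (comp == "mitochondrial") footnote_a_mito else TRUE
      apply_c <- if (comp == "mitochondrial") footnote_c_mito else TRUE
      res <- ambiguity_filter(hits, any(!in_trna), apply_a, apply_c, poly_mode)
      if (!res$keep) {
        drop_rows[[length(drop_rows) + 1L]] <-
          data.frame(sequence = read, compartment = comp, reason = res$reason,
                     stringsAsFactors = FALSE)
        break
      }
      kept <- res$hits[order(res$hits$gene_id, res$hits$start), , drop = FALSE]
      ref <- kept[1L, ]
      trf_rows[[length(trf_rows) + 1L]] <- cbind(
        data.frame(sequence = read, compartment = comp,
                   anticodon = ref$anticodon, isotype = ref$isotype,
                   parents = paste(unique(kept$gene_id), collapse = ","),
                   n_parents = length(unique(kept$gene_id)),
                   span_start = ref$start, span_end = ref$end,
                   cca_masked = ref$cca_masked, stringsAsFactors = FALSE),
        unique_reads[i, c(scols, "pooled_count"), drop = FALSE])
      hit_rows[[length(hit_rows) + 1L]] <-
        cbind(data.frame(sequence = read, stringsAsFactors = FALSE),
              kept[, c("gene_id", "anticodon", "start", "end", "cca_masked")])
      break
    }
    if (!assigned) {
      drop_rows[[length(drop_rows) + 1L]] <-
        data.frame(sequence = read, compartment = NA_character_,
                   reason = "unassigned", stringsAsFactors = FALSE)
    }
  }
  bindr <- function(rows, proto) {
    if (length(rows) == 0L) proto else {
      out <- do.call(rbind, rows); rownames(out) <- NULL; out
    }
  }
  trfs <- bindr(trf_rows, cbind(
    data.frame(sequence = character(), compartment = character(),
               anticodon = character(), isotype = character(),
               parents = character(), n_parents = integer(),
               span_start = integer(), span_end = integer(),
               cca_masked = logical(), stringsAsFactors = FALSE),
    unique_reads[0, c(scols, "pooled_count"), drop = FALSE]))
  dropped <- bindr(drop_rows,
                   data.frame(sequence = character(), compartment = character(),
                              reason = character(), stringsAsFactors = FALSE))
  hits <- bindr(hit_rows,
                data.frame(sequence = character(), gene_id = character(),
                           anticodon = character(), start = integer(),
                           end = integer(), cca_masked = logical(),
                           stringsAsFactors = FALSE))
  list(trfs = trfs, hits = hits, dropped = dropped,
       summary = summarize_anticodons(trfs))
}

#' Per-compartment, per-anticodon fragment totals
#'
#' @param trfs fragment table from [call_trfs()].
#' @return data.frame with `compartment`, `isotype`, `anticodon`, `total`
#'   (pooled read counts; each unique read counted once per anticodon),
#'   sorted by compartment then total descending.
#' @export
summarize_anticodons <- function(trfs) {
  if (nrow(trfs) == 0L) {
    return(data.frame(compartment = character(), isotype = character(),
                      anticodon = character(), total = integer(),
                      stringsAsFactors = FALSE))
  }
  key <- paste(trfs$compartment, trfs$isotype, trfs$anticodon, sep = "\r")
  tot <- tapply(trfs$pooled_count, key, sum)
  parts <- strsplit(names(tot), "\r", fixed = TRUE)
  out <- data.frame(compartment = vapply(parts, `[`, "", 1L),
                    isotype = vapply(parts, `[`, "", 2L),
                    anticodon = vapply(parts, `[`, "", 3L),
                    total = as.integer(tot), stringsAsFactors = FALSE)
  out <- out[order(out$compartment, -out$total, out$anticodon), , drop = FALSE]
  rownames(out) <- NULL
  out
}
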