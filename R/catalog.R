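#' Parse tRNAscan-SE tabular output into a tRNA gene table
#'
#' Reads the classic tab-separated output of tRNAscan-SE (v1.3-style layout:
#' sequence name, tRNA number, begin, end, isotype, anticodon, intron begin,
#' intron end, COVE bit score, optional note column). Records whose begin
#' coordinate exceeds their end coordinate are minus-strand genes; their
#' interval is normalized to `start <= end` and the strand recorded as `"-"`.
#' A note column containing "pseudo" (case-insensitive), or an isotype of
#' "Pseudo", sets the pseudogene flag.
#'
#' @param file path to a tRNAscan-SE tabular output file. Header lines (up to
#'   and including the `----` underline row, or lines starting with
#'   `Sequence`/`Name`) are skipped automatically.
#' @return data.frame of tRNA genes with columns `gene_id`, `contig_id`,
#'   `start`, `end` (1-based inclusive), `strand`, `isotype`, `anticodon`
#'   (RNA alphabet), `intron_start`, `intron_end` (`NA` when intronless),
#'   `cove_score`, and logical flags `pseudo`, `polymorphic`.
#' @export
parse_trnascan <- function(file) {
  lines <- readLines(file)
  is_header <- grepl("^(Sequence|Name|-{2,})", lines) | !nzchar(trimws(lines))
  body <- lines[!is_header]
  if (length(body) == 0L) {
    return(empty_gene_table())
  }
  fields <- strsplit(body, "\t")
  n_bad <- which(vapply(fields, length, integer(1)) < 9L)
  if (length(n_bad) > 0L) {
    stop("malformed tRNAscan-SE row at line ", which(!is_header)[n_bad[1]],
         " of ", file, ": expected >= 9 tab-separated fields")
  }
  parse_row <- function(f) {
    f <- trimws(f)
    begin <- suppressWarnings(as.integer(f[3]))
    end <- suppressWarnings(as.integer(f[4]))
    if (is.na(begin) || is.na(end)) {
      stop("malformed tRNAscan-SE row: non-numeric coordinates in '",
           paste(f, collapse = "\t"), "'")
    }
    strand <- if (begin > end) "-" else "+"
    note <- if (length(f) >= 10L) f[10] else ""
    ib <- suppressWarnings(as.integer(f[7]))
    ie <- suppressWarnings(as.integer(f[8]))
    data.frame(
      gene_id = paste0(f[1], ".trna", f[2]),
      contig_id = f[1],
      start = min(begin, end),
      end = max(begin, end),
      strand = strand,
      isotype = f[5],
      anticodon = rna_anticodon(f[6]),
      intron_start = if (!is.na(ib) && ib > 0L) min(ib, ie) else NA_integer_,
      intron_end = if (!is.na(ie) && ie > 0L) max(ib, ie) else NA_integer_,
      cove_score = suppressWarnings(as.numeric(f[9])),
      pseudo = grepl("pseudo", note, ignore.case = TRUE) ||
        grepl("^pseudo$", f[5], ignore.case = TRUE),
      polymorphic = grepl("polymorphic|heterozygous", note, ignore.case = TRUE),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, lapply(fields, parse_row))
}

empty_gene_table <- function() {
  data.frame(gene_id = character(), contig_id = character(), start = integer(),
             end = integer(), strand = character(), isotype = character(),
             anticodon = character(), intron_start = integer(),
             intron_end = integer(), cove_score = numeric(),
             pseudo = logical(), polymorphic = logical(),
             stringsAsFactors = FALSE)
}

locus_key <- function(genes) {
  paste(genes$contig_id, genes$start, genes$end, genes$strand, sep = ":")
}

#' Retain loci scoring higher under the eukaryotic covariance model
#'
#' Nuclear tRNA predictions are accepted when the eukaryotic-model COVE bit
#' score exceeds the bacterial-model score at the same locus. Loci reported
#' only by the eukaryotic search are retained (the comparison is defined only
#' where both searches report the locus). Mitochondrial genes, predicted with
#' the organellar model, never pass through this step.
#'
#' @param euk_genes,bac_genes gene tables from [parse_trnascan()] run with the
#'   eukaryotic and bacterial search options respectively.
#' @return the subset of `euk_genes` passing the score comparison, with
#'   columns `cove_score_euk` and `cove_score_bac` added.
#' @export
select_eukaryotic <- function(euk_genes, bac_genes) {
  key_e <- locus_key(euk_genes)
  key_b <- locus_key(bac_genes)
  bac_score <- bac_genes$cove_score[match(key_e, key_b)]
  keep <- is.na(bac_score) | euk_genes$cove_score > bac_score
  out <- euk_genes[keep, , drop = FALSE]
  out$cove_score_euk <- out$cove_score
  out$cove_score_bac <- bac_score[keep]
  rownames(out) <- NULL
  out
}

#' Curate a tRNA gene catalog
#'
#' Removes pseudogene-flagged genes, genes lying within `edge_margin`
#' nucleotides of a contig boundary (truncated models at the ends of draft
#' contigs are unreliable), and genes carrying polymorphic sites. Genes at
#' overlapping loci on the same contig and strand are treated as polymorphic
#' evidence (two unresolved alleles) and both copies are flagged and removed.
#'
#' @param genes gene table as from [parse_trnascan()].
#' @param contig_lengths named integer vector of contig lengths; every contig
#'   referenced by `genes` must be present.
#' @param edge_margin genes closer than this many nucleotides to a contig
#'   boundary are removed (default 5).
#' @return the curated gene table (the calling catalog), with a
#'   `removed` attribute holding the rejected rows and their reasons.
#' @export
curate_genes <- function(genes, contig_lengths, edge_margin = 5L) {
  if (nrow(genes) == 0L) return(genes)
  unknown <- setdiff(genes$contig_id, names(contig_lengths))
  if (length(unknown) > 0L) {
    stop("gene references unknown contig(s): ", paste(unknown, collapse = ", "))
  }
  poly <- genes$polymorphic
  # overlapping loci on the same contig+strand imply unresolved alleles
  for (i in seq_len(nrow(genes))) {
    ov <- genes$contig_id == genes$contig_id[i] &
      genes$strand == genes$strand[i] &
      genes$start <= genes$end[i] & genes$end >= genes$start[i]
    if (sum(ov) > 1L) poly[ov] <- TRUE
  }
  len <- contig_lengths[genes$contig_id]
  at_edge <- (genes$start - 1L) < edge_margin | (len - genes$end) < edge_margin
  reason <- ifelse(genes$pseudo, "pseudo",
                   ifelse(at_edge, "contig_end",
                          ifelse(poly, "polymorphic", NA_character_)))
  keep <- is.na(reason)
  out <- genes[keep, , drop = FALSE]
  out$polymorphic <- poly[keep]
  removed <- genes[!keep, , drop = FALSE]
  removed$reason <- reason[!keep]
  removed$polymorphic <- poly[!keep]
  rownames(out) <- NULL
  attr(out, "removed") <- removed
  out
}

#' Derive the mature tRNA sequence of a gene
#'
#' Extracts the genomic gene body (reverse-complemented for minus-strand
#' genes), removes an annotated intron, and appends the post-transcriptional
#' "CCA" tail, which eukaryotic genomes do not encode. The anticodon's
#' position on the mature sequence is then located as the occurrence of the
#' anticodon triplet whose center lies closest to `anticodon_center`
#' (cloverleaf position 34 by default), leftmost on ties.
#'
#' @param gene one-row gene table (as from [parse_trnascan()]).
#' @param contigs named character vector of contig sequences.
#' @param anticodon_center expected mature position of the middle anticodon
#'   base (default 34).
#' @return one-row data.frame with `gene_id`, `isotype`, `anticodon`,
#'   `sequence` (ends in "CCA"), `length`, `anticodon_start`, `anticodon_end`.
#' @export
mature_sequence <- function(gene, contigs, anticodon_center = 34L) {
  stopifnot(nrow(gene) == 1L)
  contig <- contigs[[gene$contig_id]]
  if (is.null(contig) || is.na(gene$start) || gene$start < 1L ||
      gene$end > nchar(contig)) {
    stop("gene ", gene$gene_id, " interval out of bounds on contig ",
         gene$contig_id)
  }
  body <- substr(contig, gene$start, gene$end)
  # intron coordinates are genomic; convert to gene-local before strand flip
  if (!is.na(gene$intron_start)) {
    a <- gene$intron_start - gene$start + 1L
    b <- gene$intron_end - gene$start + 1L
    body <- paste0(substr(body, 1L, a - 1L), substr(body, b + 1L, nchar(body)))
  }
  if (gene$strand == "-") body <- revcomp(body)
  seqn <- paste0(body, "CCA")
  ac <- locate_anticodon(seqn, gene$anticodon, anticodon_center)
  data.frame(gene_id = gene$gene_id, isotype = gene$isotype,
             anticodon = gene$anticodon, sequence = seqn,
             length = nchar(seqn), anticodon_start = ac,
             anticodon_end = ac + 2L, stringsAsFactors = FALSE)
}

locate_anticodon <- function(sequence, anticodon, center = 34L) {
  triplet <- dna_anticodon(anticodon)
  n <- nchar(sequence)
  # all occurrences, including overlapping ones (homopolymeric anticodons
  # such as CCC can self-overlap, which gregexpr would skip)
  pos <- which(substring(sequence, 1:(n - 2L), 3:n) == triplet)
  if (length(pos) == 0L) {
    stop("anticodon ", anticodon, " not found in mature sequence")
  }
  pos[which.min(abs(pos + 1L - center))]
}

#' Mature sequences for a whole catalog
#'
#' @param genes curated gene table.
#' @param contigs named character vector of contig sequences.
#' @param anticodon_center see [mature_sequence()].
#' @return data.frame with one row per gene, as in [mature_sequence()].
#' @export
mature_sequences <- function(genes, contigs, anticodon_center = 34L) {
  if (nrow(genes) == 0L) {
    return(data.frame(gene_id = character(), isotype = character(),
                      anticodon = character(), sequence = character(),
                      length = integer(), anticodon_start = integer(),
                      anticodon_end = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
    mature_sequence(genes[i, , drop = FALSE], contigs, anticodon_center)
  }))
}

#' Structural region map of a mature tRNA
#'
#' Anchored on the anticodon: the anticodon loop is the 7-nt window
#' `anticodon +/- 2`; the anticodon stem-loop extends the loop by the stem
#' width on each side. Half and end windows are defined relative to the loop
#' by the fragment classifier (see [classify_region()]).
#'
#' @param trna one-row mature-tRNA data.frame (from [mature_sequence()]).
#' @param stem_width paired-stem width flanking the loop (default 5 bp).
#' @return list with `length`, `loop_start`, `loop_end`, `sl_start`,
#'   `sl_end` (stem-loop window, clipped to the sequence).
#' @export
region_map <- function(trna, stem_width = 5L) {
  loop_start <- trna$anticodon_start - 2L
  loop_end <- trna$anticodon_end + 2L
  if (loop_start < 1L || loop_end > trna$length) {
    stop("anticodon of ", trna$gene_id,
         " too close to a terminus for the anticodon loop to fit")
  }
  list(length = as.integer(trna$length),
       loop_start = as.integer(loop_start), loop_end = as.integer(loop_end),
       sl_start = as.integer(max(1L, loop_start - stem_width)),
       sl_end = as.integer(min(trna$length, loop_end + stem_width)))
}

#' Add region-map columns to a mature-tRNA table
#' @param matures data.frame from [mature_sequences()].
#' @param stem_width see [region_map()].
#' @return `matures` with `loop_start`, `loop_end`, `sl_start`, `sl_end`.
#' @export
add_region_map <- function(matures, stem_width = 5L) {
  if (nrow(matures) == 0L) {
    matures$loop_start <- matures$loop_end <- integer(0)
    matures$sl_start <- matures$sl_end <- integer(0)
    return(matures)
  }
  rm_ <- lapply(seq_len(nrow(matures)), function(i) {
    region_map(matures[i, , drop = FALSE], stem_width)
  })
  matures$loop_start <- vapply(rm_, `[[`, integer(1), "loop_start")
  matures$loop_end <- vapply(rm_, `[[`, integer(1), "loop_end")
  matures$sl_start <- vapply(rm_, `[[`, integer(1), "sl_start")
  matures$sl_end <- vapply(rm_, `[[`, integer(1), "sl_end")
  matures
}

#' Write a catalog TSV
#' @param genes curated gene table.
#' @param matures matching mature-tRNA table.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_catalog_tsv <- function(genes, matures, file) {
  tab <- merge(genes[, c("gene_id", "contig_id", "start", "end", "strand",
                         "isotype", "anticodon", "pseudo", "polymorphic")],
               matures[, c("gene_id", "sequence", "anticodon_start",
                           "anticodon_end")],
               by = "gene_id", sort = TRUE)
  write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
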