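# independent predicate evaluation of the region rules, written as a flat
# truth-table over the six categories rather than a decision cascade
predicate_region <- function(s, e, map, t5 = 2L, t3 = 2L, w = 5L) {
  a5 <- s <= 1L + t5
  a3 <- e >= map$length - t3
  in_loop <- function(p) p >= map$loop_start && p <= map$loop_end
  cats <- c(
    "5' half" = a5 && in_loop(e),
    "3' half" = a3 && in_loop(s),
    "5' end" = a5 && e < map$loop_start,
    "3' end" = a3 && s > map$loop_end,
    "AC stem-loop" = !a5 && !a3 && s >= map$sl_start - w &&
      e <= map$sl_end + w)
  hit <- names(cats)[cats]
  if (length(hit) == 0L) "other" else hit[1L]
}

# brute-force oracle for fragment calling: enumerates every substring
# occurrence of every read against every mature sequence and every contig
# strand by direct position-wise comparison, then applies the filter
# predicates literally; independent of the package's search code paths

occ_all <- function(pattern, subject) {
  n <- nchar(pattern)
  L <- nchar(subject)
  if (n > L) return(integer(0))
  starts <- 1:(L - n + 1L)
  starts[substring(subject, starts, starts + n - 1L) == pattern]
}

oracle_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]), collapse = "")
}

# all (gene, span, cca) mature hits of one read under the CCA rule: a hit
# may end at or before the last genomic base, or exactly at the mature 3'
# end (full CCA tail); anything ending inside the tail is discarded
oracle_mature_hits <- function(read, matures) {
  out <- list()
  for (i in seq_len(nrow(matures))) {
    L <- matures$length[i]
    for (s in occ_all(read, matures$sequence[i])) {
      e <- s + nchar(read) - 1L
      if (e <= L - 3L || e == L) {
        out[[length(out) + 1L]] <- data.frame(
          gene_id = matures$gene_id[i], anticodon = matures$anticodon[i],
          isotype = matures$isotype[i],
          polymorphic = matures$polymorphic[i], start = s, end = e,
          cca_masked = e == L, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    data.frame(gene_id = character(), anticodon = character(),
               isotype = character(), polymorphic = logical(),
               start = integer(), end = integer(), cca_masked = logical())
  } else {
    do.call(rbind, out)
  }
}

oracle_genomic <- function(read, contigs) {
  out <- list()
  for (nm in names(contigs)) {
    for (s in occ_all(read, contigs[[nm]])) {
      out[[length(out) + 1L]] <- data.frame(
        subject = nm, start = s, end = s + nchar(read) - 1L, strand = "+",
        stringsAsFactors = FALSE)
    }
    rc <- oracle_revcomp(contigs[[nm]])
    L <- nchar(rc)
    for (s in occ_all(read, rc)) {
      e <- s + nchar(read) - 1L
      out[[length(out) + 1L]] <- data.frame(
        subject = nm, start = L - e + 1L, end = L - s + 1L, strand = "-",
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    data.frame(subject = character(), start = integer(), end = integer(),
               strand = character(), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, out)
  }
}

# literal per-read oracle: returns list(status, compartment, anticodon,
# parents); status is "called" or a drop reason or "unassigned"
oracle_one_read <- function(read, mito, nuclear, footnote_a_mito = FALSE,
                            footnote_c_mito = TRUE, poly_mode = "any") {
  for (comp in c("mitochondrial", "nuclear")) {
    cat_ <- if (comp == "mitochondrial") mito else nuclear
    if (is.null(cat_)) next
    hits <- oracle_mature_hits(read, cat_$matures)
    occ <- oracle_genomic(read, cat_$contigs)
    if (nrow(hits) == 0L && nrow(occ) == 0L) next
    if (nrow(hits) == 0L) {
      return(list(status = "non_trna_locus", compartment = comp,
                  anticodon = NA, parents = NA))
    }
    non_trna <- FALSE
    for (j in seq_len(nrow(occ))) {
      g <- cat_$all_genes
      covered <- any(g$contig_id == occ$subject[j] &
                       g$strand == occ$strand[j] &
                       g$start <= occ$start[j] & g$end >= occ$end[j])
      if (!covered) non_trna <- TRUE
    }
    apply_a <- if (comp == "mitochondrial") footnote_a_mito else TRUE
    apply_c <- if (comp == "mitochondrial") footnote_c_mito else TRUE
    if (apply_a && non_trna) {
      return(list(status = "ambiguous_genomic", compartment = comp,
                  anticodon = NA, parents = NA))
    }
    if (poly_mode == "any") {
      if (any(hits$polymorphic)) {
        return(list(status = "polymorphic", compartment = comp,
                    anticodon = NA, parents = NA))
      }
    } else {
      hits <- hits[!hits$polymorphic, , drop = FALSE]
      if (nrow(hits) == 0L) {
        return(list(status = "polymorphic", compartment = comp,
                    anticodon = NA, parents = NA))
      }
    }
    if (apply_c && length(unique(hits$anticodon)) > 1L) {
      return(list(status = "multi_anticodon", compartment = comp,
                  anticodon = NA, parents = NA))
    }
    return(list(status = "called", compartment = comp,
                anticodon = hits$anticodon[1],
                parents = paste(sort(unique(hits$gene_id)), collapse = ",")))
  }
  list(status = "unassigned", compartment = NA, anticodon = NA, parents = NA)
}

oracle_call <- function(unique_reads, mito, nuclear, ...) {
  res <- lapply(unique_reads$sequence, oracle_one_read, mito = mito,
                nuclear = nuclear, ...)
  data.frame(sequence = unique_reads$sequence,
             status = vapply(res, function(r) r$status, ""),
             compartment = vapply(res, function(r) as.character(r$compartment), ""),
             anticodon = vapply(res, function(r) as.character(r$anticodon), ""),
             parents = vapply(res, function(r) as.character(r$parents), ""),
             pooled_count = unique_reads$pooled_count,
             stringsAsFactors = FALSE)
}

# random mapping instance: small genome bundle + adversarial read mixture
# (mature spans with/without CCA tails, partial-tail suffixes, contig
# windows, decoy windows, antisense reads, random reads)
random_instance <- function(seed, n_reads = 40L) {
  set.seed(seed)
  cfg <- sim_config(seed = seed, n_mito_genes = 2L,
                    n_nuclear_anticodons = 4L, n_fragment_reads = 500L)
  b <- generate_genome(cfg)
  cats <- bundle_catalogs(b)
  matures <- rbind(cats$mitochondrial$matures, cats$nuclear$matures)
  contigs <- c(cats$mitochondrial$contigs, cats$nuclear$contigs)
  draw_read <- function() {
    kind <- sample(c("span", "cca", "partial", "contig", "random",
                     "antisense"), 1L,
                   prob = c(0.35, 0.2, 0.1, 0.15, 0.1, 0.1))
    len <- sample(25:45, 1L)
    m <- matures[sample(nrow(matures), 1L), ]
    switch(kind,
           span = {
             s <- sample(max(1L, m$length - 3L - len + 1L), 1L)
             substr(m$sequence, s, s + len - 1L)
           },
           cca = substr(m$sequence, m$length - len + 1L, m$length),
           partial = substr(m$sequence, m$length - len,
                            m$length - sample(1:2, 1L)),
           contig = {
             ctg <- contigs[[sample(length(contigs), 1L)]]
             s <- sample(nchar(ctg) - len + 1L, 1L)
             substr(ctg, s, s + len - 1L)
           },
           random = rand_dna(len),
           antisense = {
             s <- sample(max(1L, m$length - 3L - len + 1L), 1L)
             oracle_revcomp(substr(m$sequence, s, s + len - 1L))
           })
  }
  seqs <- unique(replicate(n_reads, draw_read()))
  counts <- lapply(seqs, function(s) {
    as.integer(rmultinom(1L, sample(5:20, 1L), rep(1, 6)))
  })
  names(counts) <- seqs
  ur <- make_unique_reads(counts)
  list(unique_reads = ur, cats = cats)
}

# run both routes on an instance and compare them row by row
compare_with_oracle <- function(inst, ...) {
  got <- call_trfs(inst$unique_reads, inst$cats$mitochondrial,
                   inst$cats$nuclear, ...)
  want <- oracle_call(inst$unique_reads, inst$cats$mitochondrial,
                      inst$cats$nuclear, ...)
  got_status <- setNames(rep("unassigned", nrow(inst$unique_reads)),
                         inst$unique_reads$sequence)
  got_status[got$trfs$sequence] <- "called"
  dr <- got$dropped
  dr <- dr[dr$reason != "unassigned", , drop = FALSE]
  got_status[dr$sequence] <- dr$reason
  ok_status <- identical(unname(got_status[want$sequence]), want$status)
  called <- want[want$status == "called", , drop = FALSE]
  idx <- match(called$sequence, got$trfs$sequence)
  ok_called <- !anyNA(idx) &&
    identical(got$trfs$anticodon[idx], called$anticodon) &&
    identical(got$trfs$compartment[idx], called$compartment) &&
    identical(got$trfs$parents[idx], called$parents)
  # summary totals must agree with the oracle's independent tally
  want_tot <- tapply(called$pooled_count,
                     paste(called$compartment, called$anticodon), sum)
  got_tot <- setNames(got$summary$total,
                      paste(got$summary$compartment, got$summary$anticodon))
  ok_tot <- length(want_tot) == length(got_tot) &&
    all(sort(names(want_tot)) == sort(names(got_tot))) &&
    all(got_tot[names(want_tot)] == want_tot)
  ok_status && ok_called && ok_tot
}
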