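test_that("matching is exact and CCA-tail aware", {
  m <- toy_mature(L = 75)
  seqn <- m$sequence
  # interior span
  read <- substr(seqn, 1, 33)
  h <- match_to_trna(read, seqn)
  expect_equal(nrow(h), 1L)
  expect_equal(c(h$start, h$end), c(1L, 33L))
  expect_false(h$cca_masked)
  # last 30 genomic nt + CCA: flush 3' hit, mask required
  read2 <- substr(seqn, 75 - 32, 75)
  h2 <- match_to_trna(read2, seqn)
  expect_equal(nrow(h2), 1L)
  expect_equal(h2$end, 75L)
  expect_true(h2$cca_masked)
  # one substitution kills the hit
  mut <- paste0("A", substr(read, 2, 33))
  if (substr(read, 1, 1) == "A") mut <- paste0("G", substr(read, 2, 33))
  expect_equal(nrow(match_to_trna(mut, seqn)), 0L)
  # partial CCA tails are dropped by default, kept on request
  partial <- substr(seqn, 75 - 30, 74)
  expect_equal(nrow(match_to_trna(partial, seqn)), 0L)
  expect_equal(nrow(match_to_trna(partial, seqn, cca_partial = TRUE)), 1L)
})

test_that("genomic occurrence scan covers both strands with plus coordinates", {
  contig <- c(c1 = paste0("TTTT", "ACGTACGTACGTACGTACGTACGTA", "GGGG"))
  read <- "ACGTACGTACGTACGTACGTACGTA"
  occ <- find_genomic_occurrences(read, contig)
  expect_true(any(occ$strand == "+" & occ$start == 5 & occ$end == 29))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(read)))
  occ2 <- find_genomic_occurrences(rc, contig)
  minus <- occ2[occ2$strand == "-", ]
  expect_equal(nrow(minus), 1L)
  expect_equal(c(minus$start, minus$end), c(5L, 29L))
})

test_that("ambiguity filters implement the three removal rules", {
  hits <- data.frame(gene_id = c("g1", "g2"), anticodon = c("GCC", "GCC"),
                     isotype = "Gly", polymorphic = c(FALSE, FALSE),
                     start = 1L, end = 30L, cca_masked = FALSE,
                     stringsAsFactors = FALSE)
  # (a) non-tRNA genomic occurrence
  expect_equal(ambiguity_filter(hits, TRUE)$reason, "ambiguous_genomic")
  # same-anticodon subtypes are kept with both parents
  keep <- ambiguity_filter(hits, FALSE)
  expect_true(keep$keep)
  expect_equal(nrow(keep$hits), 2L)
  # (c) two distinct anticodons
  hits_c <- hits
  hits_c$anticodon <- c("CUC", "UUC")
  expect_equal(ambiguity_filter(hits_c, FALSE)$reason, "multi_anticodon")
  # (b) polymorphic parents under both modes
  hits_b <- hits
  hits_b$polymorphic <- c(TRUE, FALSE)
  expect_equal(ambiguity_filter(hits_b, FALSE, poly_mode = "any")$reason,
               "polymorphic")
  only <- ambiguity_filter(hits_b, FALSE, poly_mode = "only")
  expect_true(only$keep)
  expect_equal(only$hits$gene_id, "g2")
  hits_b$polymorphic <- c(TRUE, TRUE)
  expect_equal(ambiguity_filter(hits_b, FALSE, poly_mode = "only")$reason,
               "polymorphic")
})

test_that("mitochondrial occurrences claim reads before the nuclear search", {
  m_mito <- toy_mature(L = 75, anticodon = "GCU", gene_id = "m.trna1",
                       isotype = "Ser")
  m_nuc <- toy_mature(L = 75, anticodon = "GCC", gene_id = "n.trna1")
  mito <- toy_catalog(m_mito, "mitochondrial")
  nuc <- toy_catalog(m_nuc)
  # a read present in both compartments' tRNAs is mitochondrial
  shared <- substr(m_mito$sequence, 1, 30)
  nuc2 <- nuc
  nuc2$matures <- rbind(nuc2$matures, mito$matures)
  ur <- make_unique_reads(setNames(list(c(5L, 1L, 0L, 0L, 0L, 0L)), shared))
  res <- call_trfs(ur, mito, nuc2)
  expect_equal(res$trfs$compartment, "mitochondrial")
  # a read found only in mitochondrial non-tRNA sequence is consumed
  spacer_read <- paste0(substr(mito$contigs[[1]], 3, 20),
                        substr(mito$contigs[[1]], 21, 29))
  spacer_read <- substr(mito$contigs[[1]], 2, 29)
  ur2 <- make_unique_reads(setNames(list(c(6L, 0L, 0L, 0L, 0L, 0L)),
                                    spacer_read))
  res2 <- call_trfs(ur2, mito, nuc)
  expect_equal(nrow(res2$trfs), 0L)
  expect_equal(res2$dropped$reason, "non_trna_locus")
  expect_equal(res2$dropped$compartment, "mitochondrial")
  # no occurrence anywhere: unassigned
  ur3 <- make_unique_reads(setNames(list(c(6L, 0L, 0L, 0L, 0L, 0L)),
                                    strrep("ACGGT", 6)))
  res3 <- call_trfs(ur3, mito, nuc)
  expect_equal(res3$dropped$reason, "unassigned")
  # empty catalogs: everything unassigned
  res4 <- call_trfs(ur, NULL, NULL)
  expect_equal(nrow(res4$trfs), 0L)
  expect_equal(res4$dropped$reason, "unassigned")
})

test_that("calling is invariant under read and catalog permutations", {
  inst <- random_instance(seed = 77, n_reads = 30L)
  base <- call_trfs(inst$unique_reads, inst$cats$mitochondrial,
                    inst$cats$nuclear)
  perm <- inst$unique_reads[rev(seq_len(nrow(inst$unique_reads))), ]
  cats2 <- inst$cats
  cats2$nuclear$matures <-
    cats2$nuclear$matures[rev(seq_len(nrow(cats2$nuclear$matures))), ]
  got <- call_trfs(perm, cats2$mitochondrial, cats2$nuclear)
  expect_identical(base$summary, got$summary)
  ord <- function(x) x[order(x$sequence), , drop = FALSE]
  expect_equal(ord(base$trfs), ord(got$trfs), ignore_attr = TRUE)
})

test_that("spans stay on the mature tRNA and masked hits end at its 3' end", {
  inst <- random_instance(seed = 5, n_reads = 60L)
  res <- call_trfs(inst$unique_reads, inst$cats$mitochondrial,
                   inst$cats$nuclear)
  matures <- rbind(inst$cats$mitochondrial$matures,
                   inst$cats$nuclear$matures)
  idx <- match(res$hits$gene_id, matures$gene_id)
  expect_true(all(res$hits$start >= 1L))
  expect_true(all(res$hits$end <= matures$length[idx]))
  masked <- res$hits$cca_masked
  expect_true(all(res$hits$end[masked] == matures$length[idx][masked]))
})

test_that("calls match the brute-force oracle on random instances", {
  for (seed in 1:20) {
    expect_true(compare_with_oracle(random_instance(seed)),
                label = paste("oracle agreement, instance", seed))
  }
})

test_that("a decoy locus removes exactly the reads it can absorb", {
  cfg <- small_cfg(seed = 17)
  b <- generate_genome(cfg)
  sim <- simulate_reads(b, withr::local_tempdir())
  cats <- bundle_catalogs(b)
  filt <- filter_reads(sim$fastq)
  res <- call_trfs(filt$unique_reads, cats$mitochondrial, cats$nuclear)
  tr <- sim$truth
  decoy_reads <- sum(tr$count[tr$fate == "ambiguous_decoy"])
  expect_gt(decoy_reads, 0L)
  # decoy-absorbed reads are dropped with the genomic-ambiguity reason
  decoy_seqs <- unique(tr$sequence[tr$fate == "ambiguous_decoy"])
  expect_true(all(decoy_seqs %in%
                    res$dropped$sequence[res$dropped$reason ==
                                           "ambiguous_genomic"]))
  expect_false(any(decoy_seqs %in% res$trfs$sequence))
  # and the affected anticodon total is short by exactly the absorbed count
  src <- b$genes[b$genes$gene_id == b$decoys$source_gene[1], ]
  planted_total <- sum(tr$count[!is.na(tr$anticodon) &
                                  tr$anticodon == src$anticodon &
                                  tr$fate %in% c("called", "ambiguous_decoy")])
  called_total <- res$summary$total[res$summary$anticodon == src$anticodon &
                                      res$summary$compartment == "nuclear"]
  expect_equal(planted_total - decoy_reads, called_total)
})
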