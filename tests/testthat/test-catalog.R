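write_scan_file <- function(rows) {
  f <- withr::local_tempfile(fileext = ".tsv",
                             .local_envir = parent.frame())
  header <- c("Sequence\ttRNA\tBounds\t\ttRNA\tAnti\tIntron\tBounds\tCove\tNote",
              "Name\t#\tBegin\tEnd\tType\tCodon\tBegin\tEnd\tScore\t",
              paste(rep("--------", 10), collapse = "\t"))
  writeLines(c(header, rows), f)
  f
}

test_that("tRNAscan tabular output parses with strand and flag handling", {
  f <- write_scan_file(c(
    "ctg1\t1\t100\t171\tGly\tGCC\t0\t0\t65.20\t",
    "ctg1\t2\t5000\t4928\tGlu\tCTC\t0\t0\t60.00\t",
    "ctg2\t1\t300\t371\tSer\tGCT\t0\t0\t55.00\tpseudo",
    "ctg2\t2\t600\t680\tLeu\tCAA\t640\t649\t58.00\t"))
  g <- parse_trnascan(f)
  expect_equal(nrow(g), 4L)
  expect_equal(g$anticodon, c("GCC", "CUC", "GCU", "CAA"))
  expect_equal(g$strand, c("+", "-", "+", "+"))
  expect_equal(g$start[2], 4928L)
  expect_equal(g$end[2], 5000L)
  expect_equal(g$pseudo, c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(g$intron_start[4], 640L)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("ctg1\t1\t100", "x"), bad)
  expect_error(parse_trnascan(bad), "malformed")
})

test_that("eukaryotic-vs-bacterial score comparison keeps the right loci", {
  euk <- write_scan_file(c(
    "c1\t1\t100\t171\tGly\tGCC\t0\t0\t65.20\t",
    "c1\t2\t300\t371\tGlu\tCTC\t0\t0\t40.00\t",
    "c1\t3\t500\t571\tLys\tCTT\t0\t0\t70.00\t"))
  bac <- write_scan_file(c(
    "c1\t1\t100\t171\tGly\tGCC\t0\t0\t50.10\t",
    "c1\t2\t300\t371\tGlu\tCTC\t0\t0\t45.00\t"))
  sel <- select_eukaryotic(parse_trnascan(euk), parse_trnascan(bac))
  expect_setequal(sel$gene_id, c("c1.trna1", "c1.trna3"))
  expect_equal(sel$cove_score_euk[sel$gene_id == "c1.trna1"], 65.2)
  expect_equal(sel$cove_score_bac[sel$gene_id == "c1.trna1"], 50.1)
  expect_true(is.na(sel$cove_score_bac[sel$gene_id == "c1.trna3"]))
})

test_that("curation removes pseudo, boundary and polymorphic genes", {
  f <- write_scan_file(c(
    "c1\t1\t100\t171\tGly\tGCC\t0\t0\t65.00\t",
    "c1\t2\t300\t371\tSer\tGCT\t0\t0\t55.00\tpseudo",
    "c1\t3\t930\t998\tGlu\tCTC\t0\t0\t60.00\t",
    "c1\t4\t500\t571\tLys\tCTT\t0\t0\t70.00\t",
    "c1\t5\t520\t590\tLys\tCTT\t0\t0\t69.00\t"))
  g <- parse_trnascan(f)
  cur <- curate_genes(g, c(c1 = 1000L), edge_margin = 5L)
  expect_equal(cur$gene_id, "c1.trna1")
  removed <- attr(cur, "removed")
  expect_setequal(removed$reason,
                  c("pseudo", "contig_end", "polymorphic"))
  # gene ending 2 nt before the contig end is a boundary gene
  expect_equal(removed$reason[removed$gene_id == "c1.trna3"], "contig_end")
  # overlapping same-strand loci are polymorphic evidence for both copies
  expect_equal(sum(removed$reason == "polymorphic"), 2L)
  expect_error(curate_genes(g, c(other = 1000L)), "unknown contig")
})

test_that("mature sequences are strand-resolved, intronless and CCA-tailed", {
  body <- paste0(rand_dna(32), "GCC", rand_dna(37))  # 72 nt, anticodon 33-35
  contig <- paste0("T", rand_dna(48), "A", body, "T", rand_dna(48), "A")
  gene <- data.frame(gene_id = "g1", contig_id = "c", start = 51L,
                     end = 122L, strand = "+", isotype = "Gly",
                     anticodon = "GCC", intron_start = NA_integer_,
                     intron_end = NA_integer_, cove_score = 60,
                     pseudo = FALSE, polymorphic = FALSE,
                     stringsAsFactors = FALSE)
  m <- mature_sequence(gene, c(c = contig))
  expect_equal(m$length, 75L)
  expect_identical(m$sequence, paste0(body, "CCA"))
  expect_true(endsWith(m$sequence, "CCA"))
  expect_equal(c(m$anticodon_start, m$anticodon_end), c(33L, 35L))

  minus <- gene
  minus$strand <- "-"
  m2 <- mature_sequence(minus, c(c = contig))
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(contig, 51, 122))))
  expect_identical(m2$sequence, paste0(rc, "CCA"))

  with_intron <- gene
  with_intron$intron_start <- 90L
  with_intron$intron_end <- 99L
  m3 <- mature_sequence(with_intron, c(c = contig))
  expect_equal(m3$length, 72L - 10L + 3L)

  oob <- gene
  oob$end <- 5000L
  expect_error(mature_sequence(oob, c(c = contig)), "out of bounds")
})

test_that("region map anchors on the anticodon and rejects degenerate cases", {
  m <- toy_mature(L = 75)
  rm_ <- region_map(m, stem_width = 5L)
  expect_equal(c(rm_$loop_start, rm_$loop_end), c(31L, 37L))
  expect_equal(c(rm_$sl_start, rm_$sl_end), c(26L, 42L))
  bad <- m
  bad$anticodon_start <- 2L
  bad$anticodon_end <- 4L
  expect_error(region_map(bad), "too close")
})

test_that("parse-select-curate-mature reproduces planted mature sequences", {
  b <- generate_genome(small_cfg(seed = 13))
  paths <- write_bundle(b, withr::local_tempdir())
  contigs <- setNames(
    as.character(Biostrings::readDNAStringSet(paths[["nuclear_fasta"]])),
    names(Biostrings::readDNAStringSet(paths[["nuclear_fasta"]])))
  sel <- select_eukaryotic(parse_trnascan(paths[["euk_annot"]]),
                           parse_trnascan(paths[["bac_annot"]]))
  cur <- curate_genes(sel, nchar(contigs))
  mat <- mature_sequences(cur, contigs)
  planted <- b$genes[b$genes$compartment == "nuclear" &
                       b$genes$role %in% c("clean", "decoy_source"), ]
  expect_setequal(mat$gene_id, planted$gene_id)
  idx <- match(mat$gene_id, planted$gene_id)
  expect_identical(mat$sequence, planted$mature[idx])
  # the anticodon sits at its recomputed positions in every mature sequence
  expect_identical(substr(mat$sequence, mat$anticodon_start,
                          mat$anticodon_end),
                   chartr("U", "T", mat$anticodon))
})
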