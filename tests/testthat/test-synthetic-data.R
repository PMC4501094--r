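test_that("genome generation is deterministic and honors planted structure", {
  cfg <- small_cfg(seed = 11)
  b1 <- generate_genome(cfg)
  b2 <- generate_genome(cfg)
  expect_identical(b1, b2)

  g <- b1$genes
  # every planted gene body occurs at its recorded interval, strand-resolved
  for (i in seq_len(nrow(g))) {
    contig <- c(b1$mito_contigs, b1$nuclear_contigs)[[g$contig_id[i]]]
    found <- substr(contig, g$start[i], g$end[i])
    planted <- if (g$strand[i] == "-") {
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(g$body[i])))
    } else {
      g$body[i]
    }
    expect_identical(found, planted)
  }
  # genomic bodies never end in CCA; matures always do
  expect_false(any(endsWith(g$body, "CCA")))
  expect_true(all(endsWith(g$mature, "CCA")))
  expect_true(any(g$strand == "-"))
})

test_that("isodecoder subtypes share the anticodon but differ elsewhere", {
  b <- generate_genome(small_cfg(seed = 3))
  g <- b$genes
  pairs <- split(g, paste(g$compartment, g$anticodon))
  multi <- Filter(function(x) nrow(x) > 1L, pairs)
  expect_gte(length(multi), 1L)
  for (m in multi) {
    expect_length(unique(m$anticodon), 1L)
    expect_gt(length(unique(m$body)), 1L)
    # the difference lies outside the anticodon (positions 33-35)
    expect_true(all(substr(m$body, 33, 35) == substr(m$body[1], 33, 35)))
  }
})

test_that("decoys are unannotated exact copies of a tRNA body", {
  b <- generate_genome(small_cfg(seed = 5))
  expect_equal(nrow(b$decoys), 1L)
  d <- b$decoys[1, ]
  src <- b$genes[b$genes$gene_id == d$source_gene, ]
  copy <- substr(b$nuclear_contigs[[d$contig_id]], d$start, d$end)
  expect_identical(copy, src$body)
  expect_false(d$contig_id == src$contig_id)
  ann <- b$genes[b$genes$contig_id == d$contig_id, ]
  expect_false(any(ann$start <= d$end & ann$end >= d$start))
})

test_that("spike sequences occur nowhere in genes or contigs", {
  b <- generate_genome(small_cfg(seed = 9))
  hay <- c(b$mito_contigs, b$nuclear_contigs, b$genes$mature)
  for (s in b$spikes) {
    expect_false(any(vapply(hay, grepl, logical(1), pattern = s,
                            fixed = TRUE)))
  }
  expect_false(b$spikes[1] == b$spikes[2])
})

test_that("simulated libraries carry planted reads, spikes and artifacts", {
  cfg <- small_cfg(seed = 21)
  b <- generate_genome(cfg)
  d <- withr::local_tempdir()
  sim <- simulate_reads(b, d)
  expect_identical(simulate_reads(b, withr::local_tempdir())$truth, sim$truth)
  expect_true(all(file.exists(sim$fastq)))

  tr <- sim$truth
  # fragment reads (whatever their fate) are exact substrings of a mature
  frag <- tr[!is.na(tr$anticodon), ]
  expect_gt(nrow(frag), 0L)
  in_mature <- vapply(unique(frag$sequence), function(s) {
    any(vapply(b$genes$mature, grepl, logical(1), pattern = s, fixed = TRUE))
  }, logical(1))
  expect_true(all(in_mature))
  # spikes appear at the configured per-stage counts
  for (k in 1:2) {
    sp <- tr[tr$sequence == b$spikes[k], ]
    expect_identical(setNames(sp$count, sp$stage)[STAGES],
                     setNames(as.integer(cfg$spike_counts[k, ]), STAGES))
  }
  # low-quality records carry mean Phred below 20
  fq <- read_fastq(sim$fastq[["egg"]])
  lowseqs <- tr$sequence[tr$fate == "low_quality" & tr$stage == "egg"]
  if (length(lowseqs) > 0L) {
    q <- fq$quality[fq$sequence %in% lowseqs]
    mq <- vapply(q, function(s) mean(as.integer(charToRaw(s)) - 33), 0)
    expect_true(all(mq < 20))
  }
  # every truth read is present in its stage library at its count
  egg <- table(fq$sequence)
  egg_truth <- tr[tr$stage == "egg", ]
  expect_identical(as.integer(egg[egg_truth$sequence]), egg_truth$count)
})

test_that("a pure 5'-half profile puts every fragment at mature position 1", {
  cfg <- small_cfg(seed = 2)
  b <- generate_genome(cfg)
  b$profiles$dominant_region <- "5' half"
  b$profiles$dominant_share <- 1
  sim <- simulate_reads(b, withr::local_tempdir())
  frag <- sim$truth[!is.na(sim$truth$anticodon), ]
  starts <- vapply(seq_len(nrow(frag)), function(i) {
    parents <- strsplit(frag$parents[i], ",")[[1]]
    m <- b$genes$mature[b$genes$gene_id == parents[1]]
    regexpr(frag$sequence[i], m, fixed = TRUE)[1]
  }, integer(1))
  expect_true(all(starts == 1L))
  expect_true(all(frag$region == "5' half"))
})

test_that("with zero noise every non-spike, non-artifact read has a parent", {
  cfg <- small_cfg(seed = 4, noise_fraction = 0)
  b <- generate_genome(cfg)
  sim <- simulate_reads(b, withr::local_tempdir())
  tr <- sim$truth
  expect_false(any(tr$fate == "noise"))
  substantive <- !(tr$fate %in% c("spike", "low_quality", "contains_n",
                                  "too_short", "too_long"))
  artificial <- is.na(tr$parents) & substantive &
    tr$fate != "below_threshold"
  expect_true(all(!is.na(tr$parents[artificial])) || sum(artificial) == 0L)
  expect_true(all(!is.na(tr$parents[tr$fate == "called"])))
})
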