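# shared fixtures: toy mature tRNAs, small unique-read tables, and a
# reduced simulation config for fast end-to-end tests

STAGES <- c("egg", "L1", "L2", "L3", "L4", "adult")

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# one-row mature-tRNA data.frame with the anticodon at 33-35 (loop 31-37,
# stem-loop 26-42 at stem width 5), built independently of the generator
toy_mature <- function(L = 75L, anticodon = "GCC", gene_id = "toy.trna1",
                       isotype = "Gly") {
  body <- rand_dna(L - 3L)
  body <- paste0(substr(body, 1, 32), chartr("U", "T", anticodon),
                 substr(body, 36, L - 3L))
  if (substr(body, L - 5L, L - 3L) == "CCA") {
    body <- paste0(substr(body, 1, L - 4L), "G")
  }
  df <- data.frame(gene_id = gene_id, isotype = isotype,
                   anticodon = anticodon, sequence = paste0(body, "CCA"),
                   length = L, anticodon_start = 33L, anticodon_end = 35L,
                   stringsAsFactors = FALSE)
  add_region_map(df)
}

toy_map <- function(L = 75L) {
  list(length = L, loop_start = 31L, loop_end = 37L, sl_start = 26L,
       sl_end = 42L)
}

# unique-read table from a named list sequence -> six stage counts
make_unique_reads <- function(counts) {
  m <- do.call(rbind, counts)
  colnames(m) <- STAGES
  out <- data.frame(sequence = names(counts), stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(m))
  out$pooled_count <- as.integer(rowSums(m))
  rownames(out) <- NULL
  out
}

small_cfg <- function(seed = 1L, ...) {
  sim_config(seed = seed, n_mito_genes = 3L, n_nuclear_anticodons = 6L,
             n_fragment_reads = 2500L, ...)
}

# a minimal single-compartment catalog around explicit mature tRNAs; the
# contig simply concatenates the gene bodies with constrained spacers
toy_catalog <- function(matures, compartment = "nuclear") {
  spacer <- function() paste0("T", rand_dna(38), "A")
  contig <- spacer()
  genes <- matures[, c("gene_id", "isotype", "anticodon"), drop = FALSE]
  genes$contig_id <- "ctg1"
  genes$start <- NA_integer_; genes$end <- NA_integer_
  genes$strand <- "+"
  genes$intron_start <- NA_integer_; genes$intron_end <- NA_integer_
  genes$cove_score <- 70; genes$pseudo <- FALSE; genes$polymorphic <- FALSE
  for (i in seq_len(nrow(matures))) {
    body <- substr(matures$sequence[i], 1, matures$length[i] - 3L)
    genes$start[i] <- nchar(contig) + 1L
    genes$end[i] <- nchar(contig) + nchar(body)
    contig <- paste0(contig, body, spacer())
  }
  curated <- genes
  attr(curated, "removed") <- genes[0, ]
  build_catalog(genes, curated, c(ctg1 = contig))
}
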