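#' Standard anticodon pool
#'
#' Isotype/anticodon pairs (RNA alphabet) used by the synthetic-data
#' generator when planting tRNA genes.
#'
#' @return data.frame with `isotype` and `anticodon`.
#' @export
anticodon_pool <- function() {
  pool <- c(
    Gly = "GCC,CCC,UCC", Glu = "CUC,UUC", Lys = "CUU,UUU", Asp = "GUC",
    His = "GUG", Thr = "UGU,AGU,CGU", Ser = "GCU,AGA,UGA,CGA,ACU",
    Val = "UAC,AAC,CAC", Phe = "GAA", Asn = "GUU", Met = "CAU",
    Tyr = "GUA", Cys = "GCA", Pro = "UGG,AGG,CGG", Gln = "UUG,CUG",
    Leu = "UAA,CAA,AAG,UAG,CAG", Ala = "UGC,AGC,CGC",
    Ile = "GAU,AAU,UAU", Arg = "ACG,CCG,UCU,CCU,UCG", SeC = "UCA")
  acs <- strsplit(pool, ",", fixed = TRUE)
  data.frame(isotype = rep(names(acs), lengths(acs)),
             anticodon = unlist(acs, use.names = FALSE),
             stringsAsFactors = FALSE)
}

#' Configuration for the synthetic-data generator
#'
#' Defines the study conditions the generator emulates: six developmental
#' stage libraries (egg, four instars, adult) of small RNA reads that are
#' fragments of planted mitochondrial and nuclear tRNA genes, plus two
#' spike-in sequences, random noise reads, and planted filter fodder
#' (low-quality, N-containing, too-short/too-long, below-abundance reads),
#' decoy loci and polymorphic genes.
#'
#' Fragmentation is controlled per anticodon: each fragment-bearing
#' anticodon is assigned a dominant structural region (cycled through
#' 5' half, 3' half, 5' end, 3' end, AC stem-loop) holding
#' `dominant_share` of its reads, the remainder spread evenly over the
#' other regions, and a developmental trend (increasing, decreasing,
#' egg-enriched, flat) shaping its per-stage read budget.
#'
#' @param seed integer RNG seed; the whole bundle is a deterministic
#'   function of the config.
#' @param stage_names exactly six stage labels.
#' @param n_mito_genes,n_nuclear_anticodons fragment-bearing mitochondrial
#'   genes and nuclear anticodons to plant.
#' @param n_subtypes_per_anticodon,n_anticodons_with_subtypes plant this
#'   many isodecoder subtypes (same anticodon, >= 1 nt difference outside
#'   the anticodon) for the first so-many nuclear anticodons.
#' @param n_nuclear_contigs nuclear contigs to spread genes over.
#' @param body_length_range genomic gene-body length range (mature length
#'   adds the 3-nt CCA tail).
#' @param anticodon_mature_start anticodon start on the mature sequence
#'   (default 33, i.e. anticodon at 33-35, loop 31-37).
#' @param n_fragment_reads total fragment reads across all stages.
#' @param dominant_share share of an anticodon's reads in its dominant
#'   region (default 0.7).
#' @param noise_fraction random unmappable reads, as a fraction of
#'   `n_fragment_reads` (default 0.05).
#' @param low_quality_fraction,contains_n_fraction,short_fraction,long_fraction,below_threshold_fraction
#'   planted filter-fodder reads, as fractions of `n_fragment_reads`.
#' @param decoy_count unannotated exact copies of a tRNA gene body planted
#'   in non-tRNA context (each decoy source gets its own anticodon).
#' @param polymorphic_count planted genes flagged as carrying polymorphic
#'   sites (own anticodons; their reads must be removed by the caller).
#' @param pseudo_count,contig_end_count planted pseudogenes and
#'   contig-boundary genes (annotated, never expressed).
#' @param spike_counts 2 x 6 matrix of per-stage spike-in read counts;
#'   defaults differ across stages so normalization factors are
#'   nontrivial.
#' @param read_length_range legal fragment length range (default 25-45 nt).
#' @return a `trf_sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       stage_names = STAGE_NAMES,
                       n_mito_genes = 6L,
                       n_nuclear_anticodons = 14L,
                       n_subtypes_per_anticodon = 2L,
                       n_anticodons_with_subtypes = 2L,
                       n_nuclear_contigs = 4L,
                       body_length_range = c(70L, 73L),
                       anticodon_mature_start = 33L,
                       n_fragment_reads = 10000L,
                       dominant_share = 0.7,
                       noise_fraction = 0.05,
                       low_quality_fraction = 0.005,
                       contains_n_fraction = 0.003,
                       short_fraction = 0.003,
                       long_fraction = 0.003,
                       below_threshold_fraction = 0.003,
                       decoy_count = 1L,
                       polymorphic_count = 1L,
                       pseudo_count = 1L,
                       contig_end_count = 1L,
                       spike_counts = NULL,
                       read_length_range = c(25L, 45L)) {
  if (length(stage_names) != 6L) stop("exactly six stage labels are required")
  if (is.null(spike_counts)) {
    spike_counts <- matrix(c(120L, 80L, 100L, 140L, 90L, 110L,
                             60L, 40L, 50L, 70L, 45L, 55L),
                           nrow = 2L, byrow = TRUE,
                           dimnames = list(c("spike1", "spike2"), stage_names))
  }
  fracs <- c(noise_fraction, low_quality_fraction, contains_n_fraction,
             short_fraction, long_fraction, below_threshold_fraction)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must lie in [0, 1]")
  if (dominant_share <= 0 || dominant_share > 1) {
    stop("dominant_share must lie in (0, 1]")
  }
  structure(list(
    seed = as.integer(seed), stage_names = stage_names,
    n_mito_genes = n_mito_genes,
    n_nuclear_anticodons = n_nuclear_anticodons,
    n_subtypes_per_anticodon = n_subtypes_per_anticodon,
    n_anticodons_with_subtypes = n_anticodons_with_subtypes,
    n_nuclear_contigs = n_nuclear_contigs,
    body_length_range = body_length_range,
    anticodon_mature_start = anticodon_mature_start,
    n_fragment_reads = n_fragment_reads,
    dominant_share = dominant_share,
    noise_fraction = noise_fraction,
    low_quality_fraction = low_quality_fraction,
    contains_n_fraction = contains_n_fraction,
    short_fraction = short_fraction,
    long_fraction = long_fraction,
    below_threshold_fraction = below_threshold_fraction,
    decoy_count = decoy_count, polymorphic_count = polymorphic_count,
    pseudo_count = pseudo_count, contig_end_count = contig_end_count,
    spike_counts = spike_counts,
    read_length_range = read_length_range), class = "trf_sim_config")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a gene body with the anticodon planted so that it sits at mature
# positions [ac_start, ac_start+2]; never ends in CCA (the genome does not
# encode the tail)
make_gene_body <- function(len, anticodon_dna, ac_start) {
  body <- random_dna(len)
  body <- paste0(substr(body, 1L, ac_start - 1L), anticodon_dna,
                 substr(body, ac_start + 3L, len))
  if (substr(body, len - 2L, len) == "CCA") {
    body <- paste0(substr(body, 1L, len - 1L), "G")
  }
  body
}

mutate_base <- function(seqn, pos) {
  old <- substr(seqn, pos, pos)
  new <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
  paste0(substr(seqn, 1L, pos - 1L), new, substr(seqn, pos + 1L, nchar(seqn)))
}

#' Generate a toy genome bundle with planted tRNA genes
#'
#' Deterministically (given the config seed) builds one mitochondrial
#' sequence and several nuclear contigs hosting planted tRNA genes:
#' fragment-bearing mitochondrial genes and nuclear anticodons (the first
#' few with isodecoder subtypes differing outside the anticodon), plus
#' decoy-source genes whose bodies are copied unannotated into another
#' contig, polymorphic-flagged genes, pseudogenes, contig-boundary genes,
#' and one locus scoring higher under the bacterial covariance model (to be
#' rejected by the eukaryotic-score comparison). At least one gene is on
#' the minus strand. Gene bodies never end in CCA; mature sequences are
#' body + "CCA". Two spike-in sequences absent from every contig are drawn.
#'
#' @param config a [sim_config()].
#' @return a `trf_genome_bundle` list with `config`, `genes` (planted gene
#'   table with bodies, mature sequences, roles and scores), `mito_contigs`,
#'   `nuclear_contigs`, `decoys` (intervals of the unannotated copies),
#'   `spikes` (two sequences), `profiles` (per-anticodon dominant region and
#'   trend), `bac_artifact` (the bacterial-model locus).
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "trf_sim_config"))
  set.seed(config$seed)
  pool <- anticodon_pool()
  pool <- pool[sample(nrow(pool)), , drop = FALSE]
  ac_start <- config$anticodon_mature_start
  n_extra <- config$decoy_count + config$polymorphic_count +
    config$pseudo_count + config$contig_end_count + 1L
  need <- config$n_mito_genes + config$n_nuclear_anticodons + n_extra
  if (need > nrow(pool)) stop("anticodon pool too small for requested genes")

  take <- function(n) {
    out <- pool[seq_len(n), , drop = FALSE]
    pool <<- pool[-seq_len(n), , drop = FALSE]
    out
  }
  draw_len <- function() {
    sample(seq(config$body_length_range[1], config$body_length_range[2]), 1L)
  }
  genes <- list()
  add_gene <- function(compartment, isotype, anticodon, role, subtype = "I") {
    len <- draw_len()
    body <- make_gene_body(len, dna_anticodon(anticodon), ac_start)
    genes[[length(genes) + 1L]] <<- list(
      compartment = compartment, isotype = isotype, anticodon = anticodon,
      role = role, subtype = subtype, body = body)
  }
  mito_acs <- take(config$n_mito_genes)
  for (i in seq_len(config$n_mito_genes)) {
    add_gene("mitochondrial", mito_acs$isotype[i], mito_acs$anticodon[i],
             "clean")
  }
  nuc_acs <- take(config$n_nuclear_anticodons)
  for (i in seq_len(config$n_nuclear_anticodons)) {
    add_gene("nuclear", nuc_acs$isotype[i], nuc_acs$anticodon[i], "clean")
    if (i <= config$n_anticodons_with_subtypes &&
        config$n_subtypes_per_anticodon > 1L) {
      # isodecoder subtypes: same body with one substitution outside the
      # anticodon (at mature position 50, inside 3'-anchored spans)
      base <- genes[[length(genes)]]
      for (s in seq_len(config$n_subtypes_per_anticodon - 1L)) {
        sub <- base
        sub$body <- mutate_base(base$body, 50L)
        sub$subtype <- c("II", "III", "IV", "V")[s]
        genes[[length(genes) + 1L]] <- sub
      }
    }
  }
  decoy_src <- character(0)
  if (config$decoy_count > 0L) {
    dacs <- take(config$decoy_count)
    for (i in seq_len(config$decoy_count)) {
      add_gene("nuclear", dacs$isotype[i], dacs$anticodon[i], "decoy_source")
    }
  }
  if (config$polymorphic_count > 0L) {
    pacs <- take(config$polymorphic_count)
    for (i in seq_len(config$polymorphic_count)) {
      add_gene("nuclear", pacs$isotype[i], pacs$anticodon[i], "polymorphic")
    }
  }
  if (config$pseudo_count > 0L) {
    sacs <- take(config$pseudo_count)
    for (i in seq_len(config$pseudo_count)) {
      add_gene("nuclear", sacs$isotype[i], sacs$anticodon[i], "pseudo")
    }
  }
  if (config$contig_end_count > 0L) {
    eacs <- take(config$contig_end_count)
    for (i in seq_len(config$contig_end_count)) {
      add_gene("nuclear", eacs$isotype[i], eacs$anticodon[i], "contig_end")
    }
  }
  gtab <- do.call(rbind, lapply(genes, function(g) {
    data.frame(compartment = g$compartment, isotype = g$isotype,
               anticodon = g$anticodon, role = g$role, subtype = g$subtype,
               body = g$body, stringsAsFactors = FALSE)
  }))
  # every 4th gene goes on the minus strand (at least one is guaranteed for
  # any bundle with >= 4 genes); boundary genes stay on plus for simplicity
  gtab$strand <- ifelse(seq_len(nrow(gtab)) %% 4L == 0L &
                          gtab$role != "contig_end", "-", "+")
  gtab$mature <- paste0(gtab$body, "CCA")
  gtab$gene_id <- NA_character_
  gtab$contig_id <- NA_character_
  gtab$start <- NA_integer_
  gtab$end <- NA_integer_

  # ---- contig assembly ----
  place <- function(rows, contig_name, trailing_gene = NA_integer_) {
    seqs <- character(0)
    pos <- 0L
    margin <- 30L
    seqs <- c(seqs, filler_dna(margin)); pos <- margin
    for (i in rows) {
      spacer <- filler_dna(sample(50:90, 1L))
      seqs <- c(seqs, spacer); pos <- pos + nchar(spacer)
      ins <- if (gtab$strand[i] == "-") revcomp(gtab$body[i]) else gtab$body[i]
      gtab$contig_id[i] <<- contig_name
      gtab$start[i] <<- pos + 1L
      gtab$end[i] <<- pos + nchar(ins)
      seqs <- c(seqs, ins); pos <- pos + nchar(ins)
    }
    if (!is.na(trailing_gene)) {
      spacer <- filler_dna(60L)
      seqs <- c(seqs, spacer); pos <- pos + nchar(spacer)
      i <- trailing_gene
      gtab$contig_id[i] <<- contig_name
      gtab$start[i] <<- pos + 1L
      gtab$end[i] <<- pos + nchar(gtab$body[i])
      # only 2 nt of margin: curation must remove this gene
      seqs <- c(seqs, gtab$body[i], filler_dna(2L))
    } else {
      seqs <- c(seqs, filler_dna(margin))
    }
    paste(seqs, collapse = "")
  }
  mito_rows <- which(gtab$compartment == "mitochondrial")
  mito_contig <- place(mito_rows, "mito")
  nuc_rows <- which(gtab$compartment == "nuclear" & gtab$role != "contig_end")
  edge_rows <- which(gtab$role == "contig_end")
  contig_names <- paste0("contig", seq_len(config$n_nuclear_contigs))
  assign_contig <- rep(contig_names, length.out = length(nuc_rows))
  nuclear_contigs <- setNames(vector("character", length(contig_names)),
                              contig_names)
  for (k in seq_along(contig_names)) {
    rows_k <- nuc_rows[assign_contig == contig_names[k]]
    trailing <- if (k == 1L && length(edge_rows) > 0L) edge_rows[1L] else NA_integer_
    nuclear_contigs[k] <- place(rows_k, contig_names[k], trailing)
  }
  gtab$gene_id <- paste0(gtab$contig_id, ".trna",
                         stats::ave(seq_len(nrow(gtab)), gtab$contig_id,
                                    FUN = seq_along))

  # decoys: exact copies of a source gene body appended (unannotated) to a
  # different contig, inside its interior
  decoys <- data.frame(contig_id = character(), start = integer(),
                       end = integer(), source_gene = character(),
                       stringsAsFactors = FALSE)
  src_rows <- which(gtab$role == "decoy_source")
  for (i in seq_along(src_rows)) {
    r <- src_rows[i]
    target <- setdiff(contig_names, gtab$contig_id[r])[1L]
    body <- gtab$body[r]
    old <- nuclear_contigs[[target]]
    nuclear_contigs[[target]] <- paste0(old, body, filler_dna(30L))
    decoys <- rbind(decoys, data.frame(
      contig_id = target, start = nchar(old) + 1L,
      end = nchar(old) + nchar(body), source_gene = gtab$gene_id[r],
      stringsAsFactors = FALSE))
  }

  # COVE scores: eukaryotic model wins for every planted gene; two genes are
  # absent from the bacterial output (loci found only by the eukaryotic
  # search are retained); one extra locus scores higher under the bacterial
  # model and must be rejected
  gtab$cove_euk <- round(runif(nrow(gtab), 60, 85), 2)
  gtab$cove_bac <- round(gtab$cove_euk - runif(nrow(gtab), 5, 20), 2)
  gtab$in_bac_output <- TRUE
  nuc_all <- which(gtab$compartment == "nuclear")
  gtab$in_bac_output[utils::tail(nuc_all, 2L)] <- FALSE
  bac_artifact <- data.frame(
    contig_id = contig_names[1L], start = 5L, end = 20L, strand = "+",
    isotype = "Und", anticodon = "NNN", cove_euk = 38.5, cove_bac = 47.2,
    stringsAsFactors = FALSE)

  # spike-ins: two distinct sequences occurring nowhere in the bundle
  all_seq <- c(mito_contig, nuclear_contigs, gtab$mature)
  draw_spike <- function() {
    repeat {
      s <- random_dna(30L)
      hit <- any(vapply(all_seq, function(x) grepl(s, x, fixed = TRUE),
                        logical(1)))
      if (!hit) return(s)
    }
  }
  spikes <- c(draw_spike(), draw_spike())
  while (spikes[2] == spikes[1]) spikes[2] <- draw_spike()

  # per-anticodon fragmentation profile: dominant region and stage trend
  frag_rows <- which(gtab$role %in% c("clean", "decoy_source", "polymorphic") &
                       gtab$subtype == "I")
  regions <- REGION_LEVELS[1:5]
  trends <- c("increasing", "decreasing", "egg-enriched", "flat")
  profiles <- data.frame(
    compartment = gtab$compartment[frag_rows],
    isotype = gtab$isotype[frag_rows],
    anticodon = gtab$anticodon[frag_rows],
    dominant_region = regions[(seq_along(frag_rows) - 1L) %% 5L + 1L],
    trend = trends[(seq_along(frag_rows) - 1L) %% 4L + 1L],
    weight = 0.9^(seq_along(frag_rows) - 1L),
    stringsAsFactors = FALSE)

  structure(list(config = config, genes = gtab,
                 mito_contigs = c(mito = mito_contig),
                 nuclear_contigs = nuclear_contigs, decoys = decoys,
                 spikes = spikes, profiles = profiles,
                 bac_artifact = bac_artifact),
            class = "trf_genome_bundle")
}
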