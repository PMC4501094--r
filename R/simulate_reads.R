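# filler sequence that can neither complete a CCA tail after a plus-strand
# gene body (never starts with C) nor a TGG before a minus-strand body
# (never ends with G); keeps accidental flush CCA extensions out of the
# genome so 3'-anchored fragment reads occur genomically nowhere
filler_dna <- function(n) {
  if (n <= 2L) return(strrep("T", n))
  paste0("T", random_dna(n - 2L), "A")
}

stage_weights <- function(trend) {
  w <- switch(trend,
              increasing = 2^(0:5),
              decreasing = 2^(5:0),
              `egg-enriched` = c(0.70, rep(0.06, 5)),
              flat = rep(1, 6),
              stop("unknown trend: ", trend))
  w / sum(w)
}

# draw one element of a vector (safe for length-1 vectors, where sample()
# would treat the single value as a range)
pick1 <- function(v) v[sample.int(length(v), 1L)]

# one fragment span per draw, anchored per region category; geometry assumes
# the anticodon at mature 33-35 (loop 31-37, stem-loop window 26-42)
sample_span <- function(region, L, min_len = 25L, max_len = 45L) {
  switch(region,
         "5' half" = c(1L, pick1(31:37)),
         "5' end" = c(1L, pick1(min_len:30)),
         "3' half" = {
           s <- pick1(max(31L, L - max_len + 1L):37L)
           c(s, L)
         },
         "3' end" = {
           s <- pick1(38L:(L - min_len + 1L))
           c(s, L)
         },
         "AC stem-loop" = {
           len <- pick1(min_len:min(27L, max_len))
           s <- pick1(21L:(48L - len))
           c(s, s + len - 1L)
         },
         stop("unknown region: ", region))
}

#' Simulate six stage-resolved small RNA FASTQ libraries with known truth
#'
#' Draws fragment reads as exact substrings of the planted mature tRNAs
#' (CCA tail included for 3'-anchored classes), according to each
#' anticodon's dominant-region profile and developmental trend; adds
#' spike-in reads at the configured per-stage counts, random noise reads
#' matching nothing, and planted filter fodder: low-quality reads (mean
#' Phred < 20), N-containing reads, too-short/too-long reads, and reads
#' sequenced fewer than five times in total. Writes one Phred+33 FASTQ per
#' stage plus a truth-table TSV and a run manifest.
#'
#' Each truth row records the intended fate of a read sequence in a stage:
#' `called` (expected in the final fragment calls), `polymorphic` or
#' `ambiguous_decoy` (expected removals by the ambiguity filters),
#' `below_threshold`, `low_quality`, `contains_n`, `too_short`, `too_long`
#' (expected removals by the read filters), `noise` and `spike` (expected
#' to stay unassigned). Fragment reads whose sampled pooled count falls
#' below the abundance threshold are recorded as `below_threshold`, so the
#' truth table is exact by construction.
#'
#' @param bundle a `trf_genome_bundle` from [generate_genome()].
#' @param dir output directory (created if needed).
#' @param min_count abundance threshold used when recording intended fates
#'   (default 5, the pipeline default).
#' @return list with `fastq` (named vector of the six FASTQ paths),
#'   `truth` (data.frame: sequence, stage, count, compartment, isotype,
#'   anticodon, parents, region, fate), `truth_path`, `manifest_path`.
#' @export
simulate_reads <- function(bundle, dir, min_count = 5L) {
  stopifnot(inherits(bundle, "trf_genome_bundle"))
  config <- bundle$config
  set.seed(config$seed + 1L)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stage_names
  lr <- config$read_length_range
  gtab <- bundle$genes
  genome_text <- c(bundle$mito_contigs, bundle$nuclear_contigs,
                   revcomp(c(bundle$mito_contigs, bundle$nuclear_contigs)),
                   gtab$mature)

  rows <- list()
  add_rows <- function(df) rows[[length(rows) + 1L]] <<- df

  ## ---- fragment reads ----
  prof <- bundle$profiles
  if (is.null(prof$dominant_share)) prof$dominant_share <- config$dominant_share
  budgets <- round(config$n_fragment_reads * prof$weight / sum(prof$weight))
  for (p in seq_len(nrow(prof))) {
    grp <- gtab[gtab$anticodon == prof$anticodon[p] &
                  gtab$compartment == prof$compartment[p], , drop = FALSE]
    dom <- prof$dominant_region[p]
    share <- prof$dominant_share[p]
    minor <- setdiff(REGION_LEVELS[1:5], dom)
    cat_share <- c(setNames(share, dom),
                   setNames(rep((1 - share) / 4, 4), minor))
    cat_share <- cat_share[cat_share > 0]
    # fixed per-anticodon variant set: 3 variants in the dominant region,
    # one per minor region, drawn per subtype
    cells <- list()
    for (region in names(cat_share)) {
      nv <- if (region == dom) 3L else 1L
      vw <- if (nv == 3L) c(0.6, 0.25, 0.15) else 1
      for (g in seq_len(nrow(grp))) {
        L <- nchar(grp$mature[g])
        for (v in seq_len(nv)) {
          sp <- sample_span(region, L, lr[1], lr[2])
          cells[[length(cells) + 1L]] <- data.frame(
            sequence = substr(grp$mature[g], sp[1], sp[2]), region = region,
            prob = cat_share[[region]] * vw[v] / nrow(grp),
            stringsAsFactors = FALSE)
        }
      }
    }
    cells <- do.call(rbind, cells)
    # identical sequences across subtypes collapse into one cell
    agg <- tapply(cells$prob, cells$sequence, sum)
    region_of <- cells$region[match(names(agg), cells$sequence)]
    sw <- stage_weights(prof$trend[p])
    for (s in seq_along(stages)) {
      n_s <- round(budgets[p] * sw[s])
      if (n_s == 0L) next
      counts <- as.integer(rmultinom(1L, n_s, as.numeric(agg)))
      keep <- counts > 0L
      if (!any(keep)) next
      add_rows(data.frame(
        sequence = names(agg)[keep], stage = stages[s], count = counts[keep],
        compartment = prof$compartment[p], isotype = prof$isotype[p],
        anticodon = prof$anticodon[p], region = region_of[keep],
        fate = "fragment", qual = "good", stringsAsFactors = FALSE))
    }
  }

  ## ---- spikes ----
  for (k in 1:2) {
    add_rows(data.frame(sequence = bundle$spikes[k], stage = stages,
                        count = as.integer(config$spike_counts[k, ]),
                        compartment = NA, isotype = NA, anticodon = NA,
                        region = NA, fate = "spike", qual = "good",
                        stringsAsFactors = FALSE))
  }

  ## ---- noise and filter fodder ----
  draw_unmapped <- function(len, with_n = FALSE) {
    repeat {
      s <- random_dna(len)
      if (with_n) {
        pos <- sample(len, 1L)
        s <- paste0(substr(s, 1, pos - 1L), "N", substr(s, pos + 1L, len))
      }
      if (!any(vapply(genome_text, function(x) grepl(s, x, fixed = TRUE),
                      logical(1)))) {
        return(s)
      }
    }
  }
  spread_stages <- function(count) {
    as.integer(rmultinom(1L, count, rep(1, length(stages))))
  }
  add_artifacts <- function(total, fate, len_fun, count_fun, qual = "good",
                            with_n = FALSE, min_need = 1L) {
    spent <- 0L
    while (spent < total) {
      rem <- total - spent
      cnt <- count_fun()
      if (cnt > rem) {
        # the remainder must still be a viable read of this class (e.g. a
        # planted too-short read below the abundance threshold would be
        # rejected by the wrong filter); drop a too-small remainder
        if (rem < min_need) break
        cnt <- rem
      }
      s <- draw_unmapped(len_fun(), with_n)
      per_stage <- spread_stages(cnt)
      keep <- per_stage > 0L
      add_rows(data.frame(sequence = s, stage = stages[keep],
                          count = per_stage[keep], compartment = NA,
                          isotype = NA, anticodon = NA, region = NA,
                          fate = fate, qual = qual, stringsAsFactors = FALSE))
      spent <- spent + cnt
    }
  }
  n_of <- function(f) as.integer(round(f * config$n_fragment_reads))
  len_in_range <- function() sample(lr[1]:lr[2], 1L)
  add_artifacts(n_of(config$noise_fraction), "noise", len_in_range,
                function() sample(5:9, 1L), min_need = min_count)
  add_artifacts(n_of(config$low_quality_fraction), "low_quality",
                len_in_range, function() sample(3:8, 1L), qual = "low")
  add_artifacts(n_of(config$contains_n_fraction), "contains_n", len_in_range,
                function() sample(3:8, 1L), with_n = TRUE)
  add_artifacts(n_of(config$short_fraction), "too_short",
                function() sample(18:24, 1L), function() sample(5:8, 1L),
                min_need = min_count)
  add_artifacts(n_of(config$long_fraction), "too_long",
                function() sample(46:55, 1L), function() sample(5:8, 1L),
                min_need = min_count)
  add_artifacts(n_of(config$below_threshold_fraction), "below_threshold",
                len_in_range, function() sample(1:4, 1L))

  reads <- do.call(rbind, rows)

  ## ---- intended fates for fragment reads ----
  frag_seqs <- unique(reads$sequence[reads$fate == "fragment"])
  decoy_bodies <- if (nrow(bundle$decoys) > 0L) {
    vapply(seq_len(nrow(bundle$decoys)), function(i) {
      substr(bundle$nuclear_contigs[[bundle$decoys$contig_id[i]]],
             bundle$decoys$start[i], bundle$decoys$end[i])
    }, character(1))
  } else {
    character(0)
  }
  pooled <- tapply(reads$count[reads$fate == "fragment"],
                   reads$sequence[reads$fate == "fragment"], sum)
  frag_info <- lapply(frag_seqs, function(s) {
    parent_idx <- which(vapply(gtab$mature, grepl, logical(1), pattern = s,
                               fixed = TRUE, USE.NAMES = FALSE))
    # the abundance filter runs before mapping, so a sub-threshold read is
    # lost there whatever its parents would have implied
    fate <- if (pooled[[s]] < min_count) {
      "below_threshold"
    } else if (any(gtab$role[parent_idx] == "polymorphic")) {
      "polymorphic"
    } else if (length(decoy_bodies) > 0L &&
               any(vapply(decoy_bodies, grepl, logical(1), pattern = s,
                          fixed = TRUE, USE.NAMES = FALSE))) {
      "ambiguous_decoy"
    } else {
      "called"
    }
    list(parents = paste(sort(gtab$gene_id[parent_idx]), collapse = ","),
         fate = fate)
  })
  names(frag_info) <- frag_seqs
  is_frag <- reads$fate == "fragment"
  reads$parents <- NA_character_
  reads$parents[is_frag] <- vapply(frag_info[reads$sequence[is_frag]],
                                   `[[`, "", "parents")
  reads$fate[is_frag] <- vapply(frag_info[reads$sequence[is_frag]],
                                `[[`, "", "fate")

  ## ---- FASTQ output ----
  fastq <- setNames(file.path(dir, paste0("reads_", stages, ".fastq")), stages)
  for (s in stages) {
    sub <- reads[reads$stage == s, , drop = FALSE]
    seqs <- rep(sub$sequence, sub$count)
    quals <- rep(ifelse(sub$qual == "low", "0", "I"), sub$count)
    quals <- strrep(quals, nchar(seqs))
    dna <- DNAStringSet(seqs)
    names(dna) <- sprintf("r_%s_%06d", s, seq_along(dna))
    writeXStringSet(dna, fastq[[s]], format = "fastq",
                    qualities = BStringSet(quals))
  }

  truth <- reads[, c("sequence", "stage", "count", "compartment", "isotype",
                     "anticodon", "parents", "region", "fate")]
  rownames(truth) <- NULL
  truth_path <- file.path(dir, "truth_table.tsv")
  write.table(truth, truth_path, sep = "\t", quote = FALSE, row.names = FALSE)
  manifest_path <- file.path(dir, "sim_manifest.yaml")
  yaml::write_yaml(list(seed = config$seed, stages = as.list(stages),
                        n_fragment_reads = config$n_fragment_reads,
                        generator = "trfscape synthetic bundle"),
                   manifest_path)
  list(fastq = fastq, truth = truth, truth_path = truth_path,
       manifest_path = manifest_path)
}

#' Write a genome bundle to FASTA and annotation files
#'
#' Writes the mitochondrial and nuclear genome FASTAs, tRNAscan-SE-style
#' tabular annotation files (mitochondrial/organellar; nuclear eukaryotic
#' and nuclear bacterial search outputs, with their respective COVE
#' scores), and the spike-in FASTA.
#'
#' @param bundle a `trf_genome_bundle`.
#' @param dir output directory.
#' @return named character vector of the written paths.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gtab <- bundle$genes
  paths <- c(mito_fasta = file.path(dir, "genome_mito.fa"),
             nuclear_fasta = file.path(dir, "genome_nuclear.fa"),
             mito_annot = file.path(dir, "trnascan_mito.tsv"),
             euk_annot = file.path(dir, "trnascan_nuclear_euk.tsv"),
             bac_annot = file.path(dir, "trnascan_nuclear_bac.tsv"),
             spikes = file.path(dir, "spikes.fa"))
  writeXStringSet(DNAStringSet(bundle$mito_contigs), paths[["mito_fasta"]])
  writeXStringSet(DNAStringSet(bundle$nuclear_contigs),
                  paths[["nuclear_fasta"]])
  writeXStringSet(DNAStringSet(setNames(bundle$spikes,
                                        c("spike1", "spike2"))),
                  paths[["spikes"]])

  scan_row <- function(contig, num, start, end, strand, isotype, anticodon,
                       score, note = "") {
    b <- if (strand == "-") c(end, start) else c(start, end)
    paste(contig, num, b[1], b[2], isotype, dna_anticodon(anticodon),
          0L, 0L, format(score, nsmall = 2), note, sep = "\t")
  }
  header <- c(paste("Sequence", "tRNA", "Bounds", "", "tRNA", "Anti",
                    "Intron", "Bounds", "Cove", "Note", sep = "\t"),
              paste("Name", "#", "Begin", "End", "Type", "Codon", "Begin",
                    "End", "Score", "", sep = "\t"),
              paste(rep("--------", 10), collapse = "\t"))
  write_scan <- function(rows, path) {
    writeLines(c(header, rows), path)
  }
  trna_num <- function(idx) {
    stats::ave(seq_along(idx), gtab$contig_id[idx], FUN = seq_along)
  }
  note_of <- function(i) {
    switch(gtab$role[i], polymorphic = "polymorphic site(s)",
           pseudo = "pseudo", "")
  }
  mito_idx <- which(gtab$compartment == "mitochondrial")
  write_scan(vapply(seq_along(mito_idx), function(k) {
    i <- mito_idx[k]
    scan_row(gtab$contig_id[i], k, gtab$start[i], gtab$end[i], gtab$strand[i],
             gtab$isotype[i], gtab$anticodon[i], gtab$cove_euk[i], note_of(i))
  }, character(1)), paths[["mito_annot"]])

  nuc_idx <- which(gtab$compartment == "nuclear")
  nums <- stats::ave(seq_along(nuc_idx), gtab$contig_id[nuc_idx],
                     FUN = seq_along)
  euk_rows <- vapply(seq_along(nuc_idx), function(k) {
    i <- nuc_idx[k]
    scan_row(gtab$contig_id[i], nums[k], gtab$start[i], gtab$end[i],
             gtab$strand[i], gtab$isotype[i], gtab$anticodon[i],
             gtab$cove_euk[i], note_of(i))
  }, character(1))
  ba <- bundle$bac_artifact
  euk_rows <- c(euk_rows, scan_row(ba$contig_id, 900L, ba$start, ba$end,
                                   ba$strand, ba$isotype, ba$anticodon,
                                   ba$cove_euk))
  write_scan(euk_rows, paths[["euk_annot"]])

  bac_keep <- which(gtab$in_bac_output[nuc_idx])
  bac_rows <- vapply(bac_keep, function(k) {
    i <- nuc_idx[k]
    scan_row(gtab$contig_id[i], nums[k], gtab$start[i], gtab$end[i],
             gtab$strand[i], gtab$isotype[i], gtab$anticodon[i],
             gtab$cove_bac[i], note_of(i))
  }, character(1))
  bac_rows <- c(bac_rows, scan_row(ba$contig_id, 900L, ba$start, ba$end,
                                   ba$strand, ba$isotype, ba$anticodon,
                                   ba$cove_bac))
  write_scan(bac_rows, paths[["bac_annot"]])
  paths
}

#' Build calling catalogs directly from a genome bundle
#'
#' Convenience path from a `trf_genome_bundle` to the catalogs
#' [call_trfs()] consumes, without going through annotation files: the
#' planted gene table is converted to the parsed-annotation layout
#' (pseudo/polymorphic roles become flags), curated, and assembled per
#' compartment.
#'
#' @param bundle a `trf_genome_bundle`.
#' @param edge_margin,anticodon_center,stem_width see [curate_genes()],
#'   [build_catalog()].
#' @return list with `mitochondrial` and `nuclear` catalogs.
#' @export
bundle_catalogs <- function(bundle, edge_margin = 5L, anticodon_center = 34L,
                            stem_width = 5L) {
  gtab <- bundle$genes
  genes <- data.frame(
    gene_id = gtab$gene_id, contig_id = gtab$contig_id, start = gtab$start,
    end = gtab$end, strand = gtab$strand, isotype = gtab$isotype,
    anticodon = gtab$anticodon, intron_start = NA_integer_,
    intron_end = NA_integer_, cove_score = gtab$cove_euk,
    pseudo = gtab$role == "pseudo", polymorphic = gtab$role == "polymorphic",
    stringsAsFactors = FALSE)
  one <- function(comp, contigs) {
    g <- genes[gtab$compartment == comp, , drop = FALSE]
    cur <- curate_genes(g, nchar(contigs), edge_margin)
    build_catalog(g, cur, contigs, anticodon_center, stem_width)
  }
  list(mitochondrial = one("mitochondrial", bundle$mito_contigs),
       nuclear = one("nuclear", bundle$nuclear_contigs))
}

#' Expected per-anticodon outcome from a truth table
#'
#' Bookkeeping oracle over the simulator's truth table: pooled totals of
#' `called` reads per compartment and anticodon, the expected main region
#' label, and expected per-stage totals.
#'
#' @param truth truth data.frame from [simulate_reads()].
#' @param f main-region reporting fraction (default 0.25).
#' @return data.frame with `compartment`, `isotype`, `anticodon`, `total`,
#'   `main_region`, and one expected-total column per stage.
#' @export
truth_summary <- function(truth, f = 0.25) {
  called <- truth[truth$fate == "called", , drop = FALSE]
  if (nrow(called) == 0L) {
    return(data.frame(compartment = character(), isotype = character(),
                      anticodon = character(), total = integer(),
                      main_region = character(), stringsAsFactors = FALSE))
  }
  key <- paste(called$compartment, called$isotype, called$anticodon,
               sep = "\r")
  stages <- unique(truth$stage)
  out <- lapply(split(called, key), function(g) {
    per_seq <- tapply(g$count, g$sequence, sum)
    reg <- g$region[match(names(per_seq), g$sequence)]
    stage_tot <- vapply(stages, function(s) {
      sum(g$count[g$stage == s])
    }, numeric(1))
    cbind(data.frame(compartment = g$compartment[1], isotype = g$isotype[1],
                     anticodon = g$anticodon[1],
                     total = as.integer(sum(g$count)),
                     main_region = main_region(reg, as.numeric(per_seq), f),
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(stage_tot), col.names = stages))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$compartment, -out$total, out$anticodon), , drop = FALSE]
}
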