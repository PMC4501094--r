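#' Build a pipeline run configuration
#'
#' One configuration object drives the whole pipeline: input paths, every
#' threshold of the filtering/mapping/classification/profiling stages, and
#' the output directory. It round-trips through YAML unchanged (see
#' [write_run_config()]).
#'
#' @param fastq named character vector of six FASTQ paths, one per stage,
#'   in stage order (egg first).
#' @param mito_fasta,nuclear_fasta genome FASTA paths (`NA` to skip a
#'   compartment).
#' @param mito_annot,euk_annot,bac_annot tRNAscan-SE tabular annotation
#'   paths: organellar search for the mitochondrial genome, eukaryotic and
#'   bacterial searches for the nuclear genome (`bac_annot` may be `NA`;
#'   the eukaryotic-vs-bacterial score comparison is then skipped).
#' @param spikes_fasta FASTA with the two spike-in sequences.
#' @param out_dir output directory.
#' @param min_quality,quality_mode,min_count,per_stage,min_len,max_len read
#'   filter thresholds (see [filter_reads()]).
#' @param edge_margin contig-boundary margin for gene curation (nt).
#' @param anticodon_center,stem_width mature-tRNA geometry (see
#'   [mature_sequence()], [region_map()]).
#' @param t5,t3,w classifier tolerances (see [classify_region()]).
#' @param main_region_f main-region reporting fraction (see
#'   [main_region()]).
#' @param cca_partial,poly_mode,footnote_a_mito,footnote_c_mito mapping
#'   options (see [call_trfs()]).
#' @param anchor spike normalization anchor (see
#'   [normalization_factors()]).
#' @param top_k variants per anticodon for the heatmap (default 3).
#' @param seed RNG seed recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return a `trf_run_config` list.
#' @export
run_config <- function(fastq, mito_fasta = NA, nuclear_fasta = NA,
                       mito_annot = NA, euk_annot = NA, bac_annot = NA,
                       spikes_fasta = NA, out_dir = tempfile("trfscape_run"),
                       min_quality = 20, quality_mode = "mean",
                       min_count = 5L, per_stage = FALSE, min_len = 25L,
                       max_len = 45L, edge_margin = 5L,
                       anticodon_center = 34L, stem_width = 5L, t5 = 2L,
                       t3 = 2L, w = 5L, main_region_f = 0.25,
                       cca_partial = FALSE, poly_mode = "any",
                       footnote_a_mito = FALSE, footnote_c_mito = TRUE,
                       anchor = "geometric", top_k = 3L, seed = 1L) {
  if (length(fastq) != 6L) stop("six stage FASTQ paths are required")
  if (is.null(names(fastq))) names(fastq) <- STAGE_NAMES
  structure(list(fastq = fastq, mito_fasta = mito_fasta,
                 nuclear_fasta = nuclear_fasta, mito_annot = mito_annot,
                 euk_annot = euk_annot, bac_annot = bac_annot,
                 spikes_fasta = spikes_fasta, out_dir = out_dir,
                 min_quality = min_quality, quality_mode = quality_mode,
                 min_count = min_count, per_stage = per_stage,
                 min_len = min_len, max_len = max_len,
                 edge_margin = edge_margin,
                 anticodon_center = anticodon_center,
                 stem_width = stem_width, t5 = t5, t3 = t3, w = w,
                 main_region_f = main_region_f, cca_partial = cca_partial,
                 poly_mode = poly_mode, footnote_a_mito = footnote_a_mito,
                 footnote_c_mito = footnote_c_mito, anchor = anchor,
                 top_k = top_k, seed = seed),
            class = "trf_run_config")
}

#' Write / read a run configuration as YAML
#'
#' @param config a `trf_run_config`.
#' @param path YAML path.
#' @return `path` (writer) or the restored `trf_run_config` (reader).
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  x$fastq <- as.list(x$fastq)
  yaml::write_yaml(x, path)
  path
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$fastq <- unlist(x$fastq)
  do.call(run_config, x)
}

check_paths <- function(config) {
  paths <- c(config$fastq,
             mito_fasta = config$mito_fasta,
             nuclear_fasta = config$nuclear_fasta,
             mito_annot = config$mito_annot, euk_annot = config$euk_annot,
             bac_annot = config$bac_annot,
             spikes_fasta = config$spikes_fasta)
  paths <- paths[!is.na(paths)]
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0L) {
    stop("input path does not exist: ", paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}

load_compartment <- function(fasta, annot, bac_annot = NA,
                             edge_margin = 5L, anticodon_center = 34L,
                             stem_width = 5L) {
  contigs <- as.character(readDNAStringSet(fasta))
  names(contigs) <- sub("\\s.*$", "", names(contigs))
  genes <- parse_trnascan(annot)
  if (!is.na(bac_annot)) {
    genes <- select_eukaryotic(genes, parse_trnascan(bac_annot))
  }
  curated <- curate_genes(genes, nchar(contigs), edge_margin)
  build_catalog(genes, curated, contigs, anticodon_center, stem_width)
}

#' Per-anticodon summary with main regions
#'
#' The layout of the published-style summary: per compartment and
#' anticodon, the pooled fragment read total and the main region label(s).
#'
#' @param trfs classified fragment table (from [classify_trfs()]).
#' @param f main-region fraction (see [main_region()]).
#' @return data.frame `compartment`, `isotype`, `anticodon`, `total`,
#'   `main_region`, sorted by compartment then total descending.
#' @export
summary_table <- function(trfs, f = 0.25) {
  s <- summarize_anticodons(trfs)
  if (nrow(s) == 0L) {
    s$main_region <- character(0)
    return(s)
  }
  s$main_region <- vapply(seq_len(nrow(s)), function(i) {
    g <- trfs[trfs$compartment == s$compartment[i] &
                trfs$anticodon == s$anticodon[i] &
                trfs$isotype == s$isotype[i], , drop = FALSE]
    main_region(g$region, g$pooled_count, f)
  }, character(1))
  s
}

#' Render the two-section summary report
#'
#' Mitochondrial then nuclear fragments, rows sorted by total read count
#' descending, columns isotype (anticodon) / total / main region, with a
#' per-compartment total in each section header.
#'
#' @param tab summary table from [summary_table()].
#' @return character vector of report lines.
#' @export
summary_report <- function(tab) {
  lines <- character(0)
  for (comp in c("mitochondrial", "nuclear")) {
    sec <- tab[tab$compartment == comp, , drop = FALSE]
    lines <- c(lines, sprintf("%s tRF (total reads: %d)",
                              if (comp == "mitochondrial") "Mitochondrial"
                              else "Nuclear",
                              sum(sec$total)))
    if (nrow(sec) > 0L) {
      lines <- c(lines, sprintf("%s (%s)\t%d\t%s", sec$isotype,
                                sec$anticodon, sec$total, sec$main_region))
    }
    lines <- c(lines, "")
  }
  lines
}

#' Run the full fragment-calling pipeline
#'
#' Chains catalog construction, read filtering, fragment calling, region
#' classification, and expression profiling, writing every result table to
#' `config$out_dir` together with a manifest (package version, seed,
#' config hash). Any stage failure aborts with the stage name and cause.
#'
#' @param config a `trf_run_config` (see [run_config()]).
#' @return invisibly, a list with `catalogs`, `filtered`, `calls`, `trfs`
#'   (classified), `summary`, `factors`, `spike_counts`, `heatmap`,
#'   `clustering`, `trends`, `coverage`, and `paths` (written files).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "trf_run_config"))
  stage <- "configuration"
  run <- function(name, expr) {
    stage <<- name
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  run("configuration", check_paths(config))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  mito <- run("catalog", if (!is.na(config$mito_fasta)) {
    load_compartment(config$mito_fasta, config$mito_annot, NA,
                     config$edge_margin, config$anticodon_center,
                     config$stem_width)
  })
  nuclear <- run("catalog", if (!is.na(config$nuclear_fasta)) {
    load_compartment(config$nuclear_fasta, config$euk_annot,
                     config$bac_annot, config$edge_margin,
                     config$anticodon_center, config$stem_width)
  })

  filtered <- run("filter", filter_reads(
    config$fastq, config$min_quality, config$quality_mode,
    config$min_count, config$per_stage, config$min_len, config$max_len))

  spikes <- run("normalize", {
    s <- as.character(readDNAStringSet(config$spikes_fasta))
    count_spikes(filtered$all_unique, s)
  })
  factors <- run("normalize",
                 normalization_factors(spikes, config$anchor))

  calls <- run("call", call_trfs(
    filtered$unique_reads, mito, nuclear, config$cca_partial,
    config$footnote_a_mito, config$footnote_c_mito, config$poly_mode))

  matures <- rbind(if (!is.null(mito)) mito$matures,
                   if (!is.null(nuclear)) nuclear$matures)
  trfs <- run("classify", classify_trfs(calls$trfs, matures, config$t5,
                                        config$t3, config$w))
  stab <- run("classify", summary_table(trfs, config$main_region_f))

  profile <- run("profile", {
    groups <- split(trfs, paste(trfs$compartment, trfs$isotype,
                                trfs$anticodon, sep = "\r"))
    tops <- lapply(groups, top_variants, k = config$top_k)
    tv <- if (length(tops) > 0L) do.call(rbind, tops) else trfs
    rownames(tv) <- NULL
    labels <- if (nrow(tv) > 0L) {
      stats::ave(seq_len(nrow(tv)),
                 paste(tv$compartment, tv$anticodon), FUN = seq_along)
    } else {
      integer(0)
    }
    hm <- heatmap_matrix(tv, factors,
                         row_names = sprintf("%s(%s)_%d", tv$isotype,
                                             tv$anticodon, labels))
    cl <- cluster_rows(hm)
    trends <- if (nrow(tv) > 0L) {
      norm <- sweep(as.matrix(tv[, names(factors), drop = FALSE]), 2L,
                    unlist(factors), `*`)
      vapply(seq_len(nrow(tv)), function(i) expression_trend(norm[i, ]),
             character(1))
    } else {
      character(0)
    }
    ref_gene <- vapply(strsplit(trfs$parents, ",", fixed = TRUE), `[`, "",
                       1L)
    cov <- lapply(split(seq_len(nrow(trfs)), ref_gene), function(idx) {
      g <- trfs[idx, , drop = FALSE]
      L <- matures$length[matures$gene_id == ref_gene[idx[1]]][1]
      positional_coverage(g, L, factors)
    })
    list(top_variants = tv, heatmap = hm, clustering = cl, trends = trends,
         coverage = cov)
  })

  paths <- run("report", {
    out <- config$out_dir
    p <- c(unique_reads = file.path(out, "unique_reads.tsv"),
           filter_report = file.path(out, "filter_report.tsv"),
           trf_table = file.path(out, "trf_table.tsv"),
           anticodon_summary = file.path(out, "anticodon_summary.tsv"),
           heatmap = file.path(out, "heatmap_matrix.tsv"),
           coverage = file.path(out, "coverage.tsv"),
           trends = file.path(out, "trends.tsv"),
           report = file.path(out, "summary_report.txt"),
           manifest = file.path(out, "manifest.yaml"))
    wt <- function(x, f) write.table(x, f, sep = "\t", quote = FALSE,
                                     row.names = FALSE)
    wt(filtered$unique_reads, p[["unique_reads"]])
    wt(filtered$report, p[["filter_report"]])
    wt(trfs, p[["trf_table"]])
    wt(stab, p[["anticodon_summary"]])
    hm_df <- data.frame(variant = rownames(profile$heatmap),
                        profile$heatmap, check.names = FALSE)
    wt(hm_df, p[["heatmap"]])
    cov_df <- do.call(rbind, lapply(names(profile$coverage), function(g) {
      m <- profile$coverage[[g]]
      data.frame(gene_id = g, position = seq_len(nrow(m)), m,
                 check.names = FALSE)
    }))
    if (is.null(cov_df)) {
      cov_df <- data.frame(gene_id = character(), position = integer())
    }
    wt(cov_df, p[["coverage"]])
    tr_df <- data.frame(variant = rownames(profile$heatmap),
                        sequence = profile$top_variants$sequence,
                        anticodon = profile$top_variants$anticodon,
                        trend = profile$trends)
    wt(tr_df, p[["trends"]])
    writeLines(summary_report(stab), p[["report"]])
    if (!is.null(profile$clustering$newick)) {
      nwk <- file.path(out, "dendrogram.nwk")
      writeLines(profile$clustering$newick, nwk)
      p <- c(p, dendrogram = nwk)
    }
    cfg_path <- file.path(out, "run_config.yaml")
    write_run_config(config, cfg_path)
    yaml::write_yaml(list(
      package = "trfscape",
      version = as.character(utils::packageVersion("trfscape")),
      seed = config$seed,
      config_hash = unname(tools::md5sum(cfg_path))), p[["manifest"]])
    c(p, run_config = cfg_path)
  })

  invisible(list(catalogs = list(mitochondrial = mito, nuclear = nuclear),
                 filtered = filtered, calls = calls, trfs = trfs,
                 summary = stab, factors = factors, spike_counts = spikes,
                 heatmap = profile$heatmap,
                 top_variants = profile$top_variants,
                 clustering = profile$clustering, trends = profile$trends,
                 coverage = profile$coverage, paths = paths))
}
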