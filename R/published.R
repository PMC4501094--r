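#' Published tRF deep-sequencing summary for *Triops cancriformis*
#'
#' The published per-anticodon summary of tRNA-derived fragments detected
#' across six developmental stages of the tadpole shrimp *Triops
#' cancriformis*: the 16 mitochondrial anticodon rows and the 16 most
#' abundant nuclear anticodon rows, each with its pooled read total and
#' main-region label, plus the applied-ambiguity-filter notes (a: removed
#' reads also mapping to non-tRNA genomic regions; b: removed reads mapping
#' to tRNA genes with polymorphic sites; c: removed reads mapping to tRNA
#' genes with several different anticodons). Bundled so that the internal
#' arithmetic of the published analysis (compartment totals, fold ratio,
#' per-anticodon shares, region tallies) can be recomputed.
#'
#' @return data.frame with `compartment`, `isotype`, `anticodon`, `total`,
#'   `main_region`, `notes`.
#' @export
published_trf_summary <- function() {
  f <- system.file("extdata", "published_trf_summary.tsv",
                   package = "trfscape", mustWork = TRUE)
  read.delim(f, stringsAsFactors = FALSE, na.strings = NULL)
}

#' Published headline figures of the same analysis
#'
#' Overall printed quantities accompanying [published_trf_summary()]: raw
#' and unique read counts, the mitochondrial and nuclear fragment read
#' totals, the nuclear-to-mitochondrial fold ratio, the shares of the two
#' dominant glycine fragments, and anticodon tallies.
#'
#' @return named numeric vector.
#' @export
published_totals <- function() {
  f <- system.file("extdata", "published_totals.tsv", package = "trfscape",
                   mustWork = TRUE)
  x <- read.delim(f, stringsAsFactors = FALSE)
  setNames(x$value, x$quantity)
}
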