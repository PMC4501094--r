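#' @keywords internal
"_PACKAGE"

#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet
#'   reverseComplement BStringSet
#' @importFrom stats cor hclust as.dist rmultinom runif setNames
#' @importFrom utils read.delim write.table head
NULL

STAGE_NAMES <- c("egg", "L1", "L2", "L3", "L4", "adult")

REGION_LEVELS <- c("5' half", "5' end", "3' half", "3' end", "AC stem-loop", "other")

# reverse complement of a plain character vector (DNA alphabet, may contain N)
revcomp <- function(x) {
  as.character(reverseComplement(DNAStringSet(x)))
}

rna_anticodon <- function(x) chartr("Tt", "Uu", toupper(x))
dna_anticodon <- function(x) chartr("Uu", "Tt", toupper(x))

#' Find all exact occurrences of a pattern in a set of sequences
#'
#' Exact substring search (no mismatches, no gaps) of one read against a
#' character vector of subject sequences. Used for both mature-tRNA matching
#' and genome-wide occurrence scans.
#'
#' @param pattern single nucleotide string.
#' @param subjects named character vector of subject sequences.
#' @return data.frame with columns `subject`, `start`, `end` (1-based
#'   inclusive), one row per occurrence; zero rows when the pattern is absent.
#' @keywords internal
find_occurrences <- function(pattern, subjects) {
  if (length(subjects) == 0L || nchar(pattern) == 0L) {
    return(data.frame(subject = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  n <- nchar(pattern)
  hits <- lapply(seq_along(subjects), function(i) {
    m <- gregexpr(pattern, subjects[[i]], fixed = TRUE)[[1]]
    if (m[1] == -1L) return(NULL)
    data.frame(subject = names(subjects)[i], start = as.integer(m),
               end = as.integer(m) + n - 1L, stringsAsFactors = FALSE)
  })
  hits <- hits[!vapply(hits, is.null, logical(1))]
  if (length(hits) == 0L) {
    return(data.frame(subject = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, hits)
}

# deterministic stage-count matrix helper: ensures integer matrix with the
# canonical stage columns
as_stage_matrix <- function(x, stages = STAGE_NAMES) {
  m <- as.matrix(x)
  stopifnot(ncol(m) == length(stages))
  colnames(m) <- stages
  storage.mode(m) <- "integer"
  m
}

geometric_mean <- function(x) exp(mean(log(x)))

# uncentered (cosine) correlation between rows of a matrix, the default
# similarity of the Cluster 3.0 program
uncentered_correlation <- function(m) {
  norms <- sqrt(rowSums(m^2))
  norms[norms == 0] <- 1
  mn <- m / norms
  tcrossprod(mn)
}
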