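## Substrate k-mer diversity and motif-free transcript scanning.
##
## The k-mer saturation of a substrate pool bounds which cleavage motifs
## the assay can in principle detect: a motif absent from the substrates
## can never produce a coverage step.  Counting is forward-strand only --
## the enzymes act on the single-stranded RNA as synthesized.

#' k-mer saturation of a substrate set
#'
#' Counts every overlapping k-mer of every sequence (forward strand only)
#' and reports how many of the 4^k possible words are observed. The
#' percentage is carried at full precision; `percent_display` rounds to
#' one decimal for reporting.
#'
#' @param refs a [reference_set()].
#' @param k word length (>= 1; at least one sequence must reach length k).
#' @param occurrences also return the k-mer-by-sequence occurrence matrix
#'   of all observed k-mers.
#' @return a `kmer_coverage_report` list with `k`, `distinct_observed`,
#'   `possible`, `percent`, `percent_display` and (optionally)
#'   `per_sequence_counts`.
#' @export
kmer_coverage <- function(refs, k, occurrences = FALSE) {
  stopifnot(inherits(refs, "reference_set"), k >= 1L)
  k <- as.integer(k)
  if (all(nchar(refs$seqs) < k)) {
    stop("k = ", k, " is longer than every sequence in the set")
  }
  set <- Biostrings::DNAStringSet(canonical_dna(refs$seqs))
  counts <- Biostrings::oligonucleotideFrequency(set, width = k)
  total_per_kmer <- colSums(counts)
  distinct <- sum(total_per_kmer > 0L)
  possible <- 4^k
  percent <- 100 * distinct / possible
  out <- list(k = k, distinct_observed = distinct, possible = possible,
              percent = percent, percent_display = round(percent, 1))
  if (occurrences) {
    obs <- counts[, total_per_kmer > 0L, drop = FALSE]
    m <- t(obs)
    colnames(m) <- names(refs$seqs)
    if (refs$alphabet == "RNA") rownames(m) <- to_rna(rownames(m))
    out$per_sequence_counts <- m
  }
  structure(out, class = "kmer_coverage_report")
}

#' @export
print.kmer_coverage_report <- function(x, ...) {
  cat(sprintf("k=%d: %d / %d k-mers observed (%.1f%%)\n",
              x$k, x$distinct_observed, x$possible, x$percent))
  invisible(x)
}

#' Summarise k-mer saturation over several word lengths as TSV
#'
#' @param refs a [reference_set()].
#' @param ks integer vector of word lengths.
#' @param path optional TSV output path.
#' @return data.frame with one row per k.
#' @export
kmer_coverage_table <- function(refs, ks, path = NULL) {
  df <- do.call(rbind, lapply(ks, function(k) {
    r <- kmer_coverage(refs, k)
    data.frame(k = r$k, distinct_observed = r$distinct_observed,
               possible = r$possible, percent = r$percent_display)
  }))
  if (!is.null(path)) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  df
}

#' Find sequences lacking a motif entirely
#'
#' Exact-string scan in the canonical alphabet; transcripts with zero
#' occurrences of the motif are the ones an enzyme with that recognition
#' sequence cannot cleave.
#'
#' @param transcripts a [reference_set()] of transcript sequences.
#' @param motif non-empty motif string (T/U equivalent).
#' @return list with `motif_free_ids`, `n_total`, `n_motif_free`.
#' @export
motif_free_sequences <- function(transcripts, motif) {
  stopifnot(inherits(transcripts, "reference_set"))
  if (!nzchar(motif)) stop("motif must be non-empty")
  if (length(transcripts$seqs) == 0L) stop("empty transcript set")
  set <- Biostrings::DNAStringSet(canonical_dna(transcripts$seqs))
  n_occ <- Biostrings::vcountPattern(canonical_dna(motif), set, fixed = TRUE)
  ids <- names(transcripts$seqs)[n_occ == 0L]
  list(motif_free_ids = ids,
       n_total = length(transcripts$seqs),
       n_motif_free = length(ids))
}
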