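## Read preparation: quality/ambiguity trimming, barcode-anchor detection
## with 5' stripping, and length filtering.
##
## The anchor is the 3'-terminal 15 nt of the ligated barcode; in a read it
## marks the boundary immediately upstream of the cleavage-derived 5'
## nucleotide, so everything strictly 3' of it is the fragment of interest.

#' Read-preparation configuration
#'
#' Defaults mirror the standard analysis settings for barcode-ligation
#' 5'-end libraries: an error-probability trim limit of 0.05, zero
#' ambiguities allowed, the 15-base barcode anchor `CTGGCTTTGATGAAA`, a
#' 15-base minimum fragment length, and anchor search on both strands.
#'
#' With a 15-nt anchor under the reference aligner's score model (match +1,
#' mismatch -5, gap -5, minimum match score 15), any single-edit variant of
#' the anchor scores at most 10 < 15, so exact substring search is provably
#' equivalent to that model and is what this package implements.
#'
#' @param quality_limit error-probability limit for modified-Mott trimming
#'   (0 < limit < 1).
#' @param max_ambiguities maximum number of N bases tolerated after
#'   trimming.
#' @param anchor anchor sequence (DNA alphabet, length >= 8).
#' @param min_length_after_trim minimum fragment length kept after anchor
#'   stripping.
#' @param search_both_orientations also search the reverse complement of
#'   each read for the anchor.
#' @return a `prep_config` list.
#' @export
prep_config <- function(quality_limit = 0.05,
                        max_ambiguities = 0L,
                        anchor = "CTGGCTTTGATGAAA",
                        min_length_after_trim = 15L,
                        search_both_orientations = TRUE) {
  stopifnot(quality_limit > 0, quality_limit < 1,
            nchar(anchor) >= 8L,
            min_length_after_trim >= 1L,
            max_ambiguities >= 0L)
  structure(list(quality_limit = quality_limit,
                 max_ambiguities = as.integer(max_ambiguities),
                 anchor = canonical_dna(anchor),
                 min_length_after_trim = as.integer(min_length_after_trim),
                 search_both_orientations = isTRUE(search_both_orientations)),
            class = "prep_config")
}

#' Quality-trim reads with the modified-Mott algorithm
#'
#' Each base scores `limit - 10^(-Q/10)`; the retained subread is the
#' contiguous segment with the maximal score sum (empty when all segment
#' sums are non-positive). Ties break toward the earliest end, then the
#' earliest start. Trimming is idempotent. Reads whose trimmed subread
#' still contains more than `max_ambiguities` N bases are rejected
#' (a tagged outcome, not an error).
#'
#' @param sequence,quality parallel character vectors (quality Phred+33).
#' @param limit error-probability limit.
#' @param max_ambiguities maximum number of Ns tolerated after trimming.
#' @return a data.frame with columns `sequence`, `quality` (trimmed),
#'   `start`, `end` (1-based bounds into the input, 0/-1 when empty) and
#'   `status` (`"ok"`, `"empty"`, or `"ambiguous"`).
#' @export
quality_trim <- function(sequence, quality, limit = 0.05,
                         max_ambiguities = 0L) {
  stopifnot(length(sequence) == length(quality))
  if (length(sequence) == 0L) {
    return(data.frame(sequence = character(0), quality = character(0),
                      start = integer(0), end = integer(0),
                      status = character(0)))
  }
  b <- .mott_bounds(quality, limit)
  start <- b[, 1L]
  end <- b[, 2L]
  keep <- end >= start
  seq_trim <- ifelse(keep, substr(sequence, start, end), "")
  qual_trim <- ifelse(keep, substr(quality, start, end), "")
  n_amb <- nchar(seq_trim) - nchar(gsub("[Nn]", "", seq_trim))
  status <- ifelse(!keep, "empty",
                   ifelse(n_amb > max_ambiguities, "ambiguous", "ok"))
  data.frame(sequence = seq_trim, quality = qual_trim,
             start = start, end = end, status = status,
             stringsAsFactors = FALSE)
}

# leftmost exact anchor occurrence per sequence; returns the 1-based start
# or NA.  fixed = TRUE: N in a read never matches the anchor.
.anchor_starts <- function(sequences, anchor) {
  if (length(sequences) == 0L) return(integer(0))
  subject <- Biostrings::DNAStringSet(sequences)
  hits <- Biostrings::vmatchPattern(anchor, subject, fixed = TRUE)
  first <- rep(NA_integer_, length(sequences))
  n_hits <- lengths(hits)
  has <- n_hits > 0L
  if (any(has)) {
    first[has] <- vapply(Biostrings::startIndex(hits)[has],
                         function(s) min(s), integer(1))
  }
  first
}

#' Strip the barcode anchor and extract the downstream fragment
#'
#' Searches each quality-trimmed sequence (and, optionally, its reverse
#' complement) for an exact occurrence of the anchor. On a hit, everything
#' strictly 3' of the leftmost anchor occurrence -- in the orientation where
#' it was found -- is returned; its first base is the putative
#' cleavage-derived 5' nucleotide. The forward orientation is searched
#' first and the first orientation with a hit wins. Fragments shorter than
#' `min_length` and anchor-free reads are rejected (tagged, not errors).
#'
#' @param sequence character vector of quality-trimmed read sequences
#'   (DNA alphabet).
#' @param anchor anchor sequence (DNA).
#' @param min_length minimum fragment length retained.
#' @param search_both_orientations search the reverse complement too.
#' @return a data.frame with columns `fragment`, `orientation`
#'   (`"forward"`/`"reverse"`), `anchor_start` (1-based, in the searched
#'   orientation) and `status` (`"ok"`, `"no_anchor"`, `"too_short"`).
#' @export
strip_barcode <- function(sequence, anchor = "CTGGCTTTGATGAAA",
                          min_length = 15L,
                          search_both_orientations = TRUE) {
  anchor <- canonical_dna(anchor)
  n <- length(sequence)
  frag <- character(n)
  orientation <- rep(NA_character_, n)
  anchor_start <- rep(NA_integer_, n)
  status <- rep("no_anchor", n)
  if (n == 0L) {
    return(data.frame(fragment = frag, orientation = orientation,
                      anchor_start = anchor_start, status = status))
  }
  seq_canon <- canonical_dna(sequence)
  fwd <- .anchor_starts(seq_canon, anchor)
  hit_f <- !is.na(fwd)
  if (any(hit_f)) {
    cut_at <- fwd[hit_f] + nchar(anchor)
    frag[hit_f] <- substr(seq_canon[hit_f], cut_at,
                          nchar(seq_canon[hit_f]))
    orientation[hit_f] <- "forward"
    anchor_start[hit_f] <- fwd[hit_f]
    status[hit_f] <- "ok"
  }
  if (search_both_orientations && any(!hit_f)) {
    rc <- reverse_complement(seq_canon[!hit_f], "DNA")
    rev_hit <- .anchor_starts(rc, anchor)
    hit_r <- !is.na(rev_hit)
    if (any(hit_r)) {
      idx <- which(!hit_f)[hit_r]
      cut_at <- rev_hit[hit_r] + nchar(anchor)
      frag[idx] <- substr(rc[hit_r], cut_at, nchar(rc[hit_r]))
      orientation[idx] <- "reverse"
      anchor_start[idx] <- rev_hit[hit_r]
      status[idx] <- "ok"
    }
  }
  short <- status == "ok" & nchar(frag) < min_length
  status[short] <- "too_short"
  frag[short] <- ""
  data.frame(fragment = frag, orientation = orientation,
             anchor_start = anchor_start, status = status,
             stringsAsFactors = FALSE)
}

#' Prepare a FASTQ file of raw reads into mapped-ready 5' fragments
#'
#' Runs the full left half of the workflow on one FASTQ file:
#' modified-Mott quality trimming, ambiguity filtering (after trimming,
#' matching the trim-then-filter order of the reference workflow), anchor
#' detection in both orientations, 5' stripping and the minimum-length
#' filter. R1 and R2 files are processed independently through this
#' identical path and their surviving fragments pooled by the caller.
#'
#' @param path FASTQ path (Phred+33; optionally gzipped).
#' @param config a [prep_config()].
#' @param chunk_size records per streamed chunk.
#' @param verbose log one line per chunk to stderr.
#' @return list with `fragments` (data.frame: `id`, `fragment`,
#'   `orientation`) and `counts` (named integer vector: `input`,
#'   `quality_rejected`, `ambiguous`, `no_anchor`, `too_short`,
#'   `surviving`).
#' @export
prepare_reads <- function(path, config = prep_config(),
                          chunk_size = 200000L, verbose = FALSE) {
  stopifnot(inherits(config, "prep_config"))
  counts <- c(input = 0L, quality_rejected = 0L, ambiguous = 0L,
              no_anchor = 0L, too_short = 0L, surviving = 0L)
  frags <- list()
  done <- 0L
  chunks <- fastq_apply(path, chunk_size = chunk_size, fun = function(chunk) {
    qt <- quality_trim(chunk$sequence, chunk$quality,
                       limit = config$quality_limit,
                       max_ambiguities = config$max_ambiguities)
    ok <- qt$status == "ok"
    sb <- strip_barcode(qt$sequence[ok], anchor = config$anchor,
                        min_length = config$min_length_after_trim,
                        search_both_orientations =
                          config$search_both_orientations)
    kept <- sb$status == "ok"
    if (verbose) {
      done <<- done + length(chunk$sequence)
      message(sprintf("prepared %d reads (%d surviving so far)",
                      done, counts[["surviving"]] + sum(kept)))
    }
    list(counts = c(input = length(chunk$sequence),
                    quality_rejected = sum(qt$status == "empty"),
                    ambiguous = sum(qt$status == "ambiguous"),
                    no_anchor = sum(sb$status == "no_anchor"),
                    too_short = sum(sb$status == "too_short"),
                    surviving = sum(kept)),
         fragments = data.frame(id = chunk$id[ok][kept],
                                fragment = sb$fragment[kept],
                                orientation = sb$orientation[kept],
                                stringsAsFactors = FALSE))
  })
  for (ch in chunks) {
    counts <- counts + ch$counts
    frags[[length(frags) + 1L]] <- ch$fragments
  }
  fragments <- if (length(frags)) do.call(rbind, frags) else
    data.frame(id = character(0), fragment = character(0),
               orientation = character(0))
  list(fragments = fragments, counts = counts)
}

#' Write a read-preparation report as TSV
#'
#' @param counts named counts from [prepare_reads()] (summed over files).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_prep_report <- function(counts, path) {
  df <- data.frame(category = names(counts), reads = as.integer(counts))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
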