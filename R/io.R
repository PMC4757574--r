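## FASTA / FASTQ input and output, built on Biostrings.

#' Construct a reference set
#'
#' A reference set holds the named substrate sequences together with an
#' alphabet flag. Sequences must be non-empty, ids unique, and only the
#' plain bases A, C, G, T, U are allowed (substrates are fully defined
#' synthetic RNAs; ambiguity codes are rejected).
#'
#' @param seqs named character vector of sequences.
#' @param alphabet `"RNA"`, `"DNA"` or `"auto"` (any U implies RNA).
#' @return an object of class `reference_set` with fields `seqs` (named
#'   character) and `alphabet`.
#' @export
reference_set <- function(seqs, alphabet = "auto") {
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids))) {
    stop("reference sequences must be named")
  }
  if (anyDuplicated(ids)) {
    stop("duplicate reference id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (length(seqs) == 0L) stop("reference set is empty")
  if (any(!nzchar(seqs))) {
    stop("empty sequence for record(s): ",
         paste(ids[!nzchar(seqs)], collapse = ", "))
  }
  bad <- .non_plain_records(seqs, ids)
  if (length(bad)) {
    stop("non-IUPAC or ambiguous characters in record(s): ",
         paste(bad, collapse = ", "))
  }
  if (identical(alphabet, "auto")) {
    alphabet <- if (any(grepl("[Uu]", seqs))) "RNA" else "DNA"
  }
  alphabet <- match.arg(alphabet, c("RNA", "DNA"))
  structure(list(seqs = seqs, alphabet = alphabet), class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("reference_set: %d %s sequence(s)\n", length(x$seqs), x$alphabet))
  for (i in seq_along(x$seqs)) {
    cat(sprintf("  %s  (%d nt)\n", names(x$seqs)[i], nchar(x$seqs[i])))
  }
  invisible(x)
}

#' @export
length.reference_set <- function(x) length(x$seqs)

#' Read a multi-record FASTA file into a reference set
#'
#' Records are returned in file order; U and T are both accepted and stored
#' as given, with the alphabet auto-detected (any U implies RNA). Empty
#' files, duplicate ids, empty sequences and non-plain characters are
#' format errors naming the offending record.
#'
#' @param path path to a FASTA file (plain or gzipped).
#' @return a [reference_set()].
#' @export
read_reference_fasta <- function(path) {
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = "fasta"),
    error = function(e) stop("cannot parse FASTA '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (length(set) == 0L) stop("FASTA file '", path, "' contains no records")
  seqs <- as.character(set)
  # id = first whitespace-delimited word of the header
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  reference_set(seqs)
}

#' Write a reference set to FASTA
#'
#' @param refs a [reference_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(refs, path) {
  stopifnot(inherits(refs, "reference_set"))
  set <- Biostrings::BStringSet(refs$seqs)
  Biostrings::writeXStringSet(set, path, format = "fasta")
  invisible(path)
}

#' Read a FASTQ file (Phred+33)
#'
#' Sanger-encoded (Phred+33) FASTQ only; no quality-encoding autodetection.
#' Gzipped input is handled transparently. `nrec`/`skip` allow chunked
#' reading of large files (see [fastq_apply()]).
#'
#' @param path path to a FASTQ file.
#' @param nrec maximum number of records to read (-1 = all).
#' @param skip number of records to skip before reading.
#' @return a list with `id` (character), `sequence` (character) and
#'   `quality` (character, Phred+33 encoded, same width as `sequence`).
#' @export
read_fastq <- function(path, nrec = -1L, skip = 0L) {
  if (skip == 0L) .validate_fastq(path)
  x <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq",
                                 with.qualities = TRUE,
                                 nrec = nrec, skip = skip),
    error = function(e) stop("cannot parse FASTQ '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  ids <- if (is.null(names(x))) sprintf("read%d", seq_along(x)) else
    sub("\\s.*$", "", names(x))
  qual <- as.character(S4Vectors::mcols(x)$qualities)
  seqs <- unname(as.character(x))
  bad <- which(nchar(seqs) != nchar(qual))
  if (length(bad)) {
    stop("sequence/quality length mismatch for record '", ids[bad[1L]],
         "' in '", path, "'")
  }
  list(id = ids, sequence = seqs, quality = unname(qual))
}

# Structural validation of a four-line-per-record FASTQ file: every
# record's quality line must match its sequence line in length.  The
# Biostrings parser does not enforce this invariant, so it is checked
# here once per file (on the first chunk); multi-line FASTQ, long
# obsolete, is not supported.
.validate_fastq <- function(path, block_records = 250000L) {
  con <- file(path, "r")
  on.exit(close(con))
  rec <- 0L
  repeat {
    lines <- readLines(con, n = 4L * block_records)
    if (length(lines) == 0L) break
    if (length(lines) %% 4L != 0L) {
      stop("truncated FASTQ record at end of '", path, "'")
    }
    ids <- lines[c(TRUE, FALSE, FALSE, FALSE)]
    seqs <- lines[c(FALSE, TRUE, FALSE, FALSE)]
    quals <- lines[c(FALSE, FALSE, FALSE, TRUE)]
    if (any(!startsWith(ids, "@"))) {
      stop("malformed FASTQ header near record ", rec +
             which(!startsWith(ids, "@"))[1L], " in '", path, "'")
    }
    bad <- which(nchar(seqs) != nchar(quals))
    if (length(bad)) {
      stop("sequence/quality length mismatch for record '",
           sub("\\s.*$", "", sub("^@", "", ids[bad[1L]])), "' in '", path,
           "'")
    }
    rec <- rec + length(ids)
  }
  invisible(TRUE)
}

#' Apply a function over a FASTQ file in chunks
#'
#' Streams the file `chunk_size` records at a time so arbitrarily large
#' files never need to be resident in memory at once.
#'
#' @param path path to a FASTQ file.
#' @param fun function taking a read chunk (as returned by [read_fastq()]).
#' @param chunk_size records per chunk.
#' @return list of `fun` results, one per chunk.
#' @export
fastq_apply <- function(path, fun, chunk_size = 200000L) {
  out <- list()
  skip <- 0L
  repeat {
    chunk <- read_fastq(path, nrec = chunk_size, skip = skip)
    if (length(chunk$sequence) == 0L) break
    out[[length(out) + 1L]] <- fun(chunk)
    if (length(chunk$sequence) < chunk_size) break
    skip <- skip + chunk_size
  }
  out
}

#' Write reads to FASTQ (Phred+33)
#'
#' @param id,sequence,quality parallel character vectors; `quality` is
#'   Phred+33 encoded and must match `sequence` in width.
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(id, sequence, quality, path) {
  stopifnot(length(id) == length(sequence),
            length(sequence) == length(quality))
  if (any(nchar(sequence) != nchar(quality))) {
    bad <- which(nchar(sequence) != nchar(quality))[1L]
    stop("sequence/quality length mismatch for record '", id[bad], "'")
  }
  seqs <- Biostrings::DNAStringSet(sequence)
  names(seqs) <- id
  qual <- Biostrings::PhredQuality(quality)
  x <- Biostrings::QualityScaledDNAStringSet(seqs, qual)
  Biostrings::writeQualityScaledXStringSet(
    x, path, compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Decode Phred+33 quality strings to integer scores
#'
#' @param quality character vector of Phred+33 encoded quality strings.
#' @return list of integer vectors of per-base Phred scores.
#' @export
phred_scores <- function(quality) {
  lapply(quality, function(q) {
    if (!nzchar(q)) return(integer(0))
    as.integer(charToRaw(q)) - 33L
  })
}
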