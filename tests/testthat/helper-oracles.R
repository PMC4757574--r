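# Independent oracles and small fixture builders used across the suite.
# Each oracle is a deliberately naive reimplementation (enumeration /
# per-base counting) kept free of the code paths it checks.

# O(L^2) best-subread oracle for modified-Mott trimming: enumerate every
# contiguous segment, maximise the score sum, break ties toward the
# earliest end then the earliest start (the convention the trimmer
# documents). Returns c(start, end), 1-based, or c(0, -1) when empty.
mott_oracle <- function(quality, limit) {
  q <- as.integer(charToRaw(quality)) - 33L
  s <- limit - 10^(-q / 10)
  L <- length(s)
  best <- 0
  bi <- 0L
  bj <- -1L
  for (j in seq_len(L)) {
    acc <- 0
    for (i in rev(seq_len(j))) {
      acc <- acc + s[i]
      better <- acc > best + 1e-12
      tie <- abs(acc - best) <= 1e-12 && bj > 0L &&
        (j < bj || (j == bj && i < bi))
      if (better || tie) {
        best <- acc
        bi <- i
        bj <- j
      }
    }
  }
  c(bi, bj)
}

# naive all-position exact-occurrence scan for one fragment
map_oracle <- function(fragment, ref_seqs) {
  hits <- list()
  for (id in names(ref_seqs)) {
    r <- ref_seqs[[id]]
    L <- nchar(r)
    w <- nchar(fragment)
    if (w > L || w == 0L) next
    for (st in seq_len(L - w + 1L)) {
      if (substr(r, st, st + w - 1L) == fragment) {
        hits[[length(hits) + 1L]] <- list(ref = id, start = st - 1L)
      }
    }
  }
  hits
}

# per-base counting oracle for coverage profiles
coverage_oracle <- function(mapped, ref_len) {
  cov <- integer(ref_len)
  for (k in seq_len(nrow(mapped))) {
    span <- seq.int(mapped$start[k] + 1L,
                    mapped$start[k] + mapped$length[k])
    cov[span] <- cov[span] + 1L
  }
  cov
}

# best local-alignment score of `pattern` against `subject` under the
# reference aligner's score model (match +1, mismatch -5, gap -5)
local_score <- function(pattern, subject) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -5,
                                                  baseOnly = TRUE)
  as.numeric(Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(pattern),
    subject = Biostrings::DNAString(subject),
    type = "local", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = 5, scoreOnly = TRUE))
}

# all single-edit (substitution / insertion / deletion) variants of a
# DNA string, excluding any variant equal to the original
single_edit_variants <- function(x) {
  bases <- c("A", "C", "G", "T")
  n <- nchar(x)
  ch <- strsplit(x, "")[[1]]
  out <- character(0)
  for (i in seq_len(n)) {
    for (b in setdiff(bases, ch[i])) {
      v <- ch
      v[i] <- b
      out <- c(out, paste(v, collapse = ""))
    }
    out <- c(out, paste(ch[-i], collapse = ""))             # deletion
  }
  for (i in 0:n) {                                          # insertions
    for (b in bases) {
      out <- c(out, paste(c(ch[seq_len(i)], b, ch[seq_len(n - i) + i]),
                          collapse = ""))
    }
  }
  setdiff(unique(out), x)
}

# random Phred+33 quality string
random_quality <- function(n, qmin = 2L, qmax = 40L) {
  intToUtf8(33L + sample(qmin:qmax, n, replace = TRUE))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# write a small FASTQ and return its path
tmp_fastq <- function(id, sequence, quality) {
  path <- tempfile(fileext = ".fastq")
  write_fastq(id, sequence, quality, path)
  path
}

bundled_substrates <- function() {
  read_reference_fasta(system.file("extdata", "substrates_synthetic.fasta",
                                   package = "cleavemap"))
}

# distinct-kmer brute-force oracle
kmer_oracle <- function(seqs, k) {
  words <- unlist(lapply(chartr("Uu", "Tt", toupper(seqs)), function(s) {
    if (nchar(s) < k) return(character(0))
    st <- seq_len(nchar(s) - k + 1L)
    substring(s, st, st + k - 1L)
  }))
  length(unique(words))
}
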