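## Sequence alphabet helpers.
##
## References are RNA (U) as synthesized; sequencer output is DNA (T).  All
## comparisons happen in a canonical T-alphabet; motif windows and consensus
## strings are reported back in U when the reference set is RNA.

#' Convert a nucleotide string to the canonical DNA (T) alphabet
#'
#' Uppercases and replaces U with T. Used before any read-vs-reference
#' comparison so that RNA references and DNA reads live in one alphabet.
#'
#' @param x character vector of nucleotide sequences.
#' @return character vector in the canonical T-alphabet.
#' @export
canonical_dna <- function(x) {
  chartr("acgtun", "ACGTTN", chartr("U", "T", toupper(x)))
}

#' Convert a nucleotide string to the RNA (U) alphabet
#'
#' @param x character vector of nucleotide sequences.
#' @return character vector with T replaced by U.
#' @export
to_rna <- function(x) {
  chartr("Tt", "Uu", toupper(x))
}

#' Reverse complement of nucleotide sequences
#'
#' Standard complement honouring the alphabet (A-U for RNA, A-T for DNA),
#' then reversal; N maps to N. An involution: applying it twice is the
#' identity.
#'
#' @param x character vector of sequences over A, C, G, T/U, N.
#' @param alphabet `"DNA"` or `"RNA"`; controls whether A complements to T
#'   or to U in the output.
#' @return character vector of reverse-complemented sequences.
#' @export
reverse_complement <- function(x, alphabet = c("DNA", "RNA")) {
  alphabet <- match.arg(alphabet)
  if (length(x) == 0L) return(character(0))
  if (alphabet == "DNA") {
    out <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(canonical_dna(x))))
  } else {
    out <- as.character(Biostrings::reverseComplement(
      Biostrings::RNAStringSet(to_rna(x))))
  }
  unname(out)
}

# validate sequences against the plain {A,C,G,T,U} alphabet (no ambiguity
# codes at all -- substrate references must be unambiguous); returns the
# offending record ids
.non_plain_records <- function(seqs, ids) {
  bad <- grepl("[^ACGTUacgtu]", seqs)
  ids[bad]
}
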