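## Exact full-length mapping of prepared 5' fragments to the substrate
## references, and per-position coverage / relative-coverage-increase
## profiles.
##
## Mapping semantics: a fragment maps only if it occurs as an exact,
## full-length substring of a reference (no mismatches, no indels).
## Exactly one occurrence across the whole set -> mapped; none -> unmapped;
## two or more (same or different reference) -> multimapped and excluded
## from coverage, a deterministic and conservative choice for a
## step-detection statistic.  Orientation was already fixed when the
## barcode anchor was found, so fragments are searched in one orientation
## only.

# seed-and-verify index: every seed_len-mer of every reference with its
# (reference, offset) of origin.  Behaviour is checked against a naive
# all-position scan in the test suite.
.build_seed_index <- function(ref_seqs_canonical, seed_len) {
  ids <- names(ref_seqs_canonical)
  seeds <- character(0)
  ref_i <- integer(0)
  pos0 <- integer(0)
  for (i in seq_along(ref_seqs_canonical)) {
    s <- ref_seqs_canonical[[i]]
    L <- nchar(s)
    if (L < seed_len) next
    st <- seq_len(L - seed_len + 1L)
    seeds <- c(seeds, substring(s, st, st + seed_len - 1L))
    ref_i <- c(ref_i, rep.int(i, length(st)))
    pos0 <- c(pos0, st - 1L)
  }
  uniq <- unique(seeds)
  gid <- match(seeds, uniq)
  groups <- split(seq_along(seeds), gid)
  list(uniq = uniq, groups = groups, ref_i = ref_i, pos0 = pos0,
       seed_len = seed_len, ids = ids)
}

#' Map prepared fragments exactly to a reference set
#'
#' @param fragments character vector of fragment sequences (any of T/U
#'   alphabet; comparison happens in the canonical T-alphabet).
#' @param refs a [reference_set()].
#' @param min_length fragments shorter than this are unmappable by
#'   contract; also the seed length of the index.
#' @return a data.frame, one row per fragment, with columns `fragment`,
#'   `ref_id`, `start` (0-based), `length`, `n_hits` and `status`
#'   (`"mapped"`, `"unmapped"`, `"multimapped"`).
#' @export
map_fragments <- function(fragments, refs, min_length = 15L) {
  stopifnot(inherits(refs, "reference_set"))
  n <- length(fragments)
  out <- data.frame(fragment = as.character(fragments),
                    ref_id = rep(NA_character_, n),
                    start = rep(NA_integer_, n),
                    length = nchar(fragments),
                    n_hits = rep(0L, n),
                    status = rep("unmapped", n),
                    stringsAsFactors = FALSE)
  if (n == 0L) return(out)
  ref_canon <- canonical_dna(refs$seqs)
  names(ref_canon) <- names(refs$seqs)
  idx <- .build_seed_index(ref_canon, min_length)
  frag_canon <- canonical_dna(fragments)
  uniq_frag <- unique(frag_canon)
  res <- lapply(uniq_frag, function(f) {
    L <- nchar(f)
    if (L < idx$seed_len) return(list(hits = 0L))
    g <- match(substr(f, 1L, idx$seed_len), idx$uniq)
    if (is.na(g)) return(list(hits = 0L))
    cand <- idx$groups[[g]]
    ri <- idx$ref_i[cand]
    p0 <- idx$pos0[cand]
    full <- substring(ref_canon[ri], p0 + 1L, p0 + L)
    hit <- full == f
    k <- sum(hit)
    if (k == 1L) {
      list(hits = 1L, ref = idx$ids[ri[hit]], start = p0[hit])
    } else {
      list(hits = k)
    }
  })
  m <- match(frag_canon, uniq_frag)
  hits <- vapply(res, function(r) r$hits, integer(1))[m]
  out$n_hits <- hits
  out$status[hits >= 2L] <- "multimapped"
  one <- hits == 1L
  if (any(one)) {
    ref_u <- vapply(res, function(r)
      if (r$hits == 1L) r$ref else NA_character_, character(1))
    st_u <- vapply(res, function(r)
      if (r$hits == 1L) r$start else NA_integer_, integer(1))
    out$ref_id[one] <- ref_u[m][one]
    out$start[one] <- st_u[m][one]
    out$status[one] <- "mapped"
  }
  out
}

#' Map one fragment (scalar convenience wrapper)
#'
#' @inheritParams map_fragments
#' @param fragment a single fragment sequence.
#' @return a one-row data.frame as in [map_fragments()].
#' @export
map_exact <- function(fragment, refs, min_length = 15L) {
  map_fragments(fragment, refs, min_length = min_length)
}

#' Build per-reference coverage and relative-coverage-increase profiles
#'
#' Coverage at position n counts the mapped fragments whose interval
#' contains n.  The relative coverage increase (RCI) at position n is
#' `coverage[n] / coverage[n-1]`, undefined (NA) at position 0 and wherever
#' `coverage[n-1]` is zero -- such positions can never become candidates,
#' which avoids pseudocount artifacts.  `start_counts[n]` counts fragment
#' 5' start events at n.
#'
#' @param mappings data.frame from [map_fragments()] (rows with status
#'   `"mapped"` are used).
#' @param refs a [reference_set()].
#' @return a named list of `coverage_profile` objects, one per reference,
#'   each with fields `ref_id`, `coverage`, `start_counts`, `rci` (all
#'   indexed by 0-based position + 1).
#' @export
build_profiles <- function(mappings, refs) {
  stopifnot(inherits(refs, "reference_set"))
  mapped <- mappings[mappings$status == "mapped", , drop = FALSE]
  ref_len <- nchar(refs$seqs)
  if (nrow(mapped)) {
    bad <- mapped$start < 0L |
      mapped$start + mapped$length > ref_len[mapped$ref_id]
    if (any(bad, na.rm = TRUE)) {
      stop("mapping outside reference bounds -- upstream integrity error")
    }
  }
  profiles <- lapply(names(refs$seqs), function(id) {
    L <- ref_len[[id]]
    rows <- mapped[mapped$ref_id == id, , drop = FALSE]
    if (nrow(rows)) {
      ir <- IRanges::IRanges(start = rows$start + 1L, width = rows$length)
      cov <- as.integer(IRanges::coverage(ir, width = L))
      starts <- tabulate(rows$start + 1L, nbins = L)
    } else {
      cov <- integer(L)
      starts <- integer(L)
    }
    prev <- c(NA_integer_, cov[-L])
    rci <- ifelse(!is.na(prev) & prev > 0L, cov / prev, NA_real_)
    structure(list(ref_id = id, coverage = cov, start_counts = starts,
                   rci = rci),
              class = "coverage_profile")
  })
  names(profiles) <- names(refs$seqs)
  profiles
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat(sprintf("coverage_profile %s: %d positions, max coverage %d\n",
              x$ref_id, length(x$coverage), max(x$coverage)))
  invisible(x)
}

#' Write a mapping summary TSV
#'
#' @param mappings data.frame from [map_fragments()].
#' @param path output TSV path.
#' @return the summary data.frame, invisibly.
#' @export
write_mapping_summary <- function(mappings, path) {
  total <- nrow(mappings)
  mapped <- sum(mappings$status == "mapped")
  df <- data.frame(
    total = total,
    mapped = mapped,
    unmapped = sum(mappings$status == "unmapped"),
    multimapped = sum(mappings$status == "multimapped"),
    percent_mapped = if (total > 0) round(100 * mapped / total, 2) else NA_real_)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Write per-position coverage tracks as TSV
#'
#' Positions are reported 1-based inclusive (stated in the header line);
#' undefined RCI values are written as NA.
#'
#' @param profiles list from [build_profiles()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_coverage_tsv <- function(profiles, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# positions are 1-based inclusive", con)
  df <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(ref_id = p$ref_id,
               pos_1based = seq_along(p$coverage),
               coverage = p$coverage,
               starts = p$start_counts,
               rci = p$rci)
  }))
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}
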