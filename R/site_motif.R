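## Candidate cleavage-site calling from coverage profiles, window
## extraction, position-frequency-matrix construction, information content
## and consensus motif.
##
## A cleavage-derived 5' end shows up as a step increase in coverage: many
## reads begin at the first nucleotide 3' of the cut.  That nucleotide is
## numbered zero in all motif coordinates, and the cut falls between
## positions -1 and 0 by construction.

#' Site-calling configuration
#'
#' @param min_coverage a candidate position must have coverage strictly
#'   greater than this (the filter applies at the stepped-up zero position
#'   itself, not its predecessor). Default 1000.
#' @param top_k_per_ref candidates retained per reference after sorting by
#'   relative coverage increase. Default 5.
#' @param flank bases extracted on each side of the zero position.
#'   Default 5, giving 11-base windows.
#' @param min_rci minimum relative coverage increase for a position to
#'   count as a step at all (inclusive). The default 2.0 demands at least
#'   a doubling of coverage; set to 0 to rank every position with defined
#'   RCI, recovering the permissive top-k-only rule.
#' @return a `site_call_config` list.
#' @export
site_call_config <- function(min_coverage = 1000L, top_k_per_ref = 5L,
                             flank = 5L, min_rci = 2.0) {
  stopifnot(min_coverage >= 1L, top_k_per_ref >= 1L, flank >= 0L,
            min_rci >= 0)
  structure(list(min_coverage = as.integer(min_coverage),
                 top_k_per_ref = as.integer(top_k_per_ref),
                 flank = as.integer(flank),
                 min_rci = min_rci),
            class = "site_call_config")
}

# window of 2*flank+1 bases around 0-based zero_pos, N-padded past the
# reference edges; reported in the reference alphabet (U for RNA).
.extract_window <- function(ref_seq, zero_pos, flank, rna = TRUE) {
  L <- nchar(ref_seq)
  padded <- paste0(strrep("N", flank), ref_seq, strrep("N", flank))
  w <- substr(padded, zero_pos + 1L, zero_pos + 2L * flank + 1L)
  if (rna) to_rna(w) else canonical_dna(w)
}

#' Call candidate cleavage sites on one coverage profile
#'
#' Candidate positions have defined RCI of at least `min_rci`, and coverage
#' strictly above `min_coverage` at the position itself. They are sorted by
#' RCI descending (ties: larger coverage first, then smaller position) and
#' the top `top_k_per_ref` are kept; if fewer qualify, all are returned
#' with a message. Windows of `flank` bases either side of the zero
#' position are cut from the reference (U alphabet when the reference set
#' is RNA) and N-padded at edges.
#'
#' @param profile a `coverage_profile` from [build_profiles()].
#' @param refs the [reference_set()] the profile was built against.
#' @param config a [site_call_config()].
#' @return data.frame with columns `ref_id`, `zero_pos` (0-based),
#'   `rci`, `coverage`, `window`.
#' @export
call_candidates <- function(profile, refs, config = site_call_config()) {
  stopifnot(inherits(profile, "coverage_profile"),
            inherits(refs, "reference_set"),
            inherits(config, "site_call_config"))
  ref_seq <- refs$seqs[[profile$ref_id]]
  cov <- profile$coverage
  rci <- profile$rci
  qual <- which(!is.na(rci) & rci >= config$min_rci &
                  cov > config$min_coverage)
  if (length(qual) < config$top_k_per_ref) {
    message(sprintf("reference %s: only %d qualifying position(s) (top_k = %d)",
                    profile$ref_id, length(qual), config$top_k_per_ref))
  }
  ord <- qual[order(-rci[qual], -cov[qual], qual)]
  keep <- head(ord, config$top_k_per_ref)
  zero0 <- keep - 1L  # to 0-based
  data.frame(ref_id = rep(profile$ref_id, length(keep)),
             zero_pos = zero0,
             rci = rci[keep],
             coverage = cov[keep],
             window = vapply(zero0, function(z)
               .extract_window(ref_seq, z, config$flank,
                               rna = refs$alphabet == "RNA"), character(1)),
             stringsAsFactors = FALSE)
}

#' Build a motif model from candidate windows
#'
#' Counts each window column over the non-N symbols into a 4 x W position
#' frequency matrix (rows A, C, G, U; W = 2*flank+1), computes the
#' per-column information content `ic_j = 2 + sum_b f_bj log2 f_bj` in bits
#' from the non-N frequencies (no small-sample correction by default; the
#' standard `3/(2 ln 2 n)` correction can be enabled for display), and
#' calls a consensus: a column is called when its information content is at
#' least `ic_min` bits and its modal base frequency is at least
#' `modal_min`; the reported motif is the maximal contiguous run of called
#' columns containing position 0 (or position -1 when 0 is uncalled but -1
#' is). With fewer than `min_support` windows, or when no run qualifies,
#' the model reports no conserved motif -- conservation cannot be claimed
#' from a handful of observations.
#'
#' @param windows character vector of equal-length candidate windows
#'   (A/C/G/U/T/N; T is treated as U).
#' @param flank flank size the windows were built with (W = 2*flank+1).
#' @param ic_min information-content threshold (bits) for calling a column.
#' @param modal_min modal-base frequency threshold for calling a column.
#' @param min_support minimum number of windows needed to call any
#'   consensus.
#' @param small_sample_correction subtract the standard small-sample
#'   entropy correction from the information content used for column
#'   calling (the `ic` field itself stays uncorrected).
#' @return a `motif_model` with fields `pfm` (4 x W counts), `column_totals`,
#'   `ic`, `consensus` (string or NA), `called` (logical per column),
#'   `consensus_span` (motif-coordinate range or NULL), `cut_site`
#'   (`c(-1, 0)`), `n_windows`, `positions` (motif coordinates
#'   -flank..flank).
#' @export
build_motif <- function(windows, flank, ic_min = 1.0, modal_min = 0.8,
                        min_support = 5L, small_sample_correction = FALSE) {
  if (length(windows) == 0L) stop("no candidate windows: cannot build a motif")
  W <- 2L * flank + 1L
  if (any(nchar(windows) != W)) {
    stop("all windows must have length 2*flank+1 = ", W)
  }
  bases <- c("A", "C", "G", "U")
  chars <- matrix(unlist(strsplit(to_rna(windows), "")), ncol = W,
                  byrow = TRUE)
  pfm <- vapply(seq_len(W), function(j)
    vapply(bases, function(b) sum(chars[, j] == b), integer(1)),
    integer(4))
  rownames(pfm) <- bases
  positions <- seq(-flank, flank)
  colnames(pfm) <- positions
  totals <- colSums(pfm)
  ic <- vapply(seq_len(W), function(j) {
    tot <- totals[j]
    if (tot == 0L) return(NA_real_)
    f <- pfm[, j] / tot
    f <- f[f > 0]
    2 + sum(f * log2(f))
  }, numeric(1))
  n <- length(windows)
  ic_eff <- ic
  if (small_sample_correction && n > 0L) {
    ic_eff <- ic - 3 / (2 * log(2) * n)
  }
  modal_f <- vapply(seq_len(W), function(j) {
    if (totals[j] == 0L) return(NA_real_)
    max(pfm[, j]) / totals[j]
  }, numeric(1))
  called <- !is.na(ic_eff) & ic_eff >= ic_min &
    !is.na(modal_f) & modal_f >= modal_min
  consensus <- NA_character_
  span <- NULL
  if (n >= min_support && any(called)) {
    zero_j <- flank + 1L            # column index of motif position 0
    anchor_j <- if (called[zero_j]) zero_j else
      if (flank >= 1L && called[zero_j - 1L]) zero_j - 1L else NA_integer_
    if (!is.na(anchor_j)) {
      lo <- anchor_j
      while (lo > 1L && called[lo - 1L]) lo <- lo - 1L
      hi <- anchor_j
      while (hi < W && called[hi + 1L]) hi <- hi + 1L
      consensus <- paste(vapply(lo:hi, function(j)
        bases[which.max(pfm[, j])], character(1)), collapse = "")
      span <- c(positions[lo], positions[hi])
    }
  }
  structure(list(pfm = pfm, column_totals = totals, ic = ic,
                 consensus = consensus, called = called,
                 consensus_span = span, cut_site = c(-1L, 0L),
                 n_windows = n, positions = positions),
            class = "motif_model")
}

#' One-line motif report
#'
#' @param motif a `motif_model`.
#' @return a character scalar, e.g.
#'   `"consensus=UAC (positions -1..1), cut between -1 and 0, support 25 windows"`,
#'   or a "no conserved motif" line.
#' @export
motif_report <- function(motif) {
  stopifnot(inherits(motif, "motif_model"))
  if (is.na(motif$consensus)) {
    sprintf("no conserved motif (support %d windows)", motif$n_windows)
  } else {
    sprintf("consensus=%s (positions %d..%d), cut between -1 and 0, support %d windows",
            motif$consensus, motif$consensus_span[1], motif$consensus_span[2],
            motif$n_windows)
  }
}

#' @export
print.motif_model <- function(x, ...) {
  cat(motif_report(x), "\n")
  invisible(x)
}

#' Export a motif as a PFM matrix file and an information-content logo
#'
#' The tab-separated matrix file is the contract (round-trips exactly via
#' [read_pfm_tsv()]); the logo image is best-effort and skipped with a
#' warning when no graphics device is available.
#'
#' @param motif a `motif_model`.
#' @param pfm_path output path for the PFM TSV.
#' @param image_path optional output path for a PNG logo.
#' @return `pfm_path`, invisibly.
#' @export
export_logo <- function(motif, pfm_path, image_path = NULL) {
  stopifnot(inherits(motif, "motif_model"))
  con <- file(pfm_path, "w")
  writeLines(c("# position frequency matrix: rows A,C,G,U; columns are motif positions",
               "# (zero = first base 3' of the cut; cut falls between -1 and 0)"),
             con)
  df <- data.frame(base = rownames(motif$pfm), motif$pfm, check.names = FALSE)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  close(con)
  if (!is.null(image_path)) {
    ok <- tryCatch({
      grDevices::png(image_path, width = 720, height = 360)
      on.exit(grDevices::dev.off(), add = TRUE)
      .plot_logo(motif)
      TRUE
    }, error = function(e) {
      warning("logo image could not be written: ", conditionMessage(e))
      FALSE
    })
    invisible(ok)
  }
  invisible(pfm_path)
}

# information-content letter stack (heights f_bj * ic_j), base graphics
.plot_logo <- function(motif) {
  W <- ncol(motif$pfm)
  cols <- c(A = "#33a02c", C = "#1f78b4", G = "#ff7f00", U = "#e31a1c")
  graphics::plot(NA, xlim = c(0.5, W + 0.5), ylim = c(0, 2),
                 xlab = "position (0 = first base 3' of cut)",
                 ylab = "information content (bits)", xaxt = "n", bty = "n")
  graphics::axis(1, at = seq_len(W), labels = motif$positions)
  for (j in seq_len(W)) {
    tot <- motif$column_totals[j]
    if (tot == 0L || is.na(motif$ic[j])) next
    f <- motif$pfm[, j] / tot
    h <- f * motif$ic[j]
    ord <- order(h)
    y <- 0
    for (b in ord) {
      if (h[b] <= 0) next
      graphics::rect(j - 0.4, y, j + 0.4, y + h[b],
                     col = "white", border = NA)
      graphics::text(j, y + h[b] / 2, rownames(motif$pfm)[b],
                     col = cols[rownames(motif$pfm)[b]],
                     cex = 0.6 + 2.2 * h[b] / 2, font = 2)
      y <- y + h[b]
    }
  }
}

#' Read back a PFM TSV written by [export_logo()]
#'
#' @param path PFM TSV path.
#' @return the 4 x W integer count matrix (rows A,C,G,U).
#' @export
read_pfm_tsv <- function(path) {
  df <- read.delim(path, comment.char = "#", check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}

#' Write the candidate table as TSV (1-based positions)
#'
#' @param candidates data.frame from [call_candidates()] (possibly pooled
#'   over references).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_candidates_tsv <- function(candidates, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# zero_pos_1based is 1-based inclusive; the cut falls immediately 5' of it",
             con)
  df <- data.frame(ref_id = candidates$ref_id,
                   zero_pos_1based = candidates$zero_pos + 1L,
                   rci = candidates$rci,
                   coverage = candidates$coverage,
                   window = candidates$window)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}
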