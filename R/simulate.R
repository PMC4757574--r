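## Generative model of the sequencing library: motif-directed digestion of
## synthetic substrate RNAs, partial barcode ligation, and MiSeq-like
## paired reads with full ground truth.
##
## The model follows the wet protocol stage by stage.  T7 transcripts (GGG
## head + diverse region + poly(A) tail) are partially digested by an
## enzyme that cuts at a fixed offset inside its recognition motif.
## Cleavage susceptibility is heterogeneous, as in a real partial digest:
## a few "efficient" sites per substrate are cut at `p_cleave` while the
## remaining motif occurrences are cut at `weak_efficiency`, and every
## other internucleotide bond can break nonspecifically.  This is what
## gives 5'-end libraries their characteristic shape -- sharp coverage
## steps at efficient sites rising above a diffuse baseline of weak and
## background 5' ends -- and efficient sites are kept further apart than
## one mapped-read span so adjacent steps do not sit on each other's
## plateau.  Cleavage leaves 5'-OH ends that the kinase step
## phosphorylates; a 45-nt barcode is then ligated to a fraction of
## fragment 5' ends.  Transcript-start 5' ends carry a triphosphate that
## the ligase cannot join, so they are never barcoded.

# 45-nt barcode: the standard 5' RACE adapter whose 3'-terminal 15 nt are
# the anchor searched for during read preparation.
.default_barcode <- "GCTGATGGCGATGAATGAACACTGCGTTTGCTGGCTTTGATGAAA"

#' Simulation configuration
#'
#' Defaults emulate the study conditions of the assay: five 1000-nt
#' diverse-region substrates flanked by a GGG head and a 30-nt poly(A)
#' tail (1033 nt total), partial motif-directed digestion (three
#' efficient, well-separated sites per substrate cut at 0.9, the
#' remaining motif occurrences at 0.05), background breakage 1e-4 per
#' internucleotide bond, barcode-ligation efficiency 0.15, 2 x 250 nt
#' reads, and 200,000 read pairs.
#'
#' @param n_refs number of reference substrates.
#' @param ref_length diverse-region length (nt).
#' @param head 5' constant sequence.
#' @param tail_length poly(A) tail length.
#' @param motif recognition motif (RNA or DNA alphabet), or `NULL` for
#'   background-only fragmentation (structure-nonspecific control).
#' @param cut_offset 0-based index within the motif before which the cut
#'   falls (0 = 5' of motif base 0; 1 = between bases 0 and 1).
#' @param p_cleave per-template cleavage probability at efficient sites.
#' @param weak_efficiency per-template cleavage probability at the
#'   remaining motif sites.
#' @param n_efficient_sites efficiently-cleaved sites designated per
#'   reference (mutually separated by at least
#'   `efficient_min_separation`).
#' @param efficient_min_separation minimum distance (nt) between efficient
#'   sites; `NULL` = just beyond the longest mappable fragment span,
#'   `read_length - 15 + 10` (the anchor is the 3'-terminal 15 nt of the
#'   barcode, so an anchored mate can map at most `read_length - 15`
#'   fragment bases).
#' @param efficient_min_offset efficient sites are only designated at
#'   least this many nt into the transcript, so the upstream baseline
#'   that the relative-coverage-increase denominator divides by has room
#'   to exist.
#' @param background_break_rate per-bond probability of nonspecific
#'   breakage.
#' @param ligation_efficiency probability that a ligatable fragment 5' end
#'   receives the barcode; the default 0.15 makes the surviving-read
#'   fraction of the default geometry come out near the ~9% recovery
#'   typical of this library chemistry.
#' @param barcode 45-nt barcode whose 3'-terminal 15 nt are the prep
#'   anchor.
#' @param read_length read length (nt).
#' @param n_read_pairs number of read pairs to emit.
#' @param templates_per_ref digested template molecules per reference.
#' @param error_rate per-base substitution error rate in reads.
#' @param seed RNG seed used by [run_simulation()].
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_refs = 5L,
                              ref_length = 1000L,
                              head = "GGG",
                              tail_length = 30L,
                              motif = "ACA",
                              cut_offset = 0L,
                              p_cleave = 0.9,
                              weak_efficiency = 0.05,
                              n_efficient_sites = 3L,
                              efficient_min_separation = NULL,
                              efficient_min_offset = 150L,
                              background_break_rate = 1e-4,
                              ligation_efficiency = 0.15,
                              barcode = .default_barcode,
                              read_length = 250L,
                              n_read_pairs = 200000L,
                              templates_per_ref = 500L,
                              error_rate = 0,
                              seed = 1L) {
  stopifnot(n_refs >= 1L, ref_length >= 1L, tail_length >= 0L,
            p_cleave >= 0, p_cleave <= 1,
            weak_efficiency >= 0, weak_efficiency <= 1,
            n_efficient_sites >= 0L,
            background_break_rate >= 0, background_break_rate <= 1,
            ligation_efficiency >= 0, ligation_efficiency <= 1,
            error_rate >= 0, error_rate <= 1,
            read_length >= 1L, n_read_pairs >= 0L, templates_per_ref >= 1L)
  if (!is.null(motif)) {
    stopifnot(nzchar(motif), cut_offset >= 0L, cut_offset < nchar(motif))
  }
  barcode <- canonical_dna(barcode)
  anchor <- prep_config()$anchor
  if (!endsWith(barcode, anchor)) {
    stop("barcode must end with the prep anchor ", anchor)
  }
  if (is.null(efficient_min_separation)) {
    efficient_min_separation <- max(read_length - 15L + 10L, 1L)
  }
  structure(list(n_refs = as.integer(n_refs),
                 ref_length = as.integer(ref_length),
                 head = toupper(head), tail_length = as.integer(tail_length),
                 motif = if (is.null(motif)) NULL else toupper(motif),
                 cut_offset = as.integer(cut_offset),
                 p_cleave = p_cleave,
                 weak_efficiency = weak_efficiency,
                 n_efficient_sites = as.integer(n_efficient_sites),
                 efficient_min_separation =
                   as.integer(efficient_min_separation),
                 efficient_min_offset = as.integer(efficient_min_offset),
                 background_break_rate = background_break_rate,
                 ligation_efficiency = ligation_efficiency,
                 barcode = barcode,
                 read_length = as.integer(read_length),
                 n_read_pairs = as.integer(n_read_pairs),
                 templates_per_ref = as.integer(templates_per_ref),
                 error_rate = error_rate,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# all (possibly overlapping) motif occurrences; 0-based starts
.motif_sites <- function(seq_canonical, motif_canonical) {
  if (nchar(seq_canonical) < nchar(motif_canonical)) return(integer(0))
  Biostrings::start(Biostrings::matchPattern(
    motif_canonical, Biostrings::DNAString(seq_canonical), fixed = TRUE)) - 1L
}

# pick up to n positions pairwise >= sep apart, retrying random orders a
# few times to escape bad layouts
.pick_separated <- function(positions, n, sep, tries = 25L) {
  if (length(positions) == 0L || n == 0L) return(integer(0))
  best <- integer(0)
  for (t in seq_len(tries)) {
    picked <- integer(0)
    for (p in sample(positions)) {
      if (all(abs(p - picked) >= sep)) picked <- c(picked, p)
      if (length(picked) == n) break
    }
    if (length(picked) > length(best)) best <- picked
    if (length(best) == n) break
  }
  sort(best)
}

#' Generate reference substrates and their ground-truth cleavage sites
#'
#' Diverse regions are drawn uniformly over A, C, G, U (near-uniform base
#' composition, as for algorithmically designed diverse substrates),
#' rejecting draws whose pooled set of read-length-mers contains an
#' internal exact repeat (which would cause multimapping), that contain
#' the barcode anchor, or in which `n_efficient_sites` motif sites with
#' the required mutual separation cannot be designated. The GGG head and
#' poly(A) tail are appended, and every motif occurrence in the full span
#' is recorded with its cut coordinate, efficiency and efficient-site flag
#' as ground truth.
#'
#' Uses the current RNG state; seed via [run_simulation()] or `set.seed()`.
#'
#' @param cfg a [simulation_config()].
#' @return list with `refs` (a [reference_set()], RNA) and `sites`
#'   (data.frame: `ref_id`, `site_start`, `cut_pos` (0-based),
#'   `efficient`, `efficiency`; the cut falls immediately 5' of
#'   `cut_pos`).
#' @export
generate_references <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "simulation_config"))
  anchor_rna <- to_rna(cfg$barcode)
  anchor_rna <- substr(anchor_rna, nchar(anchor_rna) - 14L, nchar(anchor_rna))
  motif_t <- if (is.null(cfg$motif)) NULL else canonical_dna(cfg$motif)
  ids <- sprintf("synth1000-%d", seq_len(cfg$n_refs))
  seqs <- character(cfg$n_refs)
  site_tabs <- vector("list", cfg$n_refs)
  for (i in seq_len(cfg$n_refs)) {
    ok <- FALSE
    for (attempt in seq_len(200L)) {
      region <- paste(sample(c("A", "C", "G", "U"), cfg$ref_length,
                             replace = TRUE), collapse = "")
      full <- paste0(to_rna(cfg$head), region,
                     strrep("A", cfg$tail_length))
      if (grepl(anchor_rna, full, fixed = TRUE)) next
      seqs[i] <- full
      if (.has_internal_repeat(seqs[seq_len(i)], cfg$read_length)) {
        seqs[i] <- ""
        next
      }
      if (is.null(motif_t)) {
        site_tabs[[i]] <- data.frame(ref_id = character(0),
                                     site_start = integer(0),
                                     cut_pos = integer(0),
                                     efficient = logical(0),
                                     efficiency = numeric(0))
        ok <- TRUE
        break
      }
      st <- .motif_sites(canonical_dna(full), motif_t)
      st_eligible <- st[st >= cfg$efficient_min_offset]
      want <- min(cfg$n_efficient_sites, length(st_eligible))
      eff_sites <- .pick_separated(st_eligible, want,
                                   cfg$efficient_min_separation)
      if (length(eff_sites) < want) {
        seqs[i] <- ""
        next  # layout cannot host the designated efficient sites
      }
      efficient <- st %in% eff_sites
      site_tabs[[i]] <- data.frame(
        ref_id = rep(ids[i], length(st)),
        site_start = st,
        cut_pos = st + cfg$cut_offset,
        efficient = efficient,
        efficiency = ifelse(efficient, cfg$p_cleave, cfg$weak_efficiency),
        stringsAsFactors = FALSE)
      ok <- TRUE
      break
    }
    if (!ok) stop("could not generate an admissible reference ", ids[i])
  }
  names(seqs) <- ids
  refs <- reference_set(seqs, alphabet = "RNA")
  list(refs = refs, sites = do.call(rbind, site_tabs))
}

# TRUE when any read_length-mer of the pooled set occurs twice
# (poly(A)-only words are tolerated: multimapping there is expected and
# excluded downstream)
.has_internal_repeat <- function(seqs, k) {
  words <- unlist(lapply(seqs, function(s) {
    L <- nchar(s)
    if (L < k) return(character(0))
    st <- seq_len(L - k + 1L)
    substring(s, st, st + k - 1L)
  }))
  words <- words[words != strrep("A", k)]
  anyDuplicated(words) > 0L
}

#' Digest reference templates into fragments
#'
#' Each of `templates_per_ref` template molecules per reference is cut
#' independently: every motif site with its per-site efficiency (at
#' `site_start + cut_offset`), and every other internucleotide bond with
#' probability `background_break_rate`. When the site table has no
#' `efficiency` column every site is cut with `cfg$p_cleave` (uniform
#' susceptibility). Fragments are the maximal uncut intervals;
#' concatenating a template's fragments in order reconstructs the
#' reference exactly. `five_prime_is_cleavage` marks fragment 5' ends
#' arising from motif cleavage.
#'
#' Uses the current RNG state.
#'
#' @param refs a [reference_set()].
#' @param sites ground-truth site table from [generate_references()] (or
#'   any data.frame with `ref_id` and `cut_pos`, optionally `efficiency`).
#' @param cfg a [simulation_config()].
#' @return data.frame with `ref_id`, `template`, `start` (0-based),
#'   `length`, `sequence` (reference alphabet), `five_prime_is_cleavage`.
#' @export
digest_references <- function(refs, sites, cfg) {
  stopifnot(inherits(refs, "reference_set"))
  if (is.null(sites$efficiency)) {
    sites$efficiency <- rep(cfg$p_cleave, nrow(sites))
  }
  nT <- cfg$templates_per_ref
  out <- lapply(names(refs$seqs), function(id) {
    seq_ref <- refs$seqs[[id]]
    L <- nchar(seq_ref)
    s <- sites[sites$ref_id == id, , drop = FALSE]
    ns <- nrow(s)
    # motif cuts: one Bernoulli draw per site per template, all at once
    cut_pos <- integer(0)
    cut_tmpl <- integer(0)
    if (ns > 0L) {
      hit <- runif(ns * nT) < rep(s$efficiency, nT)
      cut_pos <- rep(s$cut_pos, nT)[hit]
      cut_tmpl <- rep(seq_len(nT), each = ns)[hit]
    }
    if (cfg$background_break_rate > 0 && L > 1L) {
      n_bg <- rbinom(nT, L - 1L, cfg$background_break_rate)
      for (tmpl in which(n_bg > 0L)) {
        cut_pos <- c(cut_pos, sample.int(L - 1L, n_bg[tmpl]))
        cut_tmpl <- c(cut_tmpl, rep(tmpl, n_bg[tmpl]))
      }
    }
    keep <- cut_pos > 0L & cut_pos < L
    cut_pos <- cut_pos[keep]
    cut_tmpl <- cut_tmpl[keep]
    dup <- duplicated(cbind(cut_tmpl, cut_pos))
    spl <- split(cut_pos[!dup],
                 factor(cut_tmpl[!dup], levels = seq_len(nT)))
    spl <- lapply(spl, sort)
    starts <- unlist(lapply(spl, function(cc) c(0L, cc)), use.names = FALSE)
    ends <- unlist(lapply(spl, function(cc) c(cc, L)), use.names = FALSE)
    data.frame(
      ref_id = rep(id, length(starts)),
      template = rep(seq_len(nT), lengths(spl) + 1L),
      start = starts,
      length = ends - starts,
      sequence = substring(seq_ref, starts + 1L, ends),
      five_prime_is_cleavage = starts %in% s$cut_pos,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Build a paired-read library from digestion fragments
#'
#' Each fragment with a ligatable 5' end (i.e. not the triphosphate
#' transcript start) is barcoded independently with probability
#' `ligation_efficiency`. Read pairs are then sampled uniformly from the
#' fragment pool (i.e. proportional to fragment multiplicity): R1 is the
#' first `read_length` bases of the (possibly barcoded) fragment, R2 the
#' reverse complement of its last `read_length` bases, both in the DNA
#' alphabet with uniform Q36 qualities and optional substitution errors.
#'
#' Uses the current RNG state.
#'
#' @param fragments data.frame from [digest_references()].
#' @param cfg a [simulation_config()].
#' @return list with `r1`, `r2` (each `id`/`sequence`/`quality`) and
#'   `truth` (per-read provenance: fragment of origin, barcode status, and
#'   whether its 5' end is a cleavage end).
#' @export
make_library <- function(fragments, cfg) {
  n_frag <- nrow(fragments)
  eligible <- fragments$start > 0L  # transcript 5' ends are not ligatable
  barcoded <- eligible & runif(n_frag) < cfg$ligation_efficiency
  frag_dna <- canonical_dna(fragments$sequence)
  with_bar <- ifelse(barcoded, paste0(cfg$barcode, frag_dna), frag_dna)
  if (cfg$n_read_pairs == 0L) {
    empty <- list(id = character(0), sequence = character(0),
                  quality = character(0))
    return(list(r1 = empty, r2 = empty,
                truth = data.frame(read_id = character(0),
                                   ref_id = character(0),
                                   template = integer(0),
                                   frag_start = integer(0),
                                   frag_length = integer(0),
                                   barcoded = logical(0),
                                   five_prime_is_cleavage = logical(0))))
  }
  idx <- sample.int(n_frag, cfg$n_read_pairs, replace = TRUE)
  full <- with_bar[idx]
  len <- nchar(full)
  r1_seq <- substr(full, 1L, cfg$read_length)
  r2_seq <- reverse_complement(
    substr(full, pmax(1L, len - cfg$read_length + 1L), len), "DNA")
  if (cfg$error_rate > 0) {
    r1_seq <- .add_substitution_errors(r1_seq, cfg$error_rate)
    r2_seq <- .add_substitution_errors(r2_seq, cfg$error_rate)
  }
  ids <- sprintf("read%07d", seq_len(cfg$n_read_pairs))
  q36 <- strrep("E", max(nchar(r1_seq), nchar(r2_seq), 1L))  # Phred 36
  list(r1 = list(id = ids, sequence = r1_seq,
                 quality = substr(rep(q36, length(r1_seq)), 1L,
                                  nchar(r1_seq))),
       r2 = list(id = ids, sequence = r2_seq,
                 quality = substr(rep(q36, length(r2_seq)), 1L,
                                  nchar(r2_seq))),
       truth = data.frame(read_id = ids,
                          ref_id = fragments$ref_id[idx],
                          template = fragments$template[idx],
                          frag_start = fragments$start[idx],
                          frag_length = fragments$length[idx],
                          barcoded = barcoded[idx],
                          five_prime_is_cleavage =
                            fragments$five_prime_is_cleavage[idx],
                          stringsAsFactors = FALSE))
}

.add_substitution_errors <- function(seqs, rate) {
  n_err <- rbinom(length(seqs), nchar(seqs), rate)
  hit <- which(n_err > 0L)
  for (i in hit) {
    pos <- sample.int(nchar(seqs[i]), n_err[i])
    s <- strsplit(seqs[i], "")[[1]]
    for (p in pos) {
      s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1L)
    }
    seqs[i] <- paste(s, collapse = "")
  }
  seqs
}

#' Run the full simulation and write its file set
#'
#' Seeds the RNG from `cfg$seed`, generates references, digests them,
#' builds the library, and writes: `reads_R1.fastq[.gz]`,
#' `reads_R2.fastq[.gz]`, `references.fasta`, `truth.tsv` (per-read
#' provenance), `sites.tsv` (ground-truth cleavage sites) and
#' `config.yaml` (the resolved configuration, for provenance). Re-running
#' with the same config is byte-identical.
#'
#' @param cfg a [simulation_config()].
#' @param outdir output directory (created if absent).
#' @param gzip compress the FASTQ files.
#' @return (invisibly) list with `paths`, `refs`, `sites`, `truth`.
#' @export
run_simulation <- function(cfg = simulation_config(), outdir, gzip = FALSE) {
  stopifnot(inherits(cfg, "simulation_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  gen <- generate_references(cfg)
  fragments <- digest_references(gen$refs, gen$sites, cfg)
  lib <- make_library(fragments, cfg)
  ext <- if (gzip) ".fastq.gz" else ".fastq"
  paths <- list(
    r1 = file.path(outdir, paste0("reads_R1", ext)),
    r2 = file.path(outdir, paste0("reads_R2", ext)),
    references = file.path(outdir, "references.fasta"),
    truth = file.path(outdir, "truth.tsv"),
    sites = file.path(outdir, "sites.tsv"),
    config = file.path(outdir, "config.yaml"))
  write_fastq(lib$r1$id, lib$r1$sequence, lib$r1$quality, paths$r1)
  write_fastq(lib$r2$id, lib$r2$sequence, lib$r2$quality, paths$r2)
  write_reference_fasta(gen$refs, paths$references)
  write.table(lib$truth, paths$truth, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(gen$sites, paths$sites, sep = "\t", quote = FALSE,
              row.names = FALSE)
  cfg_out <- unclass(cfg)
  cfg_out$motif <- if (is.null(cfg$motif)) "none" else cfg$motif
  yaml::write_yaml(cfg_out, paths$config)
  message(sprintf("simulated %d read pairs from %d fragments; truth table: %s",
                  cfg$n_read_pairs, nrow(fragments), paths$truth))
  invisible(list(paths = paths, refs = gen$refs, sites = gen$sites,
                 truth = lib$truth))
}
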