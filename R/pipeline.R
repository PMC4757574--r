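## End-to-end orchestration: prep -> map -> profiles -> candidates ->
## motif, with every stage report written next to the outputs.

#' Pipeline configuration
#'
#' @param r1 path to the R1 FASTQ file.
#' @param r2 optional path to the R2 FASTQ file (processed through the
#'   identical prep path; surviving fragments are pooled).
#' @param references path to the reference FASTA.
#' @param outdir output directory (created if absent).
#' @param prep a [prep_config()].
#' @param sites a [site_call_config()].
#' @param motif_opts list of [build_motif()] options (`ic_min`,
#'   `modal_min`, `min_support`, `small_sample_correction`).
#' @param write_logo also attempt the best-effort PNG logo.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(r1, r2 = NULL, references, outdir,
                            prep = prep_config(),
                            sites = site_call_config(),
                            motif_opts = list(),
                            write_logo = FALSE) {
  structure(list(r1 = r1, r2 = r2, references = references,
                 outdir = outdir, prep = prep, sites = sites,
                 motif_opts = motif_opts, write_logo = write_logo),
            class = "pipeline_config")
}

#' Run the cleavage-site identification pipeline
#'
#' Executes read preparation, exact mapping, coverage/RCI profiling,
#' candidate calling and motif construction, writing every stage report:
#' `prep_report.tsv`, `mapping_summary.tsv`, `coverage.tsv`,
#' `candidates.tsv`, `pfm.tsv`, optionally `logo.png`, `motif_report.txt`
#' and `summary.json`. Partial outputs are retained when a stage fails.
#'
#' @param cfg a [pipeline_config()].
#' @param verbose log stage progress to stderr.
#' @return list with `motif` (a `motif_model`, or NULL when no candidate
#'   windows were found), `report` (one-line motif report), `candidates`,
#'   `profiles`, `prep_counts`, `map_summary`, `paths`.
#' @export
run_pipeline <- function(cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  paths <- list(prep_report = file.path(cfg$outdir, "prep_report.tsv"),
                mapping_summary = file.path(cfg$outdir, "mapping_summary.tsv"),
                coverage = file.path(cfg$outdir, "coverage.tsv"),
                candidates = file.path(cfg$outdir, "candidates.tsv"),
                pfm = file.path(cfg$outdir, "pfm.tsv"),
                logo = file.path(cfg$outdir, "logo.png"),
                motif_report = file.path(cfg$outdir, "motif_report.txt"),
                summary = file.path(cfg$outdir, "summary.json"))

  say("[prep] reading references from %s", cfg$references)
  refs <- read_reference_fasta(cfg$references)

  say("[prep] preparing reads")
  prep1 <- prepare_reads(cfg$r1, cfg$prep, verbose = verbose)
  counts <- prep1$counts
  frag_tabs <- list(prep1$fragments)
  if (!is.null(cfg$r2)) {
    prep2 <- prepare_reads(cfg$r2, cfg$prep, verbose = verbose)
    counts <- counts + prep2$counts
    frag_tabs[[2L]] <- prep2$fragments
  }
  write_prep_report(counts, paths$prep_report)
  if (counts[["input"]] == 0L) {
    stop("input FASTQ contains no reads (prep report written to ",
         paths$prep_report, ")")
  }
  fragments <- do.call(rbind, frag_tabs)
  say("[prep] %d/%d reads surviving", nrow(fragments), counts[["input"]])

  say("[map] exact mapping of %d fragments", nrow(fragments))
  mappings <- map_fragments(fragments$fragment, refs,
                            min_length = cfg$prep$min_length_after_trim)
  map_summary <- write_mapping_summary(mappings, paths$mapping_summary)
  say("[map] %d mapped, %d unmapped, %d multimapped",
      map_summary$mapped, map_summary$unmapped, map_summary$multimapped)

  say("[profiles] building coverage and RCI tracks")
  profiles <- build_profiles(mappings, refs)
  write_coverage_tsv(profiles, paths$coverage)

  say("[callsites] calling candidates")
  candidates <- do.call(rbind, lapply(profiles, function(p)
    call_candidates(p, refs, cfg$sites)))
  rownames(candidates) <- NULL
  write_candidates_tsv(candidates, paths$candidates)

  motif <- NULL
  if (nrow(candidates) > 0L) {
    motif <- do.call(build_motif,
                     c(list(windows = candidates$window,
                            flank = cfg$sites$flank),
                       cfg$motif_opts))
    export_logo(motif, paths$pfm,
                image_path = if (cfg$write_logo) paths$logo else NULL)
    report <- motif_report(motif)
  } else {
    report <- "no conserved motif (support 0 windows)"
    warning("zero candidate cleavage sites; no motif built")
  }
  writeLines(report, paths$motif_report)
  say("[motif] %s", report)

  summary <- list(
    reads = as.list(counts),
    mapping = as.list(map_summary),
    n_candidates = nrow(candidates),
    motif = report)
  jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE,
                       pretty = TRUE)
  list(motif = motif, report = report, candidates = candidates,
       profiles = profiles, prep_counts = counts,
       map_summary = map_summary, paths = paths)
}

#' Fetch the original substrate records from GenBank (network required)
#'
#' Downloads the five 1033-nt synthetic substrate records
#' (AB610944.1-AB610948.1) from NCBI E-utilities into a FASTA file, so the
#' published k-mer saturation percentages can be reproduced on the real
#' substrate pool. This is the only operation in the package that needs
#' network access; everything else runs fully offline (a synthetic
#' stand-in substrate set ships with the package).
#'
#' @param dest output FASTA path.
#' @param accessions GenBank accession ids.
#' @return `dest` invisibly, or an error when offline.
#' @export
fetch_substrates <- function(dest,
                             accessions = c("AB610944.1", "AB610945.1",
                                            "AB610946.1", "AB610947.1",
                                            "AB610948.1")) {
  url <- paste0("https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi",
                "?db=nuccore&id=", paste(accessions, collapse = ","),
                "&rettype=fasta&retmode=text")
  utils::download.file(url, dest, quiet = TRUE)
  invisible(dest)
}
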