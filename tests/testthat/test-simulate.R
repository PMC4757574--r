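# Generative model: references, digestion, library construction.

small_cfg <- function(...) {
  simulation_config(n_read_pairs = 2000L, templates_per_ref = 50L, ...)
}

test_that("generated references have the full transcript anatomy", {
  set.seed(1)
  gen <- generate_references(simulation_config())
  expect_equal(length(gen$refs), 5L)
  expect_true(all(nchar(gen$refs$seqs) == 1033L))
  expect_true(all(startsWith(gen$refs$seqs, "GGG")))
  expect_true(all(endsWith(gen$refs$seqs, strrep("A", 30))))
  expect_equal(gen$refs$alphabet, "RNA")
})

test_that("diverse regions are near-uniform in base composition", {
  set.seed(2)
  gen <- generate_references(simulation_config())
  regions <- substr(gen$refs$seqs, 4, 1003)
  pooled <- paste(regions, collapse = "")
  counts <- table(strsplit(pooled, "")[[1]])
  n <- nchar(pooled)
  # each base within 3 sigma of Binomial(n, 1/4)
  sigma <- sqrt(n * 0.25 * 0.75)
  expect_true(all(abs(counts - n / 4) < 3 * sigma))
})

test_that("ground-truth sites enumerate every motif occurrence", {
  set.seed(3)
  cfg <- simulation_config(motif = "ACA", cut_offset = 0L)
  gen <- generate_references(cfg)
  for (id in names(gen$refs$seqs)) {
    s <- chartr("U", "T", gen$refs$seqs[[id]])
    # brute-force overlapping occurrence scan as the oracle
    found <- integer(0)
    for (p in seq_len(nchar(s) - 2L)) {
      if (substr(s, p, p + 2L) == "ACA") found <- c(found, p - 1L)
    }
    tab <- gen$sites[gen$sites$ref_id == id, ]
    expect_equal(sort(tab$site_start), found)
    expect_equal(tab$cut_pos, tab$site_start)  # cut_offset 0
    # occurrence count in the expected Poisson-style band around 1031/64
    expect_gt(nrow(tab), 5L)
    expect_lt(nrow(tab), 35L)
  }
  # efficient sites respect separation and offset
  eff <- gen$sites[gen$sites$efficient, ]
  expect_equal(as.integer(table(eff$ref_id)[names(gen$refs$seqs)]), rep(3L, 5))
  expect_true(all(eff$site_start >= cfg$efficient_min_offset))
  for (id in unique(eff$ref_id)) {
    gaps <- diff(sort(eff$site_start[eff$ref_id == id]))
    expect_true(all(gaps >= cfg$efficient_min_separation))
  }
})

test_that("deterministic digestion limits behave as expected", {
  ref <- reference_set(c(x = "GGAACAGGTTGGCCAATTGG"))
  sites <- data.frame(ref_id = "x", site_start = 3L, cut_pos = 3L)
  cfg1 <- simulation_config(p_cleave = 1, background_break_rate = 0,
                            templates_per_ref = 1L)
  frags <- digest_references(ref, sites, cfg1)
  expect_equal(nrow(frags), 2L)
  expect_equal(frags$start, c(0L, 3L))
  expect_equal(frags$sequence, c("GGA", "ACAGGTTGGCCAATTGG"))
  expect_equal(frags$five_prime_is_cleavage, c(FALSE, TRUE))

  cfg0 <- simulation_config(p_cleave = 0, background_break_rate = 0,
                            templates_per_ref = 1L)
  frags0 <- digest_references(ref, sites, cfg0)
  expect_equal(nrow(frags0), 1L)
  expect_equal(frags0$sequence, ref$seqs[["x"]])
})

test_that("digestion conserves sequence and matches binomial expectations", {
  set.seed(21)
  region <- random_dna(400)
  # plant 10 well-separated sites by construction
  starts <- seq(10L, 370L, by = 40L)
  for (st in starts) substr(region, st + 1L, st + 3L) <- "ACA"
  ref <- reference_set(c(x = region))
  sites <- data.frame(ref_id = "x", site_start = starts, cut_pos = starts)
  cfg <- simulation_config(p_cleave = 0.5, background_break_rate = 0,
                           templates_per_ref = 400L)
  frags <- digest_references(ref, sites, cfg)
  # conservation: per template, concatenation reconstructs the reference
  for (tmpl in sample(unique(frags$template), 20)) {
    ft <- frags[frags$template == tmpl, ]
    ft <- ft[order(ft$start), ]
    expect_identical(paste(ft$sequence, collapse = ""), region)
  }
  # mean fragments per template = 1 + 10 * 0.5, within 4 sigma
  per_tmpl <- table(frags$template)
  expect_lt(abs(mean(per_tmpl) - 6), 4 * sqrt(10 * 0.25 / 400))
  # every cleavage-flagged start is a ground-truth cut
  expect_true(all(frags$start[frags$five_prime_is_cleavage] %in% starts))
})

test_that("ligation efficiency 0 and 1 bound the anchored read fraction", {
  set.seed(31)
  cfg0 <- small_cfg(ligation_efficiency = 0)
  gen <- generate_references(cfg0)
  frags <- digest_references(gen$refs, gen$sites, cfg0)
  lib0 <- make_library(frags, cfg0)
  anchor <- prep_config()$anchor
  expect_equal(sum(grepl(anchor, lib0$r1$sequence, fixed = TRUE)), 0L)
  expect_false(any(lib0$truth$barcoded))

  cfg1 <- small_cfg(ligation_efficiency = 1)
  lib1 <- make_library(frags, cfg1)
  # every read from a ligatable (non-transcript-start) fragment carries
  # the full barcode at the R1 5' end
  bc <- lib1$truth$barcoded
  expect_true(all(lib1$truth$frag_start[bc] > 0L))
  expect_true(all(startsWith(lib1$r1$sequence[bc], cfg1$barcode)))
  # transcript-start fragments are never ligated (5'-triphosphate)
  expect_true(all(!bc[lib1$truth$frag_start == 0L]))
})

test_that("read geometry and qualities match the configuration", {
  set.seed(41)
  cfg <- small_cfg()
  gen <- generate_references(cfg)
  frags <- digest_references(gen$refs, gen$sites, cfg)
  lib <- make_library(frags, cfg)
  expect_true(all(nchar(lib$r1$sequence) <= cfg$read_length))
  expect_equal(nchar(lib$r1$sequence), nchar(lib$r1$quality))
  expect_true(all(strsplit(paste(unique(lib$r1$quality), collapse = ""),
                           "")[[1]] == "E"))  # Phred 36
  # R2 is the reverse complement of the fragment (+barcode) 3' end
  i <- which(nchar(lib$r2$sequence) < cfg$read_length)[1]
  expect_false(is.na(i))
  tr <- lib$truth[i, ]
  frag <- frags[frags$ref_id == tr$ref_id & frags$template == tr$template &
                  frags$start == tr$frag_start, ][1, ]
  full <- chartr("U", "T", frag$sequence)
  if (tr$barcoded) full <- paste0(cfg$barcode, full)
  expect_equal(lib$r2$sequence[i], reverse_complement(full, "DNA"))
})

test_that("a fixed seed reproduces the library byte for byte", {
  cfg <- small_cfg(seed = 99L)
  d1 <- file.path(tempdir(), "simrep1")
  d2 <- file.path(tempdir(), "simrep2")
  suppressMessages(run_simulation(cfg, d1))
  suppressMessages(run_simulation(cfg, d2))
  for (f in c("reads_R1.fastq", "reads_R2.fastq", "references.fasta",
              "truth.tsv", "sites.tsv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  # a different seed changes the reads but not the reference anatomy
  cfg2 <- small_cfg(seed = 100L)
  d3 <- file.path(tempdir(), "simrep3")
  suppressMessages(run_simulation(cfg2, d3))
  expect_false(identical(readLines(file.path(d1, "reads_R1.fastq")),
                         readLines(file.path(d3, "reads_R1.fastq"))))
  r1 <- read_reference_fasta(file.path(d1, "references.fasta"))
  r3 <- read_reference_fasta(file.path(d3, "references.fasta"))
  expect_equal(nchar(r1$seqs), nchar(r3$seqs))
  unlink(c(d1, d2, d3), recursive = TRUE)
})

test_that("zero read pairs yields empty files plus headers", {
  cfg <- simulation_config(n_read_pairs = 0L, templates_per_ref = 50L)
  d <- file.path(tempdir(), "simzero")
  suppressMessages(run_simulation(cfg, d))
  expect_equal(length(readLines(file.path(d, "reads_R1.fastq"))), 0L)
  tr <- read.delim(file.path(d, "truth.tsv"))
  expect_equal(nrow(tr), 0L)
  expect_true(all(c("read_id", "ref_id", "barcoded") %in% names(tr)))
  unlink(d, recursive = TRUE)
})
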