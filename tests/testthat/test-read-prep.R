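# Quality trimming, ambiguity filtering, anchor stripping.

ANCHOR <- "CTGGCTTTGATGAAA"

test_that("all-high-quality reads pass trimming unchanged", {
  r <- quality_trim("ACGTACGTACGTACGTACGT", strrep("I", 20))
  expect_equal(r$status, "ok")
  expect_equal(r$sequence, "ACGTACGTACGTACGTACGT")
  expect_equal(c(r$start, r$end), c(1L, 20L))
})

test_that("low-quality flanks are trimmed to the best-scoring subread", {
  # qualities 2,2,40,40,40,2,2: only the middle segment scores positively
  qual <- intToUtf8(33L + c(2L, 2L, 40L, 40L, 40L, 2L, 2L))
  r <- quality_trim("AACGTAA", qual)
  expect_equal(c(r$start, r$end), c(3L, 5L))
  expect_equal(r$sequence, "CGT")
  expect_equal(unname(unlist(mott_oracle(qual, 0.05))), c(3L, 5L))
})

test_that("trimming agrees with the exhaustive best-subread oracle", {
  set.seed(202)
  for (i in 1:300) {
    L <- sample(1:60, 1)
    qual <- random_quality(L)
    b <- quality_trim(random_dna(L), qual)
    o <- mott_oracle(qual, 0.05)
    if (o[2] < o[1]) {
      expect_equal(b$status, "empty")
    } else {
      expect_equal(c(b$start, b$end), o,
                   info = sprintf("case %d: qual %s", i, qual))
    }
  }
})

test_that("trimming is idempotent", {
  set.seed(7)
  for (i in 1:50) {
    L <- sample(5:80, 1)
    s <- random_dna(L)
    q <- random_quality(L)
    once <- quality_trim(s, q)
    if (once$status != "ok") next
    twice <- quality_trim(once$sequence, once$quality)
    expect_equal(twice$sequence, once$sequence)
    expect_equal(twice$status, "ok")
  }
})

test_that("ambiguity filter applies after trimming", {
  # N inside the retained subread rejects the read with max_ambiguities 0
  r <- quality_trim("ACNGT", strrep("I", 5), max_ambiguities = 0L)
  expect_equal(r$status, "ambiguous")
  # N in the trimmed-away flank does not
  qual <- intToUtf8(33L + c(2L, 40L, 40L, 40L, 40L))
  r2 <- quality_trim("NACGT", qual, max_ambiguities = 0L)
  expect_equal(r2$status, "ok")
  expect_equal(r2$sequence, "ACGT")
  # tolerated when max_ambiguities allows it
  r3 <- quality_trim("ACNGT", strrep("I", 5), max_ambiguities = 1L)
  expect_equal(r3$status, "ok")
})

test_that("anchor stripping returns the fragment strictly 3' of the anchor", {
  frag <- "ACATTTGGCCAATTGGCAC"
  r <- strip_barcode(paste0("GG", ANCHOR, frag))
  expect_equal(r$status, "ok")
  expect_equal(r$fragment, frag)
  expect_equal(r$orientation, "forward")
  expect_equal(r$anchor_start, 3L)

  expect_equal(strip_barcode(strrep("A", 20))$status, "no_anchor")

  # anchor followed by only 14 bases: shorter than the minimum length
  r14 <- strip_barcode(paste0(ANCHOR, substr(frag, 1, 14)))
  expect_equal(r14$status, "too_short")

  # anchor on the reverse strand: same fragment, orientation recorded
  rc <- reverse_complement(paste0("GG", ANCHOR, frag), "DNA")
  rrev <- strip_barcode(rc)
  expect_equal(rrev$status, "ok")
  expect_equal(rrev$fragment, frag)
  expect_equal(rrev$orientation, "reverse")
})

test_that("stripping output reconstructs the searched orientation", {
  set.seed(31)
  for (i in 1:40) {
    prefix <- random_dna(sample(0:30, 1))
    frag <- random_dna(sample(15:60, 1))
    fwd <- sample(c(TRUE, FALSE), 1)
    read <- paste0(prefix, ANCHOR, frag)
    if (!fwd) read <- reverse_complement(read, "DNA")
    r <- strip_barcode(read)
    if (r$status != "ok") next  # chance second anchor in random flank
    searched <- if (r$orientation == "forward") read else
      reverse_complement(read, "DNA")
    rebuilt <- paste0(substr(searched, 1, r$anchor_start - 1L), ANCHOR,
                      r$fragment)
    expect_identical(rebuilt, searched)
    expect_false(startsWith(r$fragment, ANCHOR) &&
                   !grepl(ANCHOR, frag, fixed = TRUE))
  }
})

test_that("leftmost anchor occurrence wins", {
  frag1 <- "GGGTTTAAACCCGGG"
  read <- paste0("CC", ANCHOR, frag1, ANCHOR, "TTTTTTTTTTTTTTTT")
  r <- strip_barcode(read)
  expect_equal(r$fragment, paste0(frag1, ANCHOR, "TTTTTTTTTTTTTTTT"))
})

test_that("exact anchor search is equivalent to the aligner score model", {
  # under match +1 / mismatch -5 / gap -5 with minimum score 15, a 15-nt
  # anchor reaches the threshold exactly when the read contains the full
  # anchor verbatim: edge insertions leave it intact, while any edit that
  # touches the anchor keeps the best score strictly below 15
  expect_equal(local_score(ANCHOR, ANCHOR), 15)
  variants <- single_edit_variants(ANCHOR)
  scores <- unname(vapply(variants, function(v) local_score(ANCHOR, v),
                          numeric(1)))
  contains <- grepl(ANCHOR, variants, fixed = TRUE)
  expect_identical(scores >= 15, contains)
  expect_true(all(scores[!contains] < 15))
  # and exact substring search classifies the same reads as anchored
  hits <- strip_barcode(paste0(variants, strrep("G", 20)))
  expect_identical(hits$status == "ok", contains)
})

test_that("prepare_reads filters and counts every category", {
  good <- paste0("GG", ANCHOR, random_dna(20))
  noanchor <- random_dna(40)
  short <- paste0(ANCHOR, "ACGTACGTACGTAC")           # 14 nt after anchor
  lowq <- paste0("GG", ANCHOR, random_dna(20))
  ambig <- paste0("GG", chartr("G", "N", ANCHOR), random_dna(20))
  seqs <- c(good, noanchor, short, lowq, ambig)
  quals <- c(strrep("I", nchar(good)), strrep("I", nchar(noanchor)),
             strrep("I", nchar(short)), strrep("#", nchar(lowq)),
             strrep("I", nchar(ambig)))
  p <- tmp_fastq(sprintf("r%d", 1:5), seqs, quals)
  res <- prepare_reads(p)
  expect_equal(unname(res$counts["input"]), 5L)
  expect_equal(unname(res$counts["quality_rejected"]), 1L)
  expect_equal(unname(res$counts["no_anchor"]), 1L)
  expect_equal(unname(res$counts["too_short"]), 1L)
  expect_equal(unname(res$counts["ambiguous"]), 1L)
  expect_equal(unname(res$counts["surviving"]), 1L)
  expect_equal(res$fragments$id, "r1")
  expect_equal(nchar(res$fragments$fragment), 20L)
})
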