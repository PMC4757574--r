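---
title: "Mapping endoribonuclease cleavage sites from barcoded 5'-end sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping endoribonuclease cleavage sites from barcoded 5'-end sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cleavemap)
```

## The assay and the computational problem

Sequence-specific endoribonucleases — RNA interferases such as MazF and
its homologues, the toxin halves of many bacterial toxin–antitoxin
modules — cleave single-stranded RNA at short recognition motifs
(typically 3–7 nt). Which motif a given enzyme recognises is usually
unknown, and classical assays (primer extension, mass spectrometry,
gels) do not scale.

The assay cleavemap supports determines the motif by sequencing the 5'
ends that the enzyme creates. Synthetic substrate RNAs of high sequence
diversity (here: a GGG transcription head, a 1000-nt diverse region,
and a 30-nt poly(A) tail; 1033 nt in total) are digested in vitro.
Cleavage leaves 5'-OH ends; a polynucleotide-kinase step phosphorylates
them, and a 45-nt RNA barcode is ligated onto a fraction of fragment 5'
ends. After standard paired-end sequencing (2 x 250 nt), any read that
contains the barcode's 3'-terminal 15 nt (the *anchor*,
`CTGGCTTTGATGAAA`) marks the next base downstream as a genuine RNA 5'
end. Mapped onto the known substrate sequences, those bases pile up as
step increases in coverage exactly at the cleavage positions, and
aligning the sequence windows around the steps exposes the motif.

The pipeline is:

1. **Quality/ambiguity trimming** — modified-Mott trimming at an
   error-probability limit, then an ambiguity filter.
2. **Anchor detection and 5' stripping** — exact search for the anchor
   on both strands; everything 3' of its leftmost occurrence is the
   cleavage-derived fragment; fragments shorter than 15 nt are
   discarded.
3. **Exact mapping** — the fragment must match a reference substring
   full-length with zero mismatches; fragments matching more than one
   location are excluded.
4. **Coverage and relative coverage increase (RCI)** — per-position
   depth, and the step statistic `rci[n] = coverage[n]/coverage[n-1]`.
5. **Candidate calling** — positions with defined RCI of at least
   `min_rci`, coverage strictly above `min_coverage`, ranked by RCI;
   the top `top_k_per_ref` per reference are kept, and ±`flank` base
   windows around each *zero position* (the first base 3' of the cut)
   are extracted.
6. **Motif model** — the windows are stacked into a position frequency
   matrix (PFM); per-column information content
   `ic_j = 2 + sum_b f_bj log2 f_bj` (bits) and a consensus call
   summarise the motif; the cut always falls between motif positions
   −1 and 0 by construction.

## Coordinates and alphabets

Internally every position is 0-based with half-open intervals; every
file the package writes reports 1-based inclusive coordinates and says
so in a header comment. References are RNA (U) as synthesized while
reads are DNA (T); all comparisons run in a canonical T-alphabet and
all motif output uses U whenever the references are RNA, which is why
the reported motifs read ACA/UAC rather than ACA/TAC.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `quality_limit` | 0.05 | error-probability limit of the Mott trimmer |
| `max_ambiguities` | 0 | N bases tolerated after trimming |
| `anchor` | `CTGGCTTTGATGAAA` | barcode 3'-terminal 15-mer |
| `min_length_after_trim` | 15 nt | minimum fragment length |
| `min_coverage` | 1000 reads | candidate filter, strictly greater, applied at the zero position itself |
| `top_k_per_ref` | 5 | candidates kept per reference |
| `flank` | 5 nt | window half-width (11-nt windows) |
| `min_rci` | 2.0 | minimum coverage step (a doubling) |
| `ic_min`, `modal_min` | 1.0 bit, 0.8 | column-calling thresholds |
| `min_support` | 5 windows | minimum support for any consensus |

Three of these deserve comment.

**`min_rci` (default 2).** The candidate definition ranks positions by
relative coverage increase, but a position whose coverage merely equals
its neighbour's (RCI ≈ 1) is not a step at all — it is the interior of
a covered interval. Requiring at least a doubling removes those plateau
positions deterministically instead of letting them fill the top-k list
whenever a reference has fewer genuine steps than `top_k_per_ref`.
Setting `min_rci = 0` restores the permissive rank-only behaviour.

**`min_support` (default 5).** Information content of a single window
is 2 bits at every column; any consensus rule without a support floor
would therefore "discover" a perfectly conserved motif in one stray
window. Five windows — one reference's worth in the 5-per-reference
design — is the floor below which the package reports *no conserved
motif* rather than a consensus.

**Small-sample correction.** The information content field is the
uncorrected `2 + sum f log2 f`; the standard `3/(2 ln 2 n)` correction
can be applied to the column-calling step with
`small_sample_correction = TRUE`, but the uncorrected formula is the
documented contract (logo programs differ on this by version, so the
choice is explicit rather than inherited).

## Numerical and procedural choices

* **Mott trimming** keeps the contiguous subread maximising
  `sum(limit − 10^(−Q/10))`; ties break toward the earliest end, then
  the earliest start. With integer Phred scores and `limit = 0.05`
  per-base scores are never exactly zero, so ties essentially never
  occur in practice, but the rule is fixed for determinism. Trimming is
  idempotent; the ambiguity filter applies *after* trimming.
* **Anchor matching is exact substring search.** Under the reference
  score model (match +1, mismatch −5, gap −5, minimum score 15), a
  15-nt anchor reaches the threshold exactly when it occurs verbatim:
  any edit touching the anchor caps the best local score below 15. The
  test suite proves this by brute force over all single-edit anchor
  variants against a local aligner. The leftmost occurrence wins;
  forward orientation is searched before the reverse complement.
* **Multimapped fragments are excluded**, not placed randomly:
  exclusion is deterministic and conservative for a step-detection
  statistic. In practice only poly(A)-tail fragments multimap on these
  substrates.
* **RCI at positions with zero upstream coverage is undefined** (not 0,
  not infinity) and such positions are never candidates; this avoids
  pseudocount artifacts.
* **The coverage filter is strict (`> 1000`) and applies at the zero
  position** — the stepped-up base — not at its predecessor; both
  choices are configurable.
* **Ranking is filter-then-rank:** positions failing the coverage
  filter are removed before RCI ordering.
* **Candidate tie-breaks:** equal RCI is resolved by larger coverage,
  then smaller position.
* **Windows at reference edges are N-padded;** N-containing columns
  reduce that column's total rather than being imputed, keeping column
  frequencies unbiased.

## The simulator's generative model

`run_simulation()` emulates the library construction end to end so that
every pipeline stage is testable without any sequencing data:

1. **References.** Diverse regions drawn uniformly over A/C/G/U
   (near-uniform base composition, like algorithm-designed diverse
   substrates), flanked by GGG and a 30-nt poly(A) tail. Draws are
   rejected if any read-length-mer repeats within the pool (which would
   cause multimapping), if the anchor occurs in a reference, or if the
   designated efficient sites cannot be placed.
2. **Digestion.** Every motif occurrence is a potential site, but
   susceptibility is heterogeneous, as in a real partial digest:
   `n_efficient_sites` (default 3) sites per reference are cut with
   probability `p_cleave` (0.9) per template molecule, the remaining
   occurrences with `weak_efficiency` (0.05), and every other
   internucleotide bond breaks with `background_break_rate` (1e-4).
   `templates_per_ref` (500) template molecules are digested
   independently; fragments are the maximal uncut intervals, and
   concatenating a template's fragments reconstructs the reference
   exactly.
3. **Ligation.** Fragment 5' ends arising from cleavage or breakage
   (5'-OH, phosphorylated by the kinase step) are barcoded with
   probability `ligation_efficiency`; transcript-start 5' ends carry a
   triphosphate the ligase cannot join and are never barcoded.
4. **Reads.** Pairs are sampled uniformly from the fragment pool; R1 is
   the first 250 nt of the (possibly barcoded) fragment, R2 the reverse
   complement of the last 250 nt, with uniform Q36 qualities and an
   optional substitution-error rate (default 0). A truth table records
   every read's fragment of origin, barcode status and whether its 5'
   end is a cleavage end.

**Why heterogeneous susceptibility?** If every motif occurrence were
cut with the same high probability, coverage would converge to the same
depth at every site and the relative coverage increase would converge
to 1 everywhere — the step statistic the assay relies on would be
degenerate. Real partial digests are not like that: cleavage efficiency
depends strongly on sequence and structural context (fluorometric
assays show order-of-magnitude differences between, say, UAC and UAU
substrates for the same enzyme), and 5'-end libraries show sharp steps
at a subset of well-cleaved positions rising above a diffuse baseline
of weakly-cleaved and nonspecifically broken ends. The simulator models
exactly that structure.

**Calibrated geometry.** Three generator defaults are calibrated to
observable properties of this class of library rather than taken from
first principles:

* `ligation_efficiency = 0.15` makes the default geometry's
  surviving-read fraction come out at ~8–9%, the recovery typical of
  barcode-ligation libraries of this design (ligation of a 5' adapter
  is inefficient, and unligated molecules dominate the raw reads).
* Efficient sites are separated by more than one mappable fragment
  span (`read_length − 15 + 10 = 245` nt by default). An anchored mate
  can map at most `read_length − anchor length` fragment bases, so
  with closer spacing an efficient site's coverage step would sit on
  its upstream neighbour's plateau instead of rising from the baseline
  and the step ratio would collapse toward 1.
* Efficient sites are only designated ≥ 150 nt (`efficient_min_offset`)
  into the transcript, leaving upstream room for the baseline coverage
  that the RCI denominator divides by; a 5'-proximal site has no
  upstream catchment and its RCI is undefined in any library.

**What the simulator does not model:** PCR duplication bias and jackpot
effects, position-dependent quality decay, indel sequencing errors,
secondary-structure-dependent cleavage (the diverse substrates are
designed not to form stable structures), and structure-specific
enzymes such as RNase III — the negative control is emulated by
background-only breakage (`motif = NULL`), which reproduces the
relevant observable (no conserved motif) without modelling hairpin
recognition. Passing tests on simulated data therefore demonstrate the
pipeline's correctness and the assay's statistical logic, not
robustness to every artifact of a real instrument run.

## Substrate diversity evaluation

`kmer_coverage()` reports which fraction of the `4^k` possible words a
substrate pool contains (forward strand only — the enzymes act on the
single-stranded RNA as synthesized). This bounds what the assay can
detect: a motif absent from the substrates can never produce a step.
On the bundled synthetic stand-in pool (five uniform-random 1033-nt
transcripts) the saturation is 100% of triplets, 100% of quartets,
99.3% of pentads and 26.2% of heptads — uniform-random substrates
saturate short words quickly, but heptad-recognising enzymes
(MazF-hw-class cutters) are out of reach at this pool size, matching
the known limitation of 1000-nt substrate designs. Note that
algorithm-designed substrate pools differ slightly from uniform-random
ones (designed pools trade a little k-mer saturation for structural
constraints), so the synthetic percentages are not expected to equal
those of any specific published substrate set; `fetch_substrates()`
retrieves the original GenBank records for users who want the real
pool. `motif_free_sequences()` supports the complementary genome-scale
question — which transcripts *lack* a motif entirely and therefore
escape cleavage — as an exact-string scan.

## Problem sizes used in the tests and acceptance script

The unit tests run on small constructed instances plus a handful of
full-scale simulations (5 references x 1033 nt, 200,000 read pairs).
The acceptance checks run the full pipeline across 20 seeds per motif
(ACA with the cut 5' of the motif, UAC with the cut inside it), 10
background-only control seeds, and one fully-ligated
five-sites-per-reference scenario; `scripts/acceptance.R` reports the
same quantities over 10 seeds per motif. These sizes give stable
recovery statistics (the per-seed consensus-recovery probability at
defaults is effectively 1, with 13–15 of 15 efficient sites typically
surviving all filters, and every surviving window at a true cleavage
position) while keeping a complete run in minutes on one CPU.

## Known limitations

* Exact full-length mapping discards any fragment with a sequencing
  error; the pipeline is designed for high-quality short reads on
  small, fully-known reference pools, not for genome-scale or
  error-tolerant mapping.
* The candidate statistic detects step *increases* only; an enzyme
  leaving 3' ends (or a protocol capturing 3' ends) needs a mirrored
  statistic that is not implemented.
* Motifs longer than the window (`2*flank + 1` nt) cannot be
  characterised, and substrate diversity bounds detectable motif length
  in any case (see above).
* The consensus caller reports a single contiguous motif containing
  position 0 (or −1); enzymes with two disjoint specificity blocks
  would need manual inspection of the PFM.
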