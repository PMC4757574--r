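# cleavemap

Determine the recognition motif and cut position of sequence-specific
endoribonucleases (RNA interferases such as MazF and its homologues)
from barcoded 5'-end sequencing of digested synthetic substrate RNAs.

Bacterial toxin–antitoxin toxins of the MazF family cleave
single-stranded RNA at short motifs (ACA for *E. coli* MazF; UAC for
the *Pseudomonas putida* homologue), reshaping translation under
stress. The assay this package analyses digests a pool of
high-diversity synthetic RNAs with the enzyme, phosphorylates the
resulting 5'-OH ends, ligates a 45-nt barcode onto a fraction of them,
and sequences the library. A read containing the barcode's 3'-terminal
15-nt anchor (`CTGGCTTTGATGAAA`) pinpoints a genuine RNA 5' end at the
next base; mapped to the substrate references, cleavage-derived 5' ends
appear as step increases in coverage.

For each reference position *n* the pipeline computes the coverage
*c(n)* (mapped anchored fragments overlapping *n*) and the **relative
coverage increase** RCI(*n*) = *c(n)* / *c(n − 1)*. Candidate cleavage
sites are positions with *c(n)* > 1000 and a large RCI; the top five
per reference are kept, and the ±5-base windows around the step (the
*zero position*, numbered 0, with the cut between −1 and 0) are stacked
into a position frequency matrix. Per-column information content

    ic_j = 2 + Σ_b f_bj · log2 f_bj   (bits)

and a consensus call (columns with ≥ 1 bit and modal frequency ≥ 0.8,
with a minimum support of 5 windows) summarise the motif.

The package also provides:

* a full **generative simulator** of the library (partial
  motif-directed digestion with heterogeneous site susceptibility,
  background fragmentation, partial barcode ligation, paired MiSeq-like
  reads, complete ground truth) so every stage is testable without
  sequencing data;
* a **substrate k-mer saturation** evaluator (which fraction of all
  4^k words a substrate pool contains bounds which motifs the assay can
  detect) and a **motif-free transcript** scanner;
* a thin command-line interface (`inst/cli/cleavemap`) with
  subcommands `simulate`, `prep`, `map`, `callsites`, `motif`, `kmers`,
  `motif-free`, `run-all`.

## Worked example

Simulate a MazF-like digestion (motif ACA, cut 5' of the first A) and
run the pipeline:

```r
library(cleavemap)

cfg <- simulation_config(motif = "ACA", cut_offset = 0L, seed = 1L)
sim <- run_simulation(cfg, outdir = "sim")
#> simulated 200000 read pairs from 11281 fragments; truth table: sim/truth.tsv

res <- run_pipeline(pipeline_config(
  r1 = sim$paths$r1, r2 = sim$paths$r2,
  references = sim$paths$references, outdir = "out"))
res$report
#> [1] "consensus=ACA (positions 0..2), cut between -1 and 0, support 13 windows"
```

About 8.5% of the raw reads survive preparation (they carry the
barcode anchor; the rest derive from unligated molecules), all
surviving fragments map exactly, and the 13 windows entering the motif
model all sit at ground-truth efficient cleavage sites (`sim/sites.tsv`
holds the truth). The consensus line says: the conserved motif is ACA
occupying window positions 0–2, i.e. the enzyme cuts immediately 5' of
the ACA. Per-stage reports (`prep_report.tsv`, `mapping_summary.tsv`,
`coverage.tsv`, `candidates.tsv`, `pfm.tsv`, `summary.json`) are
written to `out/`.

Substrate diversity of the bundled synthetic substrate pool:

```r
refs <- read_reference_fasta(system.file("extdata",
          "substrates_synthetic.fasta", package = "cleavemap"))
kmer_coverage_table(refs, c(3, 4, 5, 7))
#>   k distinct_observed possible percent
#> 1 3                64       64   100.0
#> 2 4               256      256   100.0
#> 3 5              1017     1024    99.3
#> 4 7              4299    16384    26.2
```

Short words saturate; heptad-recognising enzymes are beyond what five
1-kb substrates can characterise. (The original substrate records can
be fetched from GenBank with `fetch_substrates()` on a machine with
network access.)

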