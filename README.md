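# barcodetrack

De novo consensus DNA barcodes from noisy long-read amplicon sequencing.

DNA barcoding identifies species from a short standardized marker — for
animals, typically a ~658 bp fragment of the mitochondrial *COI* gene.
Because congeneric species often differ by only ~2%, a usable barcode must
be accurate to a few parts per thousand, while portable nanopore sequencers
deliver reads with 10–15% errors concentrated in homopolymer indels.
`barcodetrack` closes that gap without any reference database, which makes
it suitable for field barcoding of taxa that have never been sequenced.
It is aimed at molecular ecologists and barcoding labs working from pooled
amplicon runs, and at method developers who need a fully simulated test bed
for consensus algorithms.

## Method

For each sample the pipeline runs:

1. **Dual-tag demultiplexing** — semi-global alignment of every sample's
   index tags against both ends of each read, on both strands; a read is
   kept only when the two ends agree on the same sample (identity ≥ 0.75
   per end).
2. **Trimming and 2-SD length filter** — adapters/tags cut at the located
   tag boundaries, reads re-oriented to the forward strand, then reads
   deviating more than 2 population SDs from the sample's mean length are
   dropped.
3. **Abundance clustering at 70% identity** (greedy centroid; identity =
   matches / alignment columns) — only the most abundant cluster survives,
   removing NUMTs and non-specific PCR products.
4. **Draft consensus** — 200 seeded reads, partial-order alignment, then a
   plurality call per column: a base needs `0.15 × 200 = 30` supporting
   reads; majority-gap columns are dropped and residual `N`s deleted.
5. **Polishing** — a second seeded 200-read draw is aligned back to the
   draft; positions are re-voted by pileup plurality over
   `{A, C, G, T, deletion}`, well-supported insertions restored, and every
   homopolymer run re-estimated from the read segments spanning it.
6. **Iteration majority** — the draft+polish stage runs three times (seeds
   1/3/5 and 2/4/6); the consensus produced most often wins, ties keep the
   earliest; finally the PCR primers are trimmed off.

A read simulator (`simulate_sample()`) with a homopolymer-aware error
channel (substitution/insertion/deletion = 5/3/4%, deletions compounding
inside runs) generates full-architecture reads from a known reference, so
every claim above is testable against ground truth.  See the methods
vignette (`vignettes/consensus-barcoding.Rmd`) for model details, parameter
rationale and known limitations.

## Worked example

```r
library(barcodetrack)

ref   <- default_reference(seed = 42)          # 658 nt, runs of 6/7/8 nt
tmpl  <- barcode_template(ref)                 # COI primers + example tags
reads <- simulate_sample(tmpl, n_reads = 1000, rng_seed = 42)
tags  <- data.frame(sample_id = "S1",
                    fwd_tag = tmpl$fwd_tag, rev_tag = tmpl$rev_tag)

res <- run_pipeline(reads, tags, truth = c(S1 = ref))
attr(res, "summary")
```

```
input: 1000 reads, 1 sample(s)
demultiplexed: 10 unassigned
S1: 990 assigned, 945 after length filter [686, 715]
S1: 2 cluster(s); dominant has 799 reads (84.6%)
S1: final consensus 658 nt, support 3/3, accuracy 100.00%
  sample_id n_input n_retained dominant_cluster n_clusters support_count
1        S1     990        945              799          2             3
  consensus_len accuracy
1           658        1
```

Reading the output: 990 of 1000 reads carried matching tags at both ends;
the length filter kept 945; clustering split them into the target cluster
(799 reads, 85%) and the planted 25%-divergent contaminant, which is
discarded; all three seeded iterations produced the identical consensus
(support 3/3), whose 658 nt match the generating reference exactly
(accuracy 1.0 — on real data this column compares against a Sanger-derived
reference and is `NA` when no truth is supplied).

A shell interface wrapping the same functions is installed under
`inst/cli/barcodetrack` (subcommands `simulate`, `preprocess`, `cluster`,
`consensus`, `polish`, `run`).

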