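---
title: "De novo consensus barcoding from noisy long reads: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{De novo consensus barcoding from noisy long reads: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodetrack)
```

## The problem

DNA barcoding identifies species from a short standardized marker — for
animals, usually a ~658 bp fragment of the mitochondrial cytochrome oxidase
subunit I (COI) gene.  Since typical interspecific COI divergence is about
2%, a useful barcode must be accurate to a few parts per thousand.  Portable
nanopore sequencers make it possible to generate barcodes in the field, but
their reads carry 10–15% errors, concentrated in insertions and deletions
and strongly enriched in homopolymer runs.  `barcodetrack` reconstructs a
high-accuracy consensus barcode *de novo* — without any reference database —
from a pool of such reads, and provides a read simulator so that the whole
pipeline can be validated against a known truth.

## The pipeline

Starting from basecalled amplicon reads, one sample is processed as:

1. **Dual-tag demultiplexing.** Each read is scanned on both strands for the
   sample index tags within the first and last 150 nt (semi-global
   alignment, identity ≥ 0.75 per end).  A read is assigned only when the
   best front and back hits name the *same* sample on a consistent strand —
   the both-ends-agree rule that keeps misassignment rates well below 0.1%.
2. **Trimming and orientation.** Adapter and tags are cut at the located tag
   boundaries; reverse-strand reads are reverse-complemented so the multiple
   alignment never mixes strands.  PCR primers are retained on the reads and
   removed only from the final consensus.
3. **Length filter.** Reads deviating more than 2 population standard
   deviations from the sample's mean length are dropped (single pass).
4. **Abundance clustering.** Greedy centroid clustering at 70% identity
   (identity = matches / alignment columns, gaps counted); only the most
   abundant cluster is kept.  This removes co-amplified contaminants such as
   nuclear mitochondrial insertions (NUMTs) and non-specific PCR products.
5. **Draft consensus.** 200 reads are drawn with a fixed seed and aligned
   with a partial-order aligner (match +2, mismatch −2, gap −2); per MSA
   column, a base is called when at least 15% of reads carry it
   (plurality threshold 0.15 × 200 = 30), columns that are majority-gap are
   dropped, sub-threshold columns become `N` and all `N`s are deleted.
6. **Polishing.** A second seeded draw of 200 reads is aligned back to the
   draft (banded global alignment); every position is re-voted by the
   pileup plurality over `{A, C, G, T, deletion}`, insertions carried
   identically by >50% of reads are added, and every homopolymer run is
   re-estimated from the per-read segments between its flanking anchors
   (details below).
7. **Iteration majority.** Steps 5–6 run three times with subsampling seeds
   1/3/5 (draft) and 2/4/6 (polish); the consensus produced most often wins
   (exact string equality; a full tie keeps the earliest iteration).  The
   PCR primers are then trimmed from the winner by semi-global alignment.

Every stage is deterministic given the input reads and the configured seeds;
the whole run is reproducible byte for byte.

## The read simulator

`simulate_sample()` emits full-architecture reads —
`adapter + tag + primer + insert + rc(primer) + rc(tag) + rc(adapter)` on a
uniformly random strand — through an independent per-base error channel:
substitution 5%, insertion 3%, deletion 4% (12% total, matching the ~87–89%
read accuracy of R9.4-era amplicon data).  Inside a homopolymer run of
length $r$ the deletion probability is multiplied by
$\min(m^{\max(0, r-3)}, 10)$ with $m = 1.2$ by default: a modest per-unit
compounding that reproduces the observed behaviour of real consensus runs —
runs of ≤ 5 nt essentially always correct, occasional single-base errors in
runs of 6–8 nt.  The relative proportions 5/3/4 are a modelling choice (the
underlying read-accuracy statistics do not constrain them), declared here
once.

Contamination is modelled as a single NUMT-like haplotype: a copy of the
reference with 25% of positions substituted, supplying 15% of the reads by
default.  With the identity definition above, two 12%-error reads from the
*same* template align at ≈ 0.81 identity, and target-versus-contaminant
reads at ≈ 0.81 × (1 − divergence ·0.8).  A 10% divergent contaminant lands
at ≈ 0.74 — *above* the 0.70 clustering threshold — so such close paralogs
are not separable by clustering alone; 25% divergence (≈ 0.66) separates
cleanly.  The default is therefore chosen to emulate the clearly-divergent
contaminant class that abundance clustering is meant to remove, and the
threshold behaviour near 10% is a documented limitation rather than a bug.

What the simulator does **not** model: chimeras, quality-score structure
(qualities are written as a constant Q12 and never used for filtering —
quality-dependent filters are deliberately avoided because they track
basecaller versions), fragmentation (amplicons are unfragmented), or
length-dependent coverage bias.  Passing tests therefore demonstrate
correctness of the algorithms under a realistic error *channel*, not
robustness to every artefact of real flow cells.

## Alignment machinery

Three compiled kernels drive the pipeline:

* an affine-gap global aligner (match +1, mismatch −1, gap open −2, extend
  −1) with an optional band around the length-proportional diagonal; banded
  and unbanded scores are property-tested to be identical on simulated
  read/draft pairs, and scores are cross-checked against
  `Biostrings::pairwiseAlignment` and a pure-R dynamic programme;
* a semi-global locator (pattern global, free text ends) for tags and
  primers;
* a partial-order aligner (POA): reads are added one at a time to a sequence
  graph by optimal sequence-to-graph alignment, matches fuse into existing
  nodes, mismatches into "aligned-ring" alternatives, insertions into new
  nodes; the ring-collapsed graph is topologically sorted into MSA columns,
  so removing the gaps of row *i* reproduces read *i* exactly.  The graph
  dynamic programme is banded (±100 columns) around each node's approximate
  template position; any read the band cannot accommodate is realigned
  unbanded.

## Polishing details and numerical choices

Base-space polishing replaces signal-space polishing deliberately: this
package ingests only basecalled reads.  Three refinements make pileup voting
effective at 12% error:

* **Indel left-normalization.** Optimal alignments place an indel inside a
  repeat at an arbitrary equivalent offset; before voting, every gap run is
  shifted to its leftmost score-neutral position (the convention used by
  standard variant-calling tools), so equivalent placements vote at the same
  draft position.
* **Run re-voting.** For every maximal draft run of length ≥ 2 (with both
  flanking anchors present), each spanning read contributes the segment it
  carries between the anchor columns, with an anchor-column character that
  equals the run base counted as part of the run.  The modal segment
  *length* wins (ties keep the draft's length) and the emitted content is
  the column-wise majority over the modal-length segments.  Three details
  matter.  The threshold of 2: a true 3-run that lost a base in the draft
  appears as a 2-run and would otherwise be unrecoverable, because the
  reads supporting the missing base split across alignment representations
  and fall below the 50% insertion rule.  The anchor-column term: where
  two runs are adjacent (e.g. `C…CT…T`), a run's anchor is the first base
  of its neighbour, and a surplus base aligns as a mismatch *on* that
  anchor column; ignoring it biases the length vote downward by the
  neighbour's indel rate, which can make a compensating draft error (one
  run short, its neighbour long) locally stable.  And the content vote:
  emitting the run as pure repeats of its base would cement a substituted
  base inside the draft's run region, while the column majority restores
  it; boundary-spill characters fix the length vote but are outvoted
  column-wise, so nothing is double-counted.  Counting all characters (not
  only run-base characters) keeps the length vote invariant to
  substitutions inside the run.  The polishing draw takes up
  to `2n` reads: the first `n` feed the pileup votes, all of them feed the
  run-length votes, because the modal length is the statistically tightest
  call in the whole pipeline (at 200 reads the mode at an 8-nt run flips
  with ~7% probability under the default channel, at 400 with ~2%) — the
  extra statistical depth is the base-space compensation for not having
  signal-level evidence.  The draft-stage subsample is deliberately *not*
  reused here: the partial-order alignment concentrates a run's deletion
  gaps into one column, so drafts are systematically one base short at
  long runs, and the reads that built the draft carry exactly the errors
  polishing must overrule.
* **Two voting rounds.** The voting pass runs twice over the same subsample
  (stopping early at a fixed point): a first pass occasionally leaves a run
  one base off; the second pass sees that run cleanly and corrects it.
  Measured on the package's own simulations, the second round moves the
  typical per-iteration error count from ~1 to ~0 and raises the iteration
  agreement (support counts concentrate at 2–3 of 3).

Other numerical conventions: plurality comparison uses the real-valued
product `p × n` (no rounding); base ties in column votes break
alphabetically; pileup ties keep the draft base; positions with depth < 10
keep the draft base with a warning; reads shorter than half the draft are
excluded from pileups; the polish alignment band is `max(50, 0.1 × draft
length)` plus the read/draft length difference.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `identity_threshold` | 0.70 | greedy clustering threshold (fraction) |
| `subsample_n` | 200 | reads per draft/polish subsample |
| `plurality_p` | 0.15 | draft inclusion fraction |
| `sd_k` | 2 | length-filter SD multiplier |
| `n_iterations` | 3 | seeded iterations combined by majority |
| `draft_seeds` / `polish_seeds` | 1/3/5, 2/4/6 | subsampling seeds |
| `min_tag_identity` | 0.75 | per-end demultiplexing identity |
| `tag_window` | 150 nt | end window searched for tags |

Raising `subsample_n` increases runtime roughly linearly with little
accuracy gain beyond ~200 at these error rates; `n_iterations` is a plain
knob with no convergence rule — samples without a majority after 3
iterations can simply be run with more.

## Benchmark scale and expectations

`run_simulation_study()` regenerates, per replicate, a 658-nt reference
carrying planted homopolymer runs of 6, 7 and 8 nt, simulates reads under
the default channel and runs the full pipeline against the known truth.  At
5000 or 1000 reads per sample (10 replicates each) the final consensus
identity is ≥ 99.8% in essentially every replicate with a median of
99.9–100%, residual errors confined to the longest homopolymer runs; a
replicate completes in well under a minute on one CPU.  These problem sizes
are the package's standard validation scale and are what the test suite and
`scripts/acceptance.R` run.

## Design points that were genuinely open

* The polishing subsample is drawn from the dominant cluster (not from all
  preprocessed reads): the cluster is the pipeline's definition of "reads
  from the target molecule", and polishing with possible contaminants would
  re-admit exactly what clustering removed.
* Clustering is deterministic and seed-free, so the three iterations share
  one clustering rather than recomputing identical results.
* Iterations are combined by exact string equality.  Aligning near-identical
  candidates with a permissive gap penalty, as field pipelines do before
  comparing them, only blurs the comparison; equality is the unambiguous
  determinization, and a full tie keeps the earliest iteration.
* The number of iterations is a plain configuration knob with no
  convergence rule; primer trimming is applied once, after the majority
  selection.
* Qualities are carried through I/O but never used for filtering; the
  length filter and abundance clustering do the read selection.

## Known limitations

* Dinucleotide and other short tandem repeats are canonicalized only through
  left-normalization; a draft error in a repeat that is not a homopolymer
  run of ≥ 2 can occasionally survive one iteration (the iteration majority
  usually removes it).
* Contaminants less than ~15% divergent from the target merge into the
  dominant cluster at the 0.70 threshold (see above); they are then
  out-voted at the consensus stage as long as they stay a clear minority.
* Heteroplasmy/diploidy is out of scope: one haplotype per sample is
  assumed.
* The BLAST-based taxonomic assignment step of field workflows is exposed
  only as the final consensus FASTA, ready to be used as a query.
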