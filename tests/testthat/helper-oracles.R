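# Independent oracles used across the test suite.

# Pure-R affine-gap (Gotoh) global alignment score: an independent,
# brute-force dynamic programme kept deliberately separate from the package's
# compiled aligner.
r_gotoh_score <- function(a, b, match = 1, mismatch = -1,
                          gap_open = -2, gap_extend = -1) {
  a <- strsplit(a, "", fixed = TRUE)[[1]]
  b <- strsplit(b, "", fixed = TRUE)[[1]]
  m <- length(a)
  n <- length(b)
  NEG <- -1e18
  M <- matrix(NEG, m + 1, n + 1)
  X <- matrix(NEG, m + 1, n + 1)
  Y <- matrix(NEG, m + 1, n + 1)
  M[1, 1] <- 0
  for (i in 2:(m + 1)) X[i, 1] <- gap_open + (i - 2) * gap_extend
  for (j in 2:(n + 1)) Y[1, j] <- gap_open + (j - 2) * gap_extend
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      s <- if (a[i - 1] == b[j - 1]) match else mismatch
      M[i, j] <- s + max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      X[i, j] <- max(M[i - 1, j] + gap_open, X[i - 1, j] + gap_extend,
                     Y[i - 1, j] + gap_open)
      Y[i, j] <- max(M[i, j - 1] + gap_open, X[i, j - 1] + gap_open,
                     Y[i, j - 1] + gap_extend)
    }
  }
  max(M[m + 1, n + 1], X[m + 1, n + 1], Y[m + 1, n + 1])
}

# Biostrings global alignment score under the same scoring scheme
# (gapOpening = 1, gapExtension = 1 charges 2 for the first gap base).
biostrings_score <- function(a, b, match = 1, mismatch = -1) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = TRUE)
  Biostrings::pairwiseAlignment(a, b, type = "global",
                                substitutionMatrix = mat,
                                gapOpening = 1, gapExtension = 1,
                                scoreOnly = TRUE)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# A small single-sample simulated data set shared by several tests.
make_sim_sample <- function(n_reads = 300, seed = 11, contam_frac = 0.15,
                            contam_divergence = 0.25, model = error_model(),
                            ref_seed = 1) {
  ref <- default_reference(seed = ref_seed)
  tmpl <- barcode_template(ref)
  reads <- simulate_sample(tmpl, n_reads, model, contam_frac,
                           contam_divergence, rng_seed = seed)
  list(ref = ref, tmpl = tmpl, reads = reads,
       tags = data.frame(sample_id = "S1", fwd_tag = tmpl$fwd_tag,
                         rev_tag = tmpl$rev_tag, stringsAsFactors = FALSE),
       truth_core = paste0(tmpl$fwd_primer, ref, revcomp(tmpl$rev_primer)))
}

# Demultiplex + trim + length-filter a simulated sample (pipeline front end).
preprocess_sim <- function(sim) {
  dmx <- demultiplex(sim$reads, sim$tags)
  tr <- trim_ends(dmx$samples$S1, sim$tmpl$fwd_tag, sim$tmpl$rev_tag)
  lf <- suppressWarnings(length_filter(tr))
  lf$records
}
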