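#' Nanopore-style read error model
#'
#' Per-base substitution, insertion and deletion probabilities, plus a
#' homopolymer deletion multiplier: inside a maximal run of identical bases of
#' length `r`, the deletion probability is scaled by
#' `min(hp_del_multiplier^(max(0, r - 3)), 10)`.  The defaults total 12%
#' error, i.e. read accuracy around 87-89%, with deletions mildly enriched in
#' long homopolymer runs -- the error structure typical of R9.4-era nanopore
#' amplicon reads.
#'
#' @param p_sub per-base substitution probability.
#' @param p_ins per-base insertion probability.
#' @param p_del per-base deletion probability (baseline, outside runs).
#' @param hp_del_multiplier multiplicative deletion factor per repeat unit
#'   beyond run length 3, capped at a 10-fold total increase.
#' @return An `error_model` list.
#' @export
error_model <- function(p_sub = 0.05, p_ins = 0.03, p_del = 0.04,
                        hp_del_multiplier = 1.2) {
  stopifnot(p_sub >= 0, p_sub <= 1, p_ins >= 0, p_ins <= 1,
            p_del >= 0, p_del <= 1, hp_del_multiplier >= 0)
  # degenerate channels (a probability of exactly 1) are allowed for testing;
  # realistic models must stay below 50% total error
  if (p_sub + p_ins + p_del >= 0.5 && !any(c(p_sub, p_ins, p_del) == 1))
    stop("total error rate must be below 0.5")
  structure(list(p_sub = p_sub, p_ins = p_ins, p_del = p_del,
                 hp_del_multiplier = hp_del_multiplier),
            class = "error_model")
}

#' Amplicon template for read simulation
#'
#' Describes the full molecule the simulator emits reads from:
#' `adapter + fwd_tag + fwd_primer + reference + revcomp(rev_primer) +
#' revcomp(rev_tag) + revcomp(adapter)`, on a uniformly random strand.
#' Defaults use the universal COI barcoding primers LCO1490/HCO2198 and
#' example 24-nt indexing tags.
#'
#' @param reference ground-truth barcode insert (~658-710 nt for COI).
#' @param fwd_primer,rev_primer PCR primers, 5'->3' on their own strands.
#' @param fwd_tag,rev_tag per-sample index tags (>= 8 nt).
#' @param adapter sequencing adapter.
#' @return A `barcode_template` list.
#' @export
barcode_template <- function(reference,
                             fwd_primer = "GGTCAACAAATCATAAAGATATTGG",
                             rev_primer = "TAAACTTCAGGGTGACCAAAAAATCA",
                             fwd_tag = "AAGAAAGTTGTCGGTGTCTTTGTG",
                             rev_tag = "TCGATTCCGTTTGTAGTCGTCTGT",
                             adapter = "TTTCTGTTGGTGCTGATATTGC") {
  parts <- list(reference = reference, fwd_primer = fwd_primer,
                rev_primer = rev_primer, fwd_tag = fwd_tag, rev_tag = rev_tag,
                adapter = adapter)
  parts <- lapply(parts, function(x) toupper(as.character(x)))
  if (!all(vapply(parts, function(x) grepl("^[ACGT]+$", x), logical(1))))
    stop("all template parts must be non-empty ACGT strings")
  if (nchar(parts$fwd_tag) < 8 || nchar(parts$rev_tag) < 8)
    stop("tags must be at least 8 nt")
  structure(parts, class = "barcode_template")
}

# Maximal-run length at every position of a sequence.
run_lengths_by_pos <- function(chars) {
  r <- rle(chars)
  rep(r$lengths, r$lengths)
}

# Per-position deletion probabilities under the homopolymer-aware model.
hp_del_prob <- function(chars, model) {
  runlen <- run_lengths_by_pos(chars)
  fac <- pmin(model$hp_del_multiplier^pmax(0, runlen - 3), 10)
  pmin(model$p_del * fac, 0.95)
}

#' Pass a sequence through the read error channel
#'
#' Each template position is independently substituted (uniform different
#' base), followed by a random-base insertion, and/or deleted, with the
#' deletion probability scaled up inside homopolymer runs (see
#' [error_model()]).  Uses the current R random number generator state.
#'
#' @param template DNA string.
#' @param model an [error_model()].
#' @return The mutated DNA string.
#' @export
mutate_sequence <- function(template, model = error_model()) {
  stopifnot(nchar(template) >= 1)
  chars <- strsplit(template, "", fixed = TRUE)[[1]]
  mutate_chars(chars, hp_del_prob(chars, model), model)
}

# Fast path of the error channel: template characters and their per-position
# deletion probabilities are precomputed once per template.
mutate_chars <- function(chars, p_del, model) {
  bases <- c("A", "C", "G", "T")
  L <- length(chars)
  keep <- stats::runif(L) >= p_del
  sub <- stats::runif(L) < model$p_sub
  ins <- stats::runif(L) < model$p_ins
  out <- chars
  n_sub <- sum(sub)
  if (n_sub > 0) {
    # uniformly one of the three other bases
    shift <- sample.int(3L, n_sub, replace = TRUE)
    cur <- match(chars[sub], bases)
    out[sub] <- bases[(cur - 1L + shift) %% 4L + 1L]
  }
  n_ins <- sum(ins)
  ins_base <- character(L)
  if (n_ins > 0) ins_base[ins] <- sample(bases, n_ins, replace = TRUE)
  pieces <- ifelse(keep, out, "")
  pieces <- paste0(pieces, ins_base)
  paste(pieces, collapse = "")
}

#' Simulate an amplicon read set
#'
#' Generates `n_reads` full-architecture reads (adapter, tags, primers,
#' insert) from a [barcode_template()]: `floor((1 - contam_frac) * n_reads)`
#' reads derive from the reference and the remainder from a single
#' contaminant haplotype (a NUMT-like co-amplified sequence) obtained by
#' substituting a fraction `contam_divergence` of reference positions, fixed
#' for the whole run.  Every read is passed through the error channel, placed
#' on a uniformly random strand, given a constant Q12 quality string, and the
#' read order is shuffled.  Deterministic for a fixed `rng_seed`.
#'
#' @param template a [barcode_template()].
#' @param n_reads number of reads (>= 1).
#' @param model an [error_model()].
#' @param contam_frac fraction of contaminant-derived reads, in `[0, 0.5)`.
#' @param contam_divergence substitution divergence of the contaminant.
#' @param rng_seed integer seed.
#' @return A [seq_records] data frame with extra columns `origin`
#'   (`"target"`/`"contaminant"`) and `strand` (`"+"`/`"-"`).
#' @export
simulate_sample <- function(template, n_reads, model = error_model(),
                            contam_frac = 0.15, contam_divergence = 0.25,
                            rng_seed = 1L) {
  stopifnot(inherits(template, "barcode_template"), n_reads >= 1)
  if (contam_frac < 0 || contam_frac >= 0.5)
    stop("contam_frac must be in [0, 0.5): the target must stay dominant")
  with_seed(rng_seed, {
    n_target <- floor((1 - contam_frac) * n_reads)
    n_contam <- n_reads - n_target
    contam_ref <- diverge_reference(template$reference, contam_divergence)
    molecule <- function(core) {
      paste0(template$adapter, template$fwd_tag, template$fwd_primer, core,
             revcomp(template$rev_primer), revcomp(template$rev_tag),
             revcomp(template$adapter))
    }
    origin <- c(rep("target", n_target), rep("contaminant", n_contam))
    mol_target <- strsplit(molecule(template$reference), "", fixed = TRUE)[[1]]
    mol_contam <- strsplit(molecule(contam_ref), "", fixed = TRUE)[[1]]
    pdel_target <- hp_del_prob(mol_target, model)
    pdel_contam <- hp_del_prob(mol_contam, model)
    seqs <- vapply(seq_len(n_reads), function(i) {
      if (i <= n_target) mutate_chars(mol_target, pdel_target, model)
      else mutate_chars(mol_contam, pdel_contam, model)
    }, character(1))
    strand <- sample(c("+", "-"), n_reads, replace = TRUE)
    seqs[strand == "-"] <- revcomp(seqs[strand == "-"])
    ord <- sample.int(n_reads)
    seqs <- seqs[ord]; origin <- origin[ord]; strand <- strand[ord]
    qual <- vapply(nchar(seqs),
                   function(n) strrep(rawToChar(as.raw(45L)), n), character(1))
    out <- seq_records(sprintf("read_%05d", seq_len(n_reads)), seqs, qual)
    out$origin <- origin
    out$strand <- strand
    out
  })
}

# Substitute a fixed fraction of positions (uniformly chosen, different base).
diverge_reference <- function(reference, divergence) {
  if (divergence <= 0) return(reference)
  chars <- strsplit(reference, "", fixed = TRUE)[[1]]
  k <- round(divergence * length(chars))
  if (k == 0) return(reference)
  idx <- sample.int(length(chars), k)
  chars[idx] <- vapply(chars[idx],
                       function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                       character(1))
  paste(chars, collapse = "")
}

#' Generate a random reference with planted homopolymer runs
#'
#' The background sequence contains no run longer than 5 nt; each requested
#' run is planted as a maximal run of exactly the requested length.
#'
#' @param length total reference length.
#' @param homopolymer_spec list of `c(base, run_length, start_position)`
#'   entries (positions 1-based); runs must fit and must not overlap.
#' @param seed optional integer seed.
#' @return A DNA string.
#' @export
make_reference <- function(length, homopolymer_spec = list(), seed = NULL) {
  n <- as.integer(length)
  stopifnot(n >= 1)
  gen <- function() {
    bases <- c("A", "C", "G", "T")
    chars <- character(n)
    for (i in seq_len(n)) {
      if (i > 5 && all(chars[(i - 5):(i - 1)] == chars[i - 1]))
        chars[i] <- sample(setdiff(bases, chars[i - 1]), 1)
      else chars[i] <- sample(bases, 1)
    }
    spans <- list()
    for (sp in homopolymer_spec) {
      base <- toupper(as.character(sp[[1]]))
      rl <- as.integer(sp[[2]]); pos <- as.integer(sp[[3]])
      if (!base %in% bases || rl < 1) stop("bad homopolymer spec entry")
      if (pos < 1 || pos + rl - 1 > n)
        stop("planted run does not fit in the reference")
      for (old in spans)
        if (pos <= old[2] + 1 && pos + rl - 1 >= old[1] - 1)
          stop("planted homopolymer runs overlap")
      spans[[base::length(spans) + 1]] <- c(pos, pos + rl - 1)
      chars[pos:(pos + rl - 1)] <- base
      for (fl in c(pos - 1, pos + rl)) {
        if (fl >= 1 && fl <= n && chars[fl] == base)
          chars[fl] <- sample(setdiff(bases, base), 1)
      }
    }
    planted <- unlist(lapply(spans, function(s) s[1]:s[2]))
    # break any unplanned run longer than 5 introduced by planting flanks
    repeat {
      r <- rle(chars)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      long <- which(r$lengths > 5)
      long <- long[!(starts[long] %in% planted)]
      if (base::length(long) == 0) break
      i <- starts[long[1]] + 2
      nb <- setdiff(bases, c(chars[i - 1], chars[min(i + 1, n)]))
      chars[i] <- sample(nb, 1)
    }
    paste(chars, collapse = "")
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Default simulation reference used by the package's benchmark
#'
#' A 658-nt COI-length reference carrying one planted homopolymer run each of
#' 6, 7 and 8 nt, the run lengths at which nanopore consensus errors persist.
#'
#' @param seed integer seed controlling the random background.
#' @return A DNA string.
#' @export
default_reference <- function(seed = 1L) {
  make_reference(658, list(c("A", 6, 120), c("T", 7, 330), c("C", 8, 520)),
                 seed = seed)
}
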