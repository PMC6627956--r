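#' Pipeline configuration
#'
#' Collects every tunable parameter of the consensus pipeline.  Defaults are
#' the published operating point: clustering identity 0.70, 200-read
#' subsamples, plurality fraction 0.15, 2-SD length filter, 3 iterations with
#' draft seeds 1/3/5 and polishing seeds 2/4/6, and 0.75 minimum tag
#' identity for demultiplexing.
#'
#' @param identity_threshold clustering identity threshold `t`.
#' @param subsample_n reads per draft/polish subsample.
#' @param plurality_p draft plurality fraction.
#' @param sd_k length-filter standard-deviation multiplier.
#' @param n_iterations number of seeded pipeline iterations `R`.
#' @param draft_seeds,polish_seeds integer seed vectors, each of length
#'   `n_iterations`, with no seed shared between the two sets.
#' @param min_tag_identity demultiplexing tag identity threshold.
#' @param tag_window bases searched for tags at each read end.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(identity_threshold = 0.70, subsample_n = 200,
                            plurality_p = 0.15, sd_k = 2, n_iterations = 3,
                            draft_seeds = c(1L, 3L, 5L),
                            polish_seeds = c(2L, 4L, 6L),
                            min_tag_identity = 0.75, tag_window = 150) {
  if (length(draft_seeds) != n_iterations ||
      length(polish_seeds) != n_iterations)
    stop("need one draft seed and one polish seed per iteration")
  if (length(intersect(draft_seeds, polish_seeds)) > 0)
    stop("draft and polish seed sets must be disjoint")
  structure(list(identity_threshold = identity_threshold,
                 subsample_n = subsample_n, plurality_p = plurality_p,
                 sd_k = sd_k, n_iterations = n_iterations,
                 draft_seeds = as.integer(draft_seeds),
                 polish_seeds = as.integer(polish_seeds),
                 min_tag_identity = min_tag_identity,
                 tag_window = tag_window),
            class = "pipeline_config")
}

# Draft + polish from an already selected dominant cluster.
consensus_from_cluster <- function(cluster_reads, config, draft_seed,
                                   polish_seed) {
  sub <- subsample_reads(cluster_reads, config$subsample_n, draft_seed)
  msa <- build_msa(sub)
  draft <- plurality_consensus(msa, config$plurality_p)
  polish_consensus(draft, cluster_reads, n = config$subsample_n,
                   seed = polish_seed)
}

#' Run one pipeline iteration
#'
#' Cluster at the configured identity, keep the dominant cluster, build the
#' seeded draft consensus and polish it with the second seeded subsample.
#' Fully deterministic given `(reads, seeds)`.
#'
#' @param reads preprocessed single-sample [seq_records].
#' @param config a [pipeline_config()].
#' @param draft_seed,polish_seed seeds for the two subsampling steps.
#' @param clusters optionally a precomputed [greedy_cluster()] result
#'   (clustering is seed-free, so iterations may share it).
#' @return The iteration's polished consensus DNA string.
#' @export
run_iteration <- function(reads, config = pipeline_config(),
                          draft_seed = 1L, polish_seed = 2L,
                          clusters = NULL) {
  reads <- as_seq_records(reads)
  if (is.null(clusters))
    clusters <- greedy_cluster(reads, config$identity_threshold)
  dom <- select_dominant(clusters)
  if (dom$abundance < 10)
    stop("dominant cluster has fewer than 10 reads")
  if (dom$abundance < 50)
    warning("dominant cluster has fewer than 50 reads; ",
            "consensus accuracy may be degraded")
  cluster_reads <- reads[dom$member_idx, , drop = FALSE]
  class(cluster_reads) <- c("seq_records", "data.frame")
  consensus_from_cluster(cluster_reads, config, draft_seed, polish_seed)
}

#' Majority rule over iteration consensuses
#'
#' Sequences are compared by exact string equality after removing any gap
#' characters; the most frequent sequence wins, and a full tie returns the
#' sequence from the earliest iteration.
#'
#' @param seqs character vector of per-iteration consensus sequences.
#' @return List with `sequence`, `support` (iterations carrying the winner)
#'   and `iteration` (earliest iteration producing it).
#' @export
majority_consensus <- function(seqs) {
  stopifnot(length(seqs) >= 1)
  norm <- toupper(gsub("-", "", seqs, fixed = TRUE))
  counts <- table(norm)
  mx <- max(counts)
  winners <- names(counts)[counts == mx]
  first_occurrence <- vapply(winners, function(w) match(w, norm), integer(1))
  win <- winners[which.min(first_occurrence)]
  list(sequence = win, support = as.integer(mx),
       iteration = match(win, norm))
}

#' Trim PCR primers from a consensus sequence
#'
#' The forward primer is located (semi-global alignment) in the 5' `window`
#' bases and the reverse complement of the reverse primer in the 3' `window`
#' bases; each end is cut at the inner boundary of a hit with identity >=
#' `min_identity`.  An end whose primer cannot be located is left untouched,
#' with a warning.
#'
#' @param consensus DNA string.
#' @param fwd_primer,rev_primer PCR primers (5'->3' on their own strands).
#' @param min_identity minimum primer alignment identity.
#' @param window bases searched at each end.
#' @return The trimmed DNA string.
#' @export
trim_primers <- function(consensus,
                         fwd_primer = "GGTCAACAAATCATAAAGATATTGG",
                         rev_primer = "TAAACTTCAGGGTGACCAAAAAATCA",
                         min_identity = 0.75, window = 100) {
  consensus <- toupper(consensus)
  L <- nchar(consensus)
  stopifnot(L > nchar(fwd_primer) + nchar(rev_primer))
  w <- min(window, L)
  from <- 1L
  to <- L
  hit5 <- sg_locate_cpp(toupper(fwd_primer), substr(consensus, 1, w))
  if (hit5$identity >= min_identity) from <- hit5$end + 1L
  else warning("forward primer not located; 5' end left untrimmed")
  hit3 <- sg_locate_cpp(revcomp(rev_primer), substr(consensus, L - w + 1, L))
  if (hit3$identity >= min_identity) to <- L - w + hit3$start - 1L
  else warning("reverse primer not located; 3' end left untrimmed")
  if (from > to) stop("primer trimming removed the whole consensus")
  substr(consensus, from, to)
}

#' Evaluate consensus accuracy against a known reference
#'
#' Global alignment; accuracy is `matches / alignment_columns`.  The error
#' report lists every non-match column with flanking reference context and
#' the length of the longest reference homopolymer run touching it.
#'
#' @param consensus,truth DNA strings.
#' @return List with `accuracy`, `matches`, `columns`, and `errors` (data
#'   frame: `column`, `truth_pos`, `consensus_pos`, `type`, `truth_context`,
#'   `hp_run_len`).
#' @export
evaluate_accuracy <- function(consensus, truth) {
  stopifnot(nchar(consensus) >= 1, nchar(truth) >= 1)
  al <- nw_align_cpp(toupper(consensus), toupper(truth), 1, -1, -2, -1, 0L)
  qa <- strsplit(al$aligned_a, "", fixed = TRUE)[[1]]
  ta <- strsplit(al$aligned_b, "", fixed = TRUE)[[1]]
  tpos <- cumsum(ta != "-")
  qpos <- cumsum(qa != "-")
  bad <- which(qa != ta)
  tchars <- strsplit(toupper(truth), "", fixed = TRUE)[[1]]
  runlen <- run_lengths_by_pos(tchars)
  Lt <- length(tchars)
  errors <- data.frame(
    column = bad,
    truth_pos = tpos[bad],
    consensus_pos = qpos[bad],
    type = ifelse(ta[bad] == "-", "insertion",
                  ifelse(qa[bad] == "-", "deletion", "mismatch")),
    truth_context = vapply(tpos[bad], function(p) {
      lo <- max(1, p - 5); hi <- min(Lt, p + 5)
      paste(tchars[lo:hi], collapse = "")
    }, character(1)),
    hp_run_len = vapply(tpos[bad], function(p) {
      idx <- unique(pmin(pmax(c(p - 1, p, p + 1), 1), Lt))
      max(runlen[idx])
    }, integer(1)),
    stringsAsFactors = FALSE)
  list(accuracy = al$identity, matches = al$matches, columns = al$columns,
       errors = errors)
}

#' Run the full consensus pipeline
#'
#' Demultiplex, trim, length-filter, cluster, run the configured number of
#' seeded draft+polish iterations, combine them by the majority rule, trim
#' the PCR primers and (when the truth is known) evaluate accuracy.
#'
#' @param reads a [seq_records] data frame or a FASTQ/FASTA path.
#' @param tag_table data frame (or TSV path) with `sample_id`, `fwd_tag`,
#'   `rev_tag`.
#' @param config a [pipeline_config()].
#' @param truth optional named character vector (or FASTA path) of reference
#'   sequences, named by sample id.
#' @param fwd_primer,rev_primer PCR primers used for final consensus
#'   trimming.
#' @param out_dir optional output directory; per-sample consensus FASTA, a
#'   TSV summary and a JSON run manifest are written there.
#' @param quiet suppress progress messages.
#' @return Named list of `consensus_result` objects (one per sample), with a
#'   `summary` data frame attached as an attribute.
#' @export
run_pipeline <- function(reads, tag_table, config = pipeline_config(),
                         truth = NULL,
                         fwd_primer = "GGTCAACAAATCATAAAGATATTGG",
                         rev_primer = "TAAACTTCAGGGTGACCAAAAAATCA",
                         out_dir = NULL, quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  if (is.character(reads) && length(reads) == 1) {
    reads <- if (grepl("\\.(fa|fasta)(\\.gz)?$", reads)) read_fasta(reads)
             else read_fastq(reads)
  }
  reads <- as_seq_records(reads)
  if (is.character(tag_table) && length(tag_table) == 1)
    tag_table <- read_tag_table(tag_table)
  tag_table <- validate_tag_table(tag_table)
  if (is.character(truth) && length(truth) == 1 && file.exists(truth)) {
    tr <- read_fasta(truth)
    truth <- stats::setNames(tr$seq, tr$id)
  }
  say(sprintf("input: %d reads, %d sample(s)", nrow(reads), nrow(tag_table)))
  dmx <- demultiplex(reads, tag_table, config$min_tag_identity,
                     config$tag_window)
  say(sprintf("demultiplexed: %s unassigned",
              nrow(dmx$unassigned)))
  results <- list()
  for (s in tag_table$sample_id) {
    srec <- dmx$samples[[s]]
    if (nrow(srec) == 0) {
      warning("sample ", s, " received no reads; skipped")
      next
    }
    row <- tag_table[tag_table$sample_id == s, ]
    trimmed <- trim_ends(srec, row$fwd_tag, row$rev_tag)
    lf <- length_filter(trimmed, k = config$sd_k)
    say(sprintf("%s: %d assigned, %d after length filter [%d, %d]", s,
                nrow(srec), lf$report$n_retained,
                round(lf$report$low_bound), round(lf$report$high_bound)))
    clusters <- greedy_cluster(lf$records, config$identity_threshold)
    dom <- select_dominant(clusters)
    say(sprintf("%s: %d cluster(s); dominant has %d reads (%.1f%%)", s,
                length(clusters), dom$abundance,
                100 * dom$abundance / nrow(lf$records)))
    iters <- vapply(seq_len(config$n_iterations), function(i) {
      run_iteration(lf$records, config, config$draft_seeds[i],
                    config$polish_seeds[i], clusters = clusters)
    }, character(1))
    maj <- majority_consensus(iters)
    final <- trim_primers(maj$sequence, fwd_primer, rev_primer)
    acc <- NULL
    if (!is.null(truth) && s %in% names(truth))
      acc <- evaluate_accuracy(final, truth[[s]])
    res <- structure(list(
      sample_id = s, iteration_consensuses = iters,
      final_consensus = final, support_count = maj$support,
      accuracy_vs_truth = if (is.null(acc)) NA_real_ else acc$accuracy,
      evaluation = acc,
      n_input = nrow(srec), n_retained = lf$report$n_retained,
      cluster_sizes = vapply(clusters, `[[`, integer(1), "abundance"),
      length_report = lf$report), class = "consensus_result")
    say(sprintf("%s: final consensus %d nt, support %d/%d%s", s,
                nchar(final), maj$support, config$n_iterations,
                if (is.null(acc)) ""
                else sprintf(", accuracy %.2f%%", 100 * acc$accuracy)))
    results[[s]] <- res
  }
  summary <- do.call(rbind, lapply(results, function(r) data.frame(
    sample_id = r$sample_id, n_input = r$n_input, n_retained = r$n_retained,
    dominant_cluster = max(r$cluster_sizes), n_clusters =
      length(r$cluster_sizes), support_count = r$support_count,
    consensus_len = nchar(r$final_consensus),
    accuracy = r$accuracy_vs_truth, stringsAsFactors = FALSE)))
  rownames(summary) <- NULL
  attr(results, "summary") <- summary
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (r in results)
      write_fasta(seq_records(paste0(r$sample_id, "_consensus"),
                              r$final_consensus),
                  file.path(out_dir, paste0(r$sample_id, "_consensus.fasta")))
    utils::write.table(summary, file.path(out_dir, "summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest <- list(package = "barcodetrack",
                     version = as.character(utils::packageVersion("barcodetrack")),
                     config = unclass(config),
                     n_input_reads = nrow(reads),
                     samples = summary)
    jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  results
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("<consensus_result %s: %d nt, support %d%s>\n", x$sample_id,
              nchar(x$final_consensus), x$support_count,
              if (is.na(x$accuracy_vs_truth)) ""
              else sprintf(", accuracy %.2f%%", 100 * x$accuracy_vs_truth)))
  invisible(x)
}

#' Simulation benchmark of the full pipeline
#'
#' For each replicate, generates a fresh 658-nt reference carrying 6/7/8-nt
#' homopolymer runs ([default_reference()]), simulates a read set under the
#' default error model, runs the complete pipeline and records the final
#' consensus identity to the generating reference.
#'
#' @param n_reads reads per replicate.
#' @param sim_seeds integer vector of simulator seeds (one per replicate).
#' @param config a [pipeline_config()].
#' @param model an [error_model()].
#' @param contam_frac,contam_divergence contamination settings passed to
#'   [simulate_sample()].
#' @param quiet suppress per-replicate messages.
#' @return Data frame: `sim_seed`, `accuracy`, `support`, `n_errors`,
#'   `elapsed_s`.
#' @export
run_simulation_study <- function(n_reads = 5000, sim_seeds = 1:10,
                                 config = pipeline_config(),
                                 model = error_model(),
                                 contam_frac = 0.15,
                                 contam_divergence = 0.25,
                                 quiet = TRUE) {
  rows <- lapply(sim_seeds, function(s) {
    t0 <- proc.time()[["elapsed"]]
    ref <- default_reference(seed = s)
    tmpl <- barcode_template(ref)
    reads <- simulate_sample(tmpl, n_reads, model, contam_frac,
                             contam_divergence, rng_seed = s)
    tags <- data.frame(sample_id = "S1", fwd_tag = tmpl$fwd_tag,
                       rev_tag = tmpl$rev_tag, stringsAsFactors = FALSE)
    res <- run_pipeline(reads, tags, config, truth = c(S1 = ref),
                        quiet = quiet)
    r <- res[["S1"]]
    data.frame(sim_seed = s, accuracy = r$accuracy_vs_truth,
               support = r$support_count,
               n_errors = nrow(r$evaluation$errors),
               elapsed_s = proc.time()[["elapsed"]] - t0)
  })
  do.call(rbind, rows)
}
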