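#' Demultiplex reads by dual end-tags
#'
#' Each read is scanned on both strands: the first and last `window` bases are
#' searched (semi-global alignment) against every sample's forward and
#' reverse tags.  A read is assigned to a sample only when the best front-end
#' hit and the best back-end hit belong to the same sample, on a consistent
#' strand, both with identity at least `min_identity`; everything else lands
#' in the `UNASSIGNED` bucket.  This both-ends-agree rule is what keeps tag
#' misassignment rates low in multiplexed pools.
#'
#' @param reads a [seq_records] data frame.
#' @param tag_table data frame with columns `sample_id`, `fwd_tag`, `rev_tag`
#'   (or a path to such a TSV).  Duplicate tags across samples are rejected.
#' @param min_identity minimum per-end tag alignment identity.
#' @param window number of bases searched at each read end.
#' @return A list with `samples` (named list of [seq_records], each with
#'   boundary columns `front_end`, `back_start`, `strand` used later for
#'   trimming), `unassigned`, and `assignments` (one row per read:
#'   `read_id`, `sample_id`, `front_score`, `back_score`).
#' @export
demultiplex <- function(reads, tag_table, min_identity = 0.75, window = 150) {
  reads <- as_seq_records(reads)
  if (is.character(tag_table) && length(tag_table) == 1)
    tag_table <- read_tag_table(tag_table)
  tag_table <- validate_tag_table(tag_table)
  n_samp <- nrow(tag_table)
  if (nrow(reads) == 0) {
    empty <- reads
    return(list(samples = stats::setNames(rep(list(empty), n_samp),
                                          tag_table$sample_id),
                unassigned = empty,
                assignments = data.frame(read_id = character(0),
                                         sample_id = character(0),
                                         front_score = numeric(0),
                                         back_score = numeric(0))))
  }
  # front panel: fwd tags (forward strand) then rev tags (reverse strand);
  # back panel: revcomp(rev tags) then revcomp(fwd tags), same order
  front_pats <- c(tag_table$fwd_tag, tag_table$rev_tag)
  back_pats <- c(revcomp(tag_table$rev_tag), revcomp(tag_table$fwd_tag))
  sc <- tag_scan_cpp(reads$seq, front_pats, back_pats, as.integer(window))
  f_sample <- ifelse(sc[, "front_idx"] > n_samp,
                     sc[, "front_idx"] - n_samp, sc[, "front_idx"])
  f_strand <- ifelse(sc[, "front_idx"] > n_samp, "-", "+")
  b_sample <- ifelse(sc[, "back_idx"] > n_samp,
                     sc[, "back_idx"] - n_samp, sc[, "back_idx"])
  b_strand <- ifelse(sc[, "back_idx"] > n_samp, "-", "+")
  ok <- f_sample == b_sample & f_strand == b_strand &
    sc[, "front_id"] >= min_identity & sc[, "back_id"] >= min_identity
  sample_id <- ifelse(ok, tag_table$sample_id[f_sample], "UNASSIGNED")
  assignments <- data.frame(read_id = reads$id, sample_id = sample_id,
                            front_score = sc[, "front_id"],
                            back_score = sc[, "back_id"],
                            stringsAsFactors = FALSE)
  samples <- lapply(tag_table$sample_id, function(s) {
    sel <- which(sample_id == s)
    out <- reads[sel, , drop = FALSE]
    out$front_end <- sc[sel, "front_end"]
    out$back_start <- sc[sel, "back_start"]
    out$demux_strand <- f_strand[sel]
    class(out) <- c("seq_records", "data.frame")
    out
  })
  names(samples) <- tag_table$sample_id
  unassigned <- reads[sample_id == "UNASSIGNED", , drop = FALSE]
  class(unassigned) <- c("seq_records", "data.frame")
  list(samples = samples, unassigned = unassigned, assignments = assignments)
}

#' Trim adapters and tags from assigned reads
#'
#' Cuts each read at the inner boundaries of its located end tags, removing
#' adapter and tag at both ends while retaining the PCR primers (primers are
#' trimmed from the final consensus, not from reads).  Reads found on the
#' reverse strand are reverse-complemented into forward orientation so that
#' downstream multiple alignment never mixes strands.  When a boundary cannot
#' be located the corresponding end is left untrimmed, with a warning.
#'
#' Boundary columns produced by [demultiplex()] (`front_end`, `back_start`,
#' `demux_strand`) are reused when present; otherwise the tags are located by
#' semi-global alignment in the first/last `window` bases.
#'
#' @param reads a [seq_records] data frame for a single sample.
#' @param fwd_tag,rev_tag the sample's tags.
#' @param adapter adapter sequence (removed implicitly: it lies outside the
#'   tags).
#' @param min_identity minimum tag identity to accept a boundary.
#' @param window end window searched for tags.
#' @return A [seq_records] data frame of trimmed, forward-oriented reads.
#' @export
trim_ends <- function(reads, fwd_tag, rev_tag, adapter = NULL,
                      min_identity = 0.6, window = 150) {
  reads <- as_seq_records(reads)
  if (nrow(reads) == 0) return(reads)
  fwd_tag <- toupper(fwd_tag); rev_tag <- toupper(rev_tag)
  if (!all(c("front_end", "back_start", "demux_strand") %in% names(reads))) {
    sc <- tag_scan_cpp(reads$seq, c(fwd_tag, rev_tag),
                       c(revcomp(rev_tag), revcomp(fwd_tag)),
                       as.integer(window))
    f_strand <- ifelse(sc[, "front_idx"] == 2, "-", "+")
    b_strand <- ifelse(sc[, "back_idx"] == 2, "-", "+")
    strand <- ifelse(f_strand == b_strand, f_strand, NA_character_)
    ok_f <- sc[, "front_id"] >= min_identity & !is.na(strand)
    ok_b <- sc[, "back_id"] >= min_identity & !is.na(strand)
    front_end <- ifelse(ok_f, sc[, "front_end"], NA_real_)
    back_start <- ifelse(ok_b, sc[, "back_start"], NA_real_)
    strand[is.na(strand)] <- "+"
  } else {
    front_end <- reads$front_end
    back_start <- reads$back_start
    strand <- reads$demux_strand
  }
  n_missing <- sum(is.na(front_end)) + sum(is.na(back_start))
  if (n_missing > 0)
    warning(n_missing, " read end(s) had no locatable tag boundary; ",
            "left untrimmed")
  len <- nchar(reads$seq)
  from <- ifelse(is.na(front_end), 1, front_end + 1)
  to <- ifelse(is.na(back_start), len, back_start - 1)
  bad <- from > to
  if (any(bad)) { from[bad] <- 1; to[bad] <- len[bad] }
  core <- substr(reads$seq, from, to)
  qual <- ifelse(is.na(reads$qual), NA_character_,
                 substr(reads$qual, from, to))
  rev <- strand == "-"
  core[rev] <- revcomp(core[rev])
  qual[rev & !is.na(qual)] <- vapply(qual[rev & !is.na(qual)], function(q)
    paste(rev(strsplit(q, "", fixed = TRUE)[[1]]), collapse = ""),
    character(1))
  out <- seq_records(reads$id, core, qual)
  out$strand <- strand
  if ("origin" %in% names(reads)) out$origin <- reads$origin
  out
}

#' Filter reads of abnormal length
#'
#' Single-pass filter: reads whose length deviates by more than `k`
#' (population) standard deviations from the sample mean are removed.
#'
#' @param reads a [seq_records] data frame.
#' @param k standard-deviation multiplier (default 2).
#' @return List with `records` (retained reads) and `report`, a one-row data
#'   frame with `mean_len`, `sd_len`, `low_bound`, `high_bound`, `n_in`,
#'   `n_retained`.
#' @export
length_filter <- function(reads, k = 2) {
  reads <- as_seq_records(reads)
  len <- nchar(reads$seq)
  n <- length(len)
  if (n < 2) {
    warning("fewer than 2 reads: length filter skipped, all retained")
    report <- data.frame(mean_len = if (n) mean(len) else NA_real_,
                         sd_len = NA_real_, low_bound = -Inf,
                         high_bound = Inf, n_in = n, n_retained = n)
    return(list(records = reads, report = report))
  }
  m <- mean(len)
  s <- sqrt(mean((len - m)^2))  # population SD
  lo <- m - k * s
  hi <- m + k * s
  keep <- len >= lo & len <= hi
  out <- reads[keep, , drop = FALSE]
  class(out) <- c("seq_records", "data.frame")
  report <- data.frame(mean_len = m, sd_len = s, low_bound = lo,
                       high_bound = hi, n_in = n, n_retained = sum(keep))
  list(records = out, report = report)
}
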