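#' Align a read to the draft consensus
#'
#' Banded global alignment (band 10% of the draft length, at least 50
#' columns).  Reads shorter than half the draft are flagged unmappable and
#' excluded from polishing pileups.
#'
#' @param read DNA string.
#' @param draft draft consensus DNA string.
#' @param band band half-width; `NULL` picks `max(50, 0.1 * nchar(draft))`.
#' @return `NULL` when the read is unmappable, else a list with `score`,
#'   `cigar` (M/I/D, I = extra base in the read), `aligned_read`,
#'   `aligned_draft`, `matches`, `columns`, `identity`.
#' @export
align_to_draft <- function(read, draft, band = NULL) {
  stopifnot(nchar(draft) >= 1)
  if (nchar(read) < nchar(draft) / 2) return(NULL)
  if (is.null(band))
    band <- max(50L, ceiling(0.1 * nchar(draft)))
  band <- band + abs(nchar(read) - nchar(draft))
  al <- nw_align_cpp(toupper(read), toupper(draft), 1, -1, -2, -1,
                     as.integer(band))
  list(score = al$score, cigar = al$cigar, aligned_read = al$aligned_a,
       aligned_draft = al$aligned_b, matches = al$matches,
       columns = al$columns, identity = al$identity)
}

# Left-normalize indels in an alignment (score-neutral shifts only): every
# gap run is pushed as far left as possible, so equivalent indel placements
# inside repeats land on the same draft position for all reads.
left_normalize_alignment <- function(qa, da) {
  shift_runs <- function(fixed, moving) {
    # `moving` carries the gaps of this pass; its non-gap chars slide left
    r <- rle(moving == "-")
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      c1 <- starts[k]; c2 <- ends[k]
      while (c1 > 1 && moving[c1 - 1] != "-" && fixed[c1 - 1] != "-" &&
             (fixed[c1 - 1] == moving[c1 - 1]) ==
             (fixed[c2] == moving[c1 - 1])) {
        moving[c2] <- moving[c1 - 1]
        moving[c1 - 1] <- "-"
        c1 <- c1 - 1
        c2 <- c2 - 1
      }
    }
    moving
  }
  # insertions: gaps in the draft row; deletions: gaps in the read row
  da <- shift_runs(qa, da)
  qa <- shift_runs(da, qa)
  list(qa = qa, da = da)
}

#' Polish a draft consensus by pileup voting
#'
#' A second seeded subsample of reads is aligned to the draft; read indels
#' are left-normalized (score-neutral shifts, as in standard variant-calling
#' practice) so that equivalent indel placements inside repeats vote at the
#' same draft position.  Every draft
#' position is re-voted as the plurality of `{A, C, G, T, deletion}` (ties
#' keep the draft base; positions with depth below 10 keep the draft base
#' with a warning).  Insertions are emitted when the identical inserted
#' string occurs in more than 50% of the aligned reads.  Finally every
#' maximal draft homopolymer run of length >= 2 is re-estimated between its
#' flanking anchor bases: per read, the segment between the anchor columns
#' is extracted (an anchor-column character equal to the run base counts as
#' part of the run -- a neighbouring run's indel can push the run's
#' outermost base onto the anchor); the modal segment length wins (ties
#' keep the draft's length) and the emitted content is the column-wise
#' majority over the modal-length segments, so a run shortened, lengthened
#' or carrying a substituted base in the draft is restored from the reads.
#' Reads not spanning both anchors are excluded from that run's vote.
#' Deterministic for a fixed seed.
#'
#' The voting pass is applied `rounds` times (stopping early at a fixed
#' point), always with the same seeded subsample: a first pass occasionally
#' leaves a run one base long or short, which the second pass then sees as a
#' clean draft run and corrects.
#'
#' @param draft draft consensus DNA string.
#' @param reads a [seq_records] data frame (dominant-cluster reads).
#' @param n polishing subsample size (default 200).
#' @param seed subsampling seed (disjoint from the draft seed).
#' @param band see [align_to_draft()].
#' @param rounds maximum number of voting passes.
#' @return The polished consensus DNA string.
#' @export
polish_consensus <- function(draft, reads, n = 200, seed = 2L, band = NULL,
                             rounds = 2) {
  reads <- as_seq_records(reads)
  # one seeded draw of up to 2n reads: the first n feed the pileup votes,
  # all of them feed the homopolymer run-length votes.  The run-length call
  # is the statistically tightest decision in the pipeline (at 200 reads the
  # modal length of an 8-nt run flips with ~7% probability under a 12%
  # error channel, at 400 with ~2%), and unlike the draft-stage subsample
  # these reads are uncorrelated with the draft's own run-length errors.
  n_draw <- min(2L * n, nrow(reads))
  idx <- if (nrow(reads) <= n) seq_len(nrow(reads))
         else with_seed(seed, sample.int(nrow(reads), n_draw))
  drawn <- reads$seq[idx]
  pile_seqs <- drawn[seq_len(min(n, length(drawn)))]
  aux_seqs <- if (length(drawn) > length(pile_seqs))
    drawn[(length(pile_seqs) + 1):length(drawn)] else character(0)
  out <- toupper(draft)
  for (round in seq_len(max(1, rounds))) {
    nxt <- polish_round(out, pile_seqs, band, aux_seqs)
    if (nxt == out) break
    out <- nxt
  }
  out
}

# One pileup-voting pass over an already drawn subsample.
polish_round <- function(draft, sub_seqs, band = NULL,
                         aux_seqs = character(0)) {
  alns <- lapply(sub_seqs, align_to_draft, draft = draft, band = band)
  alns <- alns[!vapply(alns, is.null, logical(1))]
  if (length(alns) == 0) stop("polish: no mappable reads")
  n_used <- length(alns)
  if (length(aux_seqs) > 0) {
    aux <- lapply(aux_seqs, align_to_draft, draft = draft, band = band)
    alns <- c(alns, aux[!vapply(aux, is.null, logical(1))])
  }
  draft <- toupper(draft)
  L <- nchar(draft)
  counts <- matrix(0L, nrow = 5, ncol = L,
                   dimnames = list(c("A", "C", "G", "T", "del"), NULL))
  ins_keys <- character(0)

  draft_chars <- strsplit(draft, "", fixed = TRUE)[[1]]
  r <- rle(draft_chars)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1
  hp <- which(r$lengths >= 2 & run_start > 1 & run_end < L)
  hp_runs <- data.frame(start = run_start[hp], end = run_end[hp],
                        base = r$values[hp], len = r$lengths[hp],
                        stringsAsFactors = FALSE)
  # per-run, per-read segment observed between the run's anchors
  seg_obs <- matrix(NA_character_, nrow = nrow(hp_runs), ncol = length(alns))

  for (ai in seq_along(alns)) {
    al <- alns[[ai]]
    nrm <- left_normalize_alignment(
      strsplit(al$aligned_read, "", fixed = TRUE)[[1]],
      strsplit(al$aligned_draft, "", fixed = TRUE)[[1]])
    qa <- nrm$qa
    da <- nrm$da
    dpos <- cumsum(da != "-")
    dcov <- da != "-"
    qcov <- qa != "-"
    is_aux <- ai > n_used  # auxiliary reads vote on run segments only
    # base and deletion counts
    if (!is_aux) {
      sel <- dcov & qcov
      rows <- match(qa[sel], c("A", "C", "G", "T"))
      cols <- dpos[sel]
      keep <- !is.na(rows)
      idx <- (cols[keep] - 1L) * 5L + rows[keep]
      sel_del <- dcov & !qcov
      idx <- c(idx, (dpos[sel_del] - 1L) * 5L + 5L)
      tab <- tabulate(idx, nbins = 5L * L)
      counts <- counts + matrix(tab, nrow = 5)
    }
    # insertion events (runs of draft gaps), keyed by position + string
    if (!is_aux && any(!dcov)) {
      g <- rle(!dcov)
      ge <- cumsum(g$lengths)
      gs <- ge - g$lengths + 1
      wi <- which(g$values)
      for (k in wi) {
        pos <- if (gs[k] == 1) 0L else dpos[gs[k] - 1]
        ins <- paste(qa[gs[k]:ge[k]][qa[gs[k]:ge[k]] != "-"], collapse = "")
        if (nchar(ins) > 0)
          ins_keys <- c(ins_keys, paste0(pos, ":", ins))
      }
    }
    # per-run observed lengths between anchors (vectorized over runs); a
    # read character sitting on an anchor column but equal to the run base
    # belongs to the run -- a neighbouring run's indel can push the run's
    # outermost base onto the anchor column as a mismatch, and ignoring it
    # would bias the length vote downward
    if (nrow(hp_runs) > 0) {
      colof <- which(dcov)  # alignment column of each draft position
      c1 <- colof[hp_runs$start - 1L]
      c2 <- colof[hp_runs$end + 1L]
      anchored <- qa[c1] != "-" & qa[c2] != "-" & (c2 - c1) >= 1L
      nq <- cumsum(qcov)  # read position reached at each column
      read_str <- paste(qa[qcov], collapse = "")
      segs <- paste0(ifelse(qa[c1] == hp_runs$base, hp_runs$base, ""),
                     substring(read_str, nq[c1] + 1L, nq[c2] - 1L),
                     ifelse(qa[c2] == hp_runs$base, hp_runs$base, ""))
      seg_obs[, ai] <- ifelse(anchored, segs, NA_character_)
    }
  }

  depth <- colSums(counts)
  low <- depth < 10
  if (any(low))
    warning(sum(low), " draft position(s) below depth 10 kept as draft")
  winner_idx <- integer(L)
  draft_row <- match(draft_chars, c("A", "C", "G", "T"))
  for (p in seq_len(L)) {
    cc <- counts[, p]
    mx <- max(cc)
    cand <- which(cc == mx)
    if (low[p] || (length(cand) > 1 && draft_row[p] %in% cand))
      winner_idx[p] <- draft_row[p]
    else winner_idx[p] <- cand[1]
  }

  # accepted insertions: identical string after the same position in > 50%
  ins_accept <- list()
  if (length(ins_keys) > 0) {
    tb <- table(ins_keys)
    for (key in names(tb)[tb > n_used / 2]) {
      parts <- strsplit(key, ":", fixed = TRUE)[[1]]
      ins_accept[[parts[1]]] <- parts[2]
    }
  }

  # re-voted runs: the modal observed segment length wins (ties keep the
  # draft's length), and the emitted content is the column-wise majority
  # over the modal-length segments -- boundary-spill characters correct the
  # length vote but are outvoted column-wise, so nothing is double-counted
  hp_segment <- character(nrow(hp_runs))
  if (nrow(hp_runs) > 0) {
    for (k in seq_len(nrow(hp_runs))) {
      draft_seg <- strrep(hp_runs$base[k], hp_runs$len[k])
      obs <- seg_obs[k, ]
      obs <- obs[!is.na(obs)]
      if (length(obs) == 0) { hp_segment[k] <- draft_seg; next }
      lens <- nchar(obs)
      tb <- table(lens)
      mx <- max(tb)
      modes <- as.integer(names(tb)[tb == mx])
      vote_len <- if (hp_runs$len[k] %in% modes) hp_runs$len[k] else modes[1]
      if (vote_len == 0) { hp_segment[k] <- ""; next }
      sel <- obs[lens == vote_len]
      if (length(sel) == 0) { hp_segment[k] <- draft_seg; next }
      m2 <- do.call(rbind, strsplit(sel, "", fixed = TRUE))
      hp_segment[k] <- paste(apply(m2, 2, function(col) {
        cc <- table(factor(col, levels = c("A", "C", "G", "T")))
        names(cc)[which.max(cc)]  # ties alphabetical
      }), collapse = "")
      if (nchar(hp_segment[k]) == 0) hp_segment[k] <- draft_seg
    }
  }
  in_run <- integer(L)  # run index covering each position (0 = none)
  ins_blocked <- logical(L + 1)  # insertions after position p suppressed
  if (nrow(hp_runs) > 0) {
    for (k in seq_len(nrow(hp_runs))) {
      in_run[hp_runs$start[k]:hp_runs$end[k]] <- k
      # block insertions after positions (start-1) .. end of the run
      ins_blocked[hp_runs$start[k]:(hp_runs$end[k] + 1L)] <- TRUE
    }
  }

  bases <- c("A", "C", "G", "T", "")
  out <- character(0)
  if (!is.null(ins_accept[["0"]])) out <- ins_accept[["0"]]
  p <- 1L
  while (p <= L) {
    k <- in_run[p]
    if (k > 0 && p == hp_runs$start[k]) {
      out <- c(out, hp_segment[k])
      p <- hp_runs$end[k] + 1L
      next
    }
    out <- c(out, bases[winner_idx[p]])
    key <- as.character(p)
    if (!ins_blocked[p + 1L] && !is.null(ins_accept[[key]]))
      out <- c(out, ins_accept[[key]])
    p <- p + 1L
  }
  paste(out, collapse = "")
}
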