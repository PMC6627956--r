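#' Seeded read subsampling
#'
#' Uniform sampling of `min(n, nrow(reads))` reads without replacement,
#' deterministic for a fixed seed.  The sampled order (not the input order)
#' is returned; it defines the order in which reads enter the partial-order
#' graph, so a draft consensus is fully reproducible from `(reads, seed)`.
#'
#' @param reads a [seq_records] data frame.
#' @param n target subsample size.
#' @param seed integer seed.
#' @return A [seq_records] data frame of `min(n, nrow(reads))` reads.
#' @export
subsample_reads <- function(reads, n, seed) {
  reads <- as_seq_records(reads)
  if (nrow(reads) <= n) {
    if (nrow(reads) < n)
      warning("only ", nrow(reads), " reads available (requested ", n,
              "); returning all")
    return(reads)
  }
  idx <- with_seed(seed, sample.int(nrow(reads), n))
  out <- reads[idx, , drop = FALSE]
  class(out) <- c("seq_records", "data.frame")
  out
}

#' Multiple alignment by partial-order graph construction
#'
#' Reads are added one at a time to a partial-order graph by optimal global
#' alignment (match +2, mismatch -2, gap -2); the graph is then linearised so
#' that every set of mutually aligned bases forms one column.  Removing the
#' gaps of row `i` reproduces read `i` exactly.
#'
#' @param reads a [seq_records] data frame (or character vector) of
#'   strand-normalized reads.
#' @param match,mismatch,gap alignment scores.
#' @param band half-width of the band around each graph node's approximate
#'   template position; `0` disables banding.  The default comfortably
#'   absorbs the indel drift of ~700-nt amplicon reads at ~12% error (a read
#'   the band cannot accommodate is automatically realigned unbanded).
#' @return A `barcode_msa` list: `row_ids`, `rows` (equal-length gapped
#'   strings), `n_columns`.
#' @export
build_msa <- function(reads, match = 2, mismatch = -2, gap = -2, band = 100) {
  reads <- as_seq_records(reads)
  if (nrow(reads) == 0) stop("build_msa: no reads")
  rows <- as.character(poa_msa_cpp(reads$seq, match, mismatch, gap,
                                   as.integer(band)))
  structure(list(row_ids = reads$id, rows = rows,
                 n_columns = nchar(rows[1])),
            class = "barcode_msa")
}

#' @export
print.barcode_msa <- function(x, ...) {
  cat(sprintf("<barcode_msa: %d rows x %d columns>\n", length(x$rows),
              x$n_columns))
  invisible(x)
}

#' Plurality inclusion threshold
#'
#' The minimum number of aligned reads that must carry a base for it to enter
#' the draft consensus: `p * n_aligned_reads`, as a real value (no rounding).
#'
#' @param n number of aligned reads.
#' @param p plurality fraction, in `(0, 0.5]` (default 0.15).
#' @return The threshold `p * n`.
#' @export
plurality_threshold <- function(n, p = 0.15) {
  stopifnot(p > 0, p <= 0.5, n >= 1)
  p * n
}

#' Plurality draft consensus from a multiple alignment
#'
#' Per column: columns with more than 50% gaps are dropped; otherwise the
#' most frequent non-gap base (ties broken alphabetically) is emitted if at
#' least `p * n_rows` reads carry it, else a generic `N`.  All `N`s are then
#' deleted, so the draft is gap- and N-free.
#'
#' @param msa a [build_msa()] result.
#' @param p plurality fraction (default 0.15).
#' @return The draft consensus DNA string.
#' @export
plurality_consensus <- function(msa, p = 0.15) {
  stopifnot(inherits(msa, "barcode_msa"))
  m <- do.call(rbind, strsplit(msa$rows, "", fixed = TRUE))
  n <- nrow(m)
  thr <- plurality_threshold(n, p)
  counts <- vapply(c("A", "C", "G", "T", "-"),
                   function(b) colSums(m == b), numeric(ncol(m)))
  if (ncol(m) == 1) counts <- matrix(counts, nrow = 1,
                                     dimnames = list(NULL,
                                                     c("A", "C", "G", "T", "-")))
  gap_majority <- counts[, "-"] > n / 2
  base_counts <- counts[, c("A", "C", "G", "T"), drop = FALSE]
  best <- max.col(base_counts, ties.method = "first")  # alphabetical ties
  best_count <- base_counts[cbind(seq_len(nrow(base_counts)), best)]
  call <- ifelse(gap_majority, "", ifelse(best_count >= thr,
                                          c("A", "C", "G", "T")[best], "N"))
  draft <- gsub("N", "", paste(call, collapse = ""), fixed = TRUE)
  if (nchar(draft) == 0) stop("plurality consensus is empty")
  draft
}
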