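#' Global-alignment identity between two sequences
#'
#' Needleman-Wunsch with affine gaps (defaults: match +1, mismatch -1, gap
#' open -2, gap extend -1).  Identity is `matches / alignment_columns`, with
#' gap columns counted in the denominator.  Because co-optimal alignments can
#' differ in their match counts, the identity is always computed on a
#' canonical ordering of the pair, which makes it exactly symmetric.
#'
#' @param a,b DNA strings.
#' @param match,mismatch,gap_open,gap_extend alignment scores.
#' @param band optional band half-width around the length-proportional
#'   diagonal; `0` (default) runs the full dynamic programme.
#' @return Identity fraction in `[0, 1]`.
#' @export
pairwise_identity <- function(a, b, match = 1, mismatch = -1,
                              gap_open = -2, gap_extend = -1, band = 0) {
  a <- toupper(a)
  b <- toupper(b)
  if (b < a) { tmp <- a; a <- b; b <- tmp }
  nw_align_cpp(a, b, match, mismatch, gap_open, gap_extend,
               as.integer(band))$identity
}

# distinct k-mer set of a sequence
kmer_set <- function(seq, k = 8) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  unique(substring(seq, 1:(n - k + 1), k:n))
}

#' Greedy identity clustering
#'
#' Reads are processed in input order; each read joins the first existing
#' cluster whose centroid it matches at identity `>= t`, otherwise it founds
#' a new cluster with itself as centroid.  Clusters are returned sorted by
#' abundance (ties broken by centroid input order).  An optional shared
#' 8-mer prefilter skips centroid comparisons that cannot reach the
#' threshold; pairwise alignments are banded wide enough to be exact at the
#' error rates this pipeline targets.
#'
#' @param reads a [seq_records] data frame (or character vector).
#' @param t identity threshold (default 0.70).
#' @param prefilter use the shared 8-mer prefilter (skip a centroid when
#'   fewer than 3 distinct 8-mers are shared).
#' @param band band half-width for the pairwise alignments; `NULL` picks
#'   `max(80, 0.12 * length) + length difference`.
#' @return List of clusters, each `list(centroid_id, centroid_seq,
#'   member_ids, member_idx, abundance)`, with class `barcode_clusters`.
#' @export
greedy_cluster <- function(reads, t = 0.70, prefilter = TRUE, band = NULL) {
  reads <- as_seq_records(reads)
  n <- nrow(reads)
  if (n == 0) stop("greedy_cluster: no reads")
  cent_idx <- integer(0)
  cent_kmers <- list()
  assign <- integer(n)
  for (i in seq_len(n)) {
    si <- reads$seq[i]
    ki <- NULL
    hit <- 0L
    for (ci in seq_along(cent_idx)) {
      sc <- reads$seq[cent_idx[ci]]
      # the prefilter only ever skips alignments; applying it from the second
      # centroid on preserves results while sparing the k-mer scan for reads
      # that match the first centroid immediately
      if (prefilter && ci > 1L) {
        if (is.null(ki)) ki <- kmer_set(si)
        if (sum(ki %in% cent_kmers[[ci]]) < 3L) next
      }
      b <- if (is.null(band)) {
        max(80L, ceiling(0.12 * max(nchar(si), nchar(sc)))) +
          abs(nchar(si) - nchar(sc))
      } else band
      id <- nw_align_cpp(si, sc, 1, -1, -2, -1, as.integer(b))$identity
      if (id >= t) { hit <- ci; break }
    }
    if (hit == 0L) {
      cent_idx <- c(cent_idx, i)
      if (prefilter)
        cent_kmers[[length(cent_idx)]] <- if (is.null(ki)) kmer_set(si) else ki
      assign[i] <- length(cent_idx)
    } else assign[i] <- hit
  }
  clusters <- lapply(seq_along(cent_idx), function(ci) {
    idx <- which(assign == ci)
    list(centroid_id = reads$id[cent_idx[ci]],
         centroid_seq = reads$seq[cent_idx[ci]],
         member_ids = reads$id[idx], member_idx = idx,
         abundance = length(idx))
  })
  ab <- vapply(clusters, `[[`, integer(1), "abundance")
  clusters <- clusters[order(-ab, seq_along(ab))]
  structure(clusters, class = "barcode_clusters")
}

#' @export
print.barcode_clusters <- function(x, ...) {
  cat(sprintf("<barcode_clusters: %d cluster(s); sizes %s>\n", length(x),
              paste(vapply(x, `[[`, integer(1), "abundance"),
                    collapse = ", ")))
  invisible(x)
}

#' Select the most abundant cluster
#'
#' Exact abundance ties are broken toward the cluster whose centroid appeared
#' first in the input, which makes the choice deterministic.
#'
#' @param clusters result of [greedy_cluster()].
#' @return A single cluster (list).
#' @export
select_dominant <- function(clusters) {
  if (length(clusters) == 0) stop("no clusters")
  ab <- vapply(clusters, `[[`, integer(1), "abundance")
  first_idx <- vapply(clusters, function(cl) min(cl$member_idx), integer(1))
  # abundance-maximal; tie -> earliest centroid in input order
  cand <- which(ab == max(ab))
  cent <- vapply(clusters[cand], function(cl)
    cl$member_idx[match(cl$centroid_id, cl$member_ids)], integer(1))
  clusters[[cand[which.min(cent)]]]
}
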