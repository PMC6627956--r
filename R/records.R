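#' Sequence record collections
#'
#' Reads and consensus sequences are carried through the pipeline as plain
#' data frames with class `seq_records` and columns `id`, `seq` and `qual`
#' (`qual` is the Phred+33 encoded quality string, or `NA` when absent, as for
#' FASTA input).  Sequences are upper-case strings over the alphabet
#' `A`, `C`, `G`, `T`, `N`; when a quality string is present its length must
#' equal the sequence length.
#'
#' @param id character vector of record identifiers.
#' @param seq character vector of DNA sequences.
#' @param qual optional character vector of Phred+33 quality strings.
#' @return A `seq_records` data frame.
#' @examples
#' seq_records(c("r1", "r2"), c("ACGT", "ggta"))
#' @export
seq_records <- function(id, seq, qual = NULL) {
  if (length(id) != length(seq))
    stop("id and seq must have the same length")
  if (is.null(qual)) qual <- rep(NA_character_, length(seq))
  out <- data.frame(id = as.character(id), seq = toupper(as.character(seq)),
                    qual = as.character(qual), stringsAsFactors = FALSE)
  validate_records(out)
  class(out) <- c("seq_records", "data.frame")
  out
}

validate_records <- function(x) {
  stopifnot(all(c("id", "seq", "qual") %in% names(x)))
  if (nrow(x) == 0) return(invisible(x))
  bad <- !grepl("^[ACGTN]+$", x$seq)
  if (any(bad))
    stop("invalid sequence (empty or non-ACGTN) in record(s): ",
         paste(utils::head(x$id[bad], 5), collapse = ", "))
  has_q <- !is.na(x$qual)
  mism <- has_q & nchar(x$qual) != nchar(x$seq)
  if (any(mism))
    stop("quality length differs from sequence length in record(s): ",
         paste(utils::head(x$id[mism], 5), collapse = ", "))
  invisible(x)
}

as_seq_records <- function(x) {
  if (inherits(x, "seq_records")) return(x)
  if (is.character(x)) {
    ids <- names(x)
    if (is.null(ids)) ids <- sprintf("seq%d", seq_along(x))
    return(seq_records(ids, unname(x)))
  }
  if (is.data.frame(x)) {
    if (!"qual" %in% names(x)) x$qual <- NA_character_
    return(seq_records(x$id, x$seq, x$qual))
  }
  stop("cannot interpret input as sequence records")
}

#' @export
print.seq_records <- function(x, ...) {
  cat(sprintf("<seq_records: %d sequence(s)%s>\n", nrow(x),
              if (any(!is.na(x$qual))) ", with qualities" else ""))
  if (nrow(x) > 0) {
    show <- utils::head(x, 5)
    cat(sprintf("  %s  [%d nt]\n", show$id, nchar(show$seq)), sep = "")
    if (nrow(x) > 5) cat(sprintf("  ... and %d more\n", nrow(x) - 5))
  }
  invisible(x)
}

#' Reverse-complement DNA strings
#'
#' @param x character vector of DNA sequences (`ACGTN`).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Decode a Phred+33 quality string to integer scores
#'
#' @param qual character vector of quality strings.
#' @return List of integer vectors.
#' @export
phred_scores <- function(qual) {
  lapply(qual, function(q) {
    if (is.na(q)) return(integer(0))
    utf8ToInt(q) - 33L
  })
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}
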