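#' Read a FASTQ file
#'
#' Parses plain or gzip-compressed four-line-per-record FASTQ.  Identifiers
#' are truncated at the first whitespace, sequences are upper-cased, and
#' qualities are kept as Phred+33 strings.  A record whose quality string
#' length differs from its sequence length is a hard error naming the record.
#'
#' @param path path to a FASTQ file (optionally `.gz`).
#' @return A [seq_records] data frame, in file order.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("cannot read FASTQ file: ", path)
  lines <- readLines(path)
  if (length(lines) == 0) return(seq_records(character(0), character(0)))
  if (length(lines) %% 4 != 0)
    stop("malformed FASTQ (line count not a multiple of 4): ", path)
  n <- length(lines) / 4
  hdr <- lines[seq(1, by = 4, length.out = n)]
  if (!all(startsWith(hdr, "@")))
    stop("malformed FASTQ (header line missing '@'): ", path)
  ids <- sub("\\s.*$", "", sub("^@", "", hdr))
  seqs <- toupper(lines[seq(2, by = 4, length.out = n)])
  quals <- lines[seq(4, by = 4, length.out = n)]
  bad <- nchar(quals) != nchar(seqs)
  if (any(bad))
    stop("FASTQ quality/sequence length mismatch in record(s): ",
         paste(utils::head(ids[bad], 5), collapse = ", "))
  seq_records(ids, seqs, quals)
}

#' Read a FASTA file
#'
#' Accepts wrapped (multi-line) and gzip-compressed FASTA.  Identifiers are
#' truncated at the first whitespace and sequences upper-cased.
#'
#' @param path path to a FASTA file.
#' @return A [seq_records] data frame, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("cannot read FASTA file: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  seq_records(ids, toupper(as.character(ss)))
}

#' Write sequences as FASTA
#'
#' Sequences are wrapped at 80 columns.  Duplicate identifiers are written as
#' given, with a warning.
#'
#' @param records a [seq_records] data frame (or named character vector).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  records <- as_seq_records(records)
  if (anyDuplicated(records$id))
    warning("duplicate ids written to FASTA: ",
            paste(unique(records$id[duplicated(records$id)]), collapse = ", "))
  ss <- Biostrings::DNAStringSet(stats::setNames(records$seq, records$id))
  Biostrings::writeXStringSet(ss, filepath = path, width = 80L)
  invisible(path)
}

#' Write sequences as FASTQ
#'
#' Records lacking a quality string are written with a constant Q12 line.
#'
#' @inheritParams write_fasta
#' @return `path`, invisibly.
#' @export
write_fastq <- function(records, path) {
  records <- as_seq_records(records)
  qual <- ifelse(is.na(records$qual),
                 vapply(nchar(records$seq),
                        function(n) strrep(rawToChar(as.raw(12L + 33L)), n),
                        character(1)),
                 records$qual)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", records$id, "\n", records$seq, "\n+\n", qual), con,
             sep = "\n")
  invisible(path)
}

#' Read a tag table
#'
#' Tab-separated table with columns `sample_id`, `fwd_tag`, `rev_tag` used for
#' dual-tag demultiplexing.  Tags must be at least 8 nt and no tag sequence
#' may be shared between samples.
#'
#' @param path path to a TSV file (a header line is required).
#' @return Data frame with columns `sample_id`, `fwd_tag`, `rev_tag`.
#' @export
read_tag_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_tag_table(tab)
}

validate_tag_table <- function(tab) {
  need <- c("sample_id", "fwd_tag", "rev_tag")
  if (!all(need %in% names(tab)))
    stop("tag table needs columns: ", paste(need, collapse = ", "))
  if (nrow(tab) == 0) stop("tag table is empty")
  tab$fwd_tag <- toupper(tab$fwd_tag)
  tab$rev_tag <- toupper(tab$rev_tag)
  if (any(nchar(c(tab$fwd_tag, tab$rev_tag)) < 8))
    stop("tags must be at least 8 nt")
  if (!all(grepl("^[ACGT]+$", c(tab$fwd_tag, tab$rev_tag))))
    stop("tags must be ACGT strings")
  if (anyDuplicated(tab$sample_id)) stop("duplicate sample ids in tag table")
  all_tags <- c(tab$fwd_tag, tab$rev_tag)
  owner <- rep(tab$sample_id, 2)
  dup <- duplicated(all_tags) | duplicated(all_tags, fromLast = TRUE)
  if (any(dup) && length(unique(owner[dup])) > 1)
    stop("the same tag sequence is used by more than one sample")
  tab[, need]
}
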