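# Readers and writers shared by all stages: FASTQ (plain or gzipped,
# Phred+33) through Biostrings, and headered TSV tables with schema checks.

#' Read a FASTQ file into a data.frame
#'
#' Handles plain and gzipped files transparently; qualities are returned as
#' Phred+33 strings alongside the sequence.
#'
#' @param path Path to a `.fastq` or `.fastq.gz` file.
#' @return data.frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  q <- S4Vectors::mcols(x)$qualities
  data.frame(
    id = names(x),
    seq = as.character(x),
    qual = as.character(q),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Write reads to a gzipped FASTQ file
#'
#' @param reads data.frame with columns `id`, `seq`, `qual` (Phred+33
#'   quality strings, same length as each sequence).
#' @param path Output path; compressed when it ends in `.gz`.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)))
  if (any(nchar(reads$seq) != nchar(reads$qual))) {
    stop("sequence and quality lengths differ")
  }
  s <- Biostrings::DNAStringSet(reads$seq)
  names(s) <- reads$id
  Biostrings::writeXStringSet(
    s, path, format = "fastq",
    qualities = Biostrings::BStringSet(reads$qual),
    compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read a headered TSV table, checking required columns
#'
#' @param path Path to a tab-separated file with a header row.
#' @param required Character vector of column names that must be present;
#'   a missing column is an error naming it. Extra columns are kept with a
#'   warning.
#' @return data.frame of the table contents.
#' @export
read_table_checked <- function(path, required = NULL) {
  if (!file.exists(path)) stop("table not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(required)) {
    missing <- setdiff(required, names(df))
    if (length(missing)) {
      stop("missing required column(s): ", paste(missing, collapse = ", "))
    }
    extra <- setdiff(names(df), required)
    if (length(extra)) {
      warning("extra column(s) preserved: ", paste(extra, collapse = ", "))
    }
  }
  df
}

#' Write a data.frame as a headered TSV
#'
#' @param df data.frame to write.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
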