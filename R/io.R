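# ---- readers / writers ------------------------------------------------------
# AIRR-style Rearrangement TSV (tab-separated, no quoting, "NA" for missing),
# FASTQ via Biostrings, peptide lists as TSV. write/read round-trips are
# identities on supported columns; unknown columns pass through verbatim.

#' Read an AIRR-style rearrangement TSV
#'
#' @param path TSV file with a header row; `sequence_id` and `sequence` are
#'   mandatory.
#' @return data.frame; a zero-row file with a header is an empty table, a
#'   missing mandatory column is a schema error naming the column.
#' @export
read_airr <- function(path) {
  df <- utils::read.delim(path, sep = "\t", quote = "", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = NA)
  for (col in c("sequence_id", "sequence"))
    if (!col %in% names(df))
      stop("not a rearrangement table: missing mandatory column '", col, "'")
  if ("productive" %in% names(df) && !is.logical(df$productive))
    df$productive <- df$productive %in% c("T", "TRUE", "true")
  df
}

#' Write an AIRR-style rearrangement TSV
#'
#' @param table rearrangement data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_airr <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Write simulated reads as FASTQ (index tag and UMI inline at read start)
#'
#' @param reads read data.frame from [generate_reads()].
#' @param path output FASTQ (".gz" suffix gzips).
#' @return `path`, invisibly.
#' @export
write_reads_fastq <- function(reads, path) {
  full <- paste0(reads$index_tag, reads$umi, reads$payload)
  qual <- paste0(strrep("I", nchar(reads$index_tag) + nchar(reads$umi)),
                 reads$qualities)
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(full),
    Biostrings::PhredQuality(qual))
  names(x) <- reads$read_id
  Biostrings::writeQualityScaledXStringSet(x, path,
                                           compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read inline-tagged FASTQ back into a read table
#'
#' @param path FASTQ written by [write_reads_fastq()].
#' @param umi_length UMI length used at write time (8 or 12).
#' @return read data.frame (`read_id`, `index_tag`, `umi`, `payload`,
#'   `qualities`).
#' @export
read_reads_fastq <- function(path, umi_length) {
  # metadata columns are not used; suppress the drop notice
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  s <- as.character(x)
  q <- as.character(Biostrings::quality(x))
  pre <- 6L + umi_length
  data.frame(read_id = names(x),
             index_tag = substr(s, 1L, 6L),
             umi = substr(s, 7L, pre),
             payload = substr(s, pre + 1L, nchar(s)),
             qualities = substr(q, pre + 1L, nchar(q)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Read a peptide observation TSV (peptide, q_value, mode)
#'
#' @param path TSV file.
#' @return data.frame with `peptide`, `q_value`, `mode`.
#' @export
read_peptides <- function(path) {
  df <- utils::read.delim(path, sep = "\t", quote = "", header = TRUE,
                          stringsAsFactors = FALSE)
  for (col in c("peptide", "q_value", "mode"))
    if (!col %in% names(df)) stop("peptide table missing column '", col, "'")
  if (!all(df$mode %in% c("DDA", "DIA")))
    stop("mode must be DDA or DIA")
  df
}

#' Write a generic tidy TSV (no quoting, NA for missing)
#'
#' @param table data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
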