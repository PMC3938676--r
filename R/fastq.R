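#' FASTQ input and output
#'
#' Thin wrappers around Biostrings for 4-line FASTQ records; gzip is
#' transparent in both directions (by file extension on write, by content on
#' read). Qualities are ignored on read — the pipeline uses tag occurrence
#' counts, not base qualities, as its quality signal.
#'
#' @param path FASTQ path (`.gz` allowed).
#' @return `read_fastq()`: tibble with columns `id`, `seq`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  tibble::tibble(id = names(x), seq = unname(as.character(x)))
}

#' @param seq Character vector of sequences to write.
#' @param id Record identifiers.
#' @param quality_char Single character used as the uniform quality score.
#' @rdname read_fastq
#' @export
write_fastq <- function(seq, id, path, quality_char = "I") {
  stopifnot(length(seq) == length(id), nchar(quality_char) == 1L)
  x <- Biostrings::DNAStringSet(seq)
  names(x) <- id
  qual <- Biostrings::BStringSet(strrep(quality_char, nchar(seq)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual,
                              compress = endsWith(path, ".gz"))
  invisible(path)
}
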