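#' Read / write FASTQ with qualities
#'
#' Thin wrappers around Biostrings keeping sequence and per-base quality
#' together in a `QualityScaledDNAStringSet` (Phred scaling).  Gzipped
#' files are handled transparently on read.
#'
#' @param file FASTQ path.
#' @return [read_fastq()]: a `QualityScaledDNAStringSet`.
#' @export
read_fastq <- function(file) {
  # the id line is kept as the set's names; per-read metadata columns are
  # not carried and Biostrings warns about dropping them
  withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(file),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
}

#' @rdname read_fastq
#' @param reads a `QualityScaledDNAStringSet`.
#' @export
write_fastq <- function(reads, file) {
  Biostrings::writeQualityScaledXStringSet(reads, file)
  invisible(file)
}

#' Digitally convert a paired-end library to truncated single reads
#'
#' Emulates short single-read sequencing from an existing paired-end
#' library: the reverse reads are discarded and each forward read is
#' truncated to its first `keep_length` bases, sequence and quality in
#' lockstep.  Reads already shorter than `keep_length` pass through
#' unchanged, so the operation is idempotent and conserves read count.
#'
#' @param fastq_r1 forward reads, a `QualityScaledDNAStringSet`.
#' @param fastq_r2 reverse reads (ignored beyond validation); may be
#'   `NULL`.
#' @param keep_length number of leading bases to keep (default 100).
#' @return Truncated forward reads as a `QualityScaledDNAStringSet`.
#' @export
simulate_single_end <- function(fastq_r1, fastq_r2 = NULL,
                                keep_length = 100L) {
  keep_length <- as.integer(keep_length)
  if (is.na(keep_length) || keep_length < 1L)
    abort_samsa("keep_length must be >= 1", "samsa_validation_error")
  if (!methods::is(fastq_r1, "QualityScaledXStringSet"))
    abort_samsa("fastq_r1 must be a QualityScaledDNAStringSet (see read_fastq)",
                "samsa_validation_error")
  if (any(Biostrings::width(fastq_r1) !=
          Biostrings::width(Biostrings::quality(fastq_r1))))
    abort_samsa("sequence/quality length mismatch in input",
                "samsa_validation_error")
  end <- pmin(Biostrings::width(fastq_r1), keep_length)
  IRanges::narrow(fastq_r1, start = 1L, end = end)
}
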