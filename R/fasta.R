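#' Read and write FASTA files
#'
#' Thin wrappers around Biostrings that present sequences as a named
#' character vector. Record order is preserved; multi-line (wrapped)
#' sequences are concatenated; the id is the first whitespace-delimited
#' token of the header. Duplicate ids raise a warning but both records
#' are kept. An empty file is an error of class `codonlm_empty_input`.
#'
#' @param path File path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  cl_assert(is.character(path) && length(path) == 1L && file.exists(path),
            paste0("no such file: ", path), "codonlm_io_error")
  x <- tryCatch(Biostrings::readBStringSet(path),
                error = function(e) cl_stop(paste0("malformed FASTA: ",
                                                   conditionMessage(e)),
                                            "codonlm_io_error"))
  if (length(x) == 0L)
    cl_stop(paste0("empty FASTA file: ", path), "codonlm_empty_input")
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids))
    warning("duplicate ids in ", path, "; keeping all records")
  stats::setNames(as.character(x), ids)
}

#' @param seqs Named character vector of sequences.
#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  cl_assert(is.character(seqs) && length(seqs) > 0L && !is.null(names(seqs)),
            "seqs must be a nonempty named character vector", "codonlm_bad_input")
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}
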