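#' Transcript records
#'
#' The unit flowing through corpus construction is a data frame with
#' columns `id`, `cds`, `protein` and optionally `tpm`. The constructor
#' derives the protein by translation when it is not supplied and checks
#' that every CDS translates to its protein.
#'
#' @param id Character vector of identifiers.
#' @param cds Character vector of coding sequences.
#' @param protein Optional character vector of proteins; derived by
#'   [translate_cds()] when `NULL`.
#' @param tpm Optional numeric expression values (TPM).
#' @param code A [genetic_code()].
#' @return A data frame with columns `id`, `cds`, `protein`, `tpm`.
#' @export
transcript_records <- function(id, cds, protein = NULL, tpm = NULL,
                               code = genetic_code()) {
  cl_assert(length(id) == length(cds), "id and cds lengths differ",
            "codonlm_bad_input")
  tr <- vapply(cds, translate_cds, "", code = code, USE.NAMES = FALSE)
  if (is.null(protein)) {
    protein <- tr
  } else {
    cl_assert(identical(unname(protein), tr),
              "cds does not translate to protein", "codonlm_bad_input")
  }
  if (is.null(tpm)) tpm <- rep(NA_real_, length(id))
  data.frame(id = as.character(id), cds = as.character(cds),
             protein = as.character(protein), tpm = as.numeric(tpm),
             stringsAsFactors = FALSE)
}

# minimal structural check used by the pipeline verbs
check_records <- function(records, need_tpm = FALSE) {
  cl_assert(is.data.frame(records) &&
              all(c("id", "cds", "protein") %in% names(records)),
            "records must be a data frame with id, cds, protein columns",
            "codonlm_bad_input")
  if (need_tpm)
    cl_assert("tpm" %in% names(records) && !anyNA(records$tpm),
              "records lack TPM values required by the expression filter",
              "codonlm_missing_tpm")
  invisible(records)
}
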