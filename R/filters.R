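#' Expression filter
#'
#' Keeps transcripts whose expression is strictly greater than the
#' threshold (default 5 TPM, the conventional cutoff for highly expressed
#' transcripts). Record order is preserved.
#'
#' @param records Records data frame (see [transcript_records()]).
#' @param threshold TPM cutoff; strict inequality.
#' @return Filtered records.
#' @export
filter_by_tpm <- function(records, threshold = 5) {
  if (nrow(records) == 0L) return(records)
  check_records(records, need_tpm = TRUE)
  out <- records[records$tpm > threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' CAI / minimum-free-energy filter
#'
#' Keeps records with `compute_cai(cds) >= cai_min` and, when an MFE
#' provider is supplied, predicted folding free energy `<= mfe_max`.
#' An absent bound imposes no constraint. Requesting an MFE bound without
#' an available provider is an error (`codonlm_no_mfe_provider`), never a
#' silent pass-through.
#'
#' @param records Records data frame.
#' @param table A [codon_usage_table()] for the CAI.
#' @param cai_min Lower CAI bound, or `NULL`.
#' @param mfe_max Upper MFE bound (kcal/mol), or `NULL`.
#' @param mfe_provider An [mfe_provider()], required when `mfe_max` is set.
#' @param code A [genetic_code()].
#' @return Filtered records.
#' @export
filter_by_cai_mfe <- function(records, table, cai_min = NULL, mfe_max = NULL,
                              mfe_provider = NULL, code = genetic_code()) {
  check_records(records)
  if (!is.null(mfe_max) &&
      (is.null(mfe_provider) || !mfe_available(mfe_provider)))
    cl_stop("MFE bound requested but no MFE provider is available",
            "codonlm_no_mfe_provider")
  keep <- rep(TRUE, nrow(records))
  if (!is.null(cai_min) && nrow(records) > 0L) {
    cai <- vapply(records$cds, compute_cai, 0, table = table, code = code,
                  USE.NAMES = FALSE)
    keep <- keep & cai >= cai_min
  }
  if (!is.null(mfe_max) && nrow(records) > 0L) {
    mfe <- compute_mfe(mfe_provider, records$cds)
    keep <- keep & !is.na(mfe) & mfe <= mfe_max
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Default admixture proportions
#'
#' The shipped preset of admixture proportions used to build a series of
#' training corpora with increasing shares of one-codon-optimized
#' sequences. These are this package's defaults, not values taken from
#' any external study.
#'
#' @return Numeric vector of proportions.
#' @export
default_jcat_proportions <- function() c(0, 0.1, 0.25, 0.5)

#' Admix one-codon-optimized sequences into a corpus
#'
#' Replaces the CDS of a uniformly sampled `round(proportion * n)` subset
#' of records by its [jcat_optimize()] recoding; proteins are unchanged.
#' The sampled subset is reproducible under `seed`.
#'
#' @param records Records data frame.
#' @param proportion Fraction of records to replace, in \[0, 1\].
#' @param table A [codon_usage_table()].
#' @param code A [genetic_code()].
#' @param seed Integer seed for the subset draw.
#' @return Records with the replaced CDSs; the integer indices of the
#'   replaced rows are attached as attribute `"replaced"`.
#' @export
mix_jcat <- function(records, proportion, table, code = genetic_code(),
                     seed = 1L) {
  check_records(records)
  cl_assert(is.numeric(proportion) && proportion >= 0 && proportion <= 1,
            "proportion must be in [0, 1]", "codonlm_bad_input")
  n <- nrow(records)
  k <- round(proportion * n)
  idx <- if (k > 0L) withr::with_seed(seed, sort(sample.int(n, k))) else integer(0)
  if (length(idx) > 0L)
    records$cds[idx] <- vapply(records$protein[idx], jcat_optimize, "",
                               table = table, code = code, USE.NAMES = FALSE)
  attr(records, "replaced") <- idx
  records
}

#' Split records into training and test sets
#'
#' Seeded, disjoint and exhaustive partition; the test set has
#' `round(test_fraction * n)` records (at least 1).
#'
#' @param records Records data frame with at least 2 rows.
#' @param test_fraction Fraction in (0, 1).
#' @param seed Integer seed.
#' @return List with elements `train` and `test`.
#' @export
train_test_split <- function(records, test_fraction = 0.2, seed = 1L) {
  check_records(records)
  cl_assert(nrow(records) >= 2L, "need at least 2 records to split",
            "codonlm_bad_input")
  cl_assert(test_fraction > 0 && test_fraction < 1,
            "test_fraction must be in (0, 1)", "codonlm_bad_input")
  n <- nrow(records)
  k <- max(1L, round(test_fraction * n))
  idx <- withr::with_seed(seed, sort(sample.int(n, k)))
  test <- records[idx, , drop = FALSE]
  train <- records[-idx, , drop = FALSE]
  rownames(test) <- rownames(train) <- NULL
  list(train = train, test = test)
}
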