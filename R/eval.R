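#' Per-codon prediction accuracy
#'
#' Fraction of positions at which two coding sequences carry the
#' identical codon. Both sequences must have the same codon count.
#'
#' @param pred,ref CDS strings.
#' @return Fraction in \[0, 1\].
#' @export
codon_accuracy <- function(pred, ref) {
  p <- split_codons(pred)
  r <- split_codons(ref)
  cl_assert(length(p) == length(r), "codon counts differ",
            "codonlm_length_error")
  mean(p == r)
}

#' Codon usage frequencies of a set of sequences
#'
#' Pooled codon counts over all sequences, normalized to sum 1, in fixed
#' lexicographic codon order.
#'
#' @param cds_list Character vector of CDSs.
#' @return Named numeric vector of length 64 summing to 1.
#' @export
usage_frequencies <- function(cds_list) {
  cl_assert(is.character(cds_list) && length(cds_list) > 0L,
            "cds_list must be nonempty", "codonlm_empty_input")
  cod <- unlist(lapply(cds_list, split_codons), use.names = FALSE)
  cnt <- table(factor(cod, levels = all_codons()))
  v <- as.numeric(cnt) / length(cod)
  stats::setNames(v, all_codons())
}

#' Bicodon (codon-pair) usage frequencies
#'
#' Counts of ordered adjacent codon pairs within each sequence (pairs
#' never span sequence boundaries), normalized to sum 1, in lexicographic
#' order of the 4096 pairs.
#'
#' @param cds_list Character vector of CDSs, each at least 2 codons.
#' @return Named numeric vector of length 4096 summing to 1.
#' @export
pair_usage_frequencies <- function(cds_list) {
  cl_assert(is.character(cds_list) && length(cds_list) > 0L,
            "cds_list must be nonempty", "codonlm_empty_input")
  levels <- as.vector(t(outer(all_codons(), all_codons(), paste, sep = ":")))
  pairs <- unlist(lapply(cds_list, function(s) {
    cod <- split_codons(s)
    cl_assert(length(cod) >= 2L, "bicodon usage needs >= 2 codons per sequence",
              "codonlm_length_error")
    paste(cod[-length(cod)], cod[-1L], sep = ":")
  }), use.names = FALSE)
  cnt <- table(factor(pairs, levels = sort(levels)))
  stats::setNames(as.numeric(cnt) / length(pairs), names(cnt))
}

#' Pearson correlation
#'
#' Standard product-moment correlation with explicit validation (equal
#' length >= 2, nonzero variance in both vectors).
#'
#' @param x,y Numeric vectors.
#' @return Correlation in \[-1, 1\].
#' @export
pearson_corr <- function(x, y) {
  cl_assert(length(x) == length(y) && length(x) >= 2L,
            "need equal-length vectors of length >= 2", "codonlm_bad_input")
  cl_assert(stats::sd(x) > 0 && stats::sd(y) > 0,
            "zero variance input", "codonlm_zero_variance")
  stats::cor(x, y)
}

#' Evaluate a model on held-out sequences
#'
#' The full evaluation battery: every test protein is decoded with the
#' codon stream zeroed ([predict.codonlm()]); per-sequence codon accuracy
#' against the reference CDS is summarized by its median; amino-acid
#' fidelity (fraction of positions whose decoded codon is at least
#' synonymous) is reported alongside; CAI of each decoded sequence is
#' computed against the usage table; codon and bicodon usage frequency
#' vectors of the decoded set are correlated (Pearson) against the
#' training corpus; MFE per decoded sequence is added when a provider is
#' available.
#'
#' @param object A fitted [codonlm()].
#' @param test_records Records data frame with reference CDSs.
#' @param train_cds Training-corpus CDSs defining the reference usage
#'   vectors; defaults to the corpus the model was fitted on.
#' @param table A [codon_usage_table()] for CAI; defaults to the model's
#'   training-corpus table.
#' @param mfe_provider Optional [mfe_provider()].
#' @param constrain Constrain decoding to synonymous families.
#' @return Object of class `codonlm_eval`: list with `per_seq` (data
#'   frame: id, accuracy, aa_fidelity, cai, mfe), `median_accuracy`,
#'   `cai_values`, `usage_pred`, `usage_ref`, `pair_usage_pred`,
#'   `pair_usage_ref`, `pcc_usage`, `pcc_pair`, `constrain`.
#' @export
evaluate_model <- function(object, test_records, train_cds = NULL,
                           table = NULL, mfe_provider = NULL,
                           constrain = FALSE) {
  stopifnot(inherits(object, "codonlm"))
  check_records(test_records)
  cl_assert(nrow(test_records) > 0L, "empty test set", "codonlm_empty_input")
  train_cds <- train_cds %||% object$train_cds
  table <- table %||% object$train_usage
  code <- object$code

  pred <- predict(object, test_records$protein, constrain = constrain)
  acc <- mapply(codon_accuracy, pred, test_records$cds, USE.NAMES = FALSE)
  fid <- mapply(function(p, prot) {
    aa <- strsplit(prot, "", fixed = TRUE)[[1L]]
    mean(unname(code$codon_to_aa[split_codons(p)]) == aa)
  }, pred, test_records$protein, USE.NAMES = FALSE)
  cai <- vapply(pred, compute_cai, 0, table = table, code = code,
                USE.NAMES = FALSE)
  mfe <- if (!is.null(mfe_provider) && mfe_available(mfe_provider))
    compute_mfe(mfe_provider, pred) else rep(NA_real_, length(pred))

  usage_pred <- usage_frequencies(pred)
  usage_ref <- usage_frequencies(train_cds)
  pair_pred <- pair_usage_frequencies(pred)
  pair_ref <- pair_usage_frequencies(train_cds)

  structure(list(
    per_seq = data.frame(id = test_records$id, accuracy = acc,
                         aa_fidelity = fid, cai = cai, mfe = mfe,
                         stringsAsFactors = FALSE),
    median_accuracy = stats::median(acc),
    cai_values = cai,
    mfe_values = if (all(is.na(mfe))) NULL else mfe,
    usage_pred = usage_pred, usage_ref = usage_ref,
    pair_usage_pred = pair_pred, pair_usage_ref = pair_ref,
    pcc_usage = pearson_corr(usage_pred, usage_ref),
    pcc_pair = pearson_corr(pair_pred, pair_ref),
    constrain = constrain), class = "codonlm_eval")
}

#' @export
print.codonlm_eval <- function(x, ...) {
  cat("Codon model evaluation on", nrow(x$per_seq), "held-out sequences",
      if (x$constrain) "(family-constrained decoding)" else "", "\n")
  cat(sprintf("  median codon accuracy : %.1f%%\n", 100 * x$median_accuracy))
  cat(sprintf("  mean amino-acid fidelity: %.1f%%\n",
              100 * mean(x$per_seq$aa_fidelity)))
  cat(sprintf("  CAI (decoded, median) : %.4f\n",
              stats::median(x$cai_values)))
  cat(sprintf("  usage PCC vs training : %.4f\n", x$pcc_usage))
  cat(sprintf("  bicodon PCC vs training: %.4f\n", x$pcc_pair))
  if (!is.null(x$mfe_values))
    cat(sprintf("  MFE (median, kcal/mol): %.2f\n",
                stats::median(x$mfe_values, na.rm = TRUE)))
  else cat("  MFE: no provider available\n")
  invisible(x)
}

#' Write an evaluation report
#'
#' Serializes the scalar metrics and usage vectors to JSON and, when
#' `tsv_path` is given, per-sequence metrics and the codon-usage scatter
#' data (codon, predicted frequency, training frequency) to TSV.
#'
#' @param report A [evaluate_model()] result.
#' @param path JSON output path.
#' @param tsv_path Optional TSV path prefix (writes `<prefix>_per_seq.tsv`
#'   and `<prefix>_usage.tsv`).
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path, tsv_path = NULL) {
  stopifnot(inherits(report, "codonlm_eval"))
  out <- list(n_sequences = nrow(report$per_seq),
              median_accuracy = report$median_accuracy,
              mean_aa_fidelity = mean(report$per_seq$aa_fidelity),
              median_cai = stats::median(report$cai_values),
              pcc_usage = report$pcc_usage,
              pcc_pair = report$pcc_pair,
              constrain = report$constrain,
              mfe_available = !is.null(report$mfe_values),
              usage_pred = as.list(report$usage_pred),
              usage_ref = as.list(report$usage_ref))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  if (!is.null(tsv_path)) {
    utils::write.table(report$per_seq, paste0(tsv_path, "_per_seq.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(codon = names(report$usage_pred),
                 freq_pred = as.numeric(report$usage_pred),
                 freq_train = as.numeric(report$usage_ref)),
      paste0(tsv_path, "_usage.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  invisible(path)
}
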