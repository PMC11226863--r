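#' Codon usage table with relative adaptiveness
#'
#' A codon usage table holds per-codon counts, frequencies normalized over
#' all 64 codons, and the relative adaptiveness `w` used by the codon
#' adaptation index: within each synonymous family, `w(c) = freq(c) /
#' max(freq)` so that the family's most frequent codon has `w = 1`.
#' Codons never observed are floored at a pseudo-count (default 0.5)
#' before normalization, so `w` is always strictly positive and the CAI is
#' always finite.
#'
#' @param counts Named numeric vector of codon counts (names are codons;
#'   codons absent from the vector count as zero). Frequencies are also
#'   accepted; only ratios matter.
#' @param code A [genetic_code()].
#' @param pseudo Floor applied to zero counts before normalization.
#' @return Object of class `codon_usage_table`: list with `counts`,
#'   `freq` (sums to 1) and `w`, each a named numeric vector over the 64
#'   codons in lexicographic order.
#' @examples
#' tab <- codon_usage_table(c(AAA = 2, AAG = 1))
#' tab$w[c("AAA", "AAG")]  # 1 and 0.5
#' @export
codon_usage_table <- function(counts, code = genetic_code(), pseudo = 0.5) {
  cl_assert(is.numeric(counts) && !is.null(names(counts)),
            "counts must be a named numeric vector", "codonlm_bad_usage")
  bad <- setdiff(names(counts), all_codons())
  if (length(bad) > 0L)
    cl_stop(paste0("unknown codon(s): ", paste(utils::head(bad, 5), collapse = ", ")),
            "codonlm_bad_usage")
  cl_assert(all(counts >= 0) && all(is.finite(counts)),
            "counts must be finite and non-negative", "codonlm_bad_usage")
  full <- stats::setNames(numeric(64L), all_codons())
  full[names(counts)] <- counts
  full[full == 0] <- pseudo
  freq <- full / sum(full)
  w <- freq
  for (fam in code$families)
    w[fam] <- freq[fam] / max(freq[fam])
  structure(list(counts = full, freq = freq, w = w, pseudo = pseudo),
            class = "codon_usage_table")
}

#' Build a usage table from a corpus of coding sequences
#'
#' Counts every codon (including stops) across the corpus and returns the
#' resulting [codon_usage_table()].
#'
#' @param corpus Character vector of CDSs (or a records data frame with a
#'   `cds` column).
#' @param code A [genetic_code()].
#' @param pseudo Passed to [codon_usage_table()].
#' @return A `codon_usage_table`.
#' @export
build_usage_table <- function(corpus, code = genetic_code(), pseudo = 0.5) {
  if (is.data.frame(corpus)) corpus <- corpus$cds
  cl_assert(is.character(corpus) && length(corpus) > 0L,
            "corpus must be a nonempty character vector of CDSs",
            "codonlm_empty_corpus")
  cod <- unlist(lapply(corpus, split_codons), use.names = FALSE)
  counts <- table(factor(cod, levels = all_codons()))
  codon_usage_table(stats::setNames(as.numeric(counts), names(counts)),
                    code = code, pseudo = pseudo)
}

#' @export
print.codon_usage_table <- function(x, ...) {
  cat("Codon usage table (64 codons, pseudo-count", x$pseudo, ")\n")
  cat("  top codons:",
      paste(names(sort(x$freq, decreasing = TRUE))[1:5], collapse = " "), "\n")
  invisible(x)
}

#' Read / write a codon usage table
#'
#' The on-disk format is whitespace-separated text with two columns,
#' codon and count; `#` starts a comment and a single header line is
#' detected and skipped.
#'
#' @param path File path.
#' @param code,pseudo Passed to [codon_usage_table()].
#' @return [read_codon_usage()] returns a `codon_usage_table`;
#'   [write_codon_usage()] returns `path` invisibly.
#' @export
read_codon_usage <- function(path, code = genetic_code(), pseudo = 0.5) {
  cl_assert(file.exists(path), paste0("no such file: ", path), "codonlm_io_error")
  ln <- readLines(path, warn = FALSE)
  ln <- sub("#.*$", "", ln)
  ln <- trimws(ln)
  ln <- ln[nzchar(ln)]
  cl_assert(length(ln) > 0L, "empty usage table", "codonlm_empty_input")
  parts <- strsplit(ln, "[\t ]+")
  cl_assert(all(lengths(parts) >= 2L),
            "usage table rows need two columns: codon, count", "codonlm_bad_usage")
  first_num <- suppressWarnings(as.numeric(parts[[1L]][2L]))
  if (is.na(first_num)) parts <- parts[-1L]  # header line
  cl_assert(length(parts) > 0L, "usage table has no data rows", "codonlm_bad_usage")
  codons <- toupper(vapply(parts, `[`, "", 1L))
  codons <- chartr("U", "T", codons)
  cnt <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L)))
  cl_assert(!anyNA(cnt), "non-numeric count in usage table", "codonlm_bad_usage")
  cl_assert(!anyDuplicated(codons), "duplicate codon in usage table", "codonlm_bad_usage")
  codon_usage_table(stats::setNames(cnt, codons), code = code, pseudo = pseudo)
}

#' @param table A `codon_usage_table`.
#' @rdname read_codon_usage
#' @export
write_codon_usage <- function(table, path) {
  stopifnot(inherits(table, "codon_usage_table"))
  writeLines(c("codon\tcount",
               paste(names(table$counts), format(table$counts, trim = TRUE),
                     sep = "\t")), path)
  invisible(path)
}

#' Codon adaptation index
#'
#' Geometric mean of the relative adaptiveness `w` over all coding codons
#' of a CDS. A trailing stop codon is excluded; single-codon families
#' (Met, Trp) are included with `w = 1`, following the EMBOSS `cai`
#' convention of scoring the coding codons. A CDS whose every codon is
#' its family's most frequent codon scores exactly 1.
#'
#' @param cds Nucleotide string.
#' @param table A [codon_usage_table()].
#' @param code A [genetic_code()].
#' @return CAI in (0, 1].
#' @examples
#' tab <- codon_usage_table(c(AAA = 4, AAG = 1, ATG = 1))
#' compute_cai("ATGAAAAAA", tab)  # 1: every codon is the family optimum
#' @export
compute_cai <- function(cds, table, code = genetic_code()) {
  stopifnot(inherits(table, "codon_usage_table"))
  cod <- split_codons(cds)
  aa <- unname(code$codon_to_aa[cod])
  stops <- which(aa == "*")
  if (length(stops) > 0L) {
    if (length(stops) > 1L || stops[1L] != length(cod))
      cl_stop("internal stop codon in CDS", "codonlm_internal_stop")
    cod <- cod[-length(cod)]
  }
  if (length(cod) == 0L)
    cl_stop("CDS consists only of a stop codon", "codonlm_only_stop")
  exp(mean(log(table$w[cod])))
}

#' One amino acid, one codon optimization
#'
#' The classical "highest-frequency codon" strategy: every amino acid of
#' the protein is encoded by its synonymous family's most frequent codon
#' in the usage table (ties broken by the lexicographically smallest
#' codon, so results are identical across platforms). By construction the
#' output translates back to the input protein and has a codon adaptation
#' index of exactly 1 against the same table.
#'
#' @param protein Amino-acid string over the 20 standard letters.
#' @param table A [codon_usage_table()].
#' @param code A [genetic_code()].
#' @param append_stop If `TRUE`, append the most frequent stop codon.
#' @return Nucleotide CDS string.
#' @examples
#' tab <- codon_usage_table(c(AAA = 4, AAG = 1))
#' jcat_optimize("KK", tab)  # "AAAAAA"
#' @export
jcat_optimize <- function(protein, table, code = genetic_code(),
                          append_stop = FALSE) {
  stopifnot(inherits(table, "codon_usage_table"))
  aa <- check_protein(protein, code)
  best <- vapply(code$families, function(fam) fam[which.max(table$freq[fam])], "")
  out <- paste(best[aa], collapse = "")
  if (append_stop && "*" %in% names(best)) out <- paste0(out, best[["*"]])
  out
}
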