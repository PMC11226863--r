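#' The genetic code and its synonymous-codon families
#'
#' Builds the codon-to-amino-acid map together with an index of synonymous
#' families (one entry per amino acid, plus `"*"` for the stop codons).
#' Family lists are sorted lexicographically so that iteration order, and
#' therefore every tie-break downstream, is deterministic.
#'
#' @param codon_to_aa Optional named character vector mapping all 64
#'   trinucleotides (alphabet ACGT) to one-letter amino acids or `"*"`.
#'   Defaults to the standard genetic code as shipped by Biostrings.
#' @return An object of class `genetic_code`: a list with elements
#'   `codon_to_aa` (named character vector of length 64, codons in
#'   lexicographic order) and `families` (named list, amino-acid letter to
#'   sorted codon vector).
#' @examples
#' gc <- genetic_code()
#' gc$families[["W"]]  # "TGG": tryptophan has a single codon
#' @export
genetic_code <- function(codon_to_aa = NULL) {
  if (is.null(codon_to_aa)) {
    codon_to_aa <- as.character(Biostrings::GENETIC_CODE)
    names(codon_to_aa) <- names(Biostrings::GENETIC_CODE)
  }
  cl_assert(length(codon_to_aa) == 64L && !is.null(names(codon_to_aa)),
            "codon_to_aa must be a named vector over all 64 codons",
            "codonlm_bad_code")
  ord <- order(names(codon_to_aa))
  codon_to_aa <- codon_to_aa[ord]
  cl_assert(identical(names(codon_to_aa), all_codons()),
            "codon_to_aa names must be the 64 ACGT trinucleotides",
            "codonlm_bad_code")
  cl_assert(all(codon_to_aa %in% c(AA_LETTERS, "*")),
            "codon_to_aa values must be amino-acid letters or '*'",
            "codonlm_bad_code")
  fams <- split(names(codon_to_aa), codon_to_aa)
  fams <- lapply(fams, sort)
  structure(list(codon_to_aa = codon_to_aa, families = fams),
            class = "genetic_code")
}

# the 20 standard amino acids, alphabetical
AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' All 64 codons in lexicographic order
#' @return Character vector of length 64.
#' @export
all_codons <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(vapply(b, function(x) vapply(b, function(y)
    paste0(x, y, b), character(4)), matrix("", 4, 4)))
}

#' @export
print.genetic_code <- function(x, ...) {
  ns <- sum(x$codon_to_aa == "*")
  cat("Genetic code: 64 codons,", length(x$families) - (ns > 0),
      "amino-acid families,", ns, "stop codons\n")
  invisible(x)
}

# split a CDS into codons, validating alphabet and length
split_codons <- function(cds) {
  cl_assert(is.character(cds) && length(cds) == 1L && !is.na(cds),
            "cds must be a single string", "codonlm_bad_cds")
  n <- nchar(cds)
  if (n < 3L || n %% 3L != 0L)
    cl_stop(sprintf("CDS length %d is not a positive multiple of 3", n),
            "codonlm_length_error")
  if (grepl("[^ACGT]", cds))
    cl_stop("CDS contains characters outside ACGT (ambiguity codes are not supported)",
            "codonlm_alphabet_error")
  substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Translate a coding sequence
#'
#' Translates a nucleotide CDS to its protein under a genetic code. A stop
#' codon is permitted only as the final codon and is stripped from the
#' output; an internal stop, a length not divisible by three, or a
#' non-ACGT character each raise a distinct error class
#' (`codonlm_internal_stop`, `codonlm_length_error`,
#' `codonlm_alphabet_error`).
#'
#' @param cds Single nucleotide string over ACGT, length a multiple of 3.
#' @param code A [genetic_code()].
#' @return Single amino-acid string.
#' @examples
#' translate_cds("ATGTGGTAA")  # "MW", trailing stop stripped
#' @export
translate_cds <- function(cds, code = genetic_code()) {
  cod <- split_codons(cds)
  aa <- unname(code$codon_to_aa[cod])
  stops <- which(aa == "*")
  if (length(stops) > 0L) {
    if (length(stops) > 1L || stops[1L] != length(aa))
      cl_stop("internal stop codon in CDS", "codonlm_internal_stop")
    aa <- aa[-length(aa)]
    if (length(aa) == 0L)
      cl_stop("CDS consists only of a stop codon", "codonlm_only_stop")
  }
  paste(aa, collapse = "")
}

# validate a protein string against the code's families
check_protein <- function(protein, code) {
  cl_assert(is.character(protein) && length(protein) == 1L && !is.na(protein) &&
              nzchar(protein),
            "protein must be a nonempty string", "codonlm_bad_protein")
  aa <- strsplit(protein, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(aa), setdiff(names(code$families), "*"))
  if (length(bad) > 0L)
    cl_stop(paste0("amino acid(s) with no codon family: ",
                   paste(bad, collapse = ", ")), "codonlm_unknown_aa")
  aa
}
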