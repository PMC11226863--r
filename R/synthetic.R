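#' Default planted codon-usage bias
#'
#' A fixed, realistically skewed usage table used by the synthetic corpus
#' generator when no table is supplied: within every synonymous family,
#' codon weights decay geometrically (ratio `decay`) along a fixed
#' preference order on the wobble base (C > G > T > A, the broad pattern
#' seen in highly expressed human genes). Counts are arbitrary units;
#' only the within-family ratios matter downstream.
#'
#' @param code A [genetic_code()].
#' @param decay Geometric ratio between successive codons of a family.
#' @return A [codon_usage_table()].
#' @export
default_planted_usage <- function(code = genetic_code(), decay = 0.6) {
  counts <- stats::setNames(numeric(64L), all_codons())
  pref <- c(C = 1L, G = 2L, T = 3L, A = 4L)
  for (fam in code$families) {
    ord <- order(pref[substr(fam, 3L, 3L)], fam)
    counts[fam[ord]] <- 1000 * decay^(seq_along(fam) - 1L)
  }
  codon_usage_table(counts, code = code)
}

# family-conditional synonymous-choice probabilities from a usage table
family_probs <- function(table, code) {
  lapply(code$families, function(fam) {
    p <- table$freq[fam]
    p / sum(p)
  })
}

# Deterministic synonymous rule shared by the deterministic_rule mode and
# the first-order conditional: a fixed integer hash of (current amino
# acid, previous amino acid) is mapped through the planted within-family
# quantile function. Because the hash is uniformly stratified over the
# 20 x 21 contexts, the rule's codon marginal over random proteins
# reproduces the planted usage, while the choice itself is a fixed,
# learnable function of the local amino-acid context.
rule_u <- function(aa_idx, prev_idx) {
  ((prev_idx * 2654435761 + aa_idx * 40503) %% 65536 + 0.5) / 65536
}

deterministic_choice <- function(aa, prev_aa, p0, code) {
  fam <- code$families[[aa]]
  u <- rule_u(match(aa, AA_LETTERS),
              if (is.na(prev_aa)) 0L else match(prev_aa, AA_LETTERS))
  fam[findInterval(u, cumsum(p0), left.open = TRUE) + 1L]
}

#' Generate a synthetic corpus with planted codon-usage bias
#'
#' Emulates a corpus of highly expressed coding sequences: proteins are
#' drawn uniformly over the 20 amino acids with lengths uniform in
#' `length_range`, and each synonymous codon choice follows the planted
#' within-family distribution, optionally blended with a
#' previous-codon-conditioned distribution (codon-pair bias) or replaced
#' by a fixed deterministic rule.
#'
#' With `pair_dependence = p`, the choice distribution at each position is
#' `(1 - p) * planted + p * conditional`, where the conditional
#' distribution concentrates on the codon selected by a fixed
#' neighbour-conditioned rule: a uniform hash of the (current, previous)
#' residue context mapped through the planted within-family quantile
#' function. The rule plants genuine bicodon structure (the synonymous
#' choice shifts with the neighbouring residue) while its codon marginal
#' over random proteins reproduces the planted usage, so usage statistics
#' remain recoverable from decoded sequences at any `p`.
#' With `deterministic_rule = TRUE`, the codon is a fixed
#' function of the current and previous amino acid, giving a noiseless,
#' fully learnable synonymous-choice signal.
#'
#' @param n_sequences Number of records.
#' @param length_range Integer (min, max) protein length in codons, min >= 2.
#' @param planted_usage A [codon_usage_table()]; defaults to
#'   [default_planted_usage()].
#' @param pair_dependence Blend weight in \[0, 1\] of the previous-codon
#'   conditional distribution.
#' @param deterministic_rule If `TRUE`, synonymous choice is the fixed
#'   rule above and `pair_dependence` is ignored.
#' @param seed Integer seed; generation is fully reproducible.
#' @param code A [genetic_code()].
#' @return A records data frame (`id`, `cds`, `protein`, `tpm = NA`).
#' @examples
#' rec <- generate_synthetic_corpus(3, c(5, 8), seed = 7)
#' identical(vapply(rec$cds, translate_cds, ""), setNames(rec$protein, rec$cds))
#' @export
generate_synthetic_corpus <- function(n_sequences,
                                      length_range = c(30L, 60L),
                                      planted_usage = default_planted_usage(),
                                      pair_dependence = 0,
                                      deterministic_rule = FALSE,
                                      seed = 1L,
                                      code = genetic_code()) {
  cl_assert(is.numeric(n_sequences) && n_sequences >= 1,
            "n_sequences must be >= 1", "codonlm_bad_input")
  cl_assert(length(length_range) == 2L && length_range[1L] >= 2L &&
              length_range[1L] <= length_range[2L],
            "length_range must be (min, max) with 2 <= min <= max",
            "codonlm_bad_input")
  cl_assert(pair_dependence >= 0 && pair_dependence <= 1,
            "pair_dependence must be in [0, 1]", "codonlm_bad_input")
  stopifnot(inherits(planted_usage, "codon_usage_table"))

  fp <- family_probs(planted_usage, code)
  lo <- as.integer(length_range[1L]); hi <- as.integer(length_range[2L])
  withr::with_seed(seed, {
    cds <- protein <- character(n_sequences)
    for (s in seq_len(n_sequences)) {
      L <- lo + sample.int(hi - lo + 1L, 1L) - 1L
      aa <- sample(AA_LETTERS, L, replace = TRUE)
      cod <- character(L)
      for (i in seq_len(L)) {
        fam <- code$families[[aa[i]]]
        p0 <- fp[[aa[i]]]
        if (deterministic_rule) {
          cod[i] <- deterministic_choice(aa[i], if (i > 1L) aa[i - 1L] else NA,
                                         p0, code)
        } else {
          p <- p0
          if (pair_dependence > 0 && i > 1L) {
            pc <- numeric(length(fam))
            pc[match(deterministic_choice(aa[i], aa[i - 1L], p0, code), fam)] <- 1
            p <- (1 - pair_dependence) * p0 + pair_dependence * pc
          }
          cod[i] <- if (length(fam) == 1L) fam else sample(fam, 1L, prob = p)
        }
      }
      protein[s] <- paste(aa, collapse = "")
      cds[s] <- paste(cod, collapse = "")
    }
    data.frame(id = sprintf("synth_%05d", seq_len(n_sequences)),
               cds = cds, protein = protein, tpm = NA_real_,
               stringsAsFactors = FALSE)
  })
}
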