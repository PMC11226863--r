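#' Sequence-masking curriculum
#'
#' The training curriculum feeds all codon sequences for `warmup_epochs`
#' epochs, then every `step_epochs` epochs raises by `increment` the
#' fraction of codon sequences per batch that are replaced by an all-zero
#' placeholder, reaching 1 (codons predicted from protein alone) after
#' `full_mask_epoch`. Defaults are the published constants: warmup 15,
#' step 15, increment 5%, fully masked past epoch 300.
#'
#' @param warmup_epochs,step_epochs,increment,full_mask_epoch Schedule
#'   constants.
#' @return Object of class `curriculum_schedule`.
#' @export
curriculum_schedule <- function(warmup_epochs = 15L, step_epochs = 15L,
                                increment = 0.05, full_mask_epoch = 300L) {
  cl_assert(increment > 0 && increment <= 1, "increment must be in (0, 1]",
            "codonlm_config_error")
  cl_assert(warmup_epochs >= 0 && step_epochs >= 1 &&
              full_mask_epoch >= warmup_epochs,
            "invalid curriculum schedule", "codonlm_config_error")
  structure(list(warmup_epochs = as.integer(warmup_epochs),
                 step_epochs = as.integer(step_epochs),
                 increment = increment,
                 full_mask_epoch = as.integer(full_mask_epoch)),
            class = "curriculum_schedule")
}

#' @export
print.curriculum_schedule <- function(x, ...) {
  cat(sprintf(paste0("Sequence-masking curriculum: warmup %d epochs, +%g%% ",
                     "every %d epochs, fully masked after epoch %d\n"),
              x$warmup_epochs, 100 * x$increment, x$step_epochs,
              x$full_mask_epoch))
  invisible(x)
}

#' Fraction of codon sequences zeroed at a given epoch
#'
#' 0 during warmup; then `min(1, increment * ceiling((epoch - warmup) /
#' step))`; exactly 1 for every epoch beyond `full_mask_epoch`. Monotone
#' non-decreasing in the epoch. Vectorized over `epoch`.
#'
#' @param epoch Integer epoch(s), >= 1.
#' @param schedule A [curriculum_schedule()].
#' @return Fraction(s) in \[0, 1\].
#' @examples
#' sequence_mask_fraction(c(10, 31, 301))  # 0, 0.10, 1
#' @export
sequence_mask_fraction <- function(epoch, schedule = curriculum_schedule()) {
  cl_assert(is.numeric(epoch) && all(epoch >= 1), "epoch must be >= 1",
            "codonlm_bad_input")
  f <- ifelse(epoch <= schedule$warmup_epochs, 0,
              pmin(1, schedule$increment *
                     ceiling((epoch - schedule$warmup_epochs) /
                               schedule$step_epochs)))
  f[epoch > schedule$full_mask_epoch] <- 1
  f
}

#' Replace whole codon sequences with the zero placeholder
#'
#' Marks a uniformly sampled `round(fraction * batch_size)` subset of
#' batch rows as sequence-zeroed: their codon stream embeds to all zeros
#' and their codon labels cover every position, so the entire codon
#' sequence must be predicted. Uses the current R random state; seed
#' externally for reproducibility.
#'
#' @param batch A [make_batch()] result.
#' @param fraction Fraction of rows to zero, in \[0, 1\].
#' @return The modified batch.
#' @export
apply_sequence_zeroing <- function(batch, fraction) {
  cl_assert(fraction >= 0 && fraction <= 1, "fraction must be in [0, 1]",
            "codonlm_bad_input")
  B <- nrow(batch$aa_ids)
  k <- round(fraction * B)
  if (k == 0L) return(batch)
  rows <- sample.int(B, k)
  batch$seq_zeroed[rows] <- TRUE
  for (b in rows)
    batch$codon_labels[b, seq_len(batch$lens[b])] <-
      batch$codon_ids[b, seq_len(batch$lens[b])]
  batch
}

#' Random token masking
#'
#' Independently masks each non-padding position of each non-zeroed row
#' with the stream's rate: the token id becomes the MASK id and the label
#' records the original id; unmasked positions keep an ignore label.
#' Padding is never masked. Uses the current R random state.
#'
#' @param batch A [make_batch()] result.
#' @param codon_rate,aa_rate Per-position masking probabilities in \[0, 1).
#' @return The modified batch.
#' @export
apply_token_masking <- function(batch, codon_rate = 0.15, aa_rate = 0.15) {
  cl_assert(codon_rate >= 0 && codon_rate < 1 && aa_rate >= 0 && aa_rate < 1,
            "mask rates must be in [0, 1)", "codonlm_bad_input")
  B <- nrow(batch$aa_ids)
  for (b in seq_len(B)) {
    if (batch$seq_zeroed[b]) next
    n <- batch$lens[b]
    if (codon_rate > 0) {
      m <- which(stats::runif(n) < codon_rate)
      if (length(m) > 0L) {
        batch$codon_labels[b, m] <- batch$codon_ids[b, m]
        batch$codon_ids[b, m] <- CODON_MASK
      }
    }
    if (aa_rate > 0) {
      m <- which(stats::runif(n) < aa_rate)
      if (length(m) > 0L) {
        batch$aa_labels[b, m] <- batch$aa_ids[b, m]
        batch$aa_ids[b, m] <- AA_MASK
      }
    }
  }
  batch
}
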