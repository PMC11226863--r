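# Shared fixtures. Models used across test files are trained once and
# cached for the session.

.cache <- new.env(parent = emptyenv())

# a small configuration that keeps forward/backward checks fast
small_config <- function(max_len = 70L) {
  codonlm_config(NULL, embed_dim = 16L, n_blocks = 1L, n_heads = 2L,
                 ff_dim = 32L, max_len = max_len)
}

# tiny model overfitted on its own 10-sequence corpus (fully-zeroed
# codon stream from epoch 2 onwards), used by decoding/evaluation tests
overfit_fit <- function() {
  if (is.null(.cache$overfit)) {
    rec <- generate_synthetic_corpus(10, c(8, 12), deterministic_rule = TRUE,
                                     seed = 2)
    .cache$overfit_records <- rec
    .cache$overfit <- codonlm(rec, codonlm_config("tiny"), epochs = 60,
                              batch_size = 10,
                              schedule = curriculum_schedule(1, 1, 0.5, 2),
                              seed = 1)
  }
  .cache$overfit
}

overfit_records <- function() {
  overfit_fit()
  .cache$overfit_records
}

# usage table with a known skew on the lysine family
k_table <- function(aaa = 4, aag = 1)
  codon_usage_table(c(AAA = aaa, AAG = aag, ATG = 2, TGG = 2))

random_usage_table <- function() {
  counts <- stats::setNames(stats::runif(64, 1, 1000), all_codons())
  codon_usage_table(counts)
}

random_protein <- function(len)
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y"), len, replace = TRUE),
        collapse = "")
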