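# Token vocabularies. Codons occupy ids 1..64 (lexicographic); the two
# specials follow. Amino acids occupy ids 1..20 (alphabetical).
codon_vocab <- function() c(all_codons(), "<pad>", "<mask>")
aa_vocab <- function() c(AA_LETTERS, "<pad>", "<mask>")

CODON_PAD <- 65L; CODON_MASK <- 66L
AA_PAD <- 21L; AA_MASK <- 22L

codon_ids <- function(cds) {
  cod <- split_codons(cds)
  match(cod, all_codons())
}

aa_ids <- function(protein) {
  i <- match(strsplit(protein, "", fixed = TRUE)[[1L]], AA_LETTERS)
  cl_assert(!anyNA(i), "protein contains non-standard letters",
            "codonlm_unknown_aa")
  i
}

#' Model configuration
#'
#' Hyperparameters of the dual-stream encoder. The `"tiny"` preset
#' (embedding 64, 2 blocks, 4 heads, feed-forward 128) is a desk-scale
#' configuration for experiments on synthetic corpora; `"base"` is a
#' larger preset for real corpora. Both are this package's choices.
#'
#' @param preset `"tiny"` or `"base"`, or `NULL` to take the explicit
#'   arguments as given.
#' @param embed_dim Embedding width (must be divisible by `n_heads`).
#' @param n_blocks Number of stacked encoder blocks.
#' @param n_heads Attention heads per attention sublayer.
#' @param ff_dim Hidden width of the position-wise feed-forward sublayers.
#' @param max_len Maximum sequence length in codons.
#' @param dropout Dropout probability applied to every sublayer output
#'   during training.
#' @return Object of class `codonlm_config`.
#' @export
codonlm_config <- function(preset = "tiny", embed_dim = NULL, n_blocks = NULL,
                           n_heads = NULL, ff_dim = NULL, max_len = NULL,
                           dropout = NULL) {
  base <- switch(preset %||% "custom",
    tiny = list(embed_dim = 64L, n_blocks = 2L, n_heads = 4L,
                ff_dim = 128L, max_len = 128L, dropout = 0),
    base = list(embed_dim = 256L, n_blocks = 6L, n_heads = 8L,
                ff_dim = 512L, max_len = 1024L, dropout = 0.1),
    custom = list(embed_dim = 64L, n_blocks = 2L, n_heads = 4L,
                  ff_dim = 128L, max_len = 128L, dropout = 0),
    cl_stop(paste0("unknown preset: ", preset), "codonlm_config_error"))
  ov <- list(embed_dim = embed_dim, n_blocks = n_blocks, n_heads = n_heads,
             ff_dim = ff_dim, max_len = max_len, dropout = dropout)
  for (n in names(ov)) if (!is.null(ov[[n]])) base[[n]] <- ov[[n]]
  base[c("embed_dim", "n_blocks", "n_heads", "ff_dim", "max_len")] <-
    lapply(base[c("embed_dim", "n_blocks", "n_heads", "ff_dim", "max_len")],
           as.integer)
  cl_assert(base$embed_dim %% base$n_heads == 0L,
            "embed_dim must be divisible by n_heads", "codonlm_config_error")
  cl_assert(base$n_blocks >= 0L && base$max_len >= 2L &&
              base$dropout >= 0 && base$dropout < 1,
            "invalid model configuration", "codonlm_config_error")
  structure(base, class = "codonlm_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.codonlm_config <- function(x, ...) {
  cat(sprintf(paste0("Dual-stream encoder config: embed_dim=%d, n_blocks=%d, ",
                     "n_heads=%d, ff_dim=%d, max_len=%d, dropout=%g\n"),
              x$embed_dim, x$n_blocks, x$n_heads, x$ff_dim, x$max_len,
              x$dropout))
  cat("Parameters:", count_parameters(x), "\n")
  invisible(x)
}

# shapes of every parameter matrix, in a fixed order shared with the
# C++ core (names are looked up there)
param_shapes <- function(config) {
  d <- config$embed_dim; f <- config$ff_dim
  sh <- list(tok_aa = c(22L, d), tok_c = c(66L, d),
             pos = c(config$max_len, d))
  for (i in seq_len(config$n_blocks)) {
    p <- sprintf("b%d_", i)
    blk <- list(c(1L, d), c(1L, d), c(d, d), c(d, d), c(d, d), c(d, d))
    names(blk) <- paste0(p, "sa_a_", c("ln_g", "ln_b", "Wq", "Wk", "Wv", "Wo"))
    sh <- c(sh, blk)
    names(blk) <- paste0(p, "sa_c_", c("ln_g", "ln_b", "Wq", "Wk", "Wv", "Wo"))
    sh <- c(sh, blk)
    xb <- list(c(1L, d), c(1L, d), c(1L, d), c(1L, d),
               c(d, d), c(d, d), c(d, d), c(d, d))
    names(xb) <- paste0(p, "x_", c("lnq_g", "lnq_b", "lnkv_g", "lnkv_b",
                                   "Wq", "Wk", "Wv", "Wo"))
    sh <- c(sh, xb)
    fb <- list(c(1L, d), c(1L, d), c(d, f), c(1L, f), c(f, d), c(1L, d))
    names(fb) <- paste0(p, "ff_a_", c("ln_g", "ln_b", "W1", "b1", "W2", "b2"))
    sh <- c(sh, fb)
    names(fb) <- paste0(p, "ff_c_", c("ln_g", "ln_b", "W1", "b1", "W2", "b2"))
    sh <- c(sh, fb)
  }
  c(sh, list(lnf_a_g = c(1L, d), lnf_a_b = c(1L, d),
             lnf_c_g = c(1L, d), lnf_c_b = c(1L, d),
             head_c_W = c(d, 66L), head_c_b = c(1L, 66L),
             head_a_W = c(d, 22L), head_a_b = c(1L, 22L)))
}

#' Closed-form parameter count
#'
#' Number of trainable scalars of a configuration: token and positional
#' embeddings, per-block attention/feed-forward/normalization weights,
#' final normalizations and the two prediction heads. Matches the sum of
#' the sizes of the instantiated parameter matrices exactly.
#'
#' @param config A [codonlm_config()].
#' @return Integer parameter count.
#' @export
count_parameters <- function(config) {
  d <- config$embed_dim; f <- config$ff_dim
  emb <- (66L + 22L + config$max_len) * d
  per_block <- 12L * d + 12L * d^2 + 4L * d * f + 2L * f + 2L * d
  tail <- 4L * d + (66L * d + 66L) + (22L * d + 22L)
  as.integer(emb + config$n_blocks * per_block + tail)
}

# parameter initialization: N(0, 0.02^2) weights, unit gains, zero biases
init_params <- function(config, seed = 1L) {
  sh <- param_shapes(config)
  withr::with_seed(seed, {
    lapply(stats::setNames(names(sh), names(sh)), function(n) {
      dm <- sh[[n]]
      if (grepl("(_g)$", n)) return(matrix(1, dm[1L], dm[2L]))
      if (grepl("(_b|_b1|_b2)$", n) || grepl("ln_b$", n))
        return(matrix(0, dm[1L], dm[2L]))
      matrix(stats::rnorm(prod(dm), sd = 0.02), dm[1L], dm[2L])
    })
  })
}
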