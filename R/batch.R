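#' Assemble a padded token batch
#'
#' Tokenizes paired protein/CDS sequences into the two aligned integer
#' streams consumed by the encoder. Position `i` of both streams refers
#' to the same residue/codon. Sequences are right-padded to the batch
#' maximum; labels start empty (0 = ignore).
#'
#' @param proteins Character vector of proteins.
#' @param cdss Optional character vector of CDSs (same length, same codon
#'   counts). When `NULL` the codon stream is marked fully zeroed —
#'   the inference regime.
#' @param config A [codonlm_config()].
#' @return A list of class `codonlm_batch` with elements `aa_ids`,
#'   `codon_ids`, `lens`, `seq_zeroed`, `aa_labels`, `codon_labels`.
#' @export
make_batch <- function(proteins, cdss = NULL, config = codonlm_config()) {
  B <- length(proteins)
  cl_assert(B > 0L, "empty batch", "codonlm_bad_input")
  aa_tok <- lapply(proteins, aa_ids)
  lens <- lengths(aa_tok)
  cl_assert(max(lens) <= config$max_len,
            sprintf("sequence of %d codons exceeds max_len %d",
                    max(lens), config$max_len), "codonlm_too_long")
  L <- max(lens)
  aa_m <- matrix(AA_PAD, B, L)
  cd_m <- matrix(CODON_PAD, B, L)
  zeroed <- rep(is.null(cdss), B)
  if (!is.null(cdss)) {
    cl_assert(length(cdss) == B, "proteins and cdss lengths differ",
              "codonlm_bad_input")
    cd_tok <- lapply(cdss, codon_ids)
    cl_assert(all(lengths(cd_tok) == lens),
              "cds and protein codon counts differ", "codonlm_bad_input")
  }
  for (b in seq_len(B)) {
    aa_m[b, seq_len(lens[b])] <- aa_tok[[b]]
    if (!is.null(cdss)) cd_m[b, seq_len(lens[b])] <- cd_tok[[b]]
  }
  structure(list(aa_ids = aa_m, codon_ids = cd_m,
                 lens = as.integer(lens), seq_zeroed = zeroed,
                 aa_labels = matrix(0L, B, L),
                 codon_labels = matrix(0L, B, L)),
            class = "codonlm_batch")
}

# Low-level bridge to the compiled core. Returns loss, counts, and
# optionally gradients and per-sequence logit matrices.
run_network <- function(params, batch, config, grads = FALSE, logits = FALSE,
                        train = FALSE, dropout_seed = 0) {
  cfg <- list(embed_dim = config$embed_dim, n_heads = config$n_heads,
              n_blocks = config$n_blocks, dropout = config$dropout,
              train = train, dropout_seed = as.double(dropout_seed))
  cpp_dualstream_run(params, unclass(batch), cfg, grads, logits)
}
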