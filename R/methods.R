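#' @export
print.codonlm <- function(x, ...) {
  cat("Dual-stream codon language model\n")
  cat(sprintf("  trained %d epochs on %d sequences (batch %d, lr %g, seed %d)\n",
              x$epochs, length(x$train_cds), x$batch_size, x$learning_rate,
              x$seed))
  h <- x$history
  if (nrow(h) > 0L)
    cat(sprintf("  final loss %.4f, masked-codon accuracy %.3f, zeroed fraction %.2f\n",
                h$loss[nrow(h)], h$masked_accuracy[nrow(h)],
                h$seq_mask_fraction[nrow(h)]))
  print(x$config)
  invisible(x)
}

#' @export
summary.codonlm <- function(object, ...) {
  structure(list(config = object$config, schedule = object$schedule,
                 history = object$history,
                 n_train = length(object$train_cds),
                 n_params = count_parameters(object$config)),
            class = "summary.codonlm")
}

#' @export
print.summary.codonlm <- function(x, ...) {
  cat("Dual-stream codon language model —", x$n_params, "parameters,",
      x$n_train, "training sequences\n")
  print(x$config)
  print(x$schedule)
  cat("Training history (last 5 epochs):\n")
  print(utils::tail(x$history, 5), row.names = FALSE)
  invisible(x)
}

#' @export
coef.codonlm <- function(object, ...) object$params

#' @export
plot.codonlm <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mar = c(4, 4, 2, 4))
  on.exit(graphics::par(op))
  plot(h$epoch, h$loss, type = "l", xlab = "epoch", ylab = "loss",
       main = "training loss and curriculum", ...)
  graphics::par(new = TRUE)
  plot(h$epoch, h$seq_mask_fraction, type = "s", col = "red3", axes = FALSE,
       xlab = "", ylab = "", ylim = c(0, 1))
  graphics::axis(4, col.axis = "red3")
  graphics::mtext("zeroed-sequence fraction", side = 4, line = 2.5,
                  col = "red3")
  invisible(x)
}

# argmax decoding of one logit matrix; only real codon columns (1..64)
# are eligible, and with constrain only the residue's synonymous family
decode_logits <- function(logit, protein, constrain, code) {
  aa <- strsplit(protein, "", fixed = TRUE)[[1L]]
  out <- character(length(aa))
  codons <- all_codons()
  for (i in seq_along(aa)) {
    cand <- if (constrain) match(code$families[[aa[i]]], codons) else 1:64
    out[i] <- codons[cand[which.max(logit[i, cand])]]
  }
  paste(out, collapse = "")
}

#' Decode codon sequences from protein alone
#'
#' Runs a single evaluation-mode forward pass with the codon stream
#' fully zeroed (the inference regime the curriculum trains towards) and
#' takes the per-position argmax over the codon head's logits. With
#' `constrain = TRUE` the argmax is restricted to the residue's
#' synonymous family, so the decoded CDS is guaranteed to translate back
#' to the input protein; unconstrained decoding reports what the model
#' actually believes and may be non-synonymous.
#'
#' @param object A fitted [codonlm()].
#' @param proteins Character vector of amino-acid sequences.
#' @param constrain Restrict each position to its synonymous family.
#' @param type `"cds"` for decoded sequences, `"prob"` for per-position
#'   codon probability matrices (list of L x 64 matrices).
#' @param batch_size Sequences per forward pass.
#' @param ... Unused.
#' @return Character vector of CDSs (or list of probability matrices).
#' @export
predict.codonlm <- function(object, proteins, constrain = FALSE,
                            type = c("cds", "prob"), batch_size = 64L, ...) {
  type <- match.arg(type)
  cl_assert(is.character(proteins) && length(proteins) > 0L,
            "proteins must be a nonempty character vector", "codonlm_bad_input")
  res <- vector("list", length(proteins))
  for (start in seq(1L, length(proteins), batch_size)) {
    idx <- start:min(start + batch_size - 1L, length(proteins))
    batch <- make_batch(proteins[idx], NULL, object$config)
    out <- run_network(object$params, batch, object$config, logits = TRUE)
    for (j in seq_along(idx)) {
      L <- batch$lens[j]
      logit <- out$codon_logits[[j]][seq_len(L), , drop = FALSE]
      res[[idx[j]]] <- if (type == "cds")
        decode_logits(logit, proteins[idx[j]], constrain, object$code)
      else {
        z <- logit[, 1:64, drop = FALSE]
        p <- exp(z - apply(z, 1L, max))
        p <- p / rowSums(p)
        colnames(p) <- all_codons()
        p
      }
    }
  }
  if (type == "cds") {
    out <- unlist(res)
    names(out) <- names(proteins)
    out
  } else res
}

#' Sample codon sequences from the model
#'
#' Draws synonymous codons position by position from the codon head's
#' softmax distribution (optionally temperature-scaled), restricted to
#' each residue's family, with the codon stream zeroed. Unlike the
#' argmax decoder this reproduces the model's predictive distribution
#' rather than its mode.
#'
#' @param object A fitted [codonlm()].
#' @param nsim Number of sampled sequences per protein.
#' @param seed Optional integer seed.
#' @param proteins Character vector of proteins.
#' @param temperature Softmax temperature (> 0).
#' @param ... Unused.
#' @return A data frame with one row per protein and one column per
#'   simulation.
#' @export
simulate.codonlm <- function(object, nsim = 1, seed = NULL, proteins,
                             temperature = 1, ...) {
  cl_assert(temperature > 0, "temperature must be positive",
            "codonlm_bad_input")
  probs <- predict(object, proteins, type = "prob")
  draw <- function() {
    vapply(seq_along(proteins), function(i) {
      aa <- strsplit(proteins[i], "", fixed = TRUE)[[1L]]
      p <- probs[[i]]
      cod <- vapply(seq_along(aa), function(t) {
        fam <- object$code$families[[aa[t]]]
        w <- p[t, fam]^(1 / temperature)
        if (length(fam) == 1L) fam else sample(fam, 1L, prob = w / sum(w))
      }, "")
      paste(cod, collapse = "")
    }, "")
  }
  sims <- if (is.null(seed)) replicate(nsim, draw(), simplify = FALSE)
  else withr::with_seed(seed, replicate(nsim, draw(), simplify = FALSE))
  out <- as.data.frame(sims, col.names = paste0("sim_", seq_len(nsim)),
                       optional = TRUE)
  names(out) <- paste0("sim_", seq_len(nsim))
  rownames(out) <- names(proteins) %||% NULL
  out
}
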