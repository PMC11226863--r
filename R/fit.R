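# Adam optimizer over the named list of parameter matrices
adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (n in names(params)) {
    g <- grads[[n]]
    state$m[[n]] <- beta1 * state$m[[n]] + (1 - beta1) * g
    state$v[[n]] <- beta2 * state$v[[n]] + (1 - beta2) * g * g
    params[[n]] <- params[[n]] -
      lr * (state$m[[n]] / c1) / (sqrt(state$v[[n]] / c2) + eps)
  }
  list(params = params, state = state)
}

#' Fit a dual-stream codon language model
#'
#' Trains the encoder as a masked language model over paired
#' codon/amino-acid token streams under the stepwise sequence-masking
#' curriculum: each epoch, [sequence_mask_fraction()] determines the
#' fraction of codon sequences per batch replaced by the zero
#' placeholder ([apply_sequence_zeroing()]); remaining rows get random
#' token masking ([apply_token_masking()]); the loss is the sum of the
#' mean masked cross-entropies of the codon head (read off the
#' amino-acid query stream) and the amino-acid head (read off the codon
#' stream), minimized by Adam. Training is fully reproducible under
#' `seed` on a single device: the per-epoch random streams are forked
#' from the master seed up front.
#'
#' @param records Records data frame (see [transcript_records()] or
#'   [generate_synthetic_corpus()]).
#' @param config A [codonlm_config()].
#' @param epochs Number of passes over the corpus.
#' @param batch_size Sequences per optimizer step.
#' @param learning_rate Adam step size.
#' @param codon_mask_rate,aa_mask_rate Token-masking rates per stream.
#' @param schedule A [curriculum_schedule()].
#' @param seed Master seed for initialization, shuffling and masking.
#' @param verbose Print a line per epoch.
#' @param resume A previously fitted `codonlm` to continue training
#'   (typically from [load_codonlm()]). Training restarts at its next
#'   epoch with its parameters, optimizer state and master seed, and
#'   reproduces the uninterrupted run exactly because every epoch's
#'   random stream is derived from the master seed and the epoch index.
#' @param code A [genetic_code()].
#' @return Object of class `codonlm`: list with `params`, `config`,
#'   `schedule`, `history` (data frame: epoch, loss, seq_mask_fraction,
#'   masked_accuracy), `train_usage` (a [codon_usage_table()] of the
#'   training corpus), `train_cds`, and the call.
#' @seealso [predict.codonlm()], [evaluate_model()]
#' @export
codonlm <- function(records, config = codonlm_config("tiny"),
                    epochs = 25L, batch_size = 20L, learning_rate = 1e-3,
                    codon_mask_rate = 0.15, aa_mask_rate = 0.15,
                    schedule = curriculum_schedule(), seed = 1L,
                    verbose = FALSE, resume = NULL, code = genetic_code()) {
  check_records(records)
  stopifnot(inherits(config, "codonlm_config"),
            inherits(schedule, "curriculum_schedule"))
  cl_assert(epochs >= 1 && batch_size >= 1, "epochs and batch_size must be >= 1",
            "codonlm_config_error")
  n <- nrow(records)
  cl_assert(n >= 1L, "empty corpus", "codonlm_empty_corpus")

  if (is.null(resume)) {
    params <- init_params(config, seed = seed)
    opt <- adam_init(params)
    history <- data.frame(epoch = integer(0), loss = numeric(0),
                          seq_mask_fraction = numeric(0),
                          masked_accuracy = numeric(0))
    first_epoch <- 1L
  } else {
    stopifnot(inherits(resume, "codonlm"))
    cl_assert(!is.null(resume$opt), "checkpoint carries no optimizer state",
              "codonlm_bad_input")
    cl_assert(epochs >= resume$epochs,
              "epochs must be at least the checkpoint's epoch count",
              "codonlm_config_error")
    params <- resume$params
    opt <- resume$opt
    history <- resume$history
    config <- resume$config
    schedule <- resume$schedule
    seed <- resume$seed
    batch_size <- resume$batch_size
    learning_rate <- resume$learning_rate
    codon_mask_rate <- resume$codon_mask_rate
    aa_mask_rate <- resume$aa_mask_rate
    first_epoch <- resume$epochs + 1L
  }

  # each epoch's stream depends only on (master seed, epoch index), so a
  # resumed run replays the same randomness as an uninterrupted one
  epoch_seed <- function(e)
    as.integer((as.double(seed) %% 2147483647 * 48271 + e * 16807) %%
                 2147483646) + 1L

  for (e in seq(first_epoch, length.out = max(0L, epochs - first_epoch + 1L))) {
    frac <- sequence_mask_fraction(e, schedule)
    stats_ <- withr::with_seed(epoch_seed(e), {
      ord <- sample.int(n)
      loss_sum <- 0; nb <- 0L; corr <- 0; lab <- 0
      for (start in seq(1L, n, batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        batch <- make_batch(records$protein[idx], records$cds[idx], config)
        batch <- apply_sequence_zeroing(batch, frac)
        batch <- apply_token_masking(batch, codon_mask_rate, aa_mask_rate)
        if (all(batch$codon_labels == 0L) && all(batch$aa_labels == 0L))
          next  # nothing to predict in this batch (e.g. rates 0 in warmup)
        out <- run_network(params, batch, config, grads = TRUE, train = TRUE,
                           dropout_seed = epoch_seed(e) + start)
        if (!is.finite(out$loss))
          cl_stop(sprintf("non-finite loss at epoch %d (batch at %d)", e, start),
                  "codonlm_training_error")
        st <- adam_step(params, out$grads, opt, learning_rate)
        params <- st$params; opt <- st$state
        loss_sum <- loss_sum + out$loss; nb <- nb + 1L
        corr <- corr + out$n_correct_codon; lab <- lab + out$n_labeled_codon
      }
      list(loss = if (nb > 0L) loss_sum / nb else NA_real_,
           acc = if (lab > 0) corr / lab else NA_real_,
           params = params, opt = opt)
    })
    params <- stats_$params; opt <- stats_$opt
    history <- rbind(history,
                     data.frame(epoch = e, loss = stats_$loss,
                                seq_mask_fraction = frac,
                                masked_accuracy = stats_$acc))
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  zeroed %.2f  masked-acc %.3f",
                      e, stats_$loss, frac, stats_$acc))
  }

  structure(list(params = params, config = config, schedule = schedule,
                 history = history, opt = opt,
                 train_usage = build_usage_table(records$cds, code = code),
                 train_cds = records$cds, code = code,
                 epochs = epochs, batch_size = batch_size,
                 learning_rate = learning_rate,
                 codon_mask_rate = codon_mask_rate,
                 aa_mask_rate = aa_mask_rate, seed = seed,
                 call = match.call()),
            class = "codonlm")
}

#' Masked-LM loss of a model on a prepared batch
#'
#' Evaluation-mode forward pass returning the summed mean cross-entropy
#' over labeled codon and amino-acid positions. Exposed for testing and
#' diagnostics.
#'
#' @param object A fitted `codonlm` (or a bare params list).
#' @param batch A labeled [make_batch()] result.
#' @param config Required when `object` is a bare params list.
#' @return Named list: `loss`, `n_labeled_codon`, `n_labeled_aa`,
#'   `n_correct_codon`.
#' @export
model_loss <- function(object, batch, config = NULL) {
  if (inherits(object, "codonlm")) {
    params <- object$params; config <- object$config
  } else {
    params <- object
    cl_assert(!is.null(config), "config required with a bare params list",
              "codonlm_config_error")
  }
  if (all(batch$codon_labels == 0L) && all(batch$aa_labels == 0L))
    cl_stop("no labeled positions in batch", "codonlm_no_labels")
  out <- run_network(params, batch, config, grads = FALSE)
  out[c("loss", "n_labeled_codon", "n_labeled_aa", "n_correct_codon")]
}

#' Save / load a fitted model
#'
#' A checkpoint is a directory holding `config.json` (architecture,
#' schedule and training metadata, schema-versioned) and `weights.rds`
#' (parameter matrices, history and training-corpus usage).
#'
#' @param object A fitted `codonlm`.
#' @param dir Checkpoint directory (created if needed).
#' @return `save_codonlm()` returns `dir` invisibly; `load_codonlm()`
#'   returns the restored `codonlm` object.
#' @export
save_codonlm <- function(object, dir) {
  stopifnot(inherits(object, "codonlm"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(schema = 1L,
               config = unclass(object$config),
               schedule = unclass(object$schedule),
               epochs = object$epochs, batch_size = object$batch_size,
               learning_rate = object$learning_rate,
               codon_mask_rate = object$codon_mask_rate,
               aa_mask_rate = object$aa_mask_rate, seed = object$seed)
  jsonlite::write_json(meta, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  saveRDS(object, file.path(dir, "weights.rds"))
  invisible(dir)
}

#' @rdname save_codonlm
#' @export
load_codonlm <- function(dir) {
  f <- file.path(dir, "weights.rds")
  cl_assert(file.exists(f), paste0("no checkpoint at ", dir),
            "codonlm_io_error")
  obj <- readRDS(f)
  cl_assert(inherits(obj, "codonlm"), "corrupt checkpoint", "codonlm_io_error")
  obj
}
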