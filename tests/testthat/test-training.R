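test_that("curriculum fraction follows the published constants", {
  sched <- curriculum_schedule()  # warmup 15, step 15, +5%, full past 300
  expect_identical(sequence_mask_fraction(1:15, sched), rep(0, 15))
  expect_equal(sequence_mask_fraction(16, sched), 0.05, tolerance = 1e-12)
  expect_equal(sequence_mask_fraction(30, sched), 0.05, tolerance = 1e-12)
  expect_equal(sequence_mask_fraction(31, sched), 0.1, tolerance = 1e-12)
  expect_equal(sequence_mask_fraction(300, sched), 0.95, tolerance = 1e-12)
  expect_identical(sequence_mask_fraction(301:310, sched), rep(1, 10))
  f <- sequence_mask_fraction(1:1000, sched)
  expect_true(all(diff(f) >= 0))
  expect_true(all(f >= 0 & f <= 1))
  expect_error(sequence_mask_fraction(0, sched), class = "codonlm_bad_input")
})

test_that("a compressed schedule keeps the same shape", {
  sched <- curriculum_schedule(1, 1, 0.2, 6)
  expect_identical(sequence_mask_fraction(1, sched), 0)
  expect_equal(sequence_mask_fraction(2:6, sched),
               c(0.2, 0.4, 0.6, 0.8, 1), tolerance = 1e-12)
  expect_identical(sequence_mask_fraction(7:20, sched), rep(1, 14))
  f <- sequence_mask_fraction(1:100, sched)
  expect_true(all(diff(f) >= 0))
  expect_error(curriculum_schedule(10, 5, 0.1, 5),
               class = "codonlm_config_error")
  expect_error(curriculum_schedule(increment = 0),
               class = "codonlm_config_error")
})

test_that("sequence zeroing labels whole sequences and is seeded", {
  rec <- generate_synthetic_corpus(8, c(5, 10), seed = 1)
  cfg <- small_config()
  b <- make_batch(rec$protein, rec$cds, cfg)
  expect_identical(apply_sequence_zeroing(b, 0), b)
  full <- apply_sequence_zeroing(b, 1)
  expect_true(all(full$seq_zeroed))
  for (i in 1:8) {
    lab <- full$codon_labels[i, ]
    expect_identical(lab[seq_len(b$lens[i])],
                     b$codon_ids[i, seq_len(b$lens[i])])
    if (b$lens[i] < ncol(b$codon_labels))
      expect_true(all(lab[(b$lens[i] + 1):ncol(b$codon_labels)] == 0L))
  }
  h1 <- withr::with_seed(42, apply_sequence_zeroing(b, 0.5))
  h2 <- withr::with_seed(42, apply_sequence_zeroing(b, 0.5))
  expect_identical(sum(h1$seq_zeroed), 4L)
  expect_identical(h1, h2)
})

test_that("token masking hits the expected fraction and never padding", {
  rec <- generate_synthetic_corpus(200, c(50, 50), seed = 2)
  cfg <- codonlm_config("tiny")
  b <- make_batch(rec$protein, rec$cds, cfg)
  none <- apply_token_masking(b, 0, 0)
  expect_true(all(none$codon_labels == 0L) && all(none$aa_labels == 0L))
  m <- withr::with_seed(3, apply_token_masking(b, 0.15, 0.15))
  n_pos <- sum(b$lens)  # 10^4 positions
  n_masked <- sum(m$codon_labels > 0)
  expect_lt(abs(n_masked - 0.15 * n_pos), 3 * sqrt(0.15 * 0.85 * n_pos))
  # masked positions carry the original id as label, MASK as input
  idx <- which(m$codon_labels > 0)
  expect_true(all(m$codon_ids[idx] == codonlm:::CODON_MASK))
  expect_identical(m$codon_labels[idx], b$codon_ids[idx])
  # padding untouched in both streams
  pad <- b$aa_ids == codonlm:::AA_PAD
  expect_true(all(m$aa_ids[pad] == codonlm:::AA_PAD))
  expect_true(all(m$codon_labels[pad] == 0L) && all(m$aa_labels[pad] == 0L))
})

test_that("zeroed rows are exempt from token masking", {
  rec <- generate_synthetic_corpus(6, c(8, 8), seed = 4)
  cfg <- small_config()
  b <- make_batch(rec$protein, rec$cds, cfg)
  b <- withr::with_seed(1, apply_sequence_zeroing(b, 0.5))
  m <- withr::with_seed(2, apply_token_masking(b, 0.9, 0.9))
  z <- which(m$seq_zeroed)
  expect_true(all(m$codon_ids[z, ] == b$codon_ids[z, ]))
  expect_true(all(m$aa_labels[z, ] == 0L))
})

test_that("masked cross-entropy matches closed forms", {
  cfg <- small_config()
  params <- codonlm:::init_params(cfg, seed = 5)
  # zeroed heads give uniform distributions: loss = ln 66 + ln 22
  params$head_c_W[] <- 0; params$head_c_b[] <- 0
  params$head_a_W[] <- 0; params$head_a_b[] <- 0
  rec <- generate_synthetic_corpus(4, c(5, 9), seed = 6)
  b <- make_batch(rec$protein, rec$cds, cfg)
  b <- withr::with_seed(7, apply_token_masking(b, 0.4, 0.4))
  out <- model_loss(params, b, cfg)
  expect_equal(out$loss, log(66) + log(22), tolerance = 1e-10)
  # duplicating the batch leaves the mean loss unchanged
  b2 <- make_batch(rep(rec$protein, 2), rep(rec$cds, 2), cfg)
  b2$codon_labels <- rbind(b$codon_labels, b$codon_labels)
  b2$aa_labels <- rbind(b$aa_labels, b$aa_labels)
  b2$codon_ids <- rbind(b$codon_ids, b$codon_ids)
  b2$aa_ids <- rbind(b$aa_ids, b$aa_ids)
  out2 <- model_loss(params, b2, cfg)
  expect_equal(out2$loss, out$loss, tolerance = 1e-12)
  # unlabeled batches are an error
  b0 <- make_batch(rec$protein, rec$cds, cfg)
  expect_error(model_loss(params, b0, cfg), class = "codonlm_no_labels")
})

test_that("training reduces the loss and is reproducible under the seed", {
  rec <- generate_synthetic_corpus(10, c(6, 10), seed = 8)
  cfg <- small_config()
  sched <- curriculum_schedule(1, 1, 0.5, 2)
  f1 <- codonlm(rec, cfg, epochs = 12, batch_size = 10, schedule = sched,
                seed = 3)
  expect_identical(nrow(f1$history), 12L)
  expect_lt(f1$history$loss[12], f1$history$loss[1])
  f2 <- codonlm(rec, cfg, epochs = 12, batch_size = 10, schedule = sched,
                seed = 3)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$history$seq_mask_fraction,
                   sequence_mask_fraction(1:12, sched))
})

test_that("a resumed fit reproduces the uninterrupted history", {
  rec <- generate_synthetic_corpus(8, c(5, 8), seed = 9)
  cfg <- small_config()
  sched <- curriculum_schedule(1, 1, 0.5, 2)
  full <- codonlm(rec, cfg, epochs = 10, batch_size = 8, schedule = sched,
                  seed = 7)
  part <- codonlm(rec, cfg, epochs = 4, batch_size = 8, schedule = sched,
                  seed = 7)
  resumed <- codonlm(rec, cfg, epochs = 10, resume = part)
  expect_identical(resumed$history, full$history)
  expect_identical(resumed$params, full$params)
})

test_that("checkpoints round-trip through save and load", {
  fit <- overfit_fit()
  d <- withr::local_tempdir()
  save_codonlm(fit, d)
  expect_true(file.exists(file.path(d, "config.json")))
  fit2 <- load_codonlm(d)
  expect_identical(fit2$params, fit$params)
  expect_identical(fit2$history, fit$history)
  p <- overfit_records()$protein[1:2]
  expect_identical(predict(fit2, p, constrain = TRUE),
                   predict(fit, p, constrain = TRUE))
  expect_error(load_codonlm(file.path(d, "missing")),
               class = "codonlm_io_error")
})
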