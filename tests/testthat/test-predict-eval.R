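test_that("codon accuracy counts identical codons per position", {
  expect_identical(codon_accuracy("ATGAAA", "ATGAAA"), 1)
  expect_identical(codon_accuracy("AAAAAA", "AAGAAG"), 0)  # synonymous != identical
  expect_equal(codon_accuracy("ATGAAAGGG", "ATGAAAGGC"), 2 / 3)
  expect_error(codon_accuracy("ATGAAA", "ATG"), class = "codonlm_length_error")
})

test_that("usage frequencies pool codons and sum to one", {
  u <- usage_frequencies("AAA")
  expect_identical(unname(u["AAA"]), 1)
  expect_identical(sum(u), 1)
  u2 <- usage_frequencies(c("AAA", "AAG"))
  expect_identical(unname(u2[c("AAA", "AAG")]), c(0.5, 0.5))
  # concatenation invariance
  set.seed(1)
  a <- paste(sample(all_codons(), 10, replace = TRUE), collapse = "")
  b <- paste(sample(all_codons(), 7, replace = TRUE), collapse = "")
  expect_equal(usage_frequencies(paste0(a, b)), usage_frequencies(c(a, b)),
               tolerance = 1e-12)
  expect_error(usage_frequencies(character(0)), class = "codonlm_empty_input")
})

test_that("bicodon frequencies count adjacent ordered pairs within sequences", {
  p <- pair_usage_frequencies("AAAAAG")
  expect_identical(unname(p["AAA:AAG"]), 1)
  expect_length(p, 4096L)
  expect_equal(sum(p), 1, tolerance = 1e-9)
  # an n-codon sequence contributes n - 1 pairs; none cross sequences
  p2 <- pair_usage_frequencies(c("AAAAAGAAT", "GGGGGC"))
  expect_equal(sum(p2 > 0), 3)
  expect_error(pair_usage_frequencies("AAA"), class = "codonlm_length_error")
  # reversal changes pair counts but not codon counts
  s <- "AAAAAGAAT"
  r <- "AATAAGAAA"
  expect_equal(usage_frequencies(s), usage_frequencies(r), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(pair_usage_frequencies(s),
                                pair_usage_frequencies(r))))
})

test_that("pearson_corr agrees with the brute-force formula", {
  expect_equal(pearson_corr(1:5, 1:5), 1, tolerance = 1e-12)
  expect_equal(pearson_corr(1:5, -(1:5)), -1, tolerance = 1e-12)
  brute <- function(x, y) {
    mx <- sum(x) / length(x); my <- sum(y) / length(y)
    sum((x - mx) * (y - my)) /
      sqrt(sum((x - mx)^2) * sum((y - my)^2))
  }
  expect_equal(pearson_corr(c(1, 2, 3), c(1, 2, 4)),
               brute(c(1, 2, 3), c(1, 2, 4)), tolerance = 1e-12)
  set.seed(2)
  for (i in 1:10) {
    x <- rnorm(50); y <- rnorm(50)
    expect_equal(pearson_corr(x, y), brute(x, y), tolerance = 1e-12)
  }
  expect_error(pearson_corr(rep(1, 5), 1:5), class = "codonlm_zero_variance")
  expect_error(pearson_corr(1:3, 1:4), class = "codonlm_bad_input")
})

test_that("constrained decoding preserves the protein for any parameters", {
  cfg <- small_config()
  raw <- list(params = codonlm:::init_params(cfg, seed = 99), config = cfg,
              code = genetic_code())
  class(raw) <- "codonlm"
  set.seed(4)
  prots <- vapply(1:10, function(i) random_protein(sample(3:30, 1)), "")
  cds <- predict(raw, prots, constrain = TRUE)
  expect_identical(vapply(cds, translate_cds, "", USE.NAMES = FALSE), prots)
  # single-codon families are forced even unconstrained decoding aside
  expect_identical(predict(raw, "MW", constrain = TRUE), "ATGTGG")
  # unconstrained decoding emits real codons only (never PAD/MASK)
  free <- predict(raw, prots, constrain = FALSE)
  for (s in free)
    expect_true(all(codonlm:::split_codons(s) %in% all_codons()))
})

test_that("an overfit model reproduces its training corpus end to end", {
  fit <- overfit_fit()
  rec <- overfit_records()
  ev <- evaluate_model(fit, rec)
  expect_identical(ev$median_accuracy, 1)
  expect_identical(stats::median(ev$per_seq$aa_fidelity), 1)
  expect_equal(ev$pcc_usage, 1, tolerance = 0.02)
  expect_gt(ev$pcc_pair, 0.98)
  expect_equal(sum(ev$usage_pred), 1, tolerance = 1e-9)
  expect_equal(sum(ev$pair_usage_pred), 1, tolerance = 1e-9)
  expect_identical(nrow(ev$per_seq), nrow(rec))
  expect_null(ev$mfe_values)
})

test_that("sampled sequences follow the constrained families", {
  fit <- overfit_fit()
  prots <- overfit_records()$protein[1:3]
  sims <- simulate(fit, nsim = 2, seed = 5, proteins = prots)
  expect_identical(dim(sims), c(3L, 2L))
  for (j in 1:2)
    expect_identical(vapply(sims[[j]], translate_cds, "", USE.NAMES = FALSE),
                     prots)
  sims2 <- simulate(fit, nsim = 2, seed = 5, proteins = prots)
  expect_identical(sims, sims2)
})

test_that("the RNAfold adapter reports availability and folds a hairpin", {
  prov <- vienna_mfe_provider()
  expect_s3_class(prov, "mfe_provider")
  if (mfe_available(prov)) {
    hairpin <- "GGGGGGGGGAAAAACCCCCCCCC"
    expect_lt(compute_mfe(prov, hairpin), 0)
    expect_identical(compute_mfe(prov, "AAAAAAAAA"), 0)
    fit <- overfit_fit()
    ev <- evaluate_model(fit, overfit_records(), mfe_provider = prov)
    expect_false(is.null(ev$mfe_values))
    expect_true(all(ev$mfe_values <= 0))
  } else {
    expect_error(compute_mfe(prov, "AAA"), class = "codonlm_no_mfe_provider")
  }
})

test_that("evaluation reports serialize to JSON and TSV", {
  fit <- overfit_fit()
  ev <- evaluate_model(fit, overfit_records())
  d <- withr::local_tempdir()
  json <- file.path(d, "report.json")
  write_eval_report(ev, json, tsv_path = file.path(d, "report"))
  got <- jsonlite::read_json(json)
  expect_equal(got$median_accuracy, 1)
  expect_equal(got$pcc_usage, ev$pcc_usage, tolerance = 1e-12)
  per_seq <- utils::read.delim(file.path(d, "report_per_seq.tsv"))
  expect_identical(nrow(per_seq), nrow(ev$per_seq))
  usage <- utils::read.delim(file.path(d, "report_usage.tsv"))
  expect_identical(nrow(usage), 64L)
})
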