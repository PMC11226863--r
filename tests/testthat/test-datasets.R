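toy_records <- function() {
  prot <- c("MK", "MW", "KK", "MM", "WK")
  tab <- codon_usage_table(c(AAA = 2, AAG = 1, ATG = 1, TGG = 1))
  cds <- vapply(prot, jcat_optimize, "", table = tab, USE.NAMES = FALSE)
  transcript_records(paste0("tx", 1:5), cds, tpm = c(1, 5, 6, 10, 0.2))
}

test_that("record construction validates the translation invariant", {
  rec <- transcript_records("a", "ATGAAA")
  expect_identical(rec$protein, "MK")
  expect_error(transcript_records("a", "ATGAAA", protein = "MM"),
               class = "codonlm_bad_input")
})

test_that("expression filter keeps TPM strictly above the threshold", {
  rec <- toy_records()
  kept <- filter_by_tpm(rec, 5)
  expect_identical(kept$id, c("tx3", "tx4"))  # 6 and 10; the 5 is dropped
  expect_identical(filter_by_tpm(rec, 0)$id, rec$id[rec$tpm > 0])
  expect_identical(nrow(filter_by_tpm(rec[0, ], 5)), 0L)
  rec$tpm[2] <- NA
  expect_error(filter_by_tpm(rec, 5), class = "codonlm_missing_tpm")
})

test_that("CAI/MFE filter applies only the requested bounds", {
  rec <- toy_records()
  tab <- build_usage_table(rec$cds)
  expect_identical(filter_by_cai_mfe(rec, tab), rec)  # no bounds: identity
  # a record with the rare lysine codon has CAI below the optimized ones
  rec2 <- transcript_records(c("hi", "lo"), c("AAAAAA", "AAGAAG"))
  tab2 <- codon_usage_table(c(AAA = 4, AAG = 1))
  kept <- filter_by_cai_mfe(rec2, tab2, cai_min = 0.5)
  expect_identical(kept$id, "hi")
  expect_error(filter_by_cai_mfe(rec2, tab2, mfe_max = -1),
               class = "codonlm_no_mfe_provider")
  off <- mfe_provider(function(x) 0, available = FALSE)
  expect_error(filter_by_cai_mfe(rec2, tab2, mfe_max = -1, mfe_provider = off),
               class = "codonlm_no_mfe_provider")
  # a stub provider exercises the MFE bound deterministically
  stub <- mfe_provider(function(x) -nchar(x), name = "stub")
  kept2 <- filter_by_cai_mfe(rec2, tab2, mfe_max = -3, mfe_provider = stub)
  expect_identical(kept2$id, c("hi", "lo"))
})

test_that("one-codon admixture replaces a seeded subset, proteins unchanged", {
  rec <- generate_synthetic_corpus(10, c(5, 9), seed = 4)
  tab <- build_usage_table(rec$cds)
  same <- mix_jcat(rec, 0, tab, seed = 1)
  expect_identical(same$cds, rec$cds)
  half1 <- mix_jcat(rec, 0.5, tab, seed = 9)
  half2 <- mix_jcat(rec, 0.5, tab, seed = 9)
  expect_identical(half1$cds, half2$cds)
  expect_identical(length(attr(half1, "replaced")), 5L)
  untouched <- setdiff(seq_len(10), attr(half1, "replaced"))
  expect_identical(half1$cds[untouched], rec$cds[untouched])
  expect_identical(half1$protein, rec$protein)
  all_j <- mix_jcat(rec, 1, tab, seed = 2)
  cai <- vapply(all_j$cds, compute_cai, 0, table = tab, USE.NAMES = FALSE)
  expect_identical(cai, rep(1, 10))
})

test_that("train/test split is disjoint, exhaustive and reproducible", {
  rec <- generate_synthetic_corpus(10, c(4, 6), seed = 3)
  sp <- train_test_split(rec, 0.2, seed = 5)
  expect_identical(c(nrow(sp$train), nrow(sp$test)), c(8L, 2L))
  expect_identical(sort(c(sp$train$id, sp$test$id)), sort(rec$id))
  expect_length(intersect(sp$train$id, sp$test$id), 0L)
  sp2 <- train_test_split(rec, 0.2, seed = 5)
  expect_identical(sp, sp2)
  expect_error(train_test_split(rec[1, ], 0.5), class = "codonlm_bad_input")
})

test_that("synthetic records always satisfy the translation invariant", {
  for (args in list(list(pair_dependence = 0), list(pair_dependence = 0.7),
                    list(deterministic_rule = TRUE))) {
    rec <- do.call(generate_synthetic_corpus,
                   c(list(n_sequences = 15, length_range = c(3, 20), seed = 8),
                     args))
    expect_identical(vapply(rec$cds, translate_cds, "", USE.NAMES = FALSE),
                     rec$protein)
  }
})

test_that("generation is seeded and handles degenerate ranges", {
  a <- generate_synthetic_corpus(5, c(5, 5), deterministic_rule = TRUE, seed = 6)
  b <- generate_synthetic_corpus(5, c(5, 5), deterministic_rule = TRUE, seed = 6)
  expect_identical(a, b)
  expect_identical(unique(nchar(a$protein)), 5L)
  one <- generate_synthetic_corpus(1, c(5, 5), seed = 1)
  expect_identical(nrow(one), 1L)
  expect_identical(nchar(one$cds), 15L)
  expect_error(generate_synthetic_corpus(3, c(6, 5)),
               class = "codonlm_bad_input")
  expect_error(generate_synthetic_corpus(3, c(1, 4)),
               class = "codonlm_bad_input")
})

test_that("with no pair dependence the planted within-family usage is recovered", {
  tab <- default_planted_usage()
  rec <- generate_synthetic_corpus(2000, c(30, 60), planted_usage = tab,
                                   pair_dependence = 0, seed = 10)
  emp <- usage_frequencies(rec$cds)
  gc <- genetic_code()
  planted <- emp * 0
  emp_fam <- emp * 0
  for (aa in setdiff(names(gc$families), "*")) {
    fam <- gc$families[[aa]]
    planted[fam] <- tab$freq[fam] / sum(tab$freq[fam])
    emp_fam[fam] <- emp[fam] / sum(emp[fam])
  }
  keep <- planted > 0
  expect_gt(pearson_corr(emp_fam[keep], planted[keep]), 0.99)
})
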