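test_that("mutation_rate counts samples, not records, and handles silent", {
  muts <- toy_mutation_table()
  # S01 missense, S02 nonsense, S04 frame-shift; S03 silent-only
  expect_equal(mutation_rate(muts, "TP53", "TT"), 0.3)
  expect_equal(mutation_rate(muts, "TP53", "TT", include_silent = TRUE),
               0.4)
  expect_equal(mutation_rate(muts, "GENEB", "TT"), 0.1)
  expect_error(mutation_rate(muts, "TP53", "XX"),
               class = "tp53_validation_error")

  # monotone: adding a record never lowers the rate
  rec2 <- dplyr::bind_rows(muts$records, tibble::tibble(
    sample_id = "S06", cancer_type = "TT", gene_symbol = "TP53",
    variant_class = "missense"))
  muts2 <- mutation_table(rec2, muts$sample_universe)
  expect_gte(mutation_rate(muts2, "TP53", "TT"),
             mutation_rate(muts, "TP53", "TT"))
})

test_that("rank_gene uses min-rank ties and honors exclusions", {
  uni <- tibble::tibble(cancer_type = "TT",
                        sample_id = sprintf("S%d", 1:10))
  rec <- tibble::tibble(
    sample_id = c("S1", "S2", "S3", "S4", "S5", "S1", "S2", "S3", "S6"),
    cancer_type = "TT",
    gene_symbol = c(rep("TTN", 5), rep("TP53", 3), "GENEA"),
    variant_class = "missense")
  muts <- mutation_table(rec, uni)
  expect_equal(rank_gene(muts, "TTN", "TT"), 1L)
  expect_equal(rank_gene(muts, "TP53", "TT"), 2L)
  expect_equal(rank_gene(muts, "TP53", "TT", exclude = "TTN"), 1L)

  # ties share the minimum rank
  rec_tie <- dplyr::bind_rows(rec, tibble::tibble(
    sample_id = c("S4", "S5"), cancer_type = "TT",
    gene_symbol = "TP53", variant_class = "missense"))
  muts_tie <- mutation_table(rec_tie, uni)
  expect_equal(rank_gene(muts_tie, "TP53", "TT"), 1L)
  expect_equal(rank_gene(muts_tie, "TTN", "TT"), 1L)

  # absent gene is flagged
  expect_warning(r <- rank_gene(muts, "NOPE", "TT"), "undefined")
  expect_true(is.na(r))

  # single-gene table
  muts1 <- mutation_table(rec[rec$gene_symbol == "TP53", ], uni)
  expect_equal(rank_gene(muts1, "TP53", "TT"), 1L)
})

test_that("class_proportions normalises over records", {
  uni <- tibble::tibble(cancer_type = "TT",
                        sample_id = sprintf("S%d", 1:4))
  rec <- tibble::tibble(
    sample_id = c("S1", "S2", "S3", "S4"),
    cancer_type = "TT", gene_symbol = "TP53",
    variant_class = c("missense", "missense", "nonsense", "silent"))
  muts <- mutation_table(rec, uni)
  cp <- class_proportions(muts, "TP53")
  expect_equal(sum(cp$proportion), 1)
  expect_equal(cp$proportion[cp$variant_class == "missense"], 0.5)
  expect_equal(cp$proportion[cp$variant_class == "nonsense"], 0.25)
  expect_equal(cp$proportion[cp$variant_class == "silent"], 0.25)
  expect_equal(cp$proportion[cp$variant_class == "splice_site"], 0)

  # grouped truncating share
  rec2 <- tibble::tibble(
    sample_id = c("S1", "S2", "S3", "S4"),
    cancer_type = "TT", gene_symbol = "TP53",
    variant_class = c("nonsense", "frame_shift_del", "missense",
                      "missense"))
  cp2 <- class_proportions(mutation_table(rec2, uni), "TP53")
  trunc_share <- sum(cp2$proportion[cp2$variant_class %in%
                                      truncating_classes()])
  expect_equal(trunc_share, 0.5)

  # permutation invariance
  cp3 <- class_proportions(mutation_table(rec2[4:1, ], uni), "TP53")
  expect_equal(cp2, cp3)

  expect_error(class_proportions(muts, "ABSENT"),
               class = "tp53_validation_error")
})

test_that("classify_tp53_status applies truncating precedence and the silent rule", {
  uni <- tibble::tibble(cancer_type = "TT",
                        sample_id = sprintf("S%d", 1:5))
  rec <- tibble::tibble(
    sample_id = c("S1", "S2", "S2", "S3", "S4"),
    cancer_type = "TT", gene_symbol = "TP53",
    variant_class = c("nonsense", "missense", "frame_shift_del",
                      "silent", "in_frame_del"))
  st <- classify_tp53_status(mutation_table(rec, uni))
  got <- setNames(st$tp53_status, st$sample_id)
  expect_equal(unname(got["S1"]), "truncating")
  expect_equal(unname(got["S2"]), "truncating")  # mixed -> truncating
  expect_equal(unname(got["S3"]), "wildtype")    # silent-only
  expect_equal(unname(got["S4"]), "non_truncating")
  expect_equal(unname(got["S5"]), "wildtype")    # no record

  # never non_truncating when a truncating record is present
  expect_false(any(st$tp53_status == "non_truncating" &
                     st$sample_id %in% c("S1", "S2")))
})

test_that("phenotype_association builds the 2x2 and applies Fisher's test", {
  uni <- tibble::tibble(cancer_type = "TT",
                        sample_id = sprintf("S%02d", 1:16))
  # mutated: S01..S08
  rec <- tibble::tibble(sample_id = sprintf("S%02d", 1:8),
                        cancer_type = "TT", gene_symbol = "TP53",
                        variant_class = "missense")
  muts <- mutation_table(rec, uni)
  bin <- standard_binnings()$stage

  # uniform table: equal rates in both classes
  clin <- tibble::tibble(
    sample_id = sprintf("S%02d", 1:16),
    stage = rep(c("I", "III"), 8))
  res <- phenotype_association(muts, clin, bin, "TT")
  expect_false(res$skipped)
  expect_equal(res$result$effect, 1)
  expect_equal(res$result$p_value, 1)

  # all mutated samples late-stage: OR 0 for early class
  clin2 <- tibble::tibble(
    sample_id = sprintf("S%02d", 1:16),
    stage = c(rep("III", 8), rep("I", 8)))
  res2 <- phenotype_association(muts, clin2, bin, "TT")
  expect_equal(res2$result$effect, 0)
  expect_equal(res2$result$p_value,
               oracle_fisher(0, 8, 8, 0), tolerance = 1e-12)

  # missing phenotype values are excluded; stage III maps to late
  clin3 <- clin2
  clin3$stage[1] <- NA
  res3 <- phenotype_association(muts, clin3, bin, "TT")
  expect_equal(sum(res3$table), 15)
  expect_equal(res3$table["late", "mutated"], 7)

  # a degenerate (empty) class is skipped, not tested
  clin4 <- tibble::tibble(sample_id = sprintf("S%02d", 1:16),
                          stage = "I")
  res4 <- phenotype_association(muts, clin4, bin, "TT")
  expect_true(res4$skipped)
  expect_match(res4$reason, "degenerate")
})
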