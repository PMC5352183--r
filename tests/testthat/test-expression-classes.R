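test_that("diff_expr computes geometric-mean fold changes and passing sets", {
  st <- toy_study(genes = 30, shift = 1, n_shift = 6, sigma = 0.3)
  cfg <- lenient_config()
  de <- diff_expr(st, "mutated", "wildtype", cfg = cfg)
  expect_s3_class(de, "tp53_de")

  # fold change is 2^(difference of log2 means)
  expect_equal(de$fold_change, 2^(de$mean_a - de$mean_b))

  # planted genes (log2 shift 1 => FC ~2) dominate the passing set
  planted <- rownames(st$exprs)[2:7]
  expect_true(all(planted %in% passing_genes(de)))

  # identical-mean gene never passes: plant a constant gene
  m <- st$exprs; m["G029", ] <- 5
  st2 <- expression_study("TT", m, st$sample_meta)
  de2 <- diff_expr(st2, "mutated", "wildtype", cfg = cfg)
  expect_equal(de2$fold_change[de2$gene == "G029"], 1)
  expect_false("G029" %in% passing_genes(de2))
  expect_equal(de2$p_value[de2$gene == "G029"], 1)

  # sample-order permutation leaves the result unchanged
  perm <- sample(colnames(st$exprs))
  st3 <- expression_study("TT", st$exprs[, perm],
                          st$sample_meta[match(perm,
                                               st$sample_meta$sample_id), ])
  de3 <- diff_expr(st3, "mutated", "wildtype", cfg = cfg)
  expect_equal(de3$p_value, de$p_value)
  expect_equal(passing_genes(de3), passing_genes(de))

  # adding a constant to all log2 values of one gene (both groups)
  # leaves its fold change unchanged
  m4 <- st$exprs; m4["G010", ] <- m4["G010", ] + 3
  de4 <- diff_expr(expression_study("TT", m4, st$sample_meta),
                   "mutated", "wildtype", cfg = cfg)
  expect_equal(de4$fold_change[de4$gene == "G010"],
               de$fold_change[de$gene == "G010"])

  # undersized groups are skipped with a reason
  sk <- diff_expr(st, "mutated", "wildtype", cfg = run_config(
    min_group = 50))
  expect_s3_class(sk, "tp53_de_skipped")
  expect_match(sk$reason, "below required")
  expect_identical(passing_genes(sk), character(0))

  expect_error(diff_expr(st, c("A01", "A02"), c("A02", "B01"),
                         cfg = cfg),
               class = "tp53_validation_error")
})

test_that("derive_gene_classes satisfies the set algebra by construction", {
  cfg <- lenient_config()
  st <- toy_study(genes = 40, shift = 1.2, n_shift = 8, sigma = 0.4)
  cls <- derive_gene_classes(st, cfg)
  expect_setequal(cls$sets$MWN, intersect(cls$sets$MW, cls$sets$WN))
  expect_length(intersect(cls$sets$MSN, cls$sets$WN2), 0)
  expect_true(all(cls$sets$WN %in% cls$sets$WN2))
  expect_setequal(cls$sets$MSN, setdiff(cls$sets$MN, cls$sets$WN2))

  # toy hand-check of the algebra on explicit sets
  sets <- list(type1 = list(MW = c("A", "B"), WN = c("B", "C"),
                            WN2 = c("B", "C", "D"),
                            MN = c("A", "B", "C")))
  expect_setequal(intersect(sets$type1$MW, sets$type1$WN), "B")
  expect_setequal(setdiff(sets$type1$MN, sets$type1$WN2), "A")
})

test_that("missing normals empty the normal-based sets but keep MW", {
  st <- toy_study(genes = 20, n_n = 2, shift = 1.5, n_shift = 4,
                  sigma = 0.4)
  cfg <- run_config(min_group = 2, min_normals = 4)
  cls <- derive_gene_classes(st, cfg)
  expect_gt(length(cls$sets$MW), 0)
  expect_length(cls$sets$WN, 0)
  expect_length(cls$sets$MN, 0)
  expect_length(cls$sets$MSN, 0)
  expect_true(all(c("WN", "WN2", "MN") %in% names(cls$skipped)))
})

test_that("recurrence_filter applies strict-fraction and absolute modes", {
  # 29 types; gene in 8 kept (8 > 7.25), gene in 7 dropped
  types <- sprintf("t%02d", 1:29)
  sets <- setNames(lapply(1:29, function(i) {
    out <- character(0)
    if (i <= 8) out <- c(out, "KEEP8")
    if (i <= 7) out <- c(out, "DROP7")
    out
  }), types)
  rf <- recurrence_filter(sets, fraction = 0.25)
  expect_true(rf$kept[rf$gene == "KEEP8"])
  expect_false(rf$kept[rf$gene == "DROP7"])

  # absolute mode: at least 10 of 21 types
  sets21 <- setNames(lapply(1:21, function(i)
    if (i <= 10) "G10" else character(0)), sprintf("u%02d", 1:21))
  expect_true("G10" %in% recurrent_genes(sets21, min_types = 10))
  expect_false("G10" %in% recurrent_genes(sets21, min_types = 11))

  # single type: every member gene is kept (1 > 0.25)
  rf1 <- recurrence_filter(list(only = c("A", "B")), fraction = 0.25)
  expect_true(all(rf1$kept))

  expect_error(recurrence_filter(list()), class = "tp53_validation_error")
})

test_that("tp53_group_comparison reports ratio-of-means fold change", {
  st <- toy_study(genes = 10, n_shift = 0)
  res <- tp53_group_comparison(st, "mutated", "mutated")
  # comparing a group against itself: p 1, FC 1
  expect_equal(res$p_value, 1)
  expect_equal(res$fold_change, 1)

  # planted TP53 drop in group a
  m <- st$exprs
  ids_a <- sample_groups(st)$mutated
  m["TP53", ids_a] <- m["TP53", ids_a] - 1.5
  st2 <- expression_study("TT", m, st$sample_meta)
  res2 <- tp53_group_comparison(st2, "mutated", "wildtype")
  expect_lt(res2$p_value, 0.05)
  expect_lt(res2$fold_change, 1)

  # a group below 2 samples is skipped with reason
  st3 <- toy_study(genes = 5, n_a = 1, n_b = 4, n_n = 2, n_shift = 0)
  expect_s3_class(tp53_group_comparison(st3, "mutated", "wildtype"),
                  "tp53_de_skipped")
})

test_that("tp53_pattern emits orderings only when adjacent pairs separate", {
  # planted ordering non_truncating > wildtype > truncating
  withr::with_seed(21, {
    ids <- list(non_truncating = sprintf("NT%02d", 1:30),
                wildtype = sprintf("WT%02d", 1:30),
                truncating = sprintf("TR%02d", 1:30))
    samples <- unlist(ids)
    m <- matrix(rnorm(2 * length(samples), mean = 8, sd = 1), nrow = 2,
                dimnames = list(c("TP53", "G001"), samples))
    m["TP53", ids$non_truncating] <- m["TP53", ids$non_truncating] + 1
    m["TP53", ids$truncating] <- m["TP53", ids$truncating] - 1.5
    meta <- tibble::tibble(
      sample_id = samples, tissue = "tumor",
      tp53_group = rep(names(ids), each = 30))
    st <- expression_study("TT", m, meta)
  })
  pat <- tp53_pattern(st)
  expect_equal(pat$pattern, "non_truncating > wildtype > truncating")
  # only adjacent pairs are tested (2 comparisons for 3 groups)
  expect_equal(nrow(pat$pairwise), 2)

  # no pattern when groups are exchangeable
  withr::with_seed(22, {
    m0 <- matrix(rnorm(2 * length(samples), mean = 8, sd = 1), nrow = 2,
                 dimnames = list(c("TP53", "G001"), samples))
    st0 <- expression_study("TT", m0, meta)
  })
  expect_true(is.na(tp53_pattern(st0)$pattern))
})

test_that("coexpression_with_tp53 separates tumor-only correlation", {
  withr::with_seed(33, {
    tum <- sprintf("T%02d", 1:40); nor <- sprintf("N%02d", 1:20)
    samples <- c(tum, nor)
    m <- matrix(rnorm(4 * 60, mean = 8), nrow = 4,
                dimnames = list(c("TP53", "MIRROR", "BOTH", "NOISE"),
                                samples))
    m["MIRROR", tum] <- m["TP53", tum]          # tumor-only: PCOR
    m["BOTH", ] <- m["TP53", ] + rnorm(60, sd = 0.1)  # both tissues
    meta <- tibble::tibble(
      sample_id = samples,
      tissue = rep(c("tumor", "normal"), c(40, 20)),
      tp53_group = rep(c("wildtype", "not_applicable"), c(40, 20)))
    st <- expression_study("TT", m, meta)
  })
  cx <- coexpression_with_tp53(st)
  expect_true("MIRROR" %in% pcor_genes(cx))
  expect_equal(cx$r_tumor[cx$gene == "MIRROR"], 1)
  # correlated in normals too: excluded from PCOR
  expect_false("BOTH" %in% pcor_genes(cx))
  # the anchor itself is never reported
  expect_false("TP53" %in% cx$gene)

  # constant gene excluded with a note
  m2 <- st$exprs; m2["NOISE", ] <- 3
  cx2 <- coexpression_with_tp53(
    expression_study("TT", m2, st$sample_meta))
  expect_match(cx2$note[cx2$gene == "NOISE"], "constant")
  expect_false(cx2$pcor[cx2$gene == "NOISE"])

  # missing anchor is an error
  m3 <- st$exprs[-1, ]
  expect_error(coexpression_with_tp53(
    expression_study("TT", m3, st$sample_meta)),
    class = "tp53_validation_error")
})

test_that("cytoband_enrichment matches the brute-force tail computation", {
  band_map <- tibble::tibble(
    gene = sprintf("G%03d", 1:100),
    band = rep(c("chr17p13", "chr2p23", "chr5q31", "chrXq28"),
               c(10, 20, 30, 40)))
  # set entirely inside one band: minimum possible p
  set <- sprintf("G%03d", 1:5)
  res <- cytoband_enrichment(set, band_map)
  expect_equal(res$band[1], "chr17p13")
  expect_equal(res$p_value[1], oracle_hyper_tail(5, 5, 10, 100),
               tolerance = 1e-12)
  expect_equal(res$set_in_band[1], 5)

  # a band containing none of the set genes scores p = 1
  expect_equal(hypergeom_enrichment(0, 5, 40, 100)$p_value, 1)

  # empty set: empty result
  expect_equal(nrow(cytoband_enrichment(character(0), band_map)), 0)

  # uncovered universe is an error
  expect_error(cytoband_enrichment("G001", band_map,
                                   universe = c("G001", "MISSING")),
               class = "tp53_validation_error")
})
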