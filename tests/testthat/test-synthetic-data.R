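test_that("generation is deterministic under a fixed seed and varies across seeds", {
  cfg <- generator_config(n_types = 1, genes = 60, tumors_per_type = 20,
                          normals_per_type = 6, n_planted_mw = 5,
                          n_planted_wn = 5, n_planted_sl = 5,
                          cis_block = 4, n_sl_compounds = 3,
                          n_compounds = 5, n_cell_lines = 20, seed = 7)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$studies[[1]]$exprs, c2$studies[[1]]$exprs)
  expect_identical(c1$mutations$records, c2$mutations$records)
  expect_identical(c1$survival, c2$survival)
  cfg2 <- generator_config(n_types = 1, genes = 60,
                           tumors_per_type = 20, normals_per_type = 6,
                           n_planted_mw = 5, n_planted_wn = 5,
                           n_planted_sl = 5, cis_block = 4,
                           n_sl_compounds = 3, n_compounds = 5,
                           n_cell_lines = 20, seed = 8)
  c3 <- generate_cohort(cfg2)
  expect_false(identical(c1$studies[[1]]$exprs, c3$studies[[1]]$exprs))
  # the global RNG stream is left untouched
  withr::with_seed(1, before <- runif(1))
  withr::with_seed(1, {
    invisible(generate_cohort(cfg))
    after <- runif(1)
  })
  expect_identical(before, after)
})

test_that("planted sets are disjoint and configuration is validated", {
  cfg <- generator_config(n_types = 1, genes = 100,
                          tumors_per_type = 20, normals_per_type = 6,
                          n_planted_mw = 10, n_planted_wn = 10,
                          n_planted_sl = 10, cis_block = 6,
                          n_sl_compounds = 5)
  co <- generate_cohort(cfg)
  tr <- co$truth
  all_planted <- c(tr$planted_mw, tr$planted_wn, tr$planted_sl,
                   tr$cis_genes)
  expect_equal(length(all_planted), length(unique(all_planted)))
  expect_false("TP53" %in% all_planted)
  expect_equal(length(tr$planted_mw), cfg$n_planted_mw)
  expect_setequal(tr$mw_truth, c(tr$planted_mw, tr$planted_sl))

  expect_error(generator_config(genes = 50), class = "tp53_config_error")
  expect_error(generator_config(n_sl_compounds = 30),
               class = "tp53_config_error")
  expect_error(generator_config(censor_window_months = c(5, 2)),
               class = "tp53_config_error")
})

test_that("generated mutation records reproduce the annotated TP53 groups", {
  co <- generate_cohort(generator_config(n_types = 2, genes = 100,
                                         tumors_per_type = 40,
                                         normals_per_type = 6,
                                         n_planted_mw = 10,
                                         n_planted_wn = 10,
                                         n_planted_sl = 10,
                                         cis_block = 6,
                                         n_sl_compounds = 5,
                                         seed = 3))
  st <- classify_tp53_status(co$mutations)
  truth <- dplyr::filter(co$truth$status, tissue == "tumor")
  joined <- dplyr::inner_join(st, truth,
                              by = c("cancer_type", "sample_id"))
  expect_equal(nrow(joined), nrow(truth))
  expect_true(all(joined$tp53_status == joined$tp53_group))
  # silent-only samples exist and are classified wildtype
  silent_only <- co$mutations$records |>
    dplyr::group_by(sample_id) |>
    dplyr::filter(all(variant_class == "silent"),
                  gene_symbol == "TP53") |>
    dplyr::pull(sample_id)
  expect_gt(length(silent_only), 0)
})

test_that("planted effects land where declared, on average", {
  co <- generate_cohort(generator_config(n_types = 1, seed = 11))
  st <- co$studies[[1]]
  tr <- co$truth
  g <- sample_groups(st)
  gm <- function(genes, ids) mean(st$exprs[genes, ids])
  # SL genes: mutated - normal = effect; wildtype - normal = 0
  expect_equal(gm(tr$planted_sl, g$mutated) - gm(tr$planted_sl, g$normal),
               1, tolerance = 0.15)
  expect_equal(gm(tr$planted_sl, g$wildtype) -
                 gm(tr$planted_sl, g$normal), 0, tolerance = 0.15)
  # WN genes: elevated in all tumors equally
  expect_equal(gm(tr$planted_wn, g$tumor) - gm(tr$planted_wn, g$normal),
               1, tolerance = 0.15)
  expect_equal(gm(tr$planted_wn, g$mutated) -
                 gm(tr$planted_wn, g$wildtype), 0, tolerance = 0.15)
  # MW genes: mutated above wildtype, wildtype above normal
  expect_equal(gm(tr$planted_mw, g$mutated) -
                 gm(tr$planted_mw, g$wildtype), 1, tolerance = 0.15)
  expect_equal(gm(tr$planted_mw, g$wildtype) -
                 gm(tr$planted_mw, g$normal), 1, tolerance = 0.15)
  # truncating TP53 loss
  expect_equal(mean(st$exprs["TP53", g$truncating]) -
                 mean(st$exprs["TP53", g$wildtype]), -1.5,
               tolerance = 0.35)
  # cis block correlates with TP53 in tumors, not in normals
  r_tum <- cor(t(st$exprs[tr$cis_genes, g$tumor]),
               st$exprs["TP53", g$tumor])
  expect_gt(mean(r_tum), 0.4)
  r_nor <- cor(t(st$exprs[tr$cis_genes, g$normal]),
               st$exprs["TP53", g$normal])
  expect_lt(abs(mean(r_nor)), 0.2)
})

test_that("a null configuration plants no detectable classes", {
  co <- generate_cohort(generator_config(n_types = 1, effect_log2 = 0,
                                         seed = 19))
  cls <- derive_gene_classes(co$studies[[1]])
  planted <- c(co$truth$planted_mw, co$truth$planted_wn,
               co$truth$planted_sl)
  hits <- sum(vapply(cls$sets, function(s)
    length(intersect(s, planted)), integer(1)))
  expect_equal(hits, 0)
})

test_that("generate_pharmaco shifts exactly the SL compounds and maps targets", {
  cfg <- generator_config(n_types = 1, seed = 5)
  co <- generate_cohort(cfg)
  ph <- generate_pharmaco(cfg, co$truth)
  scr <- ph$screen
  expect_equal(length(ph$sl_compounds), cfg$n_sl_compounds)
  # each SL compound targets exactly one planted SL gene
  tg <- dplyr::filter(scr$targets, compound %in% ph$sl_compounds)
  expect_equal(nrow(tg), cfg$n_sl_compounds)
  expect_true(all(tg$gene %in% co$truth$planted_sl))
  expect_equal(anyDuplicated(tg$gene), 0L)
  # decoy compounds target genes outside every planted set
  decoy <- dplyr::filter(scr$targets, !compound %in% ph$sl_compounds)
  planted <- c(co$truth$planted_mw, co$truth$planted_wn,
               co$truth$planted_sl, co$truth$cis_genes, "TP53")
  expect_false(any(decoy$gene %in% planted))
  # the planted shift moves mutated-line means by about ic50_shift
  mut <- scr$status$cell_line[scr$status$tp53_status == "mutated"]
  wt <- scr$status$cell_line[scr$status$tp53_status == "wildtype"]
  d <- mean(scr$ic50[mut, ph$sl_compounds]) -
    mean(scr$ic50[wt, ph$sl_compounds])
  expect_equal(d, cfg$ic50_shift, tolerance = 0.3)
  # determinism
  ph2 <- generate_pharmaco(cfg, co$truth)
  expect_identical(scr$ic50, ph2$screen$ic50)
})
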