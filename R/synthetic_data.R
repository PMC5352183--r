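# Synthetic multi-cancer cohort generator with fully known planted
# structure, so that every downstream stage can be tested without any
# external download.

#' Synthetic cohort generator configuration
#'
#' Parameters of the planted-structure generator. Expression is Gaussian
#' on the log2 scale (log-normal on the linear scale) with per-gene
#' baselines drawn from Uniform(3, 12) and common noise `sigma_log2`.
#' Planted gene sets (disjoint by construction):
#' * `planted_mw` — elevated by `effect_log2` in all tumors and by a
#'   further `effect_log2` in TP53-mutated tumors, so they satisfy the
#'   mutated-vs-wildtype (MW) contrast while remaining part of the
#'   wildtype-vs-normal (WN/WN2) signal;
#' * `planted_wn` — elevated by `effect_log2` in all tumors vs normals;
#' * `planted_sl` — elevated by `effect_log2` in TP53-mutated tumors
#'   *only*, so they satisfy MN but not WN2 (the synthetic-lethality
#'   signature);
#' * `cis_block` — genes sharing a tumor-only latent factor with TP53 at
#'   loading `cis_loading` (co-expression signal).
#' TP53 expression is shifted by `tp53_trunc_shift_log2` in samples
#' carrying truncating mutations. Survival is exponential with baseline
#' median `surv_median_months` and hazard multiplied by
#' `hazard_ratio_mutated` for mutated patients, censored uniformly over
#' `censor_window_months`. Clinical phenotypes are drawn independently of
#' mutation status unless `planted_stage_or` differs from 1.
#'
#' @param n_types Number of cancer types. Default 3.
#' @param genes Genes per study (including TP53). Default 1000.
#' @param tumors_per_type,normals_per_type Samples per type. Defaults
#'   100 and 30.
#' @param mutated_fraction Fraction of tumors with a non-silent TP53
#'   mutation. Default 0.5.
#' @param truncating_fraction_of_mutated Fraction of mutated tumors with
#'   a truncating mutation. Default 0.4.
#' @param effect_log2 Planted log2 effect size. Default 1.
#' @param tp53_trunc_shift_log2 TP53 log2 shift in truncating samples.
#'   Default -1.5.
#' @param sigma_log2 Residual standard deviation on the log2 scale.
#'   Default 1.
#' @param n_planted_mw,n_planted_wn,n_planted_sl Planted set sizes.
#'   Defaults 50 each.
#' @param cis_block Number of TP53 cis-co-expressed genes. Default 30.
#' @param cis_loading Latent-factor loading shared by TP53 and the cis
#'   block in tumors. Default 0.8.
#' @param silent_rate Fraction of non-mutated tumors receiving a silent
#'   TP53 record (exercises the silent-as-wildtype rule). Default 0.03.
#' @param background_genes,background_rate Decoy mutation-only genes and
#'   their per-sample mutation probability (exercise gene ranking).
#'   Defaults 5 and 0.1.
#' @param surv_median_months Baseline survival median. Default 24.
#' @param hazard_ratio_mutated Hazard ratio of mutated patients.
#'   Default 2.
#' @param censor_window_months Length-2 censoring window. Default
#'   `c(12, 60)`.
#' @param planted_stage_or Odds ratio of late stage for mutated patients
#'   (1 = null association). Default 1.
#' @param n_cell_lines,n_compounds,n_sl_compounds Pharmacogenomic screen
#'   sizes. Defaults 100, 20, 5.
#' @param ic50_shift Log IC50 shift in mutated lines for compounds
#'   targeting planted SL genes. Default -1.
#' @param seed Integer seed; generation is deterministic given the
#'   configuration. Default 1.
#' @return A list of class `tp53_generator_config`.
#' @export
generator_config <- function(n_types = 3, genes = 1000,
                             tumors_per_type = 100,
                             mutated_fraction = 0.5,
                             truncating_fraction_of_mutated = 0.4,
                             normals_per_type = 30,
                             effect_log2 = 1.0,
                             tp53_trunc_shift_log2 = -1.5,
                             sigma_log2 = 1.0,
                             n_planted_mw = 50, n_planted_wn = 50,
                             n_planted_sl = 50,
                             cis_block = 30, cis_loading = 0.8,
                             silent_rate = 0.03,
                             background_genes = 5,
                             background_rate = 0.1,
                             surv_median_months = 24,
                             hazard_ratio_mutated = 2.0,
                             censor_window_months = c(12, 60),
                             planted_stage_or = 1.0,
                             n_cell_lines = 100, n_compounds = 20,
                             n_sl_compounds = 5, ic50_shift = -1.0,
                             seed = 1L) {
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  n_planted <- 1 + n_planted_mw + n_planted_wn + n_planted_sl + cis_block
  if (n_planted > genes) {
    abort(sprintf(
      "planted sets (%d genes incl. TP53) exceed gene count (%d)",
      n_planted, genes), class = "tp53_config_error")
  }
  if (n_sl_compounds > n_compounds) {
    abort("n_sl_compounds exceeds n_compounds",
          class = "tp53_config_error")
  }
  if (n_sl_compounds > n_planted_sl) {
    abort("n_sl_compounds exceeds the number of planted SL genes",
          class = "tp53_config_error")
  }
  if (mutated_fraction <= 0 || mutated_fraction >= 1 ||
      truncating_fraction_of_mutated < 0 ||
      truncating_fraction_of_mutated > 1) {
    abort("fractions out of range", class = "tp53_config_error")
  }
  if (length(censor_window_months) != 2 ||
      censor_window_months[1] <= 0 ||
      censor_window_months[2] <= censor_window_months[1]) {
    abort("censor_window_months must be an increasing positive pair",
          class = "tp53_config_error")
  }
  structure(cfg, class = "tp53_generator_config")
}

# class mixtures used to draw a variant class given forced status;
# relative weights follow the observed predominance of missense among
# non-truncating and nonsense/frame-shift among truncating mutations
trunc_class_weights <- c(nonsense = 0.41, frame_shift_del = 0.26,
                         frame_shift_ins = 0.13, splice_site = 0.20)
nontrunc_class_weights <- c(missense = 0.92, in_frame_del = 0.05,
                            in_frame_ins = 0.03)

#' Generate a synthetic multi-cancer cohort
#'
#' Draws expression studies, mutation records, clinical phenotypes and
#' survival endpoints for `n_types` cancer types, with the planted
#' structure described in [generator_config()], and returns the ground
#' truth alongside. Deterministic for a fixed configuration (the global
#' RNG state is restored on exit).
#'
#' @param cfg A [generator_config()].
#' @return A list of class `tp53_cohort` with elements `mutations`
#'   ([mutation_table()]), `studies` (named list of
#'   [expression_study()]), `clinical` (tibble), `survival` (tibble with
#'   `patient_id`, `cancer_type`, `endpoint`, `time`, `event`) and
#'   `truth` (planted sets, per-sample status, and `mw_truth` — the genes
#'   with a true mutated-vs-wildtype effect, i.e. planted MW plus planted
#'   SL genes).
#' @export
generate_cohort <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "tp53_generator_config"))
  withr::with_seed(cfg$seed, generate_cohort_impl(cfg))
}

generate_cohort_impl <- function(cfg) {
  gene_ids <- c("TP53",
                sprintf("G%04d", seq_len(cfg$genes - 1)))
  idx <- 2L
  take <- function(n) {
    out <- gene_ids[seq.int(idx, length.out = n)]
    idx <<- idx + n
    out
  }
  planted_mw <- take(cfg$n_planted_mw)
  planted_wn <- take(cfg$n_planted_wn)
  planted_sl <- take(cfg$n_planted_sl)
  cis_genes <- take(cfg$cis_block)

  types <- sprintf("T%02d", seq_len(cfg$n_types))
  mu <- runif(cfg$genes, 3, 12)
  names(mu) <- gene_ids
  mu["TP53"] <- runif(1, 7, 9)  # keep the anchor well away from zero

  studies <- list()
  status_all <- list()
  records_all <- list()
  universe_all <- list()
  clinical_all <- list()
  survival_all <- list()

  for (ct in types) {
    n_t <- cfg$tumors_per_type
    n_n <- cfg$normals_per_type
    tumor_ids <- sprintf("%s_T%03d", ct, seq_len(n_t))
    normal_ids <- sprintf("%s_N%03d", ct, seq_len(n_n))
    n_mut <- round(cfg$mutated_fraction * n_t)
    n_trunc <- round(cfg$truncating_fraction_of_mutated * n_mut)
    mut_ids <- sample(tumor_ids, n_mut)
    trunc_ids <- sample(mut_ids, n_trunc)
    nontrunc_ids <- setdiff(mut_ids, trunc_ids)
    wt_ids <- setdiff(tumor_ids, mut_ids)

    grp <- setNames(rep("wildtype", n_t), tumor_ids)
    grp[trunc_ids] <- "truncating"
    grp[nontrunc_ids] <- "non_truncating"

    samples <- c(tumor_ids, normal_ids)
    E <- matrix(rnorm(cfg$genes * length(samples), sd = cfg$sigma_log2),
                nrow = cfg$genes,
                dimnames = list(gene_ids, samples)) + mu

    is_tumor <- samples %in% tumor_ids
    is_mut <- samples %in% mut_ids
    E[planted_mw, is_tumor] <- E[planted_mw, is_tumor] + cfg$effect_log2
    E[planted_mw, is_mut] <- E[planted_mw, is_mut] + cfg$effect_log2
    E[planted_wn, is_tumor] <- E[planted_wn, is_tumor] + cfg$effect_log2
    E[planted_sl, is_mut] <- E[planted_sl, is_mut] + cfg$effect_log2

    # tumor-only latent factor shared by TP53 and the cis block: replace
    # part of the residual so the marginal variance stays sigma^2
    z <- rnorm(sum(is_tumor))
    lam <- cfg$cis_loading
    factor_rows <- c("TP53", cis_genes)
    resid <- matrix(rnorm(length(factor_rows) * sum(is_tumor),
                          sd = cfg$sigma_log2),
                    nrow = length(factor_rows))
    E[factor_rows, is_tumor] <-
      mu[factor_rows] + cfg$sigma_log2 * lam * rep(z, each =
                                                     length(factor_rows)) +
      sqrt(1 - lam^2) * resid
    E["TP53", samples %in% trunc_ids] <-
      E["TP53", samples %in% trunc_ids] + cfg$tp53_trunc_shift_log2

    meta <- tibble(
      sample_id = samples,
      tissue = ifelse(is_tumor, "tumor", "normal"),
      tp53_group = ifelse(is_tumor, unname(grp[samples]),
                          "not_applicable"))
    studies[[ct]] <- expression_study(ct, E, meta)

    draw_class <- function(ids, weights) {
      if (length(ids) == 0) return(tibble())
      tibble(sample_id = ids, cancer_type = ct, gene_symbol = "TP53",
             variant_class = sample(names(weights), length(ids),
                                    replace = TRUE, prob = weights))
    }
    rec <- bind_rows(
      draw_class(trunc_ids, trunc_class_weights),
      draw_class(nontrunc_ids, nontrunc_class_weights))
    n_silent <- round(cfg$silent_rate * length(wt_ids))
    if (n_silent > 0) {
      rec <- bind_rows(rec, tibble(
        sample_id = sample(wt_ids, n_silent), cancer_type = ct,
        gene_symbol = "TP53", variant_class = "silent"))
    }
    if (cfg$background_genes > 0) {
      for (bg in sprintf("BG%02d", seq_len(cfg$background_genes))) {
        hit <- tumor_ids[runif(n_t) < cfg$background_rate]
        if (length(hit) > 0) {
          rec <- bind_rows(rec, tibble(
            sample_id = hit, cancer_type = ct, gene_symbol = bg,
            variant_class = sample(variant_classes(), length(hit),
                                   replace = TRUE,
                                   prob = c(0.62, 0.14, 0.09, 0.04,
                                            0.01, 0.01, 0.02, 0.07))))
        }
      }
    }
    records_all[[ct]] <- rec
    universe_all[[ct]] <- tibble(cancer_type = ct, sample_id = tumor_ids)
    status_all[[ct]] <- tibble(cancer_type = ct, sample_id = samples,
                               tissue = meta$tissue,
                               tp53_group = meta$tp53_group)

    clinical_all[[ct]] <- generate_clinical(ct, tumor_ids,
                                            tumor_ids %in% mut_ids, cfg)
    survival_all[[ct]] <- generate_survival(ct, tumor_ids,
                                            tumor_ids %in% mut_ids, cfg)
  }

  truth <- list(
    planted_mw = planted_mw, planted_wn = planted_wn,
    planted_sl = planted_sl, cis_genes = cis_genes,
    mw_truth = c(planted_mw, planted_sl),
    status = bind_rows(status_all))
  structure(list(
    mutations = mutation_table(bind_rows(records_all),
                               bind_rows(universe_all)),
    studies = studies,
    clinical = bind_rows(clinical_all),
    survival = bind_rows(survival_all),
    truth = truth, config = cfg),
    class = "tp53_cohort")
}

generate_clinical <- function(ct, ids, mutated, cfg) {
  n <- length(ids)
  p_late <- 0.4
  odds <- p_late / (1 - p_late) *
    ifelse(mutated, cfg$planted_stage_or, 1)
  late <- runif(n) < odds / (1 + odds)
  stage <- ifelse(late,
                  sample(c("III", "IV"), n, replace = TRUE),
                  sample(c("I", "II"), n, replace = TRUE))
  tibble(
    sample_id = ids, patient_id = ids, cancer_type = ct,
    gender = sample(c("male", "female"), n, replace = TRUE),
    race = sample(c("african_american", "white_american"), n,
                  replace = TRUE, prob = c(0.3, 0.7)),
    stage = stage,
    t_stage = sample(c("T1", "T2", "T3", "T4"), n, replace = TRUE),
    n_stage = sample(c("N0", "N1", "N2"), n, replace = TRUE,
                     prob = c(0.5, 0.3, 0.2)),
    m_stage = sample(c("M0", "M1"), n, replace = TRUE,
                     prob = c(0.85, 0.15)))
}

generate_survival <- function(ct, ids, mutated, cfg) {
  n <- length(ids)
  h0 <- log(2) / cfg$surv_median_months
  purrr::map_dfr(c("OS", "DFS"), function(ep) {
    h <- h0 * ifelse(mutated, cfg$hazard_ratio_mutated, 1)
    t_event <- rexp(n, rate = h)
    t_cens <- runif(n, cfg$censor_window_months[1],
                    cfg$censor_window_months[2])
    tibble(patient_id = ids, cancer_type = ct, endpoint = ep,
           time = pmin(t_event, t_cens),
           event = as.integer(t_event <= t_cens))
  })
}

#' @export
print.tp53_cohort <- function(x, ...) {
  cat(sprintf(
    "<tp53_cohort> %d cancer types, %d genes, seed %d\n",
    length(x$studies), x$config$genes, x$config$seed))
  invisible(x)
}

#' Generate a synthetic pharmacogenomic screen
#'
#' Log IC50 values are standard normal per line and compound. The first
#' `n_sl_compounds` compounds each target a distinct planted SL gene and
#' receive an `ic50_shift` in TP53-mutated lines; the remaining compounds
#' target decoy genes outside all planted sets and carry no shift.
#'
#' @param cfg A [generator_config()].
#' @param truth Ground truth from [generate_cohort()] (the `truth`
#'   element).
#' @return List of class `tp53_pharmaco`: `screen`
#'   ([pharmaco_screen()]) and `sl_compounds` (character vector of the
#'   shifted compounds).
#' @export
generate_pharmaco <- function(cfg, truth) {
  stopifnot(inherits(cfg, "tp53_generator_config"))
  withr::with_seed(cfg$seed + 1000003L, {
    lines <- sprintf("CL%03d", seq_len(cfg$n_cell_lines))
    n_mut <- round(cfg$mutated_fraction * cfg$n_cell_lines)
    status <- tibble(
      cell_line = lines,
      tp53_status = ifelse(seq_along(lines) <= n_mut, "mutated",
                           "wildtype"))
    compounds <- sprintf("CP%02d", seq_len(cfg$n_compounds))
    sl_compounds <- compounds[seq_len(cfg$n_sl_compounds)]
    ic50 <- matrix(rnorm(cfg$n_cell_lines * cfg$n_compounds),
                   nrow = cfg$n_cell_lines,
                   dimnames = list(lines, compounds))
    mut_lines <- status$tp53_status == "mutated"
    ic50[mut_lines, sl_compounds] <-
      ic50[mut_lines, sl_compounds] + cfg$ic50_shift
    sl_targets <- truth$planted_sl[seq_len(cfg$n_sl_compounds)]
    planted <- c("TP53", truth$planted_mw, truth$planted_wn,
                 truth$planted_sl, truth$cis_genes)
    decoy_pool <- setdiff(sprintf("G%04d", seq_len(cfg$genes - 1)),
                          planted)
    n_decoy <- cfg$n_compounds - cfg$n_sl_compounds
    decoys <- sample(decoy_pool, n_decoy)
    targets <- tibble(compound = compounds,
                      gene = c(sl_targets, decoys))
    list_out <- list(
      screen = pharmaco_screen(ic50, status, targets, is_log = TRUE),
      sl_compounds = sl_compounds)
    structure(list_out, class = "tp53_pharmaco")
  })
}
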