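# Mutation-rate profiling, variant-class proportions, TP53 sample-status
# classification, and clinical-phenotype association.

#' Per-cancer-type mutation rate of a gene
#'
#' Fraction of sequenced samples of a cancer type carrying at least one
#' mutation record for the gene. Silent records are excluded by default:
#' downstream expression analyses define "mutated" as carrying a
#' non-silent (functionally significant) mutation, and the rate uses the
#' same reading. Set `include_silent = TRUE` for the alternative.
#'
#' @param muts A [mutation_table()].
#' @param gene Gene symbol. Default `"TP53"`.
#' @param cancer_type Cancer-type label present in the sample universe.
#' @param include_silent Count samples whose only records are silent.
#' @return A proportion in `[0, 1]`.
#' @export
mutation_rate <- function(muts, gene = "TP53", cancer_type,
                          include_silent = FALSE) {
  stopifnot(inherits(muts, "mutation_table"))
  uni <- muts$sample_universe
  if (!cancer_type %in% uni$cancer_type) {
    abort(paste0("unknown cancer type: ", cancer_type),
          class = "tp53_validation_error")
  }
  denom <- sum(uni$cancer_type == cancer_type)
  rec <- muts$records
  keep <- rec$cancer_type == cancer_type & rec$gene_symbol == gene
  if (!include_silent) keep <- keep & rec$variant_class != "silent"
  length(unique(rec$sample_id[keep])) / denom
}

#' Mutation rates of one gene across all cancer types
#'
#' @inheritParams mutation_rate
#' @return Tibble (`cancer_type`, `n_samples`, `n_mutated`, `rate`,
#'   `percent`) sorted by decreasing rate; `percent` is rounded to one
#'   decimal as conventionally reported.
#' @export
mutation_rates <- function(muts, gene = "TP53", include_silent = FALSE) {
  types <- sort(unique(muts$sample_universe$cancer_type))
  out <- purrr::map_dfr(types, function(ct) {
    r <- mutation_rate(muts, gene, ct, include_silent)
    tibble(cancer_type = ct,
           n_samples = sum(muts$sample_universe$cancer_type == ct),
           n_mutated = as.integer(round(
             r * sum(muts$sample_universe$cancer_type == ct))),
           rate = r,
           percent = round(100 * r, 1))
  })
  arrange(out, desc(.data$rate), .data$cancer_type)
}

#' Rank of a gene's mutation rate within a cancer type
#'
#' Rank 1 is the highest rate among all genes with at least one record in
#' the cancer type; ties share the minimum rank. Extremely long genes that
#' dominate rankings (e.g. TTN) can be excluded via `exclude`.
#'
#' @inheritParams mutation_rate
#' @param exclude Character vector of gene symbols removed before ranking.
#' @return Integer rank, or `NA` (with a warning) if the gene has no
#'   records in the cancer type.
#' @export
rank_gene <- function(muts, gene = "TP53", cancer_type,
                      exclude = character(), include_silent = FALSE) {
  stopifnot(inherits(muts, "mutation_table"))
  rec <- filter(muts$records, .data$cancer_type == !!cancer_type)
  if (!include_silent) rec <- filter(rec, .data$variant_class != "silent")
  rec <- filter(rec, !.data$gene_symbol %in% exclude)
  if (!gene %in% rec$gene_symbol) {
    warn(paste0("gene ", gene, " has no qualifying records in ",
                cancer_type, "; rank undefined"))
    return(NA_integer_)
  }
  rates <- rec |>
    distinct(.data$gene_symbol, .data$sample_id) |>
    dplyr::count(.data$gene_symbol, name = "n_mut")
  # min-rank over descending rate; denominators are shared so counts rank
  rates$rank <- rank(-rates$n_mut, ties.method = "min")
  as.integer(rates$rank[rates$gene_symbol == gene])
}

#' Variant-class proportions for a gene
#'
#' Proportion of each of the eight variant classes among the gene's
#' mutation *records* (not samples), within one cancer type or across all.
#'
#' @inheritParams mutation_rate
#' @param cancer_type Cancer type to restrict to, or `NULL` for all.
#' @return Tibble (`variant_class`, `n`, `proportion`) covering all eight
#'   classes; proportions sum to 1.
#' @export
class_proportions <- function(muts, gene = "TP53", cancer_type = NULL) {
  rec <- filter(muts$records, .data$gene_symbol == gene)
  if (!is.null(cancer_type)) {
    rec <- filter(rec, .data$cancer_type == !!cancer_type)
  }
  if (nrow(rec) == 0) {
    abort("no mutation records for gene in scope",
          class = "tp53_validation_error")
  }
  counts <- table(factor(rec$variant_class, levels = variant_classes()))
  tibble(variant_class = variant_classes(),
         n = as.integer(counts),
         proportion = as.numeric(counts) / nrow(rec))
}

#' TP53 status of every sample
#'
#' Classifies each sample of the universe as `truncating` (carries at
#' least one nonsense, frame-shift or splice-site record), else
#' `non_truncating` (carries a missense or in-frame record), else
#' `wildtype`. A sample with both truncating and non-truncating records is
#' `truncating` (truncation dominates the expression phenotype). Samples
#' whose only records are silent are treated as wildtype.
#'
#' @inheritParams mutation_rate
#' @return Tibble (`cancer_type`, `sample_id`, `tp53_status`).
#' @export
classify_tp53_status <- function(muts, gene = "TP53") {
  rec <- filter(muts$records, .data$gene_symbol == gene)
  status <- rec |>
    group_by(.data$cancer_type, .data$sample_id) |>
    summarise(
      tp53_status = dplyr::case_when(
        any(.data$variant_class %in% truncating_classes()) ~ "truncating",
        any(.data$variant_class %in% non_truncating_classes()) ~
          "non_truncating",
        TRUE ~ "wildtype"  # silent-only
      ),
      .groups = "drop")
  muts$sample_universe |>
    left_join(status, by = c("cancer_type", "sample_id")) |>
    mutate(tp53_status = dplyr::coalesce(.data$tp53_status, "wildtype"))
}

#' Clinical phenotype binning
#'
#' Defines a two-class binning of a clinical variable. Records whose value
#' falls outside both label sets (including missing values) are excluded
#' from the association test.
#'
#' @param phenotype Column name in the clinical table.
#' @param class_1,class_2 Disjoint character vectors of values forming the
#'   two classes.
#' @param labels Length-2 display labels. Defaults to the class value
#'   lists collapsed with "/".
#' @return An object of class `phenotype_binning`.
#' @export
phenotype_binning <- function(phenotype, class_1, class_2,
                              labels = NULL) {
  if (length(intersect(class_1, class_2)) > 0) {
    abort("binning classes must be disjoint", class = "tp53_config_error")
  }
  labels <- labels %||% c(paste(class_1, collapse = "/"),
                          paste(class_2, collapse = "/"))
  structure(list(phenotype = phenotype, class_1 = class_1,
                 class_2 = class_2, labels = labels),
            class = "phenotype_binning")
}

#' Standard clinical binnings
#'
#' The conventional two-class clinical contrasts: gender (male vs
#' female), race (African-American vs White-American), stage (I-II vs
#' III-IV), tumor size (T1-2 vs T3-4), lymph nodes (N0 vs N1-3) and
#' metastasis (M0 vs M1).
#'
#' @return Named list of [phenotype_binning()] objects.
#' @export
standard_binnings <- function() {
  list(
    gender = phenotype_binning("gender", "male", "female"),
    race = phenotype_binning("race", "african_american", "white_american"),
    stage = phenotype_binning("stage", c("I", "II"), c("III", "IV"),
                              labels = c("early", "late")),
    t_stage = phenotype_binning("t_stage", c("T1", "T2"), c("T3", "T4"),
                                labels = c("small", "large")),
    n_stage = phenotype_binning("n_stage", "N0", c("N1", "N2", "N3"),
                                labels = c("node_negative",
                                           "node_positive")),
    m_stage = phenotype_binning("m_stage", "M0", "M1",
                                labels = c("no_metastasis", "metastasis"))
  )
}

#' Association between TP53 mutation status and a clinical phenotype
#'
#' Builds the 2x2 table of binned phenotype class by TP53 status
#' (non-silent mutated vs wildtype) within one cancer type and applies
#' Fisher's exact test. Samples with missing or out-of-binning phenotype
#' values are excluded; an empty binned class yields a skipped result
#' rather than a test.
#'
#' @param muts A [mutation_table()].
#' @param clinical Tibble with `sample_id` and the binning's phenotype
#'   column.
#' @param binning A [phenotype_binning()].
#' @param cancer_type Cancer type to analyse.
#' @param gene Gene symbol. Default `"TP53"`.
#' @return List of class `tp53_phenotype_assoc`: `table` (2x2 counts),
#'   `result` (one-row test tibble or `NULL`), `skipped`, `reason`.
#' @export
phenotype_association <- function(muts, clinical, binning, cancer_type,
                                  gene = "TP53") {
  stopifnot(inherits(binning, "phenotype_binning"))
  status <- classify_tp53_status(muts, gene) |>
    filter(.data$cancer_type == !!cancer_type) |>
    mutate(mutated = .data$tp53_status != "wildtype")
  df <- inner_join(status, as_tibble(clinical), by = "sample_id")
  vals <- df[[binning$phenotype]]
  cls <- ifelse(vals %in% binning$class_1, binning$labels[1],
                ifelse(vals %in% binning$class_2, binning$labels[2], NA))
  df <- df[!is.na(cls), ]
  cls <- cls[!is.na(cls)]
  counts <- c(
    a = sum(cls == binning$labels[1] & df$mutated),
    b = sum(cls == binning$labels[1] & !df$mutated),
    c_ = sum(cls == binning$labels[2] & df$mutated),
    d = sum(cls == binning$labels[2] & !df$mutated)
  )
  tab <- matrix(counts, nrow = 2, byrow = TRUE,
                dimnames = list(binning$labels, c("mutated", "wildtype")))
  if (sum(tab[1, ]) == 0 || sum(tab[2, ]) == 0) {
    return(structure(list(table = tab, result = NULL, skipped = TRUE,
                          reason = "degenerate phenotype: empty class"),
                     class = "tp53_phenotype_assoc"))
  }
  res <- fisher_exact(counts[["a"]], counts[["b"]], counts[["c_"]],
                      counts[["d"]])
  structure(list(table = tab, result = res, skipped = FALSE,
                 reason = NA_character_),
            class = "tp53_phenotype_assoc")
}

#' @export
print.tp53_phenotype_assoc <- function(x, ...) {
  cat("<tp53_phenotype_assoc>\n")
  print(x$table)
  if (x$skipped) cat("skipped:", x$reason, "\n")
  else cat(sprintf("Fisher p = %.4g, odds ratio = %.3g\n",
                   x$result$p_value, x$result$effect))
  invisible(x)
}

#' @export
tidy.tp53_phenotype_assoc <- function(x, ...) {
  if (x$skipped) {
    return(tibble(p_value = NA_real_, odds_ratio = NA_real_,
                  skipped = TRUE, reason = x$reason))
  }
  tibble(p_value = x$result$p_value, odds_ratio = x$result$effect,
         skipped = FALSE, reason = NA_character_)
}
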