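# The gene-class calculus: per-comparison differential expression,
# derivation of the MW/WN/WN2/MN/MWN/MSN sets, recurrence filtering,
# TP53 group comparisons and expression-pattern calls.

#' Differential expression between two sample groups
#'
#' Per-gene pooled-variance t-test on log2 values between two disjoint
#' sample groups of one study. Fold change is computed as
#' `2^(mean_log2(a) - mean_log2(b))` — the ratio of geometric means, the
#' self-consistent choice for log2-stored data (set `linear_fc` in the
#' configuration for arithmetic-mean ratios on the linear scale). The
#' passing set is one-sided by construction: genes with
#' `q < fdr_de` *and* `fold_change > fc_threshold` (group a over group b).
#'
#' @param study An [expression_study()].
#' @param group_a,group_b Group label (see [sample_groups()]) or explicit
#'   sample-id vectors. Must be disjoint.
#' @param fc_threshold Fold-change threshold; defaults to
#'   `cfg$fc_primary`.
#' @param cfg A [run_config()].
#' @return A tibble of class `tp53_de` with per-gene `mean_a`, `mean_b`,
#'   `log2_fc`, `fold_change`, `statistic`, `p_value`, `q_value`,
#'   `passing`; or a `tp53_de_skipped` object when a group is smaller
#'   than the configured minimum (`min_group` for tumor groups,
#'   `min_normals` for the normal group).
#' @export
diff_expr <- function(study, group_a, group_b, fc_threshold = NULL,
                      cfg = run_config()) {
  stopifnot(inherits(study, "expression_study"))
  fc_threshold <- fc_threshold %||% cfg$fc_primary
  label_a <- if (length(group_a) == 1) group_a else "custom"
  label_b <- if (length(group_b) == 1) group_b else "custom"
  ids_a <- resolve_group(study, group_a)
  ids_b <- resolve_group(study, group_b)
  if (length(intersect(ids_a, ids_b)) > 0) {
    abort("comparison groups must be disjoint",
          class = "tp53_validation_error")
  }
  min_a <- if (identical(label_a, "normal")) cfg$min_normals else
    cfg$min_group
  min_b <- if (identical(label_b, "normal")) cfg$min_normals else
    cfg$min_group
  if (length(ids_a) < min_a || length(ids_b) < min_b) {
    return(de_skipped(study$cancer_type, label_a, label_b, sprintf(
      "group sizes %d vs %d below required %d vs %d",
      length(ids_a), length(ids_b), min_a, min_b)))
  }
  tt <- row_t_pooled(study$exprs[, ids_a, drop = FALSE],
                     study$exprs[, ids_b, drop = FALSE],
                     welch = cfg$welch)
  log2_fc <- if (cfg$linear_fc) {
    log2(rowMeans(2^study$exprs[, ids_a, drop = FALSE]) /
           rowMeans(2^study$exprs[, ids_b, drop = FALSE]))
  } else {
    tt$mean_a - tt$mean_b
  }
  out <- tibble(
    gene = rownames(study$exprs),
    mean_a = tt$mean_a, mean_b = tt$mean_b,
    log2_fc = log2_fc, fold_change = 2^log2_fc,
    statistic = tt$statistic, p_value = tt$p_value,
    q_value = bh_fdr(tt$p_value)
  )
  out$passing <- out$q_value < cfg$fdr_de & out$fold_change > fc_threshold
  structure(out,
            class = c("tp53_de", class(out)),
            cancer_type = study$cancer_type,
            group_a = label_a, group_b = label_b,
            n_a = length(ids_a), n_b = length(ids_b),
            fc_threshold = fc_threshold, fdr = cfg$fdr_de)
}

de_skipped <- function(cancer_type, group_a, group_b, reason) {
  structure(list(cancer_type = cancer_type, group_a = group_a,
                 group_b = group_b, reason = reason),
            class = "tp53_de_skipped")
}

#' @export
print.tp53_de_skipped <- function(x, ...) {
  cat(sprintf("<tp53_de_skipped> %s: %s vs %s — %s\n", x$cancer_type,
              x$group_a, x$group_b, x$reason))
  invisible(x)
}

#' Genes passing a differential-expression comparison
#'
#' @param de A `tp53_de` result (or skipped marker, giving an empty set).
#' @return Character vector of gene symbols.
#' @export
passing_genes <- function(de) {
  if (inherits(de, "tp53_de_skipped")) return(character(0))
  de$gene[de$passing]
}

#' @export
glance.tp53_de <- function(x, ...) {
  tibble(cancer_type = attr(x, "cancer_type"),
         group_a = attr(x, "group_a"), group_b = attr(x, "group_b"),
         n_a = attr(x, "n_a"), n_b = attr(x, "n_b"),
         fc_threshold = attr(x, "fc_threshold"), fdr = attr(x, "fdr"),
         n_genes = nrow(x), n_passing = sum(x$passing))
}

#' @export
tidy.tp53_de <- function(x, ...) as_tibble(x)

#' Derive the TP53 gene-class sets for one cancer type
#'
#' Runs the four underlying comparisons and assembles the named sets:
#' * `MW`  — mutated tumor vs wildtype tumor, fold change > `fc_primary`
#' * `WN`  — wildtype tumor vs normal, fold change > `fc_primary`
#' * `WN2` — wildtype tumor vs normal, fold change > `fc_secondary`
#' * `MN`  — mutated tumor vs normal, fold change > `fc_primary`
#' * `MWN` = `MW` intersect `WN` (mutated > wildtype > normal pattern)
#' * `MSN` = `MN` minus `WN2` (elevated specifically in mutated tumors)
#'
#' All comparisons use FDR < `fdr_de`. When fewer than `min_normals`
#' normal samples are available, the normal-based sets are empty with a
#' recorded reason while `MW` is still computed; when the mutated (or
#' wildtype) tumor group is below `min_group`, the affected comparisons
#' are skipped likewise.
#'
#' @param study An [expression_study()].
#' @param cfg A [run_config()].
#' @return An object of class `gene_class_sets`: `cancer_type`, `sets`
#'   (named list of gene vectors), `de` (the underlying `tp53_de`
#'   results), `skipped` (named reasons), `config`.
#' @export
derive_gene_classes <- function(study, cfg = run_config()) {
  de_mw <- diff_expr(study, "mutated", "wildtype", cfg$fc_primary, cfg)
  de_wn <- diff_expr(study, "wildtype", "normal", cfg$fc_primary, cfg)
  de_mn <- diff_expr(study, "mutated", "normal", cfg$fc_primary, cfg)

  skipped <- list()
  mw <- passing_genes(de_mw)
  if (inherits(de_mw, "tp53_de_skipped")) skipped$MW <- de_mw$reason
  if (inherits(de_wn, "tp53_de_skipped")) {
    wn <- wn2 <- character(0)
    skipped$WN <- skipped$WN2 <- de_wn$reason
  } else {
    wn <- passing_genes(de_wn)
    # same comparison, relaxed fold threshold
    wn2 <- de_wn$gene[de_wn$q_value < cfg$fdr_de &
                        de_wn$fold_change > cfg$fc_secondary]
  }
  if (inherits(de_mn, "tp53_de_skipped")) {
    mn <- character(0)
    skipped$MN <- de_mn$reason
  } else {
    mn <- passing_genes(de_mn)
  }
  sets <- list(MW = mw, WN = wn, WN2 = wn2, MN = mn,
               MWN = intersect(mw, wn), MSN = setdiff(mn, wn2))
  structure(list(cancer_type = study$cancer_type, sets = sets,
                 de = list(MW = de_mw, WN = de_wn, MN = de_mn),
                 skipped = skipped, config = cfg),
            class = "gene_class_sets")
}

#' @export
print.gene_class_sets <- function(x, ...) {
  cat(sprintf("<gene_class_sets> %s\n", x$cancer_type))
  for (nm in names(x$sets)) {
    cat(sprintf("  %-4s %5d gene(s)%s\n", nm, length(x$sets[[nm]]),
                if (nm %in% names(x$skipped))
                  paste0("  [", x$skipped[[nm]], "]") else ""))
  }
  invisible(x)
}

#' @export
tidy.gene_class_sets <- function(x, ...) {
  purrr::map_dfr(names(x$sets), function(nm) {
    tibble(cancer_type = x$cancer_type, class = nm,
           gene = x$sets[[nm]])
  })
}

#' @export
glance.gene_class_sets <- function(x, ...) {
  tibble(cancer_type = x$cancer_type,
         !!!setNames(lapply(x$sets, length), names(x$sets)))
}

#' Recurrence filter across cancer types
#'
#' Keeps genes that belong to a class in more cancer types than a stated
#' fraction of the types analysed (strict inequality), or — in absolute
#' mode — in at least `min_types` types.
#'
#' @param per_type_sets Named list (cancer type -> gene-symbol vector).
#' @param fraction Recurrence fraction (strict `>`). Default 0.25.
#' @param min_types If given, absolute mode: keep genes in at least this
#'   many types; `fraction` is ignored.
#' @return Tibble (`gene`, `n_types`, `kept`) sorted by descending
#'   recurrence then gene symbol.
#' @export
recurrence_filter <- function(per_type_sets, fraction = 0.25,
                              min_types = NULL) {
  if (length(per_type_sets) == 0) {
    abort("need at least one cancer type", class = "tp53_validation_error")
  }
  n_analyzed <- length(per_type_sets)
  counts <- table(unlist(lapply(per_type_sets, unique)))
  out <- tibble(gene = names(counts), n_types = as.integer(counts))
  out$kept <- if (!is.null(min_types)) {
    out$n_types >= min_types
  } else {
    out$n_types > fraction * n_analyzed
  }
  arrange(out, desc(.data$n_types), .data$gene)
}

#' Recurrent genes (convenience wrapper)
#'
#' @inheritParams recurrence_filter
#' @return Character vector of kept genes.
#' @export
recurrent_genes <- function(per_type_sets, fraction = 0.25,
                            min_types = NULL) {
  rf <- recurrence_filter(per_type_sets, fraction, min_types)
  rf$gene[rf$kept]
}

#' Compare TP53 expression between two status groups
#'
#' t-test on TP53 log2 expression between two of the four groups
#' (`truncating`, `non_truncating`, `wildtype`, `normal`, or the merged
#' `mutated`). The effect reported is the fold change of group a over
#' group b (ratio-of-means convention).
#'
#' @param study An [expression_study()].
#' @param group_a,group_b Group labels.
#' @param gene Gene whose expression is compared. Default `"TP53"`.
#' @param cfg A [run_config()].
#' @return A one-row test tibble with a `fold_change` column, or a
#'   `tp53_de_skipped` marker when a group has fewer than 2 samples.
#' @export
tp53_group_comparison <- function(study, group_a, group_b,
                                  gene = "TP53", cfg = run_config()) {
  if (!gene %in% rownames(study$exprs)) {
    abort(paste0(gene, " absent from expression matrix"),
          class = "tp53_validation_error")
  }
  ids_a <- resolve_group(study, group_a)
  ids_b <- resolve_group(study, group_b)
  if (length(ids_a) < 2 || length(ids_b) < 2) {
    return(de_skipped(study$cancer_type, group_a, group_b,
                      "fewer than 2 samples in a group"))
  }
  x <- study$exprs[gene, ids_a]
  y <- study$exprs[gene, ids_b]
  res <- two_sample_t(x, y, welch = cfg$welch)
  fc <- if (cfg$linear_fc) mean(2^x) / mean(2^y) else 2^(mean(x) - mean(y))
  res$fold_change <- fc
  res
}

#' TP53 expression pattern across status groups
#'
#' Orders the group means of TP53 expression (descending) and emits the
#' ordering as a pattern label only when every *adjacent* pair of groups
#' differs significantly (raw p < `p_tp53_expr`) in the observed
#' direction. Non-adjacent pairs are not required to differ. Absence of a
#' pattern is a valid result (`pattern = NA`).
#'
#' @param study An [expression_study()].
#' @param cfg A [run_config()].
#' @param groups Status groups to order. Defaults to the three tumor
#'   groups `non_truncating`, `wildtype`, `truncating`.
#' @param gene Gene analysed. Default `"TP53"`.
#' @return List of class `tp53_pattern`: `group_means` tibble, `pairwise`
#'   tibble of adjacent comparisons, `pattern` label or `NA`.
#' @export
tp53_pattern <- function(study, cfg = run_config(),
                         groups = c("non_truncating", "wildtype",
                                    "truncating"),
                         gene = "TP53") {
  if (!gene %in% rownames(study$exprs)) {
    abort(paste0(gene, " absent from expression matrix"),
          class = "tp53_validation_error")
  }
  grp_ids <- lapply(groups, resolve_group, study = study)
  names(grp_ids) <- groups
  sizes <- vapply(grp_ids, length, integer(1))
  if (any(sizes < 2)) {
    return(structure(list(
      cancer_type = study$cancer_type,
      group_means = tibble(group = groups, n = sizes, mean = NA_real_),
      pairwise = tibble(), pattern = NA_character_,
      reason = "group with fewer than 2 samples"),
      class = "tp53_pattern"))
  }
  means <- vapply(grp_ids, function(ids) mean(study$exprs[gene, ids]),
                  numeric(1))
  ord <- order(means, decreasing = TRUE)
  ordered_groups <- groups[ord]
  pairwise <- purrr::map_dfr(seq_len(length(ord) - 1), function(i) {
    ga <- ordered_groups[i]; gb <- ordered_groups[i + 1]
    res <- two_sample_t(study$exprs[gene, grp_ids[[ga]]],
                        study$exprs[gene, grp_ids[[gb]]],
                        welch = cfg$welch)
    tibble(higher = ga, lower = gb, mean_diff = res$effect,
           p_value = res$p_value,
           significant = res$p_value < cfg$p_tp53_expr &
             res$effect > 0)
  })
  pattern <- if (nrow(pairwise) > 0 && all(pairwise$significant)) {
    paste(ordered_groups, collapse = " > ")
  } else NA_character_
  structure(list(cancer_type = study$cancer_type,
                 group_means = tibble(group = groups, n = sizes,
                                      mean = means),
                 pairwise = pairwise, pattern = pattern,
                 reason = NA_character_),
            class = "tp53_pattern")
}

#' @export
print.tp53_pattern <- function(x, ...) {
  cat(sprintf("<tp53_pattern> %s: %s\n", x$cancer_type,
              if (is.na(x$pattern)) "no significant pattern" else
                x$pattern))
  print(x$group_means)
  invisible(x)
}
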