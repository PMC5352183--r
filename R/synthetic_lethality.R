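# Synthetic-lethality candidate derivation and pharmacogenomic (IC50)
# validation.

#' Pharmacogenomic screen container
#'
#' IC50 values per cell line and compound, the TP53 status of each line,
#' and the compound-to-target map.
#'
#' @param ic50 Numeric matrix, cell lines in rows, compounds in columns.
#'   Values are log-scale IC50s (public screens distribute natural-log
#'   IC50s); set `is_log = FALSE` to have a natural-log transform applied.
#' @param status Tibble (`cell_line`, `tp53_status` in
#'   `c("mutated", "wildtype")`) covering every line in the matrix.
#' @param targets Tibble (`compound`, `gene`) mapping compounds to their
#'   target genes; may be empty.
#' @param is_log Whether `ic50` is already log-scale. Default `TRUE`.
#' @return An object of class `pharmaco_screen`.
#' @export
pharmaco_screen <- function(ic50, status, targets = NULL,
                            is_log = TRUE) {
  stopifnot(is.matrix(ic50), is.numeric(ic50))
  status <- as_tibble(status)
  if (!all(c("cell_line", "tp53_status") %in% names(status))) {
    abort("status needs columns cell_line, tp53_status",
          class = "tp53_format_error")
  }
  if (!all(status$tp53_status %in% c("mutated", "wildtype"))) {
    abort("tp53_status must be 'mutated' or 'wildtype'",
          class = "tp53_format_error")
  }
  uncovered <- setdiff(rownames(ic50), status$cell_line)
  if (length(uncovered) > 0) {
    abort(paste0("cell line(s) without TP53 status: ",
                 paste(head(uncovered, 5), collapse = ", ")),
          class = "tp53_validation_error")
  }
  if (!is_log) ic50 <- log(ic50)
  targets <- if (is.null(targets)) {
    tibble(compound = character(0), gene = character(0))
  } else as_tibble(targets)
  structure(list(ic50 = ic50, status = status, targets = targets),
            class = "pharmaco_screen")
}

#' @export
print.pharmaco_screen <- function(x, ...) {
  cat(sprintf("<pharmaco_screen> %d cell lines x %d compounds (%d target mappings)\n",
              nrow(x$ic50), ncol(x$ic50), nrow(x$targets)))
  invisible(x)
}

#' Synthetic-lethality candidate genes
#'
#' Per cancer type, the candidates are the genes hyper-activated in
#' TP53-mutated tumors relative to *both* wildtype tumors and normal
#' tissue: the intersection `MW` with `MSN`. Cancer types without the
#' normal-based sets contribute no candidates. Results aggregate across
#' types with per-type provenance retained.
#'
#' @param classes_by_type Named list (cancer type ->
#'   [derive_gene_classes()] result or plain list of gene sets with
#'   elements `MW` and `MSN`).
#' @return A tibble of class `sl_candidates`: `gene`, `cancer_types`
#'   (comma-separated), `n_types`, ordered by descending `n_types` then
#'   gene.
#' @export
sl_candidates <- function(classes_by_type) {
  per_type <- lapply(classes_by_type, function(x) {
    sets <- if (inherits(x, "gene_class_sets")) x$sets else x
    intersect(sets$MW, sets$MSN)
  })
  long <- purrr::map_dfr(names(per_type), function(t) {
    tibble(cancer_type = t, gene = per_type[[t]])
  })
  if (nrow(long) == 0) {
    out <- tibble(gene = character(0), cancer_types = character(0),
                  n_types = integer(0))
  } else {
    out <- long |>
      group_by(.data$gene) |>
      summarise(
        cancer_types = paste(sort(unique(.data$cancer_type)),
                             collapse = ","),
        n_types = dplyr::n_distinct(.data$cancer_type),
        .groups = "drop") |>
      arrange(desc(.data$n_types), .data$gene)
  }
  structure(out, class = c("sl_candidates", class(out)),
            per_type = per_type)
}

#' Annotate synthetic-lethality candidates with kinase and compound
#' information
#'
#' @param candidates An [sl_candidates()] tibble.
#' @param kinase_list Character vector of kinase-encoding gene symbols
#'   (user-supplied kinome list; none is bundled).
#' @param targets Optional tibble (`compound`, `gene`) joining inhibitors
#'   onto their target genes.
#' @return The candidates tibble with `is_kinase` and `compounds`
#'   (comma-separated, `NA` when no compound targets the gene) columns.
#' @export
annotate_kinases <- function(candidates, kinase_list, targets = NULL) {
  if (length(kinase_list) == 0) {
    warn("empty kinase list: no candidate will be flagged as kinase")
  }
  out <- mutate(candidates, is_kinase = .data$gene %in% kinase_list)
  if (!is.null(targets) && nrow(targets) > 0) {
    cmp <- as_tibble(targets) |>
      group_by(.data$gene) |>
      summarise(compounds = paste(sort(unique(.data$compound)),
                                  collapse = ","),
                .groups = "drop")
    out <- left_join(out, cmp, by = "gene")
  } else {
    out$compounds <- NA_character_
  }
  out
}

#' IC50 compound screen by TP53 status
#'
#' Per compound, a two-sided t-test comparing log IC50 between
#' TP53-mutated and TP53-wildtype cell lines (missing entries excluded
#' pairwise). The SL-supporting flagged set requires
#' `p < p_ic50`, `q < fdr_ic50` *and* lower IC50 in mutated lines
#' (greater sensitivity); compounds significantly lower in wildtype are
#' recorded separately under `direction`. The FDR family is all compounds
#' tested in the run.
#'
#' @param screen A [pharmaco_screen()].
#' @param cfg A [run_config()].
#' @return A tibble of class `tp53_ic50` with per-compound group sizes,
#'   means, test and `flagged`; skipped compounds carry a `note`.
#' @export
ic50_screen <- function(screen, cfg = run_config()) {
  stopifnot(inherits(screen, "pharmaco_screen"))
  st <- setNames(screen$status$tp53_status, screen$status$cell_line)
  grp <- st[rownames(screen$ic50)]
  res <- purrr::map_dfr(colnames(screen$ic50), function(cmp) {
    v <- screen$ic50[, cmp]
    ok <- !is.na(v)
    x <- v[ok & grp == "mutated"]
    y <- v[ok & grp == "wildtype"]
    if (length(x) < 2 || length(y) < 2) {
      return(tibble(compound = cmp, n_mutated = length(x),
                    n_wildtype = length(y), mean_mutated = NA_real_,
                    mean_wildtype = NA_real_, statistic = NA_real_,
                    p_value = NA_real_,
                    note = "fewer than 2 lines in a status group"))
    }
    tt <- two_sample_t(x, y, welch = cfg$welch)
    tibble(compound = cmp, n_mutated = length(x),
           n_wildtype = length(y), mean_mutated = mean(x),
           mean_wildtype = mean(y), statistic = tt$statistic,
           p_value = tt$p_value, note = NA_character_)
  })
  tested <- !is.na(res$p_value)
  res$q_value <- NA_real_
  res$q_value[tested] <- bh_fdr(res$p_value[tested])
  res$direction <- dplyr::case_when(
    !tested ~ NA_character_,
    res$mean_mutated < res$mean_wildtype ~ "lower_in_mutated",
    res$mean_mutated > res$mean_wildtype ~ "lower_in_wildtype",
    TRUE ~ "equal")
  res$flagged <- tested & res$p_value < cfg$p_ic50 &
    res$q_value < cfg$fdr_ic50 & res$direction == "lower_in_mutated"
  structure(res, class = c("tp53_ic50", class(res)),
            p_ic50 = cfg$p_ic50, fdr_ic50 = cfg$fdr_ic50)
}

#' Flagged compounds of an IC50 screen
#'
#' @param screen_result A `tp53_ic50` tibble.
#' @return Character vector of compounds flagged as SL-supporting
#'   (significantly lower IC50 in mutated lines).
#' @export
flagged_compounds <- function(screen_result) {
  screen_result$compound[screen_result$flagged]
}

#' @export
glance.tp53_ic50 <- function(x, ...) {
  tibble(n_compounds = nrow(x), n_tested = sum(!is.na(x$p_value)),
         n_flagged = sum(x$flagged),
         n_lower_in_wildtype = sum(!is.na(x$p_value) & !x$flagged &
                                     x$p_value < attr(x, "p_ic50") &
                                     x$q_value < attr(x, "fdr_ic50") &
                                     x$direction == "lower_in_wildtype"))
}

#' Cross-validate SL candidates against flagged compounds
#'
#' For each flagged compound, intersects its target genes with the
#' candidate set, yielding an evidence table of (gene, compound,
#' cancer types) rows.
#'
#' @param candidates An [sl_candidates()] tibble.
#' @param screen A [pharmaco_screen()] supplying the target map.
#' @param flagged Character vector of flagged compounds, e.g. from
#'   [flagged_compounds()].
#' @return Tibble (`gene`, `compound`, `cancer_types`).
#' @export
cross_validate_candidates <- function(candidates, screen, flagged) {
  tg <- filter(as_tibble(screen$targets), .data$compound %in% flagged)
  out <- inner_join(tg, as_tibble(candidates)[, c("gene", "cancer_types")],
                    by = "gene")
  arrange(select(out, "gene", "compound", "cancer_types"),
          .data$gene, .data$compound)
}
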