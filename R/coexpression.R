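# TP53 co-expression screening (PCOR/NCOR) and positional (cytoband)
# over-representation.

#' Genes co-expressed with TP53 in tumors but not in normal tissue
#'
#' For every gene, Pearson correlation with TP53 expression across tumor
#' samples (BH-adjusted across tested genes) and across normal samples
#' (raw p; with few normals an FDR there would be over-strict). The sets:
#' * `PCOR` — `q_tumor < fdr_de`, `r_tumor > 0`, and
#'   `p_normal >= p_corr_normal` (no evidence of correlation in normals);
#' * `NCOR` — likewise with `r_tumor < 0`.
#'
#' TP53 itself is excluded; genes constant in tumors or normals are
#' excluded with a recorded note.
#'
#' @param study An [expression_study()] with at least 3 tumor and 3
#'   normal samples.
#' @param cfg A [run_config()].
#' @param gene Anchor gene. Default `"TP53"`.
#' @return A tibble of class `tp53_coexpr` with per-gene `r_tumor`,
#'   `p_tumor`, `q_tumor`, `r_normal`, `p_normal`, `pcor`, `ncor`,
#'   `note`; the PCOR/NCOR sets are available via [pcor_genes()] /
#'   [ncor_genes()].
#' @export
coexpression_with_tp53 <- function(study, cfg = run_config(),
                                   gene = "TP53") {
  stopifnot(inherits(study, "expression_study"))
  if (!gene %in% rownames(study$exprs)) {
    abort(paste0(gene, " absent from expression matrix"),
          class = "tp53_validation_error")
  }
  grp <- sample_groups(study)
  if (length(grp$tumor) < 3 || length(grp$normal) < 3) {
    abort("need at least 3 tumor and 3 normal samples",
          class = "tp53_validation_error")
  }
  tum <- study$exprs[, grp$tumor, drop = FALSE]
  nor <- study$exprs[, grp$normal, drop = FALSE]
  anchor_t <- tum[gene, ]
  anchor_n <- nor[gene, ]
  if (sd(anchor_t) == 0) {
    abort("anchor gene constant in tumors",
          class = "tp53_undefined_correlation")
  }
  genes <- setdiff(rownames(study$exprs), gene)
  sd_t <- apply(tum[genes, , drop = FALSE], 1, sd)
  sd_n <- apply(nor[genes, , drop = FALSE], 1, sd)
  testable <- genes[sd_t > 0 & sd_n > 0]
  r_t <- as.numeric(cor(t(tum[testable, , drop = FALSE]), anchor_t))
  p_t <- corr_p_value(r_t, length(anchor_t))
  q_t <- bh_fdr(p_t)
  if (sd(anchor_n) == 0) {
    # anchor flat in normals: no normal-tissue correlation is estimable
    r_n <- rep(NA_real_, length(testable))
    p_n <- rep(1, length(testable))
  } else {
    r_n <- as.numeric(cor(t(nor[testable, , drop = FALSE]), anchor_n))
    p_n <- corr_p_value(r_n, length(anchor_n))
  }
  res <- tibble(gene = testable, r_tumor = r_t, p_tumor = p_t,
                q_tumor = q_t, r_normal = r_n, p_normal = p_n,
                note = NA_character_)
  res$pcor <- res$q_tumor < cfg$fdr_de & res$r_tumor > 0 &
    res$p_normal >= cfg$p_corr_normal
  res$ncor <- res$q_tumor < cfg$fdr_de & res$r_tumor < 0 &
    res$p_normal >= cfg$p_corr_normal
  excluded <- setdiff(genes, testable)
  if (length(excluded) > 0) {
    res <- bind_rows(res, tibble(
      gene = excluded, r_tumor = NA_real_, p_tumor = NA_real_,
      q_tumor = NA_real_, r_normal = NA_real_, p_normal = NA_real_,
      note = "constant expression; correlation undefined",
      pcor = FALSE, ncor = FALSE))
  }
  res <- arrange(res, .data$gene)
  structure(res, class = c("tp53_coexpr", class(res)),
            cancer_type = study$cancer_type, anchor = gene,
            n_tumor = length(grp$tumor), n_normal = length(grp$normal))
}

#' PCOR / NCOR gene sets of a co-expression result
#'
#' @param coexpr A `tp53_coexpr` result.
#' @return Character vector of gene symbols.
#' @export
pcor_genes <- function(coexpr) coexpr$gene[coexpr$pcor]

#' @rdname pcor_genes
#' @export
ncor_genes <- function(coexpr) coexpr$gene[coexpr$ncor]

#' @export
glance.tp53_coexpr <- function(x, ...) {
  tibble(cancer_type = attr(x, "cancer_type"), anchor = attr(x, "anchor"),
         n_tumor = attr(x, "n_tumor"), n_normal = attr(x, "n_normal"),
         n_tested = sum(is.na(x$note)), n_pcor = sum(x$pcor),
         n_ncor = sum(x$ncor))
}

#' Cytoband over-representation of a gene set
#'
#' Hypergeometric upper-tail test per cytoband represented in the set,
#' BH-adjusted across the tested bands. Useful for asking whether genes
#' co-expressed with TP53 cluster near its locus (chr17p13).
#'
#' @param gene_set Character vector of gene symbols.
#' @param band_map Tibble (`gene`, `band`) covering the universe.
#' @param universe Character vector of universe genes; defaults to all
#'   genes in `band_map`.
#' @return Tibble (`band`, `band_size`, `set_in_band`, `fold_enrichment`,
#'   `p_value`, `q_value`) sorted by p-value; empty for an empty set.
#' @export
cytoband_enrichment <- function(gene_set, band_map,
                                universe = unique(band_map$gene)) {
  band_map <- distinct(as_tibble(band_map)[, c("gene", "band")])
  uncovered <- setdiff(universe, band_map$gene)
  if (length(uncovered) > 0) {
    abort(paste0("band map does not cover universe gene(s): ",
                 paste(head(uncovered, 5), collapse = ", ")),
          class = "tp53_validation_error")
  }
  gene_set <- intersect(unique(gene_set), universe)
  if (length(gene_set) == 0) {
    return(tibble(band = character(0), band_size = integer(0),
                  set_in_band = integer(0), fold_enrichment = numeric(0),
                  p_value = numeric(0), q_value = numeric(0)))
  }
  bm <- filter(band_map, .data$gene %in% universe)
  bands <- unique(bm$band[bm$gene %in% gene_set])
  out <- purrr::map_dfr(bands, function(b) {
    band_genes <- bm$gene[bm$band == b]
    k <- length(intersect(gene_set, band_genes))
    res <- hypergeom_enrichment(k, length(gene_set), length(band_genes),
                                length(universe))
    tibble(band = b, band_size = length(band_genes), set_in_band = k,
           fold_enrichment = res$effect, p_value = res$p_value)
  })
  out$q_value <- bh_fdr(out$p_value)
  arrange(out, .data$p_value, .data$band)
}
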