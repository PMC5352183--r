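# Core data containers: a long-format mutation table with its sample
# universe, and a per-cancer-type expression study (log2 matrix + sample
# annotations).

#' Somatic mutation table
#'
#' Long-format somatic mutation records together with the *sample
#' universe* — the full list of sequenced samples per cancer type, which
#' supplies the denominator for mutation rates (unmutated samples carry no
#' records but must still be counted).
#'
#' @param records Tibble with columns `sample_id`, `cancer_type`,
#'   `gene_symbol`, `variant_class` (one of [variant_classes()]).
#' @param sample_universe Tibble with columns `cancer_type`, `sample_id`
#'   listing every sequenced sample.
#' @return An object of class `mutation_table`.
#' @export
mutation_table <- function(records, sample_universe) {
  records <- as_tibble(records)
  sample_universe <- distinct(as_tibble(sample_universe))
  req <- c("sample_id", "cancer_type", "gene_symbol", "variant_class")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols) > 0) {
    abort(paste0("records missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "tp53_format_error")
  }
  if (!all(c("cancer_type", "sample_id") %in% names(sample_universe))) {
    abort("sample_universe needs columns cancer_type, sample_id",
          class = "tp53_format_error")
  }
  bad_class <- setdiff(unique(records$variant_class), variant_classes())
  if (length(bad_class) > 0) {
    abort(paste0("unknown variant class(es): ",
                 paste(bad_class, collapse = ", ")),
          class = "tp53_format_error")
  }
  # exact duplicates collapse to one record; distinct classes per
  # sample/gene are kept (they matter for status classification)
  records <- distinct(records[, req])
  orphan <- anti_join(records, sample_universe,
                      by = c("cancer_type", "sample_id"))
  if (nrow(orphan) > 0) {
    abort(paste0("record sample(s) absent from sample universe: ",
                 paste(unique(orphan$sample_id), collapse = ", ")),
          class = "tp53_validation_error")
  }
  structure(list(records = records, sample_universe = sample_universe),
            class = "mutation_table")
}

#' @export
print.mutation_table <- function(x, ...) {
  cat(sprintf("<mutation_table> %d records, %d samples, %d cancer types\n",
              nrow(x$records), nrow(x$sample_universe),
              length(unique(x$sample_universe$cancer_type))))
  invisible(x)
}

#' @export
tidy.mutation_table <- function(x, ...) x$records

#' Per-cancer-type expression study
#'
#' A genes-by-samples matrix of log2-transformed expression values plus
#' sample annotations: tissue (`tumor`/`normal`) and the TP53 status group
#' of tumor samples (`wildtype`, `truncating`, `non_truncating`; normal
#' samples carry `not_applicable`).
#'
#' @param cancer_type Single cancer-type label.
#' @param exprs Numeric matrix, genes in rows (unique rownames), samples
#'   in columns, values on the log2 scale.
#' @param sample_meta Tibble with columns `sample_id`, `tissue`,
#'   `tp53_group` covering exactly the matrix columns.
#' @return An object of class `expression_study`.
#' @export
expression_study <- function(cancer_type, exprs, sample_meta) {
  sample_meta <- as_tibble(sample_meta)
  stopifnot(is.matrix(exprs), is.numeric(exprs))
  if (is.null(rownames(exprs)) || anyDuplicated(rownames(exprs))) {
    abort("expression matrix needs unique gene rownames",
          class = "tp53_format_error")
  }
  if (any(!is.finite(exprs))) {
    abort("expression values must be finite", class = "tp53_format_error")
  }
  req <- c("sample_id", "tissue", "tp53_group")
  if (!all(req %in% names(sample_meta))) {
    abort("sample_meta needs columns sample_id, tissue, tp53_group",
          class = "tp53_format_error")
  }
  extra <- setdiff(sample_meta$sample_id, colnames(exprs))
  if (length(extra) > 0) {
    abort(paste0("sample(s) in metadata but not in matrix: ",
                 paste(extra, collapse = ", ")),
          class = "tp53_validation_error")
  }
  missing_meta <- setdiff(colnames(exprs), sample_meta$sample_id)
  if (length(missing_meta) > 0) {
    abort(paste0("sample(s) in matrix but not in metadata: ",
                 paste(missing_meta, collapse = ", ")),
          class = "tp53_validation_error")
  }
  ok_tissue <- c("tumor", "normal")
  if (!all(sample_meta$tissue %in% ok_tissue)) {
    abort("tissue must be 'tumor' or 'normal'", class = "tp53_format_error")
  }
  ok_grp <- c("wildtype", "truncating", "non_truncating", "not_applicable")
  if (!all(sample_meta$tp53_group %in% ok_grp)) {
    abort("invalid tp53_group label", class = "tp53_format_error")
  }
  bad_norm <- sample_meta$tissue == "normal" &
    sample_meta$tp53_group != "not_applicable"
  if (any(bad_norm)) {
    abort("normal samples must have tp53_group 'not_applicable'",
          class = "tp53_validation_error")
  }
  sample_meta <- sample_meta[match(colnames(exprs), sample_meta$sample_id), ]
  structure(list(cancer_type = cancer_type, exprs = exprs,
                 sample_meta = sample_meta),
            class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  tab <- table(x$sample_meta$tissue)
  cat(sprintf(
    "<expression_study> %s: %d genes x %d samples (%d tumor, %d normal)\n",
    x$cancer_type, nrow(x$exprs), ncol(x$exprs),
    tab["tumor"] %||% 0L, tab["normal"] %||% 0L))
  invisible(x)
}

#' Named sample groups of an expression study
#'
#' Resolves the standard group labels used throughout the class calculus
#' to sample-id vectors: `tumor`, `normal`, `mutated` (truncating or
#' non-truncating), `wildtype`, `truncating`, `non_truncating`.
#'
#' @param study An [expression_study()].
#' @return Named list of character vectors of sample ids.
#' @export
sample_groups <- function(study) {
  m <- study$sample_meta
  list(
    tumor = m$sample_id[m$tissue == "tumor"],
    normal = m$sample_id[m$tissue == "normal"],
    mutated = m$sample_id[m$tp53_group %in% c("truncating",
                                              "non_truncating")],
    wildtype = m$sample_id[m$tp53_group == "wildtype"],
    truncating = m$sample_id[m$tp53_group == "truncating"],
    non_truncating = m$sample_id[m$tp53_group == "non_truncating"]
  )
}

resolve_group <- function(study, group) {
  if (length(group) == 1 && group %in% names(sample_groups(study))) {
    return(sample_groups(study)[[group]])
  }
  unknown <- setdiff(group, colnames(study$exprs))
  if (length(unknown) > 0) {
    abort(paste0("unknown sample id(s): ",
                 paste(head(unknown, 5), collapse = ", ")),
          class = "tp53_validation_error")
  }
  group
}
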