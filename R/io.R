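# Readers and writers for the tabular formats the pipeline touches:
# MAF-dialect mutation tables, expression matrices with sample metadata,
# and the per-class gene membership reports.

#' Mapping from MAF Variant_Classification strings to the pipeline's
#' eight-class vocabulary
#'
#' Classes outside the mapping (e.g. `Translation_Start_Site`, `3'UTR`)
#' have no target class and are dropped by [read_maf()] with a reported
#' count.
#'
#' @return Named character vector: MAF label -> pipeline label.
#' @export
maf_class_map <- function() {
  c(Missense_Mutation = "missense",
    Nonsense_Mutation = "nonsense",
    Frame_Shift_Del = "frame_shift_del",
    Frame_Shift_Ins = "frame_shift_ins",
    In_Frame_Del = "in_frame_del",
    In_Frame_Ins = "in_frame_ins",
    Silent = "silent",
    Splice_Site = "splice_site")
}

#' Read a somatic mutation table
#'
#' Accepts either the TCGA MAF dialect (tab-separated with at least
#' `Hugo_Symbol`, `Variant_Classification` and `Tumor_Sample_Barcode`
#' columns; coordinates are ignored) or the pipeline's simplified
#' four-column layout (`sample_id`, `cancer_type`, `gene_symbol`,
#' `variant_class`). MAF classification strings are mapped through
#' [maf_class_map()]; unmappable records are dropped and their count
#' reported via a message.
#'
#' @param path Path to the tab-separated file.
#' @param sample_universe Tibble (`cancer_type`, `sample_id`) of all
#'   sequenced samples; also assigns cancer types to MAF barcodes.
#' @return A [mutation_table()].
#' @export
read_maf <- function(path, sample_universe) {
  sample_universe <- as_tibble(sample_universe)
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = "c"),
                        comment = "#")
  if (nrow(df) == 0) {
    abort("mutation file is empty", class = "tp53_format_error")
  }
  maf_cols <- c("Hugo_Symbol", "Variant_Classification",
                "Tumor_Sample_Barcode")
  simple_cols <- c("sample_id", "cancer_type", "gene_symbol",
                   "variant_class")
  if (all(simple_cols %in% names(df))) {
    records <- df[, simple_cols]
  } else {
    missing_cols <- setdiff(maf_cols, names(df))
    if (length(missing_cols) > 0) {
      abort(paste0("mutation file missing required column(s): ",
                   paste(missing_cols, collapse = ", ")),
            class = "tp53_format_error")
    }
    mapped <- maf_class_map()[df$Variant_Classification]
    n_drop <- sum(is.na(mapped))
    if (n_drop > 0) {
      inform(sprintf(
        "dropped %d record(s) with variant classes outside the eight-class vocabulary",
        n_drop))
    }
    df <- df[!is.na(mapped), ]
    mapped <- mapped[!is.na(mapped)]
    dup_types <- sample_universe |>
      distinct(.data$cancer_type, .data$sample_id) |>
      dplyr::count(.data$sample_id) |>
      filter(n > 1)
    if (nrow(dup_types) > 0) {
      abort(paste0("sample(s) assigned to multiple cancer types: ",
                   paste(dup_types$sample_id, collapse = ", ")),
            class = "tp53_validation_error")
    }
    type_of <- setNames(sample_universe$cancer_type,
                        sample_universe$sample_id)
    records <- tibble(
      sample_id = df$Tumor_Sample_Barcode,
      cancer_type = unname(type_of[df$Tumor_Sample_Barcode]),
      gene_symbol = df$Hugo_Symbol,
      variant_class = unname(mapped)
    )
    if (anyNA(records$cancer_type)) {
      missing_s <- unique(records$sample_id[is.na(records$cancer_type)])
      abort(paste0("record sample(s) absent from sample universe: ",
                   paste(missing_s, collapse = ", ")),
            class = "tp53_validation_error")
    }
  }
  mutation_table(records, sample_universe)
}

#' Write a mutation table in the simplified four-column layout
#'
#' @param muts A [mutation_table()].
#' @param path Output TSV path for the records; the sample universe is
#'   written next to it as `<path>.universe.tsv` unless `universe_path`
#'   is given.
#' @param universe_path Optional path for the sample universe TSV.
#' @return `path`, invisibly.
#' @export
write_maf <- function(muts, path,
                      universe_path = paste0(path, ".universe.tsv")) {
  stopifnot(inherits(muts, "mutation_table"))
  readr::write_tsv(muts$records, path)
  readr::write_tsv(muts$sample_universe, universe_path)
  invisible(path)
}

#' Read an expression study from a matrix and metadata file
#'
#' The matrix file is a genes-in-rows TSV whose first column holds gene
#' symbols; remaining columns are samples. Raw (non-negative) values are
#' transformed to `log2(x + pseudocount)`; already-logged input is passed
#' through with `pre_logged = TRUE`. The metadata file must annotate every
#' matrix column with `tissue` and `tp53_group`.
#'
#' @param path Matrix TSV path.
#' @param meta_path Metadata TSV path (`sample_id`, `tissue`,
#'   `tp53_group`).
#' @param cancer_type Cancer-type label for the study.
#' @param pre_logged If `TRUE`, values are already log2-scale.
#' @param pseudocount Added before the log2 transform. Default 1.
#' @return An [expression_study()].
#' @export
read_expression <- function(path, meta_path, cancer_type,
                            pre_logged = FALSE, pseudocount = 1) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  if (ncol(df) < 2) abort("matrix file has no sample columns",
                          class = "tp53_format_error")
  genes <- as.character(df[[1]])
  dup <- genes[duplicated(genes)]
  if (length(dup) > 0) {
    abort(paste0("duplicate gene row(s): ",
                 paste(unique(dup), collapse = ", ")),
          class = "tp53_format_error")
  }
  mat <- as.matrix(df[, -1])
  storage.mode(mat) <- "double"
  rownames(mat) <- genes
  if (!pre_logged) {
    if (any(mat < 0, na.rm = TRUE)) {
      abort("negative raw expression value", class = "tp53_format_error")
    }
    mat <- log2(mat + pseudocount)
  }
  meta <- readr::read_tsv(meta_path, show_col_types = FALSE,
                          col_types = readr::cols(.default = "c"))
  expression_study(cancer_type, mat, meta)
}

#' Write an expression study to matrix and metadata TSVs
#'
#' Values are written on the log2 scale; read back with
#' `pre_logged = TRUE`.
#'
#' @param study An [expression_study()].
#' @param path,meta_path Output paths.
#' @return `path`, invisibly.
#' @export
write_expression <- function(study, path, meta_path) {
  stopifnot(inherits(study, "expression_study"))
  df <- as_tibble(study$exprs, rownames = "gene")
  readr::write_tsv(df, path)
  readr::write_tsv(study$sample_meta, meta_path)
  invisible(path)
}

#' Write gene-class membership reports
#'
#' One TSV per gene class (MW, WN, WN2, MN, MWN, MSN, ...): genes as rows,
#' cancer types as 0/1 membership columns, plus a `recurrence` count.
#' Rows are ordered by descending recurrence, ties broken
#' lexicographically by gene symbol.
#'
#' @param sets_by_type Named list (cancer type -> [derive_gene_classes()]
#'   result, or any named list of gene-set lists with identical class
#'   names).
#' @param dir Output directory (created if needed).
#' @return Named character vector of written file paths, invisibly.
#' @export
write_gene_class_report <- function(sets_by_type, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  set_lists <- lapply(sets_by_type, function(x) {
    if (inherits(x, "gene_class_sets")) x$sets else x
  })
  class_names <- unique(unlist(lapply(set_lists, names)))
  types <- names(sets_by_type)
  paths <- character(0)
  for (cl in class_names) {
    tab <- class_membership_table(lapply(set_lists, `[[`, cl), types)
    p <- file.path(dir, paste0("class_", cl, ".tsv"))
    readr::write_tsv(tab, p)
    paths[cl] <- p
  }
  invisible(paths)
}

class_membership_table <- function(sets, types) {
  genes <- sort(unique(unlist(sets)))
  cols <- lapply(types, function(t) as.integer(genes %in% sets[[t]]))
  names(cols) <- types
  tab <- tibble(gene = genes, !!!cols)
  tab$recurrence <- if (length(genes) == 0) integer(0) else
    as.integer(rowSums(as.matrix(tab[, types, drop = FALSE])))
  arrange(tab, desc(.data$recurrence), .data$gene)
}

#' Read a gene-class membership report back
#'
#' @param path A TSV written by [write_gene_class_report()].
#' @return Named list of per-cancer-type gene sets.
#' @export
read_gene_class_report <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  types <- setdiff(names(tab), c("gene", "recurrence"))
  out <- lapply(types, function(t) tab$gene[tab[[t]] == 1])
  names(out) <- types
  out
}
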