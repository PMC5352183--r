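#' Analysis run configuration
#'
#' Bundles every tunable threshold of the pipeline into one validated
#' object. Defaults follow the conventions of pan-cancer mutation-expression
#' class comparison: differentially expressed genes require FDR < `fdr_de`
#' and fold change > `fc_primary`; the stricter wildtype-vs-normal screen
#' used to subtract genes from the mutant-specific list relaxes the fold
#' threshold to `fc_secondary`; TP53 group comparisons use a raw p-value
#' threshold `p_tp53_expr`; the pharmacogenomic screen flags compounds at
#' `p_ic50` and `fdr_ic50`.
#'
#' @param fc_primary Fold-change threshold (linear ratio) for the main
#'   differential-expression screens. Must exceed 1. Default 1.5.
#' @param fc_secondary Relaxed fold-change threshold used for the WN2
#'   (wildtype vs normal) subtraction list. Default 1.2.
#' @param fdr_de Benjamini-Hochberg FDR threshold for differential
#'   expression and co-expression. Default 0.05.
#' @param p_tp53_expr Raw p-value threshold for TP53 group-mean
#'   comparisons and expression-pattern calls. Default 0.05.
#' @param fdr_ic50 FDR threshold for the IC50 compound screen. Default 0.2.
#' @param p_ic50 Raw p-value threshold for the IC50 compound screen.
#'   Default 0.05.
#' @param p_corr_normal Raw p-value threshold above which a gene is deemed
#'   *uncorrelated* with TP53 in normal tissue (PCOR/NCOR definition).
#'   Default 0.05.
#' @param min_normals Minimum number of normal control samples required for
#'   tumor-vs-normal comparisons. Default 4.
#' @param min_group Minimum tumor-group size for tumor-vs-tumor
#'   comparisons. Default 10.
#' @param recurrence_fraction Fraction of analysed cancer types a gene must
#'   (strictly) exceed to be called recurrent. Default 0.25.
#' @param pseudocount Non-negative value added before log2 transform of raw
#'   expression. Default 1.
#' @param welch Use Welch's unequal-variance t-test instead of the
#'   pooled-variance Student's t. Default `FALSE`.
#' @param linear_fc Compute fold changes as ratios of arithmetic means on
#'   the linear scale rather than ratios of geometric means (the default,
#'   `2^(difference of log2 means)`). Default `FALSE`.
#' @param ic50_is_log Whether IC50 input values are already log-scale.
#'   Default `TRUE`.
#' @param seed Integer seed recorded with the run. Default 1.
#'
#' @return A list of class `tp53_run_config`.
#' @export
#' @examples
#' cfg <- run_config(fdr_de = 0.1)
#' cfg$fdr_de
run_config <- function(fc_primary = 1.5,
                       fc_secondary = 1.2,
                       fdr_de = 0.05,
                       p_tp53_expr = 0.05,
                       fdr_ic50 = 0.2,
                       p_ic50 = 0.05,
                       p_corr_normal = 0.05,
                       min_normals = 4,
                       min_group = 10,
                       recurrence_fraction = 0.25,
                       pseudocount = 1,
                       welch = FALSE,
                       linear_fc = FALSE,
                       ic50_is_log = TRUE,
                       seed = 1L) {
  cfg <- list(
    fc_primary = fc_primary, fc_secondary = fc_secondary,
    fdr_de = fdr_de, p_tp53_expr = p_tp53_expr,
    fdr_ic50 = fdr_ic50, p_ic50 = p_ic50,
    p_corr_normal = p_corr_normal,
    min_normals = as.integer(min_normals),
    min_group = as.integer(min_group),
    recurrence_fraction = recurrence_fraction,
    pseudocount = pseudocount,
    welch = isTRUE(welch), linear_fc = isTRUE(linear_fc),
    ic50_is_log = isTRUE(ic50_is_log),
    seed = as.integer(seed)
  )
  validate_run_config(cfg)
  structure(cfg, class = "tp53_run_config")
}

validate_run_config <- function(cfg) {
  props <- c("fdr_de", "p_tp53_expr", "fdr_ic50", "p_ic50",
             "p_corr_normal", "recurrence_fraction")
  for (p in props) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1L || v <= 0 || v >= 1) {
      abort(sprintf("`%s` must be a proportion in (0, 1), got %s", p,
                    format(v)), class = "tp53_config_error")
    }
  }
  for (p in c("fc_primary", "fc_secondary")) {
    if (!is.numeric(cfg[[p]]) || cfg[[p]] <= 1) {
      abort(sprintf("`%s` must be a ratio > 1", p),
            class = "tp53_config_error")
    }
  }
  for (p in c("min_normals", "min_group")) {
    if (cfg[[p]] < 2) {
      abort(sprintf("`%s` must be at least 2", p),
            class = "tp53_config_error")
    }
  }
  if (cfg$pseudocount < 0) {
    abort("`pseudocount` must be non-negative", class = "tp53_config_error")
  }
  invisible(cfg)
}

#' @export
print.tp53_run_config <- function(x, ...) {
  cat("<tp53_run_config>\n")
  for (nm in names(x)) cat(sprintf("  %-20s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Read or write a run configuration as YAML
#'
#' @param path Path to a YAML file whose keys mirror the arguments of
#'   [run_config()]. Unknown keys are rejected.
#' @return `read_run_config()` returns a `tp53_run_config`;
#'   `write_run_config()` returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) {
    abort(paste0("unknown configuration keys: ", paste(bad, collapse = ", ")),
          class = "tp53_config_error")
  }
  do.call(run_config, vals)
}

#' @rdname read_run_config
#' @param cfg A `tp53_run_config`.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "tp53_run_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
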