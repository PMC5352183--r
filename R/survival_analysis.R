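# Survival stratification and Kaplan-Meier / log-rank comparisons.

#' Median split of expression values
#'
#' Patients with a value strictly greater than the median are `high`;
#' everyone else — including exact ties with the median — is `low`.
#' Consequently the high group is never larger than the low group.
#'
#' @param values Named numeric vector (names = patient ids), or a tibble
#'   with columns `patient_id` and `value`.
#' @return Tibble (`patient_id`, `group`) with `group` in
#'   `c("high", "low")`.
#' @export
#' @examples
#' median_split(c(p1 = 1, p2 = 2, p3 = 3))
median_split <- function(values) {
  if (is.data.frame(values)) {
    df <- as_tibble(values)
    stopifnot(all(c("patient_id", "value") %in% names(df)))
  } else {
    if (is.null(names(values))) abort("values must be named by patient",
                                      class = "tp53_validation_error")
    df <- tibble(patient_id = names(values), value = as.numeric(values))
  }
  if (nrow(df) < 2) abort("need at least 2 patients",
                          class = "tp53_validation_error")
  med <- median(df$value)
  tibble(patient_id = df$patient_id,
         group = ifelse(df$value > med, "high", "low"))
}

#' Compare survival between two strata
#'
#' Kaplan-Meier curve per stratum plus a two-group log-rank test for one
#' endpoint (OS or DFS). Patients lacking the endpoint are excluded from
#' that endpoint only. A comparison is skipped (with a recorded reason)
#' rather than run when a stratum has fewer than `min_patients` patients
#' or fewer than `min_events` events — mirroring the exclusion of cancer
#' types with very few annotated samples.
#'
#' @param records Tibble with columns `patient_id`, `endpoint`
#'   (`"OS"`/`"DFS"`), `time` (months, positive), `event` (0/1),
#'   `stratum`.
#' @param endpoint Endpoint to analyse.
#' @param strata Length-2 character vector naming the strata to compare;
#'   defaults to the two most frequent strata present. Records in other
#'   strata are excluded (stratum algebra for combined labels).
#' @param min_patients,min_events Per-stratum thresholds below which the
#'   comparison is skipped. Defaults 10 and 1.
#' @return List of class `tp53_survcomp`: `test` (one-row tibble or
#'   `NULL`), `curves` (per-stratum KM coordinates), `sizes`, `skipped`,
#'   `reason`.
#' @export
compare_survival <- function(records, endpoint = c("OS", "DFS"),
                             strata = NULL, min_patients = 10,
                             min_events = 1) {
  endpoint <- match.arg(endpoint)
  df <- as_tibble(records) |>
    filter(.data$endpoint == !!endpoint,
           !is.na(.data$time), !is.na(.data$event))
  if (nrow(df) == 0) {
    return(surv_skipped(endpoint, "no records with this endpoint"))
  }
  if (is.null(strata)) {
    strata <- names(sort(table(df$stratum), decreasing = TRUE))
    if (length(strata) < 2) {
      return(surv_skipped(endpoint, "fewer than two strata present"))
    }
    strata <- strata[1:2]
  }
  df <- filter(df, .data$stratum %in% strata)
  sizes <- df |>
    group_by(.data$stratum) |>
    summarise(n = n(), events = sum(.data$event), .groups = "drop")
  if (!all(strata %in% sizes$stratum)) {
    return(surv_skipped(endpoint, paste0(
      "empty stratum: ", paste(setdiff(strata, sizes$stratum),
                               collapse = ", "))))
  }
  if (any(sizes$n < min_patients) || any(sizes$events < min_events)) {
    return(surv_skipped(endpoint, sprintf(
      "stratum below thresholds (min %d patients, %d events)",
      min_patients, min_events)))
  }
  a <- filter(df, .data$stratum == strata[1])
  b <- filter(df, .data$stratum == strata[2])
  test <- logrank_test(a$time, a$event, b$time, b$event)
  curves <- bind_rows(
    mutate(km_estimate(a$time, a$event), stratum = strata[1]),
    mutate(km_estimate(b$time, b$event), stratum = strata[2])
  )
  structure(list(endpoint = endpoint, strata = strata, test = test,
                 curves = curves, sizes = sizes, skipped = FALSE,
                 reason = NA_character_),
            class = "tp53_survcomp")
}

surv_skipped <- function(endpoint, reason) {
  structure(list(endpoint = endpoint, strata = NULL, test = NULL,
                 curves = NULL, sizes = NULL, skipped = TRUE,
                 reason = reason),
            class = "tp53_survcomp")
}

#' @export
print.tp53_survcomp <- function(x, ...) {
  cat(sprintf("<tp53_survcomp> endpoint %s\n", x$endpoint))
  if (x$skipped) {
    cat("skipped:", x$reason, "\n")
  } else {
    print(x$sizes)
    cat(sprintf("log-rank chi-square = %.3f, p = %.4g\n",
                x$test$statistic, x$test$p_value))
  }
  invisible(x)
}

#' @export
glance.tp53_survcomp <- function(x, ...) {
  if (x$skipped) {
    return(tibble(endpoint = x$endpoint, statistic = NA_real_,
                  p_value = NA_real_, skipped = TRUE, reason = x$reason))
  }
  tibble(endpoint = x$endpoint, statistic = x$test$statistic,
         p_value = x$test$p_value, skipped = FALSE,
         reason = NA_character_)
}

#' Build survival strata from mutation and expression status
#'
#' Helpers assembling the stratum labels used in survival comparisons:
#' by TP53 mutation status (mutated vs wildtype), by median-split TP53
#' expression (high vs low), or the combined four-way labels
#' (`mutated-high`, `wildtype-low`, ...). When a patient has several
#' tumor samples, their mean log2 expression is used for the split.
#'
#' @param status Tibble (`sample_id`, `tp53_status`) as returned by
#'   [classify_tp53_status()] (a `patient_id` column is used if present,
#'   else `sample_id` is taken as the patient id).
#' @param study Optional [expression_study()] supplying tumor TP53
#'   expression for the median split.
#' @param kind One of `"mutation"`, `"expression"`, `"combined"`.
#' @param gene Expression gene for the split. Default `"TP53"`.
#' @return Tibble (`patient_id`, `stratum`).
#' @export
build_strata <- function(status, study = NULL,
                         kind = c("mutation", "expression", "combined"),
                         gene = "TP53") {
  kind <- match.arg(kind)
  status <- as_tibble(status)
  if (!"patient_id" %in% names(status)) {
    status$patient_id <- status$sample_id
  }
  mut <- status |>
    mutate(mutation = ifelse(.data$tp53_status == "wildtype",
                             "wildtype", "mutated")) |>
    distinct(.data$patient_id, .data$mutation)
  if (kind == "mutation") {
    return(tibble(patient_id = mut$patient_id, stratum = mut$mutation))
  }
  stopifnot(inherits(study, "expression_study"))
  tum_ids <- sample_groups(study)$tumor
  expr <- tibble(sample_id = tum_ids,
                 value = study$exprs[gene, tum_ids]) |>
    left_join(select(status, "sample_id", "patient_id"),
              by = "sample_id") |>
    group_by(.data$patient_id) |>
    summarise(value = mean(.data$value), .groups = "drop")
  split <- median_split(expr)
  if (kind == "expression") {
    return(tibble(patient_id = split$patient_id, stratum = split$group))
  }
  inner_join(mut, split, by = "patient_id") |>
    mutate(stratum = paste(.data$mutation, .data$group, sep = "-")) |>
    select("patient_id", "stratum")
}
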