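# Shared statistical primitives. Each returns a one-row tibble ("test
# result") with a common column layout so results can be row-bound across
# genes, compounds or strata.

test_result <- function(method, statistic, p_value, effect, n1, n2,
                        note = NA_character_) {
  tibble(method = method, statistic = statistic, p_value = p_value,
         effect = effect, n1 = as.integer(n1), n2 = as.integer(n2),
         note = note)
}

#' Two-sample t-test with degenerate-variance conventions
#'
#' Two-sided Student's t-test with pooled variance (or Welch's variant).
#' Expression pipelines hit genes that are constant within both groups;
#' rather than propagating a division by zero, such genes are assigned
#' p = 1 when the group means agree and p = 0 when they differ (the limit
#' of the test as within-group variance vanishes).
#'
#' @param x,y Numeric vectors, each of length at least 2.
#' @param welch Use the unequal-variance (Welch) form. Default `FALSE`
#'   (pooled-variance Student's t).
#' @return A one-row tibble with `statistic`, `p_value`, `effect` (mean of
#'   `x` minus mean of `y`) and the group sizes.
#' @export
#' @examples
#' two_sample_t(c(1, 2, 3, 4), c(3, 4, 5, 6))
two_sample_t <- function(x, y, welch = FALSE) {
  if (length(x) < 2 || length(y) < 2) {
    abort("both groups need at least 2 observations",
          class = "tp53_stats_error")
  }
  if (anyNA(x) || anyNA(y)) abort("missing values in input",
                                  class = "tp53_stats_error")
  n1 <- length(x); n2 <- length(y)
  m1 <- mean(x); m2 <- mean(y)
  v1 <- var(x); v2 <- var(y)
  method <- if (welch) "welch_t" else "student_t"
  if (v1 == 0 && v2 == 0) {
    if (m1 == m2) {
      return(test_result(method, 0, 1, 0, n1, n2, "zero variance"))
    }
    return(test_result(method, sign(m1 - m2) * Inf, 0, m1 - m2, n1, n2,
                       "zero variance"))
  }
  if (welch) {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- se^4 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  stat <- (m1 - m2) / se
  p <- 2 * pt(-abs(stat), df)
  test_result(method, stat, p, m1 - m2, n1, n2)
}

# Vectorised pooled-variance t over the rows of two matrices (genes x
# samples). Applies the same degenerate-variance conventions per row.
row_t_pooled <- function(mat_a, mat_b, welch = FALSE) {
  n1 <- ncol(mat_a); n2 <- ncol(mat_b)
  m1 <- rowMeans(mat_a); m2 <- rowMeans(mat_b)
  v1 <- rowSums((mat_a - m1)^2) / (n1 - 1)
  v2 <- rowSums((mat_b - m2)^2) / (n2 - 1)
  if (welch) {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- se^4 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(m1))
  }
  stat <- (m1 - m2) / se
  p <- 2 * pt(-abs(stat), df)
  degen <- v1 == 0 & v2 == 0
  if (any(degen)) {
    eq <- degen & (m1 == m2)
    stat[eq] <- 0; p[eq] <- 1
    ne <- degen & (m1 != m2)
    stat[ne] <- sign(m1 - m2)[ne] * Inf; p[ne] <- 0
  }
  tibble(mean_a = unname(m1), mean_b = unname(m2),
         statistic = unname(stat), p_value = unname(p))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: `q_i = min_{j >= rank(i)} p_(j) * m / j`, capped
#' at 1, returned in input order. Thin wrapper over [stats::p.adjust()] with
#' input validation.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values, same length and order.
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))
bh_fdr <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    abort("p-values must lie in [0, 1]", class = "tp53_stats_error")
  }
  p.adjust(p_values, method = "BH")
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by summation of all hypergeometric outcomes (with the
#' margins fixed) whose probability does not exceed that of the observed
#' table — the convention of mainstream scientific stacks. The effect is
#' the *sample* odds ratio `a*d / (b*c)`, reported as 0 when `a*d = 0`
#' (with `b*c > 0`) and `Inf` when `b*c = 0` (with `a*d > 0`).
#'
#' @param a,b,c_,d Non-negative integer cell counts; rows index the
#'   phenotype classes, columns mutated/wildtype.
#' @return A one-row tibble; `effect` is the sample odds ratio.
#' @export
#' @examples
#' fisher_exact(3, 1, 1, 3) # p = 34/70, OR = 9
fisher_exact <- function(a, b, c_, d) {
  cells <- c(a, b, c_, d)
  if (anyNA(cells) || any(cells < 0) || any(cells != round(cells))) {
    abort("cell counts must be non-negative integers",
          class = "tp53_stats_error")
  }
  if (sum(cells) == 0) abort("table total must be positive",
                             class = "tp53_stats_error")
  r1 <- a + b; c1 <- a + c_; tot <- sum(cells)
  lo <- max(0, r1 + c1 - tot); hi <- min(r1, c1)
  probs <- dhyper(lo:hi, c1, tot - c1, r1)
  p_obs <- dhyper(a, c1, tot - c1, r1)
  # relative tolerance guards against ties lost to floating-point noise
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  ad <- a * d; bc <- b * c_
  or <- if (ad == 0 && bc == 0) NA_real_
        else if (bc == 0) Inf
        else ad / bc
  test_result("fisher_exact", p_obs, p, or, r1, c_ + d)
}

#' Pearson correlation with significance
#'
#' Pearson product-moment correlation and the two-sided p-value from the
#' t transform of r. Constant input is an error of class
#' `tp53_undefined_correlation`; callers screening many genes should
#' exclude constant genes beforehand.
#'
#' @param x,y Numeric vectors of equal length, at least 3.
#' @return A one-row tibble; `effect` is r.
#' @export
pearson_corr <- function(x, y) {
  if (length(x) != length(y)) abort("lengths differ",
                                    class = "tp53_stats_error")
  if (length(x) < 3) abort("need at least 3 paired observations",
                           class = "tp53_stats_error")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("undefined correlation: constant input",
          class = "tp53_undefined_correlation")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  test_result("pearson", unname(ct$statistic), ct$p.value,
              unname(ct$estimate), length(x), length(y))
}

# r -> two-sided p via the t transform, vectorised. n is the number of
# paired observations.
corr_p_value <- function(r, n) {
  r <- pmin(1, pmax(-1, r))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  2 * pt(-abs(tstat), n - 2)
}

#' Kaplan-Meier product-limit estimate
#'
#' Product-limit survival estimate (via [survival::survfit()]). Events are
#' processed before censorings at tied times; a fully censored input gives
#' the constant curve S(t) = 1.
#'
#' @param times Positive event/censoring times.
#' @param events 0/1 event indicators (1 = event).
#' @return A tibble of class `tp53_km` with columns `time`, `n_risk`,
#'   `n_event`, `n_censor`, `survival`, covering every distinct observed
#'   time.
#' @export
#' @examples
#' km_estimate(c(5, 10, 12, 15), c(1, 1, 0, 1))
km_estimate <- function(times, events) {
  if (length(times) != length(events)) abort("lengths differ",
                                             class = "tp53_stats_error")
  if (any(times <= 0) || anyNA(times)) {
    abort("times must be positive", class = "tp53_stats_error")
  }
  if (!all(events %in% c(0, 1))) abort("events must be 0/1",
                                       class = "tp53_stats_error")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  out <- tibble(time = fit$time, n_risk = fit$n.risk,
                n_event = fit$n.event, n_censor = fit$n.censor,
                survival = fit$surv)
  class(out) <- c("tp53_km", class(out))
  out
}

# Survival probability at time t from a tp53_km curve (right-continuous
# step function; 1 before the first observed time).
km_surv_at <- function(km, t) {
  vapply(t, function(tt) {
    idx <- which(km$time <= tt)
    if (length(idx) == 0) 1 else km$survival[max(idx)]
  }, numeric(1))
}

#' Two-group log-rank test
#'
#' Standard 1-df log-rank chi-square via [survival::survdiff()]. The
#' effect reported is the observed/expected event ratio of group a divided
#' by that of group b (a crude relative-hazard summary; not a fitted
#' hazard ratio).
#'
#' @param times_a,events_a,times_b,events_b Per-group times and 0/1 event
#'   indicators.
#' @return A one-row tibble.
#' @export
logrank_test <- function(times_a, events_a, times_b, events_b) {
  if (length(times_a) < 1 || length(times_b) < 1) {
    abort("each group needs at least one subject",
          class = "tp53_stats_error")
  }
  if (sum(events_a) + sum(events_b) == 0) {
    abort("no events; log-rank p undefined", class = "tp53_no_events")
  }
  time <- c(times_a, times_b)
  event <- c(events_a, events_b)
  grp <- rep(c("a", "b"), c(length(times_a), length(times_b)))
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ grp)
  stat <- unname(sd_$chisq)
  p <- pchisq(stat, df = 1, lower.tail = FALSE)
  oe <- (sd_$obs / sd_$exp)
  eff <- if (all(is.finite(oe)) && oe[2] > 0) oe[1] / oe[2] else NA_real_
  test_result("logrank", stat, p, eff, length(times_a), length(times_b))
}

#' Hypergeometric over-representation test
#'
#' Upper-tail probability `P(X >= observed)` for `X ~` hypergeometric:
#' drawing `set_size` genes from a universe of `universe` genes of which
#' `band_size` lie in the band of interest.
#'
#' @param observed Number of set genes inside the band.
#' @param set_size Size of the query gene set.
#' @param band_size Number of universe genes in the band.
#' @param universe Universe size.
#' @return A one-row tibble; `effect` is the fold enrichment
#'   `(observed/set_size) / (band_size/universe)`.
#' @export
hypergeom_enrichment <- function(observed, set_size, band_size, universe) {
  counts <- c(observed, set_size, band_size, universe)
  if (anyNA(counts) || any(counts < 0)) {
    abort("counts must be non-negative", class = "tp53_stats_error")
  }
  if (set_size > universe || band_size > universe ||
      observed > min(set_size, band_size) ||
      set_size - observed > universe - band_size) {
    abort("inconsistent counts", class = "tp53_stats_error")
  }
  p <- phyper(observed - 1, band_size, universe - band_size, set_size,
              lower.tail = FALSE)
  eff <- if (set_size == 0) NA_real_ else
    (observed / set_size) / (band_size / universe)
  test_result("hypergeom", observed, p, eff, set_size, band_size)
}
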