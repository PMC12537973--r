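# Median-split stratification, Kaplan-Meier estimation and Mantel-Cox
# log-rank comparison. The estimator and test are computed with the
# 'survival' package; this module fixes the stratification and tie
# conventions and the degenerate-case contracts.

#' Stratify samples at the median of a covariate
#'
#' Splits a cohort into `low` and `high` strata at the median of the given
#' covariate (typically the expression of one query gene). The median is the
#' mean of the two central order statistics for even n. Values strictly
#' below the median go to `low`, strictly above to `high`; values exactly
#' equal to the median go to the stratum named by `ties` (default `"low"`).
#'
#' @param values numeric covariate per sample; names are used as sample ids
#'   when present.
#' @param samples sample identifiers (default `names(values)` or an index).
#' @param ties stratum receiving median-tied samples, `"low"` or `"high"`.
#' @return a `stratified_cohort`: list with `sample`, `stratum` (factor
#'   low/high) and `split_value`.
#' @export
stratify_by_median <- function(values, samples = NULL, ties = c("low", "high")) {
  ties <- match.arg(ties)
  if (length(values) < 2) stop("need at least 2 samples to stratify")
  if (any(!is.finite(values))) stop("covariate values must be finite")
  if (is.null(samples))
    samples <- if (!is.null(names(values))) names(values)
               else as.character(seq_along(values))
  stopifnot(length(samples) == length(values))
  med <- stats::median(values)
  if (all(values == med))
    stop("all covariate values identical; no stratification possible")
  stratum <- ifelse(values < med, "low", ifelse(values > med, "high", ties))
  structure(list(sample = samples,
                 stratum = factor(stratum, levels = c("low", "high")),
                 split_value = med),
            class = "stratified_cohort")
}

#' @export
print.stratified_cohort <- function(x, ...) {
  cat(sprintf("Median-split cohort: %d low / %d high (split at %g)\n",
              sum(x$stratum == "low"), sum(x$stratum == "high"),
              x$split_value))
  invisible(x)
}

#' Kaplan-Meier product-limit estimate
#'
#' S(t) = prod over event times t_i <= t of (1 - d_i/n_i). Subjects censored
#' at an event time are counted at risk for that time (events before
#' censoring, the standard convention).
#'
#' @param times follow-up times, >= 0.
#' @param events event indicator, 1 = event observed, 0 = censored.
#' @return a `km_estimate`: data.frame with one row per distinct event time
#'   (`time`, `n_risk`, `n_event`, `survival`), plus attributes `n` and the
#'   underlying `survfit` object. With no events the table is empty and
#'   S(t) = 1 everywhere.
#' @export
km_estimate <- function(times, events) {
  if (!length(times)) stop("empty input")
  stopifnot(length(times) == length(events))
  if (any(!is.finite(times)) || any(times < 0)) stop("times must be finite and >= 0")
  if (!all(events %in% c(0, 1))) stop("events must be 0 or 1")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  sm <- summary(fit, censored = FALSE)
  out <- data.frame(time = sm$time, n_risk = sm$n.risk,
                    n_event = sm$n.event, survival = sm$surv)
  rownames(out) <- NULL
  attr(out, "n") <- length(times)
  attr(out, "survfit") <- fit
  class(out) <- c("km_estimate", "data.frame")
  out
}

#' Evaluate a Kaplan-Meier estimate at arbitrary times
#'
#' Right-continuous step-function evaluation of S(t); S(t) = 1 before the
#' first event.
#' @param km a `km_estimate`.
#' @param times numeric times.
#' @export
km_survival_at <- function(km, times) {
  stopifnot(inherits(km, "km_estimate"))
  if (!nrow(km)) return(rep(1, length(times)))
  stats::stepfun(km$time, c(1, km$survival), right = FALSE)(times)
}

#' @export
print.km_estimate <- function(x, ...) {
  cat(sprintf("Kaplan-Meier estimate: n = %d, %d distinct event times\n",
              attr(x, "n"), nrow(x)))
  print(as.data.frame(x))
  invisible(x)
}

#' Mantel-Cox log-rank test between two strata
#'
#' Compares the survival experience of the `low` and `high` strata by the
#' usual observed-minus-expected construction summed over distinct event
#' times, with the hypergeometric variance; the statistic is chi-squared
#' with 1 df. When the data carry no information (no events, or one stratum
#' always empty at event times) the contract is `chi_square = 0, p = 1`
#' with a warning.
#'
#' @param cohort a [stratify_by_median()] result (or any object with a
#'   two-level `stratum` factor).
#' @param times,events follow-up time and event indicator, parallel to the
#'   cohort's samples.
#' @return a `logrank_result`: list with `chi_square`, `p_value`, `df`,
#'   `observed`, `expected` (per stratum), `n` (per stratum).
#' @export
logrank_test <- function(cohort, times, events) {
  stopifnot(inherits(cohort, "stratified_cohort"))
  g <- cohort$stratum
  stopifnot(length(times) == length(g), length(events) == length(g))
  if (any(table(g) == 0)) stop("both strata must contain at least 1 subject")
  res <- tryCatch({
    # survdiff warns (NaN) or errors on event-free data; the degenerate
    # contract below supersedes both
    sd <- suppressWarnings(survival::survdiff(survival::Surv(times, events) ~ g))
    v <- sd$var[1, 1]
    if (!is.finite(v) || v <= 0) {
      warning("log-rank test carries no information; returning chi = 0, p = 1")
      list(chi = 0, p = 1, obs = sd$obs, exp = sd$exp)
    } else {
      chi <- (sd$obs[1] - sd$exp[1])^2 / v
      list(chi = chi, p = stats::pchisq(chi, df = 1, lower.tail = FALSE),
           obs = sd$obs, exp = sd$exp)
    }
  }, error = function(e) {
    # survdiff refuses when there are no events at all
    warning("log-rank test carries no information; returning chi = 0, p = 1")
    list(chi = 0, p = 1, obs = c(0, 0), exp = c(0, 0))
  })
  structure(list(chi_square = unname(res$chi), p_value = unname(res$p),
                 df = 1L,
                 observed = stats::setNames(as.numeric(res$obs), levels(g)),
                 expected = stats::setNames(as.numeric(res$exp), levels(g)),
                 n = as.numeric(table(g))),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("Log-rank (Mantel-Cox): chi-square = %.4g on %d df, p = %.4g\n",
              x$chi_square, x$df, x$p_value))
  cat(sprintf("  observed: low %.0f / high %.0f; expected: low %.2f / high %.2f\n",
              x$observed[1], x$observed[2], x$expected[1], x$expected[2]))
  invisible(x)
}

#' Compare a gene's expression between the two strata
#'
#' Welch two-sided t test of the queried gene's expression between the low
#' and high strata of a median-split cohort (e.g. cell-cycle genes across
#' strata defined by another gene's expression).
#'
#' @param values numeric expression values, parallel to the cohort samples
#'   (or named by sample).
#' @param cohort a `stratified_cohort`.
#' @return list with `t_stat` (high minus low), `df`, `p_value`, and the
#'   two group means.
#' @export
compare_expression_between_strata <- function(values, cohort) {
  stopifnot(inherits(cohort, "stratified_cohort"))
  if (!is.null(names(values))) values <- values[cohort$sample]
  stopifnot(length(values) == length(cohort$sample))
  lo <- values[cohort$stratum == "low"]
  hi <- values[cohort$stratum == "high"]
  if (length(lo) < 2 || length(hi) < 2)
    stop("each stratum needs at least 2 samples")
  tt <- welch_t(hi, lo)
  list(t_stat = tt$t_stat, df = tt$df, p_value = tt$p_value,
       mean_low = mean(lo), mean_high = mean(hi))
}

#' Export Kaplan-Meier curves of both strata as a table
#'
#' Convenience wrapper producing the per-stratum step-curve table written by
#' the pipeline (`stratum`, `time`, `n_risk`, `n_event`, `survival`).
#' @param cohort a `stratified_cohort`.
#' @param times,events follow-up data parallel to the cohort samples.
#' @export
km_curves_by_stratum <- function(cohort, times, events) {
  stopifnot(inherits(cohort, "stratified_cohort"))
  do.call(rbind, lapply(levels(cohort$stratum), function(s) {
    idx <- cohort$stratum == s
    km <- km_estimate(times[idx], events[idx])
    if (!nrow(km)) return(NULL)
    data.frame(stratum = s, as.data.frame(km), stringsAsFactors = FALSE)
  }))
}
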