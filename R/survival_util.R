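#' Split a cohort into high/low expression groups
#'
#' By default the expression is z-scored over the whole cohort and subjects
#' with z >= `z_cutoff` are "high". Alternatively an absolute expression
#' cutoff can be supplied (mirroring a manually chosen cutoff based on a
#' bimodal expression distribution), in which case the z-score is bypassed.
#'
#' @param cohort data.frame with an `expression` column.
#' @param z_cutoff z-score cutoff (default 1).
#' @param abs_cutoff optional absolute cutoff overriding the z-score rule.
#' @return the cohort with a `group` factor ("low"/"high"); a degenerate
#'   (empty) group raises a warning and sets attribute `degenerate = TRUE`.
#' @export
dichotomize_expression <- function(cohort, z_cutoff = 1, abs_cutoff = NULL) {
  stopifnot("expression" %in% names(cohort))
  if (any(is.na(cohort$expression))) stop("expression missing for some subjects")
  if (is.null(abs_cutoff)) {
    s <- stats::sd(cohort$expression)
    if (s == 0) stop("expression has zero variance; cannot z-score")
    z <- (cohort$expression - mean(cohort$expression)) / s
    high <- z >= z_cutoff
  } else {
    high <- cohort$expression >= abs_cutoff
  }
  cohort$group <- factor(ifelse(high, "high", "low"),
                         levels = c("low", "high"))
  if (any(table(cohort$group) == 0)) {
    warning("one expression group is empty; log-rank testing not possible")
    attr(cohort, "degenerate") <- TRUE
  }
  cohort
}

#' Kaplan-Meier product-limit estimate
#'
#' Product-limit estimator via \code{survival::survfit}; censored subjects
#' leave the risk set without a step (events processed first at ties).
#' Median survival is the smallest observed time with S(t) <= 0.5, NA when
#' the curve never reaches 0.5.
#'
#' @param time,event survival times and event indicators (TRUE = event), or
#'   a cohort data.frame via `cohort`.
#' @param cohort optional data.frame with `time` and `event` columns.
#' @return list of class `km_curve`: time, surv, n_risk, n_event, median.
#' @export
km_estimate <- function(time = NULL, event = NULL, cohort = NULL) {
  if (!is.null(cohort)) { time <- cohort$time; event <- cohort$event }
  stopifnot(length(time) >= 1, length(time) == length(event), all(time > 0))
  sf <- survival::survfit(survival::Surv(time, as.integer(event)) ~ 1)
  med <- if (any(sf$surv <= 0.5)) min(sf$time[sf$surv <= 0.5]) else NA_real_
  structure(list(time = sf$time, surv = sf$surv, n_risk = sf$n.risk,
                 n_event = sf$n.event, median = med),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("KM curve: %d time points, median survival %s\n",
              length(x$time),
              if (is.na(x$median)) "not reached" else format(x$median)))
  invisible(x)
}

#' Two-group log-rank test
#'
#' Standard observed-minus-expected statistic with hypergeometric variance
#' at each distinct event time (via \code{survival::survdiff}); p from
#' chi-square with 1 degree of freedom.
#'
#' @param cohort data.frame with `time`, `event` and a 2-level `group`.
#' @return list of class `logrank_result`: chisq, df, p_value.
#' @export
logrank_test <- function(cohort) {
  stopifnot(all(c("time", "event", "group") %in% names(cohort)))
  g <- droplevels(factor(cohort$group))
  if (nlevels(g) != 2) stop("need exactly two non-empty groups")
  if (!any(cohort$event)) stop("no events in the cohort")
  sd <- survival::survdiff(
    survival::Surv(time, as.integer(event)) ~ g,
    data = data.frame(time = cohort$time, event = cohort$event, g = g))
  structure(list(chisq = sd$chisq, df = 1L,
                 p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("log-rank: chisq=%.3f (df=%d), p=%.4g\n",
              x$chisq, x$df, x$p_value))
  invisible(x)
}

#' Modified-ellipsoid tumour volume
#'
#' V = a * b^2 / 2 with a the longest diameter and b the perpendicular
#' width (a >= b); inputs given in the wrong order are swapped with a
#' warning.
#'
#' @param a,b caliper measurements (mm); vectorized.
#' @return volume(s) in mm^3.
#' @export
ellipsoid_volume <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (any(a <= 0) || any(b <= 0)) stop("measurements must be positive")
  swap <- a < b
  if (any(swap)) {
    warning("a < b for ", sum(swap), " measurement(s); swapping to a >= b")
    tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  }
  a * b^2 / 2
}
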