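#' Normalize raw viability signal to the vehicle control
#'
#' Viability fraction = raw signal divided by the mean vehicle (dose 0)
#' signal, so the vehicle replicates average exactly 1.
#'
#' @param dose dose vector (nM); 0 marks vehicle wells.
#' @param signal raw viability signal (same length).
#' @return data.frame of class `viability_series`: dose, signal, viability.
#' @export
normalize_viability <- function(dose, signal) {
  stopifnot(length(dose) == length(signal))
  veh <- signal[dose == 0]
  if (!length(veh)) stop("no vehicle (dose 0) wells present")
  m <- mean(veh)
  if (m <= 0) stop("vehicle mean signal must be positive")
  out <- data.frame(dose = dose, signal = signal, viability = signal / m)
  class(out) <- c("viability_series", "data.frame")
  out
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares 4PL fit f(d) = bottom + (top - bottom)/(1 + (d/ED50)^hill)
#' by Levenberg-Marquardt with multi-start over a coarse ED50 x hill grid;
#' replicates at the same dose are averaged before fitting. ED50 is the dose
#' where the fitted curve crosses (top + bottom)/2, which for this model is
#' the ED50 parameter itself. Flat responses are flagged non-determined.
#'
#' @param series a `viability_series` (or data.frame with dose, viability).
#' @param flat_tol response range below which the series is declared flat.
#' @return a [dose_response_fit()]; non-converged fits carry `converged =
#'   FALSE` and `ed50 = NA`.
#' @export
fit_dose_response <- function(series, flat_tol = 0.05) {
  stopifnot(all(c("dose", "viability") %in% names(series)))
  agg <- stats::aggregate(viability ~ dose, data = series, FUN = mean)
  d <- agg$dose
  v <- agg$viability
  if (sum(d > 0) < 4) stop("need at least 4 distinct nonzero doses")
  if (diff(range(v)) < flat_tol)
    return(dose_response_fit(top = max(v), bottom = min(v), ed50 = NA_real_,
                             hill = NA_real_, converged = FALSE))

  dpos <- d[d > 0]
  ed50_grid <- exp(seq(log(min(dpos)), log(max(dpos)), length.out = 5))
  hill_grid <- c(0.5, 1, 2, 4)
  lo <- c(top = min(v) - 0.5, bottom = min(v) - 0.5,
          ed50 = min(dpos) / 100, hill = 0.05)
  hi <- c(top = max(v) + 0.5, bottom = max(v) + 0.5,
          ed50 = max(dpos) * 100, hill = 20)

  best <- NULL
  for (e0 in ed50_grid) for (h0 in hill_grid) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        v ~ bottom + (top - bottom) / (1 + (d / ed50)^hill),
        start = list(top = max(v), bottom = min(v), ed50 = e0, hill = h0),
        lower = lo, upper = hi,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ssr <- sum(stats::resid(fit)^2)
    if (is.null(best) || ssr < best$ssr) best <- list(fit = fit, ssr = ssr)
  }
  if (is.null(best))
    return(dose_response_fit(top = max(v), bottom = min(v), ed50 = NA_real_,
                             hill = NA_real_, converged = FALSE))
  p <- as.list(stats::coef(best$fit))
  if (p$bottom > p$top) p[c("top", "bottom")] <- p[c("bottom", "top")]
  dose_response_fit(top = p$top, bottom = p$bottom, ed50 = p$ed50,
                    hill = p$hill, converged = TRUE,
                    rse = sqrt(best$ssr / max(1, length(v) - 4)))
}

# inverse of the 4PL: dose producing viability y; Inf as y -> bottom,
# 0 as y -> top (for hill > 0)
invert_dose <- function(fit, y) {
  fit$ed50 * ((fit$top - y) / (y - fit$bottom))^(1 / fit$hill)
}

#' Loewe-additivity expected viability for a dose pair
#'
#' Solves for the unique response y with dA/DA(y) + dB/DB(y) = 1, where
#' D(y) is the inverse of each monotherapy's 4PL curve. When one dose is 0
#' this reduces to the other monotherapy; a drug combined with itself obeys
#' the sham-combination principle f(dA + dB). The root is bracketed inside
#' the overlap of the two curves' response ranges; if no overlap exists the
#' nearer bound is returned with attribute `clamped = TRUE`.
#'
#' @param fit_a,fit_b [dose_response_fit()] objects (converged).
#' @param d_a,d_b doses (nM), >= 0.
#' @param tol root-finding tolerance on y.
#' @return expected viability fraction.
#' @export
loewe_expected <- function(fit_a, fit_b, d_a, d_b, tol = 1e-9) {
  fit_a <- as_dose_response_fit(fit_a)
  fit_b <- as_dose_response_fit(fit_b)
  if (d_a < 0 || d_b < 0) stop("doses must be non-negative")
  if (d_a == 0 && d_b == 0) return(predict_viability(fit_a, 0))
  if (d_a == 0) return(predict_viability(fit_b, d_b))
  if (d_b == 0) return(predict_viability(fit_a, d_a))

  eps <- 1e-6
  lo <- max(fit_a$bottom, fit_b$bottom) + eps
  hi <- min(fit_a$top, fit_b$top) - eps
  if (lo >= hi) {
    y <- if (abs(predict_viability(fit_a, d_a) - lo) <
             abs(predict_viability(fit_a, d_a) - hi)) lo else hi
    attr(y, "clamped") <- TRUE
    return(y)
  }
  g <- function(y) d_a / invert_dose(fit_a, y) + d_b / invert_dose(fit_b, y) - 1
  if (g(lo) >= 0) { y <- lo; attr(y, "clamped") <- TRUE; return(y) }
  if (g(hi) <= 0) { y <- hi; attr(y, "clamped") <- TRUE; return(y) }
  stats::uniroot(g, c(lo, hi), tol = tol)$root
}

#' Loewe synergy map for a combination dose matrix
#'
#' Per cell, score = 100 x (Loewe-expected viability fraction - observed
#' fraction): positive scores mean more killing than additivity predicts.
#' The overall score is the mean over combination cells (both doses > 0) and
#' is classified as synergistic (> 10), additive (-10 to 10) or antagonistic
#' (< -10).
#'
#' @param dm a [dose_matrix()] (viability percent).
#' @param fit_a,fit_b monotherapy fits; when NULL they are refit from the
#'   matrix's monotherapy row/column (with the vehicle cell).
#' @return list of class `synergy_map`: `scores` (matrix, NA on monotherapy
#'   axes), `overall`, `classification`, `fit_a`, `fit_b`, `n_missing`.
#' @export
synergy_map <- function(dm, fit_a = NULL, fit_b = NULL) {
  stopifnot(inherits(dm, "dose_matrix"))
  if (is.null(fit_a))
    fit_a <- fit_dose_response(
      data.frame(dose = dm$dose_a, viability = dm$values[, 1] / 100))
  if (is.null(fit_b))
    fit_b <- fit_dose_response(
      data.frame(dose = dm$dose_b, viability = dm$values[1, ] / 100))
  if (!isTRUE(fit_a$converged) || !isTRUE(fit_b$converged))
    stop("monotherapy fit(s) not determined; cannot score synergy")

  scores <- matrix(NA_real_, nrow = nrow(dm$values), ncol = ncol(dm$values),
                   dimnames = dimnames(dm$values))
  for (i in seq_along(dm$dose_a)) for (j in seq_along(dm$dose_b)) {
    if (dm$dose_a[i] > 0 && dm$dose_b[j] > 0 && !is.na(dm$values[i, j])) {
      expected <- loewe_expected(fit_a, fit_b, dm$dose_a[i], dm$dose_b[j])
      scores[i, j] <- 100 * as.numeric(expected) - dm$values[i, j]
    }
  }
  combo <- outer(dm$dose_a > 0, dm$dose_b > 0, "&")
  n_missing <- sum(combo & is.na(dm$values))
  overall <- mean(scores[combo], na.rm = TRUE)
  classification <- if (overall > 10) "synergistic"
    else if (overall < -10) "antagonistic" else "additive"
  structure(list(scores = scores, overall = overall,
                 classification = classification,
                 fit_a = fit_a, fit_b = fit_b, n_missing = n_missing),
            class = "synergy_map")
}

#' @export
print.synergy_map <- function(x, ...) {
  cat(sprintf("Loewe synergy: overall %.2f (%s)\n",
              x$overall, x$classification))
  invisible(x)
}

#' Write a synergy map as JSON (overall, classification, per-cell grid)
#' @param x a `synergy_map`.
#' @param path output file.
#' @export
write_synergy_map <- function(x, path) {
  jsonlite::write_json(
    list(overall = x$overall, classification = x$classification,
         scores = x$scores,
         fit_a = x$fit_a[c("top", "bottom", "ed50", "hill")],
         fit_b = x$fit_b[c("top", "bottom", "ed50", "hill")]),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
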