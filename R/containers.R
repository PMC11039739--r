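#' Guide-level count matrix
#'
#' Integer sgRNA-by-sample counts together with the guide-to-gene map; the
#' screen's raw observable.
#'
#' @param counts non-negative integer matrix, guides in rows, samples in
#'   columns; rownames are guide ids.
#' @param gene_ids character vector mapping each guide (row) to one gene.
#' @return object of class `guide_counts`.
#' @export
guide_counts <- function(counts, gene_ids) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must carry guide ids as rownames")
  if (anyDuplicated(rownames(counts))) stop("duplicate guide ids")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (length(gene_ids) != nrow(counts))
    stop("gene_ids must map every guide to exactly one gene")
  structure(list(counts = counts,
                 guide_ids = rownames(counts),
                 gene_ids = as.character(gene_ids),
                 sample_ids = colnames(counts)),
            class = "guide_counts")
}

#' @export
print.guide_counts <- function(x, ...) {
  cat(sprintf("guide_counts: %d guides (%d genes) x %d samples\n",
              nrow(x$counts), length(unique(x$gene_ids)), ncol(x$counts)))
  invisible(x)
}

#' Expression matrix with phenotype labels
#'
#' @param x non-negative numeric matrix, genes in rows, samples in columns.
#' @param phenotype character vector of per-sample labels (e.g. "mimic" /
#'   "control").
#' @export
expression_matrix <- function(x, phenotype) {
  x <- as.matrix(x)
  if (any(x < 0)) stop("expression values must be non-negative")
  if (length(phenotype) != ncol(x)) stop("every sample must be labeled")
  structure(list(values = x, phenotype = as.character(phenotype),
                 gene_ids = rownames(x), sample_ids = colnames(x)),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s=%d", names(table(x$phenotype)),
                            table(x$phenotype)), collapse = ", ")))
  invisible(x)
}

#' Dose-response 4PL parameter container
#'
#' f(d) = bottom + (top - bottom) / (1 + (d / ed50)^hill); for hill > 0 this
#' is a decreasing viability curve with f(0) = top and f(ed50) =
#' (top + bottom) / 2.
#'
#' @param top,bottom asymptotic viability fractions (bottom <= top).
#' @param ed50 half-maximal dose (nM), > 0.
#' @param hill slope.
#' @param converged logical fit-convergence flag.
#' @param rse residual standard error of the fit, if any.
#' @export
dose_response_fit <- function(top, bottom, ed50, hill,
                              converged = TRUE, rse = NA_real_) {
  if (!is.na(ed50) && ed50 <= 0) stop("ed50 must be > 0")
  if (bottom > top) stop("bottom must not exceed top")
  structure(list(top = top, bottom = bottom, ed50 = ed50, hill = hill,
                 converged = converged, rse = rse),
            class = "dose_response_fit")
}

#' Coerce a plain parameter list to a dose_response_fit
#' @param x list with top, bottom, ed50, hill (or an existing fit).
#' @export
as_dose_response_fit <- function(x) {
  if (inherits(x, "dose_response_fit")) return(x)
  dose_response_fit(x$top, x$bottom, x$ed50, x$hill)
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf("4PL fit: top=%.3f bottom=%.3f ED50=%.4g nM hill=%.3f (%s)\n",
              x$top, x$bottom, x$ed50, x$hill,
              if (isTRUE(x$converged)) "converged" else "NOT determined"))
  invisible(x)
}

#' Evaluate a 4PL dose-response curve
#' @param fit a [dose_response_fit()].
#' @param d dose vector (nM), >= 0.
#' @return predicted viability fraction(s).
#' @export
predict_viability <- function(fit, d) {
  fit <- as_dose_response_fit(fit)
  fit$bottom + (fit$top - fit$bottom) / (1 + (d / fit$ed50)^fit$hill)
}

#' Drug-combination dose matrix
#'
#' Viability percentages on a dose grid; first row and column (dose 0) are
#' the monotherapies and cell (0, 0) the vehicle.
#'
#' @param values viability matrix (percent), rows follow `dose_a`, columns
#'   `dose_b`.
#' @param dose_a,dose_b dose grids (nM) including 0 first.
#' @export
dose_matrix <- function(values, dose_a, dose_b) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == length(dose_a), ncol(values) == length(dose_b))
  if (dose_a[1] != 0 || dose_b[1] != 0)
    stop("dose grids must start at 0 (vehicle / monotherapy axes)")
  dimnames(values) <- list(format(dose_a, trim = TRUE),
                           format(dose_b, trim = TRUE))
  structure(list(values = values, dose_a = dose_a, dose_b = dose_b),
            class = "dose_matrix")
}

#' @export
print.dose_matrix <- function(x, ...) {
  cat(sprintf("dose_matrix: %d x %d grid (nM)\n",
              length(x$dose_a), length(x$dose_b)))
  print(round(x$values, 1))
  invisible(x)
}
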