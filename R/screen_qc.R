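#' Normalize guide counts across samples
#'
#' Default is median-ratio normalization against the geometric-mean
#' pseudo-reference computed over guides with nonzero counts in all samples
#' (robust to composition shifts from strong selection); `total-count`
#' scales every sample to the mean sequencing depth. Size factors are
#' rescaled to geometric mean 1 so normalization is idempotent.
#'
#' @param gc a [guide_counts()] object (or a `normalized_counts` object,
#'   which renormalizes its matrix).
#' @param method "median-ratio" or "total-count".
#' @return object of class `normalized_counts` with elements `norm`
#'   (guides x samples), `size_factors`, `method` and the id vectors.
#' @export
normalize_counts <- function(gc, method = c("median-ratio", "total-count")) {
  method <- match.arg(method)
  counts <- if (inherits(gc, "normalized_counts")) gc$norm else gc$counts
  if (ncol(counts) < 2) stop("need at least 2 samples to normalize")
  zero_samples <- colnames(counts)[colSums(counts) == 0]
  if (length(zero_samples))
    stop("sample(s) with all-zero counts: ",
         paste(zero_samples, collapse = ", "))

  if (method == "total-count") {
    depth <- colSums(counts)
    sf <- depth / mean(depth)
  } else {
    pos <- rowSums(counts > 0) == ncol(counts)
    if (!any(pos)) stop("no guide has nonzero counts in every sample")
    ref <- exp(rowMeans(log(counts[pos, , drop = FALSE])))
    sf <- apply(counts[pos, , drop = FALSE], 2, function(col)
      stats::median(col / ref))
  }
  sf <- sf / exp(mean(log(sf)))
  norm <- sweep(counts, 2, sf, "/")
  structure(list(norm = norm, size_factors = sf, method = method,
                 guide_ids = rownames(counts), gene_ids = gc$gene_ids,
                 sample_ids = colnames(counts)),
            class = "normalized_counts")
}

#' Sample-level QC report for a normalized screen
#'
#' Reproduces the standard pooled-screen QC battery on log-transformed
#' normalized counts: per-sample distribution summaries (quartiles, zero
#' fraction), CDF curves, PCA coordinates (first 3 components, samples as
#' observations and guides as centered features), and the pairwise Pearson
#' correlation matrix.
#'
#' @param norm a `normalized_counts` object.
#' @param design optional screen design, stored for plotting/grouping.
#' @param pseudocount added before the log transform (default 1).
#' @param cdf_points number of grid points kept per CDF curve.
#' @return object of class `qc_report`.
#' @export
qc_report <- function(norm, design = NULL, pseudocount = 1, cdf_points = 100) {
  stopifnot(inherits(norm, "normalized_counts"), pseudocount > 0)
  x <- norm$norm
  lx <- log2(x + pseudocount)

  summaries <- t(apply(x, 2, function(col) {
    q <- stats::quantile(col, c(0.25, 0.5, 0.75))
    c(q25 = unname(q[1]), median = unname(q[2]), q75 = unname(q[3]),
      zero_fraction = mean(col == 0))
  }))

  grid <- seq(min(lx), max(lx), length.out = cdf_points)
  cdf <- vapply(seq_len(ncol(lx)), function(j) stats::ecdf(lx[, j])(grid),
                numeric(cdf_points))
  colnames(cdf) <- colnames(lx)

  pca <- NULL
  warnings <- character(0)
  if (ncol(lx) >= 3) {
    pc <- stats::prcomp(t(lx), center = TRUE, scale. = FALSE)
    k <- min(3, ncol(pc$x))
    pca <- list(coords = pc$x[, seq_len(k), drop = FALSE],
                var_explained = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)])
  } else {
    warnings <- "fewer than 3 samples: PCA skipped"
  }

  pearson <- stats::cor(lx, method = "pearson")

  structure(list(summaries = summaries,
                 cdf = list(grid = grid, curves = cdf),
                 pca = pca, pearson = pearson,
                 pseudocount = pseudocount,
                 normalization = norm$method,
                 design = design, warnings = warnings),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report: %d samples, %s normalization, pseudocount %g\n",
              nrow(x$summaries), x$normalization, x$pseudocount))
  cat(sprintf("  median Pearson r (off-diagonal): %.3f\n",
              stats::median(x$pearson[lower.tri(x$pearson)])))
  if (length(x$warnings)) cat("  warnings:", x$warnings, "\n")
  invisible(x)
}

#' Serialize a QC report to JSON
#' @param report a `qc_report`.
#' @param path output JSON file.
#' @export
write_qc_report <- function(report, path) {
  out <- list(
    normalization = report$normalization,
    pseudocount = report$pseudocount,
    summaries = as.data.frame(report$summaries),
    pearson = report$pearson,
    pca = if (!is.null(report$pca))
      list(coords = as.data.frame(report$pca$coords),
           var_explained = report$pca$var_explained),
    warnings = report$warnings
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
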