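# Target-triage funnel: prediction-score cutoff -> downregulated in both
# cell lines -> designated-pathway membership -> percent-downregulation
# validation. Each stage is a set operation; the funnel is monotone
# non-increasing after the prediction/downregulation join.

#' Filter target predictions by context++ score
#'
#' Keeps genes whose cumulative weighted context++ score is at or below the
#' cutoff (more negative = stronger predicted repression; the cutoff is
#' inclusive).
#'
#' @param preds data.frame with columns `gene` and `score`.
#' @param cutoff score cutoff (default -0.01).
#' @return character vector of predicted target genes.
#' @export
filter_predictions <- function(preds, cutoff = -0.01) {
  stopifnot(all(c("gene", "score") %in% names(preds)))
  unique(preds$gene[preds$score <= cutoff])
}

#' Predicted genes downregulated in both cell lines
#'
#' A gene passes when it is in the predicted set and its percent change is
#' strictly below `down_threshold` in both differential results; genes
#' missing from either result count as not downregulated.
#'
#' @param de_a,de_b `differential_result` data.frames for the two cell
#'   lines.
#' @param predicted character vector of predicted target genes.
#' @param down_threshold percent-change cutoff (default -20, i.e. more than
#'   20 percent down).
#' @return character vector (sorted).
#' @export
intersect_downregulated <- function(de_a, de_b, predicted,
                                    down_threshold = -20) {
  down_in <- function(de) {
    ok <- de$defined & !is.na(de$percent_change) &
      de$percent_change < down_threshold
    de$gene_id[ok]
  }
  sort(intersect(predicted, intersect(down_in(de_a), down_in(de_b))))
}

#' Keep genes belonging to at least one designated pathway
#'
#' @param genes character vector.
#' @param pathway_map list with `members` (named list of gene vectors) and
#'   `designated` (pathway ids counting as cancer-associated), as returned
#'   by [read_pathway_map()].
#' @return character vector (sorted); genes absent from the map are treated
#'   as pathway-less and reported in attribute `n_unmapped`.
#' @export
pathway_filter <- function(genes, pathway_map) {
  desig <- pathway_map$members[pathway_map$designated]
  in_designated <- as.character(unique(unlist(desig, use.names = FALSE)))
  mapped <- as.character(unique(unlist(pathway_map$members,
                                       use.names = FALSE)))
  out <- sort(intersect(genes, in_designated))
  attr(out, "n_unmapped") <- sum(!genes %in% mapped)
  out
}

#' Validation filter on measured fold changes
#'
#' Keeps genes downregulated by strictly more than `min_down_fraction` of
#' their original expression, i.e. fold change < 1 - min_down_fraction on
#' the linear scale (1 = unchanged).
#'
#' @param folds named numeric vector of linear fold changes (e.g. from
#'   [delta_delta_ct()]).
#' @param min_down_fraction required downregulation fraction (default 0.2).
#' @return character vector of gene names (sorted).
#' @export
validation_filter <- function(folds, min_down_fraction = 0.2) {
  stopifnot(!is.null(names(folds)))
  sort(names(folds)[folds < 1 - min_down_fraction])
}

#' Run the full target-triage funnel
#'
#' @param preds prediction table (gene, score).
#' @param de_a,de_b differential results for the two cell lines.
#' @param pathway_map optional pathway map; NULL skips the pathway stage.
#' @param folds optional named fold-change vector; NULL skips validation.
#' @param cutoff prediction-score cutoff.
#' @param down_threshold microarray-stage percent-change cutoff.
#' @param min_down_fraction validation-stage downregulation fraction.
#' @return list of class `triage_result` with per-stage gene sets and a
#'   `counts` summary.
#' @export
triage_funnel <- function(preds, de_a, de_b, pathway_map = NULL, folds = NULL,
                          cutoff = -0.01, down_threshold = -20,
                          min_down_fraction = 0.2) {
  predicted <- filter_predictions(preds, cutoff)
  down_a <- sort(intersect(predicted, intersect_downregulated(
    de_a, de_a, predicted, down_threshold)))
  down_b <- sort(intersect(predicted, intersect_downregulated(
    de_b, de_b, predicted, down_threshold)))
  both <- intersect_downregulated(de_a, de_b, predicted, down_threshold)
  pw <- if (!is.null(pathway_map)) pathway_filter(both, pathway_map) else both
  validated <- if (!is.null(folds)) {
    intersect(pw, validation_filter(folds, min_down_fraction))
  } else pw
  stages <- list(predicted = sort(predicted), down_a = down_a,
                 down_b = down_b, intersection = both,
                 pathway_filtered = as.character(pw),
                 validated = sort(validated))
  structure(list(stages = stages,
                 counts = vapply(stages, length, integer(1))),
            class = "triage_result")
}

#' @export
print.triage_result <- function(x, ...) {
  cat("triage funnel:\n")
  for (nm in names(x$counts))
    cat(sprintf("  %-17s %d\n", nm, x$counts[[nm]]))
  invisible(x)
}

#' Write a triage result as JSON with per-stage member lists and counts
#' @param x a `triage_result`.
#' @param path output file.
#' @export
write_triage_result <- function(x, path) {
  jsonlite::write_json(list(counts = as.list(x$counts), stages = x$stages),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
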