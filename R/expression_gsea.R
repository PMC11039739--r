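#' Quantile-normalize an expression matrix
#'
#' After normalization each sample's sorted values equal the cross-sample
#' mean of sorted values; within-sample ranks are preserved and ties receive
#' the mean of the reference values they span. Delegates to
#' \code{limma::normalizeQuantiles}.
#'
#' @param em an [expression_matrix()] (or plain matrix).
#' @return same type as the input, quantile-normalized.
#' @export
quantile_normalize <- function(em) {
  is_em <- inherits(em, "expression_matrix")
  x <- if (is_em) em$values else as.matrix(em)
  if (ncol(x) < 2) {
    warning("single sample: quantile normalization is the identity")
    return(em)
  }
  qn <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(qn) <- dimnames(x)
  if (is_em) expression_matrix(qn, phenotype = em$phenotype) else qn
}

#' Mimic-vs-control differential expression
#'
#' Per gene: control and treated group means, their ratio, percent change
#' 100 * (treated - control) / control, direction, and an `altered` flag
#' when |percent change| strictly exceeds `altered_threshold`. Genes with a
#' zero control mean get an undefined ratio, are flagged, and are excluded
#' from percent-change ranking.
#'
#' @param em an [expression_matrix()] whose phenotype labels contain
#'   `control_label` and `treated_label`.
#' @param altered_threshold percent-change magnitude for the `altered` flag
#'   (default 20).
#' @param control_label,treated_label phenotype labels of the two arms.
#' @return data.frame of class `differential_result`: gene_id, control_mean,
#'   treated_mean, ratio, log2_ratio, percent_change, direction, altered,
#'   defined.
#' @export
differential_expression <- function(em, altered_threshold = 20,
                                    control_label = "control",
                                    treated_label = "mimic") {
  stopifnot(inherits(em, "expression_matrix"))
  if (!all(c(control_label, treated_label) %in% em$phenotype))
    stop("both phenotype groups must be present")
  ctrl <- rowMeans(em$values[, em$phenotype == control_label, drop = FALSE])
  trt <- rowMeans(em$values[, em$phenotype == treated_label, drop = FALSE])
  defined <- ctrl > 0
  ratio <- ifelse(defined, trt / ctrl, NA_real_)
  pct <- ifelse(defined, 100 * (trt - ctrl) / ctrl, NA_real_)
  out <- data.frame(
    gene_id = em$gene_ids,
    control_mean = ctrl, treated_mean = trt,
    ratio = ratio, log2_ratio = log2(ratio), percent_change = pct,
    direction = ifelse(!defined, NA_character_,
                       ifelse(pct < 0, "down", ifelse(pct > 0, "up", "flat"))),
    altered = defined & abs(pct) > altered_threshold,
    defined = defined, row.names = NULL)
  class(out) <- c("differential_result", "data.frame")
  out
}

#' Relative quantification by the comparative Ct method
#'
#' Per sample, delta-Ct = Ct(target) - Ct(reference); delta-delta-Ct is the
#' mean delta-Ct of the treated group minus the control group, and the fold
#' change is 2^(-delta-delta-Ct). A per-sample plate offset added to all Ct
#' values cancels.
#'
#' @param ct data.frame with columns gene, sample, group, ct.
#' @param reference_gene housekeeping gene (e.g. GAPDH) present in every
#'   sample.
#' @param control_group group label of the calibrator arm.
#' @return data.frame: gene, ddct, fold (one row per non-reference gene).
#' @export
delta_delta_ct <- function(ct, reference_gene = "GAPDH",
                           control_group = "control") {
  stopifnot(all(c("gene", "sample", "group", "ct") %in% names(ct)))
  if (any(ct$ct <= 0)) stop("Ct values must be positive")
  samples <- unique(ct$sample)
  ref <- ct[ct$gene == reference_gene, ]
  missing_ref <- setdiff(samples, ref$sample)
  if (length(missing_ref))
    stop("reference gene absent in sample(s): ",
         paste(missing_ref, collapse = ", "))
  if (!control_group %in% ct$group) stop("control group not found")
  ref_ct <- stats::setNames(ref$ct, ref$sample)

  targets <- ct[ct$gene != reference_gene, ]
  targets$dct <- targets$ct - ref_ct[targets$sample]
  out <- do.call(rbind, lapply(split(targets, targets$gene), function(g) {
    is_ctrl <- g$group == control_group
    ddct <- mean(g$dct[!is_ctrl]) - mean(g$dct[is_ctrl])
    data.frame(gene = g$gene[1], ddct = ddct, fold = 2^(-ddct))
  }))
  rownames(out) <- NULL
  out
}

#' Build a ranked gene list from differential-expression results
#'
#' @param d a `differential_result`.
#' @param metric "log2_ratio" (default) or "percent_change".
#' @return data.frame of class `ranked_gene_list` in descending score order
#'   (ties broken by gene id), with the number of excluded (undefined) genes
#'   in attribute `n_excluded`.
#' @export
make_ranked_list <- function(d, metric = c("log2_ratio", "percent_change")) {
  metric <- match.arg(metric)
  keep <- d$defined & is.finite(d[[metric]])
  out <- data.frame(gene_id = d$gene_id[keep], score = d[[metric]][keep])
  out <- out[order(-out$score, out$gene_id), ]
  rownames(out) <- NULL
  attr(out, "n_excluded") <- sum(!keep)
  class(out) <- c("ranked_gene_list", "data.frame")
  out
}

# Weighted Kolmogorov-Smirnov running-sum enrichment score.
# scores: ranking scores in list order (descending); hit_idx: positions of
# set members. Hits step up by |score|^p / sum over hits; misses step down by
# 1 / (N - Nh). ES is the running-sum value of largest magnitude (the maximum
# deviation from zero; ties resolved toward the positive extreme).
gsea_es_core <- function(scores, hit_idx, weight_p = 1) {
  N <- length(scores)
  k <- length(hit_idx)
  hit_idx <- sort(hit_idx)
  w <- abs(scores[hit_idx])^weight_p
  sw <- sum(w)
  w <- if (sw > 0) w / sw else rep(1 / k, k)
  cw <- cumsum(w)
  miss_before <- (hit_idx - seq_len(k)) / (N - k)
  after <- cw - miss_before          # running sum just after each hit
  before <- c(0, cw[-k]) - miss_before  # just before each hit
  pos <- max(after)
  neg <- min(before)
  # positive extreme wins exact ties; tolerance guards float noise in the
  # running sums
  if (pos >= -neg - 1e-12) pos else neg
}

#' Gene-set enrichment score with permutation NES and nominal p
#'
#' Computes the weighted running-sum enrichment score over a ranked gene
#' list: members of the set increment the sum by |score|^weight_p
#' (normalized over the set), non-members decrement it by 1/(N - Nh), and ES
#' is the maximum deviation from zero. Significance comes from gene-set
#' permutation: random sets of the same size drawn under the seed. NES is ES
#' divided by the mean of the same-sign permutation ESs, and the nominal p
#' is the same-sign permutation tail fraction.
#'
#' @param ranked a `ranked_gene_list` (gene_id, score, descending).
#' @param gene_set character vector of member gene ids.
#' @param weight_p weighting exponent (0 = classic KS, 1 = weighted;
#'   default 1).
#' @param n_perm number of gene-set permutations (default 1000).
#' @param seed integer seed for the permutations.
#' @param set_name label carried into the result.
#' @return list of class `enrichment_result`: set_name, es, nes, p_value,
#'   direction, n_hits, n_perm.
#' @export
gsea_enrichment <- function(ranked, gene_set, weight_p = 1, n_perm = 1000,
                            seed = 1L, set_name = "gene_set") {
  stopifnot(inherits(ranked, "data.frame"),
            all(c("gene_id", "score") %in% names(ranked)))
  N <- nrow(ranked)
  hit_idx <- which(ranked$gene_id %in% gene_set)
  k <- length(hit_idx)
  if (k == 0) stop("gene set has no overlap with the ranked list")
  if (k == N) stop("gene set covers the entire ranked list")

  es <- gsea_es_core(ranked$score, hit_idx, weight_p)
  perm_es <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_perm), function(i)
      gsea_es_core(ranked$score, sample.int(N, k), weight_p), numeric(1))
  })

  same_sign <- if (es >= 0) perm_es[perm_es >= 0] else perm_es[perm_es < 0]
  if (length(same_sign)) {
    p <- mean(abs(same_sign) >= abs(es))
    nes <- es / mean(abs(same_sign))
  } else {
    p <- 1 / (n_perm + 1)
    nes <- sign(es) * Inf
  }
  structure(list(set_name = set_name, es = es, nes = nes, p_value = p,
                 direction = if (es >= 0) "positive" else "negative",
                 n_hits = k, n_perm = n_perm),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("%s: ES=%.3f NES=%.3f p=%.4g (%d genes, %d permutations)\n",
              x$set_name, x$es, x$nes, x$p_value, x$n_hits, x$n_perm))
  invisible(x)
}

#' Run GSEA over a gene-set collection
#'
#' @param ranked a `ranked_gene_list`.
#' @param collection named list of gene sets (e.g. from [read_gmt()]).
#' @inheritParams gsea_enrichment
#' @param min_overlap sets overlapping the list by fewer genes are skipped.
#' @return data.frame with one row per tested set: set_name, es, nes,
#'   p_value, direction, n_hits.
#' @export
gsea_collection <- function(ranked, collection, weight_p = 1, n_perm = 1000,
                            seed = 1L, min_overlap = 3) {
  rows <- lapply(names(collection), function(nm) {
    ov <- sum(ranked$gene_id %in% collection[[nm]])
    if (ov < min_overlap || ov == nrow(ranked)) return(NULL)
    r <- gsea_enrichment(ranked, collection[[nm]], weight_p = weight_p,
                         n_perm = n_perm, seed = seed, set_name = nm)
    data.frame(set_name = nm, es = r$es, nes = r$nes, p_value = r$p_value,
               direction = r$direction, n_hits = r$n_hits)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame())
  out[order(out$p_value), ]
}
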