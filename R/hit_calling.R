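#' Hit-calling configuration
#'
#' Thresholds for the fold-difference (FD) hit caller: a guide passes in a
#' screen when its FD versus vehicle strictly exceeds `fd_threshold`; a gene
#' is enriched in that screen when at least `min_guides_passing` of its
#' guides pass ("multiple sgRNAs"); a gene is a hit when enriched for every
#' drug at either dose, and a top hit when enriched in at least
#' `recurrence_min` screens.
#'
#' @param fd_threshold strict FD cutoff (default 1.8).
#' @param min_guides_passing guides required per gene (default 2).
#' @param pseudocount added to both means before the ratio (default 1).
#' @param recurrence_min screens required for `is_top` (default 3).
#' @export
hit_call_config <- function(fd_threshold = 1.8, min_guides_passing = 2,
                            pseudocount = 1, recurrence_min = 3) {
  stopifnot(fd_threshold > 0, min_guides_passing >= 1, pseudocount >= 0,
            recurrence_min >= 1)
  structure(list(fd_threshold = fd_threshold,
                 min_guides_passing = as.integer(min_guides_passing),
                 pseudocount = pseudocount,
                 recurrence_min = as.integer(recurrence_min)),
            class = "hit_call_config")
}

#' Per-guide fold differences versus vehicle
#'
#' For every screen (drug x dose) the FD of a guide is
#' (mean normalized abundance under drug + c) / (mean under vehicle + c),
#' with replicate means taken after normalization and the vehicle drawn from
#' the same screen batch.
#'
#' @param norm a `normalized_counts` object.
#' @param design screen design with columns sample_id, drug, dose; vehicle
#'   rows have drug == "vehicle".
#' @param pseudocount c above (default 1).
#' @return data.frame of class `guide_enrichment`: guide_id, gene_id, screen,
#'   fd, log2_fd.
#' @export
guide_fold_differences <- function(norm, design, pseudocount = 1) {
  stopifnot(inherits(norm, "normalized_counts"))
  if (!all(norm$sample_ids %in% design$sample_id))
    stop("design is missing samples present in the count matrix")
  veh <- design$sample_id[design$drug == "vehicle"]
  if (!length(veh)) stop("design contains no vehicle sample")
  drugs <- design[design$drug != "vehicle", , drop = FALSE]
  if (!nrow(drugs)) stop("design contains no drug sample")

  mean_veh <- rowMeans(norm$norm[, veh, drop = FALSE])
  screens <- unique(drugs[, c("drug", "dose")])
  out <- do.call(rbind, lapply(seq_len(nrow(screens)), function(i) {
    sel <- drugs$sample_id[drugs$drug == screens$drug[i] &
                             drugs$dose == screens$dose[i]]
    mean_drug <- rowMeans(norm$norm[, sel, drop = FALSE])
    fd <- (mean_drug + pseudocount) / (mean_veh + pseudocount)
    data.frame(guide_id = norm$guide_ids, gene_id = norm$gene_ids,
               drug = screens$drug[i], dose = screens$dose[i],
               screen = sprintf("%s@%s", screens$drug[i],
                                format(screens$dose[i], trim = TRUE)),
               fd = fd, log2_fd = log2(fd), row.names = NULL)
  }))
  class(out) <- c("guide_enrichment", "data.frame")
  out
}

#' Gene-level enrichment calls per screen
#'
#' A gene is enriched in a screen when the number of its guides with
#' FD strictly above the threshold reaches `min_guides_passing`; guides at
#' exactly the threshold do not pass.
#'
#' @param enrich a `guide_enrichment` data.frame.
#' @param cfg a [hit_call_config()].
#' @return data.frame: gene_id, drug, dose, screen, n_guides, n_passing,
#'   enriched.
#' @export
call_gene_hits <- function(enrich, cfg = hit_call_config()) {
  stopifnot(inherits(cfg, "hit_call_config"))
  if (any(is.na(enrich$gene_id))) stop("every guide must map to a gene")
  passing <- enrich$fd > cfg$fd_threshold
  agg <- stats::aggregate(cbind(n_guides = rep(1L, nrow(enrich)),
                                n_passing = as.integer(passing)),
                          by = list(gene_id = enrich$gene_id,
                                    drug = enrich$drug, dose = enrich$dose,
                                    screen = enrich$screen),
                          FUN = sum)
  agg$enriched <- agg$n_passing >= cfg$min_guides_passing
  agg <- agg[order(agg$screen, agg$gene_id), ]
  rownames(agg) <- NULL
  class(agg) <- c("gene_hit_call", "data.frame")
  agg
}

#' Cross-screen hit intersection and recurrence ranking
#'
#' Default rule: a gene is a hit when, for every drug in the design, it is
#' enriched at at least one of that drug's doses (both drugs, either dose).
#' A gene is `is_top` when enriched in at least `recurrence_min` screens.
#'
#' @param calls output of [call_gene_hits()].
#' @param cfg a [hit_call_config()].
#' @param drugs drugs the rule quantifies over; defaults to every drug in
#'   `calls`. Unknown labels are an error.
#' @return data.frame: gene_id, screens (comma-joined membership string),
#'   n_screens, is_hit, is_top.
#' @export
intersect_screens <- function(calls, cfg = hit_call_config(), drugs = NULL) {
  all_drugs <- unique(calls$drug)
  if (is.null(drugs)) drugs <- all_drugs
  if (!all(drugs %in% all_drugs))
    stop("rule references unknown screen drug(s): ",
         paste(setdiff(drugs, all_drugs), collapse = ", "))
  enr <- calls[calls$enriched, , drop = FALSE]
  genes <- sort(unique(calls$gene_id))
  memb <- split(enr$screen, factor(enr$gene_id, levels = genes))
  drug_of <- split(enr$drug, factor(enr$gene_id, levels = genes))
  n_screens <- lengths(memb)
  is_hit <- vapply(drug_of, function(d) all(drugs %in% d), logical(1))
  out <- data.frame(gene_id = genes,
                    screens = vapply(memb, paste, "", collapse = ","),
                    n_screens = as.integer(n_screens),
                    is_hit = unname(is_hit),
                    is_top = unname(n_screens >= cfg$recurrence_min),
                    row.names = NULL)
  class(out) <- c("hit_intersection", "data.frame")
  out
}

#' Cluster gene enrichment profiles across screens
#'
#' Lloyd's k-means with k-means++ seeding on the genes x screens matrix of
#' log2 fold differences; deterministic given the seed.
#'
#' @param profile numeric matrix, genes in rows, screens in columns
#'   (typically log2 FD); or a `guide_enrichment` data.frame, which is
#'   aggregated to gene-level mean log2 FD first.
#' @param k number of clusters (default 4, one per screen condition).
#' @param seed integer seed.
#' @param n_start k-means++ restarts; the lowest-WCSS solution is kept.
#' @param max_iter Lloyd iteration cap.
#' @return list of class `cluster_assignment`: `cluster` (named integer
#'   vector), `k`, `wcss`, `seed`, `centers`.
#' @export
cluster_profiles <- function(profile, k = 4, seed = 1L, n_start = 10,
                             max_iter = 100) {
  if (inherits(profile, "guide_enrichment")) {
    agg <- stats::aggregate(log2_fd ~ gene_id + screen, data = profile,
                            FUN = mean)
    profile <- stats::xtabs(log2_fd ~ gene_id + screen, data = agg)
    profile <- matrix(as.numeric(profile), nrow = nrow(profile),
                      dimnames = dimnames(profile))
  }
  profile <- as.matrix(profile)
  if (k < 2) stop("k must be at least 2")
  if (k > nrow(profile)) stop("k exceeds the number of genes")
  km <- withr::with_seed(as.integer(seed), {
    best <- NULL
    for (s in seq_len(n_start)) {
      centers <- kmeanspp_init(profile, k)
      cand <- suppressWarnings(
        stats::kmeans(profile, centers = centers, iter.max = max_iter,
                      algorithm = "Lloyd"))
      if (is.null(best) || cand$tot.withinss < best$tot.withinss)
        best <- cand
    }
    best
  })
  structure(list(cluster = stats::setNames(km$cluster, rownames(profile)),
                 k = k, wcss = km$tot.withinss, seed = as.integer(seed),
                 centers = km$centers),
            class = "cluster_assignment")
}

# k-means++ seeding: first center uniform, then proportional to squared
# distance to the nearest chosen center.
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1)
  d2 <- rowSums(sweep(x, 2, x[idx[1], ], "-")^2)
  for (i in seq_len(k - 1)) {
    if (all(d2 == 0)) {
      idx[i + 1] <- sample.int(n, 1)
    } else {
      idx[i + 1] <- sample.int(n, 1, prob = d2)
    }
    d2 <- pmin(d2, rowSums(sweep(x, 2, x[idx[i + 1], ], "-")^2))
  }
  x[idx, , drop = FALSE]
}

#' Rank guides by fold difference for a waterfall panel
#'
#' @param enrich a `guide_enrichment` data.frame.
#' @param screen screen label ("drug@dose").
#' @return data.frame ordered by descending FD (ties broken by guide id):
#'   rank, guide_id, gene_id, fd, log2_fd.
#' @export
rank_waterfall <- function(enrich, screen) {
  sel <- enrich[enrich$screen == screen, , drop = FALSE]
  if (!nrow(sel)) stop("unknown screen: ", screen)
  sel <- sel[order(-sel$fd, sel$guide_id), ]
  sel$rank <- seq_len(nrow(sel))
  rownames(sel) <- NULL
  sel[, c("rank", "guide_id", "gene_id", "fd", "log2_fd")]
}
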