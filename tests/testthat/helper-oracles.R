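# Independent brute-force oracles. Each recomputes its quantity from the
# definition with plain loops, deliberately sharing no code with the package.

# Full running-sum GSEA enrichment score: walk the ranked list position by
# position, return the running-sum value of largest magnitude (positive
# extreme wins ties).
oracle_es <- function(scores, hit_positions, weight_p = 0) {
  N <- length(scores)
  is_hit <- seq_len(N) %in% hit_positions
  w <- abs(scores)^weight_p
  nr <- sum(w[is_hit])
  rs <- numeric(N)
  run <- 0
  for (i in seq_len(N)) {
    run <- run + if (is_hit[i]) {
      if (nr > 0) w[i] / nr else 1 / sum(is_hit)
    } else {
      -1 / (N - sum(is_hit))
    }
    rs[i] <- run
  }
  pos <- max(rs)
  neg <- min(rs)
  if (pos >= -neg - 1e-12) pos else neg  # positive extreme wins exact ties
}

# Median-of-ratios size factors per the definition: geometric-mean reference
# over guides nonzero in all samples, per-sample median of linear ratios,
# rescaled to geometric mean 1.
oracle_median_ratio_sf <- function(counts) {
  keep <- which(apply(counts, 1, function(r) all(r > 0)))
  ref <- numeric(length(keep))
  for (i in seq_along(keep))
    ref[i] <- prod(counts[keep[i], ])^(1 / ncol(counts))
  sf <- numeric(ncol(counts))
  for (j in seq_len(ncol(counts)))
    sf[j] <- median(counts[keep, j] / ref)
  sf / prod(sf)^(1 / length(sf))
}

# Pearson correlation from the definitional formula.
oracle_pearson <- function(x, y) {
  n <- length(x)
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# Two-group log-rank statistic from the observed/expected/hypergeometric-
# variance tabulation at each distinct event time.
oracle_logrank_chisq <- function(time, event, group) {
  group <- as.integer(factor(group))
  o_minus_e <- 0
  v <- 0
  for (t in sort(unique(time[event]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == 1)
    d <- sum(event & time == t)
    d1 <- sum(event & time == t & group == 1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1)
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# Kaplan-Meier product-limit values after each distinct time, by hand.
oracle_km <- function(time, event) {
  ts <- sort(unique(time))
  s <- 1
  surv <- numeric(length(ts))
  for (i in seq_along(ts)) {
    n_risk <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event)
    s <- s * (1 - d / n_risk)
    surv[i] <- s
  }
  list(time = ts, surv = surv)
}

# Exhaustive minimum within-cluster sum of squares over all 2-partitions.
oracle_min_wcss_k2 <- function(x) {
  n <- nrow(x)
  best <- Inf
  for (mask in 1:(2^(n - 1) - 1)) {
    idx <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
    if (!any(idx) || all(idx)) next
    wcss <- 0
    for (part in list(x[idx, , drop = FALSE], x[!idx, , drop = FALSE])) {
      ctr <- colMeans(part)
      wcss <- wcss + sum(sweep(part, 2, ctr, "-")^2)
    }
    best <- min(best, wcss)
  }
  best
}

# Loewe expected response by plain bisection on dA/DA(y) + dB/DB(y) = 1.
oracle_loewe_bisect <- function(fa, fb, da, db, iters = 80) {
  inv <- function(f, y) f$ed50 * ((f$top - y) / (y - f$bottom))^(1 / f$hill)
  lo <- max(fa$bottom, fb$bottom) + 1e-9
  hi <- min(fa$top, fb$top) - 1e-9
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (da / inv(fa, mid) + db / inv(fb, mid) - 1 > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small helper: build a normalized_counts object directly from a matrix so
# hit-calling arithmetic can be tested on hand-picked abundances.
make_norm <- function(m, gene_ids) {
  structure(list(norm = m, size_factors = rep(1, ncol(m)),
                 method = "manual", guide_ids = rownames(m),
                 gene_ids = gene_ids, sample_ids = colnames(m)),
            class = "normalized_counts")
}

make_design <- function(sample_ids, drug, dose) {
  data.frame(sample_id = sample_ids, drug = drug, dose = dose,
             replicate = seq_along(sample_ids))
}
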