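test_that("quantile normalization matches the two-sample closed form", {
  m <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
  qn <- quantile_normalize(m)
  expect_equal(qn[, "a"], c(2.5, 3.5, 4.5), ignore_attr = TRUE)
  expect_equal(qn[, "b"], c(2.5, 3.5, 4.5), ignore_attr = TRUE)
})

test_that("quantile normalization equalizes sorted values and is idempotent", {
  set.seed(31)
  m <- matrix(rlnorm(100, 3, 1), nrow = 20, ncol = 5,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:5)))
  qn <- quantile_normalize(m)
  sorted <- apply(qn, 2, sort)
  expect_lt(max(abs(sorted - sorted[, 1])), 1e-12)
  expect_equal(quantile_normalize(qn), qn, tolerance = 1e-12)
  # identical distributions are a fixed point
  m2 <- cbind(a = c(5, 1, 9), b = c(9, 5, 1))
  expect_equal(quantile_normalize(m2), m2, ignore_attr = TRUE)
  expect_warning(quantile_normalize(m[, 1, drop = FALSE]), "single sample")
})

test_that("differential expression reports percent change and direction", {
  m <- cbind(c1 = c(100, 50, 10), c2 = c(100, 50, 10),
             t1 = c(70, 50, 0), t2 = c(70, 50, 0))
  rownames(m) <- c("gA", "gB", "gC")
  em <- expression_matrix(m, phenotype = c("control", "control",
                                           "mimic", "mimic"))
  de <- differential_expression(em)
  expect_equal(de$percent_change[1], -30)
  expect_equal(de$direction[1], "down")
  expect_true(de$altered[1])
  expect_equal(de$percent_change[2], 0)
  expect_false(de$altered[2])
  expect_equal(de$ratio[3], 0)
})

test_that("a zero control mean is flagged and excluded from ranking", {
  m <- cbind(c1 = c(0, 10), t1 = c(5, 20))
  rownames(m) <- c("gZero", "gOk")
  de <- differential_expression(expression_matrix(m, c("control", "mimic")))
  expect_false(de$defined[1])
  expect_true(is.na(de$ratio[1]))
  rl <- make_ranked_list(de)
  expect_equal(attr(rl, "n_excluded"), 1)
  expect_false("gZero" %in% rl$gene_id)
})

test_that("ranked lists are descending with id tie-breaks", {
  de <- data.frame(gene_id = c("A", "B", "C"),
                   percent_change = c(-30, 10, 0),
                   log2_ratio = c(-0.515, 0.138, 0),
                   defined = TRUE)
  rl <- make_ranked_list(de, metric = "percent_change")
  expect_equal(rl$gene_id, c("B", "C", "A"))
  de$percent_change[] <- 5
  expect_equal(make_ranked_list(de, "percent_change")$gene_id,
               c("A", "B", "C"))
})

test_that("delta-delta-Ct fold changes follow 2^(-ddCt)", {
  ct <- rbind(
    data.frame(gene = "tgt", sample = c("s1", "s2"),
               group = c("treated", "control"), ct = c(25, 23)),
    data.frame(gene = "GAPDH", sample = c("s1", "s2"),
               group = c("treated", "control"), ct = c(20, 20)))
  out <- delta_delta_ct(ct)
  expect_equal(out$ddct, 2)
  expect_equal(out$fold, 0.25)
  # ddCt 0 -> fold 1; ddCt -1 -> fold 2
  ct$ct <- c(23, 23, 20, 20)
  expect_equal(delta_delta_ct(ct)$fold, 1)
  ct$ct <- c(22, 23, 20, 20)
  expect_equal(delta_delta_ct(ct)$fold, 2)
})

test_that("per-sample plate offsets cancel in ddCt", {
  set.seed(32)
  ct <- expand.grid(gene = c("tgt", "GAPDH"), sample = paste0("s", 1:6),
                    stringsAsFactors = FALSE)
  ct$group <- ifelse(ct$sample %in% paste0("s", 1:3), "control", "treated")
  ct$ct <- runif(nrow(ct), 18, 28)
  base <- delta_delta_ct(ct)
  offs <- setNames(runif(6, -3, 3), paste0("s", 1:6))
  ct2 <- ct
  ct2$ct <- ct2$ct + offs[ct2$sample]
  expect_equal(delta_delta_ct(ct2)$fold, base$fold, tolerance = 1e-12)
})

test_that("a sample missing the reference gene is named in the error", {
  ct <- data.frame(gene = c("tgt", "tgt", "GAPDH"),
                   sample = c("s1", "s2", "s1"),
                   group = c("control", "treated", "control"),
                   ct = c(24, 25, 20))
  expect_error(delta_delta_ct(ct), "s2")
})

test_that("single-gene sets at the list extremes give ES of +1 and -1", {
  rl <- data.frame(gene_id = c("A", "B", "C", "D"), score = c(4, 3, 2, 1))
  top <- gsea_enrichment(rl, "A", weight_p = 0, n_perm = 50, seed = 1)
  expect_equal(top$es, 1.0)
  bottom <- gsea_enrichment(rl, "D", weight_p = 0, n_perm = 50, seed = 1)
  expect_equal(bottom$es, -1.0)
  expect_equal(sign(top$nes), 1)
  expect_equal(sign(bottom$nes), -1)
})

test_that("the enrichment score equals the brute-force running sum", {
  set.seed(33)
  for (rep in 1:50) {
    N <- sample(10:50, 1)
    k <- sample(2:min(10, N - 1), 1)
    scores <- sort(rnorm(N, sd = 2), decreasing = TRUE)
    rl <- data.frame(gene_id = sprintf("g%02d", 1:N), score = scores)
    hit_pos <- sort(sample(N, k))
    set <- rl$gene_id[hit_pos]
    for (p in c(0, 1)) {
      r <- gsea_enrichment(rl, set, weight_p = p, n_perm = 2, seed = 1)
      expect_equal(r$es, oracle_es(scores, hit_pos, p), tolerance = 1e-12)
    }
  }
})

test_that("reversing the ranking flips the unweighted ES sign exactly", {
  set.seed(34)
  for (rep in 1:20) {
    N <- 30
    scores <- sort(rnorm(N), decreasing = TRUE)
    rl <- data.frame(gene_id = sprintf("g%02d", 1:N), score = scores)
    set <- sample(rl$gene_id, 6)
    # when the positive and negative extremes tie exactly, both orientations
    # resolve to the positive one; antisymmetry applies off that tie
    rs <- cumsum(ifelse(rl$gene_id %in% set, 1 / 6, -1 / (N - 6)))
    if (abs(max(rs) + min(rs)) < 1e-12) next
    fwd <- gsea_enrichment(rl, set, weight_p = 0, n_perm = 2, seed = 1)$es
    rev_rl <- rl[N:1, ]
    bwd <- gsea_enrichment(rev_rl, set, weight_p = 0, n_perm = 2, seed = 1)$es
    expect_equal(bwd, -fwd, tolerance = 1e-12)
  }
})

test_that("degenerate gene sets are rejected", {
  rl <- data.frame(gene_id = c("A", "B", "C"), score = 3:1)
  expect_error(gsea_enrichment(rl, c("X", "Y")), "no overlap")
  expect_error(gsea_enrichment(rl, c("A", "B", "C")), "entire")
})

test_that("collection runs rank sets and skip tiny overlaps", {
  set.seed(35)
  rl <- data.frame(gene_id = sprintf("g%02d", 1:40),
                   score = sort(rnorm(40), decreasing = TRUE))
  coll <- list(top = rl$gene_id[1:6], tiny = rl$gene_id[1:2],
               spread = rl$gene_id[c(3, 12, 25, 33, 40)])
  res <- gsea_collection(rl, coll, n_perm = 100, seed = 2)
  expect_setequal(res$set_name, c("top", "spread"))
  expect_gt(res$es[res$set_name == "top"], 0)
})
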