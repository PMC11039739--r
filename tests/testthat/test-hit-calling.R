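# two genes x three guides, two screens (one drug each at one dose) built
# from hand-picked abundances
tiny_screen <- function(drug_means, veh_means) {
  m <- cbind(drug1 = drug_means, drug2 = drug_means,
             veh1 = veh_means, veh2 = veh_means)
  rownames(m) <- names(drug_means)
  make_norm(m, gene_ids = rep("geneA", length(drug_means)))
}

test_that("fold-difference arithmetic follows the definition", {
  nc <- tiny_screen(c(g1 = 190), c(g1 = 100))
  design <- make_design(colnames(nc$norm),
                        c("brig", "brig", "vehicle", "vehicle"),
                        c(300, 300, NA, NA))
  expect_equal(guide_fold_differences(nc, design, pseudocount = 0)$fd, 1.9)
  # equal means give FD 1 for any pseudocount
  nc2 <- tiny_screen(c(g1 = 77), c(g1 = 77))
  for (c0 in c(0, 1, 10))
    expect_equal(guide_fold_differences(nc2, design, pseudocount = c0)$fd, 1)
  # pseudocount guards a zero vehicle mean
  nc3 <- tiny_screen(c(g1 = 190), c(g1 = 0))
  expect_equal(guide_fold_differences(nc3, design, pseudocount = 1)$fd, 191)
})

test_that("a missing vehicle arm is an error", {
  nc <- tiny_screen(c(g1 = 10), c(g1 = 10))
  design <- make_design(colnames(nc$norm), rep("brig", 4), rep(300, 4))
  expect_error(guide_fold_differences(nc, design), "vehicle")
})

test_that("gene calls require multiple guides strictly above the threshold", {
  fd_case <- function(fds) {
    enr <- data.frame(guide_id = paste0("g", seq_along(fds)),
                      gene_id = "geneA", drug = "brig", dose = 300,
                      screen = "brig@300", fd = fds, log2_fd = log2(fds))
    class(enr) <- c("guide_enrichment", "data.frame")
    call_gene_hits(enr, hit_call_config(fd_threshold = 1.8,
                                        min_guides_passing = 2))$enriched
  }
  expect_true(fd_case(c(2.0, 1.9, 1.0)))
  expect_false(fd_case(c(1.9, 1.0, 1.0)))
  # boundary: exactly 1.8 does not pass (strict inequality)
  expect_false(fd_case(c(1.8, 1.8, 1.8)))
})

make_calls <- function(enriched_screens) {
  screens <- data.frame(
    drug = rep(c("brigatinib", "ceritinib"), each = 2),
    dose = c(300, 750, 300, 750))
  screens$screen <- sprintf("%s@%d", screens$drug, screens$dose)
  out <- data.frame(gene_id = "geneA", drug = screens$drug,
                    dose = screens$dose, screen = screens$screen,
                    n_guides = 3L,
                    n_passing = ifelse(screens$screen %in% enriched_screens,
                                       3L, 0L))
  out$enriched <- out$screen %in% enriched_screens
  out
}

test_that("hits need both drugs at either dose; top hits need 3 of 4 screens", {
  hit <- intersect_screens(make_calls(c("brigatinib@300", "ceritinib@750")))
  expect_true(hit$is_hit)
  expect_false(hit$is_top)

  one_drug <- intersect_screens(make_calls(c("brigatinib@300",
                                             "brigatinib@750")))
  expect_false(one_drug$is_hit)

  three <- intersect_screens(make_calls(c("brigatinib@300", "brigatinib@750",
                                          "ceritinib@300")))
  expect_true(three$is_top)
  expect_true(three$is_hit)

  expect_error(intersect_screens(make_calls("brigatinib@300"),
                                 drugs = c("brigatinib", "lorlatinib")),
               "unknown")
})

test_that("fold differences are invariant to rescaling all samples", {
  set.seed(21)
  m <- matrix(rpois(40, 100) + 1, nrow = 10, ncol = 4,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
  design <- make_design(paste0("s", 1:4),
                        c("brig", "brig", "vehicle", "vehicle"),
                        c(300, 300, NA, NA))
  genes <- rep(c("geneA", "geneB"), each = 5)
  fd1 <- guide_fold_differences(make_norm(m, genes), design, pseudocount = 0)
  fd2 <- guide_fold_differences(make_norm(m * 3.7, genes), design,
                                pseudocount = 0)
  expect_equal(fd1$fd, fd2$fd, tolerance = 1e-12)
})

test_that("raising the FD threshold never grows the hit set", {
  sim <- simulate_screen(screen_sim_config(n_genes = 200,
                                           n_resistance_genes = 10,
                                           resistance_effect = 2,
                                           dispersion = 0.3, seed = 22))
  enr <- guide_fold_differences(normalize_counts(sim$counts), sim$design)
  hit_sets <- lapply(c(1.5, 1.8, 2.5), function(tau) {
    calls <- call_gene_hits(enr, hit_call_config(fd_threshold = tau))
    h <- intersect_screens(calls)
    h$gene_id[h$is_hit]
  })
  expect_true(all(hit_sets[[2]] %in% hit_sets[[1]]))
  expect_true(all(hit_sets[[3]] %in% hit_sets[[2]]))
})

test_that("the caller recovers planted resistance genes on a small screen", {
  sim <- simulate_screen(screen_sim_config(n_genes = 300,
                                           n_resistance_genes = 10,
                                           resistance_effect = 4,
                                           dispersion = 0.1,
                                           mean_depth = 500, seed = 23))
  enr <- guide_fold_differences(normalize_counts(sim$counts), sim$design)
  hits <- intersect_screens(call_gene_hits(enr))
  called <- hits$gene_id[hits$is_hit]
  expect_gte(mean(called %in% sim$truth), 0.9)  # precision
  expect_gte(mean(sim$truth %in% called), 0.9)  # recall
})

test_that("k-means recovers well-separated blobs deterministically", {
  set.seed(24)
  blob1 <- matrix(rnorm(40, mean = 0, sd = 0.2), ncol = 2)
  blob2 <- matrix(rnorm(40, mean = 6, sd = 0.2), ncol = 2)
  x <- rbind(blob1, blob2)
  rownames(x) <- sprintf("gene%02d", 1:40)
  ca1 <- cluster_profiles(x, k = 2, seed = 7)
  ca2 <- cluster_profiles(x, k = 2, seed = 7)
  expect_identical(ca1$cluster, ca2$cluster)
  lab <- ca1$cluster
  expect_length(unique(lab[1:20]), 1)
  expect_length(unique(lab[21:40]), 1)
  expect_false(lab[1] == lab[21])
  expect_error(cluster_profiles(x, k = 41, seed = 1), "exceeds")
})

test_that("k-means WCSS attains the exhaustive minimum on tiny inputs", {
  set.seed(25)
  for (rep in 1:5) {
    x <- matrix(rnorm(16), ncol = 2)
    rownames(x) <- paste0("g", 1:8)
    ca <- cluster_profiles(x, k = 2, seed = rep)
    expect_equal(ca$wcss, oracle_min_wcss_k2(x), tolerance = 1e-9)
  }
})

test_that("waterfall ranking is descending with stable id tie-breaks", {
  enr <- data.frame(guide_id = c("g1", "g2", "g3"), gene_id = "geneA",
                    drug = "brig", dose = 300, screen = "brig@300",
                    fd = c(1.0, 3.0, 2.0), log2_fd = log2(c(1, 3, 2)))
  class(enr) <- c("guide_enrichment", "data.frame")
  w <- rank_waterfall(enr, "brig@300")
  expect_equal(w$guide_id, c("g2", "g3", "g1"))
  expect_equal(w$log2_fd, log2(w$fd))

  enr$fd[] <- 2; enr$log2_fd[] <- 1
  expect_equal(rank_waterfall(enr, "brig@300")$guide_id, c("g1", "g2", "g3"))
  expect_error(rank_waterfall(enr, "nope@1"), "unknown screen")
})
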