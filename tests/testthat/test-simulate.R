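test_that("all four generators are bit-identical under a repeated seed", {
  s1 <- simulate_screen(screen_sim_config(n_genes = 50, seed = 42))
  s2 <- simulate_screen(screen_sim_config(n_genes = 50, seed = 42))
  expect_identical(s1$counts$counts, s2$counts$counts)
  expect_identical(s1$truth, s2$truth)

  e1 <- simulate_expression(expression_sim_config(n_genes = 100, seed = 42))
  e2 <- simulate_expression(expression_sim_config(n_genes = 100, seed = 42))
  expect_identical(e1$matrices[[1]]$values, e2$matrices[[1]]$values)

  d1 <- simulate_dose_matrix(dose_matrix_sim_config(noise_sd = 2, seed = 42))
  d2 <- simulate_dose_matrix(dose_matrix_sim_config(noise_sd = 2, seed = 42))
  expect_identical(d1$values, d2$values)

  v1 <- simulate_survival(survival_sim_config(n_patients = 40, seed = 42))
  v2 <- simulate_survival(survival_sim_config(n_patients = 40, seed = 42))
  expect_identical(v1, v2)
})

test_that("screen simulation conserves library structure", {
  cfg <- screen_sim_config(n_genes = 120, guides_per_gene = 3, seed = 3)
  sim <- simulate_screen(cfg)
  expect_equal(nrow(sim$counts$counts), 120 * 3)
  expect_length(sim$counts$gene_ids, 120 * 3)
  # every guide maps to exactly one gene; every gene carries 3 guides
  expect_true(all(table(sim$counts$gene_ids) == 3))
  expect_equal(length(unique(sim$counts$guide_ids)), 120 * 3)
  # design covers all samples exactly once, with a vehicle arm
  expect_setequal(sim$design$sample_id, colnames(sim$counts$counts))
  expect_true(any(sim$design$drug == "vehicle"))
})

test_that("no selection means per-guide fold differences center on 1", {
  # ratio-of-means FD carries an O(CV^2) Jensen skew, so the null check uses
  # a moderate dispersion and 4 replicates to keep that skew below the band
  cfg <- screen_sim_config(n_genes = 334, guides_per_gene = 3,
                           n_resistance_genes = 20, resistance_effect = 1.0,
                           dispersion = 0.05, replicates_per_condition = 4,
                           mean_depth = 500, seed = 9)
  sim <- simulate_screen(cfg)
  nc <- normalize_counts(sim$counts)
  enr <- guide_fold_differences(nc, sim$design)
  expect_lt(abs(mean(enr$fd) - 1), 0.05)
})

test_that("screen config invariants are enforced", {
  expect_error(screen_sim_config(mean_depth = 0), "mean_depth")
  expect_error(screen_sim_config(dispersion = -1), "dispersion")
  expect_error(screen_sim_config(resistance_effect = 0), "resistance_effect")
  expect_error(screen_sim_config(n_genes = 10, n_resistance_genes = 11),
               "n_resistance_genes")
})

test_that("noiseless expression shows the exact planted downregulation", {
  cfg <- expression_sim_config(n_genes = 200, n_true_targets = 15,
                               downregulation_fraction = 0.3, noise_cv = 0,
                               seed = 5)
  sim <- simulate_expression(cfg)
  for (em in sim$matrices) {
    de <- differential_expression(em)
    expect_equal(de$percent_change[de$gene_id %in% sim$truth],
                 rep(-30, 15), tolerance = 1e-12)
    expect_equal(de$percent_change[!de$gene_id %in% sim$truth],
                 rep(0, 185), tolerance = 1e-12)
  }
})

test_that("an empty planted target set leaves the triage intersection empty", {
  sim <- simulate_expression(expression_sim_config(
    n_genes = 150, n_true_targets = 0, noise_cv = 0.02, seed = 8))
  de_a <- differential_expression(sim$matrices[[1]])
  de_b <- differential_expression(sim$matrices[[2]])
  all_genes <- de_a$gene_id
  expect_length(intersect_downregulated(de_a, de_b, all_genes), 0)
})

test_that("expression config rejects invalid fractions", {
  expect_error(expression_sim_config(downregulation_fraction = 0))
  expect_error(expression_sim_config(downregulation_fraction = 1))
  expect_error(expression_sim_config(n_genes = 5, n_true_targets = 6))
})

test_that("dose-matrix monotherapy axes equal the 4PL curves when noiseless", {
  cfg <- dose_matrix_sim_config(noise_sd = 0, interaction_offset = 15,
                                seed = 2)
  dm <- simulate_dose_matrix(cfg)
  expect_equal(dm$values[, 1],
               100 * predict_viability(cfg$fit_a, cfg$dose_grid_a),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(dm$values[1, ],
               100 * predict_viability(cfg$fit_b, cfg$dose_grid_b),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(all(dm$values >= 0 & dm$values <= 110))
  expect_error(dose_matrix_sim_config(dose_grid_a = c(0, 10, 10)),
               "strictly increasing")
})

test_that("zero censoring yields a fully observed cohort", {
  coh <- simulate_survival(survival_sim_config(n_patients = 60,
                                               censor_rate = 0, seed = 4))
  expect_true(all(coh$event))
  expect_true(all(coh$time > 0))
  expect_error(survival_sim_config(censor_rate = 1), "censor_rate")
  expect_error(survival_sim_config(hazard_ratio = 0), "hazard_ratio")
})

test_that("expression mixture responds to its component parameters", {
  coh <- simulate_survival(survival_sim_config(
    n_patients = 4000, mixture_means = c(0, 5), mixture_sds = c(0.3, 0.3),
    censor_rate = 0, seed = 6))
  # two well-separated modes: component means recovered from the draw
  expect_equal(mean(coh$expression[coh$component == 1]), 0, tolerance = 0.05)
  expect_equal(mean(coh$expression[coh$component == 2]), 5, tolerance = 0.05)
})
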