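#' Configuration for a simulated pooled CRISPR screen
#'
#' Describes a scaled-down knockout library screened under several drug
#' conditions against a vehicle (DMSO) control. A subset of genes is planted
#' as resistance genes: their knockout clones enrich multiplicatively under
#' drug selection.
#'
#' @param n_genes number of genes in the library.
#' @param guides_per_gene sgRNAs per gene (libraries typically carry 3).
#' @param n_resistance_genes number of planted resistance genes.
#' @param resistance_effect multiplicative enrichment of resistance-gene
#'   guides under drug selection; 1 means no selection.
#' @param dispersion negative-binomial dispersion alpha, giving
#'   variance mu + alpha * mu^2.
#' @param mean_depth expected reads per guide per sample.
#' @param conditions data.frame with columns `drug` and `dose` (nM), one row
#'   per drug condition; the vehicle arm is added automatically.
#' @param replicates_per_condition replicates for every arm including vehicle.
#' @param seed integer seed; all randomness in [simulate_screen()] derives
#'   from it.
#' @return an object of class `screen_sim_config`.
#' @export
screen_sim_config <- function(n_genes = 1000,
                              guides_per_gene = 3,
                              n_resistance_genes = 20,
                              resistance_effect = 4,
                              dispersion = 0.1,
                              mean_depth = 500,
                              conditions = data.frame(
                                drug = rep(c("brigatinib", "ceritinib"), each = 2),
                                dose = c(300, 750, 300, 750)
                              ),
                              replicates_per_condition = 2,
                              seed = 1L) {
  stopifnot(n_genes >= 1, guides_per_gene >= 1)
  if (n_resistance_genes > n_genes)
    stop("n_resistance_genes must not exceed n_genes")
  if (resistance_effect <= 0) stop("resistance_effect must be > 0")
  if (dispersion <= 0) stop("dispersion must be > 0")
  if (mean_depth <= 0) stop("mean_depth must be > 0")
  stopifnot(is.data.frame(conditions),
            all(c("drug", "dose") %in% names(conditions)))
  structure(list(n_genes = as.integer(n_genes),
                 guides_per_gene = as.integer(guides_per_gene),
                 n_resistance_genes = as.integer(n_resistance_genes),
                 resistance_effect = resistance_effect,
                 dispersion = dispersion,
                 mean_depth = mean_depth,
                 conditions = conditions,
                 replicates_per_condition = as.integer(replicates_per_condition),
                 seed = as.integer(seed)),
            class = "screen_sim_config")
}

#' Simulate guide-level screen counts with planted resistance genes
#'
#' Library abundances are drawn log-normal (sdlog 0.5) to mimic uneven
#' representation. Per sample, expected guide counts are the library
#' composition (times `resistance_effect` on resistance-gene guides in drug
#' samples) rescaled to the sample's total depth, and counts are drawn
#' negative-binomially with the configured dispersion. Vehicle samples are
#' unperturbed.
#'
#' @param cfg a [screen_sim_config()].
#' @return list with `counts` (a `guide_counts` object), `design` (a
#'   `screen_design` data.frame) and `truth` (character vector of planted
#'   resistance genes).
#' @export
simulate_screen <- function(cfg) {
  stopifnot(inherits(cfg, "screen_sim_config"))
  withr::with_seed(cfg$seed, {
    n_guides <- cfg$n_genes * cfg$guides_per_gene
    gene_ids <- sprintf("gene%04d", seq_len(cfg$n_genes))
    guide_gene <- rep(gene_ids, each = cfg$guides_per_gene)
    guide_ids <- paste0(guide_gene, "_g", rep(seq_len(cfg$guides_per_gene),
                                              times = cfg$n_genes))
    truth <- sort(sample(gene_ids, cfg$n_resistance_genes))
    abundance <- stats::rlnorm(n_guides, meanlog = 0, sdlog = 0.5)

    cond <- cfg$conditions
    arms <- rbind(
      data.frame(drug = "vehicle", dose = NA_real_),
      data.frame(drug = cond$drug, dose = as.numeric(cond$dose))
    )
    design <- do.call(rbind, lapply(seq_len(nrow(arms)), function(i) {
      data.frame(
        sample_id = sprintf("%s_%s_r%d", arms$drug[i],
                            ifelse(is.na(arms$dose[i]), "0",
                                   format(arms$dose[i], trim = TRUE)),
                            seq_len(cfg$replicates_per_condition)),
        drug = arms$drug[i], dose = arms$dose[i],
        replicate = seq_len(cfg$replicates_per_condition)
      )
    }))
    rownames(design) <- NULL

    resist_guide <- guide_gene %in% truth
    total_depth <- cfg$mean_depth * n_guides
    counts <- vapply(seq_len(nrow(design)), function(i) {
      w <- abundance
      if (design$drug[i] != "vehicle")
        w[resist_guide] <- w[resist_guide] * cfg$resistance_effect
      mu <- w / sum(w) * total_depth
      stats::rnbinom(n_guides, mu = mu, size = 1 / cfg$dispersion)
    }, numeric(n_guides))
    dimnames(counts) <- list(guide_ids, design$sample_id)

    gc <- guide_counts(counts, gene_ids = guide_gene)
    class(design) <- c("screen_design", "data.frame")
    list(counts = gc, design = design, truth = truth)
  })
}

#' Configuration for simulated mimic-vs-control expression
#'
#' Two cell lines are transfected with a miRNA mimic or a scrambled control;
#' a planted target set is downregulated by a fixed fraction in the mimic arm.
#'
#' @param n_genes genes per cell line.
#' @param n_true_targets number of planted mimic targets (shared across cell
#'   lines).
#' @param downregulation_fraction fraction in (0,1) by which true-target
#'   expression drops in mimic samples, before noise.
#' @param noise_cv coefficient of variation of multiplicative log-normal
#'   noise; 0 gives noiseless matrices.
#' @param n_replicates replicates per arm per cell line.
#' @param cell_lines labels of the cell lines.
#' @param seed integer seed.
#' @export
expression_sim_config <- function(n_genes = 2000,
                                  n_true_targets = 50,
                                  downregulation_fraction = 0.3,
                                  noise_cv = 0.05,
                                  n_replicates = 3,
                                  cell_lines = c("SH-SY5Y", "KELLY"),
                                  seed = 1L) {
  if (downregulation_fraction <= 0 || downregulation_fraction >= 1)
    stop("downregulation_fraction must be in (0, 1)")
  if (n_true_targets > n_genes) stop("n_true_targets must not exceed n_genes")
  stopifnot(noise_cv >= 0, n_replicates >= 1, length(cell_lines) >= 1)
  structure(list(n_genes = as.integer(n_genes),
                 n_true_targets = as.integer(n_true_targets),
                 downregulation_fraction = downregulation_fraction,
                 noise_cv = noise_cv,
                 n_replicates = as.integer(n_replicates),
                 cell_lines = cell_lines,
                 seed = as.integer(seed)),
            class = "expression_sim_config")
}

#' Simulate mimic-vs-control expression matrices with planted targets
#'
#' Per cell line, baseline gene means are log-normal; mimic-arm expression of
#' true targets equals the control mean times (1 - downregulation_fraction)
#' before noise. Noise is multiplicative log-normal with unit mean and the
#' configured CV, so `noise_cv = 0` reproduces the planted fold exactly.
#'
#' @param cfg an [expression_sim_config()].
#' @return list with `matrices` (named list of `expression_matrix` objects,
#'   one per cell line) and `truth` (planted target gene ids).
#' @export
simulate_expression <- function(cfg) {
  stopifnot(inherits(cfg, "expression_sim_config"))
  withr::with_seed(cfg$seed, {
    gene_ids <- sprintf("gene%05d", seq_len(cfg$n_genes))
    truth <- if (cfg$n_true_targets > 0)
      sort(sample(gene_ids, cfg$n_true_targets)) else character(0)
    sdlog <- sqrt(log(1 + cfg$noise_cv^2))
    n_rep <- cfg$n_replicates
    pheno <- rep(c("control", "mimic"), each = n_rep)

    matrices <- lapply(cfg$cell_lines, function(cl) {
      base <- stats::rlnorm(cfg$n_genes, meanlog = log(100), sdlog = 1)
      mu <- matrix(base, nrow = cfg$n_genes, ncol = 2 * n_rep)
      mu[gene_ids %in% truth, pheno == "mimic"] <-
        mu[gene_ids %in% truth, pheno == "mimic"] *
          (1 - cfg$downregulation_fraction)
      noise <- if (cfg$noise_cv > 0)
        matrix(stats::rlnorm(length(mu), meanlog = -sdlog^2 / 2, sdlog = sdlog),
               nrow = nrow(mu)) else 1
      x <- mu * noise
      dimnames(x) <- list(gene_ids,
                          paste(gsub("[^A-Za-z0-9]", "", cl), pheno,
                                rep(seq_len(n_rep), 2), sep = "_"))
      expression_matrix(x, phenotype = pheno)
    })
    names(matrices) <- cfg$cell_lines
    list(matrices = matrices, truth = truth)
  })
}

#' Configuration for a simulated drug-combination dose matrix
#'
#' The matrix is generated under exact Loewe additivity from two
#' four-parameter-logistic monotherapies, with an optional interaction offset
#' (percentage points of extra or reduced killing in combination cells) and
#' Gaussian plate noise.
#'
#' @param fit_a,fit_b 4PL parameter lists with elements `top`, `bottom`
#'   (viability fractions), `ed50` (nM) and `hill`.
#' @param dose_grid_a,dose_grid_b strictly increasing concentration vectors
#'   (nM); the first element may be 0 (vehicle).
#' @param interaction_offset percentage points subtracted from combination
#'   cells' viability (positive = synergy, negative = antagonism).
#' @param noise_sd Gaussian noise standard deviation (percentage points).
#' @param seed integer seed.
#' @export
dose_matrix_sim_config <- function(fit_a = list(top = 1, bottom = 0.30,
                                                ed50 = 100, hill = 1.5),
                                   fit_b = list(top = 1, bottom = 0.35,
                                                ed50 = 300, hill = 1.2),
                                   dose_grid_a = c(0, 10, 30, 100, 300, 1000, 3000),
                                   dose_grid_b = c(0, 10, 30, 100, 300, 1000, 3000),
                                   interaction_offset = 0,
                                   noise_sd = 0,
                                   seed = 1L) {
  for (g in list(dose_grid_a, dose_grid_b)) {
    if (any(diff(g) <= 0)) stop("dose grids must be strictly increasing")
    if (any(g < 0)) stop("doses must be non-negative")
  }
  stopifnot(noise_sd >= 0)
  structure(list(fit_a = as_dose_response_fit(fit_a),
                 fit_b = as_dose_response_fit(fit_b),
                 dose_grid_a = dose_grid_a, dose_grid_b = dose_grid_b,
                 interaction_offset = interaction_offset,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "dose_matrix_sim_config")
}

#' Simulate a viability dose matrix under Loewe additivity plus an offset
#'
#' Every cell holds the Loewe-expected viability (percent) for its dose pair;
#' combination cells (both doses positive) additionally lose
#' `interaction_offset` percentage points. Monotherapy row and column
#' therefore equal the 4PL curves exactly when noise is 0. Values are clipped
#' to \[0, 110\] percent.
#'
#' @param cfg a [dose_matrix_sim_config()].
#' @return a `dose_matrix` object (see [dose_matrix()]).
#' @export
simulate_dose_matrix <- function(cfg) {
  stopifnot(inherits(cfg, "dose_matrix_sim_config"))
  withr::with_seed(cfg$seed, {
    da <- cfg$dose_grid_a; db <- cfg$dose_grid_b
    v <- outer(seq_along(da), seq_along(db), Vectorize(function(i, j) {
      y <- 100 * loewe_expected(cfg$fit_a, cfg$fit_b, da[i], db[j])
      if (da[i] > 0 && db[j] > 0) y <- y - cfg$interaction_offset
      y
    }))
    if (cfg$noise_sd > 0)
      v <- v + matrix(stats::rnorm(length(v), sd = cfg$noise_sd), nrow = nrow(v))
    v <- pmin(pmax(v, 0), 110)
    dose_matrix(v, dose_a = da, dose_b = db)
  })
}

#' Configuration for a simulated survival cohort
#'
#' Expression is drawn from a two-component Gaussian mixture (the bimodal
#' pattern seen in patient expression distributions); event times are
#' exponential, with the hazard multiplied by `hazard_ratio` for subjects
#' from the high-expression component. Censoring is independent.
#'
#' @param n_patients cohort size.
#' @param mixture_means,mixture_sds length-2 parameters of the expression
#'   mixture (low component first); components are equally weighted.
#' @param hazard_ratio hazard multiplier for the high-expression component.
#' @param censor_rate target fraction of censored subjects in \[0, 1).
#' @param base_hazard baseline event hazard (per time unit) for the low
#'   component.
#' @param seed integer seed.
#' @export
survival_sim_config <- function(n_patients = 143,
                                mixture_means = c(0, 2),
                                mixture_sds = c(0.5, 0.5),
                                hazard_ratio = 3,
                                censor_rate = 0.2,
                                base_hazard = 0.02,
                                seed = 1L) {
  if (hazard_ratio <= 0) stop("hazard_ratio must be > 0")
  if (censor_rate < 0 || censor_rate >= 1)
    stop("censor_rate must be in [0, 1)")
  stopifnot(length(mixture_means) == 2, length(mixture_sds) == 2,
            all(mixture_sds > 0), base_hazard > 0, n_patients >= 1)
  structure(list(n_patients = as.integer(n_patients),
                 mixture_means = mixture_means, mixture_sds = mixture_sds,
                 hazard_ratio = hazard_ratio, censor_rate = censor_rate,
                 base_hazard = base_hazard, seed = as.integer(seed)),
            class = "survival_sim_config")
}

#' Simulate a survival cohort with a bimodal expression covariate
#'
#' @param cfg a [survival_sim_config()].
#' @return a data.frame of class `survival_cohort` with columns `id`, `time`,
#'   `event` (logical), `expression`, plus the latent `component` used for
#'   truth-aware checks.
#' @export
simulate_survival <- function(cfg) {
  stopifnot(inherits(cfg, "survival_sim_config"))
  withr::with_seed(cfg$seed, {
    n <- cfg$n_patients
    comp <- sample(1:2, n, replace = TRUE)
    expr <- stats::rnorm(n, mean = cfg$mixture_means[comp],
                         sd = cfg$mixture_sds[comp])
    hazard <- cfg$base_hazard * ifelse(comp == 2, cfg$hazard_ratio, 1)
    t_event <- stats::rexp(n, rate = hazard)
    if (cfg$censor_rate > 0) {
      # censor hazard chosen so a subject at the mean event hazard is censored
      # with the target probability; exact only per hazard stratum
      cens_rate <- cfg$censor_rate / (1 - cfg$censor_rate) * mean(hazard)
      t_cens <- stats::rexp(n, rate = cens_rate)
      event <- t_event <= t_cens
      time <- pmin(t_event, t_cens)
    } else {
      event <- rep(TRUE, n)
      time <- t_event
    }
    out <- data.frame(id = sprintf("pt%03d", seq_len(n)),
                      time = time, event = event, expression = expr,
                      component = comp)
    class(out) <- c("survival_cohort", "data.frame")
    out
  })
}
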