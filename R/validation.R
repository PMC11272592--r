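# Validation studies: calibration, parameter recovery and scenario recovery
# on synthetic cohorts. These drive both the test suite and the acceptance
# script, so the numbers they report are always recomputed from scratch.

#' Type-I error of the Mantel test under independence
#'
#' Simulates pairs of independent Euclidean distance matrices and reports the
#' fraction of two-sided permutation p values at or below `alpha`.
#'
#' @param n_sims number of null simulations
#' @param n_objects objects per matrix
#' @param n_perm permutations per test
#' @param alpha nominal level
#' @param seed integer seed
#' @return list with `rate`, `n_sims`
#' @export
validate_mantel_calibration <- function(n_sims = 1000, n_objects = 8,
                                        n_perm = 99, alpha = 0.05, seed = 1L) {
  set.seed(seed)
  seeds <- sample.int(1e6, n_sims)
  rej <- 0L
  for (i in seq_len(n_sims)) {
    set.seed(seeds[i])
    d1 <- as.matrix(dist(matrix(rnorm(n_objects * 2), n_objects)))
    d2 <- as.matrix(dist(matrix(rnorm(n_objects * 2), n_objects)))
    dimnames(d1) <- dimnames(d2) <- list(seq_len(n_objects), seq_len(n_objects))
    p <- mantel_test(distance_matrix(d1), distance_matrix(d2),
                     n_perm = n_perm, seed = seeds[i],
                     exhaustive = FALSE)$p
    if (p <= alpha) rej <- rej + 1L
  }
  list(rate = rej / n_sims, n_sims = n_sims)
}

#' Type-I error of the CADM global test under independence
#'
#' As [validate_mantel_calibration()] but for the Kendall-concordance global
#' congruence test on two independent matrices.
#'
#' @inheritParams validate_mantel_calibration
#' @return list with `rate`, `n_sims`
#' @export
validate_cadm_calibration <- function(n_sims = 1000, n_objects = 8,
                                      n_perm = 99, alpha = 0.05, seed = 2L) {
  set.seed(seed)
  seeds <- sample.int(1e6, n_sims)
  rej <- 0L
  for (i in seq_len(n_sims)) {
    set.seed(seeds[i])
    d1 <- as.matrix(dist(matrix(rnorm(n_objects * 2), n_objects)))
    d2 <- as.matrix(dist(matrix(rnorm(n_objects * 2), n_objects)))
    dimnames(d1) <- dimnames(d2) <- list(seq_len(n_objects), seq_len(n_objects))
    p <- cadm_global(list(a = distance_matrix(d1), b = distance_matrix(d2)),
                     n_perm = n_perm, seed = seeds[i])$p
    if (p <= alpha) rej <- rej + 1L
  }
  list(rate = rej / n_sims, n_sims = n_sims)
}

#' Hudson FST recovery of the Balding-Nichols divergence parameter
#'
#' Draws two population allele-frequency sets around shared ancestral
#' frequencies with divergence `F_true`, binomial allele counts at `n_hap`
#' haplotypes per population, and estimates FST by the ratio-of-averages
#' Hudson estimator, which targets `F_true` exactly under this model.
#'
#' @param n_sites number of SNPs
#' @param F_true divergence parameter
#' @param n_hap haplotypes sampled per population
#' @param seed integer seed
#' @return list with `estimate`, `true`, `rel_error`
#' @export
validate_fst_recovery <- function(n_sites = 20000, F_true = 0.1, n_hap = 100,
                                  seed = 3L) {
  set.seed(seed)
  p0 <- runif(n_sites, 0.05, 0.95)
  fa <- rbalding_nichols(p0, F_true)
  fb <- rbalding_nichols(p0, F_true)
  ca <- rbinom(n_sites, n_hap, fa); cb <- rbinom(n_sites, n_hap, fb)
  sft <- structure(list(a = rbind(A = ca, B = cb),
                        n = rbind(A = rep(n_hap, n_sites),
                                  B = rep(n_hap, n_sites)),
                        f = rbind(A = ca / n_hap, B = cb / n_hap),
                        populations = c("A", "B")),
                   class = "site_freq_table")
  est <- hudson_fst(sft, "A", "B")$fst
  list(estimate = est, true = F_true, rel_error = abs(est - F_true) / F_true)
}

#' Wald coverage of the zero-inflated Poisson count coefficients
#'
#' Repeatedly simulates dyadic counts at known coefficients, fits the model
#' by direct maximum likelihood and reports the fraction of 95% Wald
#' intervals covering the true count-model slope.
#'
#' @param n_fits simulated datasets
#' @param n dyads per dataset
#' @param beta,gamma true coefficient vectors (intercept first)
#' @param seed integer seed
#' @return list with `coverage`, `n_fits`, `n_failed`
#' @export
validate_zip_coverage <- function(n_fits = 200, n = 500,
                                  beta = c(1.0, -0.8), gamma = c(-1.0, 0.8),
                                  seed = 4L) {
  set.seed(seed)
  seeds <- sample.int(1e6, n_fits)
  cover <- 0L; failed <- 0L
  for (i in seq_len(n_fits)) {
    set.seed(seeds[i])
    X <- matrix(rnorm(n), n, 1)
    X <- scale(X)
    y <- simulate_word_counts(X, beta = beta, gamma = gamma,
                              seed = seeds[i] + 1L)
    fit <- tryCatch(zip_fit(y, X), error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$se_beta[2L]) || fit$se_beta[2L] == 0) {
      failed <- failed + 1L
      next
    }
    lo <- fit$beta[2L] - 1.96 * fit$se_beta[2L]
    hi <- fit$beta[2L] + 1.96 * fit$se_beta[2L]
    if (beta[2L] >= lo && beta[2L] <= hi) cover <- cover + 1L
  }
  list(coverage = cover / (n_fits - failed), n_fits = n_fits,
       n_failed = failed)
}

#' Scenario recovery of the layered classification
#'
#' Simulates cohorts under one causal trait scenario at the generator's
#' default conditions, runs the full layered pipeline (ancestry masking,
#' cross-population IBD masking, per-layer FST, Mantel battery with BH
#' adjustment) and reports how often the expected classification is
#' recovered. For the ecology scenario, recovery means no genetic layer is
#' significant while the ecology row is.
#'
#' @param scenario `"farmer_borrowing"`, `"hg_exchange"` or `"ecology"`
#' @param n_runs seeded replicates
#' @param seed integer base seed
#' @param n_perm Mantel permutations per run
#' @return list with `rate`, `n_runs`, `classifications` (table)
#' @export
validate_scenario_recovery <- function(scenario, n_runs = 50, seed = 5L,
                                       n_perm = 999) {
  set.seed(seed)
  seeds <- sample.int(1e6, n_runs)
  expected <- c(farmer_borrowing = "recent_farmer_origin",
                hg_exchange = "prefarming_with_continued_exchange",
                ecology = "no_signal")[[scenario]]
  cls <- character(n_runs)
  ok <- logical(n_runs)
  for (i in seq_len(n_runs)) {
    cfg <- simulation_config(trait_scenario = scenario, rng_seed = seeds[i])
    coh <- simulate_cohort(cfg)
    traits <- simulate_traits(coh)
    res <- run_layered_pipeline(coh, traits,
                                run_config(n_permutations = n_perm,
                                           rng_seed = seeds[i]))
    cls[i] <- res$timing$classification
    ok[i] <- cls[i] == expected
    if (scenario == "ecology") {
      eco <- res$association$p_adj[res$association$predictor == "ecology"]
      ok[i] <- ok[i] && !is.na(eco) && eco <= 0.05
    }
  }
  list(rate = mean(ok), n_runs = n_runs, classifications = table(cls))
}
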