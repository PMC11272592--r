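# The headline method: build ancestry layers of different antiquity, run the
# association battery per layer, and classify the timing of cultural exchange.

#' Build the four ancestry layers
#'
#' Two-step masking: `full` keeps everything; `cahg` masks farmer-ancestry
#' segments; `cahg_no_ibd` additionally masks retained cross-population IBD
#' segments (> 1 cM by default, filtered upstream); `bantu` is the complement
#' (only farmer-ancestry retained). Unmasked-entry sets are nested
#' (`cahg_no_ibd` within `cahg` within `full`) and `bantu` is disjoint from
#' `cahg`; sites in ancestry-call gaps are absent from both.
#'
#' @param hs a `haplotype_set`
#' @param calls an [ancestry_calls()] object; first class is the
#'   hunter-gatherer class, second the farmer class
#' @param ibd_filtered an [ibd_set()] of retained cross-population segments
#' @return object of class `ancestry_layers`: named list of `haplotype_set`s
#'   (`full`, `cahg`, `cahg_no_ibd`, `bantu`)
#' @export
build_layers <- function(hs, calls, ibd_filtered) {
  hg_class <- calls$classes[1L]
  farmer_class <- calls$classes[2L]
  cahg <- mask_by_ancestry(hs, calls, hg_class)
  layers <- list(full = hs,
                 cahg = cahg,
                 cahg_no_ibd = mask_ibd_segments(cahg, ibd_filtered),
                 bantu = mask_by_ancestry(hs, calls, farmer_class))
  obs <- lapply(layers, function(l) !is.na(l$alleles))
  if (any(obs$cahg_no_ibd & !obs$cahg) || any(obs$cahg & !obs$full))
    stop("layer nesting violated")
  if (any(obs$bantu & obs$cahg))
    stop("bantu and cahg layers overlap")
  structure(layers, class = "ancestry_layers")
}

#' @export
print.ancestry_layers <- function(x, ...) {
  for (nm in names(x)) {
    n_obs <- sum(!is.na(x[[nm]]$alleles))
    cat(sprintf("  %-12s %d unmasked entries\n", nm, n_obs))
  }
  invisible(x)
}

#' Layered association battery
#'
#' For each ancestry layer: ancestry-specific site frequencies, pairwise
#' Hudson FST, and a Mantel test of the FST matrix against the cultural
#' distance matrix; plus geography and ecology rows. P values are
#' Benjamini-Hochberg adjusted within the table. A layer whose site-frequency
#' table retains zero usable sites yields an `NA` row.
#'
#' @param layers an [build_layers()] result
#' @param d_culture cultural distance matrix (e.g. Jaccard) over populations
#' @param covariates named list of additional distance matrices (typically
#'   `geography` and `ecology`)
#' @param config a [run_config()] (permutations, seed, adjustment method)
#' @param mantel_method correlation flavour passed to [mantel_test()]
#' @return data.frame with one row per predictor: `predictor`, `rho`, `p`,
#'   `p_adj`, `n_sites`, `n_permutations`, `seed`
#' @export
layered_association <- function(layers, d_culture, covariates = list(),
                                config = run_config(),
                                mantel_method = "spearman") {
  pops <- rownames(d_culture)
  if (length(pops) < 3L) stop("need at least 3 groups")
  rows <- list()
  for (nm in names(covariates)) {
    mt <- mantel_test(covariates[[nm]], d_culture,
                      n_perm = config$n_permutations,
                      seed = config$rng_seed, method = mantel_method,
                      exhaustive = FALSE)
    rows[[nm]] <- data.frame(predictor = nm, rho = mt$rho, p = mt$p,
                             n_sites = NA_integer_)
  }
  for (nm in names(layers)) {
    sft <- site_frequencies(layers[[nm]], populations = pops)
    if (ncol(sft$f) == 0L) {
      rows[[nm]] <- data.frame(predictor = nm, rho = NA_real_, p = NA_real_,
                               n_sites = 0L)
      next
    }
    fst <- fst_matrix(sft)
    mt <- mantel_test(fst, d_culture, n_perm = config$n_permutations,
                      seed = config$rng_seed, method = mantel_method,
                      exhaustive = FALSE)
    rows[[nm]] <- data.frame(predictor = nm, rho = mt$rho, p = mt$p,
                             n_sites = ncol(sft$f))
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab$p_adj <- p_adjust(tab$p, method = tolower(config$adjust_method))
  tab$n_permutations <- config$n_permutations
  tab$seed <- config$rng_seed
  tab
}

#' Classify the timing of cultural exchange from the layered battery
#'
#' Maps the adjusted-significance pattern of the three mandatory genetic
#' layers onto the competing historical scenarios:
#' * hunter-gatherer layer significant (with or without the IBD-excluded
#'   layer) -> `prefarming_with_continued_exchange`;
#' * otherwise full layer significant -> `recent_farmer_origin` (culture
#'   moved with recent farmer gene flow);
#' * otherwise only the IBD-excluded layer significant -> `prefarming_only`;
#' * nothing significant -> `no_signal`.
#'
#' The precedence (cahg over full over no-IBD-only) covers the significance
#' patterns the three idealized predictions do not enumerate; the raw pattern
#' is always returned alongside. `NA` rows count as non-significant.
#'
#' @param tab a [layered_association()] table (needs rows `full`, `cahg`,
#'   `cahg_no_ibd`)
#' @param alpha significance level applied to the adjusted p values
#' @return object of class `timing_classification`: list with
#'   `classification`, `pattern` (named logical), `alpha`, `table`
#' @export
classify_timing <- function(tab, alpha = 0.05) {
  need <- c("full", "cahg", "cahg_no_ibd")
  if (!all(need %in% tab$predictor))
    stop("missing layer rows: ", paste(setdiff(need, tab$predictor), collapse = ", "))
  sig <- setNames(tab$p_adj[match(need, tab$predictor)] <= alpha, need)
  sig[is.na(sig)] <- FALSE
  cls <- if (sig["cahg"]) "prefarming_with_continued_exchange"
         else if (sig["full"]) "recent_farmer_origin"
         else if (sig["cahg_no_ibd"]) "prefarming_only"
         else "no_signal"
  structure(list(classification = cls, pattern = sig, alpha = alpha,
                 table = tab),
            class = "timing_classification")
}

#' @export
print.timing_classification <- function(x, ...) {
  cat("timing classification:", x$classification, "\n")
  cat("  significant layers (adjusted p <=", x$alpha, "):",
      if (any(x$pattern)) paste(names(x$pattern)[x$pattern], collapse = ", ")
      else "none", "\n")
  invisible(x)
}

#' Run the full layered pipeline on a synthetic cohort
#'
#' Convenience driver used by the validation studies: filters the cohort's
#' IBD segments to cross-population segments above the configured length,
#' builds the four layers, computes cultural (Jaccard), geographic and
#' ecological (Gower) distances, runs the layered association battery and
#' classifies exchange timing.
#'
#' @param cohort a [simulate_cohort()] result
#' @param traits binary trait matrix (defaults to [simulate_traits()])
#' @param config a [run_config()]
#' @return list with `association` (battery table), `timing`, `layers`
#' @export
run_layered_pipeline <- function(cohort, traits = NULL, config = run_config()) {
  if (is.null(traits)) traits <- simulate_traits(cohort)
  pops <- setNames(cohort$haplotypes$samples$population,
                   cohort$haplotypes$samples$sample)
  ibd_f <- filter_cross_population(cohort$ibd, pops,
                                   min_len_cm = config$ibd_min_len_cm)
  layers <- build_layers(cohort$haplotypes, cohort$ancestry, ibd_f)
  d_cult <- jaccard_matrix(traits)
  covs <- list(geography = greatcircle_matrix(cohort$demes),
               ecology = suppressWarnings(gower_matrix(cohort$biomes)))
  tab <- layered_association(layers, d_cult, covs, config)
  list(association = tab, timing = classify_timing(tab), layers = layers)
}
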