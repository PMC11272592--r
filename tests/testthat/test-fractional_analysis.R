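test_that("layers collapse correctly when everything is hunter-gatherer ancestry", {
  al <- matrix(rbinom(40, 1, 0.5), 10, 4)
  storage.mode(al) <- "integer"
  hs <- toy_haps(al, pops = c("w", "e"))
  cov <- do.call(rbind, lapply(colnames(hs$alleles), function(h)
    data.frame(chrom = "1", start = 1L, end = 20000L, hap_id = h,
               ancestry = "CAHG")))
  calls <- ancestry_calls(cov, c("CAHG", "FARMER"))
  layers <- build_layers(hs, calls, ibd_set(data.frame()))
  expect_identical(layers$full$alleles, layers$cahg$alleles)
  expect_identical(layers$cahg$alleles, layers$cahg_no_ibd$alleles)
  expect_true(all(is.na(layers$bantu$alleles)))
})

test_that("a farmer tract plus one IBD segment mask hand-enumerable entries per layer", {
  al <- matrix(rep(0L, 40), 10, 4)
  hs <- toy_haps(al, pops = c("w", "e"))
  # farmer tract on S01_h1 covering sites 5-9 (bp 5000-9999)
  cov <- do.call(rbind, lapply(colnames(hs$alleles), function(h)
    data.frame(chrom = "1", start = 1L, end = 20000L, hap_id = h,
               ancestry = "CAHG")))
  cov <- rbind(cov[cov$hap_id != "S01_h1", ],
               data.frame(chrom = "1", start = c(1L, 5000L, 10000L),
                          end = c(5000L, 10000L, 20000L), hap_id = "S01_h1",
                          ancestry = c("CAHG", "FARMER", "CAHG")))
  calls <- ancestry_calls(cov, c("CAHG", "FARMER"))
  # cross-population IBD on S01_h2 / S02_h1 covering sites 3-7
  seg <- ibd_set(data.frame(id1 = "S01", hap1 = 2, id2 = "S02", hap2 = 1,
                            chrom = "1", start = 3000L, end = 8000L, lod = 9,
                            length_cm = 1.5, pop1 = "w", pop2 = "e"))
  layers <- build_layers(hs, calls, seg)
  expect_equal(sum(is.na(layers$full$alleles)), 0L)
  expect_equal(sum(is.na(layers$cahg$alleles)), 5L)          # the farmer tract
  expect_equal(sum(is.na(layers$cahg_no_ibd$alleles)), 5L + 10L)
  expect_true(all(is.na(layers$cahg_no_ibd$alleles[3:7, c("S01_h2", "S02_h1")])))
  # bantu layer keeps exactly the farmer tract
  expect_equal(sum(!is.na(layers$bantu$alleles)), 5L)
  expect_true(all(!is.na(layers$bantu$alleles[5:9, "S01_h1"])))
  # nesting invariant: observed sets shrink monotonically
  obs <- lapply(layers, function(l) which(!is.na(l$alleles)))
  expect_true(all(obs$cahg_no_ibd %in% obs$cahg))
  expect_true(all(obs$cahg %in% obs$full))
  expect_length(intersect(obs$bantu, obs$cahg), 0L)
})

test_that("per-layer unmasked counts match brute-force scans on a simulated cohort", {
  cfg <- simulation_config(n_demes = 3, n_individuals = 2, n_sites = 150,
                           rng_seed = 29)
  coh <- simulate_cohort(cfg)
  pops <- setNames(coh$haplotypes$samples$population,
                   coh$haplotypes$samples$sample)
  kept <- filter_cross_population(coh$ibd, pops)
  layers <- build_layers(coh$haplotypes, coh$ancestry, kept)
  haps <- colnames(coh$haplotypes$alleles)
  n_total <- length(coh$haplotypes$alleles)
  masked_cahg <- oracle_masked_count(coh$ancestry$calls, "CAHG",
                                     coh$haplotypes$chrom, coh$haplotypes$pos,
                                     haps)
  expect_equal(sum(!is.na(layers$cahg$alleles)), n_total - masked_cahg)
  masked_bantu <- oracle_masked_count(coh$ancestry$calls, "FARMER",
                                      coh$haplotypes$chrom, coh$haplotypes$pos,
                                      haps)
  expect_equal(sum(!is.na(layers$bantu$alleles)), n_total - masked_bantu)
  # cahg_no_ibd: additionally drop segment sites on named haplotypes
  ibd_mask <- matrix(FALSE, n_sites <- nrow(coh$haplotypes$alleles),
                     length(haps), dimnames = list(NULL, haps))
  for (r in seq_len(nrow(kept$segments))) {
    s <- kept$segments[r, ]
    sel <- coh$haplotypes$pos >= s$start & coh$haplotypes$pos < s$end
    ibd_mask[sel, paste0(s$id1, "_h", s$hap1)] <- TRUE
    ibd_mask[sel, paste0(s$id2, "_h", s$hap2)] <- TRUE
  }
  expected_no_ibd <- sum(!is.na(layers$cahg$alleles) & !ibd_mask)
  expect_equal(sum(!is.na(layers$cahg_no_ibd$alleles)), expected_no_ibd)
})

test_that("timing classification is total and deterministic over all patterns", {
  mk_tab <- function(p_full, p_cahg, p_noibd) {
    data.frame(predictor = c("geography", "full", "cahg", "cahg_no_ibd"),
               rho = 0.4, p = 0.5,
               p_adj = c(0.5, p_full, p_cahg, p_noibd), n_sites = 100L)
  }
  sig <- 0.01; ns <- 0.5
  cases <- list(
    list(c(ns, ns, ns), "no_signal"),
    list(c(sig, ns, ns), "recent_farmer_origin"),
    list(c(ns, sig, ns), "prefarming_with_continued_exchange"),
    list(c(ns, ns, sig), "prefarming_only"),
    list(c(sig, sig, ns), "prefarming_with_continued_exchange"),
    list(c(sig, ns, sig), "recent_farmer_origin"),
    list(c(ns, sig, sig), "prefarming_with_continued_exchange"),
    list(c(sig, sig, sig), "prefarming_with_continued_exchange"))
  for (cs in cases) {
    tl <- classify_timing(mk_tab(cs[[1]][1], cs[[1]][2], cs[[1]][3]))
    expect_identical(tl$classification, cs[[2]])
  }
  # NA rows count as non-significant
  tab_na <- mk_tab(NA, sig, NA)
  expect_identical(classify_timing(tab_na)$classification,
                   "prefarming_with_continued_exchange")
  expect_error(classify_timing(mk_tab(ns, ns, ns)[-2, ]), "missing layer")
})

test_that("the layered battery returns one row per predictor with the recorded seed", {
  cfg <- simulation_config(n_demes = 5, n_individuals = 4, n_sites = 300,
                           rng_seed = 31)
  coh <- simulate_cohort(cfg)
  res <- run_layered_pipeline(coh, config = run_config(n_permutations = 99,
                                                       rng_seed = 31))
  tab <- res$association
  expect_setequal(tab$predictor,
                  c("geography", "ecology", "full", "cahg", "cahg_no_ibd",
                    "bantu"))
  expect_true(all(tab$seed == 31))
  expect_true(all(is.na(tab$p) | tab$p >= 1 / 100))
  expect_s3_class(res$timing, "timing_classification")
})
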