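test_that("exact IBD detector finds maximal identical runs", {
  # two identical haplotypes spanning a 10 cM chromosome -> one full segment
  al <- cbind(rep(c(0L, 1L), 10), rep(c(0L, 1L), 10))
  al <- cbind(al, 1L - al[, 1L], 1L - al[, 1L])  # second individual, distinct
  pos <- seq(1000L, by = 5000L, length.out = 20)
  hs <- toy_haps(al, pos = pos, cm = (pos - 1000) / 95000 * 10)
  segs <- detect_ibd_exact(hs, min_len_cm = 1)
  pair11 <- segs$segments[segs$segments$id1 == "S01" & segs$segments$id2 == "S01", ]
  expect_equal(nrow(pair11), 1L)
  expect_equal(pair11$length_cm, 10)
  expect_equal(pair11$start, 1000L)
  # a single mismatching site mid-chromosome splits the run in two
  al2 <- al; al2[10, 2L] <- 1L - al2[10, 2L]
  hs2 <- toy_haps(al2, pos = pos, cm = (pos - 1000) / 95000 * 10)
  segs2 <- detect_ibd_exact(hs2, min_len_cm = 1)
  pair11b <- segs2$segments[segs2$segments$id1 == "S01" & segs2$segments$id2 == "S01", ]
  expect_equal(nrow(pair11b), 2L)
  expect_true(all(pair11b$end <= pos[10] | pair11b$start > pos[10]))
  # missing entries error unless treated as run-breaking
  al3 <- al; al3[3, 1L] <- NA
  hs3 <- toy_haps(al3, pos = pos, cm = (pos - 1000) / 95000 * 10)
  expect_error(detect_ibd_exact(hs3), "missing")
  expect_s3_class(detect_ibd_exact(hs3, missing = "break"), "ibd_set")
})

test_that("detector agrees with a brute-force run scan on random haplotypes", {
  set.seed(41)
  n <- 1000
  al <- matrix(rbinom(n * 4, 1, 0.5), n, 4)
  pos <- seq_len(n) * 1000L
  cm <- pos / 1e5                                 # 10 cM chromosome
  hs <- toy_haps(al, pos = pos, cm = cm)
  segs <- detect_ibd_exact(hs, min_len_cm = 0.05)
  # oracle: for every pair, list runs and filter by span
  expected <- 0L
  for (i in 1:3) for (j in (i + 1):4) {
    for (run in oracle_runs(al[, i], al[, j])) {
      if (cm[run[2]] - cm[run[1]] >= 0.05) expected <- expected + 1L
    }
  }
  expect_equal(nrow(segs$segments), expected)
  # spans match the oracle exactly for one chosen pair
  sub <- segs$segments[segs$segments$id1 == "S01" & segs$segments$hap1 == 1 &
                         segs$segments$id2 == "S01" & segs$segments$hap2 == 2, ]
  runs <- Filter(function(r) cm[r[2]] - cm[r[1]] >= 0.05,
                 oracle_runs(al[, 1], al[, 2]))
  expect_equal(sub$start, vapply(runs, function(r) pos[r[1]], integer(1)))
})

test_that("IBD merge respects the 0.6 cM gap and one-inconsistency rules", {
  # 100 sites at 0.1 cM spacing; two haplotypes identical except a window
  n <- 100
  a <- rbinom(n, 1, 0.5)
  b <- a
  b[41:44] <- 1L - b[41:44]       # mismatch block; gap = sites 41..44
  al <- cbind(a, b, rbinom(n, 1, 0.5), rbinom(n, 1, 0.5))
  storage.mode(al) <- "integer"
  pos <- seq_len(n) * 1000L
  hs <- toy_haps(al, pos = pos, cm = pos / 1e4)   # 0.1 cM per site
  seg <- function(s, e) data.frame(id1 = "S01", hap1 = 1, id2 = "S01",
                                   hap2 = 2, chrom = "1",
                                   start = pos[s], end = pos[e] + 1L,
                                   lod = 10, length_cm = (pos[e] - pos[s]) / 1e4)
  # gap 0.4 cM (sites 41-44, 4 mismatches) -> too many inconsistencies
  two <- ibd_set(rbind(seg(1, 40), seg(45, 100)))
  m1 <- merge_ibd_blocks(two, hs)
  expect_equal(nrow(m1$segments), 2L)
  # same geometry with a single mismatching site in the gap -> merged
  b2 <- a; b2[42] <- 1L - b2[42]
  al2 <- al; al2[, 2] <- b2
  hs2 <- toy_haps(al2, pos = pos, cm = pos / 1e4)
  m2 <- merge_ibd_blocks(two, hs2)
  expect_equal(nrow(m2$segments), 1L)
  expect_equal(m2$segments$start, pos[1])
  expect_equal(m2$segments$end, pos[100] + 1L)
  # gap 0.8 cM stays unmerged even with zero mismatches
  b3 <- a
  al3 <- al; al3[, 2] <- b3
  hs3 <- toy_haps(al3, pos = pos, cm = pos / 1e4)
  wide <- ibd_set(rbind(seg(1, 40), seg(49, 100)))  # gap sites 41..48 = 0.8 cM
  m3 <- merge_ibd_blocks(wide, hs3)
  expect_equal(nrow(m3$segments), 2L)
  # idempotence
  m4 <- merge_ibd_blocks(m2, hs2)
  expect_identical(m4$segments, m2$segments)
  # different pairs never merge
  other <- seg(45, 100); other$id2 <- "S02"; other$hap2 <- 1
  mixed <- ibd_set(rbind(seg(1, 40), other))
  expect_equal(nrow(merge_ibd_blocks(mixed, hs2)$segments), 2L)
})

test_that("cross-population filter keeps only between-population segments above 1 cM", {
  df <- data.frame(id1 = c("A1", "A2", "A3"), hap1 = 1,
                   id2 = c("B1", "A9", "B2"), hap2 = 2, chrom = "1",
                   start = 1000L, end = 2000L, lod = 10,
                   length_cm = c(5, 5, 0.9))
  pops <- c(A1 = "west", A2 = "west", A3 = "west", A9 = "west",
            B1 = "east", B2 = "east")
  kept <- filter_cross_population(ibd_set(df), pops)
  expect_equal(nrow(kept$segments), 1L)            # within-pop and 0.9 cM removed
  expect_identical(kept$segments$id1, "A1")
  edge <- df[3, ]; edge$length_cm <- 1.0            # exactly 1 cM: excluded
  expect_equal(nrow(filter_cross_population(ibd_set(edge), pops)$segments), 0L)
  edge$length_cm <- 1.5
  expect_equal(nrow(filter_cross_population(ibd_set(edge), pops)$segments), 1L)
  expect_error(filter_cross_population(ibd_set(df), pops[-1]), "unlabeled")
  # conservation: total retained cM equals per-haplotype sum / 2
  segs <- kept$segments
  per_hap <- c(tapply(segs$length_cm, paste0(segs$id1, "_h", segs$hap1), sum),
               tapply(segs$length_cm, paste0(segs$id2, "_h", segs$hap2), sum))
  expect_equal(sum(segs$length_cm), sum(per_hap) / 2)
})

test_that("IBD masking hits exactly the named haplotypes and sites", {
  al <- matrix(rbinom(40, 1, 0.5), 10, 4)
  storage.mode(al) <- "integer"
  hs <- toy_haps(al, pos = seq_len(10) * 1000L, cm = seq_len(10) / 10,
                 pops = c("west", "east"))
  seg <- ibd_set(data.frame(id1 = "S01", hap1 = 2, id2 = "S02", hap2 = 1,
                            chrom = "1", start = 3000L, end = 8000L,
                            lod = 5, length_cm = 0.5))
  m <- mask_ibd_segments(hs, seg)
  expect_equal(sum(is.na(m$alleles)), 10L)         # 5 sites x 2 haplotypes
  expect_true(all(is.na(m$alleles[3:7, c("S01_h2", "S02_h1")])))
  expect_identical(m$alleles[, c("S01_h1", "S02_h2")],
                   hs$alleles[, c("S01_h1", "S02_h2")])
  # empty set -> identity; unknown haplotype -> error
  expect_identical(mask_ibd_segments(hs, ibd_set(data.frame()))$alleles,
                   hs$alleles)
  bad <- seg$segments; bad$id2 <- "S99"
  expect_error(mask_ibd_segments(hs, ibd_set(bad)), "unknown haplotype")
})

test_that("masking implanted IBD removes all long cross-population sharing", {
  cfg <- simulation_config(n_demes = 3, n_individuals = 3, n_sites = 400,
                           rng_seed = 23)
  coh <- simulate_cohort(cfg)
  pops <- setNames(coh$haplotypes$samples$population,
                   coh$haplotypes$samples$sample)
  kept <- filter_cross_population(coh$ibd, pops)
  masked <- mask_ibd_segments(coh$haplotypes, kept)
  # brute-force newly-masked count over the retained true segments
  expected <- 0L
  seen <- list()
  for (r in seq_len(nrow(kept$segments))) {
    s <- kept$segments[r, ]
    for (h in c(paste0(s$id1, "_h", s$hap1), paste0(s$id2, "_h", s$hap2))) {
      sel <- which(coh$haplotypes$pos >= s$start & coh$haplotypes$pos < s$end)
      new <- setdiff(sel, seen[[h]])
      seen[[h]] <- union(seen[[h]], sel)
      expected <- expected + length(new)
    }
  }
  expect_equal(sum(is.na(masked$alleles)), expected)
  # re-detection (missing breaks runs) finds no surviving >= 1 cM segment
  # between the two named haplotypes inside any masked region
  redet <- detect_ibd_exact(masked, min_len_cm = 1, missing = "break")
  if (nrow(redet$segments)) {
    for (r in seq_len(nrow(kept$segments))) {
      s <- kept$segments[r, ]
      same_pair <- redet$segments$id1 == s$id1 & redet$segments$hap1 == s$hap1 &
        redet$segments$id2 == s$id2 & redet$segments$hap2 == s$hap2
      overlap <- redet$segments$start < s$end & redet$segments$end > s$start
      expect_false(any(same_pair & overlap))
    }
  }
})
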