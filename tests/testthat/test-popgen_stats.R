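test_that("site frequencies count retained alleles and apply the n > 1 filter", {
  al <- matrix(c(1L, 0L, 1L, 0L,   # site 1
                 1L, 1L, NA, 0L,   # site 2
                 NA, NA, NA, 0L,   # site 3: pop1 retains 1 allele -> dropped
                 0L, 0L, 1L, 1L),  # site 4
               nrow = 4, byrow = TRUE)
  hs <- toy_haps(al, pops = c("p1", "p2"))
  # hap columns: S01_h1, S01_h2 (p1), S02_h1, S02_h2 (p2)
  expect_error(site_frequencies(hs, populations = c("p1", "nope")), "zero individuals")
  sft <- suppressWarnings(site_frequencies(hs))
  expect_equal(sft$n_dropped, 2L)   # site 2 (pop2 keeps 1 allele) and site 3
  expect_equal(unname(sft$a["p1", ]), c(1, 0))
  expect_equal(unname(sft$n["p1", ]), c(2, 2))
  expect_equal(unname(sft$f["p1", 1]), 0.5)
  # [1,0,1] retained alleles -> a=2, n=3, f=2/3
  al2 <- matrix(c(1L, 0L, 1L, NA, 0L, 1L), nrow = 1)
  hs2 <- toy_haps(al2, pops = c("pA", "pA", "pB"))
  sft2 <- site_frequencies(hs2)
  expect_equal(unname(sft2$a["pA", 1]), 2)
  expect_equal(unname(sft2$n["pA", 1]), 3)
  expect_equal(unname(sft2$f["pA", 1]), 2 / 3)
  # unmasked: 2 populations x 5 diploids -> n = 10 everywhere
  al3 <- matrix(rbinom(200, 1, 0.5), 10, 20)
  storage.mode(al3) <- "integer"
  hs3 <- toy_haps(al3, pops = rep(c("x", "y"), each = 5))
  expect_true(all(site_frequencies(hs3)$n == 10))
})

test_that("Hudson FST matches hand-evaluated formulas and is symmetric", {
  mk <- function(fa, fb, na, nb) {
    structure(list(a = rbind(A = fa * na, B = fb * nb),
                   n = rbind(A = rep(na, length(fa)), B = rep(nb, length(fb))),
                   f = rbind(A = fa, B = fb),
                   populations = c("A", "B")),
              class = "site_freq_table")
  }
  # fixed difference: FST = 1 regardless of n
  expect_equal(hudson_fst(mk(1, 0, 4, 6), "A", "B")$fst, 1)
  # f = 0.5 both, n = 2: numerator -0.5, denominator 0.5 -> -1
  r <- hudson_fst(mk(0.5, 0.5, 2, 2), "A", "B")
  expect_equal(r$num_mean, -0.5)
  expect_equal(r$den_mean, 0.5)
  expect_equal(r$fst, -1)
  # two sites, large n: ratio of sums 0.04 / 0.86
  big <- 1e7
  r2 <- hudson_fst(mk(c(0.2, 0.3), c(0.4, 0.3), big, big), "A", "B")
  expect_equal(r2$fst, 0.04 / 0.86, tolerance = 1e-4)
  # symmetry is exact
  set.seed(3)
  fa <- runif(50); fb <- runif(50)
  expect_identical(hudson_fst(mk(fa, fb, 20, 30), "A", "B")$fst,
                   hudson_fst(mk(fa, fb, 20, 30), "B", "A")$fst)
  # all-monomorphic-in-both: undefined, flagged
  r3 <- hudson_fst(mk(0, 0, 10, 10), "A", "B")
  expect_true(r3$undefined)
  expect_true(is.na(r3$fst))
})

test_that("FST between random halves of one population is near zero", {
  set.seed(7)
  devs <- vapply(1:12, function(s) {
    set.seed(s)
    al <- matrix(rbinom(40 * 600, 1, rep(runif(600, 0.1, 0.9), each = 40)),
                 600, 40, byrow = FALSE)
    al <- matrix(as.integer(al), 600, 40)
    hs <- toy_haps(al, pops = rep(c("h1", "h2"), 10))
    hudson_fst(site_frequencies(hs), "h1", "h2")$fst
  }, numeric(1))
  expect_lt(abs(mean(devs)), 3 * sd(devs) / sqrt(length(devs)) + 0.003)
})

test_that("Hudson FST recovers the Balding-Nichols divergence parameter", {
  set.seed(19)
  n_sites <- 20000; F_true <- 0.1; n_hap <- 100
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
  expect_lt(abs(est - F_true) / F_true, 0.1)
})

test_that("pairwise-difference distance equals the allele-mismatch expectation", {
  g_same <- rbind(a = c(0, 1, 1, 0), b = c(0, 1, 1, 0))
  expect_equal(max(unclass(pairwise_difference_distance(g_same))), 0)
  g_opp <- rbind(a = rep(1, 4), b = rep(0, 4))
  expect_equal(unclass(pairwise_difference_distance(g_opp))["a", "b"], 1)
  # random dose vectors vs enumeration over the 2 x 2 haplotype draws
  set.seed(11)
  g <- matrix(sample(c(0, 0.5, 1), 30, replace = TRUE), 3, 10,
              dimnames = list(c("a", "b", "c"), NULL))
  d <- unclass(pairwise_difference_distance(g))
  mismatch <- function(ga, gb) {
    # enumerate allele pairs: P(draw 1) = dose
    ga * (1 - gb) + (1 - ga) * gb
  }
  for (i in 1:2) for (j in (i + 1):3)
    expect_equal(d[i, j], mean(mismatch(g[i, ], g[j, ])))
  # missing-aware path agrees on co-observed sites and errors with none
  g2 <- g; g2[1, 1:3] <- NA
  d2 <- unclass(pairwise_difference_distance(g2))
  expect_equal(d2["a", "b"], mean(mismatch(g[1, 4:10], g[2, 4:10])))
  g3 <- rbind(a = c(NA, 1), b = c(0, NA))
  expect_error(pairwise_difference_distance(g3), "no co-observed")
})

test_that("classical MDS reproduces planar configurations and degenerate cases", {
  set.seed(13)
  pts <- matrix(rnorm(10), 5)
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(letters[1:5], letters[1:5])
  fit <- classical_mds(distance_matrix(d), k = 2)
  expect_equal(as.matrix(dist(fit$points)), unname(d) * 1,
               ignore_attr = TRUE, tolerance = 1e-8)
  # zero matrix -> all-zero embedding
  z <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  fz <- suppressWarnings(classical_mds(distance_matrix(z), k = 2))
  expect_true(all(fz$points == 0))
  # collinear points embed exactly in one dimension
  dc <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  fc <- suppressWarnings(classical_mds(distance_matrix(dc), k = 2))
  expect_equal(as.matrix(dist(fc$points[, 1])), dc, ignore_attr = TRUE,
               tolerance = 1e-8)
  expect_equal(sum(fc$eigenvalues > 1e-8), 1L)
})
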