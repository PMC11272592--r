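toy_cognates <- function() {
  cognate_table(data.frame(
    group = c("A", "B", "C", "A", "B", "A"),
    domain = "music",
    object_id = c("drum", "drum", "drum", "flute", "flute", "harp"),
    word = c("ngoma", "ngomo", "ngma", "mbio", "mbiyo", "ngombi"),
    cognate_id = c("X", "X", "X", "Y", "Y", "Z"),
    unique_to_cahg = c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE),
    confidence = c("conclusive", "conclusive", "conclusive",
                   "conclusive", "tentative", "conclusive")))
}

test_that("shared-word counts follow cognate-set membership", {
  sw <- shared_word_counts(toy_cognates())
  # set X in {A,B,C}: dyads AB, AC, BC; set Y in {A,B}: AB again
  expect_equal(sw$counts["A", "B"], 2L)
  expect_equal(sw$counts["A", "C"], 1L)
  expect_equal(sw$counts["B", "C"], 1L)
  expect_identical(sw$degree_distribution, c(`2` = 1L, `3` = 1L))
  # restricted view drops the non-unique set Y and the tentative row
  swr <- shared_word_counts(toy_cognates(), restricted = TRUE)
  expect_equal(swr$counts["A", "B"], 1L)
  expect_identical(swr$degree_distribution, c(`3` = 1L))
  # empty table -> zero matrix
  empty <- cognate_table(toy_cognates()$records[0, ])
  expect_true(all(shared_word_counts(empty, groups = c("A", "B"))$counts == 0))
  # degree conservation: sum over sets of choose(degree, 2) = dyad mass
  expect_equal(sum(choose(as.integer(names(sw$degree_distribution)), 2) *
                     sw$degree_distribution),
               sum(sw$counts[upper.tri(sw$counts)]))
})

test_that("the bundled synthetic cognate fixture reproduces its designed counts", {
  f <- system.file("extdata", "synthetic_cognates.csv", package = "ibdlayers")
  skip_if(f == "")
  cul <- load_culture(cognates_csv = f)
  music <- shared_word_counts(cul$cognates, domain = "music")
  expect_identical(music$degree_distribution,
                   c(`2` = 17L, `3` = 3L, `4` = 3L, `5` = 1L))
  expect_equal(music$n_shared_sets, 24L)
  tools <- shared_word_counts(cul$cognates, domain = "subsistence")
  expect_identical(tools$degree_distribution, c(`2` = 10L, `3` = 1L))
  # conservation again, on a larger table
  expect_equal(sum(choose(as.integer(names(music$degree_distribution)), 2) *
                     music$degree_distribution),
               sum(music$counts[upper.tri(music$counts)]))
  # music words shared more than subsistence words across the same dyads
  w <- wilcoxon_signed_rank(music$counts[upper.tri(music$counts)],
                            tools$counts[upper.tri(tools$counts)])
  expect_lt(w$p, 0.05)
})

test_that("tree node-count and patristic distances handle the documented cases", {
  tree <- default_tree()                       # ((A:2,B:3):1,C:4)
  expect_equal(glottolog_node_distance(tree, "A", "B"), 1L)
  expect_equal(glottolog_node_distance(tree, "A", "C"), 2L)
  expect_equal(glottolog_node_distance(tree, "A", "A"), 0L)
  expect_error(glottolog_node_distance(tree, "A", "Z"), "not in tree")
  expect_equal(patristic_distance(tree, "A", "B"), 5)
  expect_equal(patristic_distance(tree, "A", "A"), 0)
  # out-of-family rule: maximum root-to-tip depth (C at depth 4)
  expect_equal(patristic_distance(tree, "A", "Efe", out_of_family = "Efe"), 4)
  expect_error(patristic_distance(tree, "A", "Z"), "not in tree")
  # metric behaviour of node counts on tips
  tips <- tree$tip.label
  for (i in tips) for (j in tips) for (k in tips)
    expect_lte(glottolog_node_distance(tree, i, j),
               glottolog_node_distance(tree, i, k) +
                 glottolog_node_distance(tree, k, j))
  # multi-language groups average over their languages
  gd <- group_language_distance(function(a, b) patristic_distance(tree, a, b),
                                c("A", "B"), "C")
  expect_equal(gd, mean(c(7, 8)))
})

test_that("ZIP fit nests Poisson regression and reproduces moments", {
  set.seed(12)
  X <- scale(matrix(rnorm(1200), 600, 2))
  # pi = 0 data: beta matches plain Poisson regression to 1e-4
  y <- simulate_word_counts(X, beta = c(1, -0.8, 0.3), gamma = c(-Inf, 0, 0),
                            seed = 5)
  fit <- zip_fit(y, X, Z = matrix(numeric(0), length(y), 0))
  pois <- glm(y ~ X, family = poisson())
  expect_lt(max(abs(fit$beta - coef(pois))), 1e-4)
  expect_lt(fit$fitted_pi[1], 0.01)               # inflation driven to zero
  # intercept-only model reproduces E[y] = (1 - pi) lambda and P(y = 0)
  y2 <- simulate_word_counts(matrix(0, 5000, 1), beta = c(log(4), 0),
                             gamma = c(qlogis(0.3), 0), seed = 6)
  fit2 <- zip_fit(y2, matrix(numeric(0), 5000, 0))
  ey <- (1 - fit2$fitted_pi[1]) * fit2$fitted_lambda[1]
  expect_lt(abs(ey - mean(y2)), 3 * sd(y2) / sqrt(length(y2)))
  p0_hat <- fit2$fitted_pi[1] + (1 - fit2$fitted_pi[1]) *
    exp(-fit2$fitted_lambda[1])
  se_p0 <- sqrt(mean(y2 == 0) * (1 - mean(y2 == 0)) / length(y2))
  expect_lt(abs(p0_hat - mean(y2 == 0)), 3 * se_p0)
  # invariants: fitted lambda > 0, pi in (0, 1), monitored loglik monotone
  expect_true(all(fit$fitted_lambda > 0))
  expect_true(all(fit$fitted_pi > 0 & fit$fitted_pi < 1))
  expect_true(all(diff(fit$loglik_trace) >= -1e-9))
  expect_error(zip_fit(rep(0L, 10), matrix(0, 10, 0)), "unidentifiable")
})

test_that("ZIP estimates agree with an independent mixed-model implementation", {
  skip_if_not_installed("glmmTMB")
  set.seed(14)
  X <- scale(matrix(rnorm(800), 400, 2))
  y <- simulate_word_counts(X, beta = c(1, -0.6, 0.4),
                            gamma = c(-0.8, 0.5, 0), seed = 7)
  fit <- zip_fit(y, X)
  df <- data.frame(y = y, x1 = X[, 1], x2 = X[, 2])
  ref <- glmmTMB::glmmTMB(y ~ x1 + x2, ziformula = ~ x1 + x2,
                          family = poisson(), data = df)
  expect_equal(unname(fit$beta), unname(glmmTMB::fixef(ref)$cond),
               tolerance = 1e-3)
  expect_equal(unname(fit$gamma), unname(glmmTMB::fixef(ref)$zi),
               tolerance = 1e-2)
})

test_that("Wilcoxon signed-rank matches exhaustive sign enumeration at n = 5", {
  x <- c(3.1, 4.2, 1.0, 6.5, 2.2)
  y <- c(1.2, 2.0, 2.5, 1.1, 2.0)
  res <- wilcoxon_signed_rank(x, y)
  d <- x - y
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  expect_equal(res$W, W_obs)
  # enumerate all 2^5 sign patterns of |d|
  stats <- apply(expand.grid(rep(list(c(0, 1)), 5)), 1,
                 function(s) sum(r[s == 1]))
  mu <- sum(r) / 2
  p_exact <- mean(abs(stats - mu) >= abs(W_obs - mu) - 1e-12)
  expect_equal(res$p, p_exact)
  expect_error(wilcoxon_signed_rank(1:3, 1:3), "zero")
})

test_that("Spearman with S matches rank-Pearson and hand values", {
  r <- spearman_with_S(1:5, c(2, 4, 6, 7, 10))
  expect_equal(r$rho, 1); expect_equal(r$S, 0)
  r2 <- spearman_with_S(1:4, c(8, 6, 4, 2))
  expect_equal(r2$rho, -1); expect_equal(r2$S, 20)
  set.seed(15)
  x <- rnorm(30); y <- rnorm(30)
  r3 <- spearman_with_S(x, y)
  expect_equal(r3$rho, cor(rank(x), rank(y)), tolerance = 1e-12)
  expect_equal(r3$S, sum((rank(x) - rank(y))^2), tolerance = 1e-9)
  expect_error(spearman_with_S(rep(1, 5), 1:5), "constant")
})
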