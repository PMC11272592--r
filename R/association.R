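# Permutation statistics on distance matrices: Mantel (Spearman by default),
# multiple matrix regression (MMRR), CADM global and a posteriori, and
# multiplicity adjustment. Permutations always relabel objects (simultaneous
# row/column permutation); p values use the add-one estimator and are
# two-sided.

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

perm_indices <- function(n, n_perm, exhaustive) {
  if (exhaustive) {
    p <- all_permutations(n)
    p[-1L, , drop = FALSE]              # identity excluded; added back as +1
  } else {
    t(vapply(seq_len(n_perm), function(i) sample.int(n), integer(n)))
  }
}

#' Mantel test between two distance matrices
#'
#' Correlation (Spearman by default, as a rank-based Mantel rho; Pearson
#' optional) of the unfolded upper triangles. The null distribution permutes
#' the object labels of `d2` (rows and columns simultaneously); the two-sided
#' p value is `(1 + #{|rho*| >= |rho|}) / (1 + n_perm)`. With
#' `exhaustive = TRUE` (automatic for 5 or fewer objects when feasible) all
#' `n!` relabelings are enumerated and the p value is exact.
#'
#' @param d1,d2 labelled distance matrices over the same objects
#' @param n_perm number of random permutations
#' @param seed integer seed (ignored when exhaustive)
#' @param method `"spearman"` or `"pearson"`
#' @param exhaustive enumerate all permutations instead of sampling
#' @return object of class `mantel_result`: list with `rho`, `p`,
#'   `n_permutations`, `seed`, `method`, `exhaustive`
#' @export
mantel_test <- function(d1, d2, n_perm = 1000, seed = 1L,
                        method = c("spearman", "pearson"),
                        exhaustive = NULL) {
  method <- match.arg(method)
  mats <- align_matrices(list(unclass(d1), unclass(d2)))
  n <- nrow(mats[[1L]])
  if (is.null(exhaustive)) exhaustive <- n <= 5L
  x <- upper_vec(mats[[1L]]); y <- upper_vec(mats[[2L]])
  if (sd(x) == 0 || sd(y) == 0) stop("constant distance matrix: correlation undefined")
  if (method == "spearman") { x <- rank(x); y0 <- mats[[2L]] }
  obs <- if (method == "spearman") cor(x, rank(y)) else cor(x, y)
  if (!exhaustive) set.seed(seed)
  perms <- perm_indices(n, n_perm, exhaustive)
  stat <- numeric(nrow(perms))
  for (i in seq_len(nrow(perms))) {
    pm <- perms[i, ]
    yp <- upper_vec(mats[[2L]][pm, pm])
    stat[i] <- if (method == "spearman") cor(x, rank(yp)) else cor(upper_vec(mats[[1L]]), yp)
  }
  p <- (1 + sum(abs(stat) >= abs(obs) - 1e-12)) / (1 + nrow(perms))
  structure(list(rho = obs, p = p, n_permutations = nrow(perms), seed = seed,
                 method = method, exhaustive = exhaustive),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel (%s): rho = %.4f, p = %.4g (%d permutations%s)\n",
              x$method, x$rho, x$p, x$n_permutations,
              if (x$exhaustive) ", exhaustive" else ""))
  invisible(x)
}

#' Multiple matrix regression with permutation tests (MMRR)
#'
#' Ordinary least squares of the unfolded upper triangle of the response
#' distance matrix on those of the predictor matrices. Significance per
#' coefficient comes from permuting the response matrix's object labels and
#' recomputing t statistics (two-sided, add-one estimator); the overall R^2
#' is tested against the permuted F statistic.
#'
#' @param d_response response distance matrix
#' @param predictors named list of predictor distance matrices
#' @param n_perm permutations
#' @param seed integer seed
#' @param exhaustive enumerate all relabelings (automatic for n <= 5)
#' @return object of class `mmrr_result`: `coefficients`, `t`, `p`
#'   (per predictor, including intercept with `NA` p), `r_squared`, `p_model`
#' @export
mmrr <- function(d_response, predictors, n_perm = 1000, seed = 1L,
                 exhaustive = NULL) {
  if (is.null(names(predictors)))
    names(predictors) <- paste0("X", seq_along(predictors))
  mats <- align_matrices(c(list(unclass(d_response)),
                           lapply(predictors, unclass)))
  n <- nrow(mats[[1L]])
  if (is.null(exhaustive)) exhaustive <- n <= 5L
  y <- upper_vec(mats[[1L]])
  X <- vapply(mats[-1L], upper_vec, numeric(length(y)))
  if (length(predictors) > 1L) {
    cc <- cor(X)
    diag(cc) <- 0
    if (any(abs(cc) > 1 - 1e-12)) {
      idx <- which(abs(cc) == max(abs(cc)), arr.ind = TRUE)[1L, ]
      stop("perfectly collinear predictors: ",
           names(predictors)[idx[1L]], " and ", names(predictors)[idx[2L]])
    }
  }
  fit_t <- function(yv) {
    f <- lm(yv ~ X)
    s <- suppressWarnings(summary(f))   # degenerate exact fits are legal here
    list(coef = coef(f), t = s$coefficients[, "t value"],
         r2 = s$r.squared,
         fstat = unname(s$fstatistic[1L]))
  }
  obs <- fit_t(y)
  if (!exhaustive) set.seed(seed)
  perms <- perm_indices(n, n_perm, exhaustive)
  tmat <- matrix(NA_real_, nrow(perms), length(obs$t))
  fvec <- numeric(nrow(perms))
  for (i in seq_len(nrow(perms))) {
    pm <- perms[i, ]
    yp <- upper_vec(mats[[1L]][pm, pm])
    r <- fit_t(yp)
    tmat[i, ] <- r$t
    fvec[i] <- r$fstat
  }
  p <- vapply(seq_along(obs$t), function(k)
    (1 + sum(abs(tmat[, k]) >= abs(obs$t[k]) - 1e-12)) / (1 + nrow(perms)),
    numeric(1L))
  p[1L] <- NA_real_                      # intercept not tested
  names(obs$coef) <- names(p) <- c("(Intercept)", names(predictors))
  p_model <- (1 + sum(fvec >= obs$fstat - 1e-12)) / (1 + nrow(perms))
  structure(list(coefficients = obs$coef, t = obs$t, p = p,
                 r_squared = obs$r2, p_model = p_model,
                 n_permutations = nrow(perms), seed = seed,
                 exhaustive = exhaustive),
            class = "mmrr_result")
}

#' @export
print.mmrr_result <- function(x, ...) {
  cat(sprintf("MMRR: R^2 = %.4f (model p = %.4g, %d permutations)\n",
              x$r_squared, x$p_model, x$n_permutations))
  print(data.frame(coefficient = x$coefficients, p = x$p))
  invisible(x)
}

#' Congruence among distance matrices: global test
#'
#' Kendall's coefficient of concordance W over the ranked unfolded distances
#' of two or more matrices, with the permutation test of Legendre &
#' Lapointe as implemented in `ape::CADM.global` (each matrix permuted
#' independently under the null of overall incongruence). For `k = 2`,
#' `W = (r + 1) / 2` with `r` the inter-matrix Spearman correlation.
#'
#' @param mats named list of at least two aligned distance matrices
#' @param n_perm permutations
#' @param seed integer seed
#' @return object of class `cadm_result`: `W`, `chi2`, `p`, `n_permutations`,
#'   `seed`
#' @export
cadm_global <- function(mats, n_perm = 1000, seed = 1L) {
  if (length(mats) < 2L) stop("CADM needs at least two matrices")
  mats <- align_matrices(lapply(mats, unclass))
  n <- nrow(mats[[1L]])
  stacked <- do.call(rbind, mats)
  set.seed(seed)
  utils::capture.output(
    res <- ape::CADM.global(stacked, nmat = length(mats), n = n,
                            nperm = n_perm))
  structure(list(W = unname(res$congruence_analysis["W", 1L]),
                 chi2 = unname(res$congruence_analysis["Chi2", 1L]),
                 p = unname(res$congruence_analysis["Prob.perm", 1L]),
                 n_permutations = n_perm, seed = seed),
            class = "cadm_result")
}

#' CADM a posteriori tests per matrix
#'
#' For each matrix, the mean rank correlation with the remaining matrices and
#' a permutation p value obtained by permuting only that matrix
#' (`ape::CADM.post`), Holm-adjusted across matrices.
#'
#' @param mats named list of aligned distance matrices
#' @param n_perm permutations
#' @param seed integer seed
#' @return data.frame with `matrix`, `mean_rank_cor`, `p`, `p_holm`
#' @export
cadm_post <- function(mats, n_perm = 1000, seed = 1L) {
  if (length(mats) < 2L) stop("CADM needs at least two matrices")
  mats <- align_matrices(lapply(mats, unclass))
  n <- nrow(mats[[1L]])
  stacked <- do.call(rbind, mats)
  set.seed(seed)
  utils::capture.output(
    res <- ape::CADM.post(stacked, nmat = length(mats), n = n, nperm = n_perm,
                          mult = "holm"))
  nm <- if (!is.null(names(mats))) names(mats)
        else paste0("M", seq_along(mats))
  raw <- res$A_posteriori_tests
  data.frame(matrix = nm,
             mean_rank_cor = unname(raw["Mantel.mean", ]),
             p = unname(raw["Prob", ]),
             p_holm = unname(raw["Corrected.prob", ]),
             row.names = NULL)
}

#' Adjust p values for multiple testing
#'
#' Benjamini-Hochberg step-up or Holm step-down (via [stats::p.adjust()]),
#' monotone and capped at 1.
#'
#' @param p numeric p values in `[0, 1]`
#' @param method `"bh"` or `"holm"`
#' @return adjusted p values
#' @export
p_adjust <- function(p, method = c("bh", "holm")) {
  method <- match.arg(tolower(method[1L]), c("bh", "holm"))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p values must lie in [0, 1]")
  p.adjust(p, method = if (method == "bh") "BH" else "holm")
}
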