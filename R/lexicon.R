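# Shared-vocabulary counting from cognate-coded word lists, tree-based
# linguistic distances, and the zero-inflated Poisson / nonparametric test
# battery.

#' Construct a cognate-coded word table
#'
#' One row per (group, word) record with its cognate-set id. The restricted
#' view of the data keeps rows whose cognate judgement is conclusive AND
#' whose term is unique to the hunter-gatherer groups.
#'
#' @param df data.frame with columns `group`, `domain`, `object_id`, `word`,
#'   `cognate_id`, `unique_to_cahg` (logical/0-1), `confidence`
#'   (`"conclusive"` or `"tentative"`)
#' @return object of class `cognate_table`
#' @export
cognate_table <- function(df) {
  need <- c("group", "domain", "object_id", "word", "cognate_id",
            "unique_to_cahg", "confidence")
  if (!all(need %in% names(df)))
    stop("missing cognate columns: ", paste(setdiff(need, names(df)), collapse = ", "))
  df$unique_to_cahg <- as.logical(df$unique_to_cahg)
  structure(list(records = df), class = "cognate_table")
}

#' @export
print.cognate_table <- function(x, ...) {
  cat(sprintf("cognate_table: %d records, %d groups, %d cognate sets\n",
              nrow(x$records), length(unique(x$records$group)),
              length(unique(x$records$cognate_id))))
  invisible(x)
}

#' Dyadic shared-word counts and cognate-set degree distribution
#'
#' A dyad's count is the number of cognate sets present in both groups; the
#' degree distribution tabulates cognate sets by the number of distinct
#' groups carrying them (degree >= 2, i.e. actually shared). Duplicate
#' (group, cognate set) rows are collapsed with a warning.
#'
#' @param tab a [cognate_table()]
#' @param domain optional domain filter (e.g. `"music"`)
#' @param restricted restrict to conclusive, CAHG-unique terms
#' @param groups optional fixed group universe for the count matrix
#' @return list with `counts` (symmetric group x group integer matrix),
#'   `degree_distribution` (named integer vector), `n_shared_sets`
#' @export
shared_word_counts <- function(tab, domain = NULL, restricted = FALSE,
                               groups = NULL) {
  df <- tab$records
  if (!is.null(domain)) df <- df[df$domain == domain, , drop = FALSE]
  if (restricted)
    df <- df[df$confidence == "conclusive" & df$unique_to_cahg, , drop = FALSE]
  if (is.null(groups)) groups <- sort(unique(tab$records$group))
  counts <- matrix(0L, length(groups), length(groups),
                   dimnames = list(groups, groups))
  if (nrow(df)) {
    pairs <- unique(df[, c("group", "cognate_id")])
    if (nrow(pairs) < nrow(df[, c("group", "cognate_id")]))
      warning("duplicate (group, cognate set) rows collapsed")
    carriers <- split(pairs$group, pairs$cognate_id)
    deg <- lengths(carriers)
    for (cs in carriers[deg >= 2L]) {
      idx <- match(cs, groups)
      for (i in seq_along(idx)[-length(idx)]) for (j in (i + 1L):length(idx)) {
        counts[idx[i], idx[j]] <- counts[idx[i], idx[j]] + 1L
        counts[idx[j], idx[i]] <- counts[idx[j], idx[i]] + 1L
      }
    }
    dd <- table(factor(deg[deg >= 2L]))
  } else dd <- table(factor(integer()))
  list(counts = counts,
       degree_distribution = setNames(as.integer(dd), names(dd)),
       n_shared_sets = sum(as.integer(dd)))
}

#' Internal-node distance between two languages on a reference tree
#'
#' The number of internal nodes strictly on the tip-to-tip path, endpoints
#' excluded (each internal node on the path counted once); identical tips
#' give 0. On `((A,B),C)`, A-B crosses one internal node and A-C two.
#'
#' @param tree an `ape::phylo` tree (e.g. a merged Glottolog subtree)
#' @param a,b tip labels
#' @return integer node count
#' @export
glottolog_node_distance <- function(tree, a, b) {
  for (tip in c(a, b)) if (!tip %in% tree$tip.label)
    stop("tip not in tree: ", tip)
  if (a == b) return(0L)
  ia <- match(a, tree$tip.label); ib <- match(b, tree$tip.label)
  path <- ape::nodepath(tree, ia, ib)
  sum(path > ape::Ntip(tree))
}

#' Patristic distance with an out-of-family maximum-depth rule
#'
#' Sum of branch lengths on the tip-to-tip path of a dated phylogeny. For
#' languages outside the family covered by the tree, the maximum root-to-tip
#' depth of the tree is returned as the distance to any other language.
#'
#' @param tree a dated `ape::phylo` tree with branch lengths
#' @param a,b tip labels (or names listed in `out_of_family`)
#' @param out_of_family character vector of languages not on the tree
#' @return numeric distance
#' @export
patristic_distance <- function(tree, a, b, out_of_family = character()) {
  if (a == b) return(0)
  if (a %in% out_of_family || b %in% out_of_family)
    return(max(ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]))
  for (tip in c(a, b)) if (!tip %in% tree$tip.label)
    stop("tip not in tree and not declared out-of-family: ", tip)
  d <- ape::cophenetic.phylo(tree)
  d[a, b]
}

#' Average pairwise linguistic distance for multi-language groups
#'
#' Groups speaking several languages contribute the mean of the pairwise
#' distances over their languages.
#'
#' @param dist_fun function of two language names returning a distance
#' @param langs_a,langs_b character vectors of the two groups' languages
#' @return averaged distance
#' @export
group_language_distance <- function(dist_fun, langs_a, langs_b) {
  mean(outer(langs_a, langs_b, Vectorize(dist_fun)))
}

# ---------------------------------------------------------------------------
# Zero-inflated Poisson regression by direct maximum likelihood
# ---------------------------------------------------------------------------

zip_nll <- function(par, y, X1, Z1, trace_env = NULL) {
  k <- ncol(X1)
  beta <- par[seq_len(k)]; gamma <- par[-seq_len(k)]
  lam <- exp(drop(X1 %*% beta))
  zeta <- drop(Z1 %*% gamma)
  pi0 <- plogis(zeta)
  ll <- numeric(length(y))
  z <- y == 0L
  ll[z] <- log(pi0[z] + (1 - pi0[z]) * exp(-lam[z]) + 1e-300)
  ll[!z] <- log1p(-pi0[!z]) - lam[!z] + y[!z] * log(lam[!z]) - lgamma(y[!z] + 1)
  nll <- -sum(ll)
  if (!is.finite(nll)) nll <- 1e12        # keep the optimizer away from overflow
  if (!is.null(trace_env)) {
    if (nll < trace_env$best) trace_env$best <- nll
    trace_env$trace <- c(trace_env$trace, trace_env$best)
  }
  nll
}

#' Fit a zero-inflated Poisson model by direct maximum likelihood
#'
#' `P(y=0) = pi + (1-pi) e^{-lambda}`, `P(y=k>0) = (1-pi) e^{-lambda}
#' lambda^k / k!`, with `log lambda = X beta` (count model) and
#' `logit pi = Z gamma` (binary part). Optimization uses BFGS from two
#' deterministic starts (a Poisson-regression start with zero inflation set
#' from the observed zero excess, and a moment start); standard errors come
#' from the observed information at the optimum. The best negative
#' log-likelihood seen is monitored and never worsens across iterations.
#'
#' @param y non-negative integer counts
#' @param X standardized predictor matrix for the count model (no intercept
#'   column; one is added)
#' @param Z predictor matrix for the zero model; defaults to `X` (same set)
#' @param max_iter optimizer iteration cap per start
#' @return object of class `zip_model`: `beta`, `gamma`, `se_beta`,
#'   `se_gamma`, `loglik`, `fitted_lambda`, `fitted_pi`, `convergence`,
#'   `loglik_trace`
#' @export
zip_fit <- function(y, X, Z = X, max_iter = 2000) {
  stopifnot(all(y >= 0), all(y == round(y)))
  if (all(y == 0)) stop("all counts zero: model unidentifiable")
  X1 <- cbind(`(Intercept)` = 1, X)
  Z1 <- cbind(`(Intercept)` = 1, Z)
  k <- ncol(X1); m <- ncol(Z1)
  pois <- glm.fit(X1, y, family = poisson())
  p0_obs <- mean(y == 0)
  p0_pois <- mean(exp(-pois$fitted.values))
  excess <- max(p0_obs - p0_pois, 0.01)
  starts <- list(
    c(pois$coefficients, qlogis(min(max(excess, 0.01), 0.95)), rep(0, m - 1L)),
    c(log(mean(y[y > 0]) + 0.5), rep(0, k - 1L),
      qlogis(min(max(p0_obs, 0.01), 0.95)), rep(0, m - 1L)))
  best <- NULL
  tr <- new.env(); tr$best <- Inf; tr$trace <- numeric()
  for (s in starts) {
    fit <- tryCatch(
      optim(s, zip_nll, y = y, X1 = X1, Z1 = Z1, trace_env = tr,
            method = "BFGS", hessian = FALSE,
            control = list(maxit = max_iter, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best))
    stop("zero-inflated Poisson fit failed from all starts")
  if (best$convergence != 0)
    stop("zero-inflated Poisson fit did not converge (code ",
         best$convergence, ")")
  H <- optimHess(best$par, zip_nll, y = y, X1 = X1, Z1 = Z1)
  cov <- tryCatch(solve(H), error = function(e) matrix(NA_real_, k + m, k + m))
  se <- sqrt(pmax(diag(cov), 0))
  beta <- setNames(best$par[seq_len(k)], colnames(X1))
  gamma <- setNames(best$par[-seq_len(k)], colnames(Z1))
  lam <- exp(drop(X1 %*% beta)); pi0 <- plogis(drop(Z1 %*% gamma))
  if (any(!is.finite(lam)) || any(lam <= 0)) stop("non-finite fitted lambda")
  structure(list(beta = beta, gamma = gamma,
                 se_beta = setNames(se[seq_len(k)], colnames(X1)),
                 se_gamma = setNames(se[-seq_len(k)], colnames(Z1)),
                 loglik = -best$value, fitted_lambda = lam, fitted_pi = pi0,
                 convergence = best$convergence,
                 loglik_trace = -tr$trace),
            class = "zip_model")
}

#' @export
print.zip_model <- function(x, ...) {
  cat("zero-inflated Poisson fit, logLik =", format(x$loglik, digits = 6), "\n")
  cat("count model (log link):\n")
  print(data.frame(estimate = x$beta, se = x$se_beta))
  cat("zero model (logit link):\n")
  print(data.frame(estimate = x$gamma, se = x$se_gamma))
  invisible(x)
}

#' Paired Wilcoxon signed-rank test
#'
#' Zero differences are dropped and ties mid-ranked; the p value is exact for
#' 25 or fewer informative (non-zero, untied) pairs and a tie-corrected
#' normal approximation otherwise.
#'
#' @param x,y paired numeric vectors
#' @return list with `W` (sum of positive-difference ranks), `p`, `n_used`
#' @export
wilcoxon_signed_rank <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[d != 0]
  if (!length(d)) stop("all paired differences are zero")
  ties <- any(duplicated(abs(d)))
  exact <- length(d) <= 25 && !ties
  res <- suppressWarnings(
    wilcox.test(d, exact = exact, correct = TRUE))
  list(W = unname(res$statistic), p = res$p.value, n_used = length(d))
}

#' Spearman correlation with the S statistic
#'
#' Reports both rho and `S = sum of squared rank differences` (mid-ranks for
#' ties, matching the conventional test statistic), with the p value from
#' [stats::cor.test()].
#'
#' @param x,y equal-length numeric vectors
#' @return list with `rho`, `S`, `p`, `n`
#' @export
spearman_with_S <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (sd(x) == 0 || sd(y) == 0) stop("constant vector: rank correlation undefined")
  res <- suppressWarnings(cor.test(x, y, method = "spearman"))
  list(rho = unname(res$estimate), S = unname(res$statistic),
       p = res$p.value, n = length(x))
}
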