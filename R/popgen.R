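# Ancestry-specific allele frequencies, Hudson's FST (ratio of averages),
# pairwise-difference distances, and classical MDS.

#' Ancestry-specific site frequency table
#'
#' Counts alternate alleles over unmasked haplotypes only: for population `i`
#' at each site, `a_i` is the alternate-allele count among retained alleles,
#' `n_i` the total retained allele count and `f_i = a_i / n_i`. Sites at which
#' any population retains one or fewer alleles are dropped for all populations
#' (so `n_i > 1` everywhere); the dropped-site count is reported.
#'
#' @param hs a (masked) `haplotype_set`
#' @param populations optional subset/order of population labels
#' @return object of class `site_freq_table`: list with matrices `a`, `n`,
#'   `f` (populations x sites), `kept_sites` (logical over input sites),
#'   `n_dropped`
#' @export
site_frequencies <- function(hs, populations = NULL) {
  popvec <- hap_populations(hs)
  pops <- if (is.null(populations)) unique(popvec) else populations
  if (any(!pops %in% popvec)) stop("population with zero individuals: ",
                                   paste(setdiff(pops, popvec), collapse = ", "))
  a <- do.call(rbind, lapply(pops, function(p) {
    rowSums(hs$alleles[, popvec == p, drop = FALSE] == 1L, na.rm = TRUE)
  }))
  n <- do.call(rbind, lapply(pops, function(p) {
    rowSums(!is.na(hs$alleles[, popvec == p, drop = FALSE]))
  }))
  rownames(a) <- rownames(n) <- pops
  keep <- colSums(n <= 1L) == 0L
  structure(list(a = a[, keep, drop = FALSE], n = n[, keep, drop = FALSE],
                 f = (a / pmax(n, 1L))[, keep, drop = FALSE],
                 kept_sites = keep, n_dropped = sum(!keep),
                 populations = pops),
            class = "site_freq_table")
}

#' @export
print.site_freq_table <- function(x, ...) {
  cat(sprintf("site_freq_table: %d populations x %d sites (%d dropped by the n>1 filter)\n",
              length(x$populations), ncol(x$f), x$n_dropped))
  invisible(x)
}

#' Hudson's FST between two populations (ratio of averages)
#'
#' Per site, numerator `(f_A - f_B)^2 - f_A(1-f_A)/(n_A-1) - f_B(1-f_B)/(n_B-1)`
#' and denominator `f_A(1-f_B) + f_B(1-f_A)`; across sites the numerator and
#' denominator are averaged separately before dividing (never an average of
#' per-site ratios).
#'
#' @param sft a [site_frequencies()] table
#' @param pop_a,pop_b population labels
#' @return list with `fst`, `num_mean`, `den_mean`, `n_sites`; `fst` is `NA`
#'   (flagged `undefined`) when the mean denominator is zero
#' @export
hudson_fst <- function(sft, pop_a, pop_b) {
  ia <- match(pop_a, sft$populations); ib <- match(pop_b, sft$populations)
  if (is.na(ia) || is.na(ib)) stop("unknown population label")
  fa <- sft$f[ia, ]; fb <- sft$f[ib, ]
  na <- sft$n[ia, ]; nb <- sft$n[ib, ]
  num <- (fa - fb)^2 - fa * (1 - fa) / (na - 1) - fb * (1 - fb) / (nb - 1)
  den <- fa * (1 - fb) + fb * (1 - fa)
  nm <- mean(num); dm <- mean(den)
  if (dm == 0)
    return(list(fst = NA_real_, num_mean = nm, den_mean = dm,
                n_sites = length(num), undefined = TRUE))
  list(fst = nm / dm, num_mean = nm, den_mean = dm, n_sites = length(num),
       undefined = FALSE)
}

#' All pairwise Hudson FST values as a distance matrix
#'
#' Negative estimates (sampling noise around zero differentiation) are
#' clamped to zero by the [distance_matrix()] container.
#'
#' @param sft a `site_freq_table`
#' @return a `dist_matrix` of kind `"fst"`
#' @export
fst_matrix <- function(sft) {
  pops <- sft$populations
  m <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_along(pops)[-length(pops)]) for (j in (i + 1L):length(pops)) {
    v <- hudson_fst(sft, pops[i], pops[j])$fst
    m[i, j] <- m[j, i] <- v
  }
  if (anyNA(m)) stop("undefined FST (zero mean denominator) for some pair")
  suppressWarnings(distance_matrix(m, kind = "fst"))
}

#' Mean pairwise-difference distance between individuals
#'
#' For genotype frequency vectors `g` (dose of the alternate allele / 2),
#' `d(a, b)` is the mean over co-observed sites of
#' `g_a (1 - g_b) + g_b (1 - g_a)` — the probability that one allele drawn
#' from each individual differs.
#'
#' @param g individuals x sites genotype frequency matrix (entries 0, 0.5, 1
#'   or `NA`)
#' @return a `dist_matrix` of kind `"pairwise-difference"`
#' @export
pairwise_difference_distance <- function(g) {
  n <- nrow(g)
  if (!anyNA(g)) {
    m1 <- g %*% t(1 - g)
    d <- (m1 + t(m1)) / ncol(g)
  } else {
    d <- matrix(0, n, n)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      ok <- !is.na(g[i, ]) & !is.na(g[j, ])
      if (!any(ok)) stop("no co-observed site for pair ",
                         rownames(g)[i], " / ", rownames(g)[j])
      d[i, j] <- d[j, i] <- mean(g[i, ok] * (1 - g[j, ok]) +
                                   g[j, ok] * (1 - g[i, ok]))
    }
  }
  dimnames(d) <- list(rownames(g), rownames(g))
  distance_matrix(d, kind = "pairwise-difference")
}

#' Classical multidimensional scaling of a distance matrix
#'
#' Double-centred Gram-matrix eigendecomposition (via [stats::cmdscale()]).
#' Negative eigenvalues are reported and their axes excluded; `k` beyond the
#' positive-eigenvalue count is truncated with a warning.
#'
#' @param d a symmetric zero-diagonal distance matrix
#' @param k requested embedding dimension
#' @return list with `points` (n x k'), `eigenvalues` (all, signed),
#'   `k` (dimension actually returned)
#' @export
classical_mds <- function(d, k = 2) {
  m <- unclass(d)
  n <- nrow(m)
  fit <- cmdscale(m, k = max(1L, min(k, n - 1L)), eig = TRUE)
  eig <- fit$eig
  n_pos <- sum(eig > max(eig) * 1e-9)
  if (k > n_pos) {
    warning("k reduced to the number of positive eigenvalues (", n_pos, ")")
    k <- n_pos
  }
  pts <- if (k >= 1L) fit$points[, seq_len(min(k, ncol(fit$points))), drop = FALSE]
         else matrix(0, n, 0, dimnames = list(rownames(m), NULL))
  if (ncol(pts) == 0L && n_pos == 0L)   # fully degenerate input: zero embedding
    pts <- matrix(0, n, 1L, dimnames = list(rownames(m), NULL))
  list(points = pts, eigenvalues = eig, k = k)
}
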