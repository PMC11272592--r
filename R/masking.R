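# Local-ancestry masking and the ancestry-specific genotype frequency matrix.

#' Assign individuals to unadmixed reference panels
#'
#' An individual joins a class panel iff its genome-wide proportion of that
#' class strictly exceeds the threshold (default 98%); all others remain
#' unassigned.
#'
#' @param proportions matrix (individuals x ancestry classes) of genome-wide
#'   ancestry proportions; rows must sum to 1.
#' @param threshold strict lower bound for panel membership
#' @param tol tolerance on the row-sum check
#' @return character vector of panel assignments (`NA` = unassigned), named by
#'   individual
#' @export
select_reference_panel <- function(proportions, threshold = 0.98, tol = 1e-6) {
  stopifnot(is.matrix(proportions), !is.null(colnames(proportions)))
  if (any(abs(rowSums(proportions) - 1) > tol))
    stop("ancestry proportions must sum to 1 per individual")
  idx <- max.col(proportions)
  best <- proportions[cbind(seq_len(nrow(proportions)), idx)]
  out <- ifelse(best > threshold, colnames(proportions)[idx], NA_character_)
  names(out) <- rownames(proportions)
  out
}

#' Mask haplotypes by local ancestry
#'
#' A site on a haplotype is retained iff its covering ancestry interval
#' carries `keep_class`; sites covered by another class or by no interval
#' (gaps) become missing. Allele values are never altered, only removed.
#' Masking is idempotent.
#'
#' @param hs a [haplotype_set()]
#' @param calls an [ancestry_calls()] object covering the haplotypes
#' @param keep_class ancestry class to retain
#' @return a `haplotype_set` with the complement masked (mask code 1; gap
#'   sites code 3)
#' @export
mask_by_ancestry <- function(hs, calls, keep_class) {
  if (!keep_class %in% calls$classes)
    stop("keep_class must be one of: ", paste(calls$classes, collapse = ", "))
  alleles <- hs$alleles
  mask <- hs$mask
  for (j in seq_len(ncol(alleles))) {
    lab <- site_ancestry(calls, colnames(alleles)[j], hs$chrom, hs$pos)
    gap <- is.na(lab)
    other <- !gap & lab != keep_class
    newmask <- (other & mask[, j] == 0L)
    mask[newmask, j] <- 1L
    mask[gap & mask[, j] == 0L, j] <- 3L
    alleles[gap | other, j] <- NA_integer_
  }
  haplotype_set(alleles, hs$chrom, hs$pos, hs$cm, hs$samples, mask)
}

#' Collapse masked haplotypes to a genotype frequency matrix
#'
#' For each diploid individual and site: both haplotypes observed gives the
#' mean alternate-allele dose (0, 0.5 or 1); exactly one observed gives that
#' haplotype's allele; neither observed gives missing. Single-haplotype sites
#' therefore contribute their allele rather than being dropped — missingness
#' is reserved for sites with no retained ancestry on either haplotype.
#'
#' @param hs a masked `haplotype_set`
#' @return individuals x sites matrix with entries in \{0, 0.5, 1, NA\}
#' @export
genotype_frequency_vector <- function(hs) {
  a <- hs$alleles
  i1 <- seq(1L, ncol(a), by = 2L)
  h1 <- a[, i1, drop = FALSE]; h2 <- a[, i1 + 1L, drop = FALSE]
  s <- h1; s[is.na(h1)] <- 0L
  s2 <- h2; s2[is.na(h2)] <- 0L
  nobs <- (!is.na(h1)) + (!is.na(h2))
  g <- (s + s2) / nobs
  g[nobs == 0L] <- NA_real_
  out <- t(g)
  dimnames(out) <- list(hs$samples$sample, NULL)
  out
}

#' Complete a genotype frequency matrix by iterative low-rank approximation
#'
#' Soft-impute-style matrix completion: missing entries are initialized at
#' the column mean of the observed entries; each iteration takes an SVD of
#' the filled matrix, soft-thresholds the singular values by `lambda` (and
#' optionally truncates to `rank`), and refills only the missing cells.
#' Stops when the RMS change over missing cells drops below `tol` or after
#' `max_iter` iterations. Filled values are clipped to `[0, 1]`; observed
#' entries are never touched. Sites with no observed entry are dropped with
#' a warning.
#'
#' @param g individuals x sites matrix with `NA` for missing
#' @param rank optional hard rank cap for the approximation
#' @param lambda soft-threshold on singular values (default 0)
#' @param max_iter iteration cap; `0` returns the column-mean initialization
#' @param tol convergence tolerance on RMS change of imputed entries
#' @return list with `completed` (no missing), `kept_sites` (logical over
#'   input columns), `iterations`
#' @export
complete_matrix <- function(g, rank = NULL, lambda = 0, max_iter = 100,
                            tol = 1e-5) {
  obs <- !is.na(g)
  all_missing <- colSums(obs) == 0L
  if (any(all_missing)) {
    warning(sum(all_missing), " all-missing site(s) dropped")
    g <- g[, !all_missing, drop = FALSE]
    obs <- obs[, !all_missing, drop = FALSE]
  }
  if (!anyNA(g))
    return(list(completed = g, kept_sites = !all_missing, iterations = 0L))
  cmeans <- colSums(g * obs, na.rm = TRUE) / colSums(obs)
  x <- g
  x[!obs] <- rep(cmeans, each = nrow(g))[!obs]
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    sv <- svd(x)
    d <- pmax(sv$d - lambda, 0)
    if (!is.null(rank)) d[-seq_len(min(rank, length(d)))] <- 0
    k <- sum(d > 0)
    if (k == 0L) break
    xhat <- sv$u[, seq_len(k), drop = FALSE] %*%
      (d[seq_len(k)] * t(sv$v[, seq_len(k), drop = FALSE]))
    new <- g
    new[!obs] <- pmin(pmax(xhat[!obs], 0), 1)
    delta <- sqrt(mean((new[!obs] - x[!obs])^2))
    x <- new
    if (delta < tol) break
  }
  list(completed = x, kept_sites = !all_missing, iterations = it)
}
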