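# Shared fixtures and independent oracles. Oracles deliberately use different
# algorithms from the package code paths they check.

# Build a small haplotype set from an explicit allele matrix (sites x haps).
toy_haps <- function(alleles, pos = NULL, cm = NULL, pops = NULL) {
  n_hap <- ncol(alleles)
  stopifnot(n_hap %% 2 == 0)
  n_ind <- n_hap / 2
  ids <- sprintf("S%02d", seq_len(n_ind))
  colnames(alleles) <- as.vector(rbind(paste0(ids, "_h1"), paste0(ids, "_h2")))
  if (is.null(pos)) pos <- seq_len(nrow(alleles)) * 1000L
  if (is.null(cm)) cm <- pos / 1e6 * 100   # 100 cM/Mb toy map
  if (is.null(pops)) pops <- rep("pop1", n_ind)
  haplotype_set(alleles, rep("1", nrow(alleles)), pos, cm,
                data.frame(sample = ids, population = pops,
                           stringsAsFactors = FALSE))
}

rand_dist <- function(n, labels = paste0("g", seq_len(n))) {
  m <- as.matrix(dist(matrix(rnorm(n * 2), n)))
  dimnames(m) <- list(labels, labels)
  distance_matrix(m)
}

# Exhaustive permutations by an insertion scheme (independent of the
# package's prefix-recursion enumerator).
oracle_perms <- function(n) {
  out <- list(1L)
  for (k in 2:n) {
    nxt <- list()
    for (p in out) for (pos in 0:(k - 1L)) {
      nxt[[length(nxt) + 1L]] <- append(p, k, after = pos)
    }
    out <- nxt
  }
  do.call(rbind, out)
}

# Exact two-sided Mantel p by enumerating all n! relabelings of d2.
oracle_mantel_exact <- function(d1, d2, method = "spearman") {
  x <- d1[upper.tri(d1)]
  obs <- cor(x, d2[upper.tri(d2)], method = method)
  perms <- oracle_perms(nrow(d1))
  stats <- apply(perms, 1L, function(pm) {
    dp <- d2[pm, pm]
    cor(x, dp[upper.tri(dp)], method = method)
  })
  list(rho = obs, p = mean(abs(stats) >= abs(obs) - 1e-12))
}

# Brute-force run scan between two haplotype vectors: list of (start, end)
# site-index runs of equality.
oracle_runs <- function(a, b) {
  runs <- list()
  i <- 1L; n <- length(a)
  while (i <= n) {
    if (a[i] == b[i]) {
      j <- i
      while (j < n && a[j + 1L] == b[j + 1L]) j <- j + 1L
      runs[[length(runs) + 1L]] <- c(i, j)
      i <- j + 1L
    } else i <- i + 1L
  }
  runs
}

# Site-by-site masked-entry count from interval records (independent of the
# findInterval-based package path).
oracle_masked_count <- function(calls_df, keep_class, chrom, pos, hap_ids) {
  cnt <- 0L
  for (h in hap_ids) {
    sub <- calls_df[calls_df$hap_id == h, , drop = FALSE]
    for (s in seq_along(pos)) {
      lab <- NA_character_
      for (r in seq_len(nrow(sub))) {
        if (sub$chrom[r] == chrom[s] && pos[s] >= sub$start[r] &&
            pos[s] < sub$end[r]) lab <- sub$ancestry[r]
      }
      if (is.na(lab) || lab != keep_class) cnt <- cnt + 1L
    }
  }
  cnt
}

default_tree <- function() ape::read.tree(text = "((A:2,B:3):1,C:4);")
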