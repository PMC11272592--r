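#' @keywords internal
"_PACKAGE"

#' @importFrom stats approx cor cmdscale qlogis plogis rbinom rbeta rpois runif
#'   rnorm rexp rgamma optim optimHess p.adjust glm.fit poisson pnorm qnorm
#'   quantile wilcox.test cor.test setNames sd var dist lm coef
#' @importFrom utils read.table write.table read.csv write.csv head
NULL

# ---------------------------------------------------------------------------
# HaplotypeSet: phased 0/1 alleles, sites x (2 * individuals)
# ---------------------------------------------------------------------------

#' Construct a phased haplotype set
#'
#' Container for a phased, bi-allelic 0/1 allele matrix over sites (rows) and
#' haplotypes (columns; two per diploid individual), with population labels and
#' a maskable missing state (`NA`).
#'
#' @param alleles integer matrix (sites x haplotypes) with entries 0, 1 or `NA`.
#'   Column names must be haplotype ids of the form `<sample>_h1` / `<sample>_h2`.
#' @param chrom chromosome per site (character or integer vector).
#' @param pos 1-based bp position per site, ascending within chromosome.
#' @param cm interpolated genetic-map position (cM) per site.
#' @param samples data.frame with columns `sample` and `population`.
#' @param mask optional integer matrix, same shape as `alleles`: 0 observed,
#'   1 ancestry-masked, 2 IBD-masked, 3 ancestry-gap. `alleles` must be `NA`
#'   exactly where `mask > 0`.
#' @return an object of class `haplotype_set`.
#' @export
haplotype_set <- function(alleles, chrom, pos, cm, samples, mask = NULL) {
  stopifnot(is.matrix(alleles), nrow(alleles) == length(pos),
            length(chrom) == length(pos), length(cm) == length(pos))
  if (is.null(colnames(alleles)))
    stop("allele matrix must carry haplotype ids as column names")
  vals <- alleles[!is.na(alleles)]
  if (length(vals) && !all(vals %in% c(0L, 1L)))
    stop("alleles must be coded 0/1 (bi-allelic)")
  if (!all(c("sample", "population") %in% names(samples)))
    stop("samples needs columns 'sample' and 'population'")
  expected <- as.vector(rbind(paste0(samples$sample, "_h1"),
                              paste0(samples$sample, "_h2")))
  if (!identical(colnames(alleles), expected))
    stop("haplotype columns must be <sample>_h1,<sample>_h2 in sample order")
  ord <- order(as.character(chrom), pos)
  if (!identical(ord, seq_along(pos)))
    stop("sites must be sorted by chromosome and ascending position")
  if (is.null(mask)) {
    mask <- matrix(0L, nrow(alleles), ncol(alleles),
                   dimnames = dimnames(alleles))
    mask[is.na(alleles)] <- 3L
  }
  stopifnot(identical(dim(mask), dim(alleles)))
  if (!all(is.na(alleles) == (mask > 0L)))
    stop("mask and NA pattern disagree")
  structure(list(alleles = alleles, chrom = as.character(chrom), pos = pos,
                 cm = cm, samples = samples, mask = mask),
            class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat(sprintf("haplotype_set: %d sites x %d haplotypes (%d individuals, %d populations)\n",
              nrow(x$alleles), ncol(x$alleles), nrow(x$samples),
              length(unique(x$samples$population))))
  nm <- sum(x$mask > 0L)
  cat(sprintf("  masked entries: %d (%.1f%%)\n", nm,
              100 * nm / length(x$alleles)))
  invisible(x)
}

n_sites <- function(hs) nrow(hs$alleles)
hap_ids <- function(hs) colnames(hs$alleles)

#' Population label for each haplotype column
#' @param hs a `haplotype_set`
#' @return character vector, one entry per haplotype column
#' @export
hap_populations <- function(hs) {
  rep(hs$samples$population, each = 2L)
}

# ---------------------------------------------------------------------------
# GeneticMap
# ---------------------------------------------------------------------------

#' Construct a genetic map
#'
#' Ordered (chromosome, bp, cM) records. Map positions must be non-decreasing
#' with bp within each chromosome; any genotyped site is resolvable to a cM
#' coordinate by linear interpolation with endpoint clamping.
#'
#' @param chrom,pos,cm parallel vectors of chromosome, bp position and cM.
#' @return object of class `genetic_map` (a data.frame).
#' @export
genetic_map <- function(chrom, pos, cm) {
  df <- data.frame(chrom = as.character(chrom), pos = as.integer(pos), cm = cm)
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  for (ch in unique(df$chrom)) {
    sub <- df[df$chrom == ch, ]
    if (is.unsorted(sub$cm))
      stop("map cM positions must be non-decreasing with bp on chromosome ", ch)
    if (anyDuplicated(sub$pos)) stop("duplicated bp position in map")
  }
  class(df) <- c("genetic_map", "data.frame")
  df
}

#' Interpolate cM coordinates for bp positions
#'
#' Linear interpolation within the map; positions beyond the mapped range are
#' clamped to the terminal cM values unless `extrapolate = TRUE`, in which case
#' the terminal map rate is extended.
#'
#' @param map a `genetic_map`
#' @param chrom,pos site coordinates
#' @param extrapolate extend beyond the mapped range instead of clamping
#' @return numeric cM vector
#' @export
cm_at <- function(map, chrom, pos, extrapolate = FALSE) {
  chrom <- as.character(chrom)
  out <- numeric(length(pos))
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    sub <- map[map$chrom == ch, , drop = FALSE]
    if (nrow(sub) == 0L) stop("chromosome ", ch, " absent from genetic map")
    if (nrow(sub) == 1L) { out[i] <- sub$cm; next }
    out[i] <- approx(sub$pos, sub$cm, xout = pos[i], rule = 2)$y
    if (extrapolate) {
      lo <- pos[i] < sub$pos[1L]; hi <- pos[i] > sub$pos[nrow(sub)]
      r_lo <- (sub$cm[2L] - sub$cm[1L]) / (sub$pos[2L] - sub$pos[1L])
      n <- nrow(sub)
      r_hi <- (sub$cm[n] - sub$cm[n - 1L]) / (sub$pos[n] - sub$pos[n - 1L])
      out[i][lo] <- sub$cm[1L] - (sub$pos[1L] - pos[i][lo]) * r_lo
      out[i][hi] <- sub$cm[n] + (pos[i][hi] - sub$pos[n]) * r_hi
    }
  }
  out
}

# ---------------------------------------------------------------------------
# LocalAncestryCalls: half-open [start, end) bp intervals per haplotype
# ---------------------------------------------------------------------------

#' Construct local-ancestry calls
#'
#' Per-haplotype genomic intervals labelled with an ancestry class. Intervals
#' are half-open `[start, end)` in 1-based bp, non-overlapping and sorted
#' within each haplotype. Gaps are legal and are treated as missing ancestry
#' (masked in every ancestry layer).
#'
#' @param df data.frame with columns `chrom`, `start`, `end`, `hap_id`,
#'   `ancestry`.
#' @param classes declared ancestry class names; labels outside this set error.
#' @return object of class `ancestry_calls`.
#' @export
ancestry_calls <- function(df, classes) {
  need <- c("chrom", "start", "end", "hap_id", "ancestry")
  if (!all(need %in% names(df))) stop("missing columns: ",
                                      paste(setdiff(need, names(df)), collapse = ", "))
  if (any(df$start >= df$end)) stop("intervals must satisfy start < end")
  bad <- setdiff(unique(df$ancestry), classes)
  if (length(bad)) stop("unknown ancestry label(s): ", paste(bad, collapse = ", "))
  df <- df[order(df$hap_id, df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  for (key in unique(paste(df$hap_id, df$chrom))) {
    sub <- df[paste(df$hap_id, df$chrom) == key, ]
    if (nrow(sub) > 1L && any(sub$start[-1L] < sub$end[-nrow(sub)]))
      stop("overlapping ancestry intervals on haplotype ", sub$hap_id[1L])
  }
  structure(list(calls = df, classes = classes), class = "ancestry_calls")
}

#' @export
print.ancestry_calls <- function(x, ...) {
  cat(sprintf("ancestry_calls: %d intervals, %d haplotypes, classes: %s\n",
              nrow(x$calls), length(unique(x$calls$hap_id)),
              paste(x$classes, collapse = ", ")))
  invisible(x)
}

# Ancestry label of each site on one haplotype; NA for uncovered (gap) sites.
site_ancestry <- function(calls, hap, chrom, pos) {
  lab <- rep(NA_character_, length(pos))
  sub <- calls$calls[calls$calls$hap_id == hap, , drop = FALSE]
  for (ch in unique(sub$chrom)) {
    s <- sub[sub$chrom == ch, , drop = FALSE]
    i <- which(chrom == ch)
    if (!length(i) || !nrow(s)) next
    k <- findInterval(pos[i], s$start)
    ok <- k > 0L & pos[i] < s$end[pmax(k, 1L)]
    lab[i][ok] <- s$ancestry[k[ok]]
  }
  lab
}

# ---------------------------------------------------------------------------
# IBDSegmentSet
# ---------------------------------------------------------------------------

#' Construct an IBD segment set
#'
#' Records of shared haplotype intervals between two named haplotypes, stored
#' in canonical pair order (lexicographic by individual id, then haplotype
#' index) so symmetric duplicates collapse.
#'
#' @param df data.frame with columns `id1`, `hap1`, `id2`, `hap2`, `chrom`,
#'   `start`, `end`, `lod`, `length_cm` (and optionally `length_cm_map`,
#'   `pop1`, `pop2`).
#' @return object of class `ibd_set`.
#' @export
ibd_set <- function(df) {
  need <- c("id1", "hap1", "id2", "hap2", "chrom", "start", "end", "lod", "length_cm")
  if (nrow(df) == 0L) {
    df <- as.data.frame(setNames(rep(list(vector()), length(need)), need))
    return(structure(list(segments = df[0, , drop = FALSE]), class = "ibd_set"))
  }
  if (!all(need %in% names(df))) stop("missing IBD columns: ",
                                      paste(setdiff(need, names(df)), collapse = ", "))
  if (any(df$start >= df$end)) stop("IBD segments must satisfy start < end")
  if (any(df$length_cm < 0)) stop("negative IBD cM length")
  if (!all(df$hap1 %in% 1:2 & df$hap2 %in% 1:2))
    stop("haplotype indices must be 1 or 2")
  swap <- df$id1 > df$id2 | (df$id1 == df$id2 & df$hap1 > df$hap2)
  if (any(swap)) {
    tmp_id <- df$id1[swap]; tmp_h <- df$hap1[swap]
    df$id1[swap] <- df$id2[swap]; df$hap1[swap] <- df$hap2[swap]
    df$id2[swap] <- tmp_id;       df$hap2[swap] <- tmp_h
    if (all(c("pop1", "pop2") %in% names(df))) {
      tp <- df$pop1[swap]; df$pop1[swap] <- df$pop2[swap]; df$pop2[swap] <- tp
    }
  }
  df <- df[order(df$id1, df$hap1, df$id2, df$hap2, df$chrom, df$start), ,
           drop = FALSE]
  rownames(df) <- NULL
  structure(list(segments = df), class = "ibd_set")
}

#' @export
print.ibd_set <- function(x, ...) {
  cat(sprintf("ibd_set: %d segments, total %.2f cM\n",
              nrow(x$segments), sum(x$segments$length_cm)))
  invisible(x)
}

ibd_hap_id <- function(id, hap) paste0(id, "_h", hap)

# ---------------------------------------------------------------------------
# DistanceMatrix
# ---------------------------------------------------------------------------

#' Construct a labelled distance matrix
#'
#' Symmetric group-by-group dissimilarities with zero diagonal. Negative
#' entries (possible for small FST estimates) are clamped to zero with a
#' warning unless `clamp = FALSE`, in which case they error.
#'
#' @param m square numeric matrix with dimnames.
#' @param kind metadata tag: one of `"jaccard"`, `"gower"`, `"geographic"`,
#'   `"fst"`, `"pcoa-derived"`, `"pairwise-difference"`, `"generic"`.
#' @param clamp clamp small negative values to zero (default TRUE).
#' @param tol symmetry tolerance.
#' @return object of class `dist_matrix` (a matrix with attributes).
#' @export
distance_matrix <- function(m, kind = "generic", clamp = TRUE, tol = 1e-12) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (is.null(rownames(m))) stop("distance matrix must be labelled")
  if (max(abs(m - t(m))) > max(tol, 1e-8 * max(abs(m), 1)))
    stop("matrix is asymmetric beyond tolerance")
  m <- (m + t(m)) / 2
  diag(m) <- 0
  if (any(m < 0)) {
    if (!clamp) stop("negative distances")
    warning(sprintf("%d negative entries clamped to 0 (kind=%s)",
                    sum(m < 0), kind))
    m[m < 0] <- 0
  }
  structure(m, kind = kind, class = c("dist_matrix", "matrix", "array"))
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("dist_matrix (%s): %d x %d\n", attr(x, "kind"), nrow(x), ncol(x)))
  print(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x)))])
  invisible(x)
}

#' Upper-triangle unfolding of a distance matrix
#' @param m square symmetric matrix
#' @return numeric vector of the strictly-upper-triangular entries
#' @export
upper_vec <- function(m) m[upper.tri(m)]

# align a list of labelled distance matrices to a common label order
align_matrices <- function(mats) {
  labs <- rownames(mats[[1L]])
  lapply(mats, function(m) {
    if (!setequal(rownames(m), labs))
      stop("distance matrices carry different label sets")
    m[labs, labs, drop = FALSE]
  })
}
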