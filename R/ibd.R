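# IBD post-processing: naive exact detector for synthetic phased data, block
# merging across small gaps, cross-population length filtering, and masking
# of retained segments on their two named haplotypes.

#' Detect exact-match IBD segments between all haplotype pairs
#'
#' Maximal runs of identical alleles between every pair of haplotypes,
#' reported when their cM span reaches `min_len_cm`. Intended for synthetic
#' phased data (a stand-in for a probabilistic IBD caller on real data);
#' missing entries either error or break runs, per `missing`.
#'
#' @param hs a `haplotype_set`
#' @param min_len_cm minimal cM span (span = cM of last minus first site in
#'   the run) for a segment to be reported
#' @param missing `"error"` (default; the detector expects complete data) or
#'   `"break"` to treat missing entries as run-breaking mismatches
#' @return an [ibd_set()] with bp endpoints covering the matched sites
#'   (half-open) and map-based cM lengths
#' @export
detect_ibd_exact <- function(hs, min_len_cm = 1.0, missing = c("error", "break")) {
  missing <- match.arg(missing)
  a <- hs$alleles
  if (anyNA(a) && missing == "error")
    stop("missing entries present; detector requires complete phased data")
  haps <- colnames(a)
  ids <- sub("_h[12]$", "", haps)
  hno <- as.integer(sub(".*_h", "", haps))
  pops <- hap_populations(hs)
  recs <- list()
  for (i in seq_len(ncol(a) - 1L)) for (j in (i + 1L):ncol(a)) {
    eq <- a[, i] == a[, j]
    eq[is.na(eq)] <- FALSE
    r <- rle(eq)
    ends <- cumsum(r$lengths); starts <- c(1L, head(ends, -1L) + 1L)
    keep <- r$values
    for (k in which(keep)) {
      s <- starts[k]; e <- ends[k]
      span <- hs$cm[e] - hs$cm[s]
      if (span >= min_len_cm) {
        recs[[length(recs) + 1L]] <- data.frame(
          id1 = ids[i], hap1 = hno[i], id2 = ids[j], hap2 = hno[j],
          chrom = hs$chrom[s], start = hs$pos[s], end = hs$pos[e] + 1L,
          lod = NA_real_, length_cm = span,
          pop1 = pops[i], pop2 = pops[j], stringsAsFactors = FALSE)
      }
    }
  }
  ibd_set(if (length(recs)) do.call(rbind, recs) else data.frame())
}

# allele mismatches between two haplotypes over sites within [start, end) bp
count_mismatches <- function(hs, hap_a, hap_b, chrom, start, end) {
  sel <- hs$chrom == chrom & hs$pos >= start & hs$pos < end
  x <- hs$alleles[sel, hap_a]; y <- hs$alleles[sel, hap_b]
  sum(x != y, na.rm = TRUE)
}

#' Merge IBD blocks across small gaps
#'
#' Two adjacent segments of the same haplotype pair merge when the cM gap
#' between them is at most `gap_max_cm` and the number of allele mismatches
#' between the two haplotypes over the combined blocks-plus-gap region is at
#' most `max_inconsistent`. Merging proceeds transitively left-to-right;
#' segments of different pairs never merge. Idempotent.
#'
#' @param ibd an `ibd_set`, cM lengths consistent with the haplotype map
#' @param hs the `haplotype_set` the segments refer to (alleles are needed to
#'   count inconsistencies)
#' @param gap_max_cm maximal gap (default 0.6 cM)
#' @param max_inconsistent maximal allele mismatches across the merge region
#'   (default 1)
#' @return merged `ibd_set`
#' @export
merge_ibd_blocks <- function(ibd, hs, gap_max_cm = 0.6, max_inconsistent = 1) {
  df <- ibd$segments
  if (nrow(df) < 2L) return(ibd)
  key <- paste(df$id1, df$hap1, df$id2, df$hap2, df$chrom)
  out <- list()
  for (k in unique(key)) {
    sub <- df[key == k, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    hap_a <- ibd_hap_id(sub$id1[1L], sub$hap1[1L])
    hap_b <- ibd_hap_id(sub$id2[1L], sub$hap2[1L])
    cur <- sub[1L, , drop = FALSE]
    for (r in seq_len(nrow(sub))[-1L]) {
      nxt <- sub[r, , drop = FALSE]
      gap_cm <- cm_at_hs(hs, nxt$chrom, nxt$start) - cm_at_hs(hs, cur$chrom, cur$end)
      mism <- count_mismatches(hs, hap_a, hap_b, cur$chrom, cur$start, nxt$end)
      if (nxt$start >= cur$end && gap_cm <= gap_max_cm && mism <= max_inconsistent) {
        cur$end <- nxt$end
        cur$length_cm <- cm_at_hs(hs, cur$chrom, cur$end) -
          cm_at_hs(hs, cur$chrom, cur$start)
        if ("length_cm_map" %in% names(cur)) cur$length_cm_map <- cur$length_cm
        cur$lod <- max(cur$lod, nxt$lod)
      } else {
        out[[length(out) + 1L]] <- cur
        cur <- nxt
      }
    }
    out[[length(out) + 1L]] <- cur
  }
  ibd_set(do.call(rbind, out))
}

# cM coordinate of a bp position interpolated on the haplotype set's own sites
cm_at_hs <- function(hs, chrom, pos) {
  sel <- hs$chrom == chrom
  approx(hs$pos[sel], hs$cm[sel], xout = pos, rule = 2)$y
}

#' Keep cross-population IBD segments above a length threshold
#'
#' Retains segments whose two carriers belong to different populations and
#' whose cM length strictly exceeds `min_len_cm` (segments "exceeding 1 cM").
#'
#' @param ibd an `ibd_set`
#' @param populations named character vector: population per individual id
#' @param min_len_cm strict retention threshold (default 1 cM)
#' @return filtered `ibd_set` with `pop1`/`pop2` columns filled
#' @export
filter_cross_population <- function(ibd, populations, min_len_cm = 1.0) {
  df <- ibd$segments
  if (nrow(df) == 0L) return(ibd)
  missing <- setdiff(unique(c(df$id1, df$id2)), names(populations))
  if (length(missing)) stop("unlabeled individual(s): ",
                            paste(missing, collapse = ", "))
  df$pop1 <- unname(populations[df$id1])
  df$pop2 <- unname(populations[df$id2])
  keep <- df$pop1 != df$pop2 & seg_cm(df) > min_len_cm
  ibd_set(df[keep, , drop = FALSE])
}

#' Mask retained IBD segments on their two named haplotypes
#'
#' Every site inside a retained segment becomes missing on exactly the two
#' haplotypes named in the record; all other entries are unchanged. Applied
#' on top of ancestry masking (mask code 2 marks IBD-masked entries).
#'
#' @param hs an (already ancestry-masked) `haplotype_set`
#' @param ibd an `ibd_set` of retained segments
#' @return a `haplotype_set` with the segments additionally masked
#' @export
mask_ibd_segments <- function(hs, ibd) {
  df <- ibd$segments
  alleles <- hs$alleles; mask <- hs$mask
  for (r in seq_len(nrow(df))) {
    for (h in c(ibd_hap_id(df$id1[r], df$hap1[r]),
                ibd_hap_id(df$id2[r], df$hap2[r]))) {
      if (!h %in% colnames(alleles))
        stop("IBD segment references unknown haplotype ", h)
      sel <- hs$chrom == df$chrom[r] & hs$pos >= df$start[r] & hs$pos < df$end[r]
      newly <- sel & mask[, h] == 0L
      mask[newly, h] <- 2L
      alleles[sel, h] <- NA_integer_
    }
  }
  haplotype_set(alleles, hs$chrom, hs$pos, hs$cm, hs$samples, mask)
}
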