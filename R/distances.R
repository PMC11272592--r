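# Cultural (Jaccard), ecological (Gower), geographic (great-circle) distance
# matrices and principal coordinates analysis.

#' Jaccard distance matrix from a binary trait matrix
#'
#' `d(A, B) = |A xor B| / |A union B|`: the number of traits present in one
#' group but not the other over the number present in at least one, ignoring
#' shared absences. A pair with an empty union gets distance 0 by convention,
#' with a warning (cannot arise in non-degenerate data).
#'
#' @param traits binary groups x traits matrix
#' @return a `dist_matrix` of kind `"jaccard"`
#' @export
jaccard_matrix <- function(traits) {
  stopifnot(all(traits %in% c(0, 1)))
  m <- traits %*% t(traits)                       # intersections
  tot <- rowSums(traits)
  uni <- outer(tot, tot, "+") - m
  d <- ifelse(uni > 0, (uni - m) / uni, 0)
  if (any(uni[upper.tri(uni)] == 0))
    warning("pair(s) with empty trait union assigned distance 0")
  dimnames(d) <- list(rownames(traits), rownames(traits))
  distance_matrix(d, kind = "jaccard")
}

#' Gower dissimilarity matrix for a mixed composition table
#'
#' Numeric variables contribute range-normalized absolute differences, binary
#' variables a simple mismatch; variables are averaged over non-missing pairs.
#' Zero-range variables are excluded with a warning.
#'
#' @param x groups x variables matrix or data.frame (numeric and/or 0/1)
#' @return a `dist_matrix` of kind `"gower"`
#' @export
gower_matrix <- function(x) {
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  n <- nrow(m)
  rng <- apply(m, 2L, function(v) diff(range(v, na.rm = TRUE)))
  if (any(rng == 0)) {
    warning("zero-range variable(s) excluded: ",
            paste(colnames(m)[rng == 0], collapse = ", "))
    m <- m[, rng > 0, drop = FALSE]
    rng <- rng[rng > 0]
  }
  if (ncol(m) == 0L) stop("no usable variables for Gower dissimilarity")
  num <- matrix(0, n, n); cnt <- matrix(0, n, n)
  for (v in seq_len(ncol(m))) {
    col <- m[, v]
    binary <- all(col %in% c(0, 1), na.rm = TRUE)
    contrib <- if (binary) outer(col, col, "!=") * 1
               else abs(outer(col, col, "-")) / rng[v]
    ok <- outer(!is.na(col), !is.na(col), "&")
    contrib[!ok] <- 0
    num <- num + contrib
    cnt <- cnt + ok
  }
  d <- num / pmax(cnt, 1)
  dimnames(d) <- list(rownames(m), rownames(m))
  distance_matrix(d, kind = "gower")
}

#' Great-circle distance matrix between group centroids
#'
#' Haversine distances on a sphere of radius 6371 km.
#'
#' @param coords data.frame with columns `group`, `lat`, `lon` (decimal
#'   degrees)
#' @return a `dist_matrix` of kind `"geographic"`, in km
#' @export
greatcircle_matrix <- function(coords) {
  if (any(abs(coords$lat) > 90) || any(abs(coords$lon) > 180))
    stop("coordinates out of range")
  d <- geosphere::distm(coords[, c("lon", "lat")],
                        fun = function(p1, p2)
                          geosphere::distHaversine(p1, p2, r = 6371000)) / 1000
  dimnames(d) <- list(coords$group, coords$group)
  distance_matrix(d, kind = "geographic")
}

#' Principal coordinates analysis
#'
#' Identical computation to [classical_mds()] (shared implementation);
#' non-Euclidean inputs (e.g. Jaccard) are allowed, with negative eigenvalues
#' reported and excluded from the embedding. `k = 0` returns eigenvalues only.
#'
#' @param d symmetric distance matrix
#' @param k embedding dimension
#' @return as [classical_mds()]
#' @export
principal_coordinates <- function(d, k = 2) {
  if (k == 0) {
    fit <- cmdscale(unclass(d), k = 1, eig = TRUE)
    return(list(points = NULL, eigenvalues = fit$eig, k = 0L))
  }
  classical_mds(d, k)
}

#' Expand a distance matrix from genetic units to cultural groups
#'
#' When one genetic unit stands for several cultural groups (assumed
#' genetically undifferentiated), its distances are duplicated to every
#' mapped group and the within-unit group pairs get distance zero.
#'
#' @param d distance matrix over genetic units
#' @param mapping named character vector: cultural group -> genetic unit
#' @return a `dist_matrix` over the cultural groups
#' @export
expand_group_distances <- function(d, mapping) {
  units <- unname(mapping)
  if (!all(units %in% rownames(d)))
    stop("mapping refers to unknown genetic unit(s): ",
         paste(setdiff(units, rownames(d)), collapse = ", "))
  m <- unclass(d)[units, units, drop = FALSE]
  dimnames(m) <- list(names(mapping), names(mapping))
  diag(m) <- 0
  distance_matrix(m, kind = attr(d, "kind"))
}
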