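# Readers/writers for the external formats the pipeline touches:
# phased VCF + PLINK-style map, msp-style local-ancestry TSV, refinedIBD-style
# IBD TSV, trait/biome/coordinate/cognate CSVs, NEXUS DISTANCES, run config.

#' Read a PLINK-style genetic map
#'
#' Four whitespace-separated columns: chromosome, marker id, cM, bp.
#'
#' @param path file path
#' @return a [genetic_map()]
#' @export
read_plink_map <- function(path) {
  df <- read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) != 4L) stop("PLINK map must have 4 columns (chrom id cM bp)")
  genetic_map(chrom = df[[1L]], pos = df[[4L]], cm = df[[3L]])
}

#' Write a PLINK-style genetic map
#' @param map a `genetic_map`
#' @param path file path
#' @export
write_plink_map <- function(map, path) {
  out <- data.frame(chrom = map$chrom,
                    id = paste0(map$chrom, ":", map$pos),
                    cm = map$cm, pos = map$pos)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Load phased genotypes from VCF plus a genetic map
#'
#' Parses a phased, bi-allelic VCF (via `vcfR`), interpolates a cM coordinate
#' for every site from the map, and returns a [haplotype_set()] together with
#' the map. Multi-allelic records either error or are dropped.
#'
#' @param vcf_path path to an uncompressed or gzipped VCF
#' @param map_path path to a PLINK-style map covering the VCF chromosomes
#' @param populations optional named character vector mapping sample id to
#'   population label; defaults to a single population `"pop1"`.
#' @param drop_multiallelic drop multi-allelic/indel records instead of erroring
#' @param extrapolate_cm allow sites outside the mapped range (terminal-rate
#'   extrapolation); with the default `FALSE`, out-of-range sites error.
#' @return list with elements `haplotypes` (a `haplotype_set`) and `map`
#' @export
load_genotypes <- function(vcf_path, map_path, populations = NULL,
                           drop_multiallelic = FALSE, extrapolate_cm = FALSE) {
  map <- read_plink_map(map_path)
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  alt <- fix[, "ALT"]; ref <- fix[, "REF"]
  biall <- !grepl(",", alt) & nchar(ref) == 1L & nchar(alt) == 1L
  if (!all(biall)) {
    if (!drop_multiallelic)
      stop("multi-allelic/indel record at ", fix[!biall, "CHROM"][1L], ":",
           fix[!biall, "POS"][1L], " (set drop_multiallelic = TRUE to drop)")
    v <- v[biall, ]
    fix <- vcfR::getFIX(v)
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (any(grepl("/", gt, fixed = TRUE)))
    stop("unphased genotype at record ",
         rownames(gt)[which(apply(gt, 1, function(r) any(grepl("/", r, fixed = TRUE))))[1L]])
  samples <- colnames(gt)
  a1 <- substr(gt, 1L, 1L); a2 <- substr(gt, 3L, 3L)
  n_site <- nrow(gt)
  alleles <- matrix(NA_integer_, n_site, 2L * length(samples))
  alleles[, seq(1L, by = 2L, length.out = length(samples))] <-
    suppressWarnings(as.integer(a1))
  alleles[, seq(2L, by = 2L, length.out = length(samples))] <-
    suppressWarnings(as.integer(a2))
  colnames(alleles) <- as.vector(rbind(paste0(samples, "_h1"),
                                       paste0(samples, "_h2")))
  chrom <- fix[, "CHROM"]; pos <- as.integer(fix[, "POS"])
  ord <- order(chrom, pos)
  alleles <- alleles[ord, , drop = FALSE]
  chrom <- chrom[ord]; pos <- pos[ord]
  if (!extrapolate_cm) {
    for (ch in unique(chrom)) {
      rng <- range(map$pos[map$chrom == ch])
      p <- pos[chrom == ch]
      if (any(p < rng[1L] | p > rng[2L]))
        stop("site outside genetic-map range on chromosome ", ch,
             " (set extrapolate_cm = TRUE)")
    }
  }
  cm <- cm_at(map, chrom, pos, extrapolate = extrapolate_cm)
  pops <- if (is.null(populations)) setNames(rep("pop1", length(samples)), samples)
          else populations
  if (!all(samples %in% names(pops)))
    stop("population label missing for sample(s): ",
         paste(setdiff(samples, names(pops)), collapse = ", "))
  hs <- haplotype_set(alleles, chrom, pos, cm,
                      data.frame(sample = samples,
                                 population = unname(pops[samples]),
                                 stringsAsFactors = FALSE))
  list(haplotypes = hs, map = map)
}

#' Write a haplotype set as a phased VCF
#'
#' Masked (`NA`) entries are written as `.` alleles.
#'
#' @param hs a `haplotype_set`
#' @param path output file path (plain text)
#' @export
write_vcf <- function(hs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=ibdlayers",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
             con)
  samples <- hs$samples$sample
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"), con)
  a <- hs$alleles
  a_chr <- matrix(as.character(a), nrow(a), ncol(a))
  a_chr[is.na(a_chr)] <- "."
  i1 <- seq(1L, ncol(a), by = 2L)
  gt <- matrix(paste(a_chr[, i1], a_chr[, i1 + 1L], sep = "|"),
               nrow(a), length(samples))
  lines <- paste(hs$chrom, hs$pos, paste0("s", seq_len(nrow(a))),
                 "A", "G", ".", "PASS", ".", "GT", sep = "\t")
  body <- apply(gt, 1L, paste, collapse = "\t")
  writeLines(paste(lines, body, sep = "\t"), con)
  invisible(path)
}

#' Load msp-style local-ancestry calls
#'
#' The dialect fixed here (one of several in circulation for local-ancestry
#' output): an optional first line `#Subpopulation order/codes: NAME=0 ...`,
#' then a header `chm spos epos <sample>.0 <sample>.1 ...`, then one row per
#' interval with integer ancestry codes per haplotype column. Intervals are
#' half-open `[spos, epos)` bp.
#'
#' @param path file path
#' @param classes ancestry class names in code order; if the file carries a
#'   codes line it must agree.
#' @return an [ancestry_calls()] object
#' @export
load_local_ancestry <- function(path, classes) {
  lines <- readLines(path)
  if (length(lines) && startsWith(lines[1L], "#Subpopulation")) {
    spec <- regmatches(lines[1L], gregexpr("([A-Za-z_]+)=([0-9]+)", lines[1L]))[[1L]]
    nm <- sub("=.*", "", spec); cd <- as.integer(sub(".*=", "", spec))
    file_classes <- nm[order(cd)]
    if (!identical(file_classes, classes))
      stop("ancestry codes line disagrees with declared classes")
    lines <- lines[-1L]
  }
  df <- read.table(text = lines, header = TRUE, check.names = FALSE,
                   comment.char = "")
  names(df)[1L] <- sub("^#", "", names(df)[1L])
  hap_cols <- setdiff(names(df), c("chm", "spos", "epos", "n_snps"))
  recs <- do.call(rbind, lapply(hap_cols, function(hc) {
    code <- df[[hc]]
    if (!all(code %in% (seq_along(classes) - 1L)))
      stop("unknown ancestry code in column ", hc)
    sample <- sub("\\.[01]$", "", hc)
    hap <- as.integer(sub(".*\\.", "", hc)) + 1L
    data.frame(chrom = as.character(df$chm), start = df$spos, end = df$epos,
               hap_id = paste0(sample, "_h", hap),
               ancestry = classes[code + 1L], stringsAsFactors = FALSE)
  }))
  ancestry_calls(recs, classes)
}

#' Write local-ancestry calls in the msp-style dialect
#'
#' Requires every haplotype to carry the same interval boundaries (true for
#' simulator output after interval harmonization; [write_cohort()] guarantees
#' it by splitting on the union of breakpoints).
#'
#' @param calls an `ancestry_calls` object
#' @param path output path
#' @export
write_local_ancestry <- function(calls, path) {
  df <- calls$calls
  classes <- calls$classes
  haps <- unique(df$hap_id)
  key <- paste(df$chrom, df$start, df$end)
  ivs <- unique(df[order(df$chrom, df$start), c("chrom", "start", "end")])
  rownames(ivs) <- NULL
  mat <- matrix(NA_integer_, nrow(ivs), length(haps),
                dimnames = list(NULL, haps))
  for (h in haps) {
    sub <- df[df$hap_id == h, ]
    idx <- match(paste(ivs$chrom, ivs$start, ivs$end),
                 paste(sub$chrom, sub$start, sub$end))
    if (anyNA(idx))
      stop("haplotypes carry different interval boundaries; cannot write msp dialect")
    mat[, h] <- match(sub$ancestry[idx], classes) - 1L
  }
  cols <- sub("_h([12])$", ".\\1", haps)
  cols <- vapply(strsplit(cols, "\\.(?=[12]$)", perl = TRUE), function(x)
    paste0(x[1L], ".", as.integer(x[2L]) - 1L), character(1L))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste0("#Subpopulation order/codes: ",
                    paste0(classes, "=", seq_along(classes) - 1L, collapse = " ")), con)
  writeLines(paste(c("chm", "spos", "epos", "n_snps", cols), collapse = "\t"), con)
  body <- cbind(ivs$chrom, ivs$start, ivs$end, 0L, mat)
  write.table(body, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Load refinedIBD-style IBD segments
#'
#' Tab-separated columns: id1, hap1, id2, hap2, chrom, start, end, LOD,
#' length-cM. When a genetic map is supplied, the cM length is recomputed from
#' the map and stored in `length_cm_map`; downstream operations use the map
#' value, the file value is retained.
#'
#' @param path file path
#' @param map optional `genetic_map`
#' @param samples optional character vector of known sample ids; unknown ids
#'   error.
#' @return an [ibd_set()]
#' @export
load_ibd <- function(path, map = NULL, samples = NULL) {
  first <- tryCatch(readLines(path, n = 1L), error = function(e) character())
  if (!length(first) || !nzchar(first)) return(ibd_set(data.frame()))
  df <- read.table(path, header = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("id1", "hap1", "id2", "hap2", "chrom", "start", "end",
                 "lod", "length_cm")[seq_len(ncol(df))]
  df$chrom <- as.character(df$chrom)
  if (!is.null(samples)) {
    bad <- setdiff(unique(c(df$id1, df$id2)), samples)
    if (length(bad)) stop("unknown sample id(s) in IBD file: ",
                          paste(bad, collapse = ", "))
  }
  if (any(df$length_cm < 0)) stop("negative IBD cM length in file")
  if (!is.null(map))
    df$length_cm_map <- cm_at(map, df$chrom, df$end) - cm_at(map, df$chrom, df$start)
  ibd_set(df)
}

#' Write IBD segments in the refinedIBD-style layout
#' @param ibd an `ibd_set`
#' @param path output path
#' @export
write_ibd <- function(ibd, path) {
  df <- ibd$segments[, c("id1", "hap1", "id2", "hap2", "chrom", "start",
                         "end", "lod", "length_cm")]
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# effective cM length of a segment set row-wise: map value when present
seg_cm <- function(segments) {
  if ("length_cm_map" %in% names(segments)) segments$length_cm_map
  else segments$length_cm
}

#' Load cultural, geographic, ecological and lexical tables
#'
#' Reads a binary group-by-trait presence/absence CSV, a group centroid
#' coordinate CSV (`group, lat, lon` in decimal degrees), a biome-composition
#' CSV (`group` plus numeric biome percentage columns) and a cognate-coded
#' word-list CSV (`group, domain, object_id, word, cognate_id, unique_to_cahg,
#' confidence`). Group name sets are reconciled: groups present in only some
#' files trigger a warning and the intersection is used.
#'
#' @param traits_csv,coords_csv,biome_csv,cognates_csv file paths; any may be
#'   `NULL` to skip.
#' @return list with elements `traits` (matrix), `coords`, `biomes`,
#'   `cognates` (a `cognate_table`)
#' @export
load_culture <- function(traits_csv = NULL, coords_csv = NULL,
                         biome_csv = NULL, cognates_csv = NULL) {
  out <- list(traits = NULL, coords = NULL, biomes = NULL, cognates = NULL)
  groups <- list()
  if (!is.null(traits_csv)) {
    df <- read.csv(traits_csv, check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- df[[1L]]
    if (!all(m %in% c(0, 1))) stop("non-binary trait cell in ", traits_csv)
    storage.mode(m) <- "integer"
    out$traits <- m
    groups$traits <- rownames(m)
  }
  if (!is.null(coords_csv)) {
    df <- read.csv(coords_csv, stringsAsFactors = FALSE)
    names(df)[1:3] <- c("group", "lat", "lon")
    if (any(abs(df$lat) > 90)) stop("latitude outside [-90, 90]")
    if (any(abs(df$lon) > 180)) stop("longitude outside [-180, 180]")
    out$coords <- df
    groups$coords <- df$group
  }
  if (!is.null(biome_csv)) {
    df <- read.csv(biome_csv, check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- df[[1L]]
    out$biomes <- m
    groups$biomes <- rownames(m)
  }
  if (!is.null(cognates_csv)) {
    df <- read.csv(cognates_csv, stringsAsFactors = FALSE)
    out$cognates <- cognate_table(df)
    groups$cognates <- unique(df$group)
  }
  if (length(groups) > 1L) {
    common <- Reduce(intersect, groups)
    if (!all(lengths(lapply(groups, setdiff, common)) == 0L)) {
      warning("group sets differ across culture files; using the intersection (",
              paste(common, collapse = ", "), ")")
      if (!is.null(out$traits)) out$traits <- out$traits[common, , drop = FALSE]
      if (!is.null(out$coords)) out$coords <- out$coords[out$coords$group %in% common, ]
      if (!is.null(out$biomes)) out$biomes <- out$biomes[common, , drop = FALSE]
      if (!is.null(out$cognates))
        out$cognates$records <- out$cognates$records[out$cognates$records$group %in% common, ]
    }
  }
  out
}

#' Export a distance matrix as a NEXUS DISTANCES block
#'
#' Writes a TAXA block and a full-matrix DISTANCES block (for external
#' split-network / NeighborNet plotting). Labels containing whitespace are
#' quoted per NEXUS rules.
#'
#' @param d a `dist_matrix` (or symmetric labelled matrix)
#' @param path output path
#' @param tol asymmetry tolerance before erroring
#' @export
export_distance_nexus <- function(d, path, tol = 1e-8) {
  m <- unclass(d)
  if (max(abs(m - t(m))) > tol) stop("asymmetry beyond tolerance")
  labs <- rownames(m)
  qlabs <- ifelse(grepl("\\s", labs), paste0("'", labs, "'"), labs)
  con <- file(path, "w"); on.exit(close(con))
  writeLines("#NEXUS", con)
  writeLines(c("BEGIN TAXA;",
               sprintf("  DIMENSIONS NTAX=%d;", nrow(m)),
               paste0("  TAXLABELS ", paste(qlabs, collapse = " "), ";"),
               "END;"), con)
  writeLines(c("BEGIN DISTANCES;",
               sprintf("  DIMENSIONS NTAX=%d;", nrow(m)),
               "  FORMAT TRIANGLE=BOTH DIAGONAL LABELS;",
               "  MATRIX"), con)
  for (i in seq_len(nrow(m)))
    writeLines(paste0("    ", qlabs[i], " ",
                      paste(format(m[i, ], digits = 15, trim = TRUE),
                            collapse = " ")), con)
  writeLines(c("  ;", "END;"), con)
  invisible(path)
}

#' Read back a NEXUS DISTANCES block written by [export_distance_nexus()]
#' @param path file path
#' @return a `dist_matrix`
#' @export
read_distance_nexus <- function(path) {
  lines <- readLines(path)
  start <- grep("MATRIX", lines)[1L]
  end <- which(trimws(lines) == ";")
  end <- end[end > start][1L]
  rows <- trimws(lines[(start + 1L):(end - 1L)])
  labs <- character(); vals <- list()
  for (r in rows) {
    if (startsWith(r, "'")) {
      lab <- sub("^'([^']*)'.*$", "\\1", r)
      rest <- trimws(sub("^'[^']*'", "", r))
    } else {
      lab <- sub("\\s.*$", "", r)
      rest <- trimws(sub("^\\S+", "", r))
    }
    labs <- c(labs, lab)
    vals[[length(vals) + 1L]] <- as.numeric(strsplit(rest, "\\s+")[[1L]])
  }
  m <- do.call(rbind, vals)
  dimnames(m) <- list(labs, labs)
  distance_matrix(m)
}

#' Run configuration for the layered pipeline
#'
#' Thresholds and permutation settings with the defaults used throughout:
#' IBD retention above 1 cM, merge gap at 0.6 cM with at most one inconsistent
#' allele, 1000 permutations. The seed is recorded in all result tables.
#'
#' @param ibd_min_len_cm retain cross-population IBD strictly longer than this
#' @param ibd_merge_gap_cm maximal cM gap for merging adjacent IBD blocks
#' @param ibd_merge_max_inconsistent allowed allele mismatches across the merge
#'   region
#' @param n_permutations permutations for Mantel/MMRR/CADM
#' @param rng_seed integer seed recorded in outputs
#' @param adjust_method multiplicity adjustment per test family (`"BH"` or
#'   `"holm"`)
#' @param ancestry_classes ancestry class names, hunter-gatherer class first
#' @param paths optional named list of input file paths
#' @return object of class `run_config`
#' @export
run_config <- function(ibd_min_len_cm = 1.0, ibd_merge_gap_cm = 0.6,
                       ibd_merge_max_inconsistent = 1, n_permutations = 1000,
                       rng_seed = 1L, adjust_method = "BH",
                       ancestry_classes = c("CAHG", "FARMER"), paths = list()) {
  stopifnot(ibd_min_len_cm > 0, ibd_merge_gap_cm > 0,
            ibd_merge_max_inconsistent >= 0, n_permutations > 0)
  structure(list(ibd_min_len_cm = ibd_min_len_cm,
                 ibd_merge_gap_cm = ibd_merge_gap_cm,
                 ibd_merge_max_inconsistent = ibd_merge_max_inconsistent,
                 n_permutations = as.integer(n_permutations),
                 rng_seed = as.integer(rng_seed),
                 adjust_method = adjust_method,
                 ancestry_classes = ancestry_classes,
                 paths = paths),
            class = "run_config")
}

#' Read a flat key=value run-configuration file
#' @param path file path
#' @return a [run_config()]
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, function(x) paste(x[-1L], collapse = "="), ""))
  num <- suppressWarnings(as.numeric(vals))
  args <- list()
  for (i in seq_along(keys)) {
    k <- keys[i]
    if (k == "ancestry_classes") args[[k]] <- strsplit(vals[i], ",")[[1L]]
    else if (k %in% c("adjust_method")) args[[k]] <- vals[i]
    else if (startsWith(k, "path.")) args$paths[[sub("^path\\.", "", k)]] <- vals[i]
    else args[[k]] <- num[i]
  }
  do.call(run_config, args)
}
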