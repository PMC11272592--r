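# Synthetic admixed cohorts with known ancestry tracts, known implanted
# cross-population IBD, and cultural/lexical data generated under three
# competing causal scenarios (farmer borrowing, hunter-gatherer exchange,
# ecological convergence), so every downstream stage has ground truth.

#' Simulation configuration
#'
#' Defaults emulate the study system at desk scale: nine demes (genetic
#' units), ten diploids per deme, 2,000 SNPs on a single 200 cM chromosome at
#' a uniform 1 cM/Mb map. The two ancestral gene pools (hunter-gatherer and
#' farmer) each diverge from a shared ancestral frequency under a
#' Balding-Nichols model; hunter-gatherer pools additionally carry
#' spatially-correlated deme-level structure (logit-normal, exponential decay
#' with distance), which produces pairwise FST of roughly 0.01-0.06 and an
#' isolation-by-distance pattern. Pulse admixture `t` generations ago gives
#' exponentially distributed ancestry tracts with mean `100/t` cM; recent
#' between-deme exchange copies contiguous blocks of at least 1 cM and logs
#' them as true IBD.
#'
#' @param n_demes number of demes
#' @param n_individuals diploid individuals per deme
#' @param n_sites number of SNP sites
#' @param chromosome_length_cm chromosome length in cM (1 cM/Mb map)
#' @param divergence_F Balding-Nichols divergence of each ancestral class pool
#'   from the shared ancestral frequency; named vector `c(cahg=, farmer=)`
#' @param deme_logit_sd sd of deme-level logit deviations of hunter-gatherer
#'   allele frequencies (controls among-deme FST scale)
#' @param gene_decay_km exponential decay length of the spatial correlation of
#'   deme deviations
#' @param admixture_time_generations pulse-admixture age `t` (tract mean
#'   `100/t` cM)
#' @param admixture_fraction farmer-ancestry fraction per deme; `NULL` draws
#'   one per deme from `U(0.05, 0.55)`
#' @param exchange_rate expected recent copy events per ordered deme pair at
#'   zero distance
#' @param exchange_decay_km distance decay of exchange rates
#' @param ibd_block_mean_cm mean of the exponential excess over the 1 cM
#'   minimum copied block length
#' @param trait_scenario one of `"farmer_borrowing"`, `"hg_exchange"`,
#'   `"ecology"`
#' @param n_traits number of binary traits
#' @param trait_base_rate marginal presence probability per trait
#' @param trait_coupling weight of the scenario similarity kernel in the
#'   trait-latent correlation (0 = independent demes)
#' @param admix_sim_scale kernel scale for farmer-admixture similarity
#' @param ecology_sim_scale kernel scale on Gower biome dissimilarity
#' @param n_biomes biome categories in the composition table
#' @param zip_params list with `beta` and `gamma` coefficient vectors
#'   (intercept first) for the shared-word count generator
#' @param rng_seed integer seed; all stages draw from sub-streams derived
#'   from it
#' @return object of class `simulation_config`
#' @export
simulation_config <- function(n_demes = 9, n_individuals = 10, n_sites = 2000,
                              chromosome_length_cm = 200,
                              divergence_F = c(cahg = 0.15, farmer = 0.3),
                              deme_logit_sd = 0.35, gene_decay_km = 800,
                              admixture_time_generations = 30,
                              admixture_fraction = NULL,
                              exchange_rate = 25, exchange_decay_km = 800,
                              ibd_block_mean_cm = 1.5,
                              trait_scenario = "hg_exchange", n_traits = 60,
                              trait_base_rate = 0.35, trait_coupling = 0.9,
                              admix_sim_scale = 0.15, ecology_sim_scale = 0.4,
                              n_biomes = 4,
                              zip_params = list(beta = c(1.0, -0.8),
                                                gamma = c(-1.0, 0.8)),
                              rng_seed = 1L) {
  stopifnot(all(divergence_F > 0), all(divergence_F < 1),
            admixture_time_generations >= 1,
            is.null(admixture_fraction) ||
              all(admixture_fraction >= 0 & admixture_fraction <= 1),
            exchange_rate >= 0,
            trait_scenario %in% c("farmer_borrowing", "hg_exchange", "ecology"),
            trait_coupling >= 0, trait_coupling < 1)
  if (chromosome_length_cm < 2 * 100 / admixture_time_generations)
    stop("chromosome shorter than minimum tract resolution (need >= 2 mean tracts)")
  structure(as.list(environment()), class = "simulation_config")
}

# per-stage sub-streams derived from one seed (kept below 2^31)
stage_seed <- function(cfg, stage) {
  (cfg$rng_seed * 97L + match(stage, c("pools", "demes", "tracts", "alleles",
                                       "exchange", "traits", "biomes",
                                       "words")) * 1009L) %% 2147483629L
}

#' Balding-Nichols frequency draw
#'
#' Draws population allele frequencies around an ancestral frequency `p` with
#' divergence parameter `F`: `Beta(p(1-F)/F, (1-p)(1-F)/F)`, so that the
#' expected FST of the derived pool relative to the ancestor equals `F`.
#'
#' @param p ancestral frequency vector
#' @param F divergence parameter in (0, 1)
#' @return frequency vector, clamped away from 0/1 by 1e-4
#' @export
rbalding_nichols <- function(p, F) {
  q <- rbeta(length(p), p * (1 - F) / F, (1 - p) * (1 - F) / F)
  pmin(pmax(q, 1e-4), 1 - 1e-4)
}

#' Simulate a synthetic admixed cohort
#'
#' Generates deme centroids, ancestral and deme-level allele frequencies,
#' per-haplotype ancestry mosaics (tract boundaries from a Poisson process at
#' rate `t/100` per cM, tract labels Bernoulli with the deme's farmer
#' fraction), alleles drawn from the tract-matched pool, recent between-deme
#' haplotype copying logged as true IBD, and a biome-composition table.
#' Deterministic under `cfg$rng_seed`.
#'
#' @param cfg a [simulation_config()]
#' @return object of class `synthetic_cohort`: list with `haplotypes`
#'   (a [haplotype_set()] including cM coordinates), `map`, `ancestry`
#'   (true [ancestry_calls()]), `ibd` (true [ibd_set()]), `demes`
#'   (centroid table), `biomes`, `admixture_fraction`, `exchange_matrix`,
#'   `config`.
#' @export
simulate_cohort <- function(cfg) {
  L_cm <- cfg$chromosome_length_cm
  L_bp <- as.integer(L_cm * 1e6)              # 1 cM/Mb
  n_hap_deme <- 2L * cfg$n_individuals
  demes <- paste0("D", seq_len(cfg$n_demes))

  set.seed(stage_seed(cfg, "demes"))
  coords <- data.frame(group = demes,
                       lat = runif(cfg$n_demes, -5, 5),
                       lon = runif(cfg$n_demes, 10, 30))
  D_km <- geosphere::distm(coords[, c("lon", "lat")],
                           fun = function(p1, p2)
                             geosphere::distHaversine(p1, p2, r = 6371000)) / 1000
  dimnames(D_km) <- list(demes, demes)
  if (is.null(cfg$admixture_fraction)) {
    admix <- runif(cfg$n_demes, 0.05, 0.55)
  } else {
    admix <- rep_len(cfg$admixture_fraction, cfg$n_demes)
  }
  names(admix) <- demes

  # ancestral pools and spatially-correlated deme frequencies
  set.seed(stage_seed(cfg, "pools"))
  p0 <- runif(cfg$n_sites, 0.05, 0.95)
  q_farmer <- rbalding_nichols(p0, cfg$divergence_F[["farmer"]])
  q_hg <- rbalding_nichols(p0, cfg$divergence_F[["cahg"]])
  R <- exp(-D_km / cfg$gene_decay_km)
  Lc <- t(chol(R + diag(1e-9, cfg$n_demes)))
  Z <- matrix(rnorm(cfg$n_sites * cfg$n_demes), cfg$n_sites)
  E <- cfg$deme_logit_sd * (Z %*% t(Lc))
  q_deme <- plogis(qlogis(q_hg) + E)          # sites x demes
  colnames(q_deme) <- demes

  # sites: evenly spaced bp, uniform map
  pos <- as.integer(round(seq(1e5, L_bp - 1e5, length.out = cfg$n_sites)))
  cm <- pos / 1e6
  map <- genetic_map(chrom = rep("1", 5),
                     pos = as.integer(seq(1, L_bp, length.out = 5)),
                     cm = seq(1, L_bp, length.out = 5) / 1e6)

  samples <- data.frame(
    sample = as.vector(t(outer(demes, sprintf("I%02d", seq_len(cfg$n_individuals)),
                               paste0))),
    population = rep(demes, each = cfg$n_individuals),
    stringsAsFactors = FALSE)
  haps <- as.vector(rbind(paste0(samples$sample, "_h1"),
                          paste0(samples$sample, "_h2")))
  hap_deme <- rep(samples$population, each = 2L)
  n_haps <- length(haps)

  # ancestry mosaics: per-site class label per haplotype
  set.seed(stage_seed(cfg, "tracts"))
  t_adm <- cfg$admixture_time_generations
  lab <- matrix(0L, cfg$n_sites, n_haps, dimnames = list(NULL, haps)) # 0 = hg
  for (j in seq_len(n_haps)) {
    a <- admix[[hap_deme[j]]]
    n_br <- rpois(1L, L_cm * t_adm / 100)
    br <- sort(runif(n_br, 0, L_cm))
    n_tr <- n_br + 1L
    tr_lab <- rbinom(n_tr, 1L, a)
    idx <- findInterval(cm, br) + 1L
    lab[, j] <- tr_lab[idx]
  }

  set.seed(stage_seed(cfg, "alleles"))
  alleles <- matrix(0L, cfg$n_sites, n_haps, dimnames = list(NULL, haps))
  for (j in seq_len(n_haps)) {
    freq <- ifelse(lab[, j] == 1L, q_farmer, q_deme[, hap_deme[j]])
    alleles[, j] <- as.integer(runif(cfg$n_sites) < freq)
  }

  # recent exchange: copy contiguous blocks between demes, log as true IBD
  set.seed(stage_seed(cfg, "exchange"))
  X <- cfg$exchange_rate * exp(-D_km / cfg$exchange_decay_km)
  diag(X) <- 0
  ibd_rec <- list()
  occupied <- lapply(setNames(vector("list", n_haps), haps), function(x) NULL)
  for (i in seq_len(cfg$n_demes)) for (j in seq_len(cfg$n_demes)) {
    if (i == j) next
    n_ev <- rpois(1L, X[i, j])
    for (ev in seq_len(n_ev)) {
      len_cm <- 1 + rexp(1L, 1 / cfg$ibd_block_mean_cm)
      if (len_cm >= L_cm) next
      donor <- haps[hap_deme == demes[i]][sample.int(n_hap_deme, 1L)]
      recip <- haps[hap_deme == demes[j]][sample.int(n_hap_deme, 1L)]
      if (donor == recip) next
      placed <- FALSE
      for (try in 1:10) {
        s_cm <- runif(1L, 0, L_cm - len_cm)
        e_cm <- s_cm + len_cm
        clash <- FALSE
        for (h in c(donor, recip)) {
          occ <- occupied[[h]]
          if (!is.null(occ) && any(occ[, 1L] < e_cm & occ[, 2L] > s_cm)) {
            clash <- TRUE; break
          }
        }
        if (!clash) { placed <- TRUE; break }
      }
      if (!placed) next
      sel <- cm >= s_cm & cm < e_cm
      if (!any(sel)) next
      alleles[sel, recip] <- alleles[sel, donor]
      lab[sel, recip] <- lab[sel, donor]
      occupied[[donor]] <- rbind(occupied[[donor]], c(s_cm, e_cm))
      occupied[[recip]] <- rbind(occupied[[recip]], c(s_cm, e_cm))
      w <- which(sel)
      s_bp <- pos[w[1L]]; e_bp <- pos[w[length(w)]] + 1L
      d_id <- sub("_h[12]$", "", donor); r_id <- sub("_h[12]$", "", recip)
      ibd_rec[[length(ibd_rec) + 1L]] <- data.frame(
        id1 = d_id, hap1 = as.integer(sub(".*_h", "", donor)),
        id2 = r_id, hap2 = as.integer(sub(".*_h", "", recip)),
        chrom = "1", start = s_bp, end = e_bp, lod = 50,
        length_cm = e_cm - s_cm, stringsAsFactors = FALSE)
    }
  }
  ibd <- ibd_set(if (length(ibd_rec)) do.call(rbind, ibd_rec) else data.frame())

  # true ancestry intervals from the per-site labels (runs -> [start, end) bp)
  classes <- c("CAHG", "FARMER")
  calls <- do.call(rbind, lapply(seq_len(n_haps), function(j) {
    r <- rle(lab[, j])
    ends <- cumsum(r$lengths); starts <- c(1L, head(ends, -1L) + 1L)
    data.frame(chrom = "1", start = pos[starts],
               end = c(pos[ends[-length(ends)] + 1L], L_bp),
               hap_id = haps[j], ancestry = classes[r$values + 1L],
               stringsAsFactors = FALSE)
  }))
  ancestry <- ancestry_calls(calls, classes)

  set.seed(stage_seed(cfg, "biomes"))
  biomes <- t(vapply(seq_len(cfg$n_demes), function(i) {
    g <- rgamma(cfg$n_biomes, shape = 0.8)
    100 * g / sum(g)
  }, numeric(cfg$n_biomes)))
  dimnames(biomes) <- list(demes, paste0("biome", seq_len(cfg$n_biomes)))

  hs <- haplotype_set(alleles, rep("1", cfg$n_sites), pos, cm, samples)
  structure(list(haplotypes = hs, map = map, ancestry = ancestry, ibd = ibd,
                 demes = coords, deme_distance_km = D_km, biomes = biomes,
                 admixture_fraction = admix, exchange_matrix = X,
                 config = cfg),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d demes x %d diploids, %d sites, %d true IBD segments\n",
              x$config$n_demes, x$config$n_individuals,
              n_sites(x$haplotypes), nrow(x$ibd$segments)))
  invisible(x)
}

# scenario similarity kernel (diag 1, positive semi-definite by construction
# or by eigenvalue clipping)
scenario_kernel <- function(cohort, cfg) {
  demes <- cohort$demes$group
  S <- switch(cfg$trait_scenario,
    farmer_borrowing = {
      a <- cohort$admixture_fraction
      exp(-abs(outer(a, a, "-")) / cfg$admix_sim_scale)
    },
    hg_exchange = exp(-cohort$deme_distance_km / cfg$exchange_decay_km),
    ecology = {
      G <- unclass(gower_matrix(cohort$biomes))
      exp(-G / cfg$ecology_sim_scale)
    })
  dimnames(S) <- list(demes, demes)
  ev <- eigen(S, symmetric = TRUE)
  if (min(ev$values) < 0) {
    S <- ev$vectors %*% diag(pmax(ev$values, 0)) %*% t(ev$vectors)
    S <- S / sqrt(outer(diag(S), diag(S)))
    dimnames(S) <- list(demes, demes)
  }
  S
}

#' Simulate binary trait matrices under a causal scenario
#'
#' Trait presence is thresholded from a latent Gaussian whose between-deme
#' correlation mixes a scenario-specific similarity kernel with independent
#' noise: farmer_borrowing couples sharing to farmer-admixture similarity,
#' hg_exchange to the recent-exchange kernel, ecology to biome similarity.
#' Marginal presence rate is `cfg$trait_base_rate` for every trait.
#'
#' @param cohort a `synthetic_cohort`
#' @param cfg the [simulation_config()] (scenario and trait parameters)
#' @return binary deme x trait matrix
#' @export
simulate_traits <- function(cohort, cfg = cohort$config) {
  set.seed(stage_seed(cfg, "traits"))
  S <- scenario_kernel(cohort, cfg)
  w <- cfg$trait_coupling
  if (cfg$exchange_rate == 0 && cfg$trait_scenario == "hg_exchange") w <- 0
  C <- w * S + (1 - w) * diag(nrow(S))
  Lc <- t(chol(C + diag(1e-9, nrow(C))))
  Z <- Lc %*% matrix(rnorm(nrow(S) * cfg$n_traits), nrow(S))
  traits <- (Z < qnorm(cfg$trait_base_rate)) * 1L
  dimnames(traits) <- list(cohort$demes$group,
                           paste0("trait", seq_len(cfg$n_traits)))
  traits
}

#' Simulate dyadic shared-word counts from a zero-inflated Poisson model
#'
#' `y = 0` with probability `pi + (1 - pi) exp(-lambda)`, otherwise a Poisson
#' draw, with `log lambda = X beta` and `logit pi = X gamma`. The design
#' matrix must already be standardized; an intercept column is prepended.
#'
#' @param X dyad-level predictor matrix (standardized columns, no intercept)
#' @param beta count-model coefficients, intercept first
#' @param gamma zero-model coefficients, intercept first; `-Inf` intercept
#'   with zero slopes means no zero inflation
#' @param seed integer seed
#' @return integer count vector
#' @export
simulate_word_counts <- function(X, beta, gamma, seed = 1L) {
  X1 <- cbind(1, X)
  stopifnot(ncol(X1) == length(beta), ncol(X1) == length(gamma))
  set.seed(seed)
  eta <- drop(X1 %*% beta)
  if (any(!is.finite(exp(eta)))) stop("non-finite Poisson mean lambda")
  lam <- exp(eta)
  zeta <- drop(X1 %*% gamma)
  pi0 <- plogis(zeta)           # plogis(-Inf) = 0
  structural_zero <- runif(nrow(X1)) < pi0
  y <- rpois(nrow(X1), lam)
  y[structural_zero] <- 0L
  y
}

#' Write a synthetic cohort in the pipeline's external formats
#'
#' Emits the same formats the loaders read — phased VCF, PLINK map, msp-style
#' ancestry TSV, refinedIBD-style IBD TSV, plus trait/biome/coordinate CSVs —
#' so the full pipeline can be exercised through its real parsers. Ancestry
#' intervals are split on the union of breakpoints across haplotypes so the
#' msp dialect (one row per interval, one column per haplotype) applies.
#'
#' @param cohort a `synthetic_cohort`
#' @param dir output directory (created if needed)
#' @param traits optional trait matrix from [simulate_traits()]
#' @return named list of file paths
#' @export
write_cohort <- function(cohort, dir, traits = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    vcf = file.path(dir, "cohort.vcf"),
    map = file.path(dir, "cohort.map"),
    ancestry = file.path(dir, "ancestry.msp.tsv"),
    ibd = file.path(dir, "ibd.tsv"),
    coords = file.path(dir, "coords.csv"),
    biomes = file.path(dir, "biomes.csv"),
    populations = file.path(dir, "populations.csv"))
  write_vcf(cohort$haplotypes, paths$vcf)
  write_plink_map(cohort$map, paths$map)
  write_local_ancestry(harmonize_intervals(cohort$ancestry), paths$ancestry)
  write_ibd(cohort$ibd, paths$ibd)
  write.csv(cohort$demes, paths$coords, row.names = FALSE)
  write.csv(data.frame(group = rownames(cohort$biomes), cohort$biomes,
                       check.names = FALSE),
            paths$biomes, row.names = FALSE)
  write.csv(cohort$haplotypes$samples, paths$populations, row.names = FALSE)
  if (!is.null(traits)) {
    paths$traits <- file.path(dir, "traits.csv")
    write.csv(data.frame(group = rownames(traits), traits, check.names = FALSE),
              paths$traits, row.names = FALSE)
  }
  paths
}

# split every haplotype's intervals on the union of breakpoints so all
# haplotypes share boundaries (required by the msp table layout)
harmonize_intervals <- function(calls) {
  df <- calls$calls
  out <- do.call(rbind, lapply(unique(df$chrom), function(ch) {
    sub <- df[df$chrom == ch, ]
    br <- sort(unique(c(sub$start, sub$end)))
    cells <- data.frame(start = br[-length(br)], end = br[-1L])
    do.call(rbind, lapply(unique(sub$hap_id), function(h) {
      s <- sub[sub$hap_id == h, ]
      k <- findInterval(cells$start, s$start)
      lab <- ifelse(k > 0L & cells$start < s$end[pmax(k, 1L)],
                    s$ancestry[pmax(k, 1L)], NA)
      keep <- !is.na(lab)
      data.frame(chrom = ch, start = cells$start[keep], end = cells$end[keep],
                 hap_id = h, ancestry = lab[keep], stringsAsFactors = FALSE)
    }))
  }))
  ancestry_calls(out, calls$classes)
}
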