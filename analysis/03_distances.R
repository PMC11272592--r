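#!/usr/bin/env Rscript
# Step 3 — distance matrices for every data domain of the hg_exchange cohort:
# cultural (Jaccard on trait presence/absence), ecological (Gower on biome
# composition), geographic (great-circle between deme centroids) and genetic
# (per-layer Hudson FST). Writes labelled CSVs plus a NEXUS DISTANCES export
# of the hunter-gatherer-layer FST for external split-network plotting.

suppressMessages(library(ibdlayers))
src <- file.path("results", "sim", "hg_exchange")
stopifnot(dir.exists(src))
cfg <- run_config(rng_seed = 20260926L)

cul <- load_culture(traits_csv = file.path(src, "traits.csv"),
                    coords_csv = file.path(src, "coords.csv"),
                    biome_csv = file.path(src, "biomes.csv"))
pops_df <- read.csv(file.path(src, "populations.csv"))
pops <- setNames(pops_df$population, pops_df$sample)
gen <- load_genotypes(file.path(src, "cohort.vcf"), file.path(src, "cohort.map"),
                      populations = pops)
calls <- load_local_ancestry(file.path(src, "ancestry.msp.tsv"),
                             cfg$ancestry_classes)
ibd <- load_ibd(file.path(src, "ibd.tsv"), map = gen$map, samples = names(pops))
kept <- filter_cross_population(ibd, pops, min_len_cm = cfg$ibd_min_len_cm)
layers <- build_layers(gen$haplotypes, calls, kept)

save_d <- function(d, name) {
  write.csv(data.frame(group = rownames(d), unclass(d), check.names = FALSE),
            file.path("results", paste0("dist_", name, ".csv")),
            row.names = FALSE)
}
d_cult <- jaccard_matrix(cul$traits);            save_d(d_cult, "jaccard_traits")
d_eco <- gower_matrix(cul$biomes);               save_d(d_eco, "gower_biomes")
d_geo <- greatcircle_matrix(cul$coords);         save_d(d_geo, "greatcircle_km")

for (nm in names(layers)) {
  sft <- site_frequencies(layers[[nm]])
  if (ncol(sft$f) == 0) { cat("layer", nm, "has no usable sites; skipped\n"); next }
  fst <- suppressWarnings(fst_matrix(sft))
  save_d(fst, paste0("fst_", nm))
  cat(sprintf("FST (%-12s): %5d usable sites, mean pairwise %.4f\n",
              nm, ncol(sft$f), mean(upper_vec(fst))))
  if (nm == "cahg") {
    export_distance_nexus(fst, "results/fst_cahg.nex")
    pc <- principal_coordinates(fst, k = 2)
    write.csv(data.frame(group = rownames(pc$points), pc$points),
              "results/pcoa_fst_cahg.csv", row.names = FALSE)
  }
}
pc_cult <- principal_coordinates(d_cult, k = 2)
write.csv(data.frame(group = rownames(pc_cult$points), pc_cult$points),
          "results/pcoa_jaccard.csv", row.names = FALSE)
cat("distance matrices and PCoA coordinates written under results/\n")
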