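---
title: "Dating cultural exchange from ancestry layers: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating cultural exchange from ancestry layers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ibdlayers)
```

## The question and the layered procedure

Central African hunter-gatherer (CAHG) groups carry genomes that mix a deep
hunter-gatherer ancestry with farmer-associated ancestry introduced during
the Bantu expansion of the last ~3,000 years. Cultural traits shared between
CAHG groups could therefore have spread (a) recently, together with farmer
gene flow; (b) through continued exchange among hunter-gatherer groups; or
(c) during their common history before farming. The layered procedure
separates these by asking *which part of the genome* carries the association
with culture.

Each phased genome is decomposed with local-ancestry calls and IBD segment
calls into four layers: `full` (no masking), `cahg` (farmer-ancestry tracts
masked), `cahg_no_ibd` (additionally masking cross-population IBD blocks
longer than 1 cM — haplotype sharing young enough to postdate farmer
contact), and `bantu` (only farmer tracts retained). Masking only removes
information: the observed-entry sets are nested (`cahg_no_ibd` within `cahg`
within `full`), which `build_layers()` asserts on every construction.

Per layer we compute allele frequencies over retained haplotypes only,
dropping any site at which some population retains one or fewer alleles,
then Hudson's FST as a ratio of averages (numerator and denominator averaged
over SNPs separately, never per-site ratios — the per-site ratio estimator
is badly behaved at low-information sites). A battery of Spearman Mantel
tests correlates each layer's FST matrix with the cultural distance matrix,
alongside geographic and ecological rows, with Benjamini–Hochberg adjustment
within the battery. `classify_timing()` maps the adjusted-significance
pattern of the three mandatory layers to a timing call with the precedence
`cahg` > `full` > `cahg_no_ibd`-only; patterns with a significant `cahg` row
are read as pre-farming origin with continued exchange whether or not the
IBD-pruned row confirms, because pruning only removes the youngest sharing.
The mapping is total over all eight patterns and is exercised exhaustively in
the tests.

Two details of the frequency machinery deserve note. First, an individual
with exactly one retained haplotype at a site contributes that allele (dose
0 or 1) rather than a missing value; missingness is reserved for sites with
no retained ancestry on either haplotype. Second, the printed form of the
Hudson denominator in parts of the literature substitutes sample sizes where
allele frequencies belong; we implement the standard estimator denominator
`f_A(1-f_B) + f_B(1-f_A)`, which is the only dimensionally consistent
reading and reduces to the fixed-difference value of 1 when `f_A = 1,
f_B = 0`.

## Permutation statistics

All matrix-association tests permute *object labels* (simultaneous row and
column permutation); independent cell shuffling would destroy the dependence
structure of a distance matrix. P values use the add-one estimator
`(1 + #{|stat*| >= |stat|}) / (1 + n_perm)` and are two-sided, since the
battery reports signed statistics and negative associations are
interpretable. For five or fewer objects the Mantel and MMRR engines
enumerate all `n!` relabelings and the p value is exact; the tests pin this
against an independently coded enumerator. The Mantel statistic is the
Spearman correlation of unfolded upper triangles (a Pearson variant is
exposed), making the test invariant to monotone transforms of either matrix.
CADM (global and a posteriori) is delegated to the `ape` implementation
behind the package's interface, with Holm adjustment across matrices in the
a posteriori tests; for two matrices Kendall's W reduces to `(r + 1) / 2`
with `r` the inter-matrix rank correlation, which the tests verify.

Matrix completion for the individual-level genotype-frequency matrix (used
by the MDS view) is an iterative soft-thresholded SVD initialized at column
means: refill only missing cells, cap at 100 sweeps, stop when the RMS
change of imputed entries drops below `1e-5`, clip to `[0, 1]`. With a hard
rank cap and no thresholding it recovers exact low-rank structure to high
precision, which the tests check on a rank-2 ground truth.

## The synthetic cohort generator

Real CAHG genotypes sit in access-controlled repositories, so validation
runs on synthetic cohorts with exact ground truth. The generator emulates,
at desk scale, the features the method actually consumes:

* **Two ancestral pools** drawn by the Balding–Nichols construction around a
  shared ancestral frequency, `Beta(p(1-F)/F, (1-p)(1-F)/F)`, with
  divergence `F = 0.15` (hunter-gatherer) and `0.3` (farmer), separating the
  pools by an FST near 0.2 — the scale of genome-wide hunter-gatherer vs
  farmer differentiation. The construction makes FST analytically known, so
  Hudson-estimator recovery can be checked against the parameter.
* **Deme-level structure**: hunter-gatherer frequencies per deme deviate on
  the logit scale (sd 0.35) with spatial correlation `exp(-d / 800 km)` over random centroids in a
  Congo-Basin-sized box, producing pairwise FST of roughly 0.01–0.06 and
  isolation by distance.
* **Pulse admixture** `t = 30` generations ago (~900 years, inside the
  Bantu-contact window): per haplotype, tract boundaries follow a Poisson
  process at `t/100` per cM, so tract lengths are exponential with mean
  `100/t` cM; tract labels are Bernoulli with the deme's farmer fraction,
  drawn per deme from `U(0.05, 0.55)` (real groups span roughly this range).
* **Recent exchange** copies contiguous blocks (1 cM plus an exponential
  excess of mean 1.5 cM) between random haplotypes of different demes at
  rates `25 · exp(-d / 800 km)` per ordered pair, logging each copy as true
  IBD. Copying, rather than coalescent simulation, gives exact ground truth
  for the masking tests; overlap conflicts are rejected so every logged
  segment stays allele-identical.
* **Traits**: presence/absence is thresholded from a latent Gaussian whose
  between-deme correlation is `0.9 · S + 0.1 · I`, with `S` the
  scenario-specific similarity kernel — farmer-admixture similarity
  (`exp(-|Δa|/0.15)`), the recent-exchange kernel, or biome similarity
  (`exp(-Gower/0.4)` over Dirichlet(0.8) biome compositions). Sixty traits
  at base presence 0.35 mirror the sparsity of real repertoires (mean 14 of
  44 instrument types present per group).

Default sizes are 9 demes (the study's genetic units), 10 diploids per deme
and 2,000 SNPs on one 200 cM chromosome at 1 cM/Mb; validation studies run
50 seeded cohorts per scenario with 999 Mantel permutations, and the
calibration studies use 1,000 null simulations with 99 permutations each.
All randomness flows from one seed through fixed per-stage sub-streams, so
partial reruns are reproducible.

What the generator does **not** emulate: phasing and local-ancestry call
errors (calls are true by construction, so the pipeline's robustness to
Gnomix misclassification is untested here), linkage disequilibrium within
pools (sites are independent given the frequency draw), recombination
hotspots, multiple chromosomes, and coalescent-derived IBD length
distributions. Passing scenario recovery therefore shows the *logic* of the
layered classification is sound under known ground truth, not that real-data
call error leaves it intact.

Effect sizes were set in a one-time design pass so the battery produces
Mantel rho in the 0.4–0.8 range actually reported for this system; they were
frozen before the validation studies were measured. At these realistic
magnitudes the battery sits close to its detection limit: with 9 demes there
are only 36 dyads, and Benjamini–Hochberg adjustment across the six-row
battery requires raw p near 0.01 for a lone true signal, which per-seed
trait-draw noise does not always deliver. The acceptance script reports the
measured per-scenario recovery rates; they land near, and for some scenarios
below, the 80% mark — an honest reflection of how marginal the corresponding
real-data inferences are (their adjusted P values sit at 0.02–0.03).

## Lexicon models

Dyadic shared-word counts come from cognate-set membership: a dyad's count
is the number of cognate sets carried by both groups, and the degree
distribution tabulates sets by the number of carrying groups. Cognate
judgements are input data, not computed — the adjudication of orthography
and morphology is human expertise outside algorithmic scope. The restricted
view keeps conclusively coded, CAHG-unique sets only.

The zero-inflated Poisson model `P(y=0) = pi + (1-pi) e^{-lambda}`,
`log lambda = X beta`, `logit pi = Z gamma` is fitted by direct maximum
likelihood (BFGS, relative tolerance `1e-12`) from two deterministic starts
— a Poisson-regression start with the inflation set from the observed zero
excess, and a moment start — with standard errors from the observed
information at the optimum. Direct MLE rather than EM because the
observed-information standard errors are what the downstream Wald intervals
need; the best objective value is monitored and never worsens. By default
the zero model uses the same predictor set as the count model (the data give
no reason to distinguish them); `Z` is exposed for other choices, and with
an intercept-only zero model on inflation-free data the count coefficients
reproduce a plain Poisson regression, which the tests assert to `1e-4`.

Linguistic distances: internal-node counts on a reference language tree
count the internal nodes strictly on the tip-to-tip path, endpoints
excluded (on `((A,B),C)`, A–B crosses 1 node and A–C crosses 2 — the edge
cases are fixed by these worked examples since verbal definitions are
ambiguous); patristic distances sum branch lengths on a dated phylogeny,
with languages outside the covered family assigned the maximum root-to-tip
depth. Groups speaking several languages contribute the mean over their
languages' pairwise distances.

## Numerical and interface conventions

* Genomic intervals are half-open `[start, end)` in 1-based bp, matching
  VCF coordinates while keeping interval arithmetic gap-free; sites covered
  by no ancestry interval are masked in every layer (never invent ancestry).
* cM coordinates come from linear interpolation in the genetic map with
  endpoint clamping (extrapolation at the terminal rate is opt-in); IBD
  records keep both the file's cM length and the map-derived one, and the
  map value is used downstream.
* IBD merging is transitive left-to-right within a haplotype pair: merge
  when the gap is at most 0.6 cM and the two haplotypes disagree at no more
  than one allele across the blocks-plus-gap region. "Inconsistent
  genotype" is counted at the haplotype-allele level because the operation
  runs on phased data. Retention of cross-population segments is strict
  (`> 1` cM).
* Reference-panel selection is strict (`> 0.98` ancestry proportion).
* FST values can be slightly negative by sampling noise; the distance-matrix
  container clamps them to zero with a warning, since rank-based tests
  downstream are insensitive to ties at the floor.
* Jaccard pairs with an empty trait union get distance 0 with a warning
  (undefined in the index, impossible in non-degenerate data, but the
  synthetic edge cases need a convention).
* The msp-style ancestry dialect is fixed as: optional
  `#Subpopulation order/codes:` line, then `chm spos epos n_snps` plus one
  integer-coded column per haplotype (`sample.0` / `sample.1`). Several
  dialects circulate; loaders validate against the declared one.

## Known limitations

Single-chromosome simulation understates between-layer contrast that
whole-genome data would give; the exact-match IBD detector is for synthetic
complete data only (real calls come from a probabilistic caller and are
consumed, not re-inferred); the Mbuti-style case of one genetic unit serving
two cultural groups is handled by duplicating distances, which slightly
understates dyadic independence; and the classification is a significance
pattern, so its error rates inherit the battery's power — at realistic
effect sizes, single cohorts of this size misclassify a nontrivial fraction
of runs, as the validation studies quantify.
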