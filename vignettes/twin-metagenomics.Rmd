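---
title: "Methods: twin-cohort gut metagenome analysis with twinmeta"
author: "twinmeta authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: twin-cohort gut metagenome analysis with twinmeta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinmeta)
```

## Scope

`twinmeta` implements the analysis stack used in twin-cohort shotgun
metagenomics studies of host genetics, environment and sub-clinical
phenotypes: taxonomic and functional profile I/O, community-level
dissimilarity and ordination, twin/self/unrelated contrast testing,
covariate-adjusted association of clade abundances with clinical variables,
marker-gene strain fingerprinting, and taxon-function attribution. A
matched synthetic cohort generator provides ground truth for validating
every stage.

The canonical study design it targets: monozygotic twin pairs, each subject
sampled at up to two timepoints, shotgun metagenomes profiled into species
relative abundances (MetaPhlAn-style clade tables, percent units), KEGG
module relative abundances, and per-species marker-gene read counts.

## The synthetic cohort model

`generate_cohort(cohort_config(...))` simulates all inputs jointly from one
seed. Defaults describe a cohort of 10 twin pairs sampled at 2 timepoints
with 4 samples missing (36 stool metagenomes), 50 species, 30 modules, and
100 markers per species.

### Species abundances

Per-species log-abundance for subject $s$ in pair $p$ is

$$\log a_{s} = \mu + \sigma_{subj}\left(\sqrt{\rho}\, z_{p} +
  \sqrt{1-\rho}\, z_{s}\right) + g_{s} + \varepsilon$$

where $\mu \sim N(0, \sigma_{sp}^2)$ is a cohort-level species mean
(`species_log_sd`, default 1.5), $z_p$ and $z_s$ are standard-normal pair
and subject latents mixed by the twin correlation $\rho$
(`twin_species_correlation`, default 0.5), $g_s$ is a shared guild factor
(species are partitioned into `n_guilds` co-varying groups, factor SD
`guild_sd` = 0.8) and $\varepsilon \sim N(0, \texttt{noise\_sd}^2)$ is
per-sample noise (default 0.3). Abundances are exponentiated and
renormalized to proportions, so every sample sums to 1.

The guild factor matters: it induces *observed* positive co-occurrence
between species, which is what the taxon-function "associated" class keys
on. Without it, non-carrier attribution would have nothing real to find.

### Clinical metadata and planted effects

Each pair shares age (30-48 years), sex and smoking status; subjects get
correlated baselines for BMI, fasting blood sugar (FBS), fasting insulin
(FBI), blood pressure, triglycerides and hsCRP, with small between-timepoint
drift. HOMA-IR is derived as `compute_homa(fbi, fbs) = fbi * fbs / 405`.

Planted clinical effects are injected on the variance-stabilized scale:
for effect specification `(variable, feature, sign, size)` the feature's
arcsin-square-root-transformed abundance is shifted by
$\text{sign} \times \text{size}$ per standard deviation of the z-scored
clinical variable, back-transformed, and the sample renormalized. Because
the association model tests slopes on the same transformed scale, `size`
is interpretable as the planted effect size in transformed units.

### Strains

Each pair draws a founder strain barcode per species: marker presence is
Bernoulli($q$) with `marker_presence_prob` $q = 0.8$. Twin B's barcode and
each timepoint-2 barcode are produced by *marginal-preserving resampling*:
each marker is independently redrawn from Bernoulli($q$) with probability

$$r = \min\!\left(1, \frac{d}{2q(1-q)}\right)$$

where $d$ is the target expected divergence (`strain_twin_divergence`,
default 0.3, and `strain_self_divergence`, default 0.02). This choice is
deliberate: redrawing (rather than flipping) keeps every barcode's marginal
presence probability at $q$, so at
$d = 2q(1-q)$ (`unrelated_strain_divergence(q)`, 0.32 at $q = 0.8$) twins
are statistically exchangeable with unrelated subjects and the
twin-vs-unrelated strain test is genuinely null. A one-sided flip scheme
would distort the flipped twin's marginals and make the "null" detectably
non-null for structural reasons unrelated to strain sharing.

Marker read abundance is `presence x species_relabund x depth x noise`,
with per-sample depth `depth_mean` $\times$ lognormal(`depth_sd`) and
per-marker lognormal noise `marker_noise_sd` (default 0.7, reflecting the
high dispersion of marker-level coverage). RPK is therefore zero exactly
where the barcode is absent.

### Functional modules

Module abundance is `A %*% C` (species abundance times carriage), perturbed
by lognormal noise `module_noise_sd` and renormalized, so a module's signal
is genuinely driven by its carriers.

## Analysis methods

**Community.** Bray-Curtis dissimilarity
$d(a,b) = \sum_i |a_i - b_i| / \sum_i (a_i + b_i)$ via `vegan::vegdist`;
classical PCoA via `stats::cmdscale` with Gower centering, retaining
eigenvalues $> 10^{-10}$ and fixing axis signs so the largest-magnitude
loading is positive. Pairs are enumerated as *self* (same subject across
timepoints), *twin* (co-twins at the first timepoint) and *unrelated*
(cross-pair subjects at the first timepoint); groups are contrasted with
Welch t-tests.

**Association.** Features pass a strict filter (abundance $> 0.001$ in
$> 10\%$ of samples), are arcsin-sqrt transformed, then screened by
component-wise L2 boosting (1000 iterations, learning rate 0.01, keeping
covariates selected in at least 5% of steps). Selected plus forced
covariates (age, sex, smoking) enter a linear mixed model with a random
intercept per twin pair (`lme4::lmer`, falling back to OLS on singular
fits), Wald p-values, and Benjamini-Hochberg correction across the whole
run as one family.

The random-effect structure is a pair intercept only — no subject-level
term. This matters for repeated-measures designs: when subjects have
strong time-stable abundance baselines, their two timepoints act as
pseudo-replicates of any spurious subject-level correlation, and the
pair-only intercept does not absorb the within-subject residual
correlation, so null p-values are anti-conservative. The FDR-control
behavior of `run_association` is calibrated and verified for
one-sample-per-subject designs; with two timepoints per subject, treat
q-values as screening scores, not calibrated FDR.

A note on the boosting screen: with 1000 iterations and a 5% retention
threshold, pure-noise candidates are retained fairly often (the screen is
deliberately permissive; the mixed model plus FDR does the error control —
the realized null fraction of q < 0.2 findings is about 1%). A stricter
threshold (e.g. 0.25) makes the screen itself nearly null-clean, at some
cost in sensitivity; `association_config(selection_frequency_threshold=)`
exposes this.

**Strain fingerprinting.** Marker RPK = reads / (length/1000); coverage
= RPK $\times$ read length / 1000, so 10 RPK at 100-nt reads is exactly
1x coverage. A species is comparable between two samples when its median
RPK over *all* its markers (zeros included) exceeds 5 in both. Strain
distance is Bray-Curtis on the two samples' marker profiles *after
normalizing each to relative abundance* — a deliberate design choice:
raw-RPK Bray-Curtis leaks sequencing depth and species abundance (both
twin-correlated) into the "strain" distance, which biases twin comparisons
even when strains carry no twin signal. Four-level barcodes (absent /
(0,1] / (1,10] / >10 RPK) support discrete strain comparisons.

**Taxon-function attribution.** Tie-corrected Spearman correlation of
every species against every module (56 species x 87 modules yields 4872
records), with nominal (p < 0.01) and FDR (q < 0.2) significance tiers;
the full matrix is one BH family. Significant positive correlations are
classified *encoded* when the species carries the module (carriage
$\ge 0.5$), *associated* when the species has a significant positive
co-occurrence edge to a carrier, else *unexplained*. We use the observed
co-occurrence network (itself BH-corrected over species pairs) rather than
any latent grouping, because "associated" is an operational claim about
what the data show. Negative or non-significant records are
*not-classified*, with anti-correlated carriers annotated.

**Pipeline.** `run_pipeline()` drives simulate-or-load, community,
association, strain and taxon-function stages from a YAML config, expands
the master seed per stage via `derive_seed()`, and writes a manifest with
MD5 digests so identical configs reproduce identical outputs. Missing and
malformed inputs raise classed conditions (`twinmeta_missing_input`,
`twinmeta_invalid_input`) that the CLI maps to exit codes 2 and 3.

## Worked example

```{r example}
co <- generate_cohort(cohort_config(seed = 7))
dm <- distance_matrix(co$abundance)
pv <- pair_values(enumerate_pairs(co$metadata), dm = dm)
tapply(pv$value, pv$pair_type, mean)
compare_groups(pv)
```

```{r strains}
sc <- strain_comparisons(co$markers,
                         eligible_comparisons(co$markers,
                                              enumerate_pairs(co$metadata)))
compare_strain_groups(sc)
```

## Validation strategy

Every numerical primitive is tested against an independent brute-force
oracle (Bray-Curtis from its sum formula, Spearman as rank-then-Pearson,
BH from the step-up definition); statistical behavior is tested on the
generator's ground truth: planted-effect recovery, null FDR control,
twin-vs-self strain power, twin-vs-unrelated exchangeability, distance
ordering self < twin < unrelated, and carrier/co-occurrence classification
recovery. `scripts/acceptance.R --seed <int> --out <path>` recomputes all
of these from scratch and writes them as JSON.

## Limitations

The generator is a caricature: log-normal abundances with a single guild
structure, independent markers, no read-level simulation, no compositional
zero-inflation model, and clinical variables drawn from plausible but
uncalibrated ranges. Cohort sizes in the tests (10-20 pairs) mirror small
twin studies; power statements do not transfer to other designs. Strain
divergence is parameterized as expected barcode disagreement, not
evolutionary distance.
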