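---
title: "Methods: community analysis of triplet-matched skin microbiome cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: community analysis of triplet-matched skin microbiome cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cutaneotyper)
```

# The study design and what the package computes

The package analyses *matched triplets*: for each affected subject a lesional
and a contralateral clinically unaffected skin swab, paired with a
site-matched swab from a healthy control subject. The unit of data is an OTU
count table (taxa × samples), a rooted phylogeny over the OTUs, a
six-rank taxonomy, and per-sample metadata carrying the clinical skin type
(`control`, `unaffected`, `lesion`), triplet and subject identifiers, body
site, cutaneous microenvironment (dry/sebaceous), demographics, psoriasis
severity scores (PASI, BSA, PGA), and an optional longitudinal week
(0/12/36).

The analysis stages mirror the standard 16S community-ecology workflow:
depth filtering, rarefaction-based α diversity, UniFrac / sqrt-JSD β
diversity, Cailliez-corrected PCoA, distance-based PERMANOVA, PAM community
typing with Calinski–Harabasz and gap-statistic model selection, and a
marker-discovery battery. Every stage is driven through plain tabular
objects so results compose with dplyr/ggplot2.

# The synthetic cohort model

Real cohorts of this kind are controlled-access, so the package carries a
generative model (`simulation_config()`, `simulate_cohort()`) that plays two
roles: it is the test bed for every downstream stage, and it documents
explicitly which data features the analysis assumes.

A sample's community is drawn as follows:

1. **Latent community type.** Each sample is of cutaneotype 1
   (Proteobacteria-dominated) or cutaneotype 2 (Firmicutes/Actinobacteria-
   dominated) with a skin-type-dependent probability of type 2
   (defaults 0.30 control, 0.50 unaffected, 0.60 lesion; the implied
   lesion-vs-control odds ratio is 3.5). Base compositions are defined over
   genera, with phylum budgets split within phyla and the four classical
   skin genera (*Corynebacterium*, *Propionibacterium*, *Staphylococcus*,
   *Streptococcus*) holding a dominant share of their phyla.
2. **Matched-subject effect.** A per-genus log-normal perturbation is drawn
   once per triplet and shared by the lesion and unaffected samples (same
   person); the control sample gets an independent draw (different person).
   Default SD 0.30 on the log scale.
3. **Skin-genera effect.** The four skin genera are multiplied by a
   skin-type multiplier (default 1.0/1.0/1.6 for control/unaffected/lesion)
   before renormalisation, producing the elevated combined skin-genera
   abundance in lesions.
4. **Marker OTUs.** Two designated OTUs (labelled OTU3855 in the *Gp4*
   genus and OTU13613 in *Schlegelella*) are *present* with skin-type-
   dependent probability. A double-positive indicator is drawn first at the
   configured joint prevalence (0.78/0.53/0.20), then residual
   single-positive draws fill the configured marginal rates (0.80/0.61/0.39
   and 0.96/0.69/0.49), so joint and marginal prevalences are both honoured.
   Absence zeroes the OTU before the compositional draw — the marker signal
   is incidence-based, exactly what the double-positive predictor tests.
5. **Compositional noise and counts.** Genus probabilities spread to OTUs by
   geometric within-genus weights; the composition is drawn
   Dirichlet(θ·p) and counts Multinomial(N, composition) with depth
   N ~ discretised lognormal (median 8,621, log-SD 0.6, matching the IQR
   shape of typical 454-era skin surveys; the depth filter default of
   >1,000 reads is strict).
6. **Severity.** Lesion-bearing subjects receive lognormal PASI/BSA/PGA
   scores anchored at means 8.7/9.4/6.6; a latent severity draw couples to
   extra marker depletion in the lesion sample via a logit shift
   (`severity_coupling`, default 0.5), giving the severity-correlation stage
   a recoverable signal.

**Per-skin-type concentration.** The Dirichlet concentration θ is a vector
over skin types (defaults 60/45/30 for control/unaffected/lesion). This is a
deliberate design choice: the within-group dissimilarity ordering
lesion > unaffected > control is a central feature of the data this package
targets, and latent-type mixing alone cannot produce it — mixing
heterogeneity `2p(1−p)` peaks at the unaffected group's 50/50 split. A
decreasing θ encodes the destabilised, more heterogeneous lesion communities
directly. The null configuration (`null_simulation_config()`) uses a common
θ = 50 so skin types are exchangeable.

The phylogeny is a pure-birth backbone over genera with pure-birth subtrees
grafted at each genus tip (so genus-level effects are phylogenetically
coherent: genus clades are monophyletic by construction) and i.i.d.
exponential branch lengths in arbitrary units.

**What the generator does not emulate.** No read-level structure (no
sequences, chimeras, or PCR artefacts), no body-site or microenvironment
effect on composition (the metadata carry the factors; their effect size is
zero by default), no taxon–taxon interactions, and no real-data taxon
inventory — 40 genera and 500 OTUs versus tens of thousands of OTUs in a
real survey. Passing recovery tests therefore demonstrates that the
*pipeline* detects the planted structure at realistic sizes and noise
levels; it does not validate the biological model against real skin data.

# Numerical and statistical choices

- **Shannon index** in natural log (vegan's convention); the base is an
  argument. Rarefaction subsamples without replacement (multivariate
  hypergeometric), 10 replicates by default; at full depth it returns the
  observed index exactly, and the test suite checks the subsampler against
  the closed-form expected richness.
- **Unweighted UniFrac** uses the pairwise denominator (branch length
  observed in the union of the two samples), the original definition.
  **Weighted UniFrac** is normalised by default by the abundance-weighted
  root-to-tip depth sum, bounding it in [0, 1]; the raw variant is a flag.
  Both are computed from per-edge mass accumulation in postorder, and both
  are verified against a branch-enumeration oracle on random small trees.
- **sqrt-JSD** uses natural log, `0·log 0 = 0`, and no pseudocount: the
  mixture `m` is positive wherever either profile is, so the divergence is
  well-defined without one. The square root is taken because it, not the
  raw divergence, is a metric (the suite checks the triangle inequality).
- **Cailliez constant** from the largest eigenvalue of the standard 2n×2n
  companion matrix; constants below `1e-8 · max(d)` are clamped to zero so
  already-Euclidean input reports c = 0. PCoA drops non-positive
  eigenvalues, clamps tiny negatives (≥ −1e-8·λ_max), and reports variance
  explained over the positive spectrum only — with the Cailliez correction
  applied first the spectrum is clean and the convention is immaterial.
- **PERMANOVA** uses sequential (Type I) sums of squares in the order the
  formula gives, computed as trace increments of projection hats against
  the Gower-centred `−½d²` matrix; permutation p values use the add-one
  rule and are never zero. Stratified permutation shuffles only within
  blocks. Both Bonferroni (capped at 1) and BH adjustments are reported
  across terms, since the adjustment convention differs between
  publications. On 1-D Euclidean data the pseudo-F reduces exactly to the
  classical ANOVA F — an identity the suite asserts, alongside agreement
  with vegan's `adonis2`.
- **PAM** enumerates all medoid sets exactly when `choose(n, k) ≤ 2000` and
  otherwise runs BUILD + SWAP descent; all ties break to the lowest sample
  index, making results deterministic and invariant to sample order. The
  exact small-instance path exists because single-swap descent provably
  stalls in local optima on a noticeable fraction of small instances
  (as does the reference implementation in the cluster package).
- **Calinski–Harabasz** is computed directly from the distance matrix via
  the sum-of-squared-distances decomposition
  `W_k = Σ_c (Σ_{i<j∈c} d²)/n_c`, `B_k = T − W_k`, which equals the
  classical centroid form for Euclidean distances (asserted to 1e-10) and
  avoids projecting non-Euclidean distances onto a truncated axis set. The
  chosen k is the CH argmax with ties to the smaller k; a `weak_structure`
  flag (threshold configurable) lets callers refuse to typify flat curves
  rather than silently forcing k = 2.
- **Gap statistic** uses Tibshirani's uniform reference over the bounding
  box of the sqrt-JSD PCoA coordinates, `B = 50` reference sets by default,
  and the usual smallest-k rule `Gap(k) ≥ Gap(k+1) − s_{k+1}`; k = 1 is
  admissible and is the no-structure verdict.
- **Community typing level.** Clustering operates on genus-level relative
  abundances, following the enterotype methodology this analysis descends
  from; the level is the caller's choice via `collapse_taxonomy()`.
- **Odds ratios** default to the conditional MLE with exact 95% CI (via
  Fisher's exact machinery), with the sample cross-product estimate always
  co-reported. The conditional MLE shrinks toward 1 relative to the
  cross-product on all-positive tables, which is the convention that best
  matches published incidence-predictor tables of this kind.
- **Abundance filter** is inclusive at the threshold (mean relative
  abundance ≥ 1% by default). Presence means at least one read. BH families
  are delimited per call: one family per taxonomic level for differential
  abundance, per severity score for correlations, per pair set for post hoc
  tests.
- **Chimera flags** are consumed, summarised and compared across groups,
  never used to filter: flagged abundance is reported so its effect can be
  judged, matching how such QC columns are treated in practice.
- The **β-group ANOVA** on pairwise distances ignores the non-independence
  of pairs sharing a sample. This replicates the established procedure for
  such comparisons; the caveat is stated in the function documentation and
  the p values should be read descriptively.

# Problem sizes in the test suite

The suite exercises full-size cohorts (51 triplets, 500 OTUs) for the
recovery simulations — 50 seeds for effect recovery, 20 for cluster-count
selection, 500 small null datasets for PERMANOVA type-I calibration, 200
random trees for the UniFrac oracles, 1,000 random vectors for the BH
step-up property — sizes chosen so each battery demonstrates its property
with comfortable statistical margin while the whole suite stays
interactive.

# Known limitations

- UniFrac here has no rarefaction-before-distance option; depth differences
  are handled by the proportion normalisation inside the metrics.
- The PERMANOVA supports sequential SS only (no marginal Type II/III), and
  continuous covariates enter as single regressors.
- The gap statistic's reference is the simple bounding-box uniform; the
  principal-component-aligned reference is not implemented.
- `simulate_longitudinal()` models treatment as geometric shrinkage of the
  skin-genera multipliers toward control with an optional transient
  overshoot at week 12; it does not model cutaneotype switching dynamics
  explicitly (switches arise only through redrawn latent types).
- The simulator's taxonomy is synthetic; names of the marker genera and
  skin genera are real, everything else is generated.
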