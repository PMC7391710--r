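---
title: "Genotype fingerprinting over LD blocks: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotype fingerprinting over LD blocks: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ldcheck)
```

# The model

## Block genotype likelihoods

An LD block is represented by its anchor SNP with major allele A and minor
allele B; the block's diploid genotype is θ ∈ {AA, AB, BB}. Every filtered
base observation over any SNP of the block is translated to the anchor's
alleles through the member's phase and contributes the factor

* θ = AA: 1 − e for a major observation, e for a minor one;
* θ = AB: ½ regardless of e;
* θ = BB: e for major, 1 − e for minor,

where e is the Phred error probability of the base (e = 10^(−Q/10), clamped
to [10⁻⁶, 0.5]; zero would produce −∞ log-likelihoods and 0.5 is the
information-free bound). Observations are assumed independent, so the block
log10-likelihood is the sum of log factors. Independence is *enforced*, not
just assumed: duplicates are excluded, and a read-pair contributes at most
one observation across the whole map (the first usable site in coordinate
order). A block with no observations keeps log-likelihoods (0, 0, 0), i.e.
likelihood 1 for every genotype — the natural representation of "no
evidence".

## The capped LOD

With Hardy–Weinberg priors p(θ) from the anchor MAF, the per-block log-odds
of shared versus distinct origin is

$$\log_{10} \frac{\sum_\theta p(x|\theta)\,p(y|\theta)\,p(\theta)}
 {\sum_\theta p(x|\theta)p(\theta)\ \sum_\varphi p(y|\varphi)p(\varphi)}$$

summed over blocks (blocks are treated as independent) and floored at
σ = −3 per block. The floor exists because the uncapped statistic has no
lower bound: overwhelming but *artifactual* evidence at a single locus
(a noisy region, a non-conforming block) could otherwise dominate thousands
of well-behaved loci. The −3 default corresponds to a ~10⁻³ chance of a
well-supported wrong genotype from sequencing error. There is deliberately
no upper cap: the positive direction is already bounded per block by
−log10 p(θ) ≤ 1.5·log10 2 ≈ 0.45 in expectation, which is also why map
construction prefers variants near MAF 0.5
(`expected_block_information()`).

Prior odds of no-swap to swap default to 1. A different prior shifts the
total by the constant log10(odds); we apply the cap to prior-1 terms and add
the shift once after summation. The source derivation writes the prior
inside every per-block term, but its prose describes a constant shift; with
the default prior both readings coincide, and we follow the prose because a
per-block prior would multiply the shift by the number of blocks.

Decision thresholds: LOD ≥ 5 match, LOD ≤ −5 mismatch, otherwise
inconclusive; the bounds themselves are conclusive.

## What the LOD is not

The LOD is not a calibrated likelihood ratio. The model ignores
contamination, relatedness, reference bias, and the incomplete dependence
of SNPs within blocks (and independence between blocks is approximate).
Magnitudes rank confidence; they do not convert to probabilities. Related
individuals score negative — siblings and parent–child pairs are
*mismatches* under this statistic, which is correct for swap detection but
means the tool does not measure kinship.

# Map construction

Candidates need global MAF ≥ 0.10 (rare alleles are uninformative for
identity) and per-population MAF spread ≤ 0.10 (so the prior is roughly
ancestry-independent; the filter is skipped with a warning on unlabeled
panels). Anchors come from windowed LD pruning: within 10 kb windows,
offending pairs (r² > 0.10) are broken by dropping the lower-MAF SNP (later
position on ties). Members join anchors greedily — anchors ordered by
descending LD score (sum of r² over ±1 cM, plus the self term 1.0) — when
r² ≥ 0.85 within 10,000 kb; a SNP eligible for two blocks joins the
higher-scoring anchor. Phase is the sign of the member–anchor indicator
covariance. The builder is fully deterministic: identical panel and
configuration give byte-identical map files.

Numerical/semantic choices worth knowing:

* **Pruning window semantics.** The published recipe mixes units: a window
  in kb with a slide in SNPs. At real panel density (~1 SNP per 300 bp) the
  slide-5 windows overlap heavily and every close pair gets examined; at
  sparse synthetic densities they can skip pairs entirely. We keep the
  slide-5 scan order but finish with a slide-1 fixpoint sweep, so the
  post-condition — no surviving pair within 10 kb above r² 0.10 — holds at
  any density. (PLINK's kb-windowed pruning similarly forces a step of 1.)
* **r² estimator.** Squared Pearson correlation of phased 0/1 allele
  indicators, identical to D²/(p_A p_a p_B p_b).
* **Genetic map.** Linear interpolation between knots; positions outside
  the map take the nearest knot's value; with no genetic map, 1 cM ≈ 1 Mb.
* **Allele coding.** Panels store 0 = major, 1 = minor; columns loaded or
  constructed with the "minor" allele above frequency 0.5 are relabeled.
  This is also where negative-phase members come from: with MAF ≤ 0.5
  coding, r² ≥ 0.85 forces positive phase except near MAF 0.5, where
  relabeling can flip the sign — matching what happens in real panels.
* **MAF storage.** Per-member MAFs are stored in the map for bookkeeping,
  but priors always use the anchor's MAF (all SNPs of a block are treated
  as sharing it). Map files print MAF with 6 decimals and are sorted by
  (CHROM, POS); the parser is two-pass, so member-before-anchor ordering is
  harmless.

# The synthetic world

`simulate_panel()` generates the world the map assumes: independent blocks;
within a block, members copy the anchor's allele per haplotype with a 2%
switch probability (giving member–anchor r² ≈ 0.92 at common MAF). Defaults:
1000 blocks, 5 SNPs per block, 200 haplotypes, anchors at MAF ~ U(0.15, 0.5),
blocks every 20 kb with 300 bp between SNPs.

Two defaults deserve justification. *Five SNPs per block* matches the
pruning slide, so the literal windowed pruning examines every within-block
pair even at synthetic density. *The 0.15 MAF floor* keeps the world
consistent with the block definition: with a 2% switch rate,
r² = f(1−f)(1−2s)² / (f′(1−f′)) with f′ = f + s(1−2f) drops below 0.85
systematically for anchors below MAF ≈ 0.14 — such "blocks" would violate
the r² ≥ 0.85 assumption by construction, which is not a world worth
emulating by default (explicit samplers can still produce it).

Individuals are drawn fresh from the generative recipe (not resampled panel
rows, which would plant cryptic relatedness). Relatives follow Mendelian
transmission per block with no intra-block recombination — consistent with
the perfect-linkage approximation the scoring model makes. Reads are emitted
directly as alignments (MAPQ 60, BQ 30 by default, Poisson per-site depth,
error flips the observed allele); optional duplicate-flagged, secondary,
low-MAPQ and low-BQ fractions exercise the filters.

What the generator does **not** emulate: indels and quality decay along
reads, reference bias, recombination within blocks, partial LD (switch
noise is i.i.d., real LD decays with distance), population structure beyond
labels, and contaminated libraries (mixtures are constructed at the read
level by `contamination_profile()` instead). A green test on this world
therefore establishes the *inference machinery* — filters, likelihoods,
capped aggregation, screening logic — not robustness to every real-data
pathology the model already disclaims.

# Screening design

Representatives per donor: the three highest self-LOD datasets (self-LOD
ranks informative map overlap), required to be mutually concordant (all
pairwise LOD ≥ 5). The one automatic repair is the single-swap pattern —
exactly one member negative against both others while the remaining pair is
concordant — which replaces that member with the next self-LOD candidate;
every other inconsistency yields MANUAL_REVIEW. Screened datasets compare
against their donor's three representatives: any LOD ≤ −5 flags a swap
(flagging takes precedence), else any score inside (−5, 5) marks the dataset
inconclusive, else it is confirmed. Donors need ≥ 4 datasets to be
screenable (otherwise flagged as such, not an error). Flagged datasets are
compared to all donors' representatives; donors whose representatives all
score ≥ 5 are nominated, ranked by minimum LOD with ties all reported (the
duplicate-donor case). Duplicate donors are found by single-linkage
clustering over conclusive positive cross-donor representative pairs. Total
comparisons stay linear in the number of datasets.

# Limitations

* Contamination is detected only as a *trend* (LOD degrades with mixture
  fraction); the fraction is not estimated.
* The inconclusive band (±5) is a fixed operating point, not re-derived per
  dataset.
* Chromosome aliasing ("chr1" vs "1") is not normalized; map and alignments
  must agree on contig names.
* Autosomes only: everything assumes diploidy.
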