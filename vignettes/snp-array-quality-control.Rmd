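---
title: "Quality control of SNP arrays with individual-level allele frequencies"
author: "snpqc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality control of SNP arrays with individual-level allele frequencies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpqc)
```

## The problem

A genotyping experiment on oligonucleotide SNP arrays can fail quietly: an
expired chip, degraded or contaminated DNA, or a bad hybridization produces
genotype calls that look superficially normal. The conventional screen, the
genotype call rate (GCR — the fraction of SNPs receiving a call), misses
failure modes that corrupt allele signals without suppressing calls, such as
pooled or contaminated DNA. `snpqc` scores each array by how far its
*individual-level allele frequencies* stray from where a good array would put
them.

The individual-level allele frequency (AF) of allele A at a SNP is the
within-sample relative abundance of the A signal. On a diploid array it is
estimated from the allele-specific hybridization intensities as

$$\lambda = \frac{I_A}{I_A + \kappa\, I_B},$$

where $\kappa$ is the SNP's *coefficient of preferential
amplification/hybridization* (CPA): the two alleles of a SNP are not
amplified and hybridized with equal efficiency, and $\kappa$ — the mean
$I_A/I_B$ ratio over samples called heterozygous — absorbs that asymmetry so
that a well-behaved heterozygote lands at $\lambda = 0.5$. Across a good
array, $\lambda$ forms three tight bands near 1, 0.5 and 0 for genotypes AA,
AB and BB. Poor arrays widen, shift or merge the bands.

## Quality indices

An *AF reference* records, per SNP and genotype class $G$, the mean $\mu_G$
and sample standard deviation $\sigma_G$ (with the conventional $n-1$
denominator) of individual-level AFs over reference samples carrying that
call. Two SNP-level standardized distances measure the departure of an
observed $\lambda$ from the reference bands:

* **genotype-based (q1):** $q = |\lambda - \mu_G|/\sigma_G$ with $G$ the
  called genotype;
* **nearest-mean-based (q2):** the same distance, but against the class
  whose mean is closest to $\lambda$, so no genotype calls are needed —
  useful when calling itself is compromised (copy-number changes,
  aberrations). When two classes are exactly equidistant, the one giving the
  smaller q (the larger $\sigma$) is chosen: deterministic and conservative.

Reference cells built on fewer than `min_count` samples (default 3) or with
$\sigma_G$ at or below `sd_floor` (default $10^{-4}$) are *ineligible* and
excluded rather than floored — flooring tiny SDs would silently deflate
distances.

The array-level index $Q_x(\rho)$ summarizes the SNP-level distances of one
array with a **winsorized mean**: every distance strictly above the $\rho$
quantile (default $\rho = 0.95$) is replaced by that quantile before
averaging, so a handful of extreme SNPs cannot dominate, while genuine
array-wide degradation still raises the index. The median and the
$\rho$-trimmed mean are available alternatives; the winsorized mean uses
strictly more of the tail information and, in the detection-rate experiment
below, dominates the median at intermediate error levels. A "Merge" index
for companion chips (e.g. Nsp + Sty) pools the SNP-level distances before
summarizing — pooling distances, never averaging part-level indices, so the
larger chip carries proportionally more weight.

One quantile convention — linear interpolation between order statistics
(type 7) — is used for winsorization, empirical confidence limits and
simulation thresholds alike, and is recorded in output metadata.
Self-consistency across these uses matters more than the particular choice.

## Reference distributions and the detector

Across reference samples, $Q$ is well modeled by a lognormal distribution.
`fit_lognormal()` estimates `meanlog`/`sdlog` as the sample mean/SD of log
values and assesses fit with a one-sample Kolmogorov–Smirnov test against
the fitted normal, parameters plugged in as known, with the asymptotic
p-value. With estimated parameters this plain KS test is conservative (its
rejection rate at $\alpha$ sits below $\alpha$); that conservativeness is
documented rather than corrected, since the index is screened, not formally
tested. Group contrasts (populations, laboratories) compare log-scale means
(two-sample Z with unpooled variances), log-scale variances (F test) and
whole distributions (two-sample KS), all two-sided.

A *QI reference* stores upper confidence limits per array stratum — by
default the empirical 95%, 97.5% and 99% quantiles of the reference QIs
(at least 20 reference arrays per stratum); lognormal quantiles
$\exp(\text{meanlog} + z_\ell\, \text{sdlog})$ are an alternative source.
`detect_poor_arrays()` flags an array when its QI **strictly exceeds** the
limit at the chosen level; equality is not flagged. Per-array and Merge
flags are reported separately, which localizes a failure: a sample poor on
one chip but fine on its companion points at the assay, not the DNA.

## The generative model behind the simulation

The detector's power is measured on synthetic data that emulate a
chromosome's worth of SNPs:

* Per SNP, a minor-allele frequency is drawn uniformly from
  `maf_range` (default 0.05–0.5) and genotypes follow Hardy–Weinberg
  proportions $p^2, 2pq, q^2$; each of the $N$ arrays draws its genotype
  independently, which realizes the multinomial genotype counts with an
  exchangeable assignment to arrays.
* Per (SNP, genotype) cell, $\lambda \sim \mathrm{Beta}(\alpha_G, \beta_G)$
  with shapes moment-matched to a band mean $\mu_G$ and total variance
  $V_{T,G}$. Band means default to AA 0.93, AB 0.50, BB 0.07 — the
  pure-allele values pulled slightly inward, as background hybridization
  does on real chips — with systematic variance $V_S = 0.0015$ (within-band
  SD ≈ 0.039, a tight band on the AF scale). Small per-SNP jitter (normal,
  SD 0.005 on means; lognormal, SD 0.1 on log variances) keeps SNPs from
  being identical clones.
* Array/DNA quality is a single knob, the *relative extra error*
  $r = V_E/V_T \in [0, 1)$: the fraction of total AF variance attributable
  to poor quality. With the systematic component fixed, the unique
  consistent total is $V_T = V_S/(1-r)$ — $r$ widens the three bands
  without moving them. Where $V_T$ would exceed the beta-family bound
  $\mu(1-\mu)$ (possible at large $r$ with extreme $\mu$), it is clamped to
  0.99 of the bound with a warning.

The detection-rate experiment mirrors a reference-database workflow: null
thresholds are the level-quantiles of array-level QIs pooled over all
$r = 0$ replications (one global threshold per level — a per-replication
mode exists as an option, and both are calibrated at the null), and the
standardization reference is the generating $(\mu_G, \sqrt{V_{S,G}})$
itself, isolating the index's behavior from reference-estimation noise.
For each $r$ on a grid (default 0–0.6 by 0.025) and each replication, the
flagged proportion of the $N = 100$ arrays is recorded; the curve reports
its mean and SD over replications.

Under these defaults the mean detection rate at the 95% level rises along
an S-shaped curve: essentially zero extra detections at $r = 0$ (the false
detection rate calibrates to $1 - \text{level}$), saturation near 100% by
$r \approx 0.4$ with 690 SNPs per array and by $r \approx 0.175$ with
6,396 — denser chips average away more noise, so the same per-SNP
degradation is visible earlier. The SD-of-rate curve is near zero at both
extremes and peaks in the transition zone, where replications disagree most.

### What the generator does and does not emulate

It reproduces the features the indices respond to: three genotype bands,
HWE genotype frequencies, band widening under degradation, and chip-size
effects. It does not emulate no-calls, linkage disequilibrium between SNPs,
probe-specific CPA asymmetry ($\kappa \ne 1$), copy-number structure,
GC-content waves, or batch effects. Passing tests therefore demonstrate the
detector's statistical behavior under band widening — the failure mode it
was designed for — not robustness to every artifact of production data, and
published real-data reference limits cannot be reproduced from it, only
consumed (via `qi_reference_from_limits()`).

## Numerical and design choices

* **Winsorization direction.** $\rho = 0.95$ caps the top 5% of distances
  at the 95% quantile. Sensible values of $\rho$ are high quantiles
  (95–99%); capping *below* $\rho$ would destroy the statistic.
* **Distances are absolute values**, so indices are nonnegative and the
  lognormal (positive support) is a coherent reference family.
* **Eligibility, not flooring**, for sparse or degenerate reference cells
  (above).
* **CPA fallback.** With fewer than `min_het` (default 3) usable
  heterozygotes the ratio mean is unstable; $\kappa$ falls back to 1 and the
  SNP is flagged. $\lambda$ outside $[0,1]$ (possible when background noise
  pushes intensities past the pure-allele bounds) is clipped, not rejected.
* **Scope minimum.** Array-level summaries need at least `min_snps`
  (default 30) usable distances; quantiles of fewer points are
  meaningless, so smaller scopes are skipped with a warning.
* **Problem sizes.** The packaged tests run the experiment at 60–200
  replications per design point, sizes at which every comparison made
  (calibration at $4\times$ the Monte-Carlo SE, saturation, curve shape)
  is already decisive; the full 1,000-replication design is a
  `simulation_config()` away.
* **Determinism.** Every experiment consumes a single seeded generator
  recorded in its output; identical config and seed give byte-identical
  report files.

## Limitations

The nearest-mean index assigns every $\lambda$ to *some* band, so a sample
whose AFs drift midway between bands registers large distances (intended)
but a sample whose AFs collapse onto a single band (e.g. severe allelic
imbalance at scale) registers against that band only. The confidence-interval
detector inherits the reference's population: limits built on one
population transfer across closely related groups but should be rebuilt for
distant ones. Chromosome X is treated like the autosomes; male hemizygosity
is not modeled.
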