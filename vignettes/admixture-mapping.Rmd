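---
title: "Case-only admixture mapping by excess local ancestry: models and methods"
author: "admixscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Case-only admixture mapping by excess local ancestry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(admixscan)
```

## The problem

Barrett's esophagus and esophageal adenocarcinoma are several-fold more
prevalent in European Americans than in African Americans, while the known
environmental risk factors are at least as common in African Americans. In a
recently admixed population such as African Americans, that disparity can be
interrogated genetically: if a locus carries European-derived susceptibility
variants, affected individuals should carry *more European local ancestry at
that locus than their own genome-wide average*. This is case-only admixture
mapping — no controls are needed, which makes the design robust to
case–control stratification differences and usable for diseases so rare in
the admixed population that assembling matched controls is impractical.

`admixscan` implements the full analysis as a reusable, tested pipeline:
simulation of admixed, disease-ascertained cohorts; genotype quality
control tailored to degraded (FFPE-derived) DNA; the excess-ancestry scan;
eigenvalue-based multiple-testing correction; region calling; and
conversion of observed ancestry excess into ancestry relative risks.

## The scan statistic

Let $q_{il} \in [0,1]$ be the estimated diploid European local-ancestry
proportion of case $i$ at locus $l$ ($0$, $\tfrac12$ or $1$ for hard calls;
posterior means in general), for $N$ cases and $L$ loci. Each case's global
ancestry is $M_i = \frac1L \sum_l q_{il}$, and the excess European ancestry
at locus $l$ is

$$\Delta\Pi_l = \frac1N \sum_{i=1}^N (q_{il} - M_i),$$

the case-average deviation of local from global ancestry. By construction
$\sum_l \Delta\Pi_l = 0$: the scan looks for *relative* displacement along
the genome, which is what removes confounding by each individual's overall
admixture proportion. The test statistic is
$Z_l = \Delta\Pi_l / \mathrm{SD}(\Delta\Pi)$, where the denominator is a
single pooled standard deviation — the root-mean-square of $\Delta\Pi_l$
over all markers (denominator $L$; the across-locus mean is structurally
zero, and at genome scale the $L$ vs $L-1$ choice is immaterial, but it is
fixed for exact reproducibility). $Z_l$ is treated as standard normal;
$1-\Phi(Z_l)$ tests excess *European* ancestry and $\Phi(Z_l)$ excess
*African* ancestry, and both one-sided p-values are always computed.

Assumptions worth keeping in mind:

* The ancestry matrix must be complete. Upstream local-ancestry inference
  produces complete posterior matrices; the readers reject missing entries
  rather than impute.
* The pooled SD is estimated in a single pass over all markers, with no
  exclusion of signal regions and no genomic-control or autocorrelation
  adjustment. A very strong, very wide signal therefore inflates the
  denominator slightly and is mildly conservative against itself.
* The normal approximation is retained even for small cohorts (the package
  applies no small-sample correction); with $N$ in the tens and hard
  ancestry calls the per-locus null is a scaled binomial mean, for which
  the approximation is adequate but not exact in the far tail.

## Effective number of tests and thresholds

Local ancestry is strongly autocorrelated along each chromosome (tracts
span megabases), so the $L$ tests are massively redundant. Per chromosome
the package computes the eigenvalues $\lambda_1..\lambda_n$ of the
locus–locus Pearson correlation matrix of the $q$ columns (zero-variance
columns are dropped and counted), summarizes them into an effective test
count, and sums over chromosomes to a genome-wide count $M$; the 5%
family-wise threshold is then $0.05/M$ per ancestry tail, reported as a
p-value (3 significant figures) and as $-\log_{10}p$ (2 decimals).

Several eigenvalue summaries are in circulation. The default here is the
participation ratio
$M_c = \left(\sum_i \lambda_i\right)^2 / \sum_i \lambda_i^2$, which equals
$n$ for independent loci, $1$ for perfectly correlated loci, and $1.6$ for
the two-locus $\rho = 0.5$ case. A Li–Ji-style estimator
($\sum_i [\mathbb{1}(\lambda_i \ge 1) + (\lambda_i - \lfloor \lambda_i
\rfloor)]$) is available via `method = "liji"` for sensitivity analysis.

**Known limitation.** The two estimators bracket the truth from opposite
sides. In the package's own null calibration (200 cohorts of 100 cases
× 5,000 markers, single-pulse admixture, $g = 7$, 0.5 cM spacing), the
per-locus test is well calibrated (rejection rate 0.053 at nominal 0.05),
but the participation-ratio threshold is mildly anti-conservative for the
family-wise rate: ~0.11 observed at nominal 0.05, because the
participation ratio under-counts effective tests when autocorrelation is
strong ($M \approx 175$ for 5,000 loci here). The Li–Ji threshold is
conservative on the same data (~0.02). The participation ratio remains the
default because its closed-form limits anchor the rest of the method's
checks; users wanting strict family-wise control at exactly the nominal
level should prefer `method = "liji"`.

Numerically, when $N < n$ (far more loci than samples — the usual regime)
the correlation matrix is rank-deficient; eigenvalues are computed from the
singular values of the standardized data matrix, which agrees with direct
eigendecomposition to $10^{-8}$ (tested) and is stabler. Eigenvalues below
$-10^{-8} n$ abort; small floating-point negatives are clipped to zero.
Trace preservation ($\sum \lambda = n$) is asserted in the tests.

## Quality control

The genotype cascade runs, in order: sample call rate (> 0.95) →
sample-heterozygosity outliers (outside mean ± 3 SD) → SNP call rate
(> 0.964) → removal of SNPs monomorphic in the sample or absent from the
reference panel → flagging of SNPs whose observed allele frequency differs
from the admixture-weighted panel expectation
$0.8\,f_{YRI} + 0.2\,f_{CEU}$ by more than 0.3 in absolute value. Design
choices, each of which was genuinely open:

* Call-rate thresholds are strict (`>`), with one exception: a complete
  record (rate exactly 1) always passes, so `min_rate = 1` means "complete
  records only" rather than "nothing".
* The heterozygosity band is symmetric (both tails removed, the reason code
  records which), and its mean/SD are computed once over the samples that
  enter the stage — not recomputed iteratively as outliers drop out.
* The frequency-concordance rule uses the absolute difference, since the
  sign is meaningless without a fixed reference-allele orientation, and is
  *flag-only by default in the workflow*: the scan can be run with and
  without the flagged SNPs. Consistent allele orientation between matrix
  and panel is the caller's responsibility.
* Samples whose heterozygosity is undefined (no non-missing calls) are
  removed with a distinct reason code.

Every filter is idempotent, and each removal set is tested against an
independent brute-force re-scan of the raw matrix.

## The cohort simulator

The generator exists because the real inputs of such studies (patient
genotypes, local-ancestry calls) are typically not public. It produces
cohorts with exactly the statistical structure the scan assumes, so that
every downstream claim can be tested against known truth.

* **Admixture model.** Single-pulse ("hybrid isolation") admixture $g$
  generations ago with European fraction $m$. Along a chromosome, haplotype
  ancestry follows a two-state Markov chain with stationary distribution
  $(m, 1-m)$ and switch intensity $g$ per Morgan: between markers at map
  distance $d$, $P(\mathrm{EUR}\to\mathrm{AFR}) = (1-m)(1-e^{-gd})$ and
  $P(\mathrm{AFR}\to\mathrm{EUR}) = m(1-e^{-gd})$; tract lengths are
  asymptotically exponential. Defaults $m = 0.2$ and $g = 7$ are standard
  round figures for African-American demography; the bundled null fixture
  uses $m = 0.27$, a typical estimated cohort mean. Maps default to 0.5 cM
  spacing and 1 cM/Mb.
* **Panels.** Balding–Nichols: ancestral frequency $p \sim U(0.05, 0.95)$,
  panel frequencies $\sim \mathrm{Beta}(p(1-F)/F, (1-p)(1-F)/F)$
  independently per panel, $F = 0.15$ by default (CEU/YRI-scale
  divergence). Markers are independent given ancestry — no within-panel LD.
* **Ascertainment.** With $j$ European haplotypes at the risk locus and
  per-haplotype relative risk $r$, risk is $r^j$ (multiplicative) or
  $1 + j(r-1)$ (additive). Candidates are kept as cases with probability
  $\mathrm{risk}(j) / \max_j \mathrm{risk}(j)$ — rejection sampling that is
  valid for $r$ above and below 1 — until the target case count is reached.
* **Observation layers.** Optional mean-preserving Beta noise on $q$
  (concentration $\kappa$; default $\kappa = \infty$, i.e. exact hard
  calls, so the statistical tests see the exact generative model);
  genotypes drawn per haplotype from its ancestry's panel frequency;
  symmetric per-allele flip errors (default $10^{-3}$); missingness as a
  per-sample mixture (default 80% of samples at 1%, 20% at 30% — the
  FFPE-dropout pattern) plus a per-call baseline.

What the simulator does **not** emulate: linkage disequilibrium within the
ancestral panels, continuous gene flow, the X chromosome, phasing or
local-ancestry *inference* error beyond the Beta noise knob, and
array-specific artifacts. Passing tests therefore demonstrate correctness
of the statistics under the stated generative model, not robustness to
misspecified local-ancestry calls on real data.

## From excess ancestry to relative risk

Under case-only ascertainment with baseline European haplotype proportion
$m$, the number of European haplotypes a case carries at the risk locus is
$j \sim \mathrm{Binomial}(2, m)$ weighted by $\mathrm{risk}(j)$, so the
expected case ancestry is

$$E[q \mid \mathrm{case}] = \frac{\sum_j (j/2)\, P(j)\, \mathrm{risk}(j)}
{\sum_j P(j)\, \mathrm{risk}(j)},$$

with the multiplicative closed form $mr/(1-m+mr)$. This is strictly
increasing in $r$, so an observed excess $\delta$ inverts uniquely;
`estimate_rr()` root-brackets $r \in [10^{-6}, 10^6]$ (additive:
$r > 1/2$, where all risk weights stay positive) to residual $<10^{-10}$,
and rejects $\delta$ outside the attainable range (the additive model
saturates at $E[q] = (1+m)/2$). Both parameterizations are reported side
by side and $m$ is a required argument, because the mapped $r$ is quite
sensitive to it and no single parameterization-plus-$m$ convention is
canonical. Estimates taken at the genome-wide maximum of a scan are
winner's-curse inflated; no shrinkage correction is applied and none is
claimed.

## Region calling

No standard boundary rule exists for admixture-scan regions, so the rule
here is explicit and parameterized rather than hidden: maximal runs of
consecutive markers with $-\log_{10}p \ge$ a *required, user-chosen*
cutoff; same-chromosome runs separated by at most `merge_gap_bp` (default
1 Mb) are merged; merged runs with fewer than `min_markers` (default 5)
qualifying markers are dropped. The peak is the qualifying marker with
maximal $|Z|$ in the tested direction (ties broken toward the smaller
position); `n_markers` and `mean_excess` summarize the qualifying markers
only, which guarantees the sign of `mean_excess` matches the tested tail.
Near-peak secondary maxima (within 10% of the peak, at least
`merge_gap_bp` apart) can be reported for regions with multi-peak
structure. A region is genome-wide significant iff its peak
$-\log_{10}p \ge$ the threshold ($\ge$ at the boundary).

## Determinism and degenerate inputs

All randomness flows from one recorded seed; rerunning a pipeline config
is bit-identical (tested on file hashes). Degenerate inputs fail loudly
with named errors: out-of-range or missing $q$ (naming marker and sample),
duplicate markers, non-increasing positions, all-identical $\Delta\Pi$
(pooled SD undefined), non-symmetric correlation input, fewer than two
non-constant loci per chromosome, relative risks outside the attainable
range.

## Problem sizes used by the test suite

Chosen so the statistical checks have real power while the whole suite
stays light: null calibration uses 200 cohorts of 100 cases × 5,000
markers; effect-size recovery uses 5,000-case cohorts on a 2,200-marker
genome-wide map (a single-locus signal then shifts each case's global
ancestry by well under one Monte-Carlo standard error, so the observed
excess is compared to the closed form without a centering correction);
QC oracle equivalence uses twenty 50 × 200 matrices; everything else runs
on toy or closed-form cases.
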