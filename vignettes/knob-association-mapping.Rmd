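---
title: "Knob marker association mapping: models, simulation design and numerical choices"
author: "knobscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Knob marker association mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(knobscan)
```

## The scientific problem

Maize heterochromatic knobs are cytologically visible blocks of satellite
repeats (mainly the 180-bp and TR-1 families) that segregate like co-dominant
bi-allelic Mendelian loci: a plant can be homozygous for knob presence,
homozygous for absence, or heterozygous. Whether knob content moves flowering
time and genome size is a long-standing question, usually attacked with
diverse panels where knob number is confounded with everything else.
`knobscan` implements the alternative design: a panel of near-isogenic inbred
lines derived by selfing from a single segregating founder, differing only in
their knob constitution at four variable loci (K3L, K5L, K7S, K9S), plus
hybrids between those lines that create heterozygous knob configurations.
The knobs themselves are then used as the markers of a small, exact
association scan.

The package provides the whole chain as testable code: a synthetic-data
generator that emulates the study design, entry-mean (BLUE) and heritability
estimation, a single-locus mixed linear model under two marker encodings, and
a phenotype-permutation significance threshold.

## The mixed linear model

For each knob locus and trait the scan fits

$$ y = S\alpha + P\beta + Ku + \varepsilon, \qquad
   u \sim N(0, K\sigma_g^2), \quad \varepsilon \sim N(0, I\sigma_e^2), $$

where $y$ is the vector of entry BLUEs, $S$ the encoded marker column with
fixed effect $\alpha$, $P$ optional structure covariates, and $u$ a polygenic
effect whose covariance is the marker-derived kinship $K$. Two encodings are
scanned:

* **additive (allele substitution)**: 0/1/2 copies of the locus's minor
  allele (ties at frequency 0.5 count the absence allele). Reported effects
  are sign-normalized to "days per knob-presence allele" so they are
  comparable across loci regardless of which allele happens to be minor.
* **dominance (heterozygous (dis)advantage)**: heterozygotes coded 1, both
  homozygotes 0, testing a heterozygote-specific shift.

REML estimation works in the eigenbasis of $K$ (decomposed once per scan):
with $H(\lambda) = \lambda K + (1-\lambda) I$ and
$\lambda = \sigma_g^2/(\sigma_g^2+\sigma_e^2)$, the total variance has a
closed-form profile and the restricted likelihood is maximized in one
dimension over $\lambda$ — a log-spaced grid on the variance ratio
($\delta = 10^{-6}$ to $10^6$, 49 points, plus the $\sigma_g^2=0$ boundary)
refined by Brent's method. The fit is deterministic; a flat profile (e.g.
$K \propto I$, where only the total variance is identifiable) is flagged
rather than silently returned.

Marker tests are generalized least squares under the fitted
$V = \sigma_g^2 K + \sigma_e^2 I$ with a Wald $t$ statistic on $n - p$
residual degrees of freedom — with at most 63 entries a normal approximation
would be anti-conservative. Two variance-component modes exist:

* `vc_mode = "exact"` (default): $\lambda$ re-estimated by REML with the
  marker in the design — the exact single-locus mixed model;
* `vc_mode = "null_once"`: the ratio $\lambda$ is fixed at its null-model
  estimate and only the total variance is re-profiled per marker. Given the
  ratio, this re-profiling is exact, and at $\lambda = 0$ the test collapses
  *exactly* to the ordinary-least-squares $t$ test — a property the test
  suite exploits as an oracle.

With only four markers, iterative multi-locus methods (e.g. pseudo-QTN
algorithms designed for genome-wide SNP sets) degenerate; `knobscan`
deliberately fits the exact per-marker mixed model that the equation above
specifies instead of wrapping such a package.

### Kinship, structure and the heterosis confound

The kinship method is a design choice: VanRaden's method-1 genomic
relationship matrix on the knob counts,
$G = ZZ^\top / (2\sum_k p_k(1-p_k))$, with a ridge of $10^{-6}$ times the
mean diagonal to guarantee positive semi-definiteness; an identity mode is
available for sensitivity analysis.

Structure covariates matter more than usual here. The panel has two groups —
inbred lines and hybrids — and hybrids flower roughly a week earlier
(heterosis). Every heterozygote in the dominance encoding is a hybrid, so a
dominance scan without a structure covariate attributes the entire heterosis
shift (several days) to the marker. `knob_scan()` therefore includes a
line-vs-hybrid indicator by default whenever the panel contains both entry
types (`structure = "auto"`); this plays the role of the $P\beta$ block in
the model. Genotype principal components remain available (`n_pcs`,
default 0: the panel shares a single genetic background, so PCs carry little
beyond the marker information itself). Additive estimates are essentially
unaffected by the indicator because the expected additive code is the same
in both groups.

## Phenotypes: BLUEs and heritability

Under a completely randomized design with homoscedastic errors the BLUE of an
entry is its arithmetic replicate mean; `compute_blues()` implements exactly
that and no spatial model. Heritability is estimated on the entry-mean basis
— the relevant repeatability for a scan whose response is the BLUE vector —
by one-way random-effects REML (`lme4`):

$$ h^2 = \frac{\sigma_g^2}{\sigma_g^2 + \sigma_e^2 / \bar r}, $$

with $\bar r$ the harmonic mean of per-entry replicate counts. An optional
group fixed effect (line vs hybrid) keeps heterosis — a group *mean* shift —
out of $\sigma_g^2$; without it the between-group contrast masquerades as
genetic variance and pushes $h^2$ toward 1 on mixed panels.

Genome size enters as a third trait: `genome_size_from_peaks()` performs the
internal-standard peak-ratio arithmetic of flow cytometry (the standard's 2C
value is a required user input, never hard-coded), and `pg_to_mbp()` converts
picograms to megabases with the standard 978 Mbp/pg factor and half-up
rounding, which reproduces the published 5.6 pg = 5477 Mbp and
5.4 pg = 5281 Mbp pairs exactly.

## The permutation threshold

Significance is declared by resampling, not by Bonferroni: the BLUE vector is
shuffled against the fixed genotype/kinship/covariate structure, the full
scan re-run, and the minimum p-value across markers recorded; the 5% empirical
quantile (type-7, linear interpolation — a documented convention, since
several exist) of those best scores after `n_perm` rounds is the threshold.
Variance components are re-estimated for every permutation. Only the
phenotype vector is shuffled; covariates stay attached to the genotype rows.
Ties at the threshold count as significant. The historical default of 50
permutations is kept for fidelity to the study design, with a warning that
the resulting 5% quantile is noisy; the package's own calibration tests use
200–5000.

For four *independent* null markers with uniform p-values the 5% threshold
would be $1 - 0.95^{1/4} \approx 0.0127$, and the permutation procedure
reproduces that limit on a matched synthetic null (independent marker
columns, identity kinship). On the real panel the permutation threshold is
noticeably larger than that limit: marker columns are correlated because
all 35 hybrids descend from the same 8 parents, and a kinship built from
only four markers necessarily contains the tested marker, which makes each
test conservative (a small-panel form of proximal contamination). This is
precisely why the resampling threshold — which calibrates against the
realized dependence structure — is the primary decision rule, and a
Bonferroni line is offered only as a plot annotation.

## What the generator emulates — and what it does not

`generator_params()` defaults *are* the study conditions: 8 lines
(3 replicates) + 35 hybrids (5 replicates) in assay 1, 20 lines × 5 in
assay 2; line genotypes drawn from the S9 fixation distribution of a founder
heterozygous at all four loci; hybrids from ordered pairs of distinct lines
(35 crosses exceed the 28 unordered pairs of 8 parents, so reciprocal crosses
are treated as distinct; the true crossing scheme is not derivable and this
default is a documented guess). Group flowering means are 70/72 days (lines,
MF/FF) and 63/64 (hybrids); genome size 5.4/5.6 pg. K9S carries the causal
effects: −0.45/−0.51 days per presence allele (MF/FF) and an additional
−1.40/−1.53 days for heterozygotes; K3L, K5L and K7S are strictly null by
default. Genome size has no knob effect by default.

Calibration choices the study leaves open, fixed once here:

* **Residual scale.** Plant-level residual SDs default to 2.5 days
  (flowering) and 0.10 pg (genome size) — realistic single-plant greenhouse
  noise.
* **Heritability calibration.** The polygenic variance is set so that the
  *total* within-group genetic variance (polygenic + realized causal-marker
  variance, pooled across groups) satisfies the target
  $h^2 = \sigma_g^2/(\sigma_g^2 + \sigma_e^2/\bar r)$; the marker share is
  subtracted and the polygenic part floored at zero. Heterosis is a group
  intercept, not entry variance.
* **Trait correlation.** MF and FF entry effects are bivariate with
  `rho_g = 0.95`. That alone cannot reproduce the observed ≈0.95 Pearson
  correlation between MF and FF BLUEs: with $h^2$ of 0.51/0.41 the
  replicate-mean noise is a fixed, uncorrelated share of the BLUE variance,
  capping the correlation near 0.89. Both traits are scored on the same
  plants, so the generator also correlates the plant-level residuals,
  `rho_e = 0.70`, chosen analytically from the variance budget to put the
  BLUE correlation at ≈0.95.
* **Noise model.** Residuals are Gaussian — the simplest defensible choice;
  nothing in the analysis depends on higher moments.

What the generator does **not** emulate: meiotic drive or any transmission
bias, linkage between knob loci (they sit on different chromosomes), knob
*size* variation (presence/absence only), year or assay effects, spatial
field structure, or non-Gaussian noise. Passing tests therefore demonstrate
that the analysis chain recovers its generating model under the study's
design and effect sizes — not that real maize data satisfy those assumptions.

## Numerical and design details

* Selfing simulation is the exact per-locus Markov chain (heterozygote →
  0/1/2 with probability ¼/½/¼), so residual heterozygosity after $g$
  generations is $0.5^g$ by construction; fixation is absorbing.
* Hybrid construction requires fixed parents and is the deterministic mean
  of parental counts.
* All randomness flows from the single top-level seed through named
  per-stage substreams (panel, phenotypes, permutations), so identical
  parameters give byte-identical outputs and stages cannot perturb each
  other's streams.
* Monomorphic loci (and dominance loci without a heterozygosity contrast)
  are excluded from scans with a warning, never silently dropped.
* p-values are floored at the smallest representable double so they remain
  in (0, 1].
* The marker "heritability" column is reported as
  $\mathrm{var}(\text{code}\cdot\hat\alpha)/\mathrm{var}(y)$ — the variance
  share explained by the fitted marker effect; how the original column was
  computed is not documented anywhere, so this definition is the package's
  own and is stated here.
* Under the dominance encoding the `freq` column holds the heterozygote
  frequency (`freq_type = "het"`), the dominance analogue of a MAF.

## Problem sizes used by the tests

The test-suite simulations are sized to estimate each quantity to the
precision its tolerance needs: 200 panels for effect and heritability
recovery (Monte-Carlo SE of the mean additive effect ≈ 0.02 days), 500 null
panels × 200 permutations for family-wise error calibration (binomial 95%
interval ±0.019 around 0.05), $10^5$ lineages for heterozygosity decay, and
a 5000-permutation run against the analytic minimum-of-uniforms quantile.

## Worked example

```{r example, eval = FALSE}
params <- generator_params(seed = 1)
study <- simulate_knob_study(params)
blues <- compute_blues(study$records, "ff", entries = study$panel$entry_id)
scan <- knob_scan(study$panel, blues, trait = "ff")
thr <- permutation_threshold(study$panel, blues, trait = "ff",
                             n_perm = 200, seed = 1)
print(apply_threshold(scan, thr))
```

Or end to end, writing every artifact:

```{r pipeline, eval = FALSE}
run_pipeline(NULL, out_dir = "knobscan_out", seed = 1)
```

## Known limitations

* Exactly bi-allelic, fully observed markers; no missing-call handling.
* BLUE = replicate mean is exact only for the stated completely randomized
  design; incomplete blocks or spatial trends would need a different entry
  mean upstream.
* The permutation test assumes exchangeable entries under the null within
  the fixed covariate structure; strong variance differences between lines
  and hybrids would violate that.
* With four markers the kinship matrix is low-rank and partially contains
  each tested marker; the exact per-marker REML absorbs most of this, but
  kinship built from markers *excluding* the tested locus is not implemented.
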