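---
title: "Two-sample Mendelian randomization with mrkit: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization with mrkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrkit)
```

## The causal model

Mendelian randomization (MR) uses genetic variants as instrumental
variables to estimate the causal effect of a modifiable exposure (say,
smoking intensity or systolic blood pressure) on a disease outcome (say,
intracranial aneurysm) from GWAS summary statistics alone. Three
assumptions define a valid instrument: it is associated with the
exposure; it is independent of confounders of the exposure–outcome
relationship; and it affects the outcome only through the exposure
(the exclusion restriction). In the two-sample design the
exposure and outcome associations come from non-overlapping GWAS
samples, so their estimation errors are independent.

For variant $j$, write $\hat\gamma_j$ (SE $\sigma_{xj}$) for the
exposure association and $\hat\Gamma_j$ (SE $\sigma_{yj}$) for the
outcome association. Under the model
$\Gamma_j = \beta\,\gamma_j + \alpha_j$, where $\beta$ is the causal
effect and $\alpha_j$ a direct (horizontally pleiotropic) effect, a
valid instrument has $\alpha_j = 0$ and the Wald ratio
$\hat\theta_j = \hat\Gamma_j / \hat\gamma_j$ estimates $\beta$ with
first-order SE $|\sigma_{yj}/\hat\gamma_j|$.

## The estimator suite

**IVW** (`mr_ivw`, the primary analysis) pools the Wald ratios with
inverse-variance weights, which is algebraically the weighted regression
of $\hat\Gamma$ on $\hat\gamma$ through the origin:
$\hat\beta = \sum_j w_j \hat\gamma_j \hat\Gamma_j \big/ \sum_j w_j
\hat\gamma_j^2$ with $w_j = \sigma_{yj}^{-2}$. The default
multiplicative random-effects model inflates the fixed-effect SE by
$\max\{1, \sqrt{Q/(J-1)}\}$, where $Q$ is the weighted residual sum of
squares, so heterogeneity widens but never narrows the interval.

**MR-Egger** (`mr_egger`) adds an intercept to the same weighted
regression after orienting every variant so $\hat\gamma_j \ge 0$
(without a fixed orientation the intercept is not identifiable). Under
the InSIDE assumption (direct effects independent of instrument
strength) the slope remains a consistent estimate of $\beta$ and the
intercept estimates the mean direct effect: a non-zero intercept is the
signature of directional pleiotropy. Inference is t-based on $J-2$
degrees of freedom, with the residual scale floored at 1 as for IVW.

**Simple and weighted median** (`mr_median`) take the (weighted) median
of the Wald ratios by linear interpolation of the cumulative
mid-weights $p_j = (S_j - w_j/2)/S_J$ at probability one half. The
weighted median is consistent as long as under half of the weight comes
from invalid instruments. Standard errors come from a parametric
bootstrap — both association vectors resampled from Gaussians at their
observed values, the weights held fixed at their observed values — with
an explicit seed so results are reproducible; `n_boot = 1000` by
default. Because the bootstrap is centred on the noisy observed
associations, the cross-sectional spread of bootstrap ratios includes
the estimation noise twice, and the resulting SE is conservative by
roughly 10–15% when the true ratios are perfectly homogeneous: the
calibration studies show median coverage of about 97–98% rather than
95% in the pleiotropy-free regime, tightening toward nominal as real
heterogeneity grows. This is a property of the bootstrap convention,
not a defect of the point estimator.

**Multivariable MR** (`mr_mvmr`) regresses the outcome associations on
a $J \times K$ matrix of exposure associations (no intercept, weights
$\sigma_{yj}^{-2}$), giving each exposure's direct effect conditional
on the others; with $K = 1$ it reduces exactly to the random-effects
IVW.

For binary outcomes all estimates are on the log-odds scale and are
additionally reported as odds ratios with exponentiated CIs.

## Instrument selection and harmonization

Selection mirrors standard MR practice: variants pass a genome-wide
significance filter ($p < 5\times10^{-8}$, strict), are greedily
clumped to pairwise LD $r^2 < 0.01$ (the lowest-p variant wins;
p-ties break lexicographically by rsID so runs are deterministic), and
instruments missing from the outcome dataset may be replaced by a proxy
in LD $r^2 > 0.9$ (strict; ties to the smallest id). A cross-trait
table can drop variants associated with more than one trait as a
sensitivity analysis; variants absent from the table are retained,
since the table records known associations only. Clumping uses $r^2$
alone, with no physical-distance window — the candidate sets here are
per-exposure instrument lists, not whole chromosomes.

Harmonization matches variants by rsID and aligns the outcome study to
the exposure's effect allele: swapped labels negate the outcome beta,
complement-strand labels are rewritten, and palindromic (A/T, G/C)
variants — whose strand cannot be read off the labels — are kept only
when allele frequencies confirm the orientation (both on the same side
of 0.5 after label alignment, both minor-allele frequencies below
0.42). The 0.42 limit is the conservative convention for ambiguous
strands; it is configurable because published pipelines differ. A
frequency of exactly 0.5, or a missing frequency, drops the variant.

## Diagnostics

Per-variant variance explained uses the summary-statistic identity
$r^2 = \beta^2 / (\mathrm{se}^2 (n-2) + \beta^2)$, summed over
(post-clumping, approximately independent) instruments, and instrument
strength is $F = r^2 (n - k - 1) / (k (1 - r^2))$. Because the additive
rule can exceed 1 on invalid input, the total is clamped just below 1
with a warning. Per-variant sample sizes are used where available, with
the exposure maximum as fallback. Leave-one-out analysis re-runs IVW
without each variant and flags any exclusion that lifts the p-value
across the significance threshold — the "association driven by a single
variant" pattern.

## The study pipeline

`run_study()` orchestrates many exposures against a primary outcome:
selection, proxy substitution, harmonization, the estimator suite,
Egger intercept test, leave-one-out, and diagnostics, then classifies
each exposure by its IVW p-value against the Bonferroni threshold
`alpha_family / n_exposures` (outcomes are not multiplied into the
correction; the suggestive band runs from that threshold up to 0.05,
closed on the left). Sensitivity estimators are reported alongside but
never drive the verdict. Exposures significant on the primary outcome
are re-run on each additional outcome (e.g. ruptured and unruptured
disease strata) with the same instrument set, which keeps the
comparison across strata about the outcome, not about re-selection.
Exposures with no surviving instruments are recorded and skipped, never
fatal. All bootstrap seeds derive deterministically from the study
seed, and the master table is written with fixed numeric formatting, so
a rerun is byte-identical.

## What the generator simulates — and what it does not

`simulate_two_sample()` draws, per variant: an allele frequency
$f_j \sim U(\text{maf range})$; a true exposure effect
$\gamma_j \sim N(0, \sigma_\gamma^2)$ on the standardized-genotype
scale (or half-normal, below); a direct effect $\alpha_j$ that is zero
for valid variants and $N(\mu_\alpha, \sigma_\alpha^2)$ for the
configured invalid fraction; and observed associations with independent
Gaussian noise at $\sigma_{xj} = (2 n_x f_j(1-f_j))^{-1/2}$ and, for a
binary outcome with case fraction $\varphi$,
$\sigma_{yj} = (2 n_y f_j(1-f_j)\,\varphi(1-\varphi))^{-1/2}$ on the
log-odds scale. There is deliberately no significance selection at
generation — winner's curse enters only if the caller applies the
selection module to the same data, so its effect can be isolated.

Defaults are chosen once as a realistic strong-instrument setting:
`gamma_sd = 0.05` means the default 50 instruments jointly explain
about 12% of the exposure and each carries a mean F near 90 at
$n_x = 10^5$. That choice has one visible consequence: like every
ratio-based estimator, IVW carries a first-order regression-dilution
bias of roughly $-\beta\,\sigma_x^2/(\sigma_\gamma^2 + \sigma_x^2)
\approx -\beta/\bar F$, about $2\times10^{-3}\,\beta$ here. It is
invisible at the scale of a single CI (coverage stays nominal) but
resolvable by a 1000-replicate mean, and it cannot be removed by
making instruments stronger without making the implied variance
explained exceed 100%. The calibration tests therefore treat it as a
property of the conditions: coverage is asserted at the nominal band,
while the strict "mean bias within Monte-Carlo error of zero" check
holds exactly at $\beta = 0$ and is attenuation-limited away from it.

Directional-pleiotropy calibration applies the genome-wide significance
filter to the simulated exposure before estimating
(`mr_calibration_study(select_p = 5e-8)`): with unselected instruments,
variants whose true effect is near zero get their sign flipped by
estimation noise during MR-Egger's orientation step, which flips their
direct effects too and drags the intercept toward zero. Selected
instruments — the only kind real analyses use — are bounded away from
zero and orientation is stable.

`gamma_dist = "halfnormal"` exists for directional-pleiotropy studies:
with sign-symmetric true effects, the effect-orientation step that
MR-Egger requires flips the sign of each variant's direct effect along
with its betas, converting directional pleiotropy into balanced
pleiotropy and driving the expected intercept to zero regardless of
$\mu_\alpha$. Consistently oriented (half-normal) instruments keep the
directional signal estimable; this is also the realistic regime, since
published instruments are conventionally reported on the
exposure-increasing allele.

The LD panel generator draws reference haplotypes from a latent
Gaussian with AR(1) correlation $\rho^{|i-j|}$ inside each block,
thresholds them at each variant's frequency (so Hardy–Weinberg holds),
and computes $r^2$ empirically from the dosages. Thresholding
attenuates the latent correlation — a latent $\rho = 0.99$ pair yields
dosage $r^2 \approx 0.8$, not $0.98$ — so block $\rho$ values should be
read as upper bounds on realized LD. The generator does not model
trans-ethnic frequency divergence, sample overlap between the two
GWAS, assortative mating, or individual-level genotype–phenotype
mechanisms; conclusions from passing tests are about the estimators
and the pipeline, not about any real dataset.

## The bundled study fixture

`make_study_fixture()` writes a complete synthetic study: exposures
with true log-odds effects cycling through
$\{0.5, -0.5, 0.2, -0.2, 0, 0\}$, a shared binary primary outcome
sized like a large intracranial-aneurysm case-control GWAS (10,754
cases of 317,636), two smaller outcome strata with the same true
effects and independent noise, an LD panel of 2,000 reference
genotypes in blocks of 3 variants at latent $\rho = 0.9$ (so clumping
keeps roughly one variant per block), a small fraction of variants
withheld from the outcome tables to exercise proxy search, and a
cross-trait table marking a few variants as multi-trait. Truth is
saved as a JSON sidecar. Per exposure 18 variants are simulated with
`gamma_sd = 0.06` at $n_x = 2\times10^5$, which puts most variants past
genome-wide significance — the fixture exists to exercise the
pipeline's selection path end-to-end at desk scale, not to emulate a
full GWAS's variant count.

## Numerical conventions and degenerate inputs

CIs use the Gaussian multiplier 1.96 for IVW and the medians (no
residual variance is estimated there) and t-quantiles for MR-Egger and
MVMR (where one is); residual scales are floored at 1 so no estimator
reports super-fixed-effect precision. P-values are floored at the
smallest positive double rather than reported as 0. A zero exposure
beta makes the Wald ratio a hard error; IVW needs 1 (fixed) or 2
(random-effects) variants, Egger and the medians 3, MVMR more variants
than exposures and a full-rank exposure matrix. Leave-one-out falls
back to the fixed-effect model when a subset has a single variant.
Files are written with `%.17g` so tables round-trip exactly; missing
allele frequencies are encoded as the literal `NA`.

## Problem sizes used in the checks

Calibration studies use $J = 50$–$100$ variants, both samples at
$10^5$, and 500–1000 replicates; the full-pipeline determinism check
runs a 51-exposure fixture. These sizes resolve coverage to better
than one percentage point and keep the whole suite comfortably within
a desktop run.

## Known limitations

Proxy substitution requires the proxy's own associations in both
studies; transferring an index variant's effect onto a proxy's alleles
(using the dosage-correlation orientation, exposed as
`proxy_orientation()`) is left to the caller. Clumping has no
physical-distance window. The binary-outcome simulator works on the
log-odds scale directly and does not model case-control ascertainment
beyond the case-fraction term. MVMR leaves construction of the shared
instrument set to the caller. None of the estimators corrects for
winner's curse when exposure selection and estimation share a sample.
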