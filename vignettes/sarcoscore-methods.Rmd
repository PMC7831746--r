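---
title: "Methods: models, parameters and design choices in sarcoscore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in sarcoscore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sarcoscore)
```

sarcoscore implements the statistical workflow of a small case-control
candidate-gene study of sarcopenia: phenotype classification, genotype
quality control, association testing, covariate-adjusted logistic models,
an unweighted polygenic score with a ROC-derived cutoff, and the power
calculation that accompanies such a design. This vignette explains each
model, its assumptions and tunable parameters, the numerical choices made
where several conventions exist, and what the synthetic-data generator does
and does not emulate.

## Phenotype model

Skeletal muscle mass is estimated from single-frequency bioimpedance with
the Janssen regression

$$\mathrm{SMM\,(kg)} = \frac{h_{cm}^2}{R_\Omega}\times 0.401
  + 3.825\,\mathrm{male} - 0.071\,\mathrm{age} + 5.102,$$

where height enters in centimetres inside the impedance index
($h^2/R$) and sex is coded 1 for men, 0 for women — both conventions of
the source regression, stated here explicitly because the formula is
otherwise unit-ambiguous. The skeletal muscle index divides SMM by height
in metres squared.

Classification follows the EWGSOP decision rule with the cutoff set used
in recent consensus practice: low grip strength below 27 kg (men) / 16 kg
(women), low muscle quantity below SMI 8.87 / 6.42 kg/m², low performance
below 0.8 m/s gait speed. *Confirmed* sarcopenia requires low strength
**and** low mass; low gait speed additionally marks *severity*. The
literature also contains a mass-only rule; we implement the
strength-and-mass combination because it is the one consistent with the
cutoff values above, and the cutoffs are fully overridable through
`ewgsop_cutoffs()`. Samples missing any required measurement are left
`unclassified` with the reason recorded rather than silently dropped.
Grip strength is expected to arrive already collapsed (best of attempts).

## Hardy-Weinberg quality control

`hwe_chisq()` is the 1-df Pearson goodness-of-fit test against expected
counts $(n\hat p^2, 2n\hat p\hat q, n\hat q^2)$, deliberately without a
continuity correction so that a sample in exact HWE proportions yields
$\chi^2 = 0$; `hwe_exact()` offers the two-sided exact (Levene
conditional) test, preferable when any expected count is below about 5.
The pipeline tests each SNP per group and excludes SNPs deviating *in
controls* — deviation in cases is reported but retained, since at a truly
associated locus the case group is expected to deviate.

One subtlety surfaced by the package's own simulations: case-control
sampling itself perturbs control-group genotype frequencies away from HWE
at a strong-effect locus (the analytic non-centrality for the bundled
MTHFR-like SNP is ≈ 1.3 at 145 controls but ≈ 13 at 1 450). The default
exclusion threshold `hwe_alpha = 0.05` therefore suits study-sized cohorts
only; at larger sample sizes the conventional genome-wide QC thresholds
(1e-4 to 1e-6) should be used, and the pipeline exposes the knob.

## Association statistics

All contingency statistics are Pearson χ² without continuity correction —
this is the convention under which the reconstructed allele tables
reproduce published p-values, and it keeps the allelic χ² identical to the
squared two-proportion z statistic. The genotypic test uses the full 2×3
table with 2 df. Odds ratios are cross-products with Woolf log-scale
intervals; a single zero cell triggers the Haldane-Anscombe +0.5 on all
four cells (flagged in the output), and two zero cells on a diagonal leave
the OR undefined. Alleles are treated as independent (2n per group), the
standard allelic-test assumption, valid under HWE.

`counts_from_freq()` inverts printed percentages to integer counts with
half-away-from-zero rounding; this choice reproduces all six published
case/control allele counts for the three associated SNPs exactly.

No multiple-testing correction is applied by default (each SNP is reported
at face value, the small-study convention); quantitative-trait comparisons
across genotypes use one-way ANOVA with Tukey HSD, sexes analyzed
separately by the caller.

## Logistic models

`fit_logistic()` is a self-contained IRLS implementation: start at
$\beta = 0$, iterate weighted least squares until
$\max|\Delta\beta| < 10^{-8}$ or $|\Delta \mathrm{deviance}| < 10^{-10}$,
cap at 50 iterations. Separation is flagged when a coefficient exceeds 15
in absolute value while still moving by more than the tolerance; exactly
collinear designs are an error; rows with missing values are dropped and
counted (complete-case analysis per model). Wald standard errors come from
the observed information at convergence. The unit tests pin the fitter to
`stats::glm` coefficients and likelihoods to 1e-6 and verify that the
unadjusted single-predictor OR equals the contingency cross-product OR —
an analytic identity of the saturated 2×2 model.

The explained-variation summary is the Nagelkerke pseudo-R²
($R^2_{CS}$ rescaled by its attainable maximum); the Cox-Snell value is
retained alongside because "percent of variance" claims in the applied
literature are ambiguous between the two. Sex enters as a male indicator,
age and physical activity as raw units, so ORs are per year / per unit.
Physical activity has no fixed semantics here — it is whatever
dimensionless score the study recorded — and is passed through untouched.

## Genetic risk score and cutoff

The score is unweighted and additive: 0/1/2 risk-allele copies per SNP,
summed over K SNPs and rescaled by $100/(2K)$, so scores live on the
lattice $\{0, 100/2K, \dots, 100\}$. Samples missing any contributing
genotype are excluded (strict mode; a mean-imputation mode exists but is
off by default because silent imputation would blur the lattice and the
group proportions). Risk alleles are oriented empirically — the allele
with case-control allelic OR above 1 — when the panel does not fix them;
an OR of exactly 1 is a hard error asking for manual orientation.

ROC candidate thresholds are the midpoints between consecutive distinct
observed scores plus sentinels outside the observed range, with
"score ≥ threshold ⇒ positive". On the three-SNP lattice the midpoint
between 50 and 66.7 is 58.3 — the midpoint convention is thus the one
under which the published cutoff value is representable at all. AUC uses
the rank (Mann-Whitney) formulation with ties counted ½ and the
Hanley-McNeil normal CI (chosen over DeLong for self-containment; the
method is recorded in the result). The Youden-optimal threshold breaks
ties toward higher sensitivity and then lower threshold, a
screening-oriented convention.

## Power model

The power calculator maps (risk-allele frequency $p$, prevalence $K$,
genotype relative risks $g_1, g_2$) to penetrances
$f_0 = K/(q^2 + 2pqg_1 + p^2g_2)$, $f_1 = g_1f_0$, $f_2 = g_2f_0$, inverts
them to expected case/control genotype frequencies, and evaluates the
non-central χ² of the chosen test. For the 1-df allelic test the default
non-centrality uses unpooled group variances; a pooled variant (whose λ is
exactly the Pearson statistic of the expected allele table) is selectable,
because public power calculators are not explicit about this convention
and the two differ by a few percent. For the published parameter set
(50/150, $p=0.4$, $K=0.25$, $g=1.5/2.5$, α=0.05) both variants give power
≈ 0.75–0.77, not the 80% sometimes quoted for these inputs; the
discrepancy presumably reflects an unstated setting of the original tool
and is why the package reports the algebraic intermediates (penetrances,
group frequencies, λ) alongside the power. `required_n()` inverts the
curve to the smallest case count reaching a target power at a fixed
case:control ratio.

## Synthetic cohorts

The generator draws population genotypes per SNP under HWE (optionally
with a heterozygote deficit `fis` to build HWE-violating SNPs), assigns
disease through a logistic liability, subsamples exact case/control
counts, draws phenotypes from status- and sex-conditional truncated
normals, and finally masks 6.5% and corrupts 2% of genotype cells —
emulating the amplification and call-quality rates of a KASP assay. A
single seed drives everything; identical seeds give byte-identical
cohorts. The emitted truth object records the pre-error genotype draws so
parameter-recovery tests can separate estimator behavior from genotyping
noise.

Two design points deserve explanation:

* **Offset scale.** Genotype liability offsets are *not* the log GRRs:
  GRRs are risk ratios, and at prevalence ≈ 0.24 risk and odds ratios
  differ materially, so log-GRR offsets would shrink the realized
  case-control ORs well below their nominal values. Offsets are instead
  $s(g) = \mathrm{logit}(f_g) - \mathrm{logit}(f_0)$ from the penetrance
  algebra, which makes the liability model exactly consistent with the
  penetrance model for a single effect SNP.
* **Joint calibration.** With several SNPs on one liability, each SNP's
  *marginal* OR is attenuated relative to its single-SNP value
  (non-collapsibility). `study_default_spec()` therefore calibrates its
  three effect SNPs by coordinate-wise root finding against the exact
  joint-model marginals (`implied_group_frequencies()`, an enumeration
  over the effect-SNP genotype combinations), so the default cohort's
  control-group allele frequencies (0.283 / 0.424 / 0.486) and marginal
  allelic ORs (3.317 / 2.037 / 1.915) equal their targets analytically.

Two samplers share this one analytic limit: the `population` sampler
simulates a 100× population and subsamples (so covariate effects can enter
the liability), and the `conditional` sampler draws genotypes directly
from the implied per-group frequencies (zero covariate effects only;
orders of magnitude faster, used for replicate-heavy calibration tests).

Default phenotype distributions were chosen once so that EWGSOP
classification of the simulated phenotypes agrees with the generating
label for roughly 19 samples in 20 — deliberate overlap, because perfectly
separated phenotypes would make classification tests vacuous. Covariate
effects default to zero (the study reported no significant case-control
age difference). What the generator does **not** emulate: linkage
disequilibrium between SNPs, population stratification, sex-specific
genetic effects, non-normal phenotype shapes, and informative
missingness — passing tests on these cohorts therefore says nothing about
robustness to those features in real data.

Problem sizes in the test suite were chosen to make each stochastic check
informative at its stated tolerance: 500 replicates at 2 000/2 000 for
Woolf CI coverage, 1 000 replicates for type-I error and HWE p-value
uniformity, 2 000 replicates at the 50/150 power design, 300 seeds for
generator-estimator consistency, and a ×10 cohort for the large-n pipeline
run.

## Known limitations

* The exact HWE test enumerates heterozygote configurations; it is meant
  for the small per-group counts of candidate-gene studies, not biobank
  scales.
* The logistic fitter offers no Firth correction, interactions, or
  stratified fits; quasi-separated models are reported as errors rather
  than penalized fits.
* The AUC interval is Hanley-McNeil, which is mildly anticonservative for
  very unbalanced groups compared to DeLong.
* The risk score is unweighted and evaluated in-sample, as in the design
  it mirrors; no cross-validation of the cutoff is attempted.
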