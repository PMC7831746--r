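# sarcoscore

Case-control genetic-association analysis for sarcopenia studies in older
adults: phenotype classification, per-SNP association statistics, an
unweighted polygenic risk score, and the power calculation that goes with a
candidate-gene design — plus a synthetic-cohort generator so the whole
workflow is testable without access to individual-level study data.

## Who this is for

Researchers running (or re-analyzing) small candidate-gene case-control
studies of sarcopenia — typically a few hundred participants phenotyped by
the EWGSOP algorithm and genotyped at a handful of SNPs (the bundled panel:
MTHFR rs1801131, ACTN3 rs1815739, NRF2 rs12594956, VDR rs2228570, ADRB2
rs1042713, CX3CR1 rs3732379, NPAS4 rs7947391).

## What it computes

**Phenotype.** Skeletal muscle mass from single-frequency BIA
(`SMM = height² / R × 0.401 + sex × 3.825 − 0.071 × age + 5.102`, height in
cm, R in ohm, sex 1 = male), the skeletal muscle index `SMI = SMM / height_m²`,
and EWGSOP classification: *sarcopenic* = low grip strength (< 27 kg men /
16 kg women) **and** low SMI (< 8.87 / 6.42 kg/m²), with gait speed
< 0.8 m/s marking severity.

**Quality control.** Hardy-Weinberg equilibrium per SNP and group — Pearson
χ² (1 df, no continuity correction) and an exact (Levene-distribution)
test for small counts; SNPs deviating in controls are excluded from
analysis.

**Association.** Genotypic (2×3), allelic, dominant and recessive codings;
Pearson χ² without continuity correction; odds ratios with Woolf
(log-scale) 95% intervals, `exp(ln OR ± 1.96 √(1/a + 1/b + 1/c + 1/d))`;
Haldane-Anscombe +0.5 for zero cells; one-way ANOVA + Tukey HSD for
quantitative traits across genotypes; a reconstruction utility that turns
printed allele percentages back into integer counts.

**Models.** Self-contained IRLS logistic regression (unadjusted and
adjusted for age, sex, physical activity) with Wald ORs/CIs and Nagelkerke
pseudo-R².

**Risk score.** The additive sarcopenia genetic score: per SNP the
risk-homozygote scores 2, heterozygote 1, other homozygote 0; the sum over
K SNPs is rescaled by `100/(2K)` (for the three-SNP panel,
`SGS = 100/6 × (MTHFR + ACTN3 + NRF2)`); ROC curve with midpoint
thresholds, Mann-Whitney AUC with Hanley-McNeil CI, and the Youden-index
(J = sens + spec − 1) optimal cutoff.

**Power.** Genetic power calculator parameterization: risk-allele
frequency, prevalence and genotype relative risks imply penetrances
`f0 = K/(q² + 2pq·g₁ + p²·g₂)`, expected case/control genotype
frequencies, a non-central χ² and the analytic power; plus the smallest
case count reaching a target power.

**Simulator.** `study_default_spec()` emulates a 190-participant cohort
(45 cases / 145 controls, age 78.3 ± 9.6 y, 67:123 men:women, 6.5% missing
genotypes, 2% genotype errors) whose three effect SNPs are calibrated so
the control-group allele frequencies and marginal allelic ORs match
published values exactly in the analytic limit.

## Worked example

```r
library(sarcoscore)

# Allele-count table reconstructed from printed frequencies:
# 45 cases (90 alleles, 56.7% C) vs 145 controls (290 alleles, 28.3% C)
tab <- table2x2(a = 51, b = 39, c = 82, d = 208)
odds_ratio_woolf(tab, model = "allelic")
#> allelic model: OR = 3.317 (95% CI 2.034-5.409), chi2 = 24.335 (df 1), p = <0.001

# Power of a 50/150 design at GRR 1.5/2.5, p = 0.4, prevalence 0.25
gpc_power(power_spec(0.4, 0.25, 1.5, 2.5, 50, 150))
#> Genetic power calculation (allelic_1df, unpooled variance)
#>   p = 0.400, K = 0.250, GRR het/hom = 1.50/2.50, N = 50/150, alpha = 0.050
#>   penetrances f0/f1/f2 = 0.168919 / 0.253378 / 0.422297
#>   risk-allele freq cases 0.513514, controls 0.362162
#>   ncp = 7.0092 (df 1), power = 0.7541

# Full pipeline on a synthetic study-shaped cohort
sim <- simulate_cohort(study_default_spec(), seed = 1)
res <- run_study_pipeline(sim$cohort, study_panel(), outdir = "run1")
subset(res$association, model == "allelic",
       select = c(snp_id, or_, ci_low, ci_high, p))
#>         snp_id  or_ ci_low ci_high        p
#> a    rs1801131 2.80  1.695    4.62 4.06e-05
#> a3   rs1815739 1.82  1.063    3.11 2.77e-02
#> a6  rs12594956 2.71  1.605    4.58 1.41e-04
#> a9   rs2228570 1.07  0.650    1.75 8.02e-01
#> a12  rs1042713 1.51  0.911    2.51 1.08e-01
#> a15  rs7947391 1.03  0.627    1.68 9.20e-01
res$grs$auc
#> AUC = 0.761 (95% CI 0.655-0.868); 30 cases / 112 controls
res$grs$cutoff
#> Youden cutoff: score >= 41.67 (J = 0.447; sens 0.867, spec 0.580)
```

At this sample size (190, with 6.5% missing genotypes and strict
score-missingness) the three effect SNPs come out significant with ORs
scattered around their generating values, the three null SNPs do not, and
the risk score separates cases from controls (AUC ≈ 0.76). The GRS stage
uses only samples with complete scores (30 cases / 112 controls here).

A thin CLI over the same functions lives in `inst/scripts/sarco-cli.R`
(subcommands `simulate`, `classify`, `assoc`, `grs`, `power`, `run`).

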