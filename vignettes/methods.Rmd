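---
title: "Models and methods behind preclinq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind preclinq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(preclinq)
```

`preclinq` quantifies three preclinical neuroimaging readouts — pCASL
perfusion, ^1^H-MRS metabolite concentrations and film autoradiography — and
tests genotype effects on them across brain regions. This vignette explains
the models, the choices that were genuinely open, and what the synthetic
cohort generator does and does not emulate.

## Perfusion quantification

### Inversion efficiency

A pCASL labeling train inverts arterial spins with an efficiency IE that
must be measured per animal, because it scales the perfusion signal
linearly. From the complex control/label images of a carotid flow scan,

$$\mathrm{IE} = \left\langle \frac{|M_\mathrm{control} -
M_\mathrm{label}|}{2\,|M_\mathrm{control}|} \right\rangle_\mathrm{mask},$$

i.e. the magnitude of the complex voxelwise difference divided by twice the
control magnitude, averaged over both carotid ROIs jointly. Two choices were
open here and are fixed as follows: the magnitude is taken per voxel
*before* averaging (so vessel-to-vessel phase differences cannot cancel),
and both carotid ROIs enter one joint mean. Perfect inversion
($M_l = -M_c$) gives IE = 1, no labeling gives 0, and the estimate is
invariant to a global phase rotation of both images — a property the test
suite checks directly.

### CBF model

With time-averaged perfusion signals $SI_c$, $SI_l$ (the 40 label/control
pairs are averaged first, then subtracted), voxel tissue $T_1$, and
constants $\lambda$ (blood–brain partition coefficient, 0.9 ml/g),
$T_{1,b}$ (arterial blood, 2.4 s), labeling duration $\tau$ = 3 s,
post-label delay PLD = 0.3 s and TR = 4 s:

$$\mathrm{CBF} = \frac{6000\,\lambda\,(SI_c - SI_l)\,
e^{\mathrm{PLD}/T_{1,b}}}
{2\,\mathrm{IE}\;T_{1,b}\;M_0\,(1 - e^{-\tau/T_{1,b}})},
\qquad M_0 = \frac{SI_c}{1 - e^{-TR/T_1}},$$

in ml/100 g/min. The control image corrected for $T_1$ saturation at the
sequence TR serves as the equilibrium magnetization $M_0$; the factor 6000
converts ml/g/s to ml/100 g/min. This is the standard single-compartment
pCASL form; the placement of the factor 2 and the signs of the exponents
follow from dimensional analysis and the requirement that a steeper $T_1$
saturation (shorter TR) inflate $M_0$. A scalar hand evaluation (for
$SI_c$ = 100, $SI_l$ = 98, $T_1$ = 1.8 s, IE = 0.85 the model gives
37.48 ml/100 g/min) was frozen into the tests before the array
implementation was written.

Numerical guards: voxels with $|SI_c|$ below a configurable epsilon or
non-positive $T_1$ are set to 0 and counted; CBF is exactly 0 where
$SI_c = SI_l$. Maps are normalized by the whole-brain mask mean, making the
regional values unitless CBF ratios whose mask mean is 1 by construction;
all group statistics run on these ratios, which removes the (large)
between-animal global perfusion variation.

## Metabolite quality control and testing

LCModel-style fits report a Cramér–Rao lower bound per metabolite as a %SD.
Estimates with CRLB ≥ 20% are classified as not accurately detectable and
discarded; the boundary is inclusive, and the filter is idempotent. Pooled
z-scores (both genotypes combined, per metabolite, sample SD with $n-1$)
are provided for display. Group comparisons are pooled-variance Student t
tests — not Welch — because the within-group SDs are similar by design and
the pooled form gives the conventional $df = n_1 + n_2 - 2$. The
Bonferroni multiplier is an explicit parameter (default 4: Glu, Gln, Glx,
GABA) rather than being inferred from the table: the family of comparisons
is a design decision, and published corrected p-values are not always
reconstructible from one fixed multiplier. Glx is treated as its own
measured column, not recomputed as Glu + Gln, since a fitted composite need
not equal the sum of separately fitted components.

## Autoradiography calibration

Film optical density responds to tritium activity nonlinearly, approaching
a maximum density. The standard curve is fitted as

$$OD = b + A\,(1 - e^{-k\,a}), \qquad A, k > 0,$$

by iteratively reweighted least squares with a redescending Tukey bisquare
weight (tuning constant 4.685, MAD residual scale, convergence tolerance
1e-8 on the weights, at most 100 iterations). A redescending weight gives a
gross film artefact asymptotically zero influence, which is the behaviour
wanted from "robust regression" calibration; the exact merit function of
proprietary implementations is not reproduced, only the contract (exact on
clean data, bounded shift under one corrupted standard) is tested. When
saturation is not identifiable — the points are collinear to machine
precision, the nonlinear fit fails, or the fitted curvature over the
calibrated range is negligible ($k \cdot a_{max} < 0.05$) — the fit falls
back to a robust straight line using the same IRLS machinery.

One curve is fitted per film, since each film carries its own standards
slide and exposure. Section ODs are converted to activity *before*
averaging the three consecutive sections, because the curve is nonlinear
and averaging ODs first would bias high-activity regions; a test pins this
order. Specific binding is total minus nonspecific activity; ligands
without displaceable nonspecific binding use the total directly. Negative
differences are retained but flagged, and a missing subject × ROI cell
propagates as `NA` rather than being imputed. Inverse interpolation is
unique by monotonicity; an OD at or above the saturation asymptote is a
hard error naming the limit, while ODs below the baseline are clamped to
activity 0 with a warning (configurable to a hard error).

## Group statistics

Regional tables are analyzed with a genotype × ROI split-plot ANOVA:
genotype is tested against the subject-within-genotype mean square, ROI and
the interaction against the within-subject residual. With complete data the
closed-form sums-of-squares decomposition is used (it handles unequal group
sizes, since every subject still contributes every ROI, and it is checked
against an independent `aov()` error-stratum decomposition to 1e-8). Only
when individual subject × ROI cells are missing does the package switch to
a REML mixed model with a random subject intercept and type-3 F tests with
Satterthwaite degrees of freedom. Keeping the balanced path closed-form
makes the oracle test exact instead of tolerance-based.

Interaction follow-ups compare genotypes within each ROI using the pooled
residual variance of the full cell-means model with
$df = N_{obs} - (\text{genotypes} \times \text{ROIs})$ — for 22 subjects
and 2 ROIs, $t_{(40)}$. This df convention matches how mixed-model post-hoc
tests are commonly reported by commercial ANOVA software; a per-ROI Welch
variant is available behind a flag for users who prefer not to pool.
Degenerate cell-means fits (zero residual variance) return a signed
infinite or zero statistic rather than NaN.

Effect sizes are converted from test statistics, not recomputed from raw
summaries: $d = 2t/\sqrt{df}$ and
$\eta^2_p = F\,df_1/(F\,df_1 + df_2)$. These two conversions reproduce
every published (statistic, effect size) pair the package's tests assert,
which is precisely why they were adopted; note that for pooled-df post-hoc
tests $2t/\sqrt{df}$ deliberately differs from the plain
mean-difference/SD definition. Supplementary ANCOVA adjustment fits
`value ~ covariates + genotype` by least squares and reports the
full-vs-reduced F for genotype; exact collinearity (including a covariate
that reproduces the outcome) is an error.

## The synthetic cohort generator

The generator is layered. A *truth layer* draws per-subject regional
quantities — CBF ratios, metabolite concentrations, binding levels — under
the cohort structure: two genotypes of 12 (9♀/3♂ mutants, 5♀/7♂ controls),
and a fixed per-modality missing-subject pattern (2 controls for
perfusion; 3 controls + 1 mutant, 1 control + 2 mutants, and 2 controls +
3 mutants for the three radioligands). An *image/film layer* embeds those
truths in synthetic measurements: 40 label/control volume pairs whose mean
difference is the exact inverse of the CBF model at the subject's truth
(so the noiseless chain must recover truth to numerical precision, a
property tested at < 1e-10), a complex carotid scan with
$M_l = (1 - 2\,\mathrm{IE})M_c$, and film ODs pushed through the generating
saturating curve. Noise is additive Gaussian on magnitude signals and
circular complex Gaussian on the IE scan — the simplest model consistent
with heavily averaged, high-SNR acquisitions.

Geometry is deliberately minimal: 32 × 32 × 10 voxels with a
three-compartment atlas (dorsal hippocampus, ventral hippocampus,
rest-of-brain). The analysis consumes labelled masks only, so realistic
anatomy would add cost without testing anything new. The rest-of-brain
compartment absorbs whatever value makes each subject's mask-mean ratio
exactly 1, so normalization is exact by construction.

**Effect calibration.** The study conditions the generator emulates are
known through *reported statistics*, not raw group summaries. Effects are
therefore parameterised in the reported metric and inverted through the
estimator's sampling expectation: for a d-type target the raw standardized
shift solves $E[\hat d] = 2\,a(df)\,\mathrm{ncp}/\sqrt{df}$ with $a(df)$
the noncentral-t mean factor (`delta_for_reported_d()`); for an
$\eta^2_p$-type target the noncentrality solves
$E[F/(F + df_2)] = \eta^2_p$ by numerical integration of the noncentral F
density (`ncp_for_eta2()`), both at the post-missingness group sizes. The
metabolite generator instead uses published group means and SDs directly
(mM): glutamine 2.29 ± 0.23 vs 2.84 ± 0.34, with Glx as the per-subject
Glu + Gln sum. Defaults place a ventral-hippocampus CBF elevation of
d = 0.8, a glutamine elevation whose expected reported d is ≈ 2, and a
uniform SV2A-binding reduction with genotype $\eta^2_p$ = 0.29.

Values not reported anywhere had to be chosen once: within-group SD of the
normalized CBF ratios (0.10 per hippocampal ROI — a plausible
coefficient of variation for ratio-normalized perfusion), whole-brain CBF
61 ± 16 ml/100 g/min, true IE 0.85 ± 0.03, binding means of 2–4 µCi/mg
with 0.5 between-subject and 0.3 subject × ROI SD, CRLB distributions
centred at 3–14 %SD (glutamine's differing by genotype, since a higher
concentration fits with lower relative uncertainty), and a film curve
$b = 0.05$, $A = 1.8$, $k = 0.25$ over standards from 0.25 to
10 µCi/mg. They are config parameters, documented at their definitions.

**What passing tests do and do not show.** The generator draws independent
Gaussian regional values; real data have spatially correlated noise,
partial-volume effects, registration error and non-Gaussian film grain.
Calibration and round-trip results therefore validate the *computations*,
not the biology: they show the pipeline recovers what the model family
assumes, unbiasedly and at the nominal error rates, under the cohort's
size, imbalance and missingness.

**Problem sizes.** Monte-Carlo checks run 1000 null cohorts (type-I
calibration) and 200 effect cohorts (recovery of d and $\eta^2_p$) on the
truth layer, whose values are identical to what the image chain recovers up
to measurement noise shown separately to be negligible; image-level
round trips use small cohorts (16 × 16 × 8 volumes, 3–4 subjects per
group), which is ample for exact-recovery properties.

## Known limitations

- The REML path's Satterthwaite denominator df will generally not equal
  the convention of any particular commercial package; with whole-subject
  missingness (the common case here) the closed-form path applies anyway.
- The saturating film model is a phenomenological choice; films driven far
  into saturation violate the invertibility range and are rejected rather
  than extrapolated.
- The pooled post-hoc assumes homoscedastic cells across ROIs and
  genotypes; use `method = "welch"` when that is implausible.
- `t_to_d` and `f_to_eta2` are exact conversions of test statistics; they
  inherit whatever small-sample bias the statistic carries and are not
  bias-corrected (no Hedges correction), matching common reporting
  practice.
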