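---
title: "Landmark-based morphometry of the internal carotid artery: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Landmark-based morphometry of the internal carotid artery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icamorph)
```

## The measurement model

Moyamoya disease (MMD) is a steno-occlusive vasculopathy of the distal
internal carotid artery (ICA), strongly associated in East-Asian
populations with the *RNF213* c.14429G>A susceptibility variant. One
gross-morphological phenotype of interest is how *tortuous* the
intracranial-extradural ICA is: straighter conduits concentrate wall
shear stress near the terminal ICA, which has been proposed as a link
between genotype and the site of occlusion.

`icamorph` implements a deliberately simple measurement model: instead
of extracting a centerline from a segmented lumen, the vessel course is
approximated by six anatomy-specific landmarks placed at the lumen
center on TOF-MRA, in RAS millimetre coordinates:

* **P1** — start of the vertical petrous ICA at the carotid canal,
* **P2** — petrous vertical/horizontal inflection,
* **P3** — petrous/cavernous inflection,
* **P4** — cavernous vertical/horizontal inflection,
* **P5** — anteriormost point of the carotid siphon,
* **P6** — emergence of the anterior choroidal artery.

From the landmark chain the package derives, per vessel:

* segment vectors $\vec{V}_{i,i+1} = P_{i+1} - P_i$ and their norms
  (vertical petrous, horizontal petrous, vertical cavernous, horizontal
  cavernous and intracranial segment lengths, in mm);
* turning angles
  $\angle_{i,i+1,i+2} = \cos^{-1}\!\big(\vec{V}_{i,i+1}\cdot\vec{V}_{i+1,i+2} /
  (|\vec{V}_{i,i+1}||\vec{V}_{i+1,i+2}|)\big)$ in degrees — the deflection
  from straight continuation (0° = straight, 180° = reversal);
* the actual length $\mathrm{ALEN} = \sum_i |\vec{V}_{i,i+1}|$ and the
  linear (chord) length $\mathrm{LLEN} = |P_6 - P_1|$;
* the arc–chord tortuosity
  $(\mathrm{ALEN} - \mathrm{LLEN})/\mathrm{LLEN} \times 100$ (percent);
* the total angle (sum of the four turning angles), a summary of the
  total change in flow direction.

Numerical choices: the cosine is clamped to $[-1, 1]$ before the arccos
(dot products of near-parallel unit vectors can exceed 1 by ~1e-16);
consecutive landmarks closer than $10^{-6}$ mm are rejected as
digitization duplicates, which also protects the angle and tortuosity
denominators. The arccos is ill-conditioned near 0° and 180°: for
exactly collinear chains the computed total angle is zero only to about
$10^{-4}$ degrees, which is far below any anatomical signal. All
arithmetic is double precision; the report stage rounds to two decimals
for display but rounded values are never fed back into computation.

## Cohort rules

Subjects are grouped by diagnosis and genotype: MMD carriers of the
variant (GA or AA — zygosity is ignored) form the *mutant* group,
non-carriers (GG) the *wild-type* group, and radiologically normal
subjects the *control* group. A subject's two ICAs are summarised by
averaging each derived parameter across sides — the derived values are
averaged, never recomputed from averaged coordinates — and the more
advanced Suzuki grade of the two sides is the subject's representative
grade.

Exclusions: subjects with unilateral disease or prior
revascularization surgery are removed in every analysis (flow through
the ICA is altered); the *main* analysis additionally restricts MMD
subjects to representative grades 2–4, while the *supplementary*
analysis keeps grades 1 and 5. Controls are never grade-filtered; a
grade recorded for a control is ignored with a warning. When several
exclusion rules apply, the logged reason follows a fixed precedence
(unilateral > surgery > grade) so logs are deterministic, and each
excluded subject carries exactly one primary reason.

The analysis unit is the *subject* by default, because the group sizes
of the motivating study design are subject counts. Treating the two
ICAs as independent vessels is a defensible alternative for purely
geometric questions, so `unit = "vessel"` is supported; it doubles the
nominal sample size and ignores within-subject correlation, so its
p-values should be read descriptively.

## Statistical battery

All continuous variables are summarised as median (IQR) and compared
nonparametrically throughout:

* **Kruskal–Wallis** across the three groups (tie-corrected $H$,
  chi-square reference on $k-1$ df). The chi-square reference is an
  approximation; it is accurate at the cohort sizes this package
  targets but visibly off for total $n \lesssim 10$, where the exact
  permutation distribution of $H$ is lumpy. The test suite therefore
  verifies $H$ itself against an independent formula oracle and checks
  the reference only through its realised type-I error at realistic
  sample sizes.
* **Pairwise Wilcoxon rank-sum tests** with Bonferroni correction
  ($m = 3$, multiply and cap at 1), run only when the overall
  Kruskal–Wallis p falls below $\alpha$ (a flag forces them for
  diagnostics). Ties receive midranks. For combined samples of at most
  25 the two-sided p-value is exact, computed from the permutation
  distribution of the rank sum by subset-sum dynamic programming over
  doubled midranks — this is exact *under ties as well*, where the
  classical no-tie tables do not apply. Larger samples use the normal
  approximation with tie-corrected variance and continuity correction.
* **Fisher's exact test** for categorical variables (sex across the
  three groups; Suzuki grade between the two MMD groups, since controls
  carry no grade), by the Freeman–Halton rule. Tables with more than
  200 observations fall back to seeded Monte-Carlo estimation with a
  reported standard error.
* **Normality screen**: a one-sample Kolmogorov–Smirnov distance
  against a normal with sample-estimated mean and SD, calibrated by
  Monte-Carlo simulation (the Lilliefors procedure; the analytic KS
  null distribution is wrong when parameters are estimated). The screen
  is advisory only — the pipeline is nonparametric regardless — which
  is why a Monte-Carlo p with $10^4$ replicates is entirely adequate.
* Quantiles use linear interpolation between order statistics
  (`quantile` type 7). IQR bounds depend on this convention, so it is
  fixed and documented rather than configurable.
* p-values print with three decimals, `<0.001` below 0.0005.

The Suzuki-grade trend analysis summarises tortuosity and total angle
per representative grade and tests adjacent grade pairs by Wilcoxon
rank-sum, starring 0.05 and 0.01; pairs in which either grade has
fewer than two subjects are skipped with a warning.

## The synthetic cohort generator

No patient coordinates are publicly available for this kind of study,
so the package ships a generator whose *defaults are the study
conditions*: analysis groups of 44 mutant, 14 wild-type and 58 control
subjects; female counts 27/44, 8/14 and 35/58; Suzuki grades 2/3/4 at
12/19/13 (mutant) and 9/3/2 (wild-type); and per-group median/IQR
targets for each segment length and turning angle taken from the
published group summaries. Categorical composition (sex, grades,
group sizes) is deterministic — exactly those counts, randomly
assigned — so the categorical tests on a default cohort reproduce the
published table's Fisher p-values exactly. With `full_flow = TRUE` the
generator also emits the screened-out stream (8 grade-1/5 mutants and
27 unilateral/prior-surgery subjects), so the exclusion stage
reproduces the published 93 → 66 → 58 patient flow; controls copy age
and sex from the main-analysis MMD subjects, mirroring the exact
matching of the study design.

Distributional choices (the published summaries constrain only
median and IQR):

* **Segment lengths** are log-normal: positive support and mild right
  skew, consistent with the asymmetry of the published IQRs. The two
  parameters are solved so the median is matched exactly and the
  quartile *ratio* $q_3/q_1$ is matched exactly; a two-parameter family
  cannot also match both absolute quartiles when the target IQR is
  log-asymmetric, and the residual discrepancy is well under the
  sampling noise at these group sizes.
* **Turning angles** are normal truncated to (0, 180), with mean and SD
  solved numerically (Nelder–Mead on the truncated quantile equations)
  so the truncated median and IQR width match the targets.
* **Left/right dependence** is a Gaussian copula: each side's latent
  normal is $\sqrt{\rho}\,z_{\text{subject}} + \sqrt{1-\rho}\,
  \varepsilon_{\text{side}}$ with $\rho = 0.5$ by default (the true
  within-subject correlation is unknown; 0.5 encodes "substantial but
  imperfect" bilateral symmetry). Marginals are exact on each side.
* **Ages** are log-normal matched to the group median/IQR the same way
  as lengths.

Vessels are built from these internal coordinates exactly as a
molecular chain is built from bond lengths, planar angles and
torsions: P2 lies along the initial direction; each later direction is
the previous one deflected by the joint's turning angle about an axis
set by the joint's dihedral in the local frame. Measuring a built chain
recovers the sampled lengths and angles to ~1e-9 relative, which is the
generator's core correctness guarantee. The dihedral (torsion) profile
defaults to (+90°, −90°, 180°) with 10° spread — an out-of-plane course
through the petro-cavernous transitions and a back-bend at the siphon
apex, giving the S-shaped siphon its character — and is *shared across
groups*. Turning angles and lengths are controlled directly, but the
chord length LLEN, and hence tortuosity, does depend on the torsion
profile; with a common profile the group contrast in tortuosity is
driven entirely by the calibrated angle and length differences. In the
default calibration the synthetic tortuosity medians run some 6–12
percentage points above the published ones (the landmark chains of real
vessels evidently twist less uniformly than the fixed profile assumes),
while preserving the ordering mutant < wild < control and the
between-group separation; analyses that need the published tortuosity
*levels*, not just contrasts, should treat the generator as a stress
rig, not a digital twin.

What passing tests on synthetic cohorts do **not** show: anything about
landmark placement error (the dominant real-world noise source, for
which no published uncertainty model exists), about real vessels'
deviation from a six-segment polyline, or about the true bilateral
correlation structure. Calibration is to summary statistics only; no
synthetic vessel can be validated against a real one.

## Pipeline and file formats

The canonical internal frame is RAS millimetres. Slicer Markups
fiducial files are read in both the `.fcsv` v4 dialect (header
`# CoordinateSystem = 0/1`, also accepting the `RAS`/`LPS` spellings of
newer versions) and the `.mrk.json` dialect; LPS coordinates are
converted at the I/O boundary by negating x and y. Points are matched
to P1..P6 by label when all six labels are present, otherwise by row
order with a warning — both labelled and order-encoded files occur in
practice. Write-then-read round trips are lossless (coordinates are
written at full double precision).

The pipeline stages are `simulate → measure → analyze → report`. The
report stage only reformats analyze-stage numbers (two decimals for
measurements, three for p-values); it never recomputes anything, so
the aligned-text report always agrees with the CSVs. A structured log
records package and R versions, the seed, a config fingerprint and the
exclusion log. Reruns with the same configuration and seed are
byte-identical.

## Problem sizes and runtime

The test-suite simulations are sized for a laptop-class single core:
1,000 random fiducial sets for the geometry oracle, 1,000 generator
round trips, 1,000 null cohorts for the type-I-error checks (three
groups of 30 for the rank tests, a 2×3 table with 66 per group for
Fisher — large enough that discreteness does not make the exact test
overly conservative), and 100 seeded default cohorts for the
power/ordering property of the calibrated tortuosity contrast. The
whole suite runs in a few minutes.

## Known limitations

* The six-landmark polyline underestimates true centerline length, so
  absolute tortuosity is biased low relative to centerline methods;
  comparisons across groups measured the same way remain valid.
* No landmark-uncertainty model is implemented: the propagation of
  sub-voxel placement error into angles and tortuosity is not
  quantified anywhere in the source material, and guessing a model
  would lend false precision.
* The Kruskal–Wallis chi-square reference should not be trusted for
  total $n \lesssim 10$ (see above).
* `unit = "vessel"` ignores within-subject correlation; its p-values
  are anticonservative to an unknown degree.
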