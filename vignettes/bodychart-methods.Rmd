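---
title: "Measuring pain surface on a digital body chart: models and methods"
author: "bodychart package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring pain surface on a digital body chart}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bodychart)
```

# The measurement problem

A digital body chart asks a patient to paint where it hurts, with a color
per intensity and separate layers for pain typology, on an avatar that
matches their body. Three quantities summarise a chart: the per-intensity
surfaces in cm², the weighted *pain surface index*, and the typology
decomposition (neuropathic / mechanical / mixed). The psychometric
question the package serves is discriminant validity: does pain surface
measure something different from the familiar 0–10 intensity rating
(NPRS)? If intensity and surface correlated strongly, a body chart would
add little; a weak correlation and near-zero shared variance argue that
the two are complementary.

# The avatar and the pixel scale

The drawable area is anchored to the Du Bois body surface area,
$BSA = 0.007184\,H^{0.725}W^{0.425}$ (m²; $H$ in cm, $W$ in kg), the
de-facto clinical standard. The package splits the BSA equally between a
front and a back view. A procedural silhouette polygon (head, trunk,
arms, legs; a single simple polygon shipped in code) is scaled
anisotropically — vertically to the patient's height, horizontally so the
rasterised view hits $BSA/2$ — and filled by an even-odd scanline
rasteriser that classifies a pixel by its centre. Signed boundary errors
largely cancel; across the admissible anthropometry grid
($H \in [100, 220]$ cm, $W \in [30, 200]$ kg) the realised drawable area
stays within 1 % of the target (typically < 0.3 %), which the validity
method of the `Avatar` class enforces at construction time.

Two remarks on this choice. First, equating the *drawable* area with the
full BSA is a convention, not anatomy: the frontal projection of a human
is nearer 35 % of BSA, so the avatar is deliberately wide. Any fixed
convention works, because all downstream quantities are areas measured on
this canvas; the constant is isolated so a Mosteller-based or
projection-corrected variant is a one-line change. Second, the default
resolution of 2 mm/pixel (0.04 cm²/pixel) keeps quantisation error below
1 % for regions of 10 cm² and above; the resolution is a user parameter
in [1, 10] mm and measured surfaces are stable under refinement within
2 %.

Coordinates are row-major, 0-based, origin top-left; pixels are half-open
boxes, so abutting polygons tile without double counting and an
axis-aligned $a \times b$ rectangle rasterises to exactly $ab$ pixels.

# Layers, precedence, and the indices

Intensity layers may overlap as drawn; they are resolved
*most-severe-wins*, a conservative clinical reading (the union is
preserved and the operation is idempotent). The mechanical and
neuropathic families are *not* resolved against each other: their overlap
is reported as mixed pain, and each family's surface excludes the mixed
region, so neuropathic + mechanical + mixed equals the area of the
typology union. Family surfaces are also crossed with the resolved
intensity layers. Note that with this exclusive convention the two family
percentages need not sum to 100 %.

The pain surface index weights each intensity surface by 1/2/3/4
(low/moderate/severe/very severe):
$PSI = \sum_k w_k S_k$, with $PSI \in [T, 4T]$ for total surface $T$. It
is homogeneous of degree 1 in the surfaces and monotone when area moves
toward a severer level. The predominant intensity is the level with the
largest surface; a painless chart has none, and ties break toward the
severer level, consistent with the layer-precedence rule. The color count
is the number of levels with positive surface.

# The validity battery

* **Pearson correlation with Fisher-z CI** —
  $\tanh(\operatorname{atanh} r \pm z_{\alpha/2}/\sqrt{n-3})$, p from the
  t distribution with $n-2$ df. `fisherCI()` reconstructs the interval
  from a printed $r$ and $n$ alone.
* **Average variance extracted** — $\mathrm{AVE} =
  \operatorname{cov}(x,y) / \tfrac{1}{2}(\sigma^2_x + \sigma^2_y)$ with
  $n-1$ denominators. Below 0.5, most variance of the two indicators is
  not shared. Because the index's variance is orders of magnitude larger
  than the NPRS's, AVE is tiny even at moderate correlation — it is a
  scale-sensitive complement to $r$, not a substitute.
* **Likelihood-ratio test of $\rho = \rho_0$** — profiling the means and
  variances of a bivariate normal out of the likelihood gives the closed
  form $\chi^2 = n\log\frac{(1-\rho_0 r)^2}{(1-r^2)(1-\rho_0^2)}$, df 1.
  The boundary $\rho_0 = \pm 1$ makes the constrained covariance singular
  and is capped at $\pm(1-10^{-6})$; the sample $r$ is capped at the same
  $\varepsilon$ so exactly collinear data remain consistent with the
  capped null. A latent-variable (SEM) formulation would treat the
  boundary natively; the capped bivariate LRT reproduces the same
  accept/reject behaviour without a factor-model engine and is the
  documented approximation here.
* **Cubic orthogonal-polynomial regression** — response
  $\log(\text{surface}+1)$ (natural log), predictors the orthonormal
  degree-1..3 polynomials of NPRS (`stats::poly`). With this basis the
  intercept equals the mean log response — which is how a printed
  intercept of the same magnitude as the mean log surface should be read;
  a raw-power basis would instead report the prediction at NPRS 0.
* **LOESS** — tricube-weighted local *linear* fits (`stats::loess`,
  degree 1, direct surface). The implementation is library-backed by
  design; the test suite pins it to an independent weighted-least-squares
  oracle with neighbourhood size $\lfloor n \cdot \mathrm{span} \rfloor$.
* **Jonckheere–Terpstra trend test** — $JT = \sum_{i<j} U_{ij}$ over
  ordered group pairs, ties counted ½, with the tie-corrected normal
  approximation (Hollander & Wolfe) for the one-sided p. A permutation
  oracle (full enumeration of label arrangements up to 10 observations,
  seeded Monte-Carlo beyond) is part of the public API and agrees with
  the normal approximation within 0.02 at 8 observations per group.
* **Variance explained** — simple-regression $R^2$ (equal to $r^2$) with
  a percentile case-resampling bootstrap interval.

No multiple-testing correction is applied across the battery, matching
the descriptive use of these statistics.

# The synthetic cohort generator

The generator exists so that every pipeline stage — scoring, statistics,
report — is testable end to end without clinical data. It is calibrated
once, from published full-cohort summary tables, and its defaults *are*
the study conditions:

| quantity | default | source of the value |
| --- | --- | --- |
| strata (painless, low..very severe) | 0.5 / 4.9 / 24.2 / 32.5 / 38.0 % | predominant-intensity group sizes |
| stratum NPRS mean (SD) | 5.1 (2.7), 5.4 (1.9), 6.4 (1.8), 7.2 (1.8) | group summaries |
| color count 0..4 | 0.5 / 33 / 34.2 / 24.3 / 8 % | color-usage distribution |
| total surface | lognormal, mean 668.2, SD 837.6 cm² | cohort surface moments |
| intensity shares | 6.7 / 23.7 / 32.6 / 37.1 % | per-level percentage means |
| typology shares | 56.2 / 28.0 / 15.8 % | family percentage means |
| copula coupling | 0.1088 | calibrated to r(NPRS, index) = 0.14 |

Per patient the generator draws the stratum; an NPRS from the stratum's
normal truncated to [0, 10] and rounded; a color count (the predominant
level is always painted); a total surface from the lognormal, linked to
the NPRS latent by a Gaussian copula of strength `coupling` (the model's
single free dependence parameter); Dirichlet intensity shares over the
painted levels with the largest share forced onto the predominant level;
and Dirichlet typology shares. Everything is driven by one seed.

Choices worth making explicit:

* **Lognormal total surface.** Mean 668 < SD 838 rules out symmetric
  models; the lognormal's parameters follow from the printed moments in
  closed form ($\sigma^2 = \log(1 + s^2/m^2)$, $\mu = \log m -
  \sigma^2/2$).
* **Stratified NPRS + copula, not one bivariate model.** A single
  bivariate model cannot simultaneously reproduce the stratum means, the
  weak global correlation and the monotone trend; the stratified model
  does all three.
* **Dirichlet concentrations** — 2.0 for intensity shares (matches the
  large printed SDs of the percentage columns, ≈ 30–37 points) and 0.4
  for typology (an SD of ≈ 42 points implies heavy mass near pure
  neuropathic or pure mechanical charts, which is clinically plausible).
* **Painless stratum NPRS** — mean 2 (SD 2), truncated and rounded: the
  painless patients drew nothing during assessment yet report on the
  previous 24 h, so a low-but-positive score is realistic. At 0.5 % of
  the cohort this choice is immaterial to the overall moments.
* **Calibration of `coupling`** — stochastic bisection with common
  random numbers against the simulated r(NPRS, index) at n = 20 000
  (`calibrateCoupling()`); the stored default 0.1088 reproduces
  r ≈ 0.14 on fresh seeds. The calibration trace is returned with the
  config.
* **Truncation bias, left in.** Truncating a normal with mean 7.2 and SD
  1.8 to [0, 10] lowers its mean by ≈ 0.23 (less for the other strata),
  so realised stratum means sit slightly below their nominal values
  (e.g. ≈ 6.96 for the very-severe stratum, overall mean ≈ 6.25 vs the
  nominal 6.4). The printed group means are used as parent-normal
  parameters, as stated; re-centering to cancel the truncation would
  make the parameters no longer the published ones.
* **One anchor had to give.** The mean of $\log(\text{index}+1)$ implied
  by the moment-matched lognormal and the weighted intensity shares is
  ≈ 7.0, slightly above the 6.9 a cubic-fit intercept would suggest;
  exactly matching both the surface *moments* and the *log-mean* is
  impossible for a lognormal (real cohort surfaces are lighter-tailed
  than lognormal in the same direction). The generator anchors on the
  moments, the primary calibration target, and accepts the ≈ +0.1 shift
  in the log-scale intercept.

`generateDrawing()` closes the loop geometrically: it grows randomised
connected pixel blobs (frontier accretion) on an avatar so that the
measured per-intensity and typology surfaces reproduce a generated
record within pixel quantisation, enabling drawing → measurement →
scoring → statistics tests of the whole chain.

## What the generator does and does not emulate

It reproduces the marginal and stratum structure of a cohort's summary
tables: group proportions, stratum NPRS moments, color counts, surface
moments and shares, typology shares, and one global dependence (the
NPRS–index correlation). It does **not** emulate spatial anatomy
(drawings are random blobs, not dermatomes or radicular patterns),
diagnosis-specific subpopulations, within-patient correlation between
intensity and typology placement, or longitudinal change. Tests passing
on synthetic cohorts therefore validate the *measurement and statistical
machinery*, not claims about real patients' spatial pain patterns.

# Numerical notes and degenerate inputs

Zero-variance inputs to the correlation machinery raise errors naming
the degenerate variable. A painless chart yields zero surfaces, index 0,
color count 0 and no predominant level, and is excluded from
predominant-group comparisons. Percentages of a zero total are 0 by
convention. The scanline rasteriser treats pixels as half-open sets; the
polyline brush marks pixels whose centre lies within the radius, so a
disc of radius $r \ge 10$ px recovers $\pi r^2$ within 5 %. Problem
sizes in the test suite (cohorts of 637, moment checks at $10^5$,
100-replicate stability studies, 4 × 8 permutation comparisons at 4 000
draws) were chosen to keep Monte-Carlo error well inside each stated
tolerance while remaining quick to run.

# Known limitations

* The BSA-to-canvas convention is a documented stand-in for the
  instrument's proprietary pixel-to-cm² conversion; absolute surfaces
  depend on it, correlations and shares essentially do not.
* One silhouette template is used for all patients (anisotropic scaling
  only); no sex- or morphology-specific templates.
* The capped-boundary LRT approximates a latent-variable treatment of
  $\rho_0 = 1$.
* Nociplastic pain, a third typology family, is not modelled.
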