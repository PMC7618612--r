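---
title: "Methods: automated pincer morphology measurement and incident hip OA risk modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated pincer morphology measurement and incident hip OA risk modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(pincer)
```

`pincer` implements a complete landmark-to-inference pipeline for studying
acetabular overcoverage (pincer morphology) and incident radiographic hip
osteoarthritis (RHOA) in pooled multi-cohort data. This vignette documents
the science, the numerical choices and the design decisions, in the order
the pipeline runs.

## 1. Angle measurement from landmarks

The input is a 2-D point set annotating the bony outline of the pelvis and
both proximal femora on an AP pelvic radiograph, with a *schema* naming the
anatomical role of each point (head contour, lateral acetabular rim, sourcil
end, cranial obturator point, caudal ischial point, caudal teardrop point,
per side). Coordinates follow the image convention (origin top-left, y
down); all geometry converts internally to the mathematical y-up frame.

**Pelvic-tilt reference.** Radiographs are rotated by unknown pelvic tilt.
The horizontal reference line is the average of four bilateral lines: the
two femoral head centres (from per-side circle fits), the most cranial
obturator points, the most caudal ischial points and the most caudal
teardrop points. Each component angle is normalised to (−90°, 90°] and the
reference is their arithmetic mean; because the QC step flags component
spreads above 10° (configurable), the circular-mean subtleties of widely
dispersed angles never arise in practice. Single-hip (AP hip) radiographs
cannot provide these bilateral landmarks, which is why the inclusion
cascade removes them.

**Femoral head circle.** The head centre comes from a best-fit circle
through the head contour points: the Kåsa algebraic fit (linear least
squares in $(2c_x, 2c_y, r^2 - \lVert c\rVert^2)$) followed by Gauss–Newton
refinement of the geometric loss $\sum_i (\lVert p_i - c \rVert - r)^2$,
converging when the parameter step falls below $10^{-10}$ or after 100
iterations. Three points yield the circumcircle exactly; collinear contours
(normalised cloud thickness below $10^{-8}$, configurable) are rejected and
QC-flagged. The geometric refinement never increases the geometric loss
relative to the algebraic start; the test suite verifies agreement with an
independent grid + Nelder–Mead minimiser of the same loss to $10^{-6}$.

**LCEA and Wiberg CEA.** The LCEA is the signed angle at the head centre
between the cranial vertical (perpendicular to the tilt-corrected
horizontal) and the ray to the lateral acetabular rim landmark; positive
means the rim lies lateral to the vertical (more coverage). Laterality is
+x for the hip imaged on the right of the film (the patient's left); right
hips are mirrored before measurement, which makes the measurement exactly
side-symmetric. The Wiberg variant targets the sourcil landmark and is used
for the dysplasia criterion; schemas without a sourcil point fall back to
the rim landmark and flag the fallback. Both angles are invariant under
rigid rotation, translation and uniform scaling of the point set — the
tilt correction must cancel any rigid rotation to within $10^{-6}$ degrees,
and the tests enforce exactly that. By convention angles are reported to
two decimals; classification applied to reported angles therefore treats
the printed precision as authoritative at threshold boundaries.

An alternative `rim_mode = "extremal"` selects the most lateral acetabular
candidate point in the tilt-corrected frame instead of the fixed schema
landmark; the fixed landmark is the default because it is deterministic
under noise.

## 2. Classification and grade harmonisation

Moderate pincer morphology is LCEA ≥ 40°, severe pincer morphology
LCEA ≥ 45°, acetabular dysplasia Wiberg CEA ≤ 25° — all boundaries
inclusive, matching the printed definitions; thresholds are arguments, not
constants. Hips with 40° ≤ LCEA < 45° are tagged `pincer_borderline`
because the severe-pincer analysis excludes them from its reference group
(so severe hips are compared with hips free of pincer morphology by any
definition).

Cohorts grade RHOA on different scales. Harmonisation maps any original
score 0 to grade 0 (free of RHOA), any score 1 to grade 1 (doubtful), and
Kellgren–Lawrence ≥ 2, modified Croft ≥ 2, modified OA score = 2 or a total
hip replacement to grade 2 (definite RHOA). The mapping is total on its
declared domain and errors on unknown systems or out-of-range scores.

## 3. Inclusion cascade

`apply_filters()` applies the study's exclusions in a fixed order:
follow-up radiograph within 4–8 years (inclusive), known age/sex/BMI,
original baseline OA score present, radiograph usable (QC pass, not an AP
hip film), follow-up score present, no dysplasia (Wiberg CEA strictly
above 25°), and completely free of RHOA at baseline (grade 0). The filters
are conjunctive predicates, so the final analysis set is order-invariant;
only the per-step counts depend on the order, and the flow report conserves
every record (`n_before − n_removed = n_after`, chained). A record failing
several criteria is counted once, at the first failing filter.

## 4. Stratified risk estimates

Subgroup analyses use 2×2 tables (exposure = pincer morphology, outcome =
incident definite RHOA) per stratum of age band, BMI band or sex. The
absolute risk has two denominator conventions, both used in the published
tables: `stratum_total` (pincer-and-RHOA hips over all hips in the
stratum) and `exposed_only` (events over exposed hips). Its interval is
the normal approximation $AR \pm z_{0.975}\sqrt{AR(1-AR)/n}$, truncated to
[0, 1]. The risk ratio is the ratio of the two unconditional maximum
likelihood estimates $a/(a{+}b)$ and $c/(c{+}d)$, with the log-scale Wald
interval
$\exp(\ln RR \pm z\sqrt{1/a - 1/(a{+}b) + 1/c - 1/(c{+}d)})$ — this is the
construction that reproduces the published stratified intervals from the
printed counts. P-values use a two-sided mid-p exact test on the
hypergeometric conditional distribution (chi-squared optional); the source
does not name its p-value method, so p-values are reported but not treated
as reproduction targets. Degenerate tables are handled explicitly: no
unexposed events gives an infinite, flagged RR; no exposed events gives
RR 0 with a 0.5 continuity-corrected interval; zero cells in the odds ratio
trigger the Haldane–Anscombe correction, flagged.

Two printed CI digits in the published subgroup table cannot be reproduced
from its own counts (its abstract and table disagree on one of them, and
one point estimate appears truncated rather than rounded); the package
reports the recomputed values.

## 5. The multilevel logistic model

The primary model is a one-stage logistic regression for incident definite
RHOA on hip-level observations:

$$\mathrm{logit}\, P(y_{hic}=1) = \beta_0 + \beta_p\,\mathrm{pincer}_{hic}
 + f(\mathrm{age}_{ic}) + \beta_s\,\mathrm{male}_{ic} + \beta_b\,\mathrm{BMI}_{ic}
 + \beta_c\,\mathrm{closed}_c + u_c + v_{ic},$$

with $u_c \sim N(0, \sigma_c^2)$ a cohort random intercept,
$v_{ic} \sim N(0, \sigma_i^2)$ an individual random intercept shared by the
two hips of one person, and $f$ a natural cubic spline with 3 df (interior
knots at the terciles of the pooled age distribution, boundary knots at the
observed range). The three-level correlation structure (hip within
individual within cohort) is represented by these two random intercepts:
a third, per-hip random effect would be unidentifiable in a binary model,
so hip side enters only through the shared individual intercept — the
standard treatment of paired hips. Open versus closed population enrolment
is a fixed binary covariate, the simplest reading of "the model accounted
for the difference" between the two cohort types.

**Likelihood.** The marginal likelihood integrates the random effects by
*nested adaptive Gauss–Hermite quadrature* (C++): for each cohort node
(centred on the profile mode of the cohort offset, scaled by the profile
curvature), each individual's integral is centred on its own conditional
mode found by a per-individual Newton search. One node per level is exactly
the Laplace approximation. A zero standard deviation removes that level's
integral exactly, so fixing both variances at zero reduces the model to
plain logistic regression (tested against `glm.fit`'s IRLS to $10^{-4}$),
and an evaluation with 25 nodes per level agrees with brute-force adaptive
numerical integration to $10^{-6}$ on toy data.

**Optimisation.** Quasi-Newton (`nlminb`) over
$(\beta, \sigma_c, \sigma_i)$ with box constraints $\sigma \ge 0$,
continuous covariates standardised internally (estimates are mapped back
exactly), starting values from the plain logistic fit and $\sigma = 0.3$.
The analytic score treats the adapted node positions as fixed — exact for
the fixed-node objective, and accurate to the quadrature error for the
adaptive one — so with ≥ 3 nodes per level it drives the search; pure
Laplace fits use numerically differenced scores because the ignored
log-determinant derivative is material there. A short polish phase with
numerically differenced scores (default on) removes the last few
hundredths of stall that the fixed-node approximation can leave on large
data. Standard errors come from the observed information (central
differences of the score), and convergence is declared when the optimizer
reports success or the Newton decrement — the parameter shift the residual
score implies — falls below 0.02 on the standardised scale. The
evaluation trace is kept so the non-decreasing-likelihood property can be
monitored.

The default of 9 quadrature nodes per level makes the score effectively
exact at the variance magnitudes seen here ($\sigma_i \approx 1$); 5 nodes
reproduce coefficients to about 0.01 at half the cost and are used in the
bulk simulation studies. `lme4::glmer` (Laplace) serves as an independent
cross-check in the tests; note that on rare-event paired binary data
glmer's Laplace surface can diverge in $\sigma_i$, a known pathology that
the quadrature likelihood does not share.

## 6. The continuation-ratio model

The ordinal outcome (0 free, 1 doubtful, 2 definite) is factorised forward:
$P(Y\ge 1)$ and $P(Y=2 \mid Y\ge 1)$. Both steps are fitted *jointly* as
one expanded binary mixed model: every hip contributes a step-1 row, hips
with $Y\ge 1$ also a step-2 row, with a step indicator, shared covariate
effects, shared random intercepts, and — under relaxed ordinality — a
step-specific pincer coefficient. Marginal level probabilities are
evaluated at a reference profile (female, mean baseline age and BMI, open
population, random effects at zero — the conditioning we adopt for the
ambiguous "with reference to the random effects" phrasing), with
delta-method intervals; they sum to one by construction. If any outcome
level is absent the model warns and collapses to the binary fit.

## 7. The synthetic-data generators

The generators define the study conditions under which the pipeline is
validated.

**Pelves.** `generate_landmarks()` builds bilateral head contours on exact
circles (default radius 60 px, separation 300 px), rim/sourcil landmarks at
configured true angles (default Wiberg offset −3°), symmetric reference
landmarks, a rigid rotation (pelvic tilt), and isotropic Gaussian landmark
noise. Ground truth is attached, so measured angles can be compared with
truth exactly (noise-free: equality to $10^{-6}$ degrees at any rotation in
±10°) or in Monte-Carlo (0.5 px noise on a 60 px head: mean error below
0.2°, SD below 1°).

**Cohorts.** `generate_cohorts()` draws a consortium-style population:
10 cohorts × 1050 individuals, 90% contributing both hips (≈ 20,000 hips,
the scale of the real study); LCEA ~ Normal(36.45°, 5.47°), the unique
Normal matching the two published prevalences (25.8% ≥ 40°, 5.9% ≥ 45°),
with half the LCEA variance at the individual level; Wiberg CEA = LCEA
− 3° ± 1.5°; age ~ Normal(62.7, 8.4) truncated to [40, 90]; 70% female;
BMI ~ Normal(27.3, 4.5) — all matching the published baseline table.
Outcomes are generated either from the same continuation-ratio structure
the package fits (default; step intercepts −1.43 and −3.37, calibrated by
Monte-Carlo so that ≈ 19% of hips reach doubtful-or-worse and ≈ 1.9%
definite RHOA, the published rates) or from a plain binary logistic model
(intercept −4.19, same 1.9% target), which makes the binary definite-RHOA
model exactly well-specified — the mode used for parameter recovery.
Random-intercept SDs default to 0.5 (cohort) and 1.0 (individual);
covariate effects default to 0.03/year (age), −0.3 (male), 0.02/unit
(BMI), −0.8 (closed cohorts); pincer effects default to the published
adjusted odds ratios (1.15 moderate, 1.50 severe) in binary mode and to
(0.3, 0.8) per step in continuation-ratio mode. Grading systems cycle
across cohorts so harmonisation is exercised; artifact rates (1% QC
failures, 2% AP hip films, 1% missing BMI, 2% missing follow-up scores,
10% baseline doubtful/definite) feed the inclusion cascade. All randomness
flows from one seed; a seed reproduces the table byte-identically.

What the generator deliberately does **not** emulate: skewness of real
LCEA distributions (a documented simplification — the Normal is matched
only at the two published quantiles), sex-specific coverage differences
(published prevalences are near-identical by sex, so the shift defaults to
zero), cohort-specific radiographic protocols, informative missingness,
and any real-image pixel content. Passing tests therefore demonstrate
correctness of the algorithms under known structure, not robustness to
every feature of real radiographs.

## 8. Problem sizes and runtime choices

The test suite runs small configurations (3–4 cohorts × 60–300
individuals) for unit checks, the full default scale (≈ 20,000 hips) for
the continuation-ratio recovery, and 50 replicates of the default scale at
5 quadrature nodes (polish off) for the coverage study of the binary
model — sizes chosen so the whole suite completes in a few minutes while
the Monte-Carlo tolerances stated above remain meaningful. The acceptance
script mirrors these choices.

## 9. Known limitations

* The real study's per-step exclusion counts cannot be reproduced (raw
  data are not public); the pipeline reproduces the printed aggregate
  arithmetic and validates the machinery on synthetic cohorts instead, so
  the published adjusted odds ratios are covered only by parameter
  recovery, not numerically.
* With one binary observation per cluster (no paired hips) the individual
  variance is unidentified; the fit is still valid but $\hat\sigma_i$ is
  arbitrary along a likelihood ridge. The tests assert the identifiable
  content (likelihood flatness, stable exposure effect).
* The mid-p exact p-value is one reasonable choice among several; the
  published subgroup p-values were not used as reproduction targets.
* Angles are exact only as geometry; osteophytes or annotation error in
  real data enter through the landmarks, which the package consumes as
  given.
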