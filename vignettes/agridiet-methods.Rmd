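---
title: "Methods: diversity scoring, instrumental variables, and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity scoring, instrumental variables, and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agridiet)
```

`agridiet` implements a farm-to-plate analysis chain for smallholder
household surveys: diversity scores for women's diets and for farm
production, Shannon-based market-access indicators, and LIML
instrumental-variable estimation of the production-diet relationship,
validated end to end on a synthetic cohort with known ground truth. This
vignette records the models, the parameter choices that matter, and the
design decisions that were genuinely open.

## Dietary diversity

Each woman contributes four 24-hour recalls, one per season. A recall is
scored on the ten MDD-W food groups (grains/roots/tubers; pulses;
nuts/seeds; dairy; meat/poultry/fish; eggs; dark green leafy vegetables;
other vitamin-A-rich fruits and vegetables; other vegetables; other
fruits). The seasonal WDDS-10 is the plain count of groups consumed; no
minimum-quantity threshold is applied, so any nonzero consumption counts.
Olive oil is excluded from the score — it provides energy but no
essential micronutrients — and is instead tracked through the annual
consumption score, defined for every group (and olive oil) as the number
of consuming recalls divided by four, hence one of
$\{0, 0.25, 0.5, 0.75, 1\}$.

The annual WDDS-10 is the arithmetic mean of the four seasonal scores.
Women without exactly one recall in each season are rejected rather than
imputed, mirroring survey practice of excluding under-interviewed
participants; partial-data imputation would silently change the estimand.
The MDD-W flag (five or more groups) is computed on the annual score,
which is where it sits in this package's descriptive tables; a per-season
flag is exposed via `mddw_flag(per_season = TRUE)` but is not headline.

Two inferential helpers accompany the scores. Seasonal variation in group
consumption is tested with a generalized Cochran–Mantel–Haenszel test
stratified by woman (`stats::mantelhaen.test`); women who consume a group
in all four seasons or in none carry no information about seasonal
*variation* and are dropped, with the dropped count reported. Pairwise
seasonal WDDS-10 comparisons use the paired Wilcoxon signed-rank test —
the pairing is genuine (same woman, two seasons), and the test is robust
on a bounded integer score. For the producing-versus-non-producing
comparison of consumption scores the groups are independent samples, so
the package uses the Mann–Whitney rank-sum test; source tables for this
kind of comparison are sometimes labelled "Wilcoxon signed-rank" even for
independent groups, and the column name `p_ranksum` makes the choice
explicit here.

## Production diversity

A farm's inventory is a list of products (29-product reference catalogue)
with annual monetary values and an outlet split (sold / donated /
self-consumed). PDI counts products; GPDI counts MDD-W groups covered
(0–10), ignoring the five unclassified products (garlic, honey, hot
pepper, olive oil, table olive); SDI and GSDI are Simpson indices
$1-\sum s_i^2$ on value shares, at product and group level respectively
(unclassified value is excluded from both the numerator and the
denominator of GSDI's shares). SDI and GSDI are invariant to currency
rescaling; GPDI ≤ PDI always holds, but no order between GSDI and SDI is
implied (aggregation can move the Simpson index either way), and none is
asserted.

The nutritional functional diversity (NFD) score works on an ultrametric
dendrogram over the 29 products. The bundled 29 × 18 nutrient matrix is
**synthetic** — drawn once from food-group archetype profiles and frozen
as `synthetic_nutrients.csv` — because the original laboratory-based
composition table is not publicly available; the pipeline's behaviour
depends only on the matrix having realistic group structure, not on its
absolute values. Columns are divided by the daily reference intakes for
adult women (so nutrients are on comparable adequacy scales; sodium is
treated like every other column — the alternative of sign-flipping
"excess" nutrients is not attempted), then z-scored across products.
Products are clustered on Euclidean distances with average linkage
(UPGMA) by default; the clustering software used for the original
analyses does not record its linkage, and average linkage is the common
default for trait dendrograms. Single, complete and Ward linkage are
available, and all acceptance-level results use the default.

Branch lengths read the dendrogram as an ultrametric tree: leaves at
height zero, internal nodes at half the merge distance, so the path
length between two leaves equals their cophenetic distance. NFD is 100 ×
(branch length of the minimal subtree connecting the farm's products *to
the root*) / (total branch length). The root-inclusive convention is the
package default because it makes monocultures score above zero and makes
NFD monotone under product addition; the leaf-spanning alternative
(`include_root_path = FALSE`), under which a monoculture scores zero, is
implemented and tested but not used by default. Since NFD is a ratio,
the half-height convention cancels and only relative branch lengths
matter.

Farm orientation uses the monetary self-consumption share: above 80%
kept, the farm is subsistence-oriented; above 80% sold, market-oriented;
otherwise mixed.

## Market access

A market's diversity index is the Shannon entropy of its species-sale
proportions (natural logarithm, $0\log 0 = 0$). Each household is
assigned the two markets nearest as the crow flies, under the exclusive-
frequentation hypothesis, and HAMDI is the mean of their MDIs; the number
of markets averaged is configurable but defaults to two. Distances are
haversine great-circle kilometres (mean Earth radius 6371 km); at the
~100 km scale of a governorate this differs from planar Euclidean
distance by well under 0.1%, and a planar mode exists for closed-form
checks. Distance ties at the cut-off rank are broken toward the lower
market id so assignments are reproducible.

## Econometric model

The outcome equation regresses a woman's annual WDDS-10 on one
production-diversity index plus covariate blocks: woman (age, three
education dummies against no schooling, domestic work-time, expenditure
responsibility, non-farm income, off-farm agricultural income, on-farm
participation), household (head age, household size, asset-based wealth
score) and market (HAMDI, nearest-market distance). Production diversity
is treated as endogenous: unobserved household factors plausibly drive
both production choices and diets when markets are incomplete. The
excluded instruments are the three agro-climatic-zone dummies (reference:
the modal temperate zone; four zones are coded as three dummies, a coding
the package fixes explicitly since survey write-ups often leave it
implicit) and farm seniority — production possibilities are constrained
by climate, and land tenure history shapes diversification, while
neither should affect diets except through production once wealth, head
age and market access are controlled.

LIML is the k-class estimator at $k=\kappa$, the smallest root of
$\det(W'M_XW - \kappa\, W'M_ZW)=0$ with $W=[y, A]$, $M_X$ annihilating
the included exogenous block and $M_Z$ annihilating instruments and
exogenous jointly; $\kappa \ge 1$ always, $\kappa = 1$ exactly in the
just-identified case where LIML, 2SLS and the ratio-form IV estimator
coincide (an identity the tests verify to 1e-8 against independently
coded oracles). Standard errors are heteroskedasticity-robust with the
HC1 small-sample factor, the usual reading of "Huber–White sandwich".
The wealth index is the first principal component of the standardized
asset indicators, oriented so more assets score higher, rescaled to
0–100.

Diagnostics: the Cragg–Donald minimum-eigenvalue F (equal to the
first-stage partial F with one endogenous regressor) is reported with the
Stock–Yogo critical value for the user's criterion, defaulting to LIML /
10% maximal size — 5.44 for the package's four excluded instruments. The
embedded Stock–Yogo table is a transcription of the published values for
one endogenous regressor; untabulated cells (including all relative-bias
cells below three instruments, where the criterion is undefined) raise a
typed "not tabulated" condition rather than interpolating.
Underidentification uses the Anderson canonical-correlation LM test
($\chi^2$, df = instruments − endogenous + 1); the clustered
Kleibergen–Paap variant is out of scope because the design has no
clustering. Overidentification reports both the Sargan statistic and the
robust Hansen J (df = instruments − endogenous), with Hansen J as the
headline. Monte Carlo checks at n = 300 with valid instruments put the
J test's 5% rejection rate at its nominal level (the acceptance suite
asserts 3.5–6.5% over 1000 replicates) and confirm Anderson LM p-values
are uniform when instruments are irrelevant.

Because the five indices live on different scales, standardized slopes
$\hat\beta_1 \cdot s_x / s_y$ are reported alongside raw ones.

## The synthetic cohort

`sim_config()` fixes the study conditions; its defaults describe a
semi-arid mixed agro-pastoral cohort of 290 one-woman farm households and
were chosen once, by matching the generator's descriptive margins to the
target values the pipeline is expected to reproduce, then frozen:

* **Farms.** Four climate zones (probabilities 0.2/0.5/0.2/0.1, the
  temperate zone modal); seniority log-normal with median 25 years
  (quartiles ≈ 15–35); products drawn by per-product Poisson thinning —
  product $i$ enters with probability $1-\exp(-\theta_i m)$, where the
  farm intensity $m$ is log-linear in zone, log-seniority and the latent
  confounder (normalized to mean 1), and the hazards $\theta_i$ derive
  from per-group prevalence targets (meat groups on 81.4% of farms,
  olive oil 53.5%, dairy 19.7%, eggs 31.7%, ...). Farms that draw no
  product are redrawn, mirroring the exclusion of households without any
  production; the resulting product count is a zero-truncated
  Poisson-binomial with median 3. The few per-group hazard multipliers
  in `prevalence_calibration` (only meat deviates from 1) absorb the
  Jensen-type gap between the raw thinning probabilities and realized
  prevalences under intensity heterogeneity; they were fitted once on
  calibration seeds and frozen. Production values are log-normal (median
  1,960 USD/yr, 10th–90th percentile ratio ≈ 50) split across products
  by a Dirichlet; the self-consumption share follows a U-shaped
  three-component Beta mixture (about half the farms keep under 20% of
  production value, about a fifth keep over 80%).
* **Households and women.** Household size is $1+\mathrm{Bin}(10, 0.431)$
  (mean 5.31, range 1–11); eight binary asset indicators load on a latent
  wealth factor and feed the PCA wealth score; education is multinomial
  (23/35/31/11%), and activity/income flags match the descriptive
  margins of the target setting.
* **Diet (LINEAR mode, default).** A latent annual score
  $\beta_0 + \beta_1\,\mathrm{PDI} + \text{education} +
  0.30\,w + 0.10\,(\text{size}-5.31) + \lambda_u u + \varepsilon$ with
  $\beta_1 = 0.10$, confounder loading $\lambda_u = 0.35$,
  $\varepsilon \sim N(0, 0.85^2)$, is clamped to $[0,10]$ and rounded to
  quarters; the intercept 5.833 was calibrated once so the cohort mean
  sits at 6.53 with SD ≈ 1.05. The annual score is then decomposed
  *exactly* into four seasonal integers whose mean reproduces it;
  leftover quarter-points are routed spring-first with probability 0.45,
  which produces the intended small spring peak (≈ +0.17 food groups)
  without touching the annual mean. Which groups fill a seasonal count is
  drawn by weighted sampling reflecting local diets (cereals nearly
  always, nuts rarely), with the dairy weight doubled on milk-producing
  farms so the own-production/consumption link is present in the data.
  The alternative `BERNOULLI_GROUPS` mode draws per-group per-season
  indicators from logistic propensities with a woman-level random effect
  whose variance implements the within-woman recall correlation
  (default 0.3 — survey write-ups rarely report this quantity, so it is a
  parameter, not an assertion) and computes WDDS-10 downstream.
* **Markets.** 24 weekly markets and all households are placed uniformly
  in a 110 km square (the extent calibrated so the median nearest-market
  distance is ≈ 11 km); species-sale proportions are symmetric
  Dirichlet(0.244) over 12 species, the concentration calibrated so
  median HAMDI ≈ 1.48.

**Endogeneity by construction.** The confounder $u$ raises both the
production intensity ($0.25$ loading on $\log m$) and the diet score
($0.35$ directly), so OLS of the outcome equation overshoots
$\beta_1 = 0.10$ by roughly half its value, while the zone and seniority
instruments — independent of $u$ — identify it. Instrument strength
(zone effects ±0.6/0.4 on the log intensity, 0.7 per unit log-seniority,
Cragg–Donald F around 40 at n = 290) was set once so that a 200-replicate
study pins the LIML median tightly; recovery experiments use **medians**,
not means, because LIML has no finite moments under weak identification.
At these settings the LIML median over 600 calibration replicates is
0.100 with the OLS median near 0.15.

## Problem sizes and numerical choices

The test suite runs the recovery study at 200 replicates of n = 290, the
J-test size check at 1000 replicates of n = 300, the LM-uniformity check
at 500 replicates, and the cohort calibration at 20 seeds — sizes chosen
so Monte-Carlo error is small relative to the asserted tolerances.
Calibration constants were fitted on seed ranges disjoint from the seeds
the tests use. Other numerical choices: $\kappa$ below $1-10^{-8}$ is
treated as a numerical failure; merge-height inversions beyond $10^{-8}$
invalidate a dendrogram (smaller ones are clipped to zero); market
proportion vectors must sum to 1 within $10^{-9}$; distance ties break
toward the lower market id; `hclust` resolves merge ties deterministically
from the input order. In small samples the model-fitting layer drops
design columns that are constant or that contain a single minority
observation (a singleton dummy yields a hat value of one, a zero
residual, and an exactly singular robust-covariance weight matrix);
fits at the default n = 290 are unaffected.

## What passing tests do and do not show

The generator emulates the *moments* of a real cohort — seasonal diet
margins, production prevalences, value distributions, spatial access —
and the endogeneity mechanism, but real surveys differ in ways the
synthetic cohort does not capture: spatial autocorrelation beyond zone
effects, within-village clustering, measurement error in recalls and in
monetary values, informative non-response, price variation, and
neighborhood grocery stores outside the weekly-market system. Passing
recovery tests therefore demonstrates that the estimators are implemented
correctly and behave as theory predicts under the stated data-generating
process — not that instruments of this kind are valid in any particular
real survey. Two further caveats: the Hansen J test shows mild
over-rejection (≈10% at the 5% level) when applied to the full synthetic
cohort, a finite-sample effect of the 19-column design at n = 290 together
with the latent-wealth proxy entering the controls, even though the
instruments are valid by construction — its size is nominal in the
cleaner IV designs the acceptance suite checks; and the bundled nutrient
matrix being synthetic, absolute NFD levels are not comparable to values
computed from laboratory composition tables, though all structural
properties (range, monotonicity, the all-product farm scoring 100) are.
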