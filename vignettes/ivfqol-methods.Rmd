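---
title: "Methods: binocular field integration, Rasch scoring and permutation importance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: binocular field integration, Rasch scoring and permutation importance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ivfqol)
```

## The analysis in one paragraph

In advanced glaucoma the residual central visual field carries most of a
patient's remaining visual function, and different daily tasks (reading,
walking, dining, ...) plausibly depend on different *parts* of that field.
`ivfqol` implements the full analysis chain for testing this: per-eye
Humphrey 10-2 and 24-2 total-deviation (TD) maps are merged into a binocular
integrated visual field (IVF), damage is summarised as mean TD (mTD) over
anatomically motivated subfields, vision-related quality of life (VRQoL) is
scored from a 30-item questionnaire with a polytomous Rasch model, and the
subfields that drive each task-specific ability score are identified with a
regression random forest whose permutation importances are tested against an
empirical permutation null. Because no patient-level dataset of this kind is
public, the package ships a seeded synthetic cohort generator with a known
ground truth, and every performance claim made by the test suite is a
statement about recovery of that truth.

## Test-point geometry and subfields

The 10-2 pattern tests the central 10 degrees on a 2-degree lattice: all
points with odd integer coordinates (in degrees, fixation at the origin)
satisfying $x^2 + y^2 \le 82$, which yields exactly 68 points — the only
such lattice-ball radius consistent with the pattern's published point
count. The 24-2 pattern has 54 points 6 degrees apart (rows at $|y| \in
\{3, 9, 15, 21\}$, widths shrinking with eccentricity) including two
nasal-step points at 27 degrees on the nasal side of the tested eye; only 12
of its points fall within 10 degrees of fixation. Both counts (and the 12)
are asserted as printed anchors in the acceptance tests.

Everything is expressed in visual-space coordinates for both eyes (positive
x to the patient's right), so corresponding points of the two eyes share
coordinates and no retinal flip is needed; the nasal-step points are the
only locations without a fellow-eye counterpart.

The 10-2 field is partitioned into eight quadrant subfields: four quadrants
given by the signs of $(x, y)$, each split into an *inner* part within 5
degrees of fixation and an *outer* part beyond it. The boundary (default 5
degrees, Euclidean eccentricity, ties assigned inner) is configurable, with
a Chebyshev metric offered as an alternative, because descriptions of
"within 5 degrees" are ambiguous between a disc and a square; no default
grid point lies at exactly 5 degrees, so the tie rule never fires in
practice. Each inner quadrant contains 4 points and each outer quadrant 13,
for any boundary between the 4th and 5th ring. The 24-2 field is split into
upper and lower hemifields (27 points each; no point lies on the horizontal
meridian).

## Binocular integration

The default integration is the *best-location* model: at each pair of
corresponding locations the better (maximum) TD of the two eyes is
recorded. TD rather than raw sensitivity is integrated, since TD is the
age-corrected quantity the downstream damage summaries use. At 24-2
nasal-step points the single available eye's value is carried through — the
choice is documented rather than dictated by any source, and it affects only
2 of 56 integrated locations per eye.

A quadratic binocular-summation model is provided as a secondary option:
TDs are linearised to relative sensitivities $s = 10^{TD/10}$, combined as
$(s_{OD}^2 + s_{OS}^2)^{1/2}$, and re-expressed in dB, so equal inputs gain
$10\log_{10}\sqrt{2} \approx 1.5$ dB. Both models dominate either monocular
field pointwise, and best-location integration is symmetric and monotone:
improving any monocular point can never lower any IVF point or subfield
mTD (property-tested).

Two 10-2 assessments bracketing the VRQoL interview are integrated first
and the *IVF TD values* averaged afterwards; averaging monocular fields
before integration would not commute with the pointwise maximum and is
deliberately not done. A cohort record with a single 10-2 assessment is
accepted with a warning rather than rejected.

## Rasch scoring of the questionnaire

The questionnaire has 30 items in 7 tasks, each answered on a three-category
difficulty scale (0 = greatly disabled, 1 = slightly disabled, 2 = not
disabled). Task raw scores are plain sums of item categories; the patient
raw score is their total. The per-task item allocation of the original
instrument is not public, so the default schema (5/5/4/4/4/4/4 items) is
explicitly synthetic plumbing, replaceable by a YAML schema.

Item easiness and person ability are estimated under the Andrich
rating-scale model
$$
P(X_{ni} = k) \propto \exp\!\Big(k(\theta_n - \delta_i) - \textstyle\sum_{j \le k}\tau_j\Big),
\qquad k \in \{0, 1, 2\},\ \tau_0 \equiv 0,
$$
with shared thresholds $\tau_1, \tau_2$; a partial-credit parameterisation
(item-specific steps) is available via `model = "partial_credit"`. The
reported easiness parameter is $-\delta_i$ (higher = easier), and the person
ability index is $\hat\theta$ (higher = better functioning).

Estimation is joint maximum likelihood, chosen for self-containment and
transparency: alternate Newton solves of the person score equations (the
raw score is sufficient, so one solve per distinct raw score), the item
score equations, and the threshold category-count equations, iterated to a
maximum parameter change below $10^{-6}$ logits (default cap 200 outer
iterations; non-convergence raises a condition carrying the last iterate).
The scale is identified by centring the item difficulties at zero;
threshold ordering is estimated, not forced. Persons with extreme raw
scores (0 or the maximum) are excluded from parameter estimation and scored
afterwards with the usual $\pm 0.5$ raw-score correction, which keeps every
ability finite. Per-task abilities are the ML solutions on that task's item
subset with parameters anchored to the joint fit, so patients with equal
task raw scores always receive equal task abilities.

JML is consistent here only as item number grows, and with 30 items its
well-known bias is a few percent of the difficulty spread; the validation
suite quantifies the practical consequence directly — at $n = 500$ the item
difficulty RMSE stays below 0.2 logits and true-vs-estimated ability rank
correlation above 0.9.

## Random forest and permutation-null p-values

Each task ability is regressed on 13 explanatory variables (age, better- and
worse-eye logMAR acuity, the eight 10-2 IVF quadrant mTDs, the two 24-2 IVF
hemifield mTDs) with a regression random forest: unpruned CART
variance-reduction trees on bootstrap samples, a random subset of variables
tried at each split. Because the subfield mTDs are strongly
inter-correlated, single-variable screens overstate how many subfields
matter; the forest's conditional structure is the reason it is used here.
Hyperparameters are unreported territory, so the defaults are conventional:
1000 trees, `mtry` $= \lfloor 13/3 \rfloor = 4$, minimum leaf size 5, all
configurable; the forest is implemented in compiled code and is bit-for-bit
reproducible from its seed.

The importance of a variable is the classic out-of-bag (OOB) quantity: the
mean over trees of the increase in the tree's OOB mean squared error when
the variable's values are scrambled. One design detail deviates from the
textbook per-tree recipe, deliberately. A single global random permutation
is drawn per importance evaluation and applied to the variable's column,
each tree evaluating its own OOB cases under that shared assignment; the
empirical null repeats the evaluation comparing two fresh independent
permutations, and
$$
p = \frac{1 + \#\{\text{null} \ge \text{observed}\}}{n_{\text{null}} + 1}.
$$
The reason is exchangeability: under the null hypothesis that the variable
carries no information, the identity assignment is just one more
permutation, so the observed statistic and the null draws are exchangeable
and the p-value is a valid finite-sample permutation p. Had each tree
permuted its OOB cases independently while the baseline kept one shared
(identity) assignment, the observed and null statistics would have
different variances and the test would be miscalibrated. Calibration is
verified empirically: across 500 simulated global-null datasets the type-I
error at $\alpha = 0.05$ must land in $[0.03, 0.07]$. The default number of
null draws is 2000 per variable (p-value resolution 1/2001); a
response-permutation null (permute the response, refit, recompute all
importances — one refit per null draw) is available via
`null = "response"` as a cross-check variant, since the exact null recipe
behind this kind of analysis is typically under-specified. Significant
variables (p below $\alpha = 0.05$) are ranked by ascending p, ties broken
by descending observed importance and then name.

Known limitation, shared with all permutation importance: permuting one
variable also breaks its correlation with its neighbours, so a null
variable that is strongly correlated with a true driver can inherit
significance. The calibration guarantee is for variables independent of
the response and of the active set; the synthetic cohort's null variable
(age) is generated independent of everything for exactly this reason.

## Classical statistics

The screening stage computes Spearman correlations (average ranks, p from
the t approximation, adequate at the intended $n > 100$; misleading below
$n \approx 10$, which the function refuses) between all 13 variables and
all 8 ability scores, flagged at the Bonferroni per-comparison threshold
$0.05 / (13 \times 8) = 0.05/104 \approx 0.00048$. Subfield damage is
compared across the eight 10-2 subfields with one-way ANOVA plus Scheffé
pairwise contrasts ($S^2_{ij} = (\bar x_i - \bar x_j)^2 / (\mathrm{MSE}
(1/n_i + 1/n_j))$ referred to $(k-1)F_{k-1,N-k}$), and upper vs lower 24-2
hemifields with a paired t-test — all through base R's `aov`/`t.test`
machinery, with hand-worked toys as oracles in the tests. The repeated-
measures structure of the subfield comparison is ignored by design: the
ANOVA is descriptive, mirroring the conventional presentation of such
tables, and the substantive inference rests on the forest analysis.
Eligibility filtering (MD $\le -20$ dB in either eye, decimal acuity
$\ge 0.5$ in both, fixation losses $< 20\%$, false positives $< 15\%$,
false negatives $< 33\%$ on every test) reports the first failed rule per
excluded patient, in the order MD, acuity, reliability. "Better eye" means
lower logMAR acuity, ties broken by higher MD and then by the right eye.

## The synthetic cohort

The generator produces what the analysis assumes and nothing more. Per
patient: a better- and worse-eye global damage level (Gaussian around
$-17$ and $-26$ dB), a patient-level upper/lower hemifield offset (upper
worse by 6 dB on average, the well-known asymmetry of glaucomatous loss),
shared per-quadrant random effects inducing the inter-subfield
correlations the forest must cope with, 3 dB of relative central sparing,
independent per-point noise, truncation to $[-35, 5]$ dB, and two 10-2
assessments differing by visit-level noise. LogMAR acuity is tied to the
eye's central 10-2 damage with Gaussian noise, so acuity and central mTDs
are realistically confounded. Reliability indices fall below the
eligibility caps except for a configured small failure rate. With the
default settings the cohort's descriptive scale (better-eye MD near
$-17$ dB, 10-2 IVF mean TD near $-13$ dB, acuities in the
$0.05$–$0.15$ logMAR range, roughly 90% eligibility) matches the kind of
advanced-glaucoma population the analysis targets, without claiming to
reproduce any particular sample.

Latent task abilities are standardised linear combinations of the 13
*realised* features under a configurable truth map (default: letters and
dressing load on better-eye acuity only; dining on the lower-right
quadrants; walking and going out on the lower-left quadrant and lower
hemifield; age loads on nothing), scaled to 1.5 logits of systematic
spread plus 0.5 logits of noise — enough signal that true drivers are
recoverable at $n = 300$, enough noise that recovery is not trivial.
Responses are then drawn from the same rating-scale model the scoring
assumes, with item difficulties spread over $[-1.2, 1.2]$ and thresholds
$(-0.8, 0.8)$.

What the generator does **not** emulate: SITA threshold estimation noise
and its eccentricity dependence, perimetric learning and fatigue effects,
floor effects of the dB scale, longitudinal progression, differential item
functioning, or missing questionnaire data. Passing tests therefore
demonstrate that the pipeline recovers structure *of the assumed form*
from data *of the assumed distribution* — they validate the machinery, not
the clinical claims.

## Validation problem sizes and numerical choices

The test suite runs the Rasch recovery at $n = 500$ patients; the
permutation calibration on 500 global-null datasets of $n = 200$ with 5
features, 100-tree forests and 199 null draws; and the end-to-end recovery
on 20 seeded cohorts of $n = 300$ with 200-tree forests and 199 null
draws — sizes chosen to make the Monte-Carlo error of each claim small
relative to its acceptance margin while keeping a full run in minutes on
one core. The analysis defaults (1000 trees, 2000 null draws) remain
larger than the simulation settings.

Numerical details worth knowing: all means and likelihood computations are
in double precision with rounding only at report output (1 decimal for dB
tables); rating-scale probabilities use a max-shifted softmax; person and
item Newton solves are damped and clamped to $[-30, 30]$ logits; forest
split candidates are midpoints between distinct sorted values, splits
require a positive variance reduction and `min_leaf` cases per child, and
the forest RNG is an own splitmix64 stream so results are identical across
platforms and independent of R's RNG state (the R-level seed arguments
draw from R's stream only when a seed is not supplied).

## Interfaces

All stages are plain functions returning data frames or small S3 objects,
orchestrated by `run_pipeline()` from a `pipeline_config()` (exactly one
input source: a synthetic cohort configuration or a set of CSV paths), which
writes every table it computes — eligibility, per-patient subfield mTDs,
abilities, the correlation screen, group statistics, the per-task
importance report and ranking, histogram-ready ability counts — plus a
manifest echoing the configuration and seed, so a run is reproducible
artifact-for-artifact. A thin command-line wrapper over `run_pipeline()`
ships in `inst/scripts/run_pipeline.R` for shell use.
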