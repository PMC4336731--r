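---
title: "A two-test cascade for stent and bypass treatment selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-test cascade for stent and bypass treatment selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The clinical problem

Percutaneous coronary intervention (PCI) today deploys drug-eluting stents
(DES) almost by default: they re-narrow (restenose) far less often than
bare-metal stents (BMS) — roughly 4–8% versus 20–30% — but they demand
prolonged dual anti-platelet therapy and carry a late-thrombosis risk, and
they cost more. Two patient groups plausibly deserve a different choice:
patients whose restenosis risk under BMS would be low anyway (BMS is cheaper
and avoids prolonged anti-platelet therapy), and patients at high risk of
death, myocardial infarction or stent thrombosis under DES, for whom bypass
surgery (CABG) is the safer, if far more expensive, alternative.

`stentstrat` implements a two-stage stratification that formalizes exactly
this deviation-only-when-justified logic, together with the closed-form
effectiveness and cost estimators needed to compare it against the
DES-dominant status quo, and a synthetic cohort generator that makes the
whole pipeline testable without access to any clinical registry.

## The model

### Two tests in cascade

Two binary risk tests are fitted per patient subgroup:

* $T_R$ predicts $P(\text{Restenosis} \mid \text{BMS})$ and is trained on
  BMS-treated records;
* $T_H$ predicts $P(\text{Hazard} \mid \text{DES})$ — hazard being the
  composite of death, myocardial infarction and stent thrombosis — and is
  trained on DES-treated records.

A new patient is routed as: if $P_R < \theta_R$ suggest **BMS**; otherwise,
if $P_H < \theta_H$ suggest **DES**; otherwise suggest **CABG**. Throughout
the package a *positive* prediction means score $\ge$ threshold; the
negative first test is the BMS suggestion. Restenosis under BMS and hazard
under DES are treated as independent competing risks (their
pathophysiologies differ), which is also what makes the closed-form
estimators below factorize.

### Subgroup-specific leaves instead of one global model

Rather than one population-wide model per test, the cohort is partitioned
by classification trees over three clinically privileged variables: age
(split at 60 years, ≤60 inclusive on the young side), sex, and diabetes.
All conjunctions of {unconstrained, level 1, level 2} over the three
variables give exactly 27 possible leaf subgroups; every hierarchical
guillotine split sequence (each variable at most once per path, children
split independently, depth at most four levels) is enumerated and
de-duplicated by the partition it induces, which yields 146 distinct
candidate trees in this package's convention. The enumeration is verified
in the test suite against an independent brute-force enumeration of
realizable set partitions of the eight fully-specified cells. (The
literature quotes much smaller "total tree" counts under unstated
conventions; we treat the convention as an open question and pin ours by an
oracle instead.) Exhaustive enumeration, in contrast to greedy CART-style
growth, guarantees the selected partition is optimal for the stated
objective.

### The leaf learner

Each leaf model is logistic regression with an $\ell_2$ penalty on the
slopes:

$$\hat\beta = \arg\max_\beta \; \ell(\beta_0, \beta) - \lambda \lVert\beta\rVert_2^2,
\qquad \lambda = 0.01,$$

with the intercept unpenalized and the penalty applied literally as the
coefficient of $\lVert\beta\rVert^2$ — no $1/n$ scaling — so the estimate is
reproducible across sample sizes. The penalty is fixed once for every model;
tuning it per leaf inside the cross-validation would multiply the
computation prohibitively and is deliberately out of scope. Optimization is
Newton's method with step-halving from a zero start, run to a penalized
score norm of $10^{-6}$; it is deterministic given the data. Continuous
features are standardized to zero mean and unit variance *on the training
fold only*; categorical features are one-hot encoded against the most
frequent training level (the data source is silent on encoding, so this is
a package choice); zero-variance columns map to zero with a warning.

### Feature-set availability

Thirty clinical variables and eleven in vitro diagnostic biomarkers are
catalogued in three era-linked sets each (C1/C2/C3 with 29/26/23 members by
the catalogue's inclusion marks — the prose count of 28/25/22 disagrees
with the marks; we follow the marks and note the discrepancy — and B1/B2/B3
with 8/5/5). A candidate classifier uses one clinical set or none, and one
biomarker set or none: 16 combinations per test and subgroup, hence at most
$27 \times 16 = 432$ classifiers per endpoint. A candidate is *eligible*
only if, after discarding rows with any missing selected feature (no
imputation), at least 100 records and 10 events remain.

### Joint feature-set and operating-point selection

For each subgroup the pair of tests is chosen by

$$\max_{i,j,\theta_R,\,p,q,\theta_H}\;
\mathrm{NPV}\!\left(T_R^{i,j}, \theta_R\right) +
\mathrm{PPV}\!\left(T_H^{p,q}, \theta_H\right),$$

an exhaustive search over all eligible feature-set pairs and over
thresholds realizing training specificities 5%–95% in 5% steps (19
operating points; the trivial 0% and 100% ends are excluded). Maximizing
NPV of $T_R$ minimizes patients falsely diverted to BMS; maximizing PPV of
$T_H$ minimizes patients falsely kept on DES while at high hazard risk.
With one pair per test the search visits $2 \times 19 = 38$ cells, with all
sixteen $2 \times 19 \times 16 = 608$. Because the two summands share no
variables, each test is maximized independently; a brute-force scan of the
full cross product in the test suite confirms the equivalence. All
selection metrics are computed by resubstitution on the training fold —
selection, like fitting, never sees held-out data. Ties are broken by fewer
total features, then lower set indices (none = 0), then the lower grid
level; candidates whose NPV or PPV denominator is zero are excluded rather
than scored zero, since the objective is undefined there.

Thresholds at a grid level are the smallest observed score (plus a sentinel
above the maximum) whose achieved training specificity is at least the
level; the achieved specificity is recorded alongside. One consequence the
test suite exercises explicitly: a feature that perfectly predicts
restenosis lets many thresholds reach a training NPV of 1, and since
$\hat P(\text{Restenosis}\mid \text{sBMS}) = 1 - \mathrm{NPV}(T_R)$, such
leaves report a zero restenosis rate under the BMS suggestion.

### Tree selection

A candidate tree's performance is the element-wise sum of its leaves'
training confusion matrices (per test), and its objective is the NPV + PPV
of those aggregated matrices. Trees with any ineligible leaf are discarded
(the single-leaf tree is always attempted; the run fails only if even that
is ineligible). The argmax tree wins; ties go to fewer leaves, then
enumeration order.

## Effectiveness estimators

With $\mathrm{Prev}$, $\mathrm{Sens}$, $\mathrm{Spec}$ taken from the
pooled held-out confusion matrices of the two tests:

$$\hat P(\text{sBMS}) = \mathrm{Prev}_R (1-\mathrm{Sens}_R) + (1-\mathrm{Prev}_R)\,\mathrm{Spec}_R$$
$$\hat P(\text{sDES}) = \left(1-\hat P(\text{sBMS})\right)\left[\mathrm{Prev}_H (1-\mathrm{Sens}_H) + (1-\mathrm{Prev}_H)\,\mathrm{Spec}_H\right]$$
$$\hat P(\text{sCABG}) = 1 - \hat P(\text{sBMS}) - \hat P(\text{sDES})$$

which sum to one identically. Adverse effects decompose per suggested
treatment:

$$P(\text{Adverse}) = P(\text{Restenosis}) + P(\text{Hazard}), \qquad
P(\text{Restenosis}) = \sum_{t} P(t)\, P(\text{Restenosis}\mid t),$$

with two provenances of conditionals: classifier-based "hat" estimates
($\hat P(\text{Restenosis}\mid\text{sBMS}) = 1-\mathrm{NPV}(T_R)$,
$\hat P(\text{Hazard}\mid\text{sDES}) = 1-\mathrm{NPV}(T_H)$) and counted
"tilde" estimates retrieved from follow-up labels. A counted rate must
reflect the outcome *under the suggested treatment*; in observational data
that label only exists for records actually treated with the matching
stent, so $\tilde P(\text{Restenosis}\mid\text{sDES})$ is counted among
DES-treated records routed to sDES and
$\tilde P(\text{Hazard}\mid\text{sBMS})$ among BMS-treated $T_R$-negatives.
(Whether the sDES conditioning includes both tests is ambiguous in the
source material; we condition on the full sDES route.) CABG conditionals
cannot be estimated from a PCI cohort and are literature constants: 8.56%
hazard, 1.9% restenosis, exposed as configuration.

The baseline workflow treats everyone with DES except a grey zone
$\omega = \lambda\, P(\text{3-vessel disease})$, $\lambda = 0.21$ (the
published low-lesion-complexity fraction), treated half DES / half CABG;
its event rates are the correspondingly weighted sums of empirical DES
rates and the CABG constants. Records a leaf cannot score (missing model
features) default to the baseline-dominant suggestion, DES, with a warning.

## Cost model

Initial cost:
$\hat P(\text{sBMS})(C_{\text{sBMS}}+C_{\text{DAPT}}) +
\hat P(\text{sDES})(C_{\text{sDES}}+C_{\text{DAPT}}) +
\hat P(\text{sCABG})\,C_{\text{CABG}}$.
Corrective cost:
$\hat P(\text{Hazard})\left(\tfrac12(C_{\text{MI}}+C_{\text{Stroke}})+C_{\text{Corr}}\right)
+ \hat P(\text{Restenosis})\,C_{\text{Corr}}$.
Baseline initial cost:
$(1-\omega)(C_{\text{sDES}}+C_{\text{DAPT}}) +
\tfrac12\omega(C_{\text{CABG}}+C_{\text{sDES}}+C_{\text{DAPT}})$.

Default stent costs are derived, not asserted: the DES cost is the midpoint
of its published ±25% sensitivity range ($9{,}342$–$15{,}571$), the BMS
cost is that minus the published $590 gap, and scaling by 0.75/1.25
reproduces all four published endpoints to within a dollar. CABG defaults
to the published $28{,}683$. The therapy and adverse-event costs
($C_{\text{DAPT}}, C_{\text{MI}}, C_{\text{Stroke}}, C_{\text{Corr}}$) have
no value in the available material; the shipped defaults are **clearly
labelled placeholders** in a plausible U.S.-reimbursement range, and any
real costing exercise must configure them. Sign and magnitude of the total
savings are sensitive to these placeholders; the package reports whatever
the configured table implies. The sensitivity grid sweeps both stent costs
±25% in 1.25% steps (41 × 41); savings are affine in each axis because the
formulas are linear in the costs.

## Evaluation scheme

Stratified 10-fold cross-validation (endpoint label within treatment arm,
so small subgroups keep both classes per fold — the source is silent on
stratification), repeated with fresh random splits; training, selection and
tree choice use only the training folds. Held-out predictions are pooled
across the folds of a repetition: effectiveness and costs come from the
pooled (micro-pooled) confusion matrices, a package choice the source does
not specify. Discrimination is summarized per repetition as the *median of
per-leaf-classifier AUCs* (midrank convention): scores from different leaf
models live on different scales, so pooling them into a single ranking
would conflate calibration with discrimination — the published comparison
is likewise a distribution over subgroup-specific classifiers. Confidence
intervals are empirical 2.5/97.5 percentiles across repetitions
(linear-interpolation quantiles, R type 7). Four endpoint pairings are
analysed: angiographic restenosis at 6 months with 1- or 3-year hazard,
and clinical restenosis (target lesion revascularization) at the matching
1- or 3-year horizon. A `global_mode` switch refits everything without
partitioning for the subgroup-versus-global contrast.

The reference repetition count for CI-quality estimates is 300; the
packaged drivers and the acceptance script default to 10 repetitions and
the unit tests to 1–3 at smaller cohort sizes, which this package treats as
its documented problem sizes for routine runs. Per-patient multiple
interventions are treated as independent records; a `patient_id` column is
carried for optional grouped splitting but unused by default.

## The synthetic cohort generator

The generator is first-class, tested code that emulates the study
conditions the analysis assumes:

* 2,733 interventions; DES assigned Bernoulli(0.342); 913/2733 lost to
  follow-up (all endpoints missing); three-vessel disease rate 0.25.
* Ages truncated-normal (mean 65, sd 10, ≥18); 24% female; 28% diabetic —
  typical interventional-cardiology demographics.
* Continuous features are drawn with exchangeable within-family correlation
  0.2 and realistic marginal locations; binary and categorical features
  from fixed plausible rates. Three collection eras (weights 0.4/0.3/0.3)
  mask all features outside that era's C/B sets, plus 0.5% sporadic
  missingness per recorded cell, reproducing the fragmented availability
  the feature-set machinery exists for.
* Outcomes follow subgroup-specific logistic models over the eight
  fully-specified age/sex/diabetes leaves. The heterogeneous default flips
  coefficient signs between diabetes strata and scales magnitudes between
  age strata (0.8 vs 1.3), so a global model is misspecified while leaf
  models are well-specified; a homogeneous variant removes the gap. The
  support is restricted to features present in every era's sets so leaf
  fits stay well-posed.
* Per-arm endpoint prevalence targets (BMS angiographic restenosis 0.25 and
  DES 0.06 are midpoints of the documented clinical ranges; clinical
  restenosis 0.20/0.28 BMS and 0.05/0.08 DES at 1/3 years; hazard 0.04/0.09
  in both arms, since hazard rates are similar across stent types) are hit
  by bisecting a per-arm intercept shift; targets of exactly 0 or 1 are
  rejected as uncalibratable. One latent uniform per endpoint family makes
  3-year events supersets of 1-year events.
* Labels are generated for **both** potential treatments; the cohort
  exposes only the assigned arm's label (observational data), while the
  counterfactual and the true linear predictors live in a `planted_truth`
  sidecar consumed only by oracle tests, never by the fitting pipeline.

What the generator does *not* emulate — and hence what passing tests do not
establish about real registries: treatment assignment is random rather than
confounded by indication; biomarker distributions are symmetric Gaussians
(real CRP or NT-proBNP are heavily skewed); no time-to-event structure, no
per-patient correlation between repeated interventions, no temporal drift
within eras, no measurement error. Parameter-recovery and
subgroup-versus-global results on this generator validate the machinery,
not the clinical effect sizes.

## Numerical choices and degenerate inputs

* Newton/IRLS with step-halving, zero start, penalized-score norm ≤ 1e-6,
  at most 100 iterations; non-convergence is an error carrying the norm.
  The ridge makes separable data finite and singular one-hot blocks
  solvable.
* AUC uses midranks (ties count half); single-class inputs are errors.
* Specificity-grid thresholds come from observed scores plus one sentinel
  above the maximum; with all negatives tied, every level maps to the
  sentinel with achieved specificity 1.
* Undefined NPV/PPV (zero denominators) excludes the candidate cell;
  undefined tilde conditionals are flagged and only fatal if weighted by a
  nonzero treatment probability.
* Empty matrices refuse to standardize; zero-variance columns are zeroed
  with a warning.
* All randomness flows through explicit integer seeds; identical seeds give
  byte-identical cohorts, splits and fits.

## Known limitations

Binary classification only (no censoring-aware time-to-event modelling);
resubstitution-based operating-point selection is optimistic, so held-out
NPV/PPV at the chosen thresholds degrade — visible at the default study
scale, where the hazard arm (~620 labelled DES records, events at 4–9%)
leaves many subgroup–feature-set candidates ineligible and the selected
trees shallow. The CABG arm rests entirely on two literature constants.
Cost conclusions inherit the placeholder corrective-cost table. These are
properties of the method and the emulated study scale, reported as
computed.
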