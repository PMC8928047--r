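---
title: "Methods: phenotype-to-risk Bayesian network analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phenotype-to-risk Bayesian network analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cvdbn` studies how metabolic health and BMI category relate to 10-year
cardiovascular disease (CVD) risk by learning a discrete Bayesian network
over a phenotyped cohort and querying it. This vignette records the model,
its assumptions, the tunable parameters, and the design decisions taken
where the problem left the design genuinely open.

## The model

A discrete Bayesian network over variables $X_1,\dots,X_n$ is a pair
$(G, P)$: a DAG $G=(V,A)$ and the factorised joint
$P(X_1,\dots,X_n)=\prod_i P(X_i \mid \mathrm{Pa}(X_i))$. We learn $G$ by
maximising the BIC score

$$\mathrm{BIC}(G) = \sum_i \left[ \max_\theta \log L(X_i \mid
\mathrm{Pa}(X_i), \theta) - \frac{\log n}{2}(r_i-1)q_i \right],$$

where $r_i$ is the level count of $X_i$ and $q_i$ the number of parent
configurations. The score decomposes over families, so a single-arc move
changes only one or two terms; zero-count cells contribute zero
log-likelihood ($0\log 0 \equiv 0$). BIC is score-equivalent: members of a
Markov equivalence class score identically (verified to $10^{-9}$ in the
tests), which is why recovery of a learned *skeleton* rather than exact
orientations is the meaningful single-run yardstick; orientations across
layers are supplied by prior knowledge (below).

### Search

`tabu_search()` walks DAG space by single-arc addition, deletion and
reversal. After a move is applied its inverse goes onto a tabu list
(default length 10) and is forbidden unless taking it would beat the best
score seen (aspiration). The search stops after 50 consecutive
non-improving moves or 10,000 iterations; ties between equal-scoring moves
break lexicographically by (operation, from, to), so results are
deterministic. These defaults follow common practice for tabu-over-DAGs
implementations; none is critical because the datasets here are far from
the regime where hill climbing stalls. There is no parent-count cap by
default — the BIC penalty (multiplicative in $q_i$) bounds parent sets on
its own; a hard cap on $q_i$ (4 × 10⁶ configurations) only guards against
degenerate walks. Families are scored in C++ with a per-search cache keyed
on (node, parent set); the tests assert cached and uncached scores agree
exactly.

### Prior knowledge

Constraints enter as a whitelist (arcs that must appear), a blacklist (arcs
that may never appear), and an ordered layering compiled into the
blacklist: no arc may point from a later layer to an earlier one. The
default layers are demographics → {behaviours, metabolic health, BMI} →
{comorbidities, biomarker bins} → risk category; the default whitelist
forces `metabolic_health → frs_category` and `bmi_category → frs_category`
(the causal reading of the phenotype effect), and the risk category can
never influence age. One extra blacklist entry deserves its own paragraph.

**Why `sex → frs_category` is blacklisted by default.** The Framingham
equation is sex-calibrated: at identical covariate values men receive much
higher risks. Learned from data, that calibration shows up as a trivial
direct sex→risk arc which then explains away the smoking pathway
(conditional on sex, smoking's BIC gain no longer clears the penalty at
$q$ = 60+ parent configurations). The substantive question is how sex acts
through modifiable pathways, so the default constraint set forbids the
direct arc and lets the mediated route (sex → smoking → risk) carry the
dependence. Like every constraint it is config-overridable.

### Model averaging

`bootstrap_learn()` learns one structure per nonparametric resample
(default B = 300, the reference analysis's choice; tests use 50–100 for
runtime). Arc **strength** is the fraction of replicate networks containing
the edge in either orientation; the **direction** frequency is tracked
separately and the consensus edge takes the majority orientation (a 0.5–0.5
tie breaks toward the lexicographically smaller from-node). Strength is
direction-agnostic because with layer-constrained orientations the
substantive stability question is about adjacency, and it makes "strength
between 0 and 1" plus majority orientation well-defined. Two thresholds
are applied: ≥ 0.5 (the averaged network) and strictly > 0.85 (the final,
simplified network; strict to honour the "above 0.85" reading). Thresholded
consensus graphs can in principle contain directed cycles; if one appears,
the weakest arc inside a cycle is dropped repeatedly, with a loud warning —
in all seeded runs exercised by the tests this never triggers on real
pipeline output.

### Parameters and inference

CPTs are fitted by maximum likelihood (`smoothing = 0`, the conventional
default); a parent configuration never observed falls back to a uniform
row with a warning, and a Laplace `smoothing` pseudo-count is available.
Queries run two ways:

- `exact_query()` sums the factorised joint over all completions —
  exact, used as the oracle, and guarded by a state-space budget
  (default $2^{21}$ completions).
- `lw_query()` is likelihood weighting: evidence nodes are clamped and each
  forward sample is weighted by the product of the evidence CPT entries
  given its sampled parents. Weights are accumulated on the log scale and
  shifted by their maximum before exponentiation.

`query_ci()` reports the mean of (default) 30 independent replicates of
10,000 samples with an empirical 2.5/97.5 percentile interval. This
captures the **Monte Carlo error of the query**, not parameter uncertainty;
a data-bootstrap mode (refit CPTs per cohort resample) is provided because
the underlying analysis does not state which source of uncertainty its
intervals reflect. Neither mode is labelled "the" method; the sampling mode
is the default because it is the one whose coverage the enumeration oracle
can certify directly (≥ 90/100 coverage runs in the acceptance suite).

## The synthetic cohort

No public version of the original survey data exists, so the generator
emulates its statistical shape: n = 6276 adults aged 30–74, 46.13% male,
the six-phenotype mix (40.6/18.1/3.2/15.2/15.6/7.3%), five decade age
groups with the observed marginals, and per-phenotype biomarker profiles
(mean/SD of height, BMI, waist/hip, lipids, blood pressure, glucose, uric
acid, HOMA-IR, hsCRP, HbA1c) mirroring the reference cohort's descriptive
table. Sampling is layered: sex and age group first; metabolic health from
a logit with an age slope; BMI category given metabolic health (so the
phenotype mix is matched in expectation); biomarkers from zero-truncated
normals given the phenotype; medication flags only where the latent
condition holds (e.g. antihypertensive use in 35% of records with
SBP ≥ 140 or DBP ≥ 90). Insulin is derived as HOMA-IR × 22.5 / FPG so the
phenotyping module reconstructs the drawn HOMA-IR exactly.

Design choices that matter:

- **Truncated normals.** Only means and SDs are available, and biomarkers
  are positive. Truncation at zero shifts means upward (noticeably for
  TG/HOMA-IR/hsCRP in the MU groups, where SD is large relative to the
  mean); tests therefore compare sample means against the *analytic
  truncated-normal mean*, the actual expectation of the configured draw.
- **SBP/DBP correlation.** The two pressures are drawn as a correlated
  pair ($\rho = 0.75$, conditional-normal, marginals unchanged). They are
  alternative triggers of the same ATP-III criterion; drawing them
  independently inflates that criterion's base rate in metabolically
  healthy groups to ~38% and buries the age–metabolic-health trend the
  generator is supposed to plant. All other biomarkers remain conditionally
  independent given the phenotype — a known simplification: real biomarker
  panels are mutually correlated, so passing tests here say nothing about
  robustness to such correlation.
- **Age effect: 0.6 logit/decade.** Labels are *re-derived* from the noisy
  biomarker draws downstream, which attenuates any planted trend (about
  78% of records keep their assigned label). The generator's age slope is
  therefore set to plant a strong, unambiguous dependence — roughly double
  the crude trend visible in the reference descriptive table — because the
  generator's contract is a qualitatively faithful, recoverable structure,
  not a calibrated reproduction of the original age gradient.
- The generator's assigned labels are kept as `gen_*` columns; the pipeline
  ignores them and re-derives phenotypes from biomarkers, exactly as it
  would on observed data.

What the generator does **not** emulate: survey weights and household
clustering, biomarker correlations beyond the BP pair, measurement error,
the sex composition differences between phenotypes, and any longitudinal
structure. Conclusions about those features cannot be drawn from this
package's tests.

## Phenotyping and risk scoring choices

- **BMI bins** are half-open: [18.5, 24), [24, 28), [28, ∞) — reconciling
  "18.5–23.9" with "overweight ≥ 24" by exact arithmetic instead of
  one-decimal rounding. Underweight records are excluded by the
  eligibility filter with a logged count, never silently reclassified.
- **ATP-III thresholds** are inclusive as printed (≥130/85, ≥1.7, ≥5.6;
  HDL < 1.04 men / < 1.3 women); each of the first three criteria is
  alternatively satisfied by its medication flag, so setting a flag can
  only raise the criteria count (a tested monotonicity).
- **Dyslipidemia** uses an ANY-of connective over LDL ≥ 4.14,
  HDL ≤ 1.036, TG ≥ 2.26 mmol/L (or lipid-lowering treatment). The
  source definition's "and" would make the flag jointly near-impossible
  and contradicts the prevalences it is reported with; the connective is
  an argument (`dyslipidemia_rule`) for anyone wanting the strict reading.
- **eGFR** uses the CKD-EPI 2009 creatinine equation from a versioned YAML
  transcription; the race multiplier is not applied (all-Chinese cohort).
- **FRS variant.** The lipid-based general-CVD equation is implemented
  (TC and HDL-C are among the stated inputs; the BMI-based variant exists
  for settings without lipids). Cholesterol betas expect mg/dL — declared
  in the config — and mmol/L inputs are converted at 38.67.
- **Risk bands** are [0, 10), [10, 20), [20, 100]: the printed "10–19%" /
  "≥20%" bands leave (19, 20) unassigned for continuous risks, so moderate
  is taken as [10, 20) to partition the range (the printed bands describe
  integer-rounded percentages).
- Whether "treatment for diabetes" means insulin only or any agent is not
  specified; a single flag is used.

## Discretization

Age maps to the five decade groups; BMI and FRS reuse their category
functions; eGFR bins at {60, 90} mL/min/1.73 m², TC at {5.2, 6.2} and LDL
at {3.4, 4.1} mmol/L, hsCRP at {1, 3} mg/L — conventional clinical cut
points chosen as package defaults, not values fixed by the reference
analysis. All bins are half-open `[lo, hi)`; a value outside every bin is
an error naming the row and variable. The network is fully discrete: the
queries of interest are all categorical, and a hybrid
continuous–discrete model would not change what can be asked of it.

## Numerical conventions

- CPT validity and probability-vector checks use a 1e-9 tolerance.
- Score comparisons inside the search use strict improvement with an
  epsilon of 1e-12 (aspiration) / 1e-9 (best-graph updates).
- Likelihood weights: log-scale accumulation, max-shift, explicit error if
  every weight is zero (degenerate evidence); exact queries raise an
  explicit undefined-conditional error on zero-probability evidence.
- Sub-seeds derive from the master seed by a fixed counter-based map
  (`derive_seed`), so bootstrap replicate *b* and every pipeline stage are
  independently reproducible and order-insensitive; all seeds stay below
  2³¹.

## Problem sizes in the test suite

The acceptance-style checks run at: structure recovery and bootstrap
separation on an 8-node ground-truth network at n = 5000 with 100 seeds
(B = 100 within each bootstrap experiment); sampler-versus-enumeration
agreement on ≤ 6-node random networks at 10⁵ samples; and 100 end-to-end
pipeline runs at the full study scale (n = 6276, B = 50, with the scenario
list reduced to the two phenotypes whose ordering is under test). These
sizes are the package's chosen desk-scale analogues of the reference
procedure (which used B = 300 on one cohort); `scripts/acceptance.R` runs
the full B = 300 configuration.

## Known limitations

- Structure learning is score-based only (tabu + BIC); no constraint-based
  or hybrid learners, and no significance estimation for arc strengths —
  the 0.5 / 0.85 thresholds are fixed choices.
- Inference is enumeration + likelihood weighting; fine at this scale
  (≤ ~15 nodes), but there is no junction-tree engine for larger models.
- Learned arcs are probabilistic dependencies under the constraint set,
  not causal claims; the cohort is cross-sectional by construction.
- The synthetic cohort is a structural emulation. Absolute conditional
  probabilities computed from it (e.g. risk given a phenotype) track the
  reference analysis only qualitatively; only the orderings and monotone
  patterns are designed to be reproducible.
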