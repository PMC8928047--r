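# cvdbn

Bayesian network analysis of metabolic obesity phenotypes and 10-year
cardiovascular disease (CVD) risk in adult cohorts.

## The problem

Whether excess weight raises cardiovascular risk in people who are otherwise
metabolically healthy is a live epidemiological question. A common design
crosses two axes — BMI category (normal weight / overweight / obese, at the
Chinese-adult cut points 24 and 28 kg/m²) and metabolic health (metabolically
unhealthy, MU, when at least two of the four Adult Treatment Panel-3 criteria
hold) — into six *metabolic obesity phenotypes* (MHNW, MHOW, MHO, MUNW, MUOW,
MUO), and asks how the 10-year CVD risk distributes across them. Standard
regression struggles with the web of mutual dependencies among age, sex,
behaviours, metabolic status and biomarkers; a discrete **Bayesian network
(BN)** instead represents the joint distribution as

P(X₁,…,Xₙ) = ∏ᵢ P(Xᵢ | Pa(Xᵢ)),

a product of each variable's conditional probability table (CPT) given its
parents in a directed acyclic graph G = (V, A), and supports *reasoning*:
conditional probabilities of any outcome under arbitrary evidence.

`cvdbn` implements that full analysis as a reusable, tested pipeline:

- **Synthetic cohort generator** — seeded emulation of the study population
  (n = 6276 adults aged 30–74, 46.13% male, six-phenotype mix with
  per-phenotype biomarker profiles, age-dependent metabolic abnormality),
  plus ancestral sampling from arbitrary known discrete networks.
- **Phenotyping** — ATP-III criteria counting (BP ≥130/85 or treatment,
  TG ≥1.7, FPG ≥5.6 mmol/L or treatment, sex-specific low HDL-C), BMI
  categories, HOMA-IR (= insulin × FPG / 22.5), CKD-EPI eGFR, comorbidity
  flags.
- **Framingham risk** — the sex-specific 10-year general-CVD equation
  (lipid variant): risk = 1 − S₀^exp(lp − l̄p), banded low (<10%), moderate
  ([10, 20)%), high (≥20%); coefficients ship as a versioned config.
- **Structure learning** — BIC-scored tabu search over DAGs with
  whitelist/blacklist and layer constraints (scoring and search in C++).
- **Model averaging** — B bootstrap-resampled networks (default 300), arc
  strength = presence frequency, consensus networks at strength ≥ 0.5
  (averaged) and > 0.85 (final).
- **Inference** — CPT fitting, exact enumeration for small networks, and
  likelihood-weighted queries with Monte Carlo 95% percentile intervals.

## Worked example

```r
library(cvdbn)

cohort  <- generate_cohort(cohort_config(n = 6276, seed = 1))
elig    <- apply_eligibility(cohort)
scored  <- score_cohort(phenotype_cohort(elig$eligible))
dataset <- discretize_cohort(scored)

cons <- arc_constraints(default_bn_nodes(), default_whitelist(),
                        default_blacklist(), default_layers())
dags <- bootstrap_learn(dataset, B = 300, cons, seed = 1)
net  <- averaged_network(arc_strengths(dags), 0.85, strict = TRUE)
fit  <- fit_cpts(net, dataset)

query_ci(fit, "frs_category", "high",
         list(metabolic_health = "MU", bmi_category = "obese"))
```

Or in one call, `run_pipeline(pipeline_config(seed = 1))`. On the default
synthetic cohort this prints (from `analysis/04_reasoning.R`):

```
by metabolic-obesity phenotype:
  P(high CVD risk | MHNW ) =  4.28%  (95% CI 3.92-4.69)
  P(high CVD risk | MHO  ) = 11.40%  (95% CI 10.98-11.79)
  P(high CVD risk | MUNW ) = 21.63%  (95% CI 20.84-22.44)
  P(high CVD risk | MUO  ) = 32.59%  (95% CI 31.62-33.60)
```

i.e. becoming obese while metabolically healthy raises the conditional
probability of a high 10-year risk modestly (4.3% → 11.4%), while losing
metabolic health raises it sharply even at normal weight (21.6%), and the
two together compound (32.6%) — the qualitative ordering the method is
designed to expose. The probability of high risk also climbs steeply with
age (0% in the 30–39 group to 52.1% at 70+) and is several-fold higher in
men than women within every phenotype, with sex reaching the risk category
through the smoking pathway in the learned graph.

The numbered scripts under `analysis/` run the same study end to end
(simulate → phenotype/score → learn → reason), writing tables, arc lists and
DOT graphs under `results/`.

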