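# trajectsim

Discrete-time multistate microsimulation of chronic-disease trajectories
from registry-style follow-up data, with prostate cancer as the worked
disease model.

## The problem

Disease pathways for chronic conditions span decades: a man diagnosed
with prostate cancer may move from active surveillance to surgery, from
surgery to salvage radiotherapy, and eventually to androgen deprivation,
while ageing and accumulating comorbidity all along. Registries record
these pathways as dated events, but predicting them — for counselling,
for planning care capacity — needs a generative model of the whole
trajectory, not a single-endpoint survival curve.

`trajectsim` is for biostatisticians and epidemiological modellers who
want that generative model estimated from registry data and validated
against it. It implements the full pipeline:

1. **State space** — an irreversible directed graph over treatment states
   (`AS`, `WW`, `RP`, `RT`, `RTADJ`, `AA`, `GNRH`), each with an ordinal
   treatment-specific risk category, plus two absorbing death states.
2. **Person-period preparation** — expansion of dated records into
   4-week steps with time-updated age and Charlson comorbidity index
   (CCI), left truncation with delayed entry, and person-level
   train/validation splitting.
3. **Estimation** — per-step transition probabilities: logistic models
   for prostate-cancer death and (conditionally) other-cause death,
   one multinomial destination model per origin state, proportional-odds
   models for the risk category at state entry, and a per-state CCI
   model (logistic any-increase + zero-truncated Poisson increment,
   capped at 3). Masked risk categories at deferred treatments are
   handled by chained-equation multiple imputation with pooling by the
   usual combination rules.
4. **Microsimulation** — an individual-level engine (compiled, with
   counter-based random-number substreams per person-replicate, so
   results are reproducible and order-invariant) advancing each person
   step by step: vital status first, then treatment change (with a
   deterministic age/CCI rule for the undated AS→WW switch), then the
   comorbidity update.
5. **Validation** — discrete-time competing-risks cumulative incidence
   (the Aalen–Johansen estimator,
   `CIF_k(t) = Σ_{s≤t} h_k(s) S(s−1)`) of first and second transitions
   and cause-specific death, observed versus simulated, with landmark
   tables at 10/15/20 years.
6. **Synthetic registry** — because the motivating nationwide registry is
   not redistributable, a generator with fully known ground truth
   emulates its schema and published cohort composition (118,743 men
   across six primary strategies), giving every downstream stage a truth
   oracle.

## Worked example

Generate a synthetic cohort, fit the transition models on one half,
simulate the other half 100 times, and compare observed with simulated
cumulative incidence for men primarily treated with radical
prostatectomy:

```r
library(trajectsim)
g   <- build_default_graph()
cfg <- default_truth_config(n_persons = 4000, seed = 7)
reg <- generate_registry(cfg)
reg
#> <registry: 4000 persons, 3525 events (1877 treatment changes), 3598 deaths>

sp   <- split_train_validation(reg, seed = 7)
fits <- fit_model_set(expand_to_steps(sp$train, g), g)
sim  <- simulate_cohort(entry_table(sp$validation), fits, g,
                        replicates = 100, seed = 8, occupancy = FALSE)

obs <- cuminc_first_transition(expand_to_steps(sp$validation, g), g)
smc <- cuminc_first_transition(sim, g)
compare_curves(obs$RP, smc$RP, landmark_years = c(10, 20))
#> <observed vs simulated: RP>
#> sup-norm differences:
#>       RTADJ          AA        GNRH   PCA_DEATH OTHER_DEATH
#>      0.0130      0.0115      0.0174      0.0199      0.0220
#> landmarks:
#>    years step destination observed simulated difference
#> 1     10  131       RTADJ    0.230     0.229      0.001
#> 2     10  131          AA    0.022     0.019      0.003
#> 3     10  131        GNRH    0.025     0.018      0.008
#> 4     10  131   PCA_DEATH    0.034     0.053     -0.018
#> 5     10  131 OTHER_DEATH    0.168     0.163      0.005
#> 6     20  261       RTADJ    0.308     0.303      0.004
#> 7     20  261          AA    0.034     0.026      0.008
#> 8     20  261        GNRH    0.042     0.026      0.016
#> 9     20  261   PCA_DEATH    0.060     0.079     -0.019
#> 10    20  261 OTHER_DEATH    0.337     0.345     -0.008
```

Reading the landmark table: among validation men whose primary treatment
was RP, 23.0% had moved to adjuvant/salvage radiotherapy within ten
years in the "observed" (generated) data versus 22.9% in the fitted
model's simulation of the same men; by twenty years 30.8% versus 30.3%.
The sup-norm row gives each destination's largest pointwise discrepancy
over the whole 25-year grid; with ~1,000 RP men in the validation half,
differences of a percentage point or two are at the sampling noise floor
(see the methods vignette).

A thin command-line front end over the same functions lives in
`inst/cli/trajectsim.R`:

```sh
Rscript inst/cli/trajectsim.R synth --n 10000 --seed 1 --out registry/
Rscript inst/cli/trajectsim.R fit --registry registry/ --out models.json
Rscript inst/cli/trajectsim.R validate --registry registry/ \
    --models models.json --reps 100 --out report/
```

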