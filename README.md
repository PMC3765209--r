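# minlpselect

Simultaneous selection among **nested dynamic models** and estimation of
their kinetic parameters, cast as a single mixed-integer nonlinear program
(MINLP) and solved with a mixed-integer scatter-search metaheuristic.

## The problem

Hypothesis-driven model refinement in systems biology produces *families*
of candidate models: a maximal superstructure in which binary switches turn
mechanisms (e.g. feedback loops) on or off and integer exponents set
kinetic orders. Fitting each of the — here 1700 — nested candidates
separately and comparing information criteria afterwards is computationally
hopeless for dynamic models. `minlpselect` selects and calibrates in one
step by minimizing the Akaike information criterion

```
AIC(p, q) = -2 Jml(p, q) + 2 Np(q)
```

over the joint decision vector of real kinetic parameters `p` (17, searched
in log10 space) and structural integers `q` (3 binaries + 5 exponents in
0..3), where `Jml` is the Gaussian log-likelihood of time-course data with
known heteroscedastic standard deviations and `Np` counts the decision
variables active under the candidate structure.

The bundled, fully testable case study is the **KdpD/KdpE two-component
system** regulating high-affinity K⁺ uptake in *Escherichia coli*: a
reduced differential-algebraic model (5 ODE states + 2 promoter-binding
algebraic states) with three hypothesized regulation mechanisms —
translation regulation, proteolysis regulation, and two alternative forms
of the stimulus-counteraction feedback. An in-silico data generator
reproduces the study design (wild type and uptake-deficient mutant at
K⁺ ∈ {1, 10, 50, 100, 500} mM, mRNA and KdpFABC observed with 5%
multiplicative noise), so every component is testable without external
data.

Besides the optimizer, the package ships the identifiability toolbox used
to audit a selected model: finite-difference relative sensitivities,
sum-of-squares sensitivity ranking, Fisher-information rank and
correlation analysis, and a likelihood-weighted pseudo-global analysis over
scrambled Sobol' samples of the parameter box.

## Worked example

```r
library(minlpselect)

# the nominal ("true") structure and parameters of the case study
nom <- nominal_parameters()
nom$structure
#> <kdp_structure> bins: 1 1 0  exponents: 3 1 2 3 0

# generate the in-silico dataset (10 experiments, 300 measurements)
dataset <- generate_dataset(generation_protocol(seed = 1))
dplyr::count(dataset, strain, K_mM) |> head(3)
#> # A tibble: 3 x 3
#>   strain  K_mM     n
#>   <chr>  <dbl> <int>
#> 1 mutant     1    30
#> 2 mutant    10    30
#> 3 mutant    50    30

# the AIC at the generating truth (the value a perfect search would beat)
objective_evaluate(nom$structure, nom$parameters, dataset)
#> <objective_value> AIC = -1033.4141 (Jml = 539.7071, Np = 23)

# fit: global scatter search + structure sweep + polish (a few minutes)
fit <- fit_kdp_model(
  dataset,
  settings = scatter_settings(max_eval = 10000, seed = 203,
                              local_freq = 2, local_budget = 1500),
  sweep_repair = 400, polish = 1500)
fit
#> <kdp_fit>
#> <kdp_structure> bins: 1 1 0  exponents: 2 2 2 2 0
#>   AIC = -988.120, Jml = 517.060, Np = 23, mean residual = 4.12%
#>   10000 objective evaluations (seed 203)

glance(fit)
#> # A tibble: 1 x 7
#>     aic logLik n_params residual_pct n_eval  seed feasible
#>   <dbl>  <dbl>    <int>        <dbl>  <int> <int> <lgl>
#> 1 -988.   517.       23         4.12  10000   203 TRUE

tidy(fit, nominal = unclass(nom$parameters))  # parameter table + % deviation
autoplot(fit)               # convergence curve
plot_fit_trajectories(fit)  # data vs fitted time courses

# identifiability audit of the selected structure (here at the generating
# parameter set; the fitted point lies on box bounds along the flat
# likelihood directions discussed in the methods vignette)
S   <- relative_sensitivities(fit$structure, nom$parameters, dataset)
fim <- fisher_information(S)      # log-scale Fisher information
fim_rank(fim)$rank                # rank with explicit tolerance
#> [1] 15
msqr_ranking(S)                   # sensitivity importance ranking
```

The fitted structure has both regulation loops switched on
(`bin1 = bin2 = 1`), matching the generating model, and the mean relative
residual (4.12%) sits at the level implied by the injected 5% noise (the
expected mean absolute relative deviation of the noise alone is
`5·sqrt(2/pi) ≈ 3.99%`; this realization gives 3.80% at the truth).
Well-expressed parameters are recovered closely (`ktr` 8%, `kd` 9%, `kz`
11%, `alpha` 14% deviation), while coordinates on flat likelihood
directions (`k2·ktl2`, `Ka`, `khy`) drift to the box bounds without
degrading the fit — the Fisher rank of 15/16 quantifies exactly this; see
the methods vignette.

A thin command-line wrapper is installed with the package:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/minlpselect.R", package="minlpselect"))') \
  generate --seed 1 --out dataset.csv
```

with subcommands `generate`, `fit`, `analyze`, `enumerate` and `report`
(the last runs the YAML-configured generate→fit→analyze pipeline,
`run_pipeline()`).

## Package layout

- `R/structure.R`, `R/parameters.R` — structure vectors, activity rule,
  enumeration/deduplication of the 1700 nested models, parameter and
  constant containers
- `R/model.R`, `src/kdp.c` — the DAE model core (compiled right-hand side
  with embedded algebraic solver), simulation, pre-stimulus steady states
- `R/objective.R` — datasets, likelihood, AIC, penalty encoding, residuals
- `R/search.R` — mixed-integer scatter search, local refinement with
  move-and-repair, multistart baseline
- `R/fit.R` — the three-phase case-study fit, `tidy`/`glance`/`autoplot`
- `R/identifiability.R`, `R/sobol.R` — sensitivities, FIM, correlation,
  pseudo-global analysis, Sobol' sequence
- `R/synthetic.R` — the in-silico data generator and fixture suite
- `R/pipeline.R`, `inst/cli/minlpselect.R` — YAML pipeline and CLI
- `vignettes/model-selection-minlp.Rmd` — the methods vignette: model
  equations, design decisions, numerical choices, identifiability caveats
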