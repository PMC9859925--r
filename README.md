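# pfasrpf

Benchmark concentrations (BMC) and relative potency factors (RPF) for in
vitro gene-expression endpoints, with the upstream RT-qPCR quantification
that produces them.

## What this is for

Several per- and polyfluoroalkyl substances (PFASs) repress the
recombination-activating genes *RAG1* and *RAG2* in human B-cell lines, an
in vitro correlate of PFAS immunotoxicity. Ranking congeners by potency on
such an endpoint requires more than fitting each compound separately: the
compounds must share a curve shape so that their potencies are comparable.
This package implements that analysis for toxicologists working with
concentration–response data summarised as group means:

* **qPCR stage** — standard-curve relative quantification of Cq values,
  reference-gene (GAPDH) normalization, fold change versus solvent control
  (`fit_standard_curve()`, `quantify()`, `summarize_to_table()`), plus
  WST-1 viability normalization (`viability_percent()`).
* **Modeling stage** — the four-parameter exponential model
  `y = a * c^(1 − exp(−(x/b)^d))` fitted to continuous summary data
  (mean, SD, n per group) under a lognormal likelihood, with independent
  studies as covariates on the background `a` and compounds as covariates
  on the potency `b` ("parallel curves"), selected by AIC
  (`fit_model()`, `select_model()`, `default_candidates()`).
* **Potency stage** — BMC at a 10% benchmark response (CES = −0.1) from the
  model's closed form, 90% profile-likelihood intervals, and RPFs versus an
  index compound (PFOA), with profile intervals on the potency ratio
  (`bmc_closed_form()`, `profile_ci_bmc()`, `rpf_from_fit()`).
* **Synthetic data** — a generator emulating the two-study, triplicate,
  two-fold-grid design of the underlying experiment, at both the
  summary-table and the raw-Cq level (`sim_design()`,
  `simulate_summary_table()`, `simulate_qpcr_experiment()`), so the whole
  pipeline is testable without laboratory data.

Under parallel curves the RPF of compound *i* is `b_index / b_i`, which
equals the BMC ratio at any benchmark response — that invariance is what
justifies a single potency factor per compound.

## Worked example

```r
library(pfasrpf)

design <- sim_design(seed = 11)          # 4 PFASs, 2 studies, triplicates
tab <- simulate_summary_table(design, endpoint = "RAG1")
res <- run_bmd_only(tab, pipeline_config(endpoint = "RAG1", seed = 11))
res
```

```
Benchmark-concentration analysis: RAG1
  candidate   a_by     b_by effect k   loglik       aic
1      null  study compound  FALSE 3 -203.034  412.0681
2    shared shared   shared   TRUE 5  -33.696   77.3921
3  parallel  study compound   TRUE 9  114.779 -211.5580
BMC(PFOA, CES = -0.1): 1.476 uM  [1.213, 1.776] (90% profile CI)
BMC(PFOS, CES = -0.1): 1.972 uM  [1.618, 2.373] (90% profile CI)
BMC(PFNA, CES = -0.1): 0.9821 uM  [0.8062, 1.183] (90% profile CI)
BMC(PFHxS, CES = -0.1): 5.24 uM  [4.313, 6.288] (90% profile CI)
RPF(PFOA) = 1 (index chemical)
RPF(PFOS vs PFOA) = 0.749  [0.675, 0.831] (90% profile CI)
RPF(PFNA vs PFOA) = 1.5  [1.36, 1.67] (90% profile CI)
RPF(PFHxS vs PFOA) = 0.282  [0.254, 0.312] (90% profile CI)
```

Reading this: the parallel-curve configuration wins model selection by a
wide AIC margin (−211.6 against 77.4 for a single shared curve), so
per-compound potencies are supported. Each compound then gets a BMC₁₀ —
the concentration producing a 10% fall in expression from background —
with its 90% profile interval, and an RPF versus PFOA: here PFNA is about
1.5× as potent as PFOA and PFHxS about 0.28×, matching the potency
ordering built into the simulation design (`b` = 9.8, 11.7, 6.1, 31.0 µM
for PFOA, PFOS, PFNA, PFHxS).

The same stages run as a numbered workflow in `analysis/`
(01 simulate → 02 quantify → 03 fit/select → 04 BMC/RPF), writing tables
under `results/`.

## Layout

```
R/                 package code: io_tables, qpcr, model, fit, bmd,
                   simulate, pipeline
analysis/          numbered workflow scripts over the package
scripts/           acceptance.R (end-to-end reproduction)
tests/testthat/    unit, property and acceptance tests
vignettes/         methods vignette (model, likelihood, design choices)
results/           tables written by the workflow scripts
```
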