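---
title: "Benchmark concentrations and relative potency factors for in vitro gene-expression endpoints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmark concentrations and relative potency factors for in vitro gene-expression endpoints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pfasrpf)
```

## The problem

Per- and polyfluoroalkyl substances (PFASs) suppress the antibody response,
and transcriptional readouts in B-cell lines — in particular repression of
the recombination-activating genes *RAG1* and *RAG2* — provide an in vitro
endpoint for ranking the immunotoxic potency of individual congeners. The
analysis this package implements takes RT-qPCR fold-change measurements for
several compounds, fits a joint concentration–response model, and summarises
each compound by a benchmark concentration (BMC) and a relative potency
factor (RPF) against an index chemical (PFOA by convention).

## The model

The concentration–response function is the four-parameter exponential model

$$y = a \, c^{\,1 - \exp(-(x/b)^d)}$$

with $x$ the concentration (µM) and $y$ the response (fold change versus the
solvent control). The parameters have direct interpretations:

* $a$ — background response at $x = 0$ (close to 1 on a fold-change scale);
* $b$ — potency (µM): the horizontal position of the curve;
* $c$ — the plateau as a fold change relative to background; $c < 1$ for a
  decreasing endpoint;
* $d$ — steepness on the log-concentration scale.

The BMC at critical effect size (CES) $q$ is the concentration where the
response reaches $a(1+q)$; for the exponential model it has the closed form

$$\mathrm{BMC} = b\left(-\log\!\left(1 - \frac{\log(1+q)}{\log c}\right)\right)^{1/d},$$

implemented in `bmc_closed_form()`. The default CES is $-0.1$ (a 10%
reduction, BMR₁₀). Because all compounds share $c$ and $d$ in the
parallel-curve configuration, the BMC ratio between two compounds equals
their $b$ ratio and is independent of the chosen CES — this is what makes
the RPF well defined.

## Likelihood for continuous summary data

The fitting input is a summary table: per group (compound × study ×
concentration) the arithmetic mean fold change, its sample SD and the
replicate count, mirroring the tab-delimited layout used by benchmark-dose
software for continuous summary data. Responses are modelled as lognormal
with a log-scale variance $\sigma^2$ shared across all groups
(homoscedastic on the log scale); the model predicts each group's geometric
mean. Reported arithmetic moments are converted to log-scale moments by
lognormal moment matching ($s^2_{\log} = \log(1 + \mathrm{cv}^2)$,
$\mu_{\log} = \log(\bar y) - s^2_{\log}/2$) rather than by taking
$\log(\bar y)$ directly, so the first two reported moments are preserved
exactly. Each group then contributes

$$-\tfrac{n}{2}\log(2\pi\sigma^2) -
  \frac{(n-1)\hat s^2 + n(\hat m - \mu)^2}{2\sigma^2}$$

which equals, up to a parameter-free constant, the log-likelihood of the
raw log-scale replicates — the package's tests verify this identity against
reconstructed raw data.

Choices worth stating explicitly:

* **Shared residual variance.** $\sigma^2$ is common to all compounds,
  studies and concentrations. This is the simplest assumption consistent
  with parallel curves; a per-study variance would add one parameter and is
  not identifiable as cleanly from triplicate groups.
* **Variance concentration.** Given the group means, the MLE of $\sigma^2$
  has closed form $\sum[(n-1)\hat s^2 + n(\hat m - \mu)^2]/\sum n$, so the
  optimizer works on the concentrated likelihood. $\sigma^2$ still counts as
  a free parameter in AIC.
* **Controls.** The solvent control is the $x = 0$ group and enters through
  $\mu = \log a_{\text{study}}$; no log-dose transform is ever applied to
  $x$ itself.

## Fitting and model selection

`fit_model()` maximizes the concentrated likelihood over log-transformed
parameters with L-BFGS-B, an analytic gradient, and box constraints
($d \in [0.1, 10]$, $b \in [10^{-6}, 10^{8}]$ µM, $a$ and $c$ within
$e^{\pm 10}$). The bounds are biologically generous; their real role is to
cut off the well-known degenerate ridge of the exponential model
($c \to 0$, $b \to \infty$ with the product held fixed) on which no
stationary point exists. Convergence is declared when the projected
gradient norm on the log-parameter scale falls below $10^{-6}$; for
noise-free tables, where the concentrated variance collapses to zero and
the likelihood is unbounded, residual collapse (variance below $10^{-12}$)
is accepted as the convergence signal instead.

Starting values are data-driven — background from the control groups,
plateau from the top concentrations, $b_0$ at the median nonzero
concentration, $d_0 = 1$ — and the optimizer is multi-start (10 starts by
default), jittering each coordinate by $\times U(0.5, 2)$ from a seeded
generator, so a fixed seed gives bit-identical fits.

`default_candidates()` compares three covariate configurations by AIC:
the no-effect null (per-study background), the fully shared curve, and the
parallel-curve model with per-compound potency and per-study background.
The study factor acts on $a$ and the compound factor on $b$; this is the
only assignment that both treats independent studies as covariates and
yields per-compound potencies. The candidate list is an argument of
`pipeline_config()`, so other configurations can be screened. Ties in AIC
break toward fewer parameters, then listed order. Because the RPF is only
defined under parallel curves, `run_bmd_only()` always derives RPFs from
the parallel-curve fit and reports the AIC table alongside, so a
non-parallel AIC winner is visible rather than silently overridden.

## Confidence intervals

Both the BMC and the RPF intervals are profile-likelihood intervals at the
$\chi^2_1$ 90% drop ($\mathrm{qchisq}(0.9, 1)/2 \approx 1.353$). For the
BMC, the model is reparameterized so the compound's CED is an explicit
parameter ($b = \mathrm{CED}/f(c, d, q)$ with $f$ the closed-form BMC
factor); for the RPF, with $b_i = b_{\text{index}}/\rho_i$. Endpoints are
located by expansion and monotone bisection on the log scale to a relative
tolerance of $10^{-4}$, warm-starting every constrained refit from the
unconstrained optimum. If the profile fails to drop within three decades of
the estimate, the bound is reported at the search limit with a warning
(one-sided interval). Profile endpoints are invariant to monotone
reparameterization of the profiled quantity; the tests check log-scale
against natural-scale bisection.

## The synthetic-data generator

`sim_design()` / `simulate_summary_table()` emulate the study design the
analysis assumes: four compounds with named true potencies, two independent
studies, triplicate wells, and two-fold concentration grids up to 100 µM
(33 µM for the most potent compound, mirroring the lower cytotoxicity limit
of that congener). Noise is lognormal with a constant natural-scale
coefficient of variation (default 0.15, a typical well-to-well spread for
RT-qPCR fold changes), applied so each group's arithmetic mean sits on the
model curve. The default true potencies
$b = (9.8, 11.7, 6.1, 31.0)$ µM with $c = 0.2$, $d = 1.5$, background 1 are
test-fixture magnitudes for a realistic decreasing endpoint, not estimates
of any real dataset. `simulate_qpcr_experiment()` goes one layer deeper and
emits raw Cq wells plus five-point two-fold dilution series, with Gaussian
Cq measurement noise (SD 0.1 cycles).

The generator draws from the same distributional family the likelihood
assumes. Passing recovery and coverage tests therefore demonstrates
correctness of the estimation machinery under the model's own assumptions —
not robustness to heteroscedasticity, cytotoxic dropout at high
concentrations, plate effects, or non-lognormal noise, none of which are
simulated.

## qPCR quantification

`fit_standard_curve()` regresses Cq on $\log_{10}$(relative dilution) and
reports slope, intercept, $R^2$ and amplification efficiency
$10^{-1/\text{slope}} - 1$. `quantify()` averages technical replicates on
the Cq scale (the conservative convention; the alternative of averaging
back-calculated quantities changes results only at high Cq spread),
back-calculates relative quantities, normalizes the target by the reference
gene (GAPDH), and scales so the solvent-control group mean is exactly 1.
The dilution axis is relative throughout — absolute copy numbers are never
computed, and fold changes are invariant to rescaling the axis per gene.
`viability_percent()` handles the companion WST-1 viability readout
(A450 − A630, percent of solvent-control mean).

## Problem sizes used in the tests

The test-suite simulations use the design above: 64 groups (4 compounds ×
8 concentrations × 2 studies) of triplicates; 50 replicate experiments for
parameter-recovery and AIC-selection checks, and 200 for profile-interval
coverage; 1000 random parameter draws for the closed-form-versus-bisection
property. These sizes give stable pass/fail behaviour for the stochastic
checks while keeping a full run within a few minutes on one core.

## Worked example

```{r example, eval = FALSE}
library(pfasrpf)

design <- sim_design(seed = 11)          # study-like synthetic experiment
tab <- simulate_summary_table(design, endpoint = "RAG1")
res <- run_bmd_only(tab, pipeline_config(endpoint = "RAG1", seed = 11))
res
```

The printed analysis lists the AIC of each candidate configuration, then a
BMC₁₀ with 90% profile interval per compound and the RPFs versus PFOA. The
`analysis/` directory of the source repository runs the same stages as a
numbered workflow (simulate → quantify → fit/select → BMC/RPF) and writes
its tables under `results/`.

## Known limitations

* The profile intervals rely on the asymptotic $\chi^2$ calibration; with
  two studies of triplicates per group the empirical coverage in the
  package's own simulations is close to, but not guaranteed at, the nominal
  90%.
* Covariate configurations beyond {background × study, potency × compound}
  (for example per-study steepness, or per-compound plateau) are not in the
  default candidate list, though the model-spec machinery accepts
  per-compound backgrounds.
* The residual variance is a single shared parameter; strong
  heteroscedasticity across concentrations would bias the weighting.
* Cytotoxicity is handled upstream (concentration grids are chosen below
  overt viability loss); the model itself has no term for dropout.
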