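Package: pfasrpf
Title: Benchmark Concentrations and Relative Potency Factors for PFAS
    Immunotoxicity Endpoints
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Concentration-response analysis of in vitro gene-expression
    endpoints measured by RT-qPCR. Implements standard-curve relative
    quantification with reference-gene normalization, the four-parameter
    exponential concentration-response model fitted to continuous summary
    data under a lognormal likelihood, AIC-based selection among covariate
    configurations, benchmark concentrations (BMC) with profile-likelihood
    confidence intervals, and relative potency factors (RPF) from
    parallel-curve fits against an index chemical. Includes a synthetic-data
    generator emulating the design of a two-study, triplicate-well PFAS
    exposure experiment so that every pipeline stage is testable without
    laboratory data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
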