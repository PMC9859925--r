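#' Configuration for an end-to-end concentration-response analysis
#'
#' @param endpoint Endpoint label (e.g. \code{"RAG1"}).
#' @param index Index compound whose potency is fixed at 1.
#' @param ces Signed critical effect size (default -0.1, a 10\% reduction).
#' @param level Confidence level for all intervals (default 0.90).
#' @param candidates List of [model_spec()] configurations to compare by
#'   AIC; defaults to [default_candidates()].
#' @param seed Integer seed for the optimizer's multi-start jitter.
#' @param out_dir Directory where reports are written (created if needed);
#'   \code{NULL} to skip writing.
#' @return An object of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(endpoint = "RAG1", index = "PFOA", ces = -0.1,
                            level = 0.90, candidates = default_candidates(),
                            seed = 1L, out_dir = NULL) {
  if (ces == 0) stop("ces must be nonzero", call. = FALSE)
  if (level <= 0 || level >= 1)
    stop("confidence level must be in (0, 1)", call. = FALSE)
  structure(list(endpoint = endpoint, index = index, ces = ces,
                 level = level, candidates = candidates,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Benchmark-concentration analysis of a summary table
#'
#' Fits every candidate covariate configuration, selects the one with the
#' lowest AIC, and derives per-compound benchmark concentrations with
#' profile-likelihood intervals plus relative potency factors versus the
#' index compound. If the AIC winner is not the parallel-curve
#' configuration, the parallel-curve fit is still used for the RPF stage
#' (parallel curves are a prerequisite of the RPF definition) and the AIC
#' table records the ranking.
#'
#' @param table A [summary_table()], or a path to a summary TSV.
#' @param config A [pipeline_config()].
#' @return A list of class \code{"bmc_analysis"}: \code{fit} (the
#'   parallel-curve fit used downstream), \code{selected} (the AIC winner),
#'   \code{aic_table} (data.frame of candidate AICs), \code{bmcs},
#'   \code{rpfs}, and \code{report_path} if a report was written.
#' @export
run_bmd_only <- function(table, config = pipeline_config()) {
  if (is.character(table))
    table <- read_summary_table(table, endpoint = config$endpoint)
  stopifnot(inherits(table, "summary_table"),
            inherits(config, "pipeline_config"))
  compounds <- unique(summary_rows(table)$compound)
  if (!config$index %in% compounds)
    stop("index compound '", config$index, "' not found in table",
         call. = FALSE)

  fits <- lapply(config$candidates, function(sp)
    fit_model(table, sp, seed = config$seed))
  selected <- select_model(fits)
  aic_table <- data.frame(
    candidate = if (!is.null(names(fits))) names(fits)
                else seq_along(fits),
    a_by = vapply(fits, function(f) f$spec$a_by, character(1)),
    b_by = vapply(fits, function(f) f$spec$b_by, character(1)),
    effect = vapply(fits, function(f) f$spec$include_effect, logical(1)),
    k = vapply(fits, function(f) f$k, numeric(1)),
    loglik = vapply(fits, function(f) f$loglik, numeric(1)),
    aic = vapply(fits, function(f) f$aic, numeric(1)),
    row.names = NULL
  )
  message("AIC ranking for ", table$endpoint, ": ",
          paste(sprintf("%s=%.2f", aic_table$candidate, aic_table$aic),
                collapse = ", "))

  is_parallel <- vapply(fits, function(f)
    f$spec$include_effect && f$spec$b_by == "compound", logical(1))
  if (!any(is_parallel))
    stop("no parallel-curve candidate (b by compound) among the candidates",
         call. = FALSE)
  par_fit <- fits[is_parallel][[which.max(
    vapply(fits[is_parallel], function(f) f$loglik, numeric(1)))]]

  bmcs <- lapply(compounds, function(cmp)
    profile_ci_bmc(table, par_fit, cmp, ces = config$ces,
                   level = config$level))
  names(bmcs) <- compounds
  rpfs <- rpf_from_fit(table, par_fit, index = config$index,
                       level = config$level)
  res <- structure(list(fit = par_fit, selected = selected,
                        aic_table = aic_table,
                        bmcs = bmcs, rpfs = rpfs[compounds],
                        endpoint = table$endpoint),
                   class = "bmc_analysis")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    path <- file.path(config$out_dir,
                      paste0(table$endpoint, "_bmc_rpf_report.tsv"))
    write_report(par_fit, res$bmcs, res$rpfs, path)
    res$report_path <- path
  }
  res
}

#' @export
print.bmc_analysis <- function(x, ...) {
  cat("Benchmark-concentration analysis:", x$endpoint, "\n")
  print(x$aic_table, digits = 6)
  for (b in x$bmcs) print(b)
  for (r in x$rpfs) print(r)
  invisible(x)
}

#' Full pipeline from raw qPCR wells to benchmark concentrations
#'
#' Runs the quantification stages (standard curves, reference-gene
#' normalization, fold change versus solvent control, grouping into a
#' summary table) and hands the summary table to [run_bmd_only()].
#'
#' @param qpcr Raw experiment as produced by [simulate_qpcr_experiment()]:
#'   a list with \code{records}, \code{dilution_series}, \code{design_map},
#'   \code{control_samples}.
#' @param config A [pipeline_config()].
#' @param target_gene,reference_gene Gene labels within \code{qpcr$records}.
#' @return A \code{"bmc_analysis"} (see [run_bmd_only()]) with the
#'   intermediate \code{summary_table} and \code{curves} attached.
#' @export
run_full <- function(qpcr, config = pipeline_config(),
                     target_gene = "RAG1", reference_gene = "GAPDH") {
  stopifnot(is.list(qpcr),
            all(c("records", "dilution_series", "design_map",
                  "control_samples") %in% names(qpcr)))
  curves <- lapply(stats::setNames(nm = c(target_gene, reference_gene)),
                   function(g)
                     fit_standard_curve(qpcr$dilution_series[[g]], gene = g))
  folds <- quantify(qpcr$records, curves, target_gene, reference_gene,
                    qpcr$control_samples)
  tab <- summarize_to_table(folds, qpcr$design_map,
                            endpoint = config$endpoint)
  res <- run_bmd_only(tab, config)
  res$summary_table <- tab
  res$curves <- curves
  res
}
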