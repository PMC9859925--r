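#' Fit a qPCR standard curve from a serial dilution series
#'
#' Ordinary least squares of Cq on log10(relative dilution). The dilution
#' axis is relative (arbitrary units): only ratios of back-calculated
#' quantities are used downstream, so no absolute copy numbers are implied.
#' Amplification efficiency is \code{10^(-1/slope) - 1}; a perfect two-fold
#' series with Cq increasing one cycle per step gives slope
#' \code{-1/log10(2)} (about -3.32 cycles per log10 unit) and efficiency 1.
#'
#' @param dilutions data.frame with columns \code{dilution} (relative
#'   dilution, > 0) and \code{cq}.
#' @param gene Gene label attached to the curve.
#' @return An object of class \code{"standard_curve"} with fields
#'   \code{gene}, \code{slope}, \code{intercept}, \code{efficiency},
#'   \code{r_squared}.
#' @export
fit_standard_curve <- function(dilutions, gene = "gene") {
  dilutions <- as.data.frame(dilutions)
  stopifnot(all(c("dilution", "cq") %in% names(dilutions)))
  if (length(unique(dilutions$dilution)) < 3L)
    stop("need at least 3 distinct dilutions to fit a standard curve",
         call. = FALSE)
  if (any(dilutions$dilution <= 0))
    stop("dilutions must be positive", call. = FALSE)
  fit <- stats::lm(cq ~ I(log10(dilution)), data = dilutions)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope >= 0)
    stop("invalid standard curve: slope must be negative (got ",
         format(slope), ")", call. = FALSE)
  # R-squared computed directly; summary.lm warns on exactly collinear series
  sst <- sum((dilutions$cq - mean(dilutions$cq))^2)
  ssr <- sum(stats::residuals(fit)^2)
  structure(list(
    gene = gene,
    slope = slope,
    intercept = unname(stats::coef(fit)[1]),
    efficiency = 10^(-1 / slope) - 1,
    r_squared = 1 - ssr / sst
  ), class = "standard_curve")
}

#' Standard-curve relative quantification with reference-gene normalization
#'
#' Back-calculates a relative quantity \code{q = 10^((cq - intercept)/slope)}
#' per measurement from the gene's standard curve, averages technical
#' replicates of the same sample and gene on the Cq scale first, normalizes
#' each sample's target quantity by its reference-gene quantity, and
#' expresses the result as fold change versus the mean normalized quantity of
#' the solvent-control samples (so the control group mean is exactly 1).
#'
#' @param records data.frame with columns \code{sample}, \code{gene},
#'   \code{cq}. Samples outside 10-40 cycles trigger a warning.
#' @param curves Named list of [fit_standard_curve()] objects, one per gene.
#' @param target_gene Gene to quantify.
#' @param reference_gene Reference (housekeeping) gene, e.g. GAPDH.
#' @param control_samples Character vector of solvent-control sample labels.
#' @return data.frame with columns \code{sample}, \code{gene},
#'   \code{normalized_quantity}, \code{fold_change}.
#' @export
quantify <- function(records, curves, target_gene, reference_gene,
                     control_samples) {
  records <- as.data.frame(records)
  stopifnot(all(c("sample", "gene", "cq") %in% names(records)))
  if (any(!is.finite(records$cq)))
    stop("Cq values must be finite", call. = FALSE)
  if (any(records$cq < 10 | records$cq > 40))
    warning("Cq value(s) outside the typical 10-40 cycle range")
  for (g in c(target_gene, reference_gene))
    if (is.null(curves[[g]]))
      stop("no standard curve supplied for gene '", g, "'", call. = FALSE)

  # average technical replicates on the Cq scale
  mean_cq <- function(gene) {
    sub <- records[records$gene == gene, , drop = FALSE]
    tapply(sub$cq, sub$sample, mean)
  }
  cq_t <- mean_cq(target_gene)
  cq_r <- mean_cq(reference_gene)
  samples <- names(cq_t)
  missing_ref <- setdiff(samples, names(cq_r))
  if (length(missing_ref))
    stop("sample(s) missing reference-gene measurements: ",
         paste(missing_ref, collapse = ", "), call. = FALSE)

  q_of <- function(cq, curve) 10^((cq - curve$intercept) / curve$slope)
  q_t <- q_of(cq_t[samples], curves[[target_gene]])
  q_r <- q_of(cq_r[samples], curves[[reference_gene]])
  nq <- q_t / q_r

  ctrl <- intersect(control_samples, samples)
  if (length(ctrl) == 0L)
    stop("control group is empty: no control sample has target-gene data",
         call. = FALSE)
  fold <- nq / mean(nq[ctrl])
  data.frame(sample = samples, gene = target_gene,
             normalized_quantity = unname(nq), fold_change = unname(fold),
             stringsAsFactors = FALSE)
}

#' Percent viability from WST-1 plate absorbances
#'
#' Background-corrects each well (A450 minus A630) and expresses the signal
#' as a percentage of the mean background-corrected signal of the
#' solvent-control wells, so the control group mean is exactly 100.
#'
#' @param plate data.frame with columns \code{sample}, \code{a450},
#'   \code{a630}.
#' @param control_samples Character vector of solvent-control sample labels.
#' @return data.frame with columns \code{sample}, \code{a450}, \code{a630},
#'   \code{percent_viability}.
#' @export
viability_percent <- function(plate, control_samples) {
  plate <- as.data.frame(plate)
  stopifnot(all(c("sample", "a450", "a630") %in% names(plate)))
  signal <- plate$a450 - plate$a630
  ctrl <- plate$sample %in% control_samples
  if (!any(ctrl)) stop("control group is empty", call. = FALSE)
  ctrl_mean <- mean(signal[ctrl])
  if (ctrl_mean <= 0)
    stop("mean control signal is not positive; cannot normalize",
         call. = FALSE)
  plate$percent_viability <- 100 * signal / ctrl_mean
  plate
}

#' Summarize per-well fold changes into a fitting-ready summary table
#'
#' Groups fold changes by (compound, study, concentration) from the plate
#' design and reports the arithmetic mean, sample standard deviation (n-1
#' denominator) and replicate count per group. Singleton groups are emitted
#' with sd = 0 and a warning.
#'
#' @param folds Output of [quantify()] (needs \code{sample},
#'   \code{fold_change}).
#' @param design data.frame mapping \code{sample} to \code{compound},
#'   \code{study}, \code{concentration}.
#' @param endpoint Endpoint label for the resulting table.
#' @return A [summary_table()].
#' @export
summarize_to_table <- function(folds, design, endpoint = "endpoint") {
  folds <- as.data.frame(folds)
  design <- as.data.frame(design)
  stopifnot(all(c("sample", "fold_change") %in% names(folds)),
            all(c("sample", "compound", "study", "concentration") %in%
                  names(design)))
  unmapped <- setdiff(folds$sample, design$sample)
  if (length(unmapped))
    stop("sample(s) not in design: ", paste(unmapped, collapse = ", "),
         call. = FALSE)
  m <- merge(folds, design, by = "sample")
  agg <- stats::aggregate(
    fold_change ~ compound + study + concentration, data = m,
    FUN = function(v) c(mean = mean(v),
                        sd = if (length(v) > 1) stats::sd(v) else 0,
                        n = length(v))
  )
  rows <- data.frame(
    compound = as.character(agg$compound),
    study = as.character(agg$study),
    concentration = agg$concentration,
    mean = agg$fold_change[, "mean"],
    sd = agg$fold_change[, "sd"],
    n = as.integer(agg$fold_change[, "n"]),
    stringsAsFactors = FALSE
  )
  rows <- rows[order(rows$compound, rows$study, rows$concentration), ]
  rownames(rows) <- NULL
  if (any(rows$n == 1L))
    warning("singleton group(s) emitted with sd = 0")
  summary_table(rows, endpoint = endpoint)
}
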