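#' @keywords internal
"_PACKAGE"

# Required columns of a summary table, in canonical order.
.summary_cols <- c("compound", "study", "concentration", "mean", "sd", "n")

#' Construct and validate a concentration-response summary table
#'
#' A summary table holds one row per exposure group: compound, study
#' (independent-experiment identifier), concentration in micromolar, the
#' group's arithmetic mean fold change versus solvent control, its sample
#' standard deviation and the replicate count. The solvent control is encoded
#' as concentration 0. This is the input format for model fitting; it mirrors
#' the tab-delimited layout used by benchmark-dose software for continuous
#' summary data.
#'
#' @param rows A data.frame with columns \code{compound}, \code{study},
#'   \code{concentration}, \code{mean}, \code{sd}, \code{n}.
#' @param endpoint Label for the measured endpoint (e.g. \code{"RAG1"}).
#' @return An object of class \code{"summary_table"}.
#' @export
summary_table <- function(rows, endpoint = "endpoint") {
  rows <- as.data.frame(rows, stringsAsFactors = FALSE)
  .validate_summary_rows(rows)
  structure(list(endpoint = endpoint, rows = rows), class = "summary_table")
}

#' @export
print.summary_table <- function(x, ...) {
  cat("Summary table for endpoint", x$endpoint, "-", nrow(x$rows), "groups,",
      length(unique(x$rows$compound)), "compounds,",
      length(unique(x$rows$study)), "studies\n")
  print(utils::head(x$rows, 10))
  invisible(x)
}

#' Rows of a summary table
#' @param table A \code{summary_table}.
#' @return The underlying data.frame of group records.
#' @export
summary_rows <- function(table) {
  stopifnot(inherits(table, "summary_table"))
  table$rows
}

.validate_summary_rows <- function(rows) {
  missing <- setdiff(.summary_cols, names(rows))
  if (length(missing))
    stop("summary table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (nrow(rows) == 0L)
    stop("summary table must be non-empty", call. = FALSE)
  for (col in c("concentration", "mean", "sd", "n")) {
    v <- rows[[col]]
    if (!is.numeric(v) || anyNA(v))
      stop("column '", col, "' must be numeric with no missing values",
           call. = FALSE)
  }
  bad <- which(rows$mean <= 0)
  if (length(bad))
    stop("mean must be positive (fold-change scale); offending row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  bad <- which(rows$sd < 0)
  if (length(bad))
    stop("sd must be non-negative; offending row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  bad <- which(rows$concentration < 0)
  if (length(bad))
    stop("concentration must be non-negative; offending row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  bad <- which(rows$n < 1 | rows$n != round(rows$n))
  if (length(bad))
    stop("n must be a positive integer; offending row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  key <- paste(rows$compound, rows$study, rows$concentration, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (compound, study, concentration) group(s): row(s) ",
         paste(which(duplicated(key)), collapse = ", "), call. = FALSE)
  for (cmp in unique(rows$compound)) {
    nz <- unique(rows$concentration[rows$compound == cmp &
                                      rows$concentration > 0])
    if (length(nz) < 3L)
      stop("compound '", cmp, "' has fewer than 3 distinct nonzero ",
           "concentrations; potency and steepness are not identifiable",
           call. = FALSE)
  }
  invisible(rows)
}

#' Read a tab-delimited concentration-response summary table
#'
#' Reads a TSV file whose header names the six required columns
#' (\code{compound}, \code{study}, \code{concentration}, \code{mean},
#' \code{sd}, \code{n}; dot decimal separator), validates every row, and
#' returns a [summary_table()]. Row order is preserved.
#'
#' @param path Path to the tab-delimited file.
#' @param endpoint Endpoint label attached to the table.
#' @return A \code{summary_table}.
#' @export
read_summary_table <- function(path, endpoint = "endpoint") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  rows <- tryCatch(
    utils::read.delim(path, header = TRUE, sep = "\t", dec = ".",
                      stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) stop("cannot parse '", path, "' as tab-delimited: ",
                             conditionMessage(e), call. = FALSE)
  )
  if (nrow(rows) == 0L)
    stop("empty summary table file: ", path, call. = FALSE)
  rows$compound <- as.character(rows$compound)
  rows$study <- as.character(rows$study)
  summary_table(rows, endpoint = endpoint)
}

#' Write a summary table to tab-delimited text
#'
#' Serializes with 15 significant digits so that a read/write round trip
#' reproduces the table exactly.
#'
#' @param table A \code{summary_table}.
#' @param path Output path.
#' @export
write_summary_table <- function(table, path) {
  rows <- summary_rows(table)
  out <- rows[, .summary_cols]
  for (col in c("concentration", "mean", "sd"))
    out[[col]] <- formatC(out[[col]], digits = 15, format = "g")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write a benchmark-concentration / relative-potency report
#'
#' Emits a tab-delimited report with one row per compound: the BMC rounded to
#' one decimal, its lower and upper confidence bounds, the RPF rounded to two
#' decimals and its confidence interval. The index compound's RPF prints as
#' exactly \code{1}.
#'
#' @param fit A [fit_model()] result (used for the endpoint/AIC header line).
#' @param bmcs List of BMC estimates from [profile_ci_bmc()].
#' @param rpfs List of RPF estimates from [rpf_from_fit()].
#' @param path Output path.
#' @export
write_report <- function(fit, bmcs, rpfs, path) {
  bmc_cmp <- vapply(bmcs, function(b) b$compound, character(1))
  rpf_cmp <- vapply(rpfs, function(r) r$compound, character(1))
  if (!setequal(bmc_cmp, rpf_cmp))
    stop("BMC and RPF compound sets differ", call. = FALSE)
  index <- rpfs[[1]]$index
  fmt1 <- function(x) formatC(x, format = "f", digits = 1)
  fmt2 <- function(x) formatC(x, format = "f", digits = 2)
  lines <- c(
    paste0("# endpoint: ", fit$endpoint, "\tAIC: ", fmt2(fit$aic),
           "\tindex: ", index),
    paste("compound", "bmc", "bmcl", "bmcu", "rpf", "rpf_ci_low",
          "rpf_ci_high", sep = "\t")
  )
  for (cmp in bmc_cmp) {
    b <- bmcs[[match(cmp, bmc_cmp)]]
    r <- rpfs[[match(cmp, rpf_cmp)]]
    rpf_txt <- if (cmp == index) "1" else fmt2(r$rpf)
    lines <- c(lines, paste(cmp, fmt1(b$ced), fmt1(b$cedl), fmt1(b$cedu),
                            rpf_txt, fmt2(r$ci_low), fmt2(r$ci_high),
                            sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}
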