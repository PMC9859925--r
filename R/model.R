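#' Four-parameter exponential concentration-response function
#'
#' Evaluates \code{y = a * c^(1 - exp(-(x/b)^d))}, the exponential model used
#' for continuous concentration-response data. \code{a} is the background
#' response at concentration zero, \code{b} the potency parameter (same units
#' as \code{x}), \code{c} the plateau expressed as a fold change relative to
#' background (\code{c < 1} gives a decreasing curve), and \code{d} the
#' steepness on the log-concentration scale. At \code{x = 0} the function
#' returns \code{a} exactly; as \code{x} grows it approaches \code{a * c}.
#'
#' @param x Concentration (micromolar), non-negative; vectorized.
#' @param a Background response at concentration zero (> 0).
#' @param b Potency parameter (> 0), micromolar.
#' @param c Plateau ratio relative to background (> 0, != 1 for a real effect).
#' @param d Steepness on the log-concentration scale (> 0).
#' @return Model response, same length as \code{x}.
#' @examples
#' expo_response(0, a = 1, b = 10, c = 0.2, d = 1)    # exactly 1
#' expo_response(1e6, a = 1, b = 10, c = 0.2, d = 1)  # ~ plateau 0.2
#' @export
expo_response <- function(x, a, b, c, d) {
  if (any(x < 0)) stop("concentrations must be non-negative", call. = FALSE)
  if (any(a <= 0) || any(b <= 0) || any(c <= 0) || any(d <= 0))
    stop("parameters a, b, c, d must be positive", call. = FALSE)
  a * c^(1 - exp(-(x / b)^d))
}

#' Convert arithmetic summary statistics to lognormal log-scale moments
#'
#' Moment-matches a lognormal distribution to a reported arithmetic mean and
#' standard deviation. With \code{cv = sd/mean}, the log-scale variance is
#' \code{s2_log = log(1 + cv^2)} and the log-scale mean is
#' \code{mu_log = log(mean) - s2_log/2}, so that the implied lognormal has
#' exactly the given first two arithmetic moments.
#'
#' @param mean Arithmetic group mean (> 0).
#' @param sd Arithmetic group standard deviation (>= 0).
#' @param n Group size (>= 1).
#' @return A list with components \code{mu_log}, \code{s2_log}, \code{n}.
#' @export
arithmetic_to_log_moments <- function(mean, sd, n) {
  if (any(mean <= 0)) stop("mean must be positive", call. = FALSE)
  if (any(sd < 0)) stop("sd must be non-negative", call. = FALSE)
  cv2 <- (sd / mean)^2
  s2 <- log1p(cv2)
  list(mu_log = log(mean) - s2 / 2, s2_log = s2, n = n)
}

# Internal: per-group log-scale moments for a summary table, computed once.
# Returns a data.frame with compound, study, concentration, mu_log, s2_log, n.
.log_moment_frame <- function(table) {
  rows <- summary_rows(table)
  lm <- arithmetic_to_log_moments(rows$mean, rows$sd, rows$n)
  data.frame(
    compound = rows$compound, study = rows$study,
    concentration = rows$concentration,
    mu_log = lm$mu_log, s2_log = lm$s2_log, n = rows$n,
    stringsAsFactors = FALSE
  )
}

#' Construct an exponential-model parameter set
#'
#' Bundles the model parameters used by [loglik_summary()]. \code{a} is a
#' named vector over study labels (or a single unnamed value shared across
#' studies), \code{b} a named vector over compound labels (or a single shared
#' value); \code{c}, \code{d} and the log-scale residual variance
#' \code{log_var} are scalars shared across all groups (parallel curves).
#'
#' @param a Background(s): named numeric by study, or length-1 shared value.
#' @param b Potency(ies): named numeric by compound, or length-1 shared value.
#' @param c Plateau ratio (> 0).
#' @param d Steepness (> 0).
#' @param log_var Log-scale residual variance (> 0), shared across groups.
#' @return An object of class \code{"expo_params"}.
#' @export
expo_params <- function(a, b, c, d, log_var) {
  stopifnot(all(a > 0), all(b > 0), c > 0, d > 0, log_var > 0)
  structure(list(a = a, b = b, c = c, d = d, log_var = log_var),
            class = "expo_params")
}

# Internal: look up a per-level parameter (named vector or shared scalar).
.param_for <- function(vec, level, what) {
  if (length(vec) == 1L && is.null(names(vec))) return(unname(vec))
  if (!level %in% names(vec))
    stop("no ", what, " parameter for level '", level, "'", call. = FALSE)
  unname(vec[[level]])
}

#' Log-likelihood of an exponential-model fit to continuous summary data
#'
#' Computes the lognormal summary-data log-likelihood. Each group (one
#' compound, study and concentration, with reported mean, SD and n) is first
#' converted to log-scale moments (m, s2, n) by lognormal moment matching;
#' the model predicts the group's log-scale mean as
#' \code{mu = log(expo_response(x; a_study, b_compound, c, d))}. The group
#' contributes
#' \deqn{-(n/2) \log(2 \pi \sigma^2) - [(n-1) s^2 + n (m - \mu)^2] / (2 \sigma^2)}
#' with \code{sigma^2 = log_var} shared across groups, and the function
#' returns the sum over all groups. This equals, up to a constant not
#' involving the parameters, the sum of normal log-densities of the raw
#' log-scale replicate values.
#'
#' @param params An [expo_params()] object covering every compound and study
#'   in the table.
#' @param table A summary table (see [read_summary_table()]).
#' @return The log-likelihood (scalar).
#' @export
loglik_summary <- function(params, table) {
  stopifnot(inherits(params, "expo_params"))
  lmf <- .log_moment_frame(table)
  .loglik_from_moments(params, lmf)
}

# Internal workhorse: likelihood from a precomputed moment frame (avoids
# re-deriving moments inside the optimizer's inner loop).
.loglik_from_moments <- function(params, lmf) {
  sigma2 <- params$log_var
  mu <- .predict_mu(params, lmf)
  q <- (lmf$n - 1) * lmf$s2_log + lmf$n * (lmf$mu_log - mu)^2
  sum(-(lmf$n / 2) * log(2 * pi * sigma2) - q / (2 * sigma2))
}

# Internal: model log-scale group means for every row of a moment frame.
.predict_mu <- function(params, lmf) {
  a <- vapply(lmf$study, function(s) .param_for(params$a, s, "background (a)"),
              numeric(1))
  b <- vapply(lmf$compound, function(cmp) .param_for(params$b, cmp, "potency (b)"),
              numeric(1))
  log(a) + log(params$c) * (1 - exp(-(lmf$concentration / b)^params$d))
}

# Internal: closed-form conditional MLE of log_var given group means mu.
.logvar_mle <- function(mu, lmf) {
  sum((lmf$n - 1) * lmf$s2_log + lmf$n * (lmf$mu_log - mu)^2) / sum(lmf$n)
}
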