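#' Closed-form benchmark concentration of the exponential model
#'
#' Solves \code{expo_response(x) = a * (1 + ces)} for \code{x}. With the
#' exponential model the solution is analytic:
#' \deqn{BMC = b \left(-\log\left(1 - \frac{\log(1+ces)}{\log c}\right)\right)^{1/d}}
#' The critical effect size \code{ces} is signed: \code{ces = -0.1} asks for
#' the concentration producing a 10\% reduction from background (the BMR10
#' convention for a decreasing endpoint). The effect must lie on the curve's
#' side (\code{sign(ces) = sign(c - 1)}) and short of the plateau
#' (\code{|log(1+ces)| < |log c|}); the plateau itself is only reached in the
#' limit.
#'
#' @param a Background (unused by the formula; kept for the response check).
#' @param b Potency parameter (> 0), micromolar.
#' @param c Plateau ratio (> 0, != 1).
#' @param d Steepness (> 0).
#' @param ces Signed critical effect size (nonzero fraction).
#' @return The benchmark concentration, micromolar.
#' @export
bmc_closed_form <- function(a, b, c, d, ces) {
  if (ces == 0) stop("ces must be nonzero", call. = FALSE)
  if (c == 1) stop("c = 1: the model has no effect to benchmark",
                   call. = FALSE)
  if (sign(ces) != sign(c - 1))
    stop("direction mismatch: sign(ces) must equal sign(c - 1)",
         call. = FALSE)
  if (abs(log1p(ces)) >= abs(log(c)))
    stop("requested effect size |", ces, "| is at or beyond the plateau ",
         "(c = ", format(c), "); unreachable", call. = FALSE)
  b * (-log(1 - log1p(ces) / log(c)))^(1 / d)
}

# Internal: the dimensionless BMC/b factor, used to tie b to an explicit CED
# during profiling.
.bmc_factor <- function(c, d, ces) {
  arg <- 1 - log1p(ces) / log(c)
  if (!is.finite(arg) || arg <= 0 || arg >= 1) return(NaN)
  (-log(arg))^(1 / d)
}

# Internal: profile log-likelihood machinery shared by the CED and RPF CIs.
# Maximizes the likelihood with one constraint baked into `builder`, warm
# starting from the unconstrained optimum. Returns the profile loglik.
.profile_ll <- function(theta0, builder, env, keep) {
  bounds <- .bounds_free(env)
  res <- .maximize(theta0, builder, env, polish = FALSE,
                   lower = bounds$lower[keep], upper = bounds$upper[keep])
  res$loglik
}

# Internal: find the value v (on one side of vhat) where profile(v) drops
# below target, by expansion then bisection on the log scale.
# side = -1 searches below vhat, +1 above. Relative tolerance 1e-4.
.invert_profile <- function(profile, vhat, llmax, target, side,
                            span = 1e3, rel_tol = 1e-4) {
  inner <- vhat
  outer <- vhat
  found <- FALSE
  for (step in 1:40) {
    outer <- if (side < 0) outer / 2 else outer * 2
    if (outer < vhat / span || outer > vhat * span) break
    if (profile(outer) < target) { found <- TRUE; break }
    inner <- outer
  }
  if (!found) {
    warning("profile log-likelihood did not drop within [",
            format(vhat / span), ", ", format(vhat * span),
            "]; confidence bound is one-sided", call. = FALSE)
    return(if (side < 0) vhat / span else vhat * span)
  }
  lo <- min(inner, outer)
  hi <- max(inner, outer)
  while (hi / lo - 1 > rel_tol) {
    mid <- sqrt(lo * hi)
    ok <- profile(mid) >= target
    # `ok` means mid is inside the confidence region
    if ((side < 0 && ok) || (side > 0 && !ok)) hi <- mid else lo <- mid
  }
  sqrt(lo * hi)
}

#' Profile-likelihood confidence interval for a benchmark concentration
#'
#' Reparameterizes the fitted model so that the chosen compound's benchmark
#' concentration (CED) is an explicit parameter (its potency \code{b} becomes
#' \code{ced / f(c, d, ces)} with \code{f} the analytic BMC factor), profiles
#' the log-likelihood over the CED, and reports the two-sided interval where
#' the profile drops by \code{qchisq(level, 1)/2} from its maximum
#' (1.35277 for a 90\% interval). Bounds are located by monotone bisection to
#' a relative tolerance of 1e-4 on the concentration scale.
#'
#' @param table The [summary_table()] the fit was obtained on.
#' @param fit A converged [fit_model()] result with per-compound potency.
#' @param compound Compound whose CED is profiled.
#' @param ces Signed critical effect size (default -0.1, i.e. BMR10 for a
#'   decreasing endpoint).
#' @param level Confidence level (default 0.90).
#' @return An object of class \code{"bmc_estimate"} with fields
#'   \code{compound}, \code{ces}, \code{ced}, \code{cedl}, \code{cedu},
#'   \code{level}.
#' @export
profile_ci_bmc <- function(table, fit, compound, ces = -0.1, level = 0.90) {
  stopifnot(inherits(fit, "expo_fit"))
  if (!fit$converged) stop("fit did not converge", call. = FALSE)
  if (!fit$spec$include_effect)
    stop("no-effect null has no benchmark concentration", call. = FALSE)
  env <- fit$env
  p <- fit$params
  b_hat <- .param_for(p$b, compound, "potency (b)")
  ced_hat <- bmc_closed_form(1, b_hat, p$c, p$d, ces)
  drop <- stats::qchisq(level, df = 1) / 2

  na <- length(env$a_levels)
  nb <- length(env$b_levels)
  i_cmp <- if (nb == 1L) 1L else match(compound, env$b_levels)
  if (is.na(i_cmp)) stop("compound '", compound, "' not in fit", call. = FALSE)

  # free theta excludes the profiled compound's b slot
  theta_full <- c(log(if (na > 1) p$a[env$a_levels] else p$a),
                  log(if (nb > 1) p$b[env$b_levels] else p$b),
                  log(p$c), log(p$d))
  keep <- setdiff(seq_along(theta_full), na + i_cmp)
  theta0 <- theta_full[keep]

  profile <- function(ced) {
    builder <- function(theta) {
      full <- numeric(na + nb + 2L)
      full[keep] <- theta
      cc <- exp(full[na + nb + 1L])
      dd <- exp(full[na + nb + 2L])
      b <- exp(full[na + seq_len(nb)])
      b[i_cmp] <- ced / .bmc_factor(cc, dd, ces)
      list(a = exp(full[seq_len(na)]), b = b, c = cc, d = dd)
    }
    .profile_ll(theta0, builder, env, keep)
  }

  llmax <- fit$loglik
  target <- llmax - drop
  cedl <- .invert_profile(profile, ced_hat, llmax, target, side = -1)
  cedu <- .invert_profile(profile, ced_hat, llmax, target, side = +1)
  structure(list(compound = compound, ces = ces, ced = ced_hat,
                 cedl = min(cedl, ced_hat), cedu = max(cedu, ced_hat),
                 level = level),
            class = "bmc_estimate")
}

#' @export
print.bmc_estimate <- function(x, ...) {
  cat(sprintf("BMC(%s, CES = %g): %.4g uM  [%.4g, %.4g] (%.0f%% profile CI)\n",
              x$compound, x$ces, x$ced, x$cedl, x$cedu, 100 * x$level))
  invisible(x)
}

#' Relative potency factors from a parallel-curve fit
#'
#' Under parallel curves (shared plateau \code{c} and steepness \code{d},
#' per-compound potency \code{b}) the relative potency factor of compound i
#' versus the index chemical is \code{rpf_i = b_index / b_i}, which equals
#' the ratio of their benchmark concentrations at any effect size. The
#' confidence interval is obtained by profile likelihood on the ratio: the
#' model is reparameterized with \code{b_i = b_index / rho} and \code{rho} is
#' profiled with the same chi-square drop as [profile_ci_bmc()]. The index
#' compound is reported with RPF exactly 1.
#'
#' @param table The [summary_table()] the fit was obtained on.
#' @param fit A converged parallel-curve [fit_model()] result
#'   (\code{b_by = "compound"}).
#' @param index Index compound label (potency fixed at 1).
#' @param level Confidence level (default 0.90).
#' @return Named list of \code{"rpf_estimate"} objects (fields
#'   \code{compound}, \code{index}, \code{rpf}, \code{ci_low},
#'   \code{ci_high}, \code{level}), one per compound, index first.
#' @export
rpf_from_fit <- function(table, fit, index, level = 0.90) {
  stopifnot(inherits(fit, "expo_fit"))
  if (!fit$spec$include_effect || fit$spec$b_by != "compound")
    stop("parallel curves (per-compound b, shared c and d) are required ",
         "to derive RPFs", call. = FALSE)
  env <- fit$env
  if (!index %in% env$b_levels)
    stop("index compound '", index, "' not present in fit", call. = FALSE)
  p <- fit$params
  b_index <- .param_for(p$b, index, "potency (b)")
  drop <- stats::qchisq(level, df = 1) / 2
  na <- length(env$a_levels)
  nb <- length(env$b_levels)
  i_idx <- match(index, env$b_levels)
  theta_full <- c(log(if (na > 1) p$a[env$a_levels] else p$a),
                  log(p$b[env$b_levels]), log(p$c), log(p$d))

  out <- list()
  out[[index]] <- structure(
    list(compound = index, index = index, rpf = 1, ci_low = 1, ci_high = 1,
         level = level),
    class = "rpf_estimate")

  for (cmp in setdiff(env$b_levels, index)) {
    i_cmp <- match(cmp, env$b_levels)
    rpf_hat <- b_index / .param_for(p$b, cmp, "potency (b)")
    keep <- setdiff(seq_along(theta_full), na + i_cmp)
    theta0 <- theta_full[keep]
    profile <- function(rho) {
      builder <- function(theta) {
        full <- numeric(na + nb + 2L)
        full[keep] <- theta
        b <- exp(full[na + seq_len(nb)])
        b[i_cmp] <- b[i_idx] / rho
        list(a = exp(full[seq_len(na)]), b = b,
             c = exp(full[na + nb + 1L]), d = exp(full[na + nb + 2L]))
      }
      .profile_ll(theta0, builder, env, keep)
    }
    target <- fit$loglik - drop
    lo <- .invert_profile(profile, rpf_hat, fit$loglik, target, side = -1)
    hi <- .invert_profile(profile, rpf_hat, fit$loglik, target, side = +1)
    out[[cmp]] <- structure(
      list(compound = cmp, index = index, rpf = rpf_hat,
           ci_low = min(lo, rpf_hat), ci_high = max(hi, rpf_hat),
           level = level),
      class = "rpf_estimate")
  }
  out
}

#' @export
print.rpf_estimate <- function(x, ...) {
  if (x$compound == x$index) {
    cat(sprintf("RPF(%s) = 1 (index chemical)\n", x$compound))
  } else {
    cat(sprintf("RPF(%s vs %s) = %.3g  [%.3g, %.3g] (%.0f%% profile CI)\n",
                x$compound, x$index, x$rpf, x$ci_low, x$ci_high,
                100 * x$level))
  }
  invisible(x)
}
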