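#' Specify a covariate configuration of the exponential model
#'
#' Controls which grouping factor each parameter may depend on. The
#' parallel-curve configuration required for relative potency factors has
#' \code{b_by = "compound"} with the plateau \code{c} and steepness \code{d}
#' shared across compounds; backgrounds may differ by study (studies as
#' covariates). With \code{include_effect = FALSE} the model collapses to the
#' no-effect null \code{y = a}.
#'
#' @param a_by One of \code{"shared"}, \code{"study"}, \code{"compound"}.
#' @param b_by One of \code{"shared"}, \code{"compound"}.
#' @param include_effect If \code{FALSE}, fit the no-effect null.
#' @return An object of class \code{"model_spec"}.
#' @export
model_spec <- function(a_by = c("study", "shared", "compound"),
                       b_by = c("compound", "shared"),
                       include_effect = TRUE) {
  a_by <- match.arg(a_by)
  b_by <- match.arg(b_by)
  structure(list(a_by = a_by, b_by = b_by, c_by = "shared", d_by = "shared",
                 include_effect = include_effect),
            class = "model_spec")
}

#' The default candidate configurations compared by AIC
#'
#' Returns, in fixed order: (1) the no-effect null with per-study
#' backgrounds; (2) the full model with every parameter shared across
#' compounds and studies; (3) the parallel-curve model: potency \code{b} per
#' compound, background \code{a} per study, \code{c} and \code{d} shared.
#' Configuration (3) is the one from which relative potency factors are
#' derived.
#'
#' @return List of [model_spec()] objects, length 3.
#' @export
default_candidates <- function() {
  list(
    null = model_spec(a_by = "study", include_effect = FALSE),
    shared = model_spec(a_by = "shared", b_by = "shared"),
    parallel = model_spec(a_by = "study", b_by = "compound")
  )
}

# ---- internal fitting machinery ---------------------------------------------

# Run expr with a temporarily seeded RNG, restoring global state afterwards.
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# Precompute everything the likelihood needs: log-scale moments plus integer
# maps from rows to background/potency parameter slots.
.fit_env <- function(table, spec) {
  lmf <- .log_moment_frame(table)
  a_levels <- switch(spec$a_by,
                     shared = "(shared)",
                     study = sort(unique(lmf$study)),
                     compound = sort(unique(lmf$compound)))
  b_levels <- switch(spec$b_by,
                     shared = "(shared)",
                     compound = sort(unique(lmf$compound)))
  a_idx <- if (spec$a_by == "shared") rep(1L, nrow(lmf)) else
    match(if (spec$a_by == "study") lmf$study else lmf$compound, a_levels)
  b_idx <- if (spec$b_by == "shared") rep(1L, nrow(lmf)) else
    match(lmf$compound, b_levels)
  list(lmf = lmf, x = lmf$concentration, m = lmf$mu_log, s2 = lmf$s2_log,
       n = lmf$n, N = sum(lmf$n), a_idx = a_idx, b_idx = b_idx,
       a_levels = a_levels, b_levels = b_levels,
       studies = sort(unique(lmf$study)),
       compounds = sort(unique(lmf$compound)))
}

# Concentrated negative log-likelihood given natural-scale parameters.
# pars: list(a = vector over a_levels, b = vector over b_levels, c, d).
# Returns attr "logvar" with the conditional variance MLE.
.conc_negll <- function(pars, env, include_effect = TRUE) {
  la <- log(pars$a)[env$a_idx]
  mu <- if (include_effect) {
    la + log(pars$c) * (1 - exp(-(env$x / pars$b[env$b_idx])^pars$d))
  } else la
  s2hat <- sum((env$n - 1) * env$s2 + env$n * (env$m - mu)^2) / env$N
  if (!is.finite(s2hat)) {
    # overflowed parameter region: steer the optimizer back
    val <- 1e10
    attr(val, "logvar") <- NA_real_
    return(val)
  }
  s2hat <- max(s2hat, 1e-300)  # exact-fit tables (cv = 0) stay finite
  val <- (env$N / 2) * (log(2 * pi * s2hat) + 1)
  attr(val, "logvar") <- s2hat
  val
}

# Analytic gradient of .conc_negll for the unconstrained parameterization
# theta = (log a per level, log b per level, log c, log d). Used both to
# steer BFGS and for the exact convergence check (finite differences are too
# noisy at the 1e-6 gradient tolerance).
.grad_free <- function(theta, env) {
  na <- length(env$a_levels)
  nb <- length(env$b_levels)
  la <- theta[seq_len(na)]
  lb <- theta[na + seq_len(nb)]
  lc <- theta[na + nb + 1L]
  d <- exp(theta[na + nb + 2L])
  b <- exp(lb)[env$b_idx]
  t_log <- ifelse(env$x > 0, log(env$x / b), -Inf)
  u <- ifelse(env$x > 0, exp(d * t_log), 0)
  eu <- exp(-u)
  mu <- la[env$a_idx] + lc * (1 - eu)
  r <- env$m - mu
  s2hat <- max(sum((env$n - 1) * env$s2 + env$n * r^2) / env$N, 1e-300)
  w <- env$n * r / s2hat          # dnegll/dmu_g aggregated weight
  dmu_lb <- -lc * eu * d * u      # per-row d mu / d log b(row)
  dmu_lc <- 1 - eu
  dmu_ld <- ifelse(env$x > 0, lc * eu * d * t_log * u, 0)
  g <- numeric(length(theta))
  for (j in seq_len(na)) g[j] <- -sum(w[env$a_idx == j])
  for (j in seq_len(nb)) {
    rows <- env$b_idx == j
    g[na + j] <- -sum(w[rows] * dmu_lb[rows])
  }
  g[na + nb + 1L] <- -sum(w * dmu_lc)
  g[na + nb + 2L] <- -sum(w * dmu_ld)
  g
}

# Maximize the concentrated likelihood over theta (log-scale free parameters).
# builder(theta) -> natural-scale parameter list for .conc_negll.
# Returns theta, loglik (full, at the conditional variance MLE), logvar,
# gradient norm and convergence flag. With polish = FALSE (profile refits,
# which warm start near the optimum) the nlm pass and the gradient-based
# convergence check are skipped for speed.
.maximize <- function(theta0, builder, env, include_effect = TRUE,
                      maxit = 2000, gradtol = 1e-6, polish = TRUE,
                      grad = NULL, lower = -Inf, upper = Inf) {
  obj <- function(theta) {
    v <- .conc_negll(builder(theta), env, include_effect)
    if (!is.finite(v)) v <- 1e10
    as.numeric(v)
  }
  lower <- rep_len(lower, length(theta0))
  upper <- rep_len(upper, length(theta0))
  theta0 <- pmin(pmax(theta0, lower), upper)
  opt <- stats::optim(theta0, obj, gr = grad, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(maxit = maxit, factr = 10))
  theta <- opt$par
  at_bound <- (theta <= lower + 1e-9) | (theta >= upper - 1e-9)
  if (polish && !any(at_bound)) {
    # L-BFGS-B can stall short of the gradient tolerance; one nlm pass from
    # the interior optimum (with the analytic gradient when available)
    # usually lands it
    obj_nlm <- if (is.null(grad)) obj else function(theta) {
      v <- obj(theta)
      attr(v, "gradient") <- grad(theta)
      v
    }
    pol <- tryCatch(
      stats::nlm(obj_nlm, opt$par, gradtol = 1e-10, steptol = 1e-14,
                 iterlim = 500),
      error = function(e) NULL
    )
    if (!is.null(pol) && pol$minimum <= opt$value) {
      theta <- pmin(pmax(pol$estimate, lower), upper)
      at_bound <- (theta <= lower + 1e-9) | (theta >= upper - 1e-9)
    }
  }
  names(theta) <- names(theta0)
  if (polish) {
    g <- if (is.null(grad)) {
      tryCatch(pracma::grad(obj, theta),
               error = function(e) rep(NA_real_, length(theta)))
    } else grad(theta)
    # projected gradient: components pinned at an active box bound do not
    # count against stationarity
    g_proj <- g
    g_proj[theta <= lower + 1e-9 & g > 0] <- 0
    g_proj[theta >= upper - 1e-9 & g < 0] <- 0
    gnorm <- sqrt(sum(g_proj^2))
    conv <- is.finite(gnorm) && gnorm < gradtol
    # exact-fit data (e.g. noise-free tables) drive the concentrated
    # variance to zero and the likelihood to infinity; there is no interior
    # stationary point, so residual collapse is the convergence signal
    v <- .conc_negll(builder(theta), env, include_effect)
    if (!conv && is.finite(attr(v, "logvar")) && attr(v, "logvar") < 1e-12)
      conv <- TRUE
  } else {
    gnorm <- NA_real_
    conv <- TRUE
  }
  final <- .conc_negll(builder(theta), env, include_effect)
  list(theta = theta, loglik = -as.numeric(final),
       logvar = attr(final, "logvar"),
       grad_norm = gnorm, converged = conv)
}

# Box bounds on the log scale for the free parameterization: backgrounds and
# the plateau within e^+-10 of 1, potency within [1e-6, 1e8] uM, steepness
# within [0.1, 10] (values outside are biologically meaningless and invite
# the c -> 0, b -> Inf likelihood ridge).
.bounds_free <- function(env) {
  na <- length(env$a_levels)
  nb <- length(env$b_levels)
  list(lower = c(rep(-10, na), rep(log(1e-6), nb), -10, log(0.1)),
       upper = c(rep(10, na), rep(log(1e8), nb), 10, log(10)))
}

# Deterministic, data-driven starting values on the log scale.
.init_theta <- function(env, spec) {
  ctrl <- env$x == 0
  mu_ctrl <- if (any(ctrl)) sum(env$n[ctrl] * env$m[ctrl]) / sum(env$n[ctrl])
             else stats::median(env$m)
  a0 <- exp(mu_ctrl)
  top <- env$x >= stats::quantile(env$x[env$x > 0], 0.75)
  mu_top <- sum(env$n[top] * env$m[top]) / sum(env$n[top])
  c0 <- exp(mu_top - mu_ctrl)
  if (abs(log(c0)) < 0.01) c0 <- if (mu_top <= mu_ctrl) 0.8 else 1.25
  b0 <- stats::median(env$x[env$x > 0])
  theta <- c(rep(log(a0), length(env$a_levels)),
             rep(log(b0), length(env$b_levels)),
             log(c0), log(1))
  names(theta) <- c(paste0("a.", env$a_levels), paste0("b.", env$b_levels),
                    "lc", "ld")
  theta
}

# Builder for an unconstrained fit of a given spec.
.builder_free <- function(env) {
  na <- length(env$a_levels)
  nb <- length(env$b_levels)
  function(theta) {
    list(a = exp(theta[seq_len(na)]),
         b = exp(theta[na + seq_len(nb)]),
         c = exp(theta[na + nb + 1L]),
         d = exp(theta[na + nb + 2L]))
  }
}

#' Fit one covariate configuration of the exponential model
#'
#' Maximum-likelihood fit of the exponential concentration-response model to
#' a continuous summary table, with the lognormal summary-data likelihood.
#' All free parameters are optimized on the log scale; the log-scale residual
#' variance is concentrated out analytically (its conditional MLE has closed
#' form), then reported as part of the parameter set and counted among the
#' \code{k} free parameters for AIC. The optimizer is multi-start: the first
#' start uses data-driven initial values (background from the control groups,
#' plateau from the top concentrations, potency from the median nonzero
#' concentration, steepness 1) and the remaining starts jitter each
#' coordinate multiplicatively by U(0.5, 2), seeded for reproducibility.
#'
#' @param table A [summary_table()].
#' @param spec A [model_spec()].
#' @param seed Integer seed controlling the multi-start jitter.
#' @param n_starts Number of optimizer starts (default 10).
#' @return An object of class \code{"expo_fit"}: the model specification, an
#'   [expo_params()] estimate, the maximized log-likelihood, the free
#'   parameter count \code{k}, \code{aic = 2k - 2 loglik}, a convergence
#'   flag, and the number of starts used.
#' @export
fit_model <- function(table, spec, seed = 1L, n_starts = 10L) {
  stopifnot(inherits(table, "summary_table"), inherits(spec, "model_spec"))
  env <- .fit_env(table, spec)

  if (!spec$include_effect) {
    # no-effect null: per-level weighted log-mean and the variance MLE are
    # closed-form; no optimizer needed
    mu_lvl <- vapply(seq_along(env$a_levels), function(i) {
      w <- env$a_idx == i
      sum(env$n[w] * env$m[w]) / sum(env$n[w])
    }, numeric(1))
    mu <- mu_lvl[env$a_idx]
    s2hat <- sum((env$n - 1) * env$s2 + env$n * (env$m - mu)^2) / env$N
    ll <- -(env$N / 2) * (log(2 * pi * s2hat) + 1)
    a <- exp(mu_lvl)
    names(a) <- if (length(a) > 1L) env$a_levels else NULL
    k <- length(a) + 1L
    params <- expo_params(a = a, b = 1, c = 1, d = 1, log_var = s2hat)
    return(structure(list(spec = spec, params = params, loglik = ll, k = k,
                          aic = 2 * k - 2 * ll, converged = TRUE,
                          n_starts_used = 0L, grad_norm = 0,
                          endpoint = table$endpoint, env = env),
                     class = "expo_fit"))
  }

  if (spec$b_by == "compound") {
    for (cmp in env$compounds) {
      nz <- unique(env$x[env$lmf$compound == cmp & env$x > 0])
      if (length(nz) < 3L)
        stop("compound '", cmp, "' has fewer than 3 nonzero concentrations; ",
             "per-compound potency is not identifiable", call. = FALSE)
    }
  }

  theta0 <- .init_theta(env, spec)
  builder <- .builder_free(env)
  jitters <- .with_seed(seed, {
    lapply(seq_len(max(0L, n_starts - 1L)), function(i)
      log(stats::runif(length(theta0), 0.5, 2)))
  })
  starts <- c(list(theta0), lapply(jitters, function(j) theta0 + j))

  best <- NULL
  used <- 0L
  for (s in starts) {
    used <- used + 1L
    bounds <- .bounds_free(env)
    res <- tryCatch(
      .maximize(s, builder, env, grad = function(th) .grad_free(th, env),
                lower = bounds$lower, upper = bounds$upper),
      error = function(e) NULL)
    if (is.null(res) || !res$converged) next
    if (is.null(best) || res$loglik > best$loglik + 1e-9) best <- res
  }
  if (is.null(best))
    stop("no optimizer start converged (", used, " starts); the model may be ",
         "unidentifiable for this table", call. = FALSE)

  pars <- builder(best$theta)
  a <- pars$a
  b <- pars$b
  names(a) <- if (length(a) > 1L) env$a_levels else NULL
  names(b) <- if (length(b) > 1L) env$b_levels else NULL
  k <- length(best$theta) + 1L  # + concentrated log_var
  params <- expo_params(a = a, b = b, c = unname(pars$c), d = unname(pars$d),
                        log_var = best$logvar)
  structure(list(spec = spec, params = params, loglik = best$loglik, k = k,
                 aic = 2 * k - 2 * best$loglik, converged = TRUE,
                 n_starts_used = used, grad_norm = best$grad_norm,
                 endpoint = table$endpoint, env = env),
            class = "expo_fit")
}

#' @export
print.expo_fit <- function(x, ...) {
  cat("Exponential model fit (", x$endpoint, "): ",
      if (x$spec$include_effect) paste0("a by ", x$spec$a_by, ", b by ",
                                        x$spec$b_by)
      else "no-effect null", "\n", sep = "")
  cat("  loglik =", format(x$loglik, digits = 8), " k =", x$k,
      " AIC =", format(x$aic, digits = 8), "\n")
  if (x$spec$include_effect) {
    cat("  b (potency, uM):\n")
    print(round(x$params$b, 4))
    cat("  c =", round(x$params$c, 4), " d =", round(x$params$d, 4),
        " log-var =", signif(x$params$log_var, 4), "\n")
  }
  invisible(x)
}

#' Select the configuration with the lowest AIC
#'
#' Ties are broken toward the smaller parameter count, then toward the
#' earlier position in the list.
#'
#' @param fits Non-empty list of [fit_model()] results on the same table.
#' @return The winning \code{expo_fit}.
#' @export
select_model <- function(fits) {
  if (length(fits) == 0L) stop("no fits to select from", call. = FALSE)
  aic <- vapply(fits, function(f) f$aic, numeric(1))
  k <- vapply(fits, function(f) f$k, numeric(1))
  ord <- order(aic, k, seq_along(fits))
  fits[[ord[1L]]]
}
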