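test_that("the closed-form BMC matches an independent bisection oracle", {
  # frozen spot value (high-precision evaluation of the root of
  # expo_response(x) = 0.9 at a = 1, b = 10, c = 0.2, d = 1)
  expect_equal(bmc_closed_form(1, 10, 0.2, 1, -0.1), 0.677053105009923,
               tolerance = 1e-12)
  set.seed(123)
  for (i in 1:200) {
    a <- runif(1, 0.5, 2)
    b <- exp(runif(1, log(0.1), log(100)))
    d <- runif(1, 0.4, 4)
    decreasing <- runif(1) < 0.5
    c <- if (decreasing) runif(1, 0.05, 0.8) else runif(1, 1.25, 5)
    ces_max <- abs(expm1(log(c)))  # effect at the plateau
    ces <- sign(c - 1) * runif(1, 0.02, 0.9) * min(ces_max, 0.9)
    x <- bmc_closed_form(a, b, c, d, ces)
    expect_equal(x, bmc_bisection_oracle(a, b, c, d, ces),
                 tolerance = 1e-8)
    # the defining equation holds to near machine precision
    expect_equal(expo_response(x, a, b, c, d), a * (1 + ces),
                 tolerance = 1e-10)
  }
})

test_that("BMC scales linearly in b and rejects unreachable or misdirected effects", {
  x1 <- bmc_closed_form(1, 10, 0.2, 1.5, -0.1)
  x2 <- bmc_closed_form(1, 20, 0.2, 1.5, -0.1)
  expect_equal(x2, 2 * x1, tolerance = 1e-12)
  expect_error(bmc_closed_form(1, 10, 0.2, 1, -0.8), "unreachable")
  expect_error(bmc_closed_form(1, 10, 0.2, 1, 0.2 - 1), "unreachable")
  expect_error(bmc_closed_form(1, 10, 0.2, 1, 0.1), "direction")
  expect_error(bmc_closed_form(1, 10, 1.5, 1, -0.1), "direction")
  expect_error(bmc_closed_form(1, 10, 0.2, 1, 0), "nonzero")
})

test_that("profile CI brackets the estimate and narrows with less noise", {
  spec <- model_spec(a_by = "study", b_by = "compound")
  tab_hi <- simulate_summary_table(sim_design(cv = 0.15, seed = 21))
  fit_hi <- fit_model(tab_hi, spec, seed = 21)
  ci_hi <- profile_ci_bmc(tab_hi, fit_hi, "PFOA")
  expect_lte(ci_hi$cedl, ci_hi$ced)
  expect_gte(ci_hi$cedu, ci_hi$ced)
  expect_equal(ci_hi$ced,
               bmc_closed_form(1, fit_hi$params$b[["PFOA"]],
                               fit_hi$params$c, fit_hi$params$d, -0.1),
               tolerance = 1e-12)
  tab_lo <- simulate_summary_table(sim_design(cv = 0.015, seed = 21))
  fit_lo <- fit_model(tab_lo, spec, seed = 21)
  ci_lo <- profile_ci_bmc(tab_lo, fit_lo, "PFOA")
  expect_lt(ci_lo$cedu - ci_lo$cedl, ci_hi$cedu - ci_hi$cedl)
})

test_that("profile endpoints sit at the chi-square drop of the profile likelihood", {
  tab <- simulate_summary_table(sim_design(seed = 31))
  fit <- fit_model(tab, model_spec(a_by = "study", b_by = "compound"),
                   seed = 31)
  ci <- profile_ci_bmc(tab, fit, "PFNA")
  drop <- qchisq(0.90, 1) / 2
  # refit with the CED pinned at each endpoint: the loglik deficit vs the
  # unconstrained maximum must equal the drop (to bisection tolerance)
  pin <- function(ced) {
    env <- fit$env
    p <- fit$params
    na <- length(env$a_levels); nb <- length(env$b_levels)
    i_cmp <- match("PFNA", env$b_levels)
    theta_full <- c(log(p$a[env$a_levels]), log(p$b[env$b_levels]),
                    log(p$c), log(p$d))
    keep <- setdiff(seq_along(theta_full), na + i_cmp)
    builder <- function(theta) {
      full <- numeric(na + nb + 2L); full[keep] <- theta
      cc <- exp(full[na + nb + 1L]); dd <- exp(full[na + nb + 2L])
      b <- exp(full[na + seq_len(nb)])
      b[i_cmp] <- ced / pfasrpf:::.bmc_factor(cc, dd, -0.1)
      list(a = exp(full[seq_len(na)]), b = b, c = cc, d = dd)
    }
    pfasrpf:::.maximize(theta_full[keep], builder, env, polish = FALSE)$loglik
  }
  expect_equal(fit$loglik - pin(ci$cedl), drop, tolerance = 2e-3)
  expect_equal(fit$loglik - pin(ci$cedu), drop, tolerance = 2e-3)
})

test_that("CED ratios equal potency ratios under parallel curves, for every effect size", {
  tab <- simulate_summary_table(sim_design(seed = 41))
  fit <- fit_model(tab, model_spec(a_by = "study", b_by = "compound"),
                   seed = 41)
  b <- fit$params$b
  for (ces in c(-0.05, -0.1, -0.2)) {
    ced <- vapply(names(b), function(cmp)
      bmc_closed_form(1, b[[cmp]], fit$params$c, fit$params$d, ces),
      numeric(1))
    expect_equal(unname(ced[["PFOA"]] / ced),
                 unname(b[["PFOA"]] / b), tolerance = 1e-10)
  }
  # random parameter sets, not just fitted ones
  set.seed(7)
  for (i in 1:20) {
    c0 <- runif(1, 0.05, 0.8); d0 <- runif(1, 0.5, 3)
    b1 <- exp(runif(1, 0, 4)); b2 <- exp(runif(1, 0, 4))
    ces <- -runif(1, 0.02, 0.5 * -expm1(log(c0)))
    r <- bmc_closed_form(1, b1, c0, d0, ces) / bmc_closed_form(1, b2, c0, d0, ces)
    expect_equal(r, b1 / b2, tolerance = 1e-10)
  }
})

test_that("RPF estimates are sane: index at 1, CI covers equal-potency truths", {
  tab <- simulate_summary_table(sim_design(
    b = c(PFOA = 10, PFOS = 10, PFNA = 5, PFHxS = 30), seed = 51))
  fit <- fit_model(tab, model_spec(a_by = "study", b_by = "compound"),
                   seed = 51)
  rpfs <- rpf_from_fit(tab, fit, index = "PFOA")
  expect_identical(rpfs$PFOA$rpf, 1)
  expect_identical(rpfs$PFOA$ci_low, 1)
  # profile endpoints sit at the chi-square drop: refit with the ratio
  # pinned at each bound and compare the log-likelihood deficit
  pin_rho <- function(rho) {
    env <- fit$env
    p <- fit$params
    na <- length(env$a_levels); nb <- length(env$b_levels)
    i_idx <- match("PFOA", env$b_levels)
    i_cmp <- match("PFOS", env$b_levels)
    theta_full <- c(log(p$a[env$a_levels]), log(p$b[env$b_levels]),
                    log(p$c), log(p$d))
    keep <- setdiff(seq_along(theta_full), na + i_cmp)
    builder <- function(theta) {
      full <- numeric(na + nb + 2L); full[keep] <- theta
      b <- exp(full[na + seq_len(nb)])
      b[i_cmp] <- b[i_idx] / rho
      list(a = exp(full[seq_len(na)]), b = b,
           c = exp(full[na + nb + 1L]), d = exp(full[na + nb + 2L]))
    }
    pfasrpf:::.maximize(theta_full[keep], builder, env, polish = FALSE)$loglik
  }
  drop <- qchisq(0.9, 1) / 2
  expect_equal(fit$loglik - pin_rho(rpfs$PFOS$ci_low), drop, tolerance = 2e-3)
  expect_equal(fit$loglik - pin_rho(rpfs$PFOS$ci_high), drop, tolerance = 2e-3)
  for (r in rpfs) {
    expect_lte(r$ci_low, r$rpf)
    expect_gte(r$ci_high, r$rpf)
  }
  # point estimates are the potency ratios
  expect_equal(rpfs$PFNA$rpf, fit$params$b[["PFOA"]] / fit$params$b[["PFNA"]],
               tolerance = 1e-12)
  # non-parallel fits are rejected
  shared <- fit_model(tab, model_spec(a_by = "shared", b_by = "shared"),
                      seed = 51)
  expect_error(rpf_from_fit(tab, shared, index = "PFOA"), "[Pp]arallel")
  expect_error(rpf_from_fit(tab, fit, index = "nope"), "index")
})

test_that("true 2:1 potency ratio is recovered as RPF 0.5 at moderate noise", {
  tab <- simulate_summary_table(sim_design(
    b = c(IDX = 10, HALF = 20, X = 15, Y = 8), cv = 0.10, seed = 61))
  fit <- fit_model(tab, model_spec(a_by = "study", b_by = "compound"),
                   seed = 61)
  rpfs <- rpf_from_fit(tab, fit, index = "IDX")
  expect_equal(rpfs$HALF$rpf, 0.5, tolerance = 0.15)
})

test_that("profile endpoints are invariant to the bisection search scale", {
  # bisect on the natural scale instead of the log scale: endpoints agree
  # to the stated relative tolerance
  tab <- simulate_summary_table(sim_design(seed = 71))
  fit <- fit_model(tab, model_spec(a_by = "study", b_by = "compound"),
                   seed = 71)
  ci <- profile_ci_bmc(tab, fit, "PFOA")
  env <- fit$env
  p <- fit$params
  na <- length(env$a_levels); nb <- length(env$b_levels)
  i_cmp <- match("PFOA", env$b_levels)
  theta_full <- c(log(p$a[env$a_levels]), log(p$b[env$b_levels]),
                  log(p$c), log(p$d))
  keep <- setdiff(seq_along(theta_full), na + i_cmp)
  profile <- function(ced) {
    builder <- function(theta) {
      full <- numeric(na + nb + 2L); full[keep] <- theta
      cc <- exp(full[na + nb + 1L]); dd <- exp(full[na + nb + 2L])
      b <- exp(full[na + seq_len(nb)])
      b[i_cmp] <- ced / pfasrpf:::.bmc_factor(cc, dd, -0.1)
      list(a = exp(full[seq_len(na)]), b = b, c = cc, d = dd)
    }
    pfasrpf:::.maximize(theta_full[keep], builder, env, polish = FALSE)$loglik
  }
  target <- fit$loglik - qchisq(0.9, 1) / 2
  # natural-scale bisection
  nat_bisect <- function(lo, hi, inside_lo) {
    while ((hi - lo) / lo > 1e-5) {
      mid <- (lo + hi) / 2
      ok <- profile(mid) >= target
      if (ok == inside_lo) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  cedl_nat <- nat_bisect(ci$ced / 10, ci$ced, inside_lo = FALSE)
  cedu_nat <- nat_bisect(ci$ced, ci$ced * 10, inside_lo = TRUE)
  expect_equal(cedl_nat, ci$cedl, tolerance = 5e-4)
  expect_equal(cedu_nat, ci$cedu, tolerance = 5e-4)
})
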