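test_that("estimate_shift is the largest integer strictly below the data", {
  expect_equal(estimate_shift(c(11.56, 15.19, 22.5)), 11)
  expect_equal(estimate_shift(c(3.0, 4.5)), 2)
  expect_equal(estimate_shift(c(4.0, 5.0)), 3)  # strict at integers
  expect_equal(estimate_shift(0.2), 0)
})

test_that("imputation recovers generating branches and matches brute force", {
  p <- toy_map()
  # m = 2, one double, noise-free data on known branches (low, high)
  z_true <- c(X = 0.5, Y = 1.8)
  w_s <- gamma_fitness(p, z_true)
  w_d <- stats::setNames(gamma_fitness(p, sum(z_true)), "XY")
  pairs <- cbind(first = "X", second = "Y")
  imp <- impute_phenotypes(p, w_s, pairs, w_d)
  expect_equal(imp$branch, c(X = "low", Y = "high"))
  expect_equal(imp$z, z_true, tolerance = 1e-7)
  expect_lt(imp$sse_doubles, 1e-12)

  # all four branch combinations enumerated by an independent loop
  bf <- brute_force_branches(p, w_s, pairs, w_d)
  expect_equal(imp$z, bf$z, tolerance = 1e-12)

  # singles at the peak: unique double-root assignment
  w_peak <- stats::setNames(rep(10, 2), c("X", "Y"))
  ip <- impute_phenotypes(p, w_peak, pairs,
                          stats::setNames(gamma_fitness(p, 2), "XY"))
  expect_equal(unname(ip$z), c(1, 1))

  # m = 9 fixture-scale enumeration equals the independent re-enumeration
  fit <- fixture_fit()
  data <- fit_input(fixture_effects())
  imp9 <- impute_phenotypes(fit$params, data$w_singles, data$pairs,
                            data$w_doubles)
  bf9 <- brute_force_branches(fit$params, data$w_singles, data$pairs,
                              data$w_doubles)
  expect_equal(imp9$z, bf9$z, tolerance = 1e-12)

  # infeasible single clamps to the mode and is flagged
  w_hi <- stats::setNames(c(10.5, 8), c("X", "Y"))
  cl <- impute_phenotypes(p, w_hi, pairs,
                          stats::setNames(6, "XY"))
  expect_true(cl$clamped[["X"]])
  expect_equal(unname(cl$z["X"]), 1)
})

test_that("curve step never worsens the SSE and flags degenerate input", {
  p <- toy_map()
  z <- c(X = 0.5, Y = 1.8)
  w_s <- gamma_fitness(p, z) + c(0.2, -0.1)
  w_d <- stats::setNames(gamma_fitness(p, sum(z)) + 0.15, "XY")
  pairs <- cbind(first = "X", second = "Y")
  entry <- sum((w_s - gamma_fitness(p, z))^2) +
    (w_d - gamma_fitness(p, sum(z)))^2
  st <- fit_curve_given_z(p, z, w_s, w_d, pairs)
  expect_lte(st$sse, entry)
  expect_false(st$degenerate)

  expect_warning(
    dg <- fit_curve_given_z(p, z["X"], w_s["X"], w_d[0], pairs[0, , drop = FALSE]),
    "degenerate")
  expect_true(dg$degenerate)
})

test_that("diagnostics decompose sums of squares with the df counting rule", {
  obs <- c(1, 2, 3, 4, 6)
  d0 <- compute_diagnostics(obs, obs, m = 1)
  expect_equal(d0$sse, 0)
  expect_equal(d0$r_squared, 1)

  dg <- compute_diagnostics(obs, rep(mean(obs), 5), m = 1)
  expect_equal(dg$r_squared, 0)

  fit <- fixture_fit()
  d <- fit$diagnostics
  expect_equal(d$df_sse, 15L)   # N = 27, m = 9: 27 - 9 - 3
  expect_equal(d$df_sst, 26L)
  expect_equal(d$df_ssm, 11L)
  expect_equal(d$sst, d$sse + d$ssm, tolerance = 1e-6)
  expect_equal(d$df_sst, d$df_sse + d$df_ssm)
  expect_gte(d$r_squared, 0)
  expect_lte(d$r_squared, 1)

  expect_warning(compute_diagnostics(c(2, 2), c(2, 2), m = 1), "undefined")
})

test_that("noise-free synthetic data are recovered essentially exactly", {
  fit <- noisefree_fit()
  cfg <- generator_config(noise_sd = 0)
  expect_gte(fit$diagnostics$r_squared, 0.999)
  expect_lt(max(abs(fit$residuals)), 1e-4)
  expect_equal(fit$settings$shift, cfg$params$shift)
  expect_equal(fit$params$shape, cfg$params$shape, tolerance = 1e-3)
  expect_equal(unname(fit$phenotypes$z), unname(cfg$z_singles),
               tolerance = 1e-3)
})

test_that("the SSE trace is non-increasing and noise degrades the fit", {
  fit <- fixture_fit()
  expect_true(all(diff(fit$sse_trace) <= 1e-9))
  expect_true(all(diff(noisefree_fit()$sse_trace) <= 1e-9))

  noisy <- effect_table(
    summarize_assays(generate_assays(generator_config(noise_sd = 1.2),
                                     seed = 7)))
  fit_noisy <- fit_gamma_map(noisy)
  expect_lt(fit_noisy$diagnostics$r_squared,
            noisefree_fit()$diagnostics$r_squared)
  expect_gt(fit_noisy$diagnostics$r_squared, 0.5)
})

test_that("fixture fit is strong and rejects the independence null", {
  fit <- fixture_fit()
  d <- fit$diagnostics
  expect_gte(d$r_squared, 0.75)
  expect_lt(d$p, 0.05)
  rep_tab <- fit_report(fit)
  expect_equal(nrow(rep_tab), 27L)
  expect_equal(rep_tab$observed - rep_tab$predicted, rep_tab$residual,
               tolerance = 1e-12)
})
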