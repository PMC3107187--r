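test_that("effect-distribution draws are uniform at kappa = -1", {
  cfg <- effect_distribution_config(0, 1)
  x <- draw_single_effects(cfg, m = 4000, seed = 9)
  expect_true(all(x >= 0 & x <= 1))
  mc_se <- sqrt(1 / 12 / 4000)
  expect_lt(abs(mean(x) - 0.5), 3 * mc_se)

  # seeded determinism
  expect_identical(draw_single_effects(cfg, 9, seed = 4),
                   draw_single_effects(cfg, 9, seed = 4))

  # general negative shape keeps the support
  cfg2 <- effect_distribution_config(2, 5, kappa = -0.5)
  y <- draw_single_effects(cfg2, 2000, seed = 2)
  expect_true(all(y >= 2 & y <= 5))

  expect_error(effect_distribution_config(1, 0), "lower")
  expect_error(effect_distribution_config(0, 1, kappa = 0.2), "unbounded")
})

test_that("fixture-calibrated bounds equal the extreme single fitnesses", {
  eff <- fixture_effects()
  singles <- eff[eff$type == "single", ]
  expect_equal(min(singles$effect), 1.42)  # I
  expect_equal(max(singles$effect), 5.84)  # G
  expect_equal(min(singles$mean), 15.19 + 1.42, tolerance = 1e-9)
  expect_equal(max(singles$mean), 15.19 + 5.84, tolerance = 1e-9)
})

test_that("gamma-map simulator honors shape, determinism and sign pattern", {
  fit <- fixture_fit()
  one <- simulate_gamma_epsilons(fit, reps = 1, seed = 1)
  expect_equal(dim(one$eps), c(1L, 18L))
  expect_equal(colnames(one$eps), epsilon_table(fixture_effects())$pair)

  a <- simulate_gamma_epsilons(fit, reps = 50, seed = 8)
  b <- simulate_gamma_epsilons(fit, reps = 50, seed = 8)
  expect_identical(a$eps, b$eps)

  sim <- fixture_compare()$sim_gamma
  expect_equal(sim$reps, 1000L)
  expect_lt(mean(sim$eps), 0)

  # zero error, both mutations on the low branch of a toy map near the
  # rising limb: epsilon checked against direct curve arithmetic
  p <- toy_map()
  z1 <- 0.3; z2 <- 0.4
  w_wt <- gamma_fitness(p, 0.1)
  eps_direct <- gamma_fitness(p, z1 + z2) - gamma_fitness(p, z1) -
    gamma_fitness(p, z2) + w_wt
  expect_equal(eps_direct,
               epsilon(gamma_fitness(p, z1 + z2) - w_wt,
                       gamma_fitness(p, z1) - w_wt,
                       gamma_fitness(p, z2) - w_wt))
})

test_that("geometric model satisfies its constraints exactly", {
  cfg <- geometric_model_config(w_max = 21.03, w_wt = 15.19, floor = 11,
                                w_min_single = 16.61)
  expect_equal(geometric_fitness(cfg, c(0, 0)), 21.03)   # optimum
  expect_equal(geometric_fitness(cfg, c(1, 0)), 15.19)   # wild type, exact
  expect_equal(geometric_fitness(cfg, c(0, 1)), 15.19)   # any direction
  # strictly decreasing in distance, floor as distance grows
  d <- seq(0, 6, by = 0.1)
  f <- geometric_fitness(cfg, cbind(d, 0))
  expect_true(all(diff(f) < 0))
  expect_equal(f[length(f)], 11, tolerance = 1e-3)
  # sampling contour: fitness at r_sample equals the smallest single fitness
  expect_equal(geometric_fitness(cfg, c(cfg$r_sample, 0)), 16.61)
  # zero-displacement mutations give zero epsilon by construction
  p_wt <- c(1, 0)
  expect_equal(geometric_fitness(cfg, p_wt) - 2 * geometric_fitness(cfg, p_wt) +
                 geometric_fitness(cfg, p_wt), 0)

  expect_error(geometric_model_config(21, 15, 11, w_min_single = 22),
               "smallest single")

  sim <- fixture_compare()$sim_geometric
  expect_lt(mean(sim$eps), 0)
  a <- simulate_geometric_epsilons(cfg, reps = 20, seed = 3)
  b <- simulate_geometric_epsilons(cfg, reps = 20, seed = 3)
  expect_identical(a$eps, b$eps)
  expect_equal(dim(a$eps), c(20L, 18L))
})

test_that("geometric model predicts the heavier antagonistic tail", {
  cmp <- fixture_compare()
  q_gamma <- stats::quantile(cmp$sim_gamma$eps, 0.05)
  q_geo <- stats::quantile(cmp$sim_geometric$eps, 0.05)
  expect_lt(q_geo, q_gamma)
  expect_lt(mean(cmp$sim_geometric$eps), mean(cmp$sim_gamma$eps))
})

test_that("histogram log-likelihood matches the uniform-density oracle", {
  set.seed(31)
  sim <- structure(list(model = "toy",
                        eps = matrix(runif(20000), nrow = 1000),
                        reps = 1000L, n_redraw = 0L),
                   class = "epsilon_distribution")
  ll <- histogram_loglik(sim, observed = 0.5)
  expect_equal(ll$lnl, 0, tolerance = 0.15)  # log density of U(0,1) at 0.5
  expect_equal(ll$n_floored, 0L)

  # value outside the simulated support uses the floor and is counted
  ll2 <- histogram_loglik(sim, observed = c(0.5, 5))
  expect_equal(ll2$n_floored, 1L)
  bw <- diff(ll2$breaks)[1L]
  expect_equal(ll2$lnl - ll$lnl, log(1 / (20000 * bw)), tolerance = 0.2)

  expect_error(histogram_loglik(structure(list(eps = matrix(1, 2, 2)),
                                          class = "epsilon_distribution"),
                                0.5),
               "1000")
})

test_that("AIC bookkeeping is exact", {
  a <- aic_compare(-40, -40)
  expect_equal(a$aic_gamma, 2 * 14 - 2 * (-40))
  expect_equal(a$aic_geometric, 2 * 2 - 2 * (-40))
  expect_equal(a$delta_aic, 24)                    # equal lnL: 2 * (14 - 2)
  expect_equal(a$k_gamma - a$k_geometric, 12L)

  tie <- aic_compare(-30, -42)                      # 12 lnL improvement
  expect_equal(tie$delta_aic, 0)
  expect_match(tie$verdict, "equally")
})
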