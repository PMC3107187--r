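test_that("epsilon and the additive expectation reproduce printed rows", {
  expect_equal(epsilon(3.47, 3.89, 4.15), -4.57)
  expect_equal(epsilon(-3.62, 4.18, 1.65), -9.45)
  expect_equal(epsilon(5.0, 2.0, 3.0), 0)
  expect_equal(additive_expectation(4.15, 5.84), 9.99)
  expect_equal(additive_expectation(0, 0), 0)
})

test_that("epsilon is symmetric and vanishes at the additive expectation", {
  set.seed(1)
  for (i in 1:50) {
    a <- runif(1, -10, 10)
    b <- runif(1, -10, 10)
    expect_equal(epsilon(additive_expectation(a, b), a, b), 0)
    s <- runif(1, -10, 10)
    expect_equal(epsilon(s, a, b), epsilon(s, b, a))
  }
})

test_that("epsilon_table reproduces the printed epistasis columns", {
  et <- epsilon_table(fixture_effects())
  expect_equal(nrow(et), 18L)
  expect_equal(stats::setNames(et$epsilon, et$pair), printed_epsilon,
               tolerance = 1e-8)
  expect_equal(stats::setNames(et$additive, et$pair), printed_additive,
               tolerance = 1e-8)
  # background-specific effects; printed Delta columns carry 0.01 rounding
  expect_equal(et$delta_bg_i[et$pair == "EI"], -4.09)
  expect_equal(et$delta_bg_i[et$pair == "AB"], -0.42)
  expect_equal(et$delta_bg_j[et$pair == "AB"], -0.68, tolerance = 0.011)
  # identity: delta_bg_i - delta_bg_j = s_j - s_i
  expect_equal(et$delta_bg_i - et$delta_bg_j, et$s_j - et$s_i,
               tolerance = 1e-12)

  one <- data.frame(genotype = c("W", "X", "Y", "XY"),
                    type = c("wild_type", "single", "single", "double"),
                    n = 2, mean = c(0, 1, 1, 1), se = NA,
                    effect = c(0, 1, 1, 1),
                    first = c(NA, NA, NA, "X"), second = c(NA, NA, NA, "Y"))
  expect_equal(epsilon_table(one)$epsilon, -1)
})

test_that("mean_epsilon_test matches the hand-summed fixture mean", {
  et <- epsilon_table(fixture_effects())
  mt <- mean_epsilon_test(et)
  expect_equal(mt$mean, -81.34 / 18, tolerance = 1e-8)
  expect_equal(mt$df, 17L)
  expect_lt(mt$p, 1e-6)  # additivity easily rejected

  z <- mean_epsilon_test(rep(0, 5))
  expect_equal(z$mean, 0)
  expect_equal(z$t, 0)

  d <- mean_epsilon_test(rep(-1, 4))
  expect_true(d$degenerate)
  expect_true(is.na(d$p))

  expect_error(mean_epsilon_test(-1), "at least 2")
})

test_that("welch_one_sided agrees with the t.test oracle", {
  # groups constructed to the spec example: means 7.32 / 5.84, sd 0.5
  mk <- function(mu, sd, n) {
    x <- seq(-1, 1, length.out = n)
    mu + (x - mean(x)) * sd / stats::sd(x)
  }
  a <- mk(7.32, 0.5, 5)
  b <- mk(5.84, 0.5, 6)
  w <- welch_one_sided(a, b, "greater")
  expect_equal(w$t, 4.89, tolerance = 0.01)
  expect_equal(w$df, 8.64, tolerance = 0.01)
  oracle <- stats::t.test(a, b, alternative = "greater")
  expect_equal(w$t, unname(oracle$statistic), tolerance = 1e-10)
  expect_equal(w$df, unname(oracle$parameter), tolerance = 1e-10)
  expect_equal(w$p, oracle$p.value, tolerance = 1e-10)

  # identical groups: t = 0, one-sided p = 1/2
  x <- c(1, 2, 3)
  same <- welch_one_sided(x, x, "greater")
  expect_equal(same$t, 0)
  expect_equal(same$p, 0.5)

  # swapping groups negates t and maps p to 1 - p
  g1 <- welch_one_sided(a, b, "greater")
  g2 <- welch_one_sided(b, a, "greater")
  expect_equal(g2$t, -g1$t)
  expect_equal(g2$p, 1 - g1$p, tolerance = 1e-12)

  # both variances zero: exact comparison, flagged
  dz <- welch_one_sided(c(2, 2), c(1, 1), "greater")
  expect_true(dz$degenerate)
  expect_equal(dz$p, 0)
})

test_that("bonferroni caps at one and is monotone", {
  expect_equal(bonferroni(0.001, 18), 0.018)
  expect_equal(bonferroni(0.5, 18), 1)
  expect_equal(bonferroni(0, 18), 0)
  expect_error(bonferroni(0.1, 0), "m must be")
  p <- sort(runif(20))
  expect_true(all(diff(bonferroni(p, 18)) >= 0))
  expect_true(all(bonferroni(p, 18) >= p))
})

test_that("mean-based categories follow the strict-inequality rules", {
  expect_equal(classify_pair(4.18, 1.65, -3.62), "below_wild_type")
  expect_equal(classify_pair(3.89, 5.84, 7.32), "exceeds_both_singles")
  expect_equal(classify_pair(1, 2, 1.5), "between_singles")
  expect_equal(classify_pair(1, 2, 0.5), "below_both_singles")
  # exact equality falls to the weaker category
  expect_equal(classify_pair(1, 2, 2), "between_singles")
  expect_equal(classify_pair(1, 2, 1), "between_singles")
})

test_that("decompensation battery: categories on means, tests on replicates", {
  calls <- decompensation_battery(NULL, fixture_effects())
  expect_equal(nrow(calls), 18L)
  below_wt <- calls$pair[calls$category == "below_wild_type"]
  expect_setequal(below_wt, c("CE", "EI"))
  exceeds <- calls$pair[calls$category == "exceeds_both_singles"]
  expect_setequal(exceeds, c("AG", "AH", "BH", "CH", "DF"))
  expect_true(all(is.na(calls$p_below_max)))  # mean-only data: no tests

  # replicate-level data: low noise makes the strong pairs significant
  cfg <- generator_config(noise_sd = 0.4, n_rep = 8L)
  assays <- generate_assays(cfg, seed = 5)
  eff <- effect_table(summarize_assays(assays))
  b <- decompensation_battery(assays, eff)
  ok <- !is.na(b$p_below_max)
  expect_true(all(ok))
  expect_true(all(b$p_below_max >= 0 & b$p_below_max <= 1))
  expect_true(all(b$p_below_max_adj >= b$p_below_max))
  # EI sits far below the wild type in this world
  expect_lt(b$p_below_wt_adj[b$pair == "EI"], 0.05)

  # missing replicate data for one genotype: per-pair omission with warning
  assays2 <- assays[assays$genotype != "AB", ]
  eff2 <- eff  # effects still contain AB (means known)
  expect_warning(b2 <- decompensation_battery(assays2, eff2), "AB")
  expect_true(is.na(b2$p_below_max[b2$pair == "AB"]))
  expect_false(anyNA(b2$p_below_max[b2$pair != "AB"]))
})
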