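# Shared helpers and a memo cache for the expensive fits, so the unit and
# acceptance files can reuse one deterministic computation.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .cache)) {
    assign(key, force(expr), envir = .cache)
  }
  get(key, envir = .cache)
}

toy_map <- function() gamma_map_params(shape = 2, scale = 1, height = 10,
                                       shift = 0)

# Printed epistasis columns (deviation from additivity and the additive
# expectation) for the 18 constructed pairs, in the fixture's pair order.
printed_epsilon <- c(AB = -4.57, AD = -3.70, AF = -4.40, AG = -2.41,
                     AH = -2.23, BD = -5.00, BE = -5.40, BG = -7.87,
                     BH = -3.30, BI = -4.23, CD = -5.28, CE = -9.45,
                     CH = -3.31, DF = -2.71, DH = -3.58, DI = -4.65,
                     EH = -3.74, EI = -5.51)
printed_additive <- c(AB = 8.04, AD = 7.33, AF = 7.28, AG = 9.73,
                      AH = 7.33, BD = 7.59, BE = 5.80, BG = 9.99,
                      BH = 7.59, BI = 5.57, CD = 7.62, CE = 5.83,
                      CH = 7.62, DF = 6.83, DH = 6.88, DI = 4.86,
                      EH = 5.09, EI = 3.07)

fixture_effects <- function() memo("fixture_effects", id11_fixture()$effects)

fixture_fit <- function() memo("fixture_fit", fit_gamma_map(fixture_effects()))

fixture_loo <- function() memo("fixture_loo", loo_predict(fixture_effects()))

fixture_compare <- function() {
  memo("fixture_compare",
       compare_models(fixture_effects(), fit = fixture_fit(), reps = 1000,
                      seed = 20110602))
}

noisefree_effects <- function() {
  memo("noisefree_effects", {
    cfg <- generator_config(noise_sd = 0)
    effect_table(summarize_assays(generate_assays(cfg, seed = 7)))
  })
}

noisefree_fit <- function() memo("noisefree_fit",
                                 fit_gamma_map(noisefree_effects()))

noisefree_loo <- function() memo("noisefree_loo",
                                 loo_predict(noisefree_effects()))

# A small three-mutation world for cheap fitting tests: singles P, Q, R with
# doubles PQ, PR, QR on a known map. Labels kept single-letter so the pair
# naming convention applies.
tiny_world <- function(noise_sd = 0, seed = 1) {
  cfg <- generator_config(
    params = gamma_map_params(shape = 2, scale = 1, height = 10, shift = 5),
    z_wt = 0.2,
    z_singles = c(P = 0.5, Q = 0.9, R = 1.6),
    pattern = rbind(c("P", "Q"), c("P", "R"), c("Q", "R")),
    noise_sd = noise_sd, n_rep = 5L, wt_label = "WT")
  effect_table(summarize_assays(generate_assays(cfg, seed = seed)),
               wild_type = "WT")
}

# Independent brute-force enumerator over branch assignments, coded as a
# plain loop (the oracle for impute_phenotypes' vectorized enumeration).
brute_force_branches <- function(params, w_singles, pairs, w_doubles) {
  m <- length(w_singles)
  labels <- names(w_singles)
  peak <- params$shift + params$height
  roots <- gamma_invert(params, pmin(w_singles, peak))
  if (m == 1L) roots <- matrix(roots, nrow = 1)
  best_sse <- Inf
  best <- NULL
  for (code in 0:(2^m - 1L)) {
    z <- numeric(m)
    for (k in seq_len(m)) {
      hi <- bitwAnd(code, bitwShiftL(1L, m - k)) > 0L
      z[k] <- if (hi) roots[k, 2L] else roots[k, 1L]
    }
    sse <- 0
    for (r in seq_len(nrow(pairs))) {
      zd <- z[match(pairs[r, 1L], labels)] + z[match(pairs[r, 2L], labels)]
      sse <- sse + (w_doubles[[r]] - gamma_fitness(params, zd))^2
    }
    if (sse < best_sse - 1e-15) {
      best_sse <- sse
      best <- z
    }
  }
  list(z = stats::setNames(best, labels), sse = best_sse)
}

# Bisection oracle for inverting the toy map, independent of gamma_invert.
bisect_root <- function(f, lo, hi, tol = 1e-10) {
  flo <- f(lo)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(hi - lo) < tol) break
    if (sign(fm) == sign(flo)) {
      lo <- mid
      flo <- fm
    } else {
      hi <- mid
    }
  }
  (lo + hi) / 2
}
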