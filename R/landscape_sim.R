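#' Default double-mutant pair pattern
#'
#' The 18 constructed pairs of the nine beneficial mutations A-I, used to
#' match simulated double mutants to the empirical design.
#'
#' @return An 18 x 2 character matrix of single-mutant labels.
#' @export
default_pair_pattern <- function() {
  pairs <- c("AB", "AD", "AF", "AG", "AH", "BD", "BE", "BG", "BH", "BI",
             "CD", "CE", "CH", "DF", "DH", "DI", "EH", "EI")
  t(vapply(pairs, split_pair, character(2)))
}

pattern_indices <- function(pattern, m) {
  if (is.character(pattern)) {
    idx <- matrix(match(pattern, LETTERS[seq_len(m)]), ncol = 2L)
    if (anyNA(idx)) stop("pair pattern labels outside A..", LETTERS[m],
                         call. = FALSE)
    idx
  } else {
    stopifnot(all(pattern >= 1L), all(pattern <= m))
    pattern
  }
}

#' Distribution of single-mutant fitness effects
#'
#' Beneficial-effect distribution on the absolute-fitness scale: a
#' generalized Pareto distribution (GPD) with shape `kappa`, truncated-
#' support parameterization with lower bound at the smallest observed
#' beneficial fitness and, for `kappa < 0`, upper bound at the largest.
#' `kappa = -1` is the uniform distribution on `[lower, upper]`.
#'
#' @param lower,upper Bounds (fitness, doublings per hour), `lower < upper`.
#' @param kappa GPD shape (default -1, uniform).
#' @return List of class `effect_distribution`.
#' @export
effect_distribution_config <- function(lower, upper, kappa = -1) {
  stopifnot(is.finite(lower), is.finite(upper))
  if (lower >= upper) stop("lower bound must be < upper bound", call. = FALSE)
  if (kappa >= 0) {
    stop("kappa >= 0 has unbounded support; incompatible with a finite ",
         "upper bound", call. = FALSE)
  }
  structure(list(lower = lower, upper = upper, kappa = kappa),
            class = "effect_distribution")
}

#' Draw single-mutant fitnesses
#'
#' Inverse-CDF GPD draws: with shape `kappa < 0` the scale is set so the
#' support is exactly `[lower, upper]`; `kappa = -1` reduces to uniform
#' draws.
#'
#' @param config An `effect_distribution` from [effect_distribution_config()].
#' @param m Number of draws (default 9).
#' @param seed Optional RNG seed.
#' @return Numeric vector of `m` fitness values.
#' @export
draw_single_effects <- function(config, m = 9L, seed = NULL) {
  stopifnot(inherits(config, "effect_distribution"))
  if (!is.null(seed)) set.seed(seed)
  u <- stats::runif(m)
  k <- config$kappa
  tau <- -k * (config$upper - config$lower)
  # GPD quantile (Pickands): Q(u) = lower + tau/k * ((1-u)^(-k) - 1)
  config$lower + tau / k * ((1 - u)^(-k) - 1)
}

#' Simulate deviations from additivity under the fitted gamma map
#'
#' Per replicate: draw nine single-mutant fitnesses from the beneficial-
#' effect distribution, invert each through the map to a phenotype (side of
#' the peak chosen by a fair coin), form 18 double-mutant phenotypes by
#' addition following the pair pattern, map back to fitness, add normal
#' assay/model error to every genotype, and compute each pair's deviation
#' from additivity relative to the wild-type fitness. Draws above the curve
#' peak are redrawn (counted; more than 50% redraws aborts).
#'
#' @param fit A `gamma_fit` object (supplies the map, the wild-type mean, the
#'   default error SD and the default effect-distribution bounds).
#' @param config Optional `effect_distribution`; default: bounds at the
#'   smallest and largest observed single-mutant fitnesses in `fit`.
#' @param pattern Pair pattern (character labels or index matrix); default
#'   [default_pair_pattern()].
#' @param error_sd Normal error SD; default `sqrt(sigma2)` from the fit.
#' @param reps Number of replicate data sets (default 1000).
#' @param seed Optional RNG seed.
#' @return Object of class `epsilon_distribution`: `model`, `eps`
#'   (`reps` x n-pairs matrix), `reps`, `n_redraw`.
#' @export
simulate_gamma_epsilons <- function(fit, config = NULL, pattern = NULL,
                                    error_sd = NULL, reps = 1000L,
                                    seed = NULL) {
  stopifnot(inherits(fit, "gamma_fit"))
  if (!is.null(seed)) set.seed(seed)
  m <- length(fit$phenotypes$z)
  w_singles_obs <- fit$observed[seq_len(m)]
  if (is.null(config)) {
    config <- effect_distribution_config(min(w_singles_obs),
                                         max(w_singles_obs))
  }
  if (is.null(pattern)) pattern <- default_pair_pattern()
  idx <- pattern_indices(pattern, m)
  if (is.null(error_sd)) error_sd <- sqrt(fit$diagnostics$sigma2)
  params <- fit$params
  peak <- params$shift + params$height
  w_wt <- fit$wt_mean
  if (is.null(w_wt)) stop("fit carries no wild-type mean", call. = FALSE)

  n_draw <- reps * m
  w <- draw_single_effects(config, n_draw)
  n_redraw <- 0L
  repeat {
    bad <- which(w > peak)
    if (length(bad) == 0L) break
    n_redraw <- n_redraw + length(bad)
    if (n_redraw > 0.5 * n_draw) {
      stop("more than 50% of effect draws exceed the curve peak; ",
           "map and effect distribution are inconsistent", call. = FALSE)
    }
    w[bad] <- draw_single_effects(config, length(bad))
  }
  roots <- gamma_invert(params, w)
  side_high <- stats::runif(n_draw) < 0.5
  z <- ifelse(side_high, roots[, "z_high"], roots[, "z_low"])
  z_mat <- matrix(z, nrow = reps, ncol = m)
  w_mat <- matrix(w, nrow = reps, ncol = m) +
    matrix(stats::rnorm(n_draw, sd = error_sd), nrow = reps)
  zd <- z_mat[, idx[, 1L], drop = FALSE] + z_mat[, idx[, 2L], drop = FALSE]
  wd <- gamma_fitness(params, zd) +
    matrix(stats::rnorm(reps * nrow(idx), sd = error_sd), nrow = reps)
  eps <- wd - w_mat[, idx[, 1L], drop = FALSE] -
    w_mat[, idx[, 2L], drop = FALSE] + w_wt
  colnames(eps) <- if (is.character(pattern)) {
    paste0(pattern[, 1L], pattern[, 2L])
  } else NULL
  structure(list(model = "gamma", eps = eps, reps = reps,
                 n_redraw = n_redraw),
            class = "epsilon_distribution")
}

#' Two-dimensional geometric model with a Gaussian fitness map
#'
#' Configuration for the Fisher-geometric comparison model: phenotypes live
#' in the plane, the optimum is at the origin with fitness `w_max`, the wild
#' type sits one phenotypic unit away with fitness exactly `w_wt`, and
#' fitness decays as a Gaussian of the distance toward a floor:
#' `w(p) = floor + (w_max - floor) * exp(-c * ||p||^2)` with
#' `c = log((w_max - floor) / (w_wt - floor))` so both constraints hold
#' exactly.
#'
#' @param w_max Fitness at the optimum.
#' @param w_wt Wild-type fitness (< `w_max`).
#' @param floor Fitness floor as distance grows (< `w_wt`).
#' @param w_min_single Fitness of the smallest-effect beneficial mutation
#'   (> `w_wt`); defines the sampling contour for mutant phenotypes.
#' @return List of class `geometric_model` including the decay constant `c`
#'   and the sampling radius `r_sample`.
#' @export
geometric_model_config <- function(w_max, w_wt, floor, w_min_single) {
  stopifnot(w_max > w_wt, w_wt > floor)
  if (w_min_single <= w_wt || w_min_single > w_max) {
    stop("smallest single-mutant fitness must lie in (w_wt, w_max]",
         call. = FALSE)
  }
  cc <- log((w_max - floor) / (w_wt - floor))
  r_sample <- sqrt(log((w_max - floor) / (w_min_single - floor)) / cc)
  structure(list(n_dim = 2L, w_max = w_max, w_wt = w_wt, floor = floor,
                 w_min_single = w_min_single, c = cc, r_sample = r_sample),
            class = "geometric_model")
}

#' Gaussian fitness of phenotype points
#'
#' @param config A `geometric_model`.
#' @param p A two-column matrix of phenotype points (optimum at the origin),
#'   or a length-2 vector.
#' @return Fitness value(s).
#' @export
geometric_fitness <- function(config, p) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 2L)
  r2 <- rowSums(p^2)
  config$floor + (config$w_max - config$floor) * exp(-config$c * r2)
}

# Uniform points in the disk of radius r (rejection in the bounding box).
runif_disk <- function(n, r) {
  out <- matrix(NA_real_, n, 2L)
  need <- n
  while (need > 0L) {
    cand <- matrix(stats::runif(2L * need, -r, r), ncol = 2L)
    ok <- rowSums(cand^2) <= r^2
    k <- sum(ok)
    if (k > 0L) {
      out[(n - need + 1L):(n - need + k), ] <- cand[ok, , drop = FALSE]
      need <- need - k
    }
  }
  out
}

#' Simulate deviations from additivity under the geometric model
#'
#' Per replicate: place the wild type one unit from the optimum, draw nine
#' mutant phenotypes uniformly inside the fitness contour of the smallest-
#' effect beneficial mutation (a disk around the optimum), form 18 double
#' mutants by adding the two displacement vectors to the wild type, map all
#' points to fitness, and compute deviations from additivity on the effect
#' scale.
#'
#' @param config A `geometric_model`.
#' @param pattern Pair pattern; default [default_pair_pattern()].
#' @param m Number of single mutants (default 9).
#' @param reps Number of replicate data sets (default 1000).
#' @param seed Optional RNG seed.
#' @return An `epsilon_distribution` (model `"geometric"`).
#' @export
simulate_geometric_epsilons <- function(config, pattern = NULL, m = 9L,
                                        reps = 1000L, seed = NULL) {
  stopifnot(inherits(config, "geometric_model"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(pattern)) pattern <- default_pair_pattern()
  idx <- pattern_indices(pattern, m)
  p_wt <- c(1, 0)
  n_pair <- nrow(idx)
  eps <- matrix(NA_real_, reps, n_pair)
  w_wt <- config$w_wt
  for (r in seq_len(reps)) {
    pts <- runif_disk(m, config$r_sample)
    w_single <- geometric_fitness(config, pts)
    d <- sweep(pts, 2L, p_wt)                    # displacement vectors
    pd <- sweep(d[idx[, 1L], , drop = FALSE] +
                  d[idx[, 2L], , drop = FALSE], 2L, p_wt, `+`)
    w_double <- geometric_fitness(config, pd)
    eps[r, ] <- w_double - w_single[idx[, 1L]] - w_single[idx[, 2L]] + w_wt
  }
  colnames(eps) <- if (is.character(pattern)) {
    paste0(pattern[, 1L], pattern[, 2L])
  } else NULL
  structure(list(model = "geometric", eps = eps, reps = reps,
                 n_redraw = 0L),
            class = "epsilon_distribution")
}

#' Histogram-density log-likelihood
#'
#' Approximates the likelihood of the observed deviations from additivity by
#' the histogram density of the pooled simulated deviations
#' (Freedman-Diaconis bins). Observations falling in empty bins or outside
#' the histogram range use the density floor `1 / (n_simulated * bin_width)`
#' (one pseudo-count), avoiding minus-infinite log-likelihoods; such events
#' are counted.
#'
#' @param sim An `epsilon_distribution`.
#' @param observed Numeric vector of observed deviations (one per pair).
#' @return List with `lnl`, `n_floored`, `breaks` and `density`.
#' @export
histogram_loglik <- function(sim, observed) {
  stopifnot(inherits(sim, "epsilon_distribution"))
  pooled <- as.vector(sim$eps)
  if (length(pooled) < 1000L) {
    stop("need at least 1000 pooled simulated values", call. = FALSE)
  }
  h <- graphics::hist(pooled, breaks = "FD", plot = FALSE)
  bw <- diff(h$breaks)[1L]
  dens_floor <- 1 / (length(pooled) * bw)
  bin <- findInterval(observed, h$breaks, rightmost.closed = TRUE)
  inside <- bin >= 1L & bin <= length(h$density)
  d <- rep(dens_floor, length(observed))
  d[inside] <- h$density[bin[inside]]
  floored <- !inside | d == 0
  d[d == 0] <- dens_floor
  list(lnl = sum(log(d)), n_floored = sum(floored), breaks = h$breaks,
       density = h$density)
}

#' AIC comparison of the two epistasis models
#'
#' `AIC = 2k - 2 lnL` with `k = 14` for the gamma map (nine imputed
#' phenotypes, four curve parameters, one error parameter) and `k = 2` for
#' the geometric model.
#'
#' @param lnl_gamma,lnl_geometric Log-likelihoods of the observed deviations
#'   under each model.
#' @param k_gamma,k_geometric Parameter counts (defaults 14 and 2).
#' @return List with per-model `aic`, `delta_aic`
#'   (`aic_gamma - aic_geometric`; negative favors the gamma map) and a
#'   qualitative `verdict`.
#' @export
aic_compare <- function(lnl_gamma, lnl_geometric, k_gamma = 14L,
                        k_geometric = 2L) {
  stopifnot(is.finite(lnl_gamma), is.finite(lnl_geometric))
  aic_g <- 2 * k_gamma - 2 * lnl_gamma
  aic_m <- 2 * k_geometric - 2 * lnl_geometric
  delta <- aic_g - aic_m
  verdict <- if (abs(delta) < 2) {
    "models explain the data about equally well"
  } else if (delta < 0) {
    "gamma map favored"
  } else {
    "geometric model favored"
  }
  list(k_gamma = k_gamma, k_geometric = k_geometric,
       lnl_gamma = lnl_gamma, lnl_geometric = lnl_geometric,
       aic_gamma = aic_g, aic_geometric = aic_m, delta_aic = delta,
       verdict = verdict)
}

#' Full simulation-based model comparison
#'
#' Calibrates both generative models on the data (effect-distribution bounds
#' at the smallest and largest observed single-mutant fitnesses; geometric
#' model's peak at the largest single fitness, wild type at its observed
#' mean, floor at the gamma fit's shift), simulates replicate deviation
#' distributions under each, and compares histogram log-likelihoods of the
#' observed deviations by AIC.
#'
#' @param effects Effect table from [effect_table()].
#' @param fit Optional pre-computed `gamma_fit` (fitted here if `NULL`).
#' @param reps Replicate data sets per model (default 1000).
#' @param seed Optional RNG seed.
#' @param floor Geometric-model floor; default the gamma fit's shift.
#' @return List of class `model_comparison`: `fit`, `sim_gamma`,
#'   `sim_geometric`, `lnl_gamma`, `lnl_geometric`, `aic` (from
#'   [aic_compare()]) and `observed` deviations.
#' @export
compare_models <- function(effects, fit = NULL, reps = 1000L, seed = NULL,
                           floor = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(fit)) fit <- fit_gamma_map(effects)
  et <- epsilon_table(effects)
  singles <- effects[effects$type == "single", , drop = FALSE]
  w_wt <- attr(effects, "wild_type_mean")
  if (is.null(floor)) floor <- fit$params$shift
  pattern <- cbind(substr(et$pair, 1L, 1L), substr(et$pair, 2L, 2L))
  geo <- geometric_model_config(w_max = max(singles$mean), w_wt = w_wt,
                                floor = floor,
                                w_min_single = min(singles$mean))
  sim_g <- simulate_gamma_epsilons(fit, pattern = pattern, reps = reps)
  sim_m <- simulate_geometric_epsilons(geo, pattern = pattern,
                                       m = nrow(singles), reps = reps)
  ll_g <- histogram_loglik(sim_g, et$epsilon)
  ll_m <- histogram_loglik(sim_m, et$epsilon)
  structure(list(fit = fit, geometric = geo, sim_gamma = sim_g,
                 sim_geometric = sim_m, lnl_gamma = ll_g,
                 lnl_geometric = ll_m,
                 aic = aic_compare(ll_g$lnl, ll_m$lnl),
                 observed = stats::setNames(et$epsilon, et$pair)),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  a <- x$aic
  cat("Simulation-based model comparison (histogram likelihoods)\n")
  cat(sprintf("  gamma map:       lnL %.2f, k %d, AIC %.2f\n",
              a$lnl_gamma, a$k_gamma, a$aic_gamma))
  cat(sprintf("  geometric model: lnL %.2f, k %d, AIC %.2f\n",
              a$lnl_geometric, a$k_geometric, a$aic_geometric))
  cat(sprintf("  delta AIC (gamma - geometric): %.2f -> %s\n",
              a$delta_aic, a$verdict))
  invisible(x)
}
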