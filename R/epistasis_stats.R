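#' Deviation from additivity
#'
#' The epistasis statistic on the growth-rate (log-fitness) scale:
#' `epsilon = s_ij - (s_i + s_j)`, where `s_i`, `s_j` are the single-mutant
#' fitness effects relative to the wild type and `s_ij` the double-mutant
#' effect. Negative values indicate antagonistic epistasis, positive values
#' synergistic epistasis, zero additivity.
#'
#' @param s_ij Double-mutant effect.
#' @param s_i,s_j Single-mutant effects.
#' @return Numeric vector of deviations from additivity.
#' @examples
#' epsilon(3.47, 3.89, 4.15)  # -4.57
#' @export
epsilon <- function(s_ij, s_i, s_j) {
  stopifnot(is.finite(s_ij), is.finite(s_i), is.finite(s_j))
  s_ij - (s_i + s_j)
}

#' Additive expectation for a double mutant
#'
#' @param s_i,s_j Single-mutant effects.
#' @return `s_i + s_j`.
#' @export
additive_expectation <- function(s_i, s_j) {
  s_i + s_j
}

#' Epistasis statistics for every double mutant
#'
#' Builds one row per double mutant with the constituent single effects, the
#' additive expectation, the deviation from additivity, and both
#' background-specific effects: `delta_bg_i = s_ij - s_i` (the effect of
#' adding mutation j into the background of i) and `delta_bg_j = s_ij - s_j`.
#'
#' @param effects Effect table from [effect_table()].
#' @return Data frame with columns `pair`, `s_i`, `s_j`, `s_ij`, `additive`,
#'   `epsilon`, `delta_bg_i`, `delta_bg_j`.
#' @export
epsilon_table <- function(effects) {
  doubles <- effects[effects$type == "double", , drop = FALSE]
  singles <- effects[effects$type == "single", , drop = FALSE]
  s <- stats::setNames(singles$effect, singles$genotype)
  s_i <- unname(s[doubles$first])
  s_j <- unname(s[doubles$second])
  s_ij <- doubles$effect
  data.frame(pair = doubles$genotype, s_i = s_i, s_j = s_j, s_ij = s_ij,
             additive = additive_expectation(s_i, s_j),
             epsilon = epsilon(s_ij, s_i, s_j),
             delta_bg_i = s_ij - s_i, delta_bg_j = s_ij - s_j,
             stringsAsFactors = FALSE)
}

#' One-sample test of mean deviation from additivity
#'
#' Tests whether the mean of the per-pair deviations from additivity differs
#' from zero by a one-sample t test across pairs.
#'
#' @param eps Numeric vector of deviations (one per double mutant), or the
#'   data frame from [epsilon_table()].
#' @return List with `mean`, `t`, `df`, `p` (two-sided) and `degenerate`
#'   (`TRUE` when the sample SD is zero, in which case `t`/`p` are `NA`
#'   unless the mean is exactly zero).
#' @export
mean_epsilon_test <- function(eps) {
  if (is.data.frame(eps)) eps <- eps$epsilon
  if (length(eps) < 2L) {
    stop("need at least 2 deviations for the mean test", call. = FALSE)
  }
  m <- mean(eps)
  s <- stats::sd(eps)
  n <- length(eps)
  if (s == 0) {
    # all deviations identical: the t statistic is undefined unless m == 0
    t_stat <- if (m == 0) 0 else NA_real_
    p <- if (m == 0) 1 else NA_real_
    return(list(mean = m, t = t_stat, df = n - 1L, p = p, degenerate = TRUE))
  }
  t_stat <- m / (s / sqrt(n))
  list(mean = m, t = t_stat, df = n - 1L,
       p = 2 * stats::pt(-abs(t_stat), df = n - 1L), degenerate = FALSE)
}

#' One-sided Welch two-sample t test
#'
#' Welch t statistic with Satterthwaite degrees of freedom, computed from the
#' two samples directly. `alternative = "greater"` tests whether the mean of
#' `a` exceeds the mean of `b`; `"less"` the reverse.
#'
#' @param a,b Numeric vectors of replicate fitnesses (each of length >= 2).
#' @param alternative `"greater"` or `"less"`.
#' @return List with `t`, `df`, `p` and `degenerate` (both variances zero;
#'   the p-value is then 0 or 1 by comparison of means).
#' @export
welch_one_sided <- function(a, b, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  d <- mean(a) - mean(b)
  if (va + vb == 0) {
    p <- switch(alternative,
                greater = if (d > 0) 0 else 1,
                less = if (d < 0) 0 else 1)
    if (d == 0) p <- 1
    return(list(t = if (d == 0) 0 else sign(d) * Inf, df = NA_real_, p = p,
                degenerate = TRUE))
  }
  t_stat <- d / sqrt(va + vb)
  df <- (va + vb)^2 /
    (va^2 / (length(a) - 1L) + vb^2 / (length(b) - 1L))
  p <- switch(alternative,
              greater = stats::pt(t_stat, df, lower.tail = FALSE),
              less = stats::pt(t_stat, df, lower.tail = TRUE))
  list(t = t_stat, df = df, p = p, degenerate = FALSE)
}

#' Bonferroni adjustment
#'
#' @param p Raw p-value(s) in \[0, 1\].
#' @param m Number of tests (default 18, the number of double mutants).
#' @return `min(1, m * p)`, elementwise.
#' @export
bonferroni <- function(p, m = 18L) {
  if (m < 1L) stop("m must be >= 1", call. = FALSE)
  stopifnot(all(p >= 0 & p <= 1))
  pmin(1, m * p)
}

#' Mean-based epistasis category for one pair
#'
#' Classifies a double mutant by comparing its mean effect against its two
#' constituent single effects and the wild type (effect 0). Comparisons are
#' strict; exact equality falls to the weaker category. Categories, from
#' weakest to strongest deviation: `exceeds_both_singles` (above both
#' singles), `between_singles`, `below_both_singles` (below both but above
#' the wild type), `below_wild_type`.
#'
#' @param s_i,s_j Single effects.
#' @param s_ij Double effect.
#' @return Category string.
#' @export
classify_pair <- function(s_i, s_j, s_ij) {
  hi <- max(s_i, s_j)
  lo <- min(s_i, s_j)
  if (s_ij < 0) "below_wild_type"
  else if (s_ij < lo) "below_both_singles"
  else if (s_ij > hi) "exceeds_both_singles"
  else "between_singles"
}

#' Decompensatory-epistasis test battery
#'
#' For each double mutant, runs the four one-sided Welch tests on
#' replicate-level data: double below the higher single (conditional
#' decompensation), double below the lower single (unconditional
#' decompensation), double below the wild type, and double above the higher
#' single (the recombination-advantage test). Raw and Bonferroni-adjusted
#' p-values are reported alongside the mean-based category. When
#' replicate-level data are unavailable for a genotype in a pair, that pair's
#' tests are omitted with a warning (the category, which needs only means, is
#' still emitted).
#'
#' @param assays Replicate-level data frame (columns `genotype`, `fitness`),
#'   or `NULL` for mean-only data.
#' @param effects Effect table from [effect_table()].
#' @param m Number of tests for the Bonferroni correction (default: number of
#'   doubles).
#' @return Data frame, one row per double, with the category, four raw
#'   p-values (`p_below_max`, `p_below_min`, `p_below_wt`, `p_above_max`) and
#'   their adjusted versions (`NA` where tests were omitted).
#' @export
decompensation_battery <- function(assays, effects, m = NULL) {
  doubles <- effects[effects$type == "double", , drop = FALSE]
  singles <- effects[effects$type == "single", , drop = FALSE]
  wt <- attr(effects, "wild_type")
  s <- stats::setNames(singles$effect, singles$genotype)
  if (is.null(m)) m <- nrow(doubles)

  reps <- if (is.null(assays)) NULL else split(assays$fitness, assays$genotype)
  get_reps <- function(g) {
    r <- reps[[g]]
    if (is.null(r) || length(r) < 2L) NULL else r
  }

  rows <- lapply(seq_len(nrow(doubles)), function(k) {
    pair <- doubles$genotype[k]
    i <- doubles$first[k]
    j <- doubles$second[k]
    s_i <- unname(s[i]); s_j <- unname(s[j])
    cat_k <- classify_pair(s_i, s_j, doubles$effect[k])
    hi_lab <- if (s_i >= s_j) i else j
    lo_lab <- if (s_i >= s_j) j else i
    p <- rep(NA_real_, 4L)
    if (!is.null(reps)) {
      rd <- get_reps(pair); rhi <- get_reps(hi_lab)
      rlo <- get_reps(lo_lab); rwt <- get_reps(wt)
      if (is.null(rd) || is.null(rhi) || is.null(rlo) || is.null(rwt)) {
        warning("missing replicate data for pair ", pair,
                "; tests omitted", call. = FALSE)
      } else {
        p[1] <- welch_one_sided(rd, rhi, "less")$p
        p[2] <- welch_one_sided(rd, rlo, "less")$p
        p[3] <- welch_one_sided(rd, rwt, "less")$p
        p[4] <- welch_one_sided(rd, rhi, "greater")$p
      }
    }
    data.frame(pair = pair, category = cat_k,
               p_below_max = p[1], p_below_min = p[2],
               p_below_wt = p[3], p_above_max = p[4],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  for (col in c("p_below_max", "p_below_min", "p_below_wt", "p_above_max")) {
    adj <- rep(NA_real_, nrow(out))
    ok <- !is.na(out[[col]])
    adj[ok] <- bonferroni(out[[col]][ok], m)
    out[[paste0(col, "_adj")]] <- adj
  }
  out
}
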