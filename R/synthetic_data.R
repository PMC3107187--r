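#' Generator configuration for synthetic replicate assays
#'
#' The generator emulates the structure the analysis assumes: a wild type and
#' nine single mutants with latent phenotypes on a unimodal gamma-shaped
#' phenotype-to-fitness map, double mutants with exactly additive phenotypes
#' (`z_ij = z_i + z_j`), and iid normal assay noise around each genotype's
#' curve fitness.
#'
#' Defaults describe a phage-like system: map with shape 2, scale 1, shift 11
#' and height 11.5 (peak fitness 22.5, just above the largest fitness such
#' assays report); wild type on the rising limb at fitness about 15.2; nine
#' single phenotypes with three short of the optimum and six overshooting it,
#' so the largest pair falls below the wild type and within one unit of the
#' curve floor (decompensatory pattern, and a world consistent with the
#' integer-shift rule of the fitter, like the empirical data); replicate
#' noise SD 0.8 doublings per hour; five replicates per genotype.
#'
#' @param params True `gamma_map` parameters.
#' @param z_wt Wild-type phenotype.
#' @param z_singles Named vector of single-mutant phenotypes (>= 0).
#' @param pattern Pair pattern for the double mutants (default the 18
#'   empirical pairs, [default_pair_pattern()]).
#' @param noise_sd Assay noise SD (>= 0).
#' @param n_rep Replicates per genotype (>= 1).
#' @param wt_label Wild-type genotype label.
#' @return List of class `generator_config`.
#' @export
generator_config <- function(params = gamma_map_params(shape = 2, scale = 1,
                                                       height = 11.5,
                                                       shift = 11),
                             z_wt = 0.155,
                             z_singles = c(A = 0.45, B = 1.10, C = 1.15,
                                           D = 0.50, E = 2.60, F = 1.05,
                                           G = 1.30, H = 0.55, I = 2.75),
                             pattern = default_pair_pattern(),
                             noise_sd = 0.8, n_rep = 5L,
                             wt_label = "ID11") {
  stopifnot(inherits(params, "gamma_map"), z_wt >= 0, all(z_singles >= 0),
            noise_sd >= 0, n_rep >= 1L)
  if (is.null(names(z_singles)) || anyNA(names(z_singles))) {
    stop("z_singles must be a named vector", call. = FALSE)
  }
  if (!all(pattern %in% names(z_singles))) {
    stop("pair pattern references undefined singles", call. = FALSE)
  }
  structure(list(params = params, z_wt = z_wt, z_singles = z_singles,
                 pattern = pattern, noise_sd = noise_sd,
                 n_rep = as.integer(n_rep), wt_label = wt_label),
            class = "generator_config")
}

#' Genotype means implied by a generator configuration
#'
#' @param config A `generator_config`.
#' @return Named vector of curve fitnesses: wild type, singles, doubles.
#' @export
generator_means <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  z_d <- config$z_singles[config$pattern[, 1L]] +
    config$z_singles[config$pattern[, 2L]]
  names(z_d) <- paste0(config$pattern[, 1L], config$pattern[, 2L])
  z_all <- c(stats::setNames(config$z_wt, config$wt_label),
             config$z_singles, z_d)
  stats::setNames(gamma_fitness(config$params, z_all), names(z_all))
}

#' Generate synthetic replicate assays
#'
#' @param config A `generator_config`.
#' @param seed Optional RNG seed; identical seeds give identical data, and
#'   genotype means do not depend on the seed.
#' @return Replicate-level data frame (`genotype`, `replicate`, `fitness`)
#'   compatible with [summarize_assays()].
#' @export
generate_assays <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  means <- generator_means(config)
  n <- config$n_rep
  genotype <- rep(names(means), each = n)
  fitness <- rep(unname(means), each = n) +
    stats::rnorm(length(means) * n, sd = config$noise_sd)
  data.frame(genotype = genotype,
             replicate = rep(seq_len(n), times = length(means)),
             fitness = fitness, stringsAsFactors = FALSE)
}

#' Mean-level fitness data for the nine-mutation phage study
#'
#' The published mean-level dataset for bacteriophage ID11 and its nine
#' beneficial single mutations (A-I) and 18 constructed double mutants:
#' per-genotype replicate counts, fitness effects relative to the wild type,
#' and the observed double-mutant fitnesses. Genotype means are reconstructed
#' as wild-type mean (15.19 doublings per hour) plus printed effect; the
#' reconstruction agrees with the independently printed double-mutant
#' fitnesses to the 0.01 printing precision (see `observed_doubles`).
#' Per-genotype standard errors are not part of the fixture (not recoverable
#' from the printed source); replicate-level analyses use
#' [generate_assays()] instead.
#'
#' @return List with `effects` (an [effect_table()]; `se` all `NA`),
#'   `observed_doubles` (named vector of printed double-mutant mean
#'   fitnesses) and `wt_mean`.
#' @export
id11_fixture <- function() {
  wt_mean <- 15.19
  singles <- c(A = 3.89, B = 4.15, C = 4.18, D = 3.44, E = 1.65,
               F = 3.39, G = 5.84, H = 3.44, I = 1.42)
  n_singles <- c(A = 5, B = 5, C = 6, D = 7, E = 5,
                 F = 5, G = 6, H = 5, I = 5)
  doubles <- c(AB = 3.47, AD = 3.63, AF = 2.88, AG = 7.32, AH = 5.10,
               BD = 2.59, BE = 0.40, BG = 2.12, BH = 4.29, BI = 1.34,
               CD = 2.34, CE = -3.62, CH = 4.31, DF = 4.12, DH = 3.30,
               DI = 0.21, EH = 1.35, EI = -2.44)
  n_doubles <- c(AB = 5, AD = 5, AF = 5, AG = 5, AH = 5,
                 BD = 5, BE = 6, BG = 7, BH = 5, BI = 7,
                 CD = 6, CE = 6, CH = 5, DF = 5, DH = 5,
                 DI = 5, EH = 5, EI = 5)
  observed_doubles <- c(AB = 18.66, AD = 18.82, AF = 18.07, AG = 22.50,
                        AH = 20.29, BD = 17.77, BE = 15.58, BG = 17.31,
                        BH = 19.47, BI = 16.52, CD = 17.52, CE = 11.56,
                        CH = 19.49, DF = 19.30, DH = 18.48, DI = 15.40,
                        EH = 16.54, EI = 12.74)
  summaries <- data.frame(
    genotype = c("ID11", names(singles), names(doubles)),
    n = as.integer(c(14, n_singles, n_doubles)),
    mean = c(wt_mean, wt_mean + singles, wt_mean + doubles),
    se = NA_real_, stringsAsFactors = FALSE)
  summaries <- summaries[order(summaries$genotype, method = "radix"), ]
  rownames(summaries) <- NULL
  list(effects = effect_table(summaries, wild_type = "ID11"),
       observed_doubles = observed_doubles, wt_mean = wt_mean)
}
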