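#' Run the full epistasis analysis pipeline
#'
#' Orchestrates data loading (a replicate-level file, the built-in
#' mean-level phage fixture, or a seeded synthetic dataset), the
#' deviation-from-additivity statistics, the gamma-map fit,
#' leave-one-double-out prediction and the simulation-based model
#' comparison, writing each stage's artifact plus a run manifest to
#' `out_dir`. Re-running with identical settings and seed reproduces every
#' numeric output; on a stage failure a `FAILED` marker naming the stage is
#' left next to any partial outputs.
#'
#' @param input Path to a replicate-level assay file (see [read_assays()]),
#'   or `NULL`.
#' @param fixture Use the built-in mean-level dataset ([id11_fixture()]).
#' @param synthetic Generate a synthetic dataset ([generate_assays()]).
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed for all randomness.
#' @param reps Simulation replicates per model (default 1000).
#' @param wild_type Wild-type label for `input` data (default `"ID11"`).
#' @param noise_sd Assay noise SD for `synthetic` data.
#' @param free_scale Let the fitter optimize the map's scale parameter.
#' @param stages Character subset of `c("stats", "fit", "loo", "compare")`.
#' @return Invisibly, a list with the per-stage results and the manifest.
#' @export
run_pipeline <- function(input = NULL, fixture = FALSE, synthetic = FALSE,
                         out_dir = "epimap-out", seed = 1L, reps = 1000L,
                         wild_type = "ID11", noise_sd = 0.8,
                         free_scale = FALSE,
                         stages = c("stats", "fit", "loo", "compare")) {
  n_sources <- sum(!is.null(input), isTRUE(fixture), isTRUE(synthetic))
  if (n_sources != 1L) {
    stop("exactly one data source required: --input, --fixture or ",
         "--synthetic", call. = FALSE)
  }
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  failed_marker <- file.path(out_dir, "FAILED")
  if (file.exists(failed_marker)) unlink(failed_marker)
  set.seed(seed)

  stage <- "load"
  res <- list()
  tryCatch({
    assays <- NULL
    if (isTRUE(fixture)) {
      fx <- id11_fixture()
      effects <- fx$effects
    } else {
      assays <- if (isTRUE(synthetic)) {
        generate_assays(generator_config(noise_sd = noise_sd), seed = seed)
      } else {
        read_assays(input)
      }
      effects <- effect_table(summarize_assays(assays), wild_type = wild_type)
    }
    write_effects(effects, file.path(out_dir, "effects.csv"))
    res$effects <- effects

    if ("stats" %in% stages) {
      stage <- "stats"
      et <- epsilon_table(effects)
      utils::write.csv(et, file.path(out_dir, "epsilon_table.csv"),
                       row.names = FALSE, quote = FALSE)
      calls <- decompensation_battery(assays, effects)
      utils::write.csv(calls, file.path(out_dir, "epistasis_calls.csv"),
                       row.names = FALSE, quote = FALSE)
      mt <- mean_epsilon_test(et)
      jsonlite::write_json(mt, file.path(out_dir, "mean_epsilon_test.json"),
                           auto_unbox = TRUE, digits = NA)
      res$epsilon_table <- et
      res$calls <- calls
      res$mean_test <- mt
    }

    fit <- NULL
    if (any(c("fit", "loo", "compare") %in% stages)) {
      stage <- "fit"
      fit <- fit_gamma_map(effects, free_scale = free_scale)
      res$fit <- fit
      if ("fit" %in% stages) {
        utils::write.csv(fit_report(fit),
                         file.path(out_dir, "fit_report.csv"),
                         row.names = FALSE, quote = FALSE)
        d <- fit$diagnostics
        jsonlite::write_json(
          list(params = fit$params[c("shape", "scale", "height", "shift")],
               phenotypes = as.list(fit$phenotypes$z),
               branch = as.list(fit$phenotypes$branch),
               diagnostics = d, iterations = fit$iterations,
               converged = fit$converged),
          file.path(out_dir, "fit_summary.json"),
          auto_unbox = TRUE, digits = NA)
      }
    }

    if ("loo" %in% stages) {
      stage <- "loo"
      loo <- loo_predict(effects, free_scale = free_scale)
      utils::write.csv(loo, file.path(out_dir, "loo.csv"),
                       row.names = FALSE, quote = FALSE)
      res$loo <- loo
    }

    if ("compare" %in% stages) {
      stage <- "compare"
      cmp <- compare_models(effects, fit = fit, reps = reps)
      for (mod in c("gamma", "geometric")) {
        sim <- cmp[[paste0("sim_", mod)]]
        utils::write.csv(as.data.frame(sim$eps),
                         file.path(out_dir,
                                   paste0("epsilons_", mod, ".csv")),
                         row.names = FALSE, quote = FALSE)
      }
      jsonlite::write_json(
        c(cmp$aic,
          list(observed_mean_epsilon = mean(cmp$observed),
               sim_mean_epsilon_gamma = mean(cmp$sim_gamma$eps),
               sim_mean_epsilon_geometric = mean(cmp$sim_geometric$eps),
               n_floored_gamma = cmp$lnl_gamma$n_floored,
               n_floored_geometric = cmp$lnl_geometric$n_floored)),
        file.path(out_dir, "model_comparison.json"),
        auto_unbox = TRUE, digits = NA)
      res$comparison <- cmp
    }

    stage <- "manifest"
    manifest <- list(
      package = "epimap",
      version = as.character(utils::packageVersion("epimap")),
      r_version = R.version.string,
      timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
      settings = list(input = input, fixture = fixture,
                      synthetic = synthetic, seed = seed, reps = reps,
                      wild_type = wild_type, noise_sd = noise_sd,
                      free_scale = free_scale, stages = stages))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    res$manifest <- manifest
  }, error = function(e) {
    writeLines(paste0("stage: ", stage, "\n", conditionMessage(e)),
               failed_marker)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}

pipeline_subcommands <- c("run", "stats", "fit", "loo", "compare",
                          "simulate")

#' Command-line entry point
#'
#' Dispatches `epimap <subcommand> [options]` with subcommands `run`
#' (everything), `stats`, `fit`, `loo`, `compare` and `simulate`. Options:
#' `--input`, `--fixture`, `--synthetic`, `--seed`, `--reps`, `--out`,
#' `--wild-type-label`, `--noise`, `--free-scale`. Messages go to stderr.
#'
#' @param args Character vector of command-line arguments (default
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Integer exit status (0 on success), invisibly.
#' @export
pipeline_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) < 1L || !args[1L] %in% pipeline_subcommands) {
    message("usage: epimap <", paste(pipeline_subcommands, collapse = "|"),
            "> [options]")
    return(invisible(1L))
  }
  sub <- args[1L]
  parser <- optparse::OptionParser(
    usage = paste0("epimap ", sub, " [options]"),
    option_list = list(
      optparse::make_option("--input", type = "character", default = NULL,
                            help = "replicate-level assay file (CSV/TSV)"),
      optparse::make_option("--fixture", action = "store_true",
                            default = FALSE,
                            help = "use the built-in mean-level dataset"),
      optparse::make_option("--synthetic", action = "store_true",
                            default = FALSE,
                            help = "generate a synthetic dataset"),
      optparse::make_option("--seed", type = "integer", default = 1L),
      optparse::make_option("--reps", type = "integer", default = 1000L),
      optparse::make_option("--out", type = "character",
                            default = "epimap-out"),
      optparse::make_option("--wild-type-label", type = "character",
                            default = "ID11", dest = "wild_type"),
      optparse::make_option("--noise", type = "double", default = 0.8),
      optparse::make_option("--free-scale", action = "store_true",
                            default = FALSE, dest = "free_scale")))
  opt <- tryCatch(optparse::parse_args(parser, args[-1L]),
                  error = function(e) {
                    message(conditionMessage(e))
                    NULL
                  })
  if (is.null(opt)) return(invisible(1L))
  stages <- switch(sub,
                   run = c("stats", "fit", "loo", "compare"),
                   stats = "stats", fit = "fit", loo = "loo",
                   compare = "compare", simulate = "compare")
  status <- tryCatch({
    run_pipeline(input = opt$input, fixture = opt$fixture,
                 synthetic = opt$synthetic, out_dir = opt$out,
                 seed = opt$seed, reps = opt$reps,
                 wild_type = opt$wild_type, noise_sd = opt$noise,
                 free_scale = opt$free_scale, stages = stages)
    message("epimap ", sub, ": outputs written to ", opt$out)
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
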