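#' Read replicate-level fitness assays
#'
#' Reads a delimited text file of replicate fitness measurements, one row per
#' assay, with a header naming the columns `genotype`, `replicate` and
#' `fitness`. Fitness is a growth rate in doublings per hour.
#'
#' @param path Path to a delimited text file.
#' @param sep Field delimiter. `NULL` (default) auto-detects comma vs tab from
#'   the header line; otherwise `","` or `"\t"`.
#' @return A data frame with columns `genotype` (character), `replicate`
#'   (integer) and `fitness` (numeric), one row per assay.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("genotype,replicate,fitness", "ID11,1,15.2", "A,1,19.1"), f)
#' read_assays(f)
#' @export
read_assays <- function(path, sep = NULL) {
  if (!file.exists(path)) {
    stop("assay file not found: ", path, call. = FALSE)
  }
  header <- readLines(path, n = 1L)
  if (is.null(sep)) {
    sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", strip.white = TRUE,
                           check.names = TRUE)
  required <- c("genotype", "replicate", "fitness")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    stop("assay file is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  fitness <- suppressWarnings(as.numeric(raw$fitness))
  bad <- which(is.na(fitness) | !is.finite(fitness))
  if (length(bad) > 0L) {
    stop("non-numeric or non-finite fitness value on data row ", bad[1L],
         " (value: '", raw$fitness[bad[1L]], "')", call. = FALSE)
  }
  replicate <- suppressWarnings(as.integer(raw$replicate))
  bad <- which(is.na(replicate) | replicate < 1L)
  if (length(bad) > 0L) {
    stop("invalid replicate id on data row ", bad[1L], call. = FALSE)
  }
  genotype <- as.character(raw$genotype)
  if (any(!nzchar(genotype))) {
    stop("empty genotype label on data row ", which(!nzchar(genotype))[1L],
         call. = FALSE)
  }
  key <- paste(genotype, replicate, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicated (genotype, replicate) pair: ",
         sub("\r", "/", key[duplicated(key)][1L]), call. = FALSE)
  }
  data.frame(genotype = genotype, replicate = replicate, fitness = fitness,
             stringsAsFactors = FALSE)
}

#' Write replicate-level fitness assays
#'
#' @param assays Data frame as returned by [read_assays()] or
#'   [generate_assays()].
#' @param path Output path.
#' @param sep Field delimiter (default comma).
#' @return `path`, invisibly.
#' @export
write_assays <- function(assays, path, sep = ",") {
  stopifnot(all(c("genotype", "replicate", "fitness") %in% names(assays)))
  utils::write.table(assays[, c("genotype", "replicate", "fitness")], path,
                     sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Summarize replicate assays per genotype
#'
#' Reduces replicate-level data to the per-genotype mean, standard error
#' (sample SD with the n-1 denominator, divided by sqrt(n)) and replicate
#' count. Genotypes are returned in lexicographic order. A genotype with a
#' single replicate gets `se = NA` with a warning rather than a fabricated
#' value.
#'
#' @param assays Data frame with columns `genotype`, `replicate`, `fitness`.
#' @return Data frame with columns `genotype`, `n`, `mean`, `se`.
#' @export
summarize_assays <- function(assays) {
  stopifnot(all(c("genotype", "fitness") %in% names(assays)),
            nrow(assays) >= 1L)
  groups <- split(assays$fitness, assays$genotype)
  groups <- groups[order(names(groups), method = "radix")]
  n <- vapply(groups, length, integer(1))
  mean_f <- vapply(groups, mean, numeric(1))
  se <- vapply(groups, function(x) {
    if (length(x) < 2L) NA_real_ else stats::sd(x) / sqrt(length(x))
  }, numeric(1))
  if (anyNA(se)) {
    warning("genotype(s) with a single replicate have undefined SE: ",
            paste(names(groups)[is.na(se)], collapse = ", "), call. = FALSE)
  }
  out <- data.frame(genotype = names(groups), n = unname(n),
                    mean = unname(mean_f), se = unname(se),
                    stringsAsFactors = FALSE)
  stopifnot(sum(out$n) == nrow(assays))
  out
}

# Split a double-mutant label like "AG" into its constituent single labels.
# Singles are single-character labels; the wild type is whatever label the
# caller designates (often multi-character, e.g. "ID11").
split_pair <- function(label) {
  strsplit(label, "", fixed = TRUE)[[1L]]
}

#' Fitness effects relative to the wild type
#'
#' Converts per-genotype summaries into an effect table: for every genotype,
#' `effect = mean - mean(wild type)`. Genotypes are classified as the wild
#' type, singles (one-letter labels) or doubles (two-letter labels); each
#' double is annotated with its two constituent single labels, which must both
#' be present as singles.
#'
#' @param summaries Data frame from [summarize_assays()], or any data frame
#'   with columns `genotype`, `n`, `mean` (an `se` column is carried through
#'   if present).
#' @param wild_type Wild-type genotype label (default `"ID11"`).
#' @return Data frame with columns `genotype`, `type` (`"wild_type"`,
#'   `"single"`, `"double"`), `n`, `mean`, `se`, `effect`, `first`, `second`
#'   (constituent singles, `NA` except for doubles), carrying the attribute
#'   `wild_type_mean`.
#' @export
effect_table <- function(summaries, wild_type = "ID11") {
  stopifnot(all(c("genotype", "n", "mean") %in% names(summaries)))
  if (!wild_type %in% summaries$genotype) {
    stop("wild-type label '", wild_type, "' not present in summaries",
         call. = FALSE)
  }
  wt_mean <- summaries$mean[summaries$genotype == wild_type]
  g <- summaries$genotype
  type <- ifelse(g == wild_type, "wild_type",
                 ifelse(nchar(g) == 1L, "single", "double"))
  if (any(nchar(g) > 2L & g != wild_type)) {
    stop("unrecognized genotype label(s): ",
         paste(g[nchar(g) > 2L & g != wild_type], collapse = ", "),
         call. = FALSE)
  }
  singles <- g[type == "single"]
  first <- second <- rep(NA_character_, length(g))
  for (k in which(type == "double")) {
    parts <- split_pair(g[k])
    if (!all(parts %in% singles) || parts[1L] == parts[2L]) {
      stop("double '", g[k], "' does not decompose into two distinct ",
           "singles present in the table", call. = FALSE)
    }
    first[k] <- parts[1L]
    second[k] <- parts[2L]
  }
  out <- data.frame(genotype = g, type = type, n = summaries$n,
                    mean = summaries$mean,
                    se = if ("se" %in% names(summaries)) summaries$se
                         else NA_real_,
                    effect = summaries$mean - wt_mean,
                    first = first, second = second,
                    stringsAsFactors = FALSE)
  attr(out, "wild_type") <- wild_type
  attr(out, "wild_type_mean") <- wt_mean
  out
}

#' Write a per-genotype summary/effect table
#'
#' @param effects Data frame from [effect_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_effects <- function(effects, path) {
  utils::write.csv(effects, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
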