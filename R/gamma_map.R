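#' Gamma-shaped phenotype-to-fitness map parameters
#'
#' The map is a unimodal gamma curve (not a probability density) with four
#' parameters: shape `alpha > 1` (an interior optimum requires a rising limb),
#' scale `lambda > 0`, height `height > 0` and shift `shift`. The curve is
#'
#' \deqn{f(z) = \beta + h \, \frac{z^{\alpha-1} e^{-z/\lambda}}
#'   {(z^*)^{\alpha-1} e^{-z^*/\lambda}}, \qquad z^* = (\alpha-1)\lambda,}
#'
#' normalized by its value at the mode so that the peak fitness is exactly
#' `shift + height` and `f(0) = shift`. The phenotype scale is arbitrary:
#' rescaling `lambda` and all phenotypes by the same factor leaves the curve
#' unchanged, which is why the fitter fixes `lambda = 1` by default.
#'
#' @param shape Shape parameter, > 1.
#' @param scale Scale parameter, > 0.
#' @param height Peak height above the shift, > 0.
#' @param shift Vertical shift (curve floor at z = 0).
#' @return An object of class `gamma_map`.
#' @export
gamma_map_params <- function(shape, scale = 1, height, shift = 0) {
  stopifnot(is.finite(shape), is.finite(scale), is.finite(height),
            is.finite(shift))
  if (shape <= 1) {
    stop("shape must be > 1 (interior optimum required)", call. = FALSE)
  }
  if (scale <= 0) stop("scale must be > 0", call. = FALSE)
  if (height <= 0) stop("height must be > 0", call. = FALSE)
  structure(list(shape = shape, scale = scale, height = height,
                 shift = shift), class = "gamma_map")
}

#' @export
print.gamma_map <- function(x, ...) {
  cat(sprintf(
    "gamma phenotype-fitness map: shape %.4g, scale %.4g, height %.4g, shift %.4g\n",
    x$shape, x$scale, x$height, x$shift))
  cat(sprintf("  mode z* = %.4g, peak fitness = %.4g, floor = %.4g\n",
              gamma_mode(x), x$shift + x$height, x$shift))
  invisible(x)
}

#' Mode of the gamma map
#'
#' @param params A `gamma_map` object.
#' @return The phenotype at which fitness peaks, `(shape - 1) * scale`.
#' @export
gamma_mode <- function(params) {
  (params$shape - 1) * params$scale
}

#' Evaluate the gamma phenotype-to-fitness map
#'
#' @param params A `gamma_map` object.
#' @param z Phenotype value(s), >= 0.
#' @return Fitness value(s) on the un-normalized (shifted) scale; the peak is
#'   `shift + height`, attained at [gamma_mode()].
#' @export
gamma_fitness <- function(params, z) {
  stopifnot(all(z >= 0))
  zstar <- gamma_mode(params)
  a1 <- params$shape - 1
  # log-scale ratio g(z)/g(z*) for numerical stability; g(0) = 0 since a1 > 0
  ratio <- ifelse(z == 0, 0,
                  exp(a1 * (log(z) - log(zstar)) - (z - zstar) / params$scale))
  params$shift + params$height * ratio
}

#' Invert the gamma map
#'
#' Solves `gamma_fitness(params, z) = w` for the two phenotypes of equal
#' fitness on either side of the peak. At the peak the double root
#' `(z*, z*)` is returned.
#'
#' @param params A `gamma_map` object.
#' @param w Fitness value(s) in `(shift, shift + height]`.
#' @param tol Absolute tolerance on fitness for the root solve.
#' @return For scalar `w`, a named vector `c(z_low, z_high)`; for vector `w`,
#'   a two-column matrix with one row per fitness.
#' @export
gamma_invert <- function(params, w, tol = 1e-10) {
  peak <- params$shift + params$height
  if (any(w > peak + 1e-12)) {
    stop("fitness above the curve peak (", signif(peak, 8),
         ") is infeasible", call. = FALSE)
  }
  if (any(w <= params$shift)) {
    stop("fitness at or below the curve floor (", signif(params$shift, 8),
         ") is infeasible", call. = FALSE)
  }
  zstar <- gamma_mode(params)
  one <- function(wk) {
    if (wk >= peak) return(c(z_low = zstar, z_high = zstar))
    g <- function(z) gamma_fitness(params, z) - wk
    lo <- stats::uniroot(g, lower = 0, upper = zstar, tol = tol)$root
    # grow the upper bracket geometrically until the curve drops below wk
    ub <- 2 * zstar
    while (g(ub) > 0) ub <- ub * 2
    hi <- stats::uniroot(g, lower = zstar, upper = ub, tol = tol)$root
    c(z_low = lo, z_high = hi)
  }
  if (length(w) == 1L) one(w) else t(vapply(w, one, numeric(2)))
}
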