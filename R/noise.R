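#' @include AllClasses.R
NULL

#' Noise model specification
#'
#' Five noise models usable as pipeline processing components: `gaussian`
#' (params `mean`, `std`), `uniform` (`low`, `high`), `gamma` (`shape`,
#' `scale`), `poisson` (scaled shot noise with `scaling`, additive-only in
#' the sense that it replaces the data by `rpois(data/scaling) * scaling`),
#' and `salt_pepper` (`fraction` of entries set to the data minimum or
#' maximum with equal probability). Gaussian, uniform and gamma noise can
#' be `additive` or `multiplicative`.
#'
#' @param model noise model name.
#' @param params named list of model parameters (see above; sensible
#'   conservative defaults are filled in).
#' @param mode `"additive"` or `"multiplicative"`.
#' @param rng_seed integer seed; identical seeds give identical noise.
#' @return A validated spec (class `"noiseSpec"`).
#' @export
noiseSpec <- function(model, params = list(), mode = "additive",
                      rng_seed = 1) {
  defaults <- switch(model,
    gaussian = list(mean = 0, std = 0.01),
    uniform = list(low = -0.01, high = 0.01),
    gamma = list(shape = 2, scale = 0.005),
    poisson = list(scaling = 0.01),
    salt_pepper = list(fraction = 0.01),
    stop("unsupported noise model '", model, "'; available: gaussian, ",
         "uniform, gamma, poisson, salt_pepper"))
  p <- modifyList(defaults, params)
  if (!mode %in% c("additive", "multiplicative"))
    stop("mode must be 'additive' or 'multiplicative'")
  if (model == "gaussian" && p$std < 0) stop("std must be >= 0")
  if (model == "uniform" && p$low > p$high) stop("low must be <= high")
  if (model == "gamma" && (p$shape <= 0 || p$scale <= 0))
    stop("shape and scale must be > 0")
  if (model == "salt_pepper" && (p$fraction < 0 || p$fraction > 1))
    stop("fraction must lie in [0, 1]")
  if (model == "poisson" && p$scaling <= 0) stop("scaling must be > 0")
  structure(list(model = model, params = p, mode = mode,
                 rng_seed = rng_seed), class = "noiseSpec")
}

#' Apply a noise model to data
#'
#' Applies the configured noise model to a numeric array/matrix or to the
#' signals of a [TimeSeriesData-class]. Entries are perturbed
#' independently; the same seed always reproduces the same output.
#'
#' @param data numeric vector/matrix/array or [TimeSeriesData-class].
#' @param spec a [noiseSpec()].
#' @return Same type as `data`.
#' @examples
#' x <- matrix(0, 100, 100)
#' n <- applyNoise(x, noiseSpec("gaussian", list(std = 1), rng_seed = 7))
#' sd(n)
#' @export
applyNoise <- function(data, spec) {
  stopifnot(inherits(spec, "noiseSpec"))
  if (is(data, "TimeSeriesData")) {
    out <- data
    out@signals <- applyNoise(data@signals, spec)
    return(out)
  }
  x <- data
  n <- length(x)
  p <- spec$params
  .with_seed(spec$rng_seed, {
    noisy <- switch(spec$model,
      gaussian = {
        eps <- stats::rnorm(n, p$mean, p$std)
        if (spec$mode == "additive") x + eps else x * eps
      },
      uniform = {
        eps <- stats::runif(n, p$low, p$high)
        if (spec$mode == "additive") x + eps else x * eps
      },
      gamma = {
        eps <- stats::rgamma(n, shape = p$shape, scale = p$scale)
        if (spec$mode == "additive") x + eps else x * eps
      },
      poisson = {
        if (any(x < 0))
          stop("Poisson noise requires non-negative data")
        stats::rpois(n, as.vector(x) / p$scaling) * p$scaling
      },
      salt_pepper = {
        k <- round(p$fraction * n)
        out <- as.vector(x)
        if (k > 0) {
          idx <- sample.int(n, k)
          salt <- stats::runif(k) < 0.5
          rng_data <- range(x)
          out[idx[salt]] <- rng_data[2]
          out[idx[!salt]] <- rng_data[1]
        }
        out
      })
    out <- x
    out[] <- noisy
    out
  })
}
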