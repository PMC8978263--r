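#' @include acoustic.R
NULL

#' Reconstruction settings
#'
#' Bundles the beamforming algorithm and the signal-conditioning options of
#' the reconstruction stage. The processing order is fixed: optional Tukey
#' bandpass, optional differential (first-derivative) mode, beamforming,
#' optional envelope detection along depth.
#'
#' @param algorithm `"das"`, `"dmas"`, `"sdmas"` or `"time_reversal"`.
#' @param bandpass `NULL`, or a list with `low_hz`, `high_hz`,
#'   `tukey_alpha` (defaults 1 kHz, 8 MHz, 0.5).
#' @param differential apply the first time derivative before beamforming.
#' @param envelope apply envelope detection to the image.
#' @param sound_speed_mps scalar beamforming sound speed; `NULL` uses the
#'   reference speed stored with the time series.
#' @param fov list with `x = c(min, max)`, `z = c(min, max)` (mm) and
#'   `spacing_mm`, defining the reconstruction pixel grid.
#' @return A validated settings list (class `"reconSettings"`).
#' @export
reconSettings <- function(algorithm = "das", bandpass = NULL,
                          differential = FALSE, envelope = FALSE,
                          sound_speed_mps = NULL, fov) {
  if (!algorithm %in% c("das", "dmas", "sdmas", "time_reversal"))
    stop("unknown reconstruction algorithm '", algorithm, "'")
  if (!is.null(bandpass)) {
    bandpass <- modifyList(list(low_hz = 1e3, high_hz = 8e6,
                                tukey_alpha = 0.5), bandpass)
    if (bandpass$low_hz >= bandpass$high_hz)
      stop("bandpass low_hz must be < high_hz")
    if (bandpass$tukey_alpha < 0 || bandpass$tukey_alpha > 1)
      stop("tukey_alpha must lie in [0, 1]")
  }
  if (!is.null(sound_speed_mps) && sound_speed_mps <= 0)
    stop("sound speed must be > 0")
  stopifnot(is.list(fov), !is.null(fov$x), !is.null(fov$z),
            !is.null(fov$spacing_mm))
  structure(list(algorithm = algorithm, bandpass = bandpass,
                 differential = isTRUE(differential),
                 envelope = isTRUE(envelope),
                 sound_speed_mps = sound_speed_mps, fov = fov),
            class = "reconSettings")
}

#' Tukey bandpass filter for detector signals
#'
#' Zero-phase bandpass: each channel is transformed to the frequency
#' domain, multiplied by a Tukey (tapered-cosine) window spanning
#' `[low_hz, high_hz]` (zero outside the band, applied symmetrically to the
#' negative frequencies so the output stays real), and transformed back.
#' The defaults reproduce the common configuration of a 0.5-alpha Tukey
#' window with 1 kHz high-pass and 8 MHz low-pass edges.
#'
#' @param ts a [TimeSeriesData-class].
#' @param low_hz,high_hz band edges, `0 <= low < high <= Nyquist`.
#' @param alpha Tukey taper fraction in `[0, 1]`.
#' @return A filtered [TimeSeriesData-class].
#' @export
tukeyBandpass <- function(ts, low_hz = 1e3, high_hz = 8e6, alpha = 0.5) {
  nyquist <- 1 / (2 * ts@dt)
  if (high_hz > nyquist)
    stop(sprintf("high_hz (%.3g Hz) exceeds the Nyquist frequency (%.3g Hz)",
                 high_hz, nyquist))
  if (low_hz < 0 || low_hz >= high_hz)
    stop("band edges must satisfy 0 <= low_hz < high_hz")
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  n <- ncol(ts@signals)
  f <- 0:(n - 1)
  f[f >= n / 2] <- f[f >= n / 2] - n
  af <- abs(f / (n * ts@dt))
  x <- (af - low_hz) / (high_hz - low_hz)
  w <- numeric(n)
  inside <- x >= 0 & x <= 1
  w[inside] <- 1
  if (alpha > 0) {
    lo <- inside & x < alpha / 2
    hi <- inside & x > 1 - alpha / 2
    w[lo] <- 0.5 * (1 + cos(pi * (2 * x[lo] / alpha - 1)))
    w[hi] <- 0.5 * (1 + cos(pi * (2 * (1 - x[hi]) / alpha - 1)))
  }
  S <- stats::mvfft(t(ts@signals))
  filt <- Re(stats::mvfft(S * w, inverse = TRUE)) / n
  out <- ts
  out@signals <- t(filt)
  out
}

#' First time derivative of detector signals (differential mode)
#'
#' Central finite differences divided by the sampling interval; one-sided
#' differences at the record endpoints.
#'
#' @param ts a [TimeSeriesData-class] with at least two samples.
#' @return A [TimeSeriesData-class] holding d/dt of each channel.
#' @export
differentialMode <- function(ts) {
  n <- ncol(ts@signals)
  if (n < 2L) stop("differential mode needs at least 2 samples")
  s <- ts@signals
  d <- s
  if (n > 2L)
    d[, 2:(n - 1)] <- (s[, 3:n] - s[, 1:(n - 2)]) / (2 * ts@dt)
  d[, 1] <- (s[, 2] - s[, 1]) / ts@dt
  d[, n] <- (s[, n] - s[, n - 1]) / ts@dt
  out <- ts
  out@signals <- d
  out
}

# envelope of one real vector via the analytic signal
.hilbert_env <- function(v) {
  n <- length(v)
  H <- stats::fft(v)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(H * h, inverse = TRUE) / n)
}

#' Envelope detection
#'
#' Magnitude of the analytic (Hilbert-transformed) signal: along time for
#' detector series, along depth (the z axis) for images. The result is
#' non-negative and bounds the input magnitude from above.
#'
#' @param x a [TimeSeriesData-class], [ReconstructedImage-class], or a
#'   numeric matrix (rows = lateral, columns = depth).
#' @return Same type as the input with the envelope as payload.
#' @export
envelopeDetect <- function(x) {
  if (is(x, "TimeSeriesData")) {
    out <- x
    out@signals <- t(apply(x@signals, 1, .hilbert_env))
    return(out)
  }
  if (is(x, "ReconstructedImage")) {
    out <- x
    out@pixels <- t(apply(x@pixels, 1, .hilbert_env))
    return(out)
  }
  if (is.matrix(x)) return(t(apply(x, 1, .hilbert_env)))
  stop("unsupported input type for envelope detection")
}

# pixel centers of a reconstruction FOV
.fov_pixels <- function(fov) {
  sp <- fov$spacing_mm
  list(x = seq(fov$x[1] + sp / 2, fov$x[2] - sp / 2 + 1e-9, by = sp),
       z = seq(fov$z[1] + sp / 2, fov$z[2] - sp / 2 + 1e-9, by = sp),
       spacing = sp)
}

# delayed-sample matrix: elements x pixels, linear interpolation, zero
# outside the record
.delayed_samples <- function(ts, px, pz, c_mps) {
  ne <- nrow(ts@signals)
  nt <- ncol(ts@signals)
  npix <- length(px)
  d <- matrix(0, ne, npix)
  ex <- ts@positions[, 1]
  ez <- ts@positions[, 3]
  for (i in seq_len(ne)) {
    tau <- sqrt((px - ex[i])^2 + (pz - ez[i])^2) * 1e-3 / c_mps
    idx <- (tau - ts@t0) / ts@dt + 1
    i0 <- floor(idx)
    frac <- idx - i0
    ok <- i0 >= 1 & i0 < nt
    v <- numeric(npix)
    v[ok] <- ts@signals[i, i0[ok]] * (1 - frac[ok]) +
      ts@signals[i, i0[ok] + 1] * frac[ok]
    exact <- i0 == nt & frac == 0
    v[exact] <- ts@signals[i, nt]
    d[i, ] <- v
  }
  d
}

#' Delay-and-sum beamforming
#'
#' For every pixel r the image value is the sum over elements of the
#' recorded signal delayed by the time of flight `|r - r_i| / c`, with
#' linear interpolation between samples and zero contribution outside the
#' record; no apodization is applied.
#'
#' @param ts a [TimeSeriesData-class].
#' @param settings a [reconSettings()] list (the `fov` and sound speed are
#'   used).
#' @return A [ReconstructedImage-class].
#' @export
delayAndSum <- function(ts, settings) {
  pix <- .fov_pixels(settings$fov)
  c_mps <- if (is.null(settings$sound_speed_mps)) ts@soundSpeed
           else settings$sound_speed_mps
  g <- expand.grid(x = pix$x, z = pix$z)
  d <- .delayed_samples(ts, g$x, g$z, c_mps)
  img <- matrix(colSums(d), length(pix$x), length(pix$z))
  new("ReconstructedImage", pixels = img, spacing = pix$spacing,
      origin = c(settings$fov$x[1], settings$fov$z[1]),
      settings = unclass(settings))
}

#' Delay-multiply-and-sum beamforming
#'
#' Pairwise-multiplicative beamforming: with delayed samples `d_i`, the
#' pixel value is the sum over unordered element pairs of
#' `sign(d_i d_j) sqrt(|d_i d_j|)`. The signed variant additionally
#' multiplies each pair term by `sign(d_i + d_j)`, preserving the polarity
#' of the dominant contribution. A single element yields a zero image
#' (empty pair sum).
#'
#' @param ts a [TimeSeriesData-class].
#' @param settings a [reconSettings()] list.
#' @param signed use the sign-preserving (sDMAS) variant.
#' @return A [ReconstructedImage-class].
#' @export
delayMultiplyAndSum <- function(ts, settings, signed = FALSE) {
  pix <- .fov_pixels(settings$fov)
  c_mps <- if (is.null(settings$sound_speed_mps)) ts@soundSpeed
           else settings$sound_speed_mps
  g <- expand.grid(x = pix$x, z = pix$z)
  d <- .delayed_samples(ts, g$x, g$z, c_mps)
  ne <- nrow(d)
  y <- sign(d) * sqrt(abs(d))
  if (ne < 2L) {
    vals <- numeric(ncol(d))
  } else if (!signed) {
    # sum_{i<j} y_i y_j = ((sum y)^2 - sum y^2) / 2
    vals <- (colSums(y)^2 - colSums(y^2)) / 2
  } else {
    vals <- numeric(ncol(d))
    for (i in seq_len(ne - 1L)) {
      yi <- y[i, ]; di <- d[i, ]
      for (j in (i + 1L):ne)
        vals <- vals + yi * y[j, ] * sign(di + d[j, ])
    }
  }
  img <- matrix(vals, length(pix$x), length(pix$z))
  new("ReconstructedImage", pixels = img, spacing = pix$spacing,
      origin = c(settings$fov$x[1], settings$fov$z[1]),
      settings = unclass(settings))
}

#' Time-reversal reconstruction
#'
#' Re-emits the recorded signals backwards in time into a numerical model
#' of the medium: the time-reversed signals are injected as additive
#' pressure sources at the detector element positions while the k-space
#' solver runs, and the image is the pressure field at the final (t = 0)
#' step restricted to the FOV.
#'
#' @param ts a [TimeSeriesData-class].
#' @param slice an [AcousticSlice-class] describing the medium (its p0 is
#'   ignored).
#' @param settings a [reconSettings()] list.
#' @return A [ReconstructedImage-class].
#' @export
timeReversal <- function(ts, slice, settings) {
  medium <- slice
  medium@p0 <- matrix(0, nrow(slice@p0), ncol(slice@p0))
  dt_solver <- medium@cfl * medium@spacing * 1e-3 / max(medium@sos)
  nt <- ncol(ts@signals)
  t_total <- (nt - 1) * ts@dt
  n_steps <- max(2L, floor(t_total / dt_solver) + 1L)
  # reversed signals resampled onto the solver time axis
  t_rev <- t_total - (seq_len(n_steps) - 1) * dt_solver
  t_rec <- (seq_len(nt) - 1) * ts@dt
  src <- t(apply(ts@signals, 1, function(s)
    stats::approx(t_rec, s, xout = t_rev, rule = 2)$y))
  prop <- kspacePropagate(medium, n_steps,
                          source = list(positions =
                                          ts@positions[, c(1, 3),
                                                       drop = FALSE],
                                        signals = src),
                          dt = dt_solver)
  pix <- .fov_pixels(settings$fov)
  g <- expand.grid(x = pix$x, z = pix$z)
  gc <- .slice_coords(medium, cbind(g$x, g$z))
  vals <- .bilinear(prop$p_final, gc[, 1], gc[, 2])
  img <- matrix(vals, length(pix$x), length(pix$z))
  new("ReconstructedImage", pixels = img, spacing = pix$spacing,
      origin = c(settings$fov$x[1], settings$fov$z[1]),
      settings = unclass(settings))
}

#' Run the configured reconstruction pipeline
#'
#' Composes the reconstruction primitives according to the settings flags:
#' Tukey bandpass, then differential mode, then the selected beamformer,
#' then envelope detection. All modes of the signal-conditioning sweep are
#' compositions of these same primitives toggled by flags.
#'
#' @param ts a [TimeSeriesData-class].
#' @param settings a [reconSettings()] list.
#' @param medium an [AcousticSlice-class]; required for time reversal.
#' @return A [ReconstructedImage-class].
#' @export
reconstructImage <- function(ts, settings, medium = NULL) {
  if (!is.null(settings$bandpass))
    ts <- tukeyBandpass(ts, settings$bandpass$low_hz,
                        settings$bandpass$high_hz,
                        settings$bandpass$tukey_alpha)
  if (settings$differential) ts <- differentialMode(ts)
  img <- switch(settings$algorithm,
    das = delayAndSum(ts, settings),
    dmas = delayMultiplyAndSum(ts, settings, signed = FALSE),
    sdmas = delayMultiplyAndSum(ts, settings, signed = TRUE),
    time_reversal = {
      if (is.null(medium))
        stop("time reversal needs the medium slice")
      timeReversal(ts, medium, settings)
    })
  if (settings$envelope) img <- envelopeDetect(img)
  img
}

#' Crop an image to a field-of-view box
#'
#' Restricts the pixel grid to the pixels whose centers fall inside the
#' box and updates the grid origin; values are unchanged. Cropping twice
#' equals cropping once with the intersected boxes.
#'
#' @param image a [ReconstructedImage-class].
#' @param box `c(xmin, xmax, zmin, zmax)` in mm.
#' @return A cropped [ReconstructedImage-class].
#' @export
cropFov <- function(image, box) {
  nx <- nrow(image@pixels); nz <- ncol(image@pixels)
  cx <- image@origin[1] + (seq_len(nx) - 0.5) * image@spacing
  cz <- image@origin[2] + (seq_len(nz) - 0.5) * image@spacing
  ix <- which(cx >= box[1] & cx <= box[2])
  iz <- which(cz >= box[3] & cz <= box[4])
  if (length(ix) == 0L || length(iz) == 0L)
    stop("crop box does not intersect the image")
  new("ReconstructedImage",
      pixels = image@pixels[ix, iz, drop = FALSE], spacing = image@spacing,
      origin = c(cx[ix[1]] - image@spacing / 2, cz[iz[1]] - image@spacing / 2),
      settings = image@settings)
}
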