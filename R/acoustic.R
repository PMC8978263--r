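#' @include optical.R
NULL

#' Construct a 2-D acoustic medium slice
#'
#' @param p0 initial pressure matrix (nx x nz, arbitrary units).
#' @param sos speed-of-sound matrix (m/s).
#' @param rho density matrix (kg/m^3).
#' @param spacing_mm grid spacing (mm).
#' @param origin_mm c(x0, z0) of the slice (mm).
#' @param pml perfectly-matched-layer width in grid points (>= 4,
#'   default 8).
#' @param cfl Courant number for the time step (default 0.3).
#' @return An [AcousticSlice-class].
#' @export
makeAcousticSlice <- function(p0, sos, rho, spacing_mm,
                              origin_mm = c(0, 0), pml = 8L, cfl = 0.3) {
  new("AcousticSlice", p0 = p0, sos = sos, rho = rho,
      spacing = as.numeric(spacing_mm), origin = as.numeric(origin_mm),
      pml = as.integer(pml), cfl = as.numeric(cfl))
}

#' Extract the imaging-plane slice from 3-D volumes
#'
#' Cuts the x-z plane at a y index (mid-plane by default) out of the
#' property volumes and the initial pressure grid; the slice inherits the
#' grid spacing.
#'
#' @param volumes a [PropertyVolumes-class].
#' @param p0 a [PressureGrid-class] on the same grid (or `NULL` for a
#'   zero-pressure medium slice).
#' @param y_index 1-based y index; default `ceiling(ny / 2)`.
#' @param pml,cfl solver controls, see [makeAcousticSlice()].
#' @return An [AcousticSlice-class].
#' @export
extractSlice <- function(volumes, p0 = NULL, y_index = NULL, pml = 8L,
                         cfl = 0.3) {
  ny <- volumes@grid@shape[2]
  if (is.null(y_index)) y_index <- as.integer(ceiling(ny / 2))
  if (y_index < 1 || y_index > ny)
    stop("y_index ", y_index, " out of range [1, ", ny, "]")
  p0m <- if (is.null(p0)) {
    array(0, dim = volumes@grid@shape)[, y_index, ]
  } else {
    if (!identical(p0@grid@shape, volumes@grid@shape))
      stop("p0 and property grids have different shapes")
    p0@p0[, y_index, ]
  }
  makeAcousticSlice(as.matrix(p0m), as.matrix(volumes@sos[, y_index, ]),
                    as.matrix(volumes@rho[, y_index, ]),
                    volumes@grid@spacing,
                    volumes@grid@origin[c(1, 3)], pml, cfl)
}

# world mm -> fractional (1-based) grid coordinates of a slice
.slice_coords <- function(slice, xy) {
  cbind((xy[, 1] - slice@origin[1]) / slice@spacing + 0.5,
        (xy[, 2] - slice@origin[2]) / slice@spacing + 0.5)
}

# bilinear interpolation of a matrix at fractional 1-based coordinates
.bilinear <- function(m, gi, gj) {
  nx <- nrow(m); nz <- ncol(m)
  i0 <- pmin(pmax(floor(gi), 1), nx - 1)
  j0 <- pmin(pmax(floor(gj), 1), nz - 1)
  fi <- pmin(pmax(gi - i0, 0), 1)
  fj <- pmin(pmax(gj - j0, 0), 1)
  m[cbind(i0, j0)] * (1 - fi) * (1 - fj) +
    m[cbind(i0 + 1, j0)] * fi * (1 - fj) +
    m[cbind(i0, j0 + 1)] * (1 - fi) * fj +
    m[cbind(i0 + 1, j0 + 1)] * fi * fj
}

#' Propagate an initial pressure field with the k-space method
#'
#' Advances the first-order coupled linear acoustics equations (pressure /
#' particle velocity / acoustic density) on a 2-D grid using spectral
#' spatial derivatives on staggered grids, the k-space temporal correction
#' `sinc(c_ref k dt / 2)`, and a split-field perfectly matched layer with a
#' quadratic absorption ramp. The initial condition is `p = p0` with zero
#' particle velocity. The time step is `dt = cfl * dx / max(sos)`; passing
#' an explicit `dt` above that limit is refused.
#'
#' @param slice an [AcousticSlice-class].
#' @param n_steps number of time steps (>= 1).
#' @param sensors optional m x 2 matrix of (x, z) world positions (mm) at
#'   which the pressure is recorded each step by bilinear interpolation.
#' @param record_fields if `TRUE`, the full pressure field of every step is
#'   returned (nx x nz x n_steps array; small grids only).
#' @param source optional additive pressure source: a list with
#'   `positions` (m x 2, mm) and `signals` (m x n_steps), injected at the
#'   nearest grid nodes after each update step (used for time reversal).
#' @param dt optional explicit time step in seconds (must satisfy the CFL
#'   limit).
#' @param record_energy if `TRUE`, the acoustic energy functional
#'   (potential `p^2 / (2 rho c^2)` plus kinetic `rho |u|^2 / 2`, summed
#'   over the physical domain) is recorded each step.
#' @return List with `sensor_data` (m x n_steps or `NULL`), `dt` (s),
#'   `fields` (array or `NULL`), `p_final` (matrix), `energy` (vector or
#'   `NULL`) and `c_ref` (m/s).
#' @export
kspacePropagate <- function(slice, n_steps, sensors = NULL,
                            record_fields = FALSE, source = NULL,
                            dt = NULL, record_energy = FALSE) {
  validObject(slice)
  if (n_steps < 1) stop("n_steps must be >= 1")
  # pad the domain by the PML width (edge-replicated medium) so that the
  # absorbing layer lies outside the physical volume
  np <- slice@pml
  pad <- function(m) {
    m2 <- m[c(rep(1, np), seq_len(nrow(m)), rep(nrow(m), np)), , drop = FALSE]
    m2[, c(rep(1, np), seq_len(ncol(m)), rep(ncol(m), np)), drop = FALSE]
  }
  phys_nx <- nrow(slice@p0); phys_nz <- ncol(slice@p0)
  slice_p0 <- pad(slice@p0)
  slice_p0[c(seq_len(np), np + phys_nx + seq_len(np)), ] <- 0
  slice_p0[, c(seq_len(np), np + phys_nz + seq_len(np))] <- 0
  work <- slice
  work@p0 <- slice_p0
  work@sos <- pad(slice@sos)
  work@rho <- pad(slice@rho)
  work@origin <- slice@origin - np * slice@spacing
  slice <- work
  crop_i <- np + seq_len(phys_nx)
  crop_j <- np + seq_len(phys_nz)

  nx <- nrow(slice@p0); nz <- ncol(slice@p0)
  dx <- slice@spacing * 1e-3
  c2 <- slice@sos^2
  rho0 <- slice@rho
  c_max <- max(slice@sos)
  dt_max <- slice@cfl * dx / c_max
  if (is.null(dt)) {
    dt <- dt_max
  } else if (dt > dt_max * (1 + 1e-12)) {
    stop(sprintf(
      "time step %.3g s violates the CFL limit %.3g s (CFL %.2f, dx %.3g mm, c_max %.0f m/s)",
      dt, dt_max, slice@cfl, slice@spacing, c_max))
  }
  c_ref <- c_max

  freqs <- function(n) {
    f <- 0:(n - 1)
    f[f >= n / 2] <- f[f >= n / 2] - n
    2 * pi * f / (n * dx)
  }
  kx <- freqs(nx); kz <- freqs(nz)
  KX <- matrix(kx, nx, nz)
  KZ <- matrix(kz, nx, nz, byrow = TRUE)
  K <- sqrt(KX^2 + KZ^2)
  arg <- c_ref * K * dt / 2
  kappa <- ifelse(arg == 0, 1, sin(arg) / arg)
  DDXp <- 1i * KX * kappa * exp(1i * KX * dx / 2)
  DDXm <- 1i * KX * kappa * exp(-1i * KX * dx / 2)
  DDZp <- 1i * KZ * kappa * exp(1i * KZ * dx / 2)
  DDZm <- 1i * KZ * kappa * exp(-1i * KZ * dx / 2)

  # quadratic PML absorption ramp
  pml <- slice@pml
  sigma_max <- 2 * c_ref / dx
  ramp <- function(n) {
    s <- numeric(n)
    if (n >= 2 * pml) {
      prof <- sigma_max * ((pml:1) / pml)^2
      s[1:pml] <- prof
      s[(n - pml + 1):n] <- rev(prof)
    }
    s
  }
  PX <- matrix(exp(-ramp(nx) * dt / 2), nx, nz)
  PZ <- matrix(exp(-ramp(nz) * dt / 2), nx, nz, byrow = TRUE)

  ifft2 <- function(M) Re(stats::fft(M, inverse = TRUE)) / length(M)

  rhox <- slice@p0 / (2 * c2)
  rhoz <- rhox
  ux <- matrix(0, nx, nz)
  uz <- matrix(0, nx, nz)
  p <- c2 * (rhox + rhoz)

  have_sensors <- !is.null(sensors)
  if (have_sensors) {
    gc <- .slice_coords(slice, sensors)
    bad <- which(gc[, 1] < 1 | gc[, 1] > nx | gc[, 2] < 1 | gc[, 2] > nz)
    if (length(bad) > 0L)
      stop("sensor element(s) outside the grid: ",
           paste(bad, collapse = ", "))
    sensor_data <- matrix(0, nrow(sensors), n_steps)
  }
  if (!is.null(source)) {
    sc <- .slice_coords(slice, source$positions)
    si <- pmin(pmax(round(sc[, 1]), 1), nx)
    sj <- pmin(pmax(round(sc[, 2]), 1), nz)
    src_idx <- cbind(si, sj)
  }
  fields <- if (record_fields)
    array(0, dim = c(phys_nx, phys_nz, n_steps)) else NULL
  energy <- if (record_energy) numeric(n_steps) else NULL

  for (step in seq_len(n_steps)) {
    Fp <- stats::fft(p)
    ux <- PX * (PX * ux - dt / rho0 * ifft2(DDXp * Fp))
    uz <- PZ * (PZ * uz - dt / rho0 * ifft2(DDZp * Fp))
    rhox <- PX * (PX * rhox - dt * rho0 * ifft2(DDXm * stats::fft(ux)))
    rhoz <- PZ * (PZ * rhoz - dt * rho0 * ifft2(DDZm * stats::fft(uz)))
    if (!is.null(source)) {
      s <- source$signals[, step]
      rhox[src_idx] <- rhox[src_idx] + s / (2 * c2[src_idx])
      rhoz[src_idx] <- rhoz[src_idx] + s / (2 * c2[src_idx])
    }
    p <- c2 * (rhox + rhoz)
    if (anyNA(p) || any(!is.finite(p)))
      stop("acoustic solver produced non-finite values at step ", step)
    if (have_sensors)
      sensor_data[, step] <- .bilinear(p, gc[, 1], gc[, 2])
    if (record_fields) fields[, , step] <- p[crop_i, crop_j]
    if (record_energy)
      energy[step] <- sum((p[crop_i, crop_j]^2 /
                             (2 * rho0[crop_i, crop_j] *
                                c2[crop_i, crop_j])) +
                          rho0[crop_i, crop_j] *
                            (ux[crop_i, crop_j]^2 +
                               uz[crop_i, crop_j]^2) / 2)
  }
  list(sensor_data = if (have_sensors) sensor_data else NULL, dt = dt,
       fields = fields, p_final = p[crop_i, crop_j], energy = energy,
       c_ref = c_ref)
}

#' Record detector time series from propagated fields
#'
#' Samples a stored pressure-field sequence at the detector element
#' positions (mapped into the slice plane by dropping y) with bilinear
#' interpolation, optionally resampling to the detector sampling rate when
#' it is lower than the solver rate.
#'
#' @param fields nx x nz x n_steps pressure array from [kspacePropagate()]
#'   run with `record_fields = TRUE`.
#' @param dt solver time step (s).
#' @param slice the [AcousticSlice-class] the fields live on.
#' @param detection a [DetectionGeometry-class].
#' @param device_position 3-vector device position (mm).
#' @param resample if `TRUE` and the detector sampling rate is below
#'   `1/dt`, signals are linearly resampled to the detector rate.
#' @return A [TimeSeriesData-class].
#' @export
recordTimeSeries <- function(fields, dt, slice, detection,
                             device_position = c(0, 0, 0),
                             resample = FALSE) {
  pos3 <- sweep(detection@positions, 2, device_position, "+")
  xy <- pos3[, c(1, 3), drop = FALSE]
  gc <- .slice_coords(slice, xy)
  nx <- dim(fields)[1]; nz <- dim(fields)[2]; nt <- dim(fields)[3]
  bad <- which(gc[, 1] < 1 | gc[, 1] > nx | gc[, 2] < 1 | gc[, 2] > nz)
  if (length(bad) > 0L)
    stop("detector element(s) outside the grid: ",
         paste(bad, collapse = ", "))
  sig <- matrix(0, nrow(xy), nt)
  for (t in seq_len(nt))
    sig[, t] <- .bilinear(fields[, , t], gc[, 1], gc[, 2])
  out_dt <- dt
  if (resample && detection@samplingRate < 1 / dt) {
    t_old <- (seq_len(nt) - 1) * dt
    out_dt <- 1 / detection@samplingRate
    t_new <- seq(0, t_old[nt], by = out_dt)
    sig <- t(apply(sig, 1, function(s)
      stats::approx(t_old, s, xout = t_new, rule = 2)$y))
  }
  new("TimeSeriesData", signals = sig, dt = out_dt, t0 = 0,
      positions = pos3, soundSpeed = mean(slice@sos))
}

#' Acoustic forward simulation for a device
#'
#' Convenience wrapper: extracts the imaging-plane slice, propagates the
#' initial pressure, and records the pressure at the device's detector
#' elements inline (without storing full field snapshots).
#'
#' @param volumes a [PropertyVolumes-class].
#' @param p0 a [PressureGrid-class].
#' @param device a [DeviceTwin-class]; elements must map into the slice.
#' @param t_end_s simulated time span (s); default covers the longest
#'   element-to-corner path at the slowest sound speed plus 20 percent.
#' @param y_index,pml,cfl see [extractSlice()].
#' @return A [TimeSeriesData-class] (time step equals the solver step).
#' @export
runAcousticForward <- function(volumes, p0, device, t_end_s = NULL,
                               y_index = NULL, pml = 8L, cfl = 0.3) {
  slice <- extractSlice(volumes, p0, y_index, pml, cfl)
  pos3 <- elementPositions(device)
  xy <- pos3[, c(1, 3), drop = FALSE]
  if (is.null(t_end_s)) {
    nx <- nrow(slice@p0); nz <- ncol(slice@p0)
    corners <- rbind(
      c(slice@origin[1], slice@origin[2]),
      c(slice@origin[1] + nx * slice@spacing, slice@origin[2]),
      c(slice@origin[1], slice@origin[2] + nz * slice@spacing),
      c(slice@origin[1] + nx * slice@spacing,
        slice@origin[2] + nz * slice@spacing))
    dmax <- max(sqrt(outer(xy[, 1], corners[, 1], "-")^2 +
                     outer(xy[, 2], corners[, 2], "-")^2))
    t_end_s <- 1.2 * (dmax * 1e-3) / min(slice@sos)
  }
  dt <- slice@cfl * slice@spacing * 1e-3 / max(slice@sos)
  n_steps <- max(1L, ceiling(t_end_s / dt))
  prop <- kspacePropagate(slice, n_steps, sensors = xy)
  new("TimeSeriesData", signals = prop$sensor_data, dt = prop$dt, t0 = 0,
      positions = pos3, soundSpeed = mean(slice@sos))
}

#' Apply homogeneous frequency-dependent acoustic attenuation
#'
#' Applies the post-hoc attenuation filter `10^(-alpha f[MHz] d[cm] / 20)`
#' per channel in the frequency domain, with a single distance proxy `d`
#' for all channels (homogeneous-medium simplification). `alpha = 0` is
#' the identity.
#'
#' @param ts a [TimeSeriesData-class].
#' @param alpha_db_cm_mhz attenuation coefficient (dB cm^-1 MHz^-1, >= 0).
#' @param distance_mm propagation distance proxy (mm).
#' @return A [TimeSeriesData-class] with filtered signals.
#' @export
applyAttenuation <- function(ts, alpha_db_cm_mhz, distance_mm) {
  if (alpha_db_cm_mhz < 0) stop("attenuation coefficient must be >= 0")
  if (alpha_db_cm_mhz == 0) return(ts)
  n <- ncol(ts@signals)
  f <- 0:(n - 1)
  f[f >= n / 2] <- f[f >= n / 2] - n
  f_hz <- f / (n * ts@dt)
  fac <- 10^(-alpha_db_cm_mhz * abs(f_hz) / 1e6 * (distance_mm / 10) / 20)
  S <- stats::mvfft(t(ts@signals))
  filt <- Re(stats::mvfft(S * fac, inverse = TRUE)) / n
  out <- ts
  out@signals <- t(filt)
  out
}
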