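#' @include AllClasses.R
NULL

#' Build a linear detector array
#'
#' Elements are spaced `pitch_mm` apart along the x axis, centered on
#' `center_mm`, with normals pointing along +z (into the tissue). The
#' aperture is `(n - 1) * pitch_mm`.
#'
#' @param n number of elements (>= 1).
#' @param pitch_mm element pitch in mm (> 0).
#' @param center_mm 3-vector, array center (mm).
#' @param sampling_rate_hz detector sampling rate (default 40 MHz).
#' @return A [DetectionGeometry-class].
#' @examples
#' arr <- buildLinearArray(128, 0.3)
#' diff(range(elementPositions(arr)[, 1]))  # aperture 38.1 mm
#' @export
buildLinearArray <- function(n, pitch_mm, center_mm = c(0, 0, 0),
                             sampling_rate_hz = 40e6) {
  if (n < 1) stop("n must be >= 1")
  if (pitch_mm <= 0) stop("pitch must be > 0")
  x <- (seq_len(n) - (n + 1) / 2) * pitch_mm
  pos <- cbind(center_mm[1] + x, center_mm[2], center_mm[3])
  nrm <- matrix(rep(c(0, 0, 1), each = n), ncol = 3)
  new("DetectionGeometry", kind = "linear_array", positions = pos,
      normals = nrm, samplingRate = sampling_rate_hz, pitch = pitch_mm,
      radius = NA_real_, span = NA_real_)
}

#' Build a curved (arc) detector array
#'
#' Elements sit on a circular arc of radius `radius_mm` around `focus_mm`
#' in the x-z plane, spanning `span_deg` degrees centered on the upward
#' (-z) direction; normals point at the focus. For a partial arc the
#' elements include both endpoints (n = 2, span = 90 subtends exactly 90
#' degrees); a full ring (span = 360) spaces the elements by `360/n`
#' degrees without duplicating the seam.
#'
#' @param n number of elements (>= 1).
#' @param radius_mm arc radius (> 0).
#' @param span_deg angular span in degrees, 0 < span <= 360.
#' @param focus_mm 3-vector, arc center / acoustic focus (mm).
#' @param sampling_rate_hz detector sampling rate (default 40 MHz).
#' @return A [DetectionGeometry-class].
#' @export
buildCurvedArray <- function(n, radius_mm, span_deg, focus_mm = c(0, 0, 0),
                             sampling_rate_hz = 40e6) {
  if (n < 1) stop("n must be >= 1")
  if (radius_mm <= 0) stop("radius must be > 0")
  if (span_deg <= 0 || span_deg > 360)
    stop("angular span must lie in (0, 360] degrees")
  if (span_deg == 360) {
    theta <- (seq_len(n) - 1) * 2 * pi / n - pi
  } else if (n == 1L) {
    theta <- 0
  } else {
    half <- span_deg / 2 * pi / 180
    theta <- seq(-half, half, length.out = n)
  }
  pos <- cbind(focus_mm[1] + radius_mm * sin(theta), focus_mm[2],
               focus_mm[3] - radius_mm * cos(theta))
  nrm <- cbind(-sin(theta), 0, cos(theta))
  new("DetectionGeometry", kind = "curved_array", positions = pos,
      normals = nrm, samplingRate = sampling_rate_hz, pitch = NA_real_,
      radius = radius_mm, span = span_deg)
}

#' Build a planar detector array
#'
#' A rectangular grid of elements in the x-y plane with normals along +z.
#'
#' @param nx,ny element counts along x and y.
#' @param pitch_mm element pitch (mm).
#' @param center_mm 3-vector, array center (mm).
#' @param sampling_rate_hz detector sampling rate (default 40 MHz).
#' @return A [DetectionGeometry-class].
#' @export
buildPlanarArray <- function(nx, ny, pitch_mm, center_mm = c(0, 0, 0),
                             sampling_rate_hz = 40e6) {
  if (nx < 1 || ny < 1) stop("element counts must be >= 1")
  if (pitch_mm <= 0) stop("pitch must be > 0")
  gx <- (seq_len(nx) - (nx + 1) / 2) * pitch_mm
  gy <- (seq_len(ny) - (ny + 1) / 2) * pitch_mm
  g <- expand.grid(x = gx, y = gy)
  pos <- cbind(center_mm[1] + g$x, center_mm[2] + g$y, center_mm[3])
  nrm <- matrix(rep(c(0, 0, 1), each = nrow(pos)), ncol = 3)
  new("DetectionGeometry", kind = "planar_array", positions = pos,
      normals = nrm, samplingRate = sampling_rate_hz, pitch = pitch_mm,
      radius = NA_real_, span = NA_real_)
}

#' Create an illumination geometry
#'
#' All bundled illumination geometries are collimated: photons start at a
#' position drawn from the geometry's footprint and travel along the shared
#' `direction`.
#'
#' @param kind one of `"pencil"`, `"pencil_array"`, `"slit"`, `"disk"`,
#'   `"gaussian"`.
#' @param origin_mm 3-vector, beam origin (mm).
#' @param direction propagation direction (normalized internally).
#' @param length_mm slit length (slit).
#' @param radius_mm disk radius (disk).
#' @param sigma_mm Gaussian beam sigma, truncated at 3 sigma (gaussian).
#' @param n,pitch_mm pencil count and spacing (pencil_array).
#' @param axis unit vector of the slit / pencil-array axis (default x).
#' @return An [IlluminationGeometry-class].
#' @export
IlluminationGeometry <- function(kind, origin_mm = c(0, 0, 0),
                                 direction = c(0, 0, 1), length_mm = 10,
                                 radius_mm = 2, sigma_mm = 1, n = 8,
                                 pitch_mm = 1, axis = c(1, 0, 0)) {
  direction <- direction / sqrt(sum(direction^2))
  axis <- axis / sqrt(sum(axis^2))
  params <- switch(kind,
    pencil = list(),
    pencil_array = list(n = n, pitch_mm = pitch_mm, axis = axis),
    slit = list(length_mm = length_mm, axis = axis),
    disk = list(radius_mm = radius_mm),
    gaussian = list(sigma_mm = sigma_mm),
    stop("unsupported illumination kind '", kind, "'"))
  new("IlluminationGeometry", kind = kind, origin = as.numeric(origin_mm),
      direction = direction, params = params)
}

# two unit vectors spanning the plane perpendicular to d
.orthobasis <- function(d) {
  ref <- if (abs(d[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- c(d[2] * ref[3] - d[3] * ref[2], d[3] * ref[1] - d[1] * ref[3],
         d[1] * ref[2] - d[2] * ref[1])
  u <- u / sqrt(sum(u^2))
  v <- c(d[2] * u[3] - d[3] * u[2], d[3] * u[1] - d[1] * u[3],
         d[1] * u[2] - d[2] * u[1])
  list(u = u, v = v)
}

#' Sample photon launch positions and directions
#'
#' Draws `n` photon launch states from an illumination geometry: a pencil
#' beam launches every photon at the origin; a pencil array distributes
#' photons uniformly over its discrete pencils; a slit draws positions
#' uniformly along its segment; a disk uniformly over its area; a Gaussian
#' beam from a 2-D normal truncated at 3 sigma. Directions are the
#' geometry direction (collimated illumination). Uses R's RNG; seed with
#' [set.seed()] for reproducibility.
#'
#' @param illum an [IlluminationGeometry-class].
#' @param n number of photons.
#' @return List with `positions` and `directions`, both n x 3 matrices.
#' @export
samplePhotonLaunch <- function(illum, n) {
  validObject(illum)
  o <- illum@origin
  d <- illum@direction
  p <- illum@params
  pos <- switch(illum@kind,
    pencil = matrix(rep(o, each = n), ncol = 3),
    pencil_array = {
      ax <- p$axis
      idx <- sample.int(p$n, n, replace = TRUE)
      offs <- (idx - (p$n + 1) / 2) * p$pitch_mm
      cbind(o[1] + offs * ax[1], o[2] + offs * ax[2], o[3] + offs * ax[3])
    },
    slit = {
      ax <- p$axis
      t <- stats::runif(n, -p$length_mm / 2, p$length_mm / 2)
      cbind(o[1] + t * ax[1], o[2] + t * ax[2], o[3] + t * ax[3])
    },
    disk = {
      b <- .orthobasis(d)
      r <- p$radius_mm * sqrt(stats::runif(n))
      th <- stats::runif(n, 0, 2 * pi)
      du <- r * cos(th); dv <- r * sin(th)
      cbind(o[1] + du * b$u[1] + dv * b$v[1],
            o[2] + du * b$u[2] + dv * b$v[2],
            o[3] + du * b$u[3] + dv * b$v[3])
    },
    gaussian = {
      b <- .orthobasis(d)
      draw_trunc <- function(m) {
        out <- numeric(0)
        while (length(out) < m) {
          cand <- stats::rnorm(2 * (m - length(out)), 0, p$sigma_mm)
          out <- c(out, cand[abs(cand) <= 3 * p$sigma_mm])
        }
        out[seq_len(m)]
      }
      du <- draw_trunc(n); dv <- draw_trunc(n)
      cbind(o[1] + du * b$u[1] + dv * b$v[1],
            o[2] + du * b$u[2] + dv * b$v[2],
            o[3] + du * b$u[3] + dv * b$v[3])
    })
  list(positions = pos,
       directions = matrix(rep(d, each = n), ncol = 3))
}

#' Create a digital device twin
#'
#' Combines any detection geometry with any illumination geometry into a
#' device, positioned in the simulation volume and carrying the
#' field-of-view box used for reconstruction and cropping.
#'
#' @param detection a [DetectionGeometry-class].
#' @param illumination an [IlluminationGeometry-class].
#' @param position_mm 3-vector device position (mm); translates detection
#'   elements and illumination origin rigidly.
#' @param fov_mm 2 x 3 matrix (rows min/max; columns x/y/z) in world
#'   coordinates, or `NULL` for a default box in front of the device.
#' @return A [DeviceTwin-class].
#' @export
DeviceTwin <- function(detection, illumination, position_mm = c(0, 0, 0),
                       fov_mm = NULL) {
  if (is.null(fov_mm)) {
    xr <- range(detection@positions[, 1]) + position_mm[1]
    fov_mm <- rbind(c(xr[1], -1, 0), c(xr[2], 1, 25))
  }
  new("DeviceTwin", detection = detection, illumination = illumination,
      position = as.numeric(position_mm), fov = fov_mm)
}

#' Illumination geometry of a device in world coordinates
#'
#' @param device a [DeviceTwin-class].
#' @return The device's [IlluminationGeometry-class] with its origin
#'   shifted by the device position.
#' @export
deviceIllumination <- function(device) {
  il <- device@illumination
  il@origin <- il@origin + device@position
  il
}

#' Named device presets
#'
#' Generic parameterized stand-ins for common probe archetypes (not
#' calibrated to any vendor hardware):
#' * `"handheld_probe"`: curved array, 256 elements, 40 mm radius, 125
#'   degree span, slit illumination.
#' * `"ring_system"`: full-ring curved array, 256 elements, 40 mm radius,
#'   disk illumination.
#' * `"linear_probe"`: 128-element linear array, 0.3 mm pitch, slit
#'   illumination.
#'
#' @param name preset name.
#' @param position_mm device position (mm).
#' @param fov_mm optional 2 x 3 FOV matrix.
#' @return A [DeviceTwin-class].
#' @export
devicePreset <- function(name, position_mm = c(0, 0, 0), fov_mm = NULL) {
  switch(name,
    handheld_probe = DeviceTwin(
      buildCurvedArray(256, 40, 125),
      IlluminationGeometry("slit", origin_mm = c(0, 0, -1), length_mm = 20),
      position_mm, fov_mm),
    ring_system = DeviceTwin(
      buildCurvedArray(256, 40, 360),
      IlluminationGeometry("disk", origin_mm = c(0, 0, -1), radius_mm = 5),
      position_mm, fov_mm),
    linear_probe = DeviceTwin(
      buildLinearArray(128, 0.3),
      IlluminationGeometry("slit", origin_mm = c(0, 0, -1), length_mm = 20),
      position_mm, fov_mm),
    stop("unknown device preset '", name, "'; available: handheld_probe, ",
         "ring_system, linear_probe"))
}
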