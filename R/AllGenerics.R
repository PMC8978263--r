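#' @include AllClasses.R
NULL

#' Accessor generics
#'
#' Small accessor layer so that user code never reaches into slots:
#' `gridSpec()` returns the [GridSpec-class] of a gridded object,
#' `wavelengths()` the simulated wavelengths (nm), `fluence()` /
#' `initialPressure()` / `pixels()` / `signals()` the numeric payloads, and
#' `elementPositions()` detector element positions in world coordinates
#' (mm).
#'
#' @param object an object of the respective class.
#' @return See the individual descriptions above.
#' @name accessors
#' @aliases gridSpec wavelengths fluence initialPressure pixels signals
#'   elementPositions timeStep
NULL

#' @rdname accessors
#' @export
setGeneric("gridSpec", function(object) standardGeneric("gridSpec"))
#' @rdname accessors
#' @export
setGeneric("wavelengths", function(object) standardGeneric("wavelengths"))
#' @rdname accessors
#' @export
setGeneric("fluence", function(object) standardGeneric("fluence"))
#' @rdname accessors
#' @export
setGeneric("initialPressure",
           function(object) standardGeneric("initialPressure"))
#' @rdname accessors
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))
#' @rdname accessors
#' @export
setGeneric("signals", function(object) standardGeneric("signals"))
#' @rdname accessors
#' @export
setGeneric("timeStep", function(object) standardGeneric("timeStep"))
#' @rdname accessors
#' @export
setGeneric("elementPositions",
           function(object) standardGeneric("elementPositions"))

#' @rdname accessors
setMethod("gridSpec", "PropertyVolumes", function(object) object@grid)
#' @rdname accessors
setMethod("gridSpec", "FluenceGrid", function(object) object@grid)
#' @rdname accessors
setMethod("gridSpec", "PressureGrid", function(object) object@grid)
#' @rdname accessors
setMethod("wavelengths", "PropertyVolumes",
          function(object) object@wavelengths)
#' @rdname accessors
setMethod("fluence", "FluenceGrid", function(object) object@phi)
#' @rdname accessors
setMethod("initialPressure", "PressureGrid", function(object) object@p0)
#' @rdname accessors
setMethod("pixels", "ReconstructedImage", function(object) object@pixels)
#' @rdname accessors
setMethod("signals", "TimeSeriesData", function(object) object@signals)
#' @rdname accessors
setMethod("timeStep", "TimeSeriesData", function(object) object@dt)
#' @rdname accessors
setMethod("elementPositions", "DetectionGeometry",
          function(object) object@positions)
#' @rdname accessors
setMethod("elementPositions", "DeviceTwin", function(object)
  sweep(object@detection@positions, 2, object@position, "+"))

setMethod("show", "Spectrum", function(object) {
  cat(sprintf("Spectrum '%s': %d knots over %g-%g nm\n", object@name,
              length(object@wavelengths), min(object@wavelengths),
              max(object@wavelengths)))
})

setMethod("show", "Molecule", function(object) {
  cat(sprintf("Molecule '%s' (vf %.3f, role %s)\n", object@name,
              object@volumeFraction, object@role))
  cat(sprintf("  sos %.0f m/s, rho %.0f kg/m^3, alpha %.3g dB/cm/MHz, Gamma %.3g\n",
              object@speedOfSound, object@density,
              object@acousticAttenuation, object@gruneisen))
})

setMethod("show", "MolecularComposition", function(object) {
  cat(sprintf("MolecularComposition '%s' with %d member(s):\n", object@name,
              length(object@members)))
  for (m in object@members)
    cat(sprintf("  %-22s vf %.4f\n", m@name, m@volumeFraction))
})

setMethod("show", "GridSpec", function(object) {
  cat(sprintf("GridSpec %d x %d x %d voxels, %.3g mm spacing, origin (%g, %g, %g) mm\n",
              object@shape[1], object@shape[2], object@shape[3],
              object@spacing, object@origin[1], object@origin[2],
              object@origin[3]))
})

setMethod("show", "Structure", function(object) {
  cat(sprintf("Structure '%s' (priority %g, tissue '%s'%s%s)\n", object@kind,
              object@priority, object@composition@name,
              if (object@partialVolume) ", partial volume" else "",
              if (object@adhereToDeformation) ", deformable" else ""))
})

setMethod("show", "PropertyVolumes", function(object) {
  cat("PropertyVolumes\n")
  show(object@grid)
  cat(sprintf("  wavelengths: %s nm\n",
              paste(object@wavelengths, collapse = ", ")))
  cat(sprintf("  segmentation labels: %s\n",
              paste(sort(unique(as.vector(object@segmentation))),
                    collapse = ", ")))
})

setMethod("show", "DetectionGeometry", function(object) {
  cat(sprintf("DetectionGeometry '%s': %d elements, fs %.3g MHz\n",
              object@kind, nrow(object@positions),
              object@samplingRate / 1e6))
})

setMethod("show", "IlluminationGeometry", function(object) {
  cat(sprintf("IlluminationGeometry '%s' at (%g, %g, %g) mm\n", object@kind,
              object@origin[1], object@origin[2], object@origin[3]))
})

setMethod("show", "DeviceTwin", function(object) {
  cat("DeviceTwin\n  ")
  show(object@detection)
  cat("  ")
  show(object@illumination)
  cat(sprintf("  position (%g, %g, %g) mm, FOV x[%g, %g] y[%g, %g] z[%g, %g] mm\n",
              object@position[1], object@position[2], object@position[3],
              object@fov[1, 1], object@fov[2, 1], object@fov[1, 2],
              object@fov[2, 2], object@fov[1, 3], object@fov[2, 3]))
})

setMethod("show", "FluenceGrid", function(object) {
  cat(sprintf("FluenceGrid at %g nm, %g photons (seed %g)\n",
              object@wavelength, object@nPhotons, object@seed))
  cat(sprintf("  absorbed %.4f, escaped %.4f of launched energy\n",
              object@absorbed, object@escaped))
})

setMethod("show", "TimeSeriesData", function(object) {
  cat(sprintf("TimeSeriesData: %d detectors x %d samples, dt %.3g ns, c_ref %.0f m/s\n",
              nrow(object@signals), ncol(object@signals), object@dt * 1e9,
              object@soundSpeed))
})

setMethod("show", "ReconstructedImage", function(object) {
  cat(sprintf("ReconstructedImage %d x %d pixels, %.3g mm spacing (%s)\n",
              nrow(object@pixels), ncol(object@pixels), object@spacing,
              if (!is.null(object@settings$algorithm))
                object@settings$algorithm else "unknown algorithm"))
})

setMethod("show", "SimulationStore", function(object) {
  cat(sprintf("SimulationStore: %s\n", object@path))
})
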