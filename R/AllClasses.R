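#' @include pasim-package.R
NULL

# ---------------------------------------------------------------------------
# Tissue property containers
# ---------------------------------------------------------------------------

#' Wavelength-dependent property spectrum
#'
#' A `Spectrum` holds a wavelength-dependent tissue property (optical
#' absorption, scattering, or anisotropy) as a table of knots. Values between
#' knots are obtained by piecewise-linear interpolation; queries outside the
#' knot range are clamped to the nearest endpoint so that coefficients can
#' never become negative by extrapolation.
#'
#' @slot name character, property/chromophore name.
#' @slot wavelengths numeric, strictly ascending wavelengths in nm.
#' @slot values numeric, property values at the knots (units depend on the
#'   property: cm^-1 for absorption/scattering, unitless for anisotropy).
#' @seealso [Spectrum()], [interpolateSpectrum()]
#' @export
setClass("Spectrum",
  representation(name = "character", wavelengths = "numeric",
                 values = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@wavelengths) < 1L)
      msg <- c(msg, "a Spectrum needs at least one knot")
    if (length(object@wavelengths) != length(object@values))
      msg <- c(msg, "wavelengths and values must have equal length")
    if (any(!is.finite(object@wavelengths)) || any(!is.finite(object@values)))
      msg <- c(msg, "wavelengths and values must be finite")
    if (length(object@wavelengths) > 1L &&
        any(diff(object@wavelengths) <= 0))
      msg <- c(msg, "wavelengths must be strictly ascending")
    if (is.null(msg)) TRUE else msg
  })

#' Optical and acoustic properties of one molecule
#'
#' A `Molecule` bundles the wavelength-dependent optical properties
#' (absorption, scattering, anisotropy spectra) with scalar acoustic
#' properties (speed of sound, density, acoustic attenuation) and the
#' Grueneisen parameter. Molecules carry the volume fraction they occupy
#' within a [MolecularComposition-class].
#'
#' @slot name character.
#' @slot absorption,scattering,anisotropy [Spectrum-class] objects
#'   (cm^-1, cm^-1, unitless).
#' @slot gruneisen unitless Grueneisen parameter (>= 0).
#' @slot speedOfSound m/s (> 0).
#' @slot density kg/m^3 (> 0).
#' @slot acousticAttenuation dB cm^-1 MHz^-1 (>= 0).
#' @slot volumeFraction fraction in `[0, 1]`.
#' @slot role one of `"oxyhemoglobin"`, `"deoxyhemoglobin"`, `"other"`;
#'   used to derive blood oxygen saturation of mixtures.
#' @export
setClass("Molecule",
  representation(name = "character", absorption = "Spectrum",
                 scattering = "Spectrum", anisotropy = "Spectrum",
                 gruneisen = "numeric", speedOfSound = "numeric",
                 density = "numeric", acousticAttenuation = "numeric",
                 volumeFraction = "numeric", role = "character"),
  validity = function(object) {
    msg <- NULL
    sc <- c(gruneisen = object@gruneisen, sos = object@speedOfSound,
            rho = object@density, alpha = object@acousticAttenuation,
            vf = object@volumeFraction)
    if (any(!is.finite(sc)))
      msg <- c(msg, "all scalar properties must be finite")
    if (object@speedOfSound <= 0) msg <- c(msg, "speed of sound must be > 0")
    if (object@density <= 0) msg <- c(msg, "density must be > 0")
    if (object@acousticAttenuation < 0)
      msg <- c(msg, "acoustic attenuation must be >= 0")
    if (object@gruneisen < 0) msg <- c(msg, "Grueneisen parameter must be >= 0")
    if (object@volumeFraction < 0 || object@volumeFraction > 1)
      msg <- c(msg, "volume fraction must lie in [0, 1]")
    if (!object@role %in% c("oxyhemoglobin", "deoxyhemoglobin", "other"))
      msg <- c(msg, "role must be oxyhemoglobin, deoxyhemoglobin or other")
    if (any(object@absorption@values < 0) || any(object@scattering@values < 0))
      msg <- c(msg, "absorption/scattering spectra must be >= 0")
    if (any(abs(object@anisotropy@values) > 1))
      msg <- c(msg, "anisotropy must lie in [-1, 1]")
    if (is.null(msg)) TRUE else msg
  })

#' Linear mixture of molecules representing a tissue type
#'
#' @slot name character.
#' @slot members list of [Molecule-class] objects; their volume fractions
#'   must sum to a value in (0, 1] (a deficit behaves as transparent filler
#'   for the optical coefficients and is renormalized away for the acoustic
#'   ones, see [mixComposition()]).
#' @export
setClass("MolecularComposition",
  representation(name = "character", members = "list"),
  validity = function(object) {
    msg <- NULL
    if (length(object@members) < 1L)
      msg <- c(msg, "a composition needs at least one member")
    if (!all(vapply(object@members, is, logical(1), "Molecule")))
      msg <- c(msg, "all members must be Molecule objects")
    else {
      ftot <- sum(vapply(object@members, function(m) m@volumeFraction,
                         numeric(1)))
      if (ftot <= 0 || ftot > 1 + 1e-6)
        msg <- c(msg, sprintf(
          "member volume fractions must sum to (0, 1]; got %.8f", ftot))
    }
    if (is.null(msg)) TRUE else msg
  })

# ---------------------------------------------------------------------------
# Voxel grids
# ---------------------------------------------------------------------------

#' Isotropic voxel grid specification
#'
#' Defines the computational grid: voxel counts along x/y/z, the isotropic
#' voxel edge length in mm, and the position of the corner of voxel
#' (1,1,1). Voxel centers sit at `origin + (i - 0.5) * spacing` (1-based
#' index); the z axis points into the tissue (depth).
#'
#' @slot shape integer vector (nx, ny, nz).
#' @slot spacing voxel edge length in mm (> 0).
#' @slot origin corner position in mm.
#' @export
setClass("GridSpec",
  representation(shape = "integer", spacing = "numeric", origin = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@shape) != 3L || any(object@shape < 1L))
      msg <- c(msg, "shape must be three voxel counts >= 1")
    if (length(object@spacing) != 1L || !is.finite(object@spacing) ||
        object@spacing <= 0)
      msg <- c(msg, "spacing must be a positive scalar (mm)")
    if (length(object@origin) != 3L || any(!is.finite(object@origin)))
      msg <- c(msg, "origin must be a finite 3-vector (mm)")
    if (is.null(msg)) TRUE else msg
  })

#' Geometric structure of a tissue scene
#'
#' A prioritized geometric primitive carrying a molecular composition.
#' Supported kinds: `layer`, `sphere`, `elliptical_tube`, `cuboid`,
#' `parallelepiped`, `vessel_tree`, `background`. Voxels claimed by several
#' structures are resolved by descending priority with fractional
#' (partial-volume) capacity sharing, see [createModelBasedVolume()].
#'
#' @slot kind character, one of the supported kinds.
#' @slot params list of kind-specific geometry parameters (mm).
#' @slot composition [MolecularComposition-class].
#' @slot priority numeric >= 0 (background is always ranked last).
#' @slot partialVolume logical; sub-voxel occupancy sampling if `TRUE`.
#' @slot adhereToDeformation logical; if `TRUE` the structure follows the
#'   surface deformation height field.
#' @export
setClass("Structure",
  representation(kind = "character", params = "list",
                 composition = "MolecularComposition", priority = "numeric",
                 partialVolume = "logical", adhereToDeformation = "logical"),
  validity = function(object) {
    kinds <- c("layer", "sphere", "elliptical_tube", "cuboid",
               "parallelepiped", "vessel_tree", "background")
    msg <- NULL
    if (!object@kind %in% kinds)
      msg <- c(msg, paste0("unsupported structure kind '", object@kind, "'"))
    if (!is.finite(object@priority) || object@priority < 0)
      msg <- c(msg, "priority must be a finite number >= 0")
    nump <- unlist(Filter(is.numeric, object@params))
    if (length(nump) && any(!is.finite(nump)))
      msg <- c(msg, "geometry parameters must be finite")
    if (is.null(msg)) TRUE else msg
  })

#' Smooth surface deformation height field
#'
#' A sum of random-phase sinusoids over the lateral (x, y) plane, scaled so
#' that the maximum absolute vertical offset does not exceed `amplitude` mm.
#' Structures with `adhereToDeformation = TRUE` evaluate their membership
#' tests at the shifted depth `z - offset(x, y)`.
#'
#' @slot amplitude maximum |offset| in mm (>= 0).
#' @slot coefficients numeric matrix with columns `a`, `kx`, `ky`, `phase`.
#' @slot extent lateral extent (mm) the mode frequencies refer to.
#' @export
setClass("DeformationField",
  representation(amplitude = "numeric", coefficients = "matrix",
                 extent = "numeric"),
  validity = function(object) {
    if (object@amplitude < 0) "amplitude must be >= 0" else TRUE
  })

#' Voxelized tissue property volumes
#'
#' Per-wavelength grids of the optical properties (absorption `mua`,
#' scattering `mus` in cm^-1, anisotropy `g`) and single-copy grids of the
#' wavelength-independent properties: Grueneisen parameter `gamma`, speed of
#' sound `sos` (m/s), density `rho` (kg/m^3), acoustic attenuation `alpha`
#' (dB cm^-1 MHz^-1), blood oxygen saturation `so2` (NA where no hemoglobin
#' is present) and the integer `segmentation` labels.
#'
#' @slot mua,mus,g named lists of 3-D arrays, one per wavelength (names are
#'   the wavelengths in nm).
#' @slot gamma,sos,rho,alpha,so2,segmentation 3-D arrays.
#' @slot grid [GridSpec-class].
#' @slot wavelengths numeric, wavelengths in nm.
#' @export
setClass("PropertyVolumes",
  representation(mua = "list", mus = "list", g = "list", gamma = "array",
                 sos = "array", rho = "array", alpha = "array", so2 = "array",
                 segmentation = "array", grid = "GridSpec",
                 wavelengths = "numeric"),
  validity = function(object) {
    msg <- NULL
    shp <- object@grid@shape
    wl <- as.character(object@wavelengths)
    for (nm in c("mua", "mus", "g")) {
      lst <- slot(object, nm)
      if (!all(wl %in% names(lst)))
        msg <- c(msg, sprintf("'%s' must hold a grid for every wavelength", nm))
      else if (!all(vapply(lst[wl], function(a) identical(dim(a), shp),
                           logical(1))))
        msg <- c(msg, sprintf("'%s' grids must match the grid shape", nm))
    }
    for (nm in c("gamma", "sos", "rho", "alpha", "so2", "segmentation"))
      if (!identical(dim(slot(object, nm)), shp))
        msg <- c(msg, sprintf("'%s' grid must match the grid shape", nm))
    if (any(object@sos <= 0) || any(object@rho <= 0))
      msg <- c(msg, "speed of sound and density must be > 0 everywhere")
    if (is.null(msg)) TRUE else msg
  })

# ---------------------------------------------------------------------------
# Devices
# ---------------------------------------------------------------------------

#' Detector array geometry
#'
#' @slot kind `"linear_array"`, `"curved_array"` or `"planar_array"`.
#' @slot positions n x 3 matrix of element positions (mm, device frame).
#' @slot normals n x 3 matrix of unit element normals.
#' @slot samplingRate detector sampling rate in Hz.
#' @slot pitch,radius,span geometry parameters (mm / mm / degrees; NA where
#'   not applicable).
#' @export
setClass("DetectionGeometry",
  representation(kind = "character", positions = "matrix", normals = "matrix",
                 samplingRate = "numeric", pitch = "numeric",
                 radius = "numeric", span = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (nrow(object@positions) < 1L)
      msg <- c(msg, "at least one detector element is required")
    if (!all(is.finite(object@positions)))
      msg <- c(msg, "element positions must be finite")
    nrm <- sqrt(rowSums(object@normals^2))
    if (any(abs(nrm - 1) > 1e-6))
      msg <- c(msg, "element normals must be unit length")
    if (object@samplingRate <= 0) msg <- c(msg, "sampling rate must be > 0")
    if (is.null(msg)) TRUE else msg
  })

#' Illumination geometry
#'
#' Collimated illumination: all photons share the geometry direction and
#' launch positions are drawn according to the kind (`pencil`,
#' `pencil_array`, `slit`, `disk`, `gaussian`).
#'
#' @slot kind illumination kind.
#' @slot origin 3-vector, beam origin (mm, device frame).
#' @slot direction unit 3-vector.
#' @slot params kind-specific sizes: `length_mm` + `axis` (slit),
#'   `radius_mm` (disk), `sigma_mm` (gaussian), `n` + `pitch_mm` + `axis`
#'   (pencil_array).
#' @export
setClass("IlluminationGeometry",
  representation(kind = "character", origin = "numeric",
                 direction = "numeric", params = "list"),
  validity = function(object) {
    msg <- NULL
    if (!object@kind %in% c("pencil", "pencil_array", "slit", "disk",
                            "gaussian"))
      msg <- c(msg, paste0("unsupported illumination kind '", object@kind, "'"))
    if (abs(sqrt(sum(object@direction^2)) - 1) > 1e-6)
      msg <- c(msg, "direction must be a unit vector")
    sizes <- unlist(Filter(is.numeric, object@params))
    if (length(sizes) && any(sizes < 0))
      msg <- c(msg, "size parameters must be >= 0")
    if (is.null(msg)) TRUE else msg
  })

#' Digital device twin
#'
#' A photoacoustic device is a combination of a detection geometry and an
#' illumination geometry together with the device position in the volume and
#' its field of view. Any detection geometry combines with any illumination
#' geometry. The stored geometries live in the device frame; world
#' coordinates are obtained by adding `position`.
#'
#' @slot detection [DetectionGeometry-class].
#' @slot illumination [IlluminationGeometry-class].
#' @slot position 3-vector (mm).
#' @slot fov 2 x 3 matrix, rows min/max, columns x/y/z extents (mm, world
#'   frame).
#' @export
setClass("DeviceTwin",
  representation(detection = "DetectionGeometry",
                 illumination = "IlluminationGeometry",
                 position = "numeric", fov = "matrix"),
  validity = function(object) {
    msg <- NULL
    if (length(object@position) != 3L || any(!is.finite(object@position)))
      msg <- c(msg, "device position must be a finite 3-vector")
    if (!identical(dim(object@fov), c(2L, 3L)))
      msg <- c(msg, "fov must be a 2 x 3 matrix (min/max rows)")
    else if (any(object@fov[2, ] - object@fov[1, ] < 0))
      msg <- c(msg, "fov extents must be non-negative")
    if (is.null(msg)) TRUE else msg
  })

# ---------------------------------------------------------------------------
# Simulation results
# ---------------------------------------------------------------------------

#' Optical fluence grid
#'
#' Normalized fluence phi (mm^-2 per unit delivered energy) from the Monte
#' Carlo solver, together with the energy bookkeeping of the run.
#'
#' @slot phi 3-D array, >= 0.
#' @slot grid [GridSpec-class].
#' @slot wavelength nm.
#' @slot nPhotons number of launched photons.
#' @slot seed RNG seed used.
#' @slot absorbed,escaped,rouletteKilled,rouletteBoosted weight fractions
#'   per launched unit energy.
#' @export
setClass("FluenceGrid",
  representation(phi = "array", grid = "GridSpec", wavelength = "numeric",
                 nPhotons = "numeric", seed = "numeric", absorbed = "numeric",
                 escaped = "numeric", rouletteKilled = "numeric",
                 rouletteBoosted = "numeric"),
  validity = function(object) {
    if (any(!is.finite(object@phi)) || any(object@phi < 0))
      "fluence must be finite and >= 0" else TRUE
  })

#' Initial pressure grid
#'
#' p0 = Grueneisen * mua * phi (arbitrary units), zero wherever mua is
#' zero. [computeInitialPressure()] always produces non-negative values;
#' the container itself only requires finiteness so that noise stages may
#' perturb a stored p0 below zero.
#'
#' @slot p0 3-D array.
#' @slot grid [GridSpec-class].
#' @slot wavelength nm.
#' @export
setClass("PressureGrid",
  representation(p0 = "array", grid = "GridSpec", wavelength = "numeric"),
  validity = function(object) {
    if (any(!is.finite(object@p0)))
      "initial pressure must be finite" else TRUE
  })

#' 2-D medium slice for the acoustic solver
#'
#' The imaging (x-z) plane of the 3-D property volumes: initial pressure,
#' speed of sound and density, plus solver controls (PML width, CFL number).
#'
#' @slot p0,sos,rho matrices (nx x nz).
#' @slot spacing grid spacing in mm.
#' @slot origin c(x0, z0) of the slice in mm.
#' @slot pml perfectly-matched-layer width in grid points (>= 4).
#' @slot cfl Courant number used to pick the time step (<= 0.3).
#' @export
setClass("AcousticSlice",
  representation(p0 = "matrix", sos = "matrix", rho = "matrix",
                 spacing = "numeric", origin = "numeric", pml = "integer",
                 cfl = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (!identical(dim(object@p0), dim(object@sos)) ||
        !identical(dim(object@p0), dim(object@rho)))
      msg <- c(msg, "p0, sos and rho slices must share their shape")
    if (any(object@sos <= 0) || any(object@rho <= 0))
      msg <- c(msg, "sos and rho must be > 0")
    if (object@pml < 4L) msg <- c(msg, "PML width must be >= 4 grid points")
    if (object@cfl <= 0 || object@cfl > 0.3)
      msg <- c(msg, "CFL number must lie in (0, 0.3]")
    if (is.null(msg)) TRUE else msg
  })

#' Detector time series
#'
#' @slot signals detectors x time-samples matrix (pressure, arbitrary units).
#' @slot dt time step in seconds.
#' @slot t0 start time in seconds.
#' @slot positions element positions (mm, world frame, n x 3).
#' @slot soundSpeed reference sound speed (m/s) for beamforming.
#' @export
setClass("TimeSeriesData",
  representation(signals = "matrix", dt = "numeric", t0 = "numeric",
                 positions = "matrix", soundSpeed = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (any(!is.finite(object@signals))) msg <- c(msg, "signals must be finite")
    if (object@dt <= 0) msg <- c(msg, "dt must be > 0")
    if (nrow(object@signals) != nrow(object@positions))
      msg <- c(msg, "one row of signals per detector element is required")
    if (is.null(msg)) TRUE else msg
  })

#' Reconstructed 2-D image
#'
#' @slot pixels nx x nz matrix (arbitrary units).
#' @slot spacing pixel edge length in mm.
#' @slot origin c(x0, z0) of the pixel grid in mm.
#' @slot settings the reconstruction settings used (provenance).
#' @export
setClass("ReconstructedImage",
  representation(pixels = "matrix", spacing = "numeric", origin = "numeric",
                 settings = "list"),
  validity = function(object) {
    if (any(!is.finite(object@pixels))) "pixels must be finite" else TRUE
  })

#' Hierarchical HDF5 simulation store
#'
#' Thin handle around the HDF5 output file with top-level groups
#' `Settings`, `Device`, `Simulations` and the `pipeline` dataset.
#'
#' @slot path file path.
#' @export
setClass("SimulationStore", representation(path = "character"))
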