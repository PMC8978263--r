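#' @include store.R reconstruction.R noise.R spectral.R
NULL

#' Registry of standardized settings tag names
#'
#' Single source of the key names used throughout the settings tree, so
#' that every pipeline element and the store agree on naming.
#'
#' @format Named list of tag strings.
#' @export
Tags <- list(
  SPACING_MM = "spacing_mm",
  WAVELENGTHS_NM = "wavelengths_nm",
  VOLUME_EXTENT_MM = "volume_extent_mm",
  RANDOM_SEED = "rng_seed",
  OUTPUT_PATH = "output_path",
  LOG_FILE = "log_file",
  N_PHOTONS = "n_photons",
  SCENE = "scene",
  DEFORMATION = "deformation",
  SUBDIV = "subdiv",
  SEGMENTATION_MASK = "mask",
  LABEL_MAP = "label_map",
  PML = "pml",
  CFL = "cfl",
  T_END_S = "t_end_s",
  ALGORITHM = "algorithm",
  BANDPASS = "bandpass",
  DIFFERENTIAL = "differential",
  ENVELOPE = "envelope",
  SOUND_SPEED_MPS = "sound_speed_mps",
  NOISE_MODEL = "model",
  NOISE_PARAMS = "params",
  NOISE_MODE = "mode",
  TARGET_FIELD = "target_field",
  CHROMOPHORES = "chromophores",
  SOURCE_FIELD = "source_field",
  N_ITERATIONS = "n_iterations")

.KNOWN_GENERAL_TAGS <- c("spacing_mm", "wavelengths_nm", "volume_extent_mm",
                         "rng_seed", "output_path", "log_file")

#' Assemble a settings tree
#'
#' The settings tree has a `general` sub-tree (grid spacing, wavelengths,
#' volume extent, seed, output path) and one sub-tree per pipeline element
#' type. Required general tags are validated; unknown general tags trigger
#' a warning, not an error.
#'
#' @param general list with at least `spacing_mm` (> 0), `wavelengths_nm`
#'   (>= 1 wavelength), `volume_extent_mm` (3-vector), `rng_seed`,
#'   `output_path`.
#' @param ... element sub-trees, e.g. `volume_creation = list(...)`,
#'   `optical = list(n_photons = 1e5)`.
#' @return A nested settings list (class `"paSettings"`).
#' @export
paSettings <- function(general, ...) {
  stopifnot(is.list(general))
  unknown <- setdiff(names(general), .KNOWN_GENERAL_TAGS)
  if (length(unknown) > 0L)
    warning("unknown general tag(s): ", paste(unknown, collapse = ", "))
  if (is.null(general$spacing_mm) || general$spacing_mm <= 0)
    stop("general settings need spacing_mm > 0")
  if (is.null(general$wavelengths_nm) || length(general$wavelengths_nm) < 1L)
    stop("general settings need at least one wavelength")
  if (is.null(general$rng_seed)) general$rng_seed <- 42L
  if (is.null(general$output_path))
    general$output_path <- tempfile(fileext = ".h5")
  structure(c(list(general = general), list(...)), class = "paSettings")
}

#' Define a pipeline element
#'
#' Pipeline elements are self-contained: they read their inputs from and
#' write their outputs to the HDF5 store only, so implementations can be
#' exchanged freely without touching other elements. Multispectral
#' elements (`linear_unmixing`, `qpai`) run once after the per-wavelength
#' loop.
#'
#' @param type one of `"volume_creation"`, `"optical"`, `"acoustic"`,
#'   `"noise"`, `"reconstruction"`, `"crop"`, `"linear_unmixing"`,
#'   `"qpai"`.
#' @param settings_key name of the element's sub-tree in the settings
#'   (defaults to `type`, so two noise elements can use different trees).
#' @return A pipeline element description (class `"pipelineElement"`).
#' @export
pipelineElement <- function(type, settings_key = type) {
  known <- c("volume_creation", "optical", "acoustic", "noise",
             "reconstruction", "crop", "linear_unmixing", "qpai")
  if (!type %in% known)
    stop("unknown pipeline element type '", type, "'")
  structure(list(type = type, settings_key = settings_key,
                 multispectral = type %in% c("linear_unmixing", "qpai")),
            class = "pipelineElement")
}

.pa_log <- function(settings, element, msg) {
  line <- sprintf("[pasim] %s %s: %s", format(Sys.time(), "%H:%M:%S"),
                  element, msg)
  message(line)
  lf <- settings$general$log_file
  if (!is.null(lf)) cat(line, "\n", file = lf, append = TRUE)
}

# deterministic per-element / per-wavelength seed below 2^31
.derive_seed <- function(global, elem_idx, wl_idx) {
  (((global %% 65536) * 31 + elem_idx) * 1009 + wl_idx * 101) %% 2147483647
}

.default_grid <- function(settings) {
  ext <- settings$general$volume_extent_mm
  sp <- settings$general$spacing_mm
  GridSpec(pmax(1L, round(ext / sp)), sp)
}

# --- element implementations (store-mediated) ------------------------------

.elem_volume <- function(store, sub, settings, device, wl, seed) {
  wavelengths <- settings$general$wavelengths_nm
  if (all(vapply(wavelengths, function(w)
    fieldExists(store, "mua", w), logical(1))))
    return(invisible(NULL))  # already created on the first wavelength pass
  grid <- .default_grid(settings)
  vols <- if (!is.null(sub$mask)) {
    createSegmentationBasedVolume(sub$mask, sub$label_map, grid, wavelengths)
  } else {
    def <- NULL
    if (!is.null(sub$deformation)) {
      d <- sub$deformation
      def <- makeDeformation(d$amplitude_mm,
                             if (is.null(d$n_modes)) 5 else d$n_modes,
                             if (is.null(d$rng_seed)) seed else d$rng_seed,
                             grid)
    }
    createModelBasedVolume(sub$scene, grid, wavelengths, def,
                           subdiv = if (is.null(sub$subdiv)) 3 else
                             sub$subdiv)
  }
  for (w in wavelengths) {
    wlk <- as.character(w)
    saveField(store, "mua", vols@mua[[wlk]], w)
    saveField(store, "mus", vols@mus[[wlk]], w)
    saveField(store, "g", vols@g[[wlk]], w)
  }
  so2 <- vols@so2
  so2[is.na(so2)] <- NaN
  saveField(store, "gamma", vols@gamma)
  saveField(store, "sos", vols@sos)
  saveField(store, "rho", vols@rho)
  saveField(store, "alpha", vols@alpha)
  saveField(store, "so2", so2)
  saveField(store, "segmentation", vols@segmentation)
  saveField(store, "grid_spacing_mm", grid@spacing)
  saveField(store, "grid_origin_mm", grid@origin)
  invisible(NULL)
}

# rebuild a PropertyVolumes for one wavelength from the store
.load_volumes <- function(store, settings, wl) {
  sp <- as.numeric(loadField(store, "grid_spacing_mm"))
  orig <- as.numeric(loadField(store, "grid_origin_mm"))
  mua <- loadField(store, "mua", wl)
  grid <- GridSpec(dim(mua), sp, orig)
  wlk <- as.character(wl)
  so2 <- loadField(store, "so2")
  new("PropertyVolumes",
      mua = setNames(list(mua), wlk),
      mus = setNames(list(loadField(store, "mus", wl)), wlk),
      g = setNames(list(loadField(store, "g", wl)), wlk),
      gamma = loadField(store, "gamma"), sos = loadField(store, "sos"),
      rho = loadField(store, "rho"), alpha = loadField(store, "alpha"),
      so2 = so2, segmentation = loadField(store, "segmentation"),
      grid = grid, wavelengths = as.numeric(wl))
}

.elem_optical <- function(store, sub, settings, device, wl, seed) {
  vols <- .load_volumes(store, settings, wl)
  n_photons <- if (is.null(sub$n_photons)) 1e5 else sub$n_photons
  fl <- runMonteCarlo(vols, wl, deviceIllumination(device), n_photons,
                      rng_seed = seed)
  p0 <- computeInitialPressure(fl, vols)
  saveField(store, "phi", fl@phi, wl)
  saveField(store, "p0", p0@p0, wl)
  invisible(NULL)
}

.elem_acoustic <- function(store, sub, settings, device, wl, seed) {
  vols <- .load_volumes(store, settings, wl)
  p0 <- new("PressureGrid", p0 = loadField(store, "p0", wl),
            grid = vols@grid, wavelength = as.numeric(wl))
  ts <- runAcousticForward(vols, p0, device,
                           t_end_s = sub$t_end_s,
                           pml = if (is.null(sub$pml)) 8L else sub$pml,
                           cfl = if (is.null(sub$cfl)) 0.3 else sub$cfl)
  saveField(store, "time_series", ts@signals, wl)
  # stored time metadata uses ms (package-wide time unit for metadata)
  saveField(store, "time_series_dt_ms", ts@dt * 1e3)
  saveField(store, "sound_speed_ref", ts@soundSpeed)
  invisible(NULL)
}

.elem_noise <- function(store, sub, settings, device, wl, seed) {
  target <- if (is.null(sub[["target_field"]])) "time_series" else
    sub[["target_field"]]
  spec <- noiseSpec(if (is.null(sub[["model"]])) "gaussian" else
                      sub[["model"]],
                    if (is.null(sub[["params"]])) list() else
                      sub[["params"]],
                    if (is.null(sub[["mode"]])) "additive" else
                      sub[["mode"]],
                    rng_seed = if (is.null(sub[["rng_seed"]])) seed else
                      sub[["rng_seed"]])
  x <- loadField(store, target,
                 if (target %in% .WL_FIELDS) wl else NULL)
  saveField(store, target, applyNoise(x, spec),
            if (target %in% .WL_FIELDS) wl else NULL)
  invisible(NULL)
}

.load_time_series <- function(store, device, wl) {
  sig <- loadField(store, "time_series", wl)
  dt <- as.numeric(loadField(store, "time_series_dt_ms")) * 1e-3
  c0 <- as.numeric(loadField(store, "sound_speed_ref"))
  new("TimeSeriesData", signals = sig, dt = dt, t0 = 0,
      positions = elementPositions(device), soundSpeed = c0)
}

.elem_reconstruction <- function(store, sub, settings, device, wl, seed) {
  ts <- .load_time_series(store, device, wl)
  fov <- list(x = device@fov[, 1], z = device@fov[, 3],
              spacing_mm = if (is.null(sub$spacing_mm))
                settings$general$spacing_mm else sub$spacing_mm)
  rs <- reconSettings(
    algorithm = if (is.null(sub$algorithm)) "das" else sub$algorithm,
    bandpass = sub$bandpass,
    differential = isTRUE(sub$differential),
    envelope = isTRUE(sub$envelope),
    sound_speed_mps = sub$sound_speed_mps, fov = fov)
  medium <- NULL
  if (rs$algorithm == "time_reversal") {
    vols <- .load_volumes(store, settings, wl)
    medium <- extractSlice(vols, NULL)
  }
  img <- reconstructImage(ts, rs, medium)
  saveField(store, "p0recon", img@pixels, wl)
  saveField(store, "p0recon_origin_mm", img@origin)
  saveField(store, "p0recon_spacing_mm", img@spacing)
  invisible(NULL)
}

.elem_crop <- function(store, sub, settings, device, wl, seed) {
  px <- loadField(store, "p0recon", wl)
  orig <- as.numeric(loadField(store, "p0recon_origin_mm"))
  sp <- as.numeric(loadField(store, "p0recon_spacing_mm"))
  img <- new("ReconstructedImage", pixels = px, spacing = sp, origin = orig,
             settings = list())
  box <- if (is.null(sub$box))
    c(device@fov[, 1], device@fov[, 3]) else sub$box
  out <- cropFov(img, box)
  saveField(store, "p0recon", out@pixels, wl)
  saveField(store, "p0recon_origin_mm", out@origin)
  invisible(NULL)
}

.elem_unmixing <- function(store, sub, settings, device, wl, seed) {
  wavelengths <- settings$general$wavelengths_nm
  src <- if (is.null(sub$source_field)) "p0recon" else sub$source_field
  imgs <- setNames(lapply(wavelengths, function(w)
    loadField(store, src, w)), as.character(wavelengths))
  chrom <- if (is.null(sub$chromophores))
    c("oxyhemoglobin", "deoxyhemoglobin") else sub$chromophores
  res <- linearUnmix(imgs, libraryEndmembers(wavelengths, chrom))
  for (nm in names(res$concentrations))
    saveField(store, paste0("unmixing/concentrations/", nm),
              res$concentrations[[nm]])
  if (!is.null(res$so2)) {
    so2 <- res$so2
    so2[is.na(so2)] <- NaN
    saveField(store, "unmixing/so2", so2)
  }
  saveField(store, "unmixing/residual", res$residual)
  invisible(NULL)
}

.elem_qpai <- function(store, sub, settings, device, wl, seed) {
  w <- if (is.null(sub$wavelength_nm))
    settings$general$wavelengths_nm[1] else sub$wavelength_nm
  vols <- .load_volumes(store, settings, w)
  p0 <- loadField(store, "p0", w)
  res <- iterativeQPAI(
    p0, vols, deviceIllumination(device), w,
    n_iterations = if (is.null(sub$n_iterations)) 5 else sub$n_iterations,
    n_photons = if (is.null(sub$n_photons)) 1e5 else sub$n_photons,
    rng_seed = seed)
  saveField(store, paste0("qpai/mua_estimate/", w), res$mua)
  saveField(store, "qpai/relative_change", res$relative_change)
  invisible(NULL)
}

.ELEMENT_RUNNERS <- list(
  volume_creation = .elem_volume, optical = .elem_optical,
  acoustic = .elem_acoustic, noise = .elem_noise,
  reconstruction = .elem_reconstruction, crop = .elem_crop,
  linear_unmixing = .elem_unmixing, qpai = .elem_qpai)

#' Run a simulation pipeline
#'
#' The main entry point: takes (1) the pipeline, a list of
#' [pipelineElement()] descriptions, (2) the settings tree, and (3) the
#' digital device twin. For every wavelength, all non-multispectral
#' elements run in list order, each appending its results to the HDF5
#' store; afterwards the multispectral elements run once. Every element
#' draws a seed derived deterministically from the global seed, its
#' pipeline position and the wavelength index, so identical inputs and
#' seeds produce identical simulation payloads, and sequential runs do not
#' influence each other (the global RNG state is left untouched).
#'
#' @param pipeline non-empty list of [pipelineElement()]s.
#' @param settings a [paSettings()] tree holding a sub-tree for every
#'   element (missing sub-trees are a configuration error naming the
#'   element).
#' @param device a [DeviceTwin-class].
#' @return The output HDF5 file path, invisibly.
#' @export
runSimulation <- function(pipeline, settings, device) {
  if (!inherits(settings, "paSettings"))
    stop("settings must be created with paSettings()")
  if (length(pipeline) == 0L)
    stop("configuration error: the pipeline is empty")
  for (el in pipeline) {
    if (!inherits(el, "pipelineElement"))
      stop("pipeline entries must be created with pipelineElement()")
    if (is.null(settings[[el$settings_key]]))
      stop("configuration error: no settings sub-tree '", el$settings_key,
           "' for element '", el$type, "'")
  }
  out <- settings$general$output_path
  store <- createStore(out, overwrite = TRUE)
  .save_settings(store, settings)
  .save_device(store, device)
  .h5_write_str(store@path, "/pipeline",
                vapply(pipeline, function(el) el$type, character(1)))
  gseed <- settings$general$rng_seed
  wavelengths <- settings$general$wavelengths_nm
  multis <- vapply(pipeline, function(el) el$multispectral, logical(1))
  for (wi in seq_along(wavelengths)) {
    wl <- wavelengths[wi]
    for (ei in which(!multis)) {
      el <- pipeline[[ei]]
      seed <- .derive_seed(gseed, ei, wi)
      .pa_log(settings, el$type,
              sprintf("start (wavelength %g nm, seed %d)", wl, seed))
      ok <- try(.ELEMENT_RUNNERS[[el$type]](
        store, settings[[el$settings_key]], settings, device, wl, seed),
        silent = TRUE)
      if (inherits(ok, "try-error")) {
        .pa_log(settings, el$type, paste("FAILED:", attr(ok, "condition")$message))
        stop("pipeline element '", el$type, "' failed at ", wl, " nm: ",
             attr(ok, "condition")$message)
      }
      .pa_log(settings, el$type, "done")
    }
  }
  for (ei in which(multis)) {
    el <- pipeline[[ei]]
    seed <- .derive_seed(gseed, ei, length(wavelengths) + 1L)
    .pa_log(settings, el$type, sprintf("start (multispectral, seed %d)", seed))
    ok <- try(.ELEMENT_RUNNERS[[el$type]](
      store, settings[[el$settings_key]], settings, device,
      wavelengths[1], seed), silent = TRUE)
    if (inherits(ok, "try-error")) {
      .pa_log(settings, el$type, paste("FAILED:", attr(ok, "condition")$message))
      stop("pipeline element '", el$type, "' failed: ",
           attr(ok, "condition")$message)
    }
    .pa_log(settings, el$type, "done")
  }
  invisible(out)
}

# ---------------------------------------------------------------------------
# scenes and demos
# ---------------------------------------------------------------------------

#' Draw a randomized forearm-like scene
#'
#' Draws vessel count, lateral positions, depths, radii and oxygenations
#' as well as the skin-curvature amplitude uniformly from the given
#' ranges, and assembles a layered forearm-like scene (epidermis, dermis,
#' muscle background, blood vessels running along y). The same seed always
#' returns the same scene; different seeds give scenes with distinct
#' vessel layouts, suitable for randomized dataset generation.
#'
#' @param rng_seed integer seed.
#' @param ranges list of ranges: `n_vessels` (integer), `radius_mm`,
#'   `depth_mm`, `so2`, `skin_amplitude_mm` (each `c(min, max)`).
#' @param extent_mm volume extent `c(x, y, z)` the scene should fill.
#' @return List with `structures` (for [createModelBasedVolume()]) and
#'   `deformation` (amplitude/modes/seed sub-list).
#' @export
generateRandomScene <- function(rng_seed,
                                ranges = list(n_vessels = c(2, 6),
                                              radius_mm = c(0.5, 2),
                                              depth_mm = c(3, 12),
                                              so2 = c(0, 1),
                                              skin_amplitude_mm = c(0, 1.5)),
                                extent_mm = c(17, 17, 17)) {
  for (r in ranges) if (length(r) != 2L || r[2] < r[1])
    stop("every range must be c(min, max) with min <= max")
  .with_seed(rng_seed, {
    nv <- if (ranges$n_vessels[1] == ranges$n_vessels[2])
      ranges$n_vessels[1] else
        sample(ranges$n_vessels[1]:ranges$n_vessels[2], 1)
    structures <- list(
      Structure("layer", list(z_start = 0, z_end = 0.6),
                tissueLibrary("epidermis"), priority = 3,
                adhere_to_deformation = TRUE),
      Structure("layer", list(z_start = 0.6, z_end = 2.0),
                tissueLibrary("dermis"), priority = 2,
                adhere_to_deformation = TRUE),
      Structure("background", composition = tissueLibrary("muscle")))
    for (i in seq_len(nv)) {
      x <- stats::runif(1, 0.1, 0.9) * extent_mm[1]
      z <- stats::runif(1, ranges$depth_mm[1], ranges$depth_mm[2])
      r <- stats::runif(1, ranges$radius_mm[1], ranges$radius_mm[2])
      s <- stats::runif(1, ranges$so2[1], ranges$so2[2])
      structures[[length(structures) + 1L]] <-
        Structure("elliptical_tube",
                  list(start = c(x, -1, z), end = c(x, extent_mm[2] + 1, z),
                       radius_a = r),
                  tissueLibrary("blood", oxygenation = s), priority = 4)
    }
    amp <- stats::runif(1, ranges$skin_amplitude_mm[1],
                        ranges$skin_amplitude_mm[2])
    list(structures = structures,
         deformation = list(amplitude_mm = amp, n_modes = 5,
                            rng_seed = rng_seed + 1))
  })
}

#' Bundled demo scenes
#'
#' * `point_absorber`: a small blood sphere in a weakly absorbing
#'   background, the canonical localization phantom.
#' * `two_layer`: two tissue layers with distinct absorption over a
#'   background, used for absorption-recovery demonstrations.
#' * `forearm`: layered skin, fat, muscle background, two blood vessels
#'   and a bone.
#' * `dataset`: the randomized forearm-like scene of
#'   [generateRandomScene()] for index `n`.
#'
#' @param name scene name.
#' @param extent_mm volume extent `c(x, y, z)` in mm.
#' @param n dataset index (seed) for `name = "dataset"`.
#' @return List with `structures` and (possibly `NULL`) `deformation`.
#' @export
demoScene <- function(name, extent_mm = c(17, 17, 17), n = 1) {
  ctr <- extent_mm / 2
  switch(name,
    point_absorber = list(
      structures = list(
        Structure("sphere", list(center = c(ctr[1], ctr[2], 6),
                                 radius = 0.5),
                  tissueLibrary("blood", oxygenation = 0.9), priority = 2),
        Structure("background", composition = tissueLibrary("background"))),
      deformation = NULL),
    two_layer = list(
      structures = list(
        Structure("layer", list(z_start = 0, z_end = 5),
                  tissueLibrary("dermis"), priority = 2),
        Structure("layer", list(z_start = 5, z_end = extent_mm[3]),
                  tissueLibrary("muscle"), priority = 1),
        Structure("background", composition = tissueLibrary("water"))),
      deformation = NULL),
    forearm = list(
      structures = list(
        Structure("layer", list(z_start = 0, z_end = 0.6),
                  tissueLibrary("epidermis"), priority = 5,
                  adhere_to_deformation = TRUE),
        Structure("layer", list(z_start = 0.6, z_end = 2.0),
                  tissueLibrary("dermis"), priority = 4,
                  adhere_to_deformation = TRUE),
        Structure("layer", list(z_start = 2.0, z_end = 3.5),
                  tissueLibrary("fat"), priority = 3,
                  adhere_to_deformation = TRUE),
        Structure("elliptical_tube",
                  list(start = c(ctr[1] - 3, -1, 6),
                       end = c(ctr[1] - 3, extent_mm[2] + 1, 6),
                       radius_a = 1.2),
                  tissueLibrary("blood", oxygenation = 0.95), priority = 6),
        Structure("elliptical_tube",
                  list(start = c(ctr[1] + 4, -1, 8),
                       end = c(ctr[1] + 4, extent_mm[2] + 1, 8),
                       radius_a = 0.9),
                  tissueLibrary("blood", oxygenation = 0.6), priority = 6),
        Structure("elliptical_tube",
                  list(start = c(ctr[1], -1, 13),
                       end = c(ctr[1], extent_mm[2] + 1, 13),
                       radius_a = 3, radius_b = 2.2),
                  tissueLibrary("bone"), priority = 2),
        Structure("background", composition = tissueLibrary("muscle"))),
      deformation = list(amplitude_mm = 0.8, n_modes = 5, rng_seed = 11)),
    dataset = generateRandomScene(n, extent_mm = extent_mm),
    stop("unknown demo scene '", name, "'; available: point_absorber, ",
         "two_layer, forearm, dataset"))
}

#' Run a bundled end-to-end demo pipeline
#'
#' Builds the scene, a linear-probe device and a volume/optical/acoustic/
#' reconstruction pipeline, and runs it to an HDF5 store.
#'
#' @param name demo scene name, see [demoScene()].
#' @param spacing_mm grid spacing (default 0.3 mm for speed).
#' @param wavelengths_nm wavelengths.
#' @param seed global seed.
#' @param output output HDF5 path.
#' @param n_photons photons per wavelength.
#' @param n dataset index for `name = "dataset"`.
#' @return The output path, invisibly.
#' @export
runDemo <- function(name, spacing_mm = 0.3, wavelengths_nm = 800,
                    seed = 1, output = tempfile(fileext = ".h5"),
                    n_photons = 2e4, n = 1) {
  extent <- c(17, 5, 17)
  scene <- demoScene(name, extent_mm = extent, n = n)
  device <- DeviceTwin(
    buildLinearArray(64, 0.25, center_mm = c(extent[1] / 2, extent[2] / 2,
                                             0.5)),
    IlluminationGeometry("slit", origin_mm = c(extent[1] / 2,
                                               extent[2] / 2, 0),
                         length_mm = 10),
    fov_mm = rbind(c(1, 0, 1), c(extent[1] - 1, extent[2], extent[3] - 3)))
  settings <- paSettings(
    general = list(spacing_mm = spacing_mm, wavelengths_nm = wavelengths_nm,
                   volume_extent_mm = extent, rng_seed = seed,
                   output_path = output),
    volume_creation = list(scene = scene$structures,
                           deformation = scene$deformation),
    optical = list(n_photons = n_photons),
    acoustic = list(),
    reconstruction = list(algorithm = "das", envelope = TRUE))
  pipeline <- list(pipelineElement("volume_creation"),
                   pipelineElement("optical"),
                   pipelineElement("acoustic"),
                   pipelineElement("reconstruction"))
  runSimulation(pipeline, settings, device)
}
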