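#' @include AllClasses.R
NULL

# fields stored per wavelength; everything else is stored once
.WL_FIELDS <- c("mua", "mus", "g", "phi", "p0", "time_series", "p0recon")

#' Create or open a simulation store
#'
#' The store is a single HDF5 file with the top-level groups `Settings`
#' (input parameters), `Device` (the digital device twin), `Simulations`
#' (all property maps and results, wavelength-dependent data in
#' per-wavelength subgroups) and the `pipeline` dataset (ordered element
#' names). The file is complete and re-openable after every pipeline
#' element finishes.
#'
#' @param path HDF5 file path.
#' @param overwrite replace an existing file (`createStore` only).
#' @return A [SimulationStore-class].
#' @export
createStore <- function(path, overwrite = TRUE) {
  if (file.exists(path) && !overwrite)
    stop("store '", path, "' already exists")
  .h5_create(path)
  new("SimulationStore", path = path)
}

#' @rdname createStore
#' @export
openStore <- function(path) {
  if (!file.exists(path)) stop("no such store: '", path, "'")
  new("SimulationStore", path = path)
}

.field_path <- function(name, wavelength) {
  if (name %in% .WL_FIELDS) {
    if (is.null(wavelength))
      stop("field '", name, "' is wavelength-dependent; a wavelength is ",
           "required")
    sprintf("/Simulations/%s/%s", name, as.character(wavelength))
  } else {
    if (!is.null(wavelength) && !grepl("/", name))
      sprintf("/Simulations/%s/%s", name, as.character(wavelength))
    else
      sprintf("/Simulations/%s", name)
  }
}

#' Save / load simulation fields
#'
#' Lossless round trip of numeric grids to the `Simulations` group.
#' Wavelength-dependent fields (`mua`, `mus`, `g`, `phi`, `p0`,
#' `time_series`, `p0recon`) are keyed by wavelength and require the
#' `wavelength` argument; wavelength-independent fields (e.g. `sos`,
#' `rho`, `alpha`, `gamma`, `so2`, `segmentation`) are stored once.
#'
#' @param store a [SimulationStore-class].
#' @param name field name.
#' @param value numeric vector/matrix/array (`saveField`).
#' @param wavelength wavelength key (nm) for wavelength-dependent fields.
#' @param compress gzip level 0-9 (0 = contiguous storage).
#' @return `loadField` returns the array with its original dimensions;
#'   `saveField` the store, invisibly.
#' @export
saveField <- function(store, name, value, wavelength = NULL, compress = 0) {
  p <- .field_path(name, wavelength)
  dims <- if (is.null(dim(value))) length(value) else dim(value)
  .h5_write_num(store@path, p, as.numeric(value), as.integer(dims),
                as.integer(compress))
  invisible(store)
}

#' @rdname saveField
#' @export
loadField <- function(store, name, wavelength = NULL) {
  p <- .field_path(name, wavelength)
  if (!.h5_exists(store@path, p)) {
    avail <- if (.h5_exists(store@path, "/Simulations"))
      paste(.h5_ls(store@path, "/Simulations")$name, collapse = ", ")
    else "(none)"
    stop("no field at '", p, "'; available fields: ", avail)
  }
  .h5_read_num(store@path, p)
}

#' @rdname saveField
#' @export
fieldExists <- function(store, name, wavelength = NULL) {
  .h5_exists(store@path, .field_path(name, wavelength))
}

# ---------------------------------------------------------------------------
# settings / device persistence
# ---------------------------------------------------------------------------

# write one R value under an HDF5 prefix; non-atomic values go through YAML
.write_value <- function(path, prefix, key, value) {
  p <- paste0(prefix, "/", key)
  if (is.numeric(value) || is.logical(value)) {
    v <- as.numeric(value)
    dims <- if (is.null(dim(value))) length(v) else dim(value)
    .h5_write_num(path, p, v, as.integer(dims), 0L)
  } else if (is.character(value)) {
    .h5_write_str(path, p, value)
  } else if (is.list(value) && !isS4(value) &&
             !any(vapply(value, isS4, logical(1)))) {
    .h5_write_str(path, paste0(p, "__yaml"), yaml::as.yaml(value))
  } else {
    .h5_write_str(path, paste0(p, "__class"), class(value)[1])
  }
}

.save_settings <- function(store, settings) {
  for (tree in names(settings)) {
    sub <- settings[[tree]]
    if (!is.list(sub)) {
      .write_value(store@path, "/Settings", tree, sub)
      next
    }
    for (key in names(sub))
      .write_value(store@path, paste0("/Settings/", tree), key, sub[[key]])
  }
  invisible(store)
}

.save_device <- function(store, device) {
  p <- store@path
  det <- device@detection
  .h5_write_str(p, "/Device/detection/kind", det@kind)
  .h5_write_num(p, "/Device/detection/positions_mm", as.numeric(det@positions),
                dim(det@positions), 0L)
  .h5_write_num(p, "/Device/detection/normals", as.numeric(det@normals),
                dim(det@normals), 0L)
  .h5_write_num(p, "/Device/detection/sampling_rate_hz", det@samplingRate,
                1L, 0L)
  il <- device@illumination
  .h5_write_str(p, "/Device/illumination/kind", il@kind)
  .h5_write_num(p, "/Device/illumination/origin_mm", il@origin, 3L, 0L)
  .h5_write_num(p, "/Device/illumination/direction", il@direction, 3L, 0L)
  if (length(il@params) > 0)
    .h5_write_str(p, "/Device/illumination/params__yaml",
                  yaml::as.yaml(lapply(il@params, function(x)
                    if (is.numeric(x)) as.numeric(x) else x)))
  .h5_write_num(p, "/Device/position_mm", device@position, 3L, 0L)
  .h5_write_num(p, "/Device/fov_mm", as.numeric(device@fov), c(2L, 3L), 0L)
  invisible(store)
}

# ---------------------------------------------------------------------------
# tree walking, payload comparison, repacking
# ---------------------------------------------------------------------------

.walk <- function(path, group = "/") {
  ls <- .h5_ls(path, group)
  out <- character(0)
  for (i in seq_along(ls$name)) {
    child <- if (group == "/") paste0("/", ls$name[i])
             else paste0(group, "/", ls$name[i])
    if (ls$is_group[i]) out <- c(out, .walk(path, child))
    else out <- c(out, child)
  }
  out
}

#' List the hierarchical contents of a store
#'
#' @param path store file path.
#' @return Character vector of all dataset paths.
#' @export
storeDatasets <- function(path) .walk(path)

#' Print the group tree of a store
#'
#' @param path store file path.
#' @param group subgroup to start from.
#' @param indent internal.
#' @return Invisibly, the printed lines.
#' @export
inspectStore <- function(path, group = "/", indent = "") {
  ls <- .h5_ls(path, group)
  lines <- character(0)
  for (i in seq_along(ls$name)) {
    child <- if (group == "/") paste0("/", ls$name[i])
             else paste0(group, "/", ls$name[i])
    tag <- if (ls$is_group[i]) "+" else "-"
    lines <- c(lines, paste0(indent, tag, " ", ls$name[i]))
    if (ls$is_group[i])
      lines <- c(lines, inspectStore(path, child, paste0(indent, "  ")))
  }
  if (indent == "") cat(lines, sep = "\n")
  invisible(lines)
}

# read any dataset (numeric first, string fallback)
.read_any <- function(path, dset) {
  tryCatch(.h5_read_num(path, dset),
           error = function(e) .h5_read_str(path, dset))
}

#' Read every dataset below a group into a named list
#'
#' Used to compare the simulation payloads of independent runs exactly
#' (determinism / independence checks).
#'
#' @param path store file path.
#' @param group group to collect (default `"/Simulations"`).
#' @return Named list, dataset path to value.
#' @export
storePayload <- function(path, group = "/Simulations") {
  dsets <- .walk(path, group)
  setNames(lapply(dsets, function(d) .read_any(path, d)), dsets)
}

#' Repack a store with compression
#'
#' Copies every dataset into a fresh gzip-compressed file and atomically
#' replaces the original; values round-trip exactly.
#'
#' @param path store file path.
#' @param level gzip level 1-9.
#' @return The path, invisibly.
#' @export
repackStore <- function(path, level = 4) {
  tmp <- paste0(path, ".repack")
  .h5_create(tmp)
  for (d in .walk(path)) {
    v <- .read_any(path, d)
    if (is.character(v)) {
      .h5_write_str(tmp, d, v)
    } else {
      dims <- if (is.null(dim(v))) length(v) else dim(v)
      .h5_write_num(tmp, d, as.numeric(v), as.integer(dims),
                    as.integer(level))
    }
  }
  file.rename(tmp, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# IPASC-style export
# ---------------------------------------------------------------------------

#' Export time-series data in an IPASC-style HDF5 layout
#'
#' Writes the detector signals to `binary_time_series_data` plus a minimal
#' `meta_data` group (sampling rate, element positions, reference sound
#' speed, optional wavelengths). This follows the structure of the
#' standardized photoacoustic interchange format but implements only a
#' minimal metadata subset, not certified compliance.
#'
#' @param ts a [TimeSeriesData-class].
#' @param device the [DeviceTwin-class] used (element positions are taken
#'   from the time series itself).
#' @param meta named list of extra metadata (numeric or character
#'   scalars/vectors), e.g. `list(wavelengths_nm = 800)`.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
exportIpasc <- function(ts, device, meta = list(), path) {
  .h5_create(path)
  .h5_write_num(path, "/binary_time_series_data", as.numeric(ts@signals),
                dim(ts@signals), 0L)
  .h5_write_num(path, "/meta_data/sampling_rate_hz", 1 / ts@dt, 1L, 0L)
  .h5_write_num(path, "/meta_data/detector_positions_mm",
                as.numeric(ts@positions), dim(ts@positions), 0L)
  .h5_write_num(path, "/meta_data/sound_speed_mps", ts@soundSpeed, 1L, 0L)
  .h5_write_num(path, "/meta_data/t0_s", ts@t0, 1L, 0L)
  for (key in names(meta))
    .write_value(path, "/meta_data", key, meta[[key]])
  invisible(path)
}

#' Re-import an IPASC-style export
#'
#' @param path file written by [exportIpasc()].
#' @return A [TimeSeriesData-class].
#' @export
importIpasc <- function(path) {
  sig <- .h5_read_num(path, "/binary_time_series_data")
  fs <- as.numeric(.h5_read_num(path, "/meta_data/sampling_rate_hz"))
  pos <- .h5_read_num(path, "/meta_data/detector_positions_mm")
  c0 <- as.numeric(.h5_read_num(path, "/meta_data/sound_speed_mps"))
  t0 <- as.numeric(.h5_read_num(path, "/meta_data/t0_s"))
  new("TimeSeriesData", signals = matrix(sig, dim(sig)[1], dim(sig)[2]),
      dt = 1 / fs, t0 = t0,
      positions = matrix(pos, dim(pos)[1], dim(pos)[2]), soundSpeed = c0)
}
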