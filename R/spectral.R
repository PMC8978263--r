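#' @include optical.R
NULL

#' Endmember matrix for linear spectral unmixing
#'
#' @param wavelengths_nm m wavelengths (m >= 2).
#' @param spectra m x k matrix of chromophore absorption values (cm^-1);
#'   columns must be linearly independent.
#' @param names k chromophore names; `"oxyhemoglobin"` and
#'   `"deoxyhemoglobin"` enable sO2 computation.
#' @param max_condition condition-number threshold above which the matrix
#'   is rejected as rank deficient.
#' @return A validated endmember list (class `"endmemberMatrix"`).
#' @export
endmemberMatrix <- function(wavelengths_nm, spectra, names,
                            max_condition = 1e10) {
  spectra <- as.matrix(spectra)
  if (length(wavelengths_nm) != nrow(spectra))
    stop("one spectra row per wavelength is required")
  if (nrow(spectra) < ncol(spectra))
    stop("need at least as many wavelengths as chromophores")
  if (length(names) != ncol(spectra))
    stop("one name per chromophore column is required")
  sv <- svd(spectra, nu = 0, nv = 0)$d
  cond <- sv[1] / sv[length(sv)]
  if (!is.finite(cond) || cond > max_condition)
    stop(sprintf(
      "endmember matrix is rank deficient (condition number %.3g)", cond))
  structure(list(wavelengths = as.numeric(wavelengths_nm),
                 spectra = spectra, names = names, condition = cond),
            class = "endmemberMatrix")
}

#' Endmembers from the bundled chromophore library
#'
#' @param wavelengths_nm wavelengths at which to evaluate the spectra.
#' @param chromophores chromophore names understood by
#'   [spectrumLibrary()].
#' @return An [endmemberMatrix()].
#' @export
libraryEndmembers <- function(wavelengths_nm,
                              chromophores = c("oxyhemoglobin",
                                               "deoxyhemoglobin")) {
  A <- vapply(chromophores, function(ch)
    interpolateSpectrum(spectrumLibrary(ch), wavelengths_nm),
    numeric(length(wavelengths_nm)))
  endmemberMatrix(wavelengths_nm, matrix(A, nrow = length(wavelengths_nm)),
                  chromophores)
}

#' SVD-based linear spectral unmixing
#'
#' Solves, per pixel, the unconstrained least-squares problem
#' `A c ~= p` via the SVD pseudoinverse, where `A` holds the endmember
#' spectra and `p` the multispectral pixel values. Where both hemoglobin
#' endmembers are present, sO2 = c_HbO2 / (c_HbO2 + c_Hb) is reported
#' (clipped to `[0, 1]`) wherever the total hemoglobin exceeds a small
#' positive threshold and set to `NA` elsewhere.
#'
#' @param images named list (names = wavelengths) of equally shaped
#'   matrices/arrays, one per endmember wavelength.
#' @param endmembers an [endmemberMatrix()].
#' @param so2_epsilon threshold on total hemoglobin below which sO2 is
#'   undefined, relative to the maximum total hemoglobin.
#' @return List (class `"unmixingResult"`) with `concentrations` (named
#'   list of maps), `so2` (map or `NULL`), `residual` (per-pixel residual
#'   norm).
#' @export
linearUnmix <- function(images, endmembers, so2_epsilon = 1e-8) {
  stopifnot(inherits(endmembers, "endmemberMatrix"))
  wl <- as.character(endmembers$wavelengths)
  if (!all(wl %in% names(images)))
    stop("missing image(s) for wavelength(s): ",
         paste(setdiff(wl, names(images)), collapse = ", "))
  shp <- dim(images[[wl[1]]])
  if (!all(vapply(images[wl], function(im) identical(dim(im), shp),
                  logical(1))))
    stop("all images must share their shape")
  P <- t(vapply(images[wl], as.vector, numeric(prod(shp))))  # m x npix
  A <- endmembers$spectra
  s <- svd(A)
  Ainv <- s$v %*% diag(1 / s$d, length(s$d)) %*% t(s$u)
  C <- Ainv %*% P                                            # k x npix
  resid <- sqrt(colSums((A %*% C - P)^2))
  conc <- lapply(seq_len(nrow(C)), function(i) array(C[i, ], dim = shp))
  names(conc) <- endmembers$names
  so2 <- NULL
  if (all(c("oxyhemoglobin", "deoxyhemoglobin") %in% endmembers$names)) {
    thb <- conc$oxyhemoglobin + conc$deoxyhemoglobin
    so2 <- pmin(1, pmax(0, conc$oxyhemoglobin / thb))
    so2[thb <= so2_epsilon * max(thb, na.rm = TRUE)] <- NA_real_
  }
  structure(list(concentrations = conc, so2 = so2,
                 residual = array(resid, dim = shp)),
            class = "unmixingResult")
}

#' Iterative fluence-compensated absorption recovery (qPAI)
#'
#' Recovers the absorption coefficient from a measured initial pressure
#' distribution by fixed-point iteration: starting from a uniform guess,
#' each iteration simulates the fluence for the current absorption estimate
#' with the package's Monte Carlo solver (scattering, anisotropy and
#' Grueneisen maps are assumed known) and updates
#' `mua <- p0 / (Gamma * phi)`, floored at zero and capped at `mua_max`.
#' Voxels where the simulated fluence vanishes while the measured pressure
#' does not are flagged unrecoverable and excluded from updates.
#'
#' @param p0_meas measured initial pressure (3-D array, >= 0).
#' @param volumes [PropertyVolumes-class] providing `mus`, `g` at
#'   `wavelength_nm` and the `gamma` grid (its `mua` is ignored).
#' @param illum the [IlluminationGeometry-class] used for the measurement.
#' @param wavelength_nm wavelength of the measurement.
#' @param n_iterations number of fixed-point iterations (>= 1).
#' @param n_photons photons per fluence simulation.
#' @param rng_seed seed for the fluence simulations. The same random
#'   number stream is reused in every iteration (fixed-sample iteration):
#'   the fixed point is then a deterministic function of the photon sample
#'   instead of chasing a fresh Monte Carlo noise realization each
#'   iteration.
#' @param mua_init uniform initial guess (cm^-1).
#' @param mua_max upper cap (cm^-1).
#' @return List (class `"qpaiResult"`) with `mua` (cm^-1 estimate),
#'   `relative_change` (per-iteration trace), `illuminated` (logical mask,
#'   fluence above 1e-4 of its maximum), `unrecoverable` (logical mask).
#' @export
iterativeQPAI <- function(p0_meas, volumes, illum, wavelength_nm,
                          n_iterations = 5, n_photons = 1e5, rng_seed = 1,
                          mua_init = 0.5, mua_max = 20) {
  if (n_iterations < 1) stop("n_iterations must be >= 1")
  if (any(p0_meas < 0)) stop("p0_meas must be >= 0")
  wl <- as.character(wavelength_nm)
  work <- volumes
  gamma <- volumes@gamma
  mua <- array(mua_init, dim = volumes@grid@shape)   # cm^-1
  trace <- numeric(n_iterations)
  illuminated <- NULL
  unrecoverable <- array(FALSE, dim = volumes@grid@shape)
  for (k in seq_len(n_iterations)) {
    work@mua[[wl]] <- mua
    fl <- runMonteCarlo(work, wavelength_nm, illum, n_photons,
                        rng_seed = rng_seed)
    phi <- fl@phi
    illuminated <- phi > 1e-4 * max(phi)
    denom <- gamma * phi * 0.1                       # cm^-1 scaling
    upd <- denom > 0
    unrecoverable <- !upd & p0_meas > 0
    mua_new <- mua
    mua_new[upd] <- pmin(mua_max, pmax(0, p0_meas[upd] / denom[upd]))
    num <- sqrt(sum((mua_new[illuminated] - mua[illuminated])^2))
    den <- sqrt(sum(mua[illuminated]^2))
    trace[k] <- if (den > 0) num / den else 0
    mua <- mua_new
  }
  structure(list(mua = mua, relative_change = trace,
                 illuminated = illuminated, unrecoverable = unrecoverable),
            class = "qpaiResult")
}
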