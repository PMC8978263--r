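#' @include devices.R volume.R
NULL

#' Run the voxel Monte Carlo fluence simulation
#'
#' Simulates photon transport through the property volumes at one
#' wavelength with a weighted-photon voxel Monte Carlo: free paths are
#' sampled from the local scattering coefficient, the photon weight decays
#' continuously with absorption along each sub-step, scattering angles
#' follow the Henyey-Greenstein phase function, and low-weight photons
#' undergo Russian roulette (threshold 1e-4, survival 0.1). Fluence is
#' accumulated with a track-length estimator (unbiased also in
#' non-absorbing voxels), normalized per launched photon and voxel volume
#' (mm^-2 per unit delivered energy). Photons leaving the grid are
#' terminated (matched boundary, no internal reflection). Identical seeds
#' give identical fluence grids.
#'
#' @param volumes a [PropertyVolumes-class] holding `mua`, `mus` (cm^-1)
#'   and `g` grids at `wavelength_nm`.
#' @param wavelength_nm wavelength to simulate (must be one of the volume's
#'   wavelengths).
#' @param illum an [IlluminationGeometry-class] (world coordinates).
#' @param n_photons number of photons (>= 1).
#' @param rng_seed integer seed controlling both the launch sampling and
#'   the transport RNG.
#' @param roulette disable only for exact energy-balance checks.
#' @return A [FluenceGrid-class].
#' @examples
#' \donttest{
#' grid <- GridSpec(c(21, 21, 40), 0.5)
#' bg <- Structure("background", composition = tissueLibrary("background"))
#' vols <- createModelBasedVolume(list(bg), grid, 800)
#' il <- IlluminationGeometry("pencil", origin_mm = c(5.25, 5.25, 0))
#' fl <- runMonteCarlo(vols, 800, il, n_photons = 2e4, rng_seed = 7)
#' }
#' @export
runMonteCarlo <- function(volumes, wavelength_nm, illum, n_photons,
                          rng_seed = 1, roulette = TRUE) {
  if (n_photons < 1) stop("n_photons must be >= 1")
  wl <- as.character(wavelength_nm)
  if (!wl %in% names(volumes@mua))
    stop("no optical properties at ", wavelength_nm, " nm; available: ",
         paste(names(volumes@mua), collapse = ", "))
  grid <- volumes@grid
  # cm^-1 -> mm^-1 at solver entry
  mua <- volumes@mua[[wl]] * 0.1
  mus <- volumes@mus[[wl]] * 0.1
  g <- volumes@g[[wl]]
  launch <- .with_seed(rng_seed, samplePhotonLaunch(illum, n_photons))
  res <- .mc_fluence(mua, mus, g, grid@shape, grid@spacing, grid@origin,
                     launch$positions, launch$directions,
                     as.double(rng_seed), isTRUE(roulette))
  new("FluenceGrid", phi = array(res$phi, dim = grid@shape), grid = grid,
      wavelength = as.numeric(wavelength_nm), nPhotons = n_photons,
      seed = as.numeric(rng_seed), absorbed = res$absorbed,
      escaped = res$escaped, rouletteKilled = res$roulette_killed,
      rouletteBoosted = res$roulette_boosted)
}

#' Sample the Henyey-Greenstein phase function
#'
#' Inverse-CDF sampling of the scattering angle cosine for anisotropy `g`;
#' `g = 0` reduces to an isotropic (uniform cosine) distribution and the
#' sample mean converges to `g` (the defining property of the
#' Henyey-Greenstein distribution). Uses R's RNG.
#'
#' @param n number of samples.
#' @param g anisotropy in (-1, 1).
#' @return Numeric vector of cos(theta) samples in `[-1, 1]`.
#' @examples
#' set.seed(1)
#' mean(sampleHenyeyGreenstein(1e5, 0.9))
#' @export
sampleHenyeyGreenstein <- function(n, g) {
  if (abs(g) >= 1) stop("anisotropy g must lie in (-1, 1)")
  u <- stats::runif(n)
  if (abs(g) < 1e-8) return(2 * u - 1)
  s <- (1 - g^2) / (1 - g + 2 * g * u)
  pmin(1, pmax(-1, (1 + g^2 - s^2) / (2 * g)))
}

#' Compute the initial pressure distribution
#'
#' The photoacoustic generation model: p0 = Gamma * mua * phi, evaluated
#' element-wise with the absorption coefficient converted to mm^-1 so that
#' units are consistent with the fluence grid (p0 in arbitrary units).
#' Voxels without absorption produce zero pressure.
#'
#' @param phi a [FluenceGrid-class].
#' @param volumes the [PropertyVolumes-class] the fluence was computed on.
#' @return A [PressureGrid-class].
#' @export
computeInitialPressure <- function(phi, volumes) {
  if (!identical(phi@grid@shape, volumes@grid@shape))
    stop("fluence and property grids have different shapes")
  wl <- as.character(phi@wavelength)
  if (!wl %in% names(volumes@mua))
    stop("volumes hold no absorption grid at ", wl, " nm")
  p0 <- volumes@gamma * (volumes@mua[[wl]] * 0.1) * phi@phi
  new("PressureGrid", p0 = p0, grid = phi@grid,
      wavelength = phi@wavelength)
}
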