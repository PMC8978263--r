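#' @include spectra-library.R
NULL

#' Create a property spectrum
#'
#' @param name property/chromophore name.
#' @param wavelengths strictly ascending wavelengths in nm.
#' @param values property values at the knots.
#' @return A [Spectrum-class].
#' @examples
#' s <- Spectrum("toy", c(700, 900), c(2, 4))
#' interpolateSpectrum(s, 800)
#' @export
Spectrum <- function(name, wavelengths, values) {
  new("Spectrum", name = as.character(name),
      wavelengths = as.numeric(wavelengths), values = as.numeric(values))
}

#' Create a molecule
#'
#' @param name molecule name.
#' @param absorption,scattering absorption and scattering spectra (cm^-1);
#'   scalars are promoted to flat spectra.
#' @param anisotropy anisotropy spectrum (unitless) or scalar.
#' @param gruneisen Grueneisen parameter (unitless, >= 0).
#' @param speedOfSound m/s (> 0).
#' @param density kg/m^3 (> 0).
#' @param acousticAttenuation dB cm^-1 MHz^-1 (>= 0).
#' @param volumeFraction fraction in `[0, 1]`.
#' @param role `"oxyhemoglobin"`, `"deoxyhemoglobin"` or `"other"`.
#' @return A [Molecule-class].
#' @export
Molecule <- function(name, absorption, scattering, anisotropy = 0.9,
                     gruneisen = 0.2, speedOfSound = 1540, density = 1000,
                     acousticAttenuation = 0.5, volumeFraction = 1,
                     role = "other") {
  as_spec <- function(x, nm) {
    if (is(x, "Spectrum")) x else .flat_spectrum(nm, x)
  }
  new("Molecule", name = as.character(name),
      absorption = as_spec(absorption, paste0(name, "_mua")),
      scattering = as_spec(scattering, paste0(name, "_mus")),
      anisotropy = as_spec(anisotropy, paste0(name, "_g")),
      gruneisen = gruneisen, speedOfSound = speedOfSound, density = density,
      acousticAttenuation = acousticAttenuation,
      volumeFraction = volumeFraction, role = role)
}

#' Create a molecular composition
#'
#' @param name composition name.
#' @param members list of [Molecule-class] objects carrying their volume
#'   fractions; the fractions must sum to a value in (0, 1].
#' @return A [MolecularComposition-class].
#' @export
MolecularComposition <- function(name, members) {
  new("MolecularComposition", name = as.character(name), members = members)
}

#' Interpolate a spectrum at arbitrary wavelengths
#'
#' Piecewise-linear interpolation between the bracketing knots; queries
#' outside the knot range return the nearest endpoint value (clamped
#' extrapolation, so absorption/scattering can never turn negative).
#'
#' @param spectrum a [Spectrum-class].
#' @param wavelength_nm numeric vector of query wavelengths (nm).
#' @return Numeric vector of interpolated values.
#' @examples
#' s <- Spectrum("toy", c(700, 900), c(2, 4))
#' interpolateSpectrum(s, c(650, 700, 800, 950))
#' @export
interpolateSpectrum <- function(spectrum, wavelength_nm) {
  stopifnot(is(spectrum, "Spectrum"))
  validObject(spectrum)
  if (length(wavelength_nm) < 1L || any(!is.finite(wavelength_nm)))
    stop("query wavelengths must be finite")
  if (length(spectrum@wavelengths) == 1L)
    return(rep(spectrum@values, length(wavelength_nm)))
  stats::approx(spectrum@wavelengths, spectrum@values, xout = wavelength_nm,
                method = "linear", rule = 2)$y
}

#' Mix a molecular composition into voxel properties
#'
#' Evaluates every member spectrum at the requested wavelength and combines
#' the members linearly. The optical coefficients (`mua`, `mus`) are
#' weighted by the absolute volume fractions, so a fraction deficit behaves
#' as transparent filler. The acoustic/thermodynamic scalars (`sos`, `rho`,
#' `alpha`, `gamma`) are renormalized over the present fractions, so a voxel
#' always has a defined sound speed. The anisotropy is the
#' scattering-weighted mean cosine (the physically meaningful average for a
#' mixture of scatterers); where the total scattering vanishes the plain
#' fraction-weighted mean is used. `so2` is the oxyhemoglobin fraction of
#' all hemoglobin members, or `NA` if the composition contains none.
#'
#' @param composition a [MolecularComposition-class].
#' @param wavelength_nm scalar wavelength (nm).
#' @return Named list with elements `mua`, `mus` (cm^-1), `g`, `gamma`,
#'   `sos` (m/s), `rho` (kg/m^3), `alpha` (dB/cm/MHz), `so2` (or `NA`).
#' @examples
#' mixComposition(tissueLibrary("blood", oxygenation = 0.7), 800)
#' @export
mixComposition <- function(composition, wavelength_nm) {
  stopifnot(is(composition, "MolecularComposition"))
  validObject(composition)
  stopifnot(length(wavelength_nm) == 1L, is.finite(wavelength_nm))
  vf <- vapply(composition@members, function(m) m@volumeFraction, numeric(1))
  ftot <- sum(vf)
  if (ftot <= 0 || ftot > 1 + 1e-6)
    stop("invalid composition: volume fractions sum to ", ftot)
  mua_i <- vapply(composition@members, function(m)
    interpolateSpectrum(m@absorption, wavelength_nm), numeric(1))
  mus_i <- vapply(composition@members, function(m)
    interpolateSpectrum(m@scattering, wavelength_nm), numeric(1))
  g_i <- vapply(composition@members, function(m)
    interpolateSpectrum(m@anisotropy, wavelength_nm), numeric(1))
  gam_i <- vapply(composition@members, function(m) m@gruneisen, numeric(1))
  sos_i <- vapply(composition@members, function(m) m@speedOfSound, numeric(1))
  rho_i <- vapply(composition@members, function(m) m@density, numeric(1))
  alp_i <- vapply(composition@members, function(m) m@acousticAttenuation,
                  numeric(1))
  role <- vapply(composition@members, function(m) m@role, character(1))

  mus <- sum(vf * mus_i)
  g <- if (mus > 0) sum(vf * mus_i * g_i) / mus else sum(vf * g_i) / ftot
  hb_oxy <- sum(vf[role == "oxyhemoglobin"])
  hb_deoxy <- sum(vf[role == "deoxyhemoglobin"])
  hb <- hb_oxy + hb_deoxy
  list(mua = sum(vf * mua_i), mus = mus, g = g,
       gamma = sum(vf * gam_i) / ftot, sos = sum(vf * sos_i) / ftot,
       rho = sum(vf * rho_i) / ftot, alpha = sum(vf * alp_i) / ftot,
       so2 = if (hb > 0) hb_oxy / hb else NA_real_)
}

# hemoglobin volume fraction of a composition (used for so2 blending)
.hemoglobin_fraction <- function(composition) {
  sum(vapply(composition@members, function(m)
    if (m@role %in% c("oxyhemoglobin", "deoxyhemoglobin"))
      m@volumeFraction else 0, numeric(1)))
}

# a tissue-level scatterer: carries the tissue scattering law scaled by
# 1/vf so that the composition reproduces the tissue-level coefficients
.scatterer <- function(name, law, vf, mua_baseline, sos, rho, alpha,
                       gruneisen) {
  s <- .mus_spectrum(law)
  Molecule(name, absorption = .flat_spectrum(paste0(name, "_mua"),
                                             mua_baseline),
           scattering = Spectrum(s@name, s@wavelengths, s@values / vf),
           anisotropy = .g_spectrum(), gruneisen = gruneisen,
           speedOfSound = sos, density = rho, acousticAttenuation = alpha,
           volumeFraction = vf)
}

.water_molecule <- function(vf) {
  Molecule("water", absorption = spectrumLibrary("water"),
           scattering = .flat_spectrum("water_mus", 0.01),
           anisotropy = .g_spectrum(), gruneisen = 0.12, speedOfSound = 1480,
           density = 997, acousticAttenuation = 0.0022, volumeFraction = vf)
}

.blood_molecules <- function(oxygenation, vf = 1) {
  mk <- function(which, frac) {
    Molecule(which, absorption = spectrumLibrary(which),
             scattering = .mus_spectrum("blood"),
             anisotropy = .g_spectrum(), gruneisen = 0.20,
             speedOfSound = 1578, density = 1050, acousticAttenuation = 0.20,
             volumeFraction = frac, role = which)
  }
  list(mk("oxyhemoglobin", vf * oxygenation),
       mk("deoxyhemoglobin", vf * (1 - oxygenation)))
}

#' Predefined tissue compositions
#'
#' Returns a [MolecularComposition-class] for a named tissue, built from the
#' bundled chromophore spectra and literature reference values so that the
#' mixed optical and acoustic properties agree with the ranges reported for
#' that tissue (see [literatureRanges()]).
#'
#' Available tissues and their tunable parameters:
#' * `blood`: `oxygenation` (sO2, default 0.7).
#' * `epidermis`: `melanin_fraction` (melanosome volume fraction,
#'   default 0.014).
#' * `dermis`, `muscle`: `oxygenation` and `blood_fraction` of the embedded
#'   capillary blood.
#' * `fat`, `bone`, `water`, `background`: no parameters.
#'
#' @param name tissue name.
#' @param oxygenation blood oxygen saturation in `[0, 1]` where applicable.
#' @param melanin_fraction melanosome volume fraction (epidermis).
#' @param blood_fraction capillary blood volume fraction (dermis, muscle).
#' @return A [MolecularComposition-class].
#' @examples
#' mixComposition(tissueLibrary("muscle"), 800)
#' @export
tissueLibrary <- function(name, oxygenation = 0.7, melanin_fraction = 0.014,
                          blood_fraction = NULL) {
  if (!is.null(oxygenation) &&
      (oxygenation < 0 || oxygenation > 1))
    stop("oxygenation must lie in [0, 1]")
  switch(name,
    blood = MolecularComposition("blood", .blood_molecules(oxygenation)),
    epidermis = {
      mf <- melanin_fraction
      mel <- Molecule("melanosome", absorption = spectrumLibrary("melanin"),
                      scattering = .mus_spectrum("skin"),
                      anisotropy = .g_spectrum(), gruneisen = 0.20,
                      speedOfSound = 1624, density = 1109,
                      acousticAttenuation = 0.60, volumeFraction = mf)
      base <- Molecule("skin_baseline", absorption = .flat_spectrum("base", 0.3),
                       scattering = .mus_spectrum("skin"),
                       anisotropy = .g_spectrum(), gruneisen = 0.20,
                       speedOfSound = 1624, density = 1109,
                       acousticAttenuation = 0.60, volumeFraction = 1 - mf)
      MolecularComposition("epidermis", list(mel, base))
    },
    dermis = {
      bf <- if (is.null(blood_fraction)) 0.002 else blood_fraction
      wf <- 0.65
      cf <- 1 - wf - bf
      coll <- .scatterer("collagen", "skin", cf, mua_baseline = 0.15,
                         sos = 1900, rho = 1320, alpha = 1.72,
                         gruneisen = 0.35)
      MolecularComposition("dermis", c(list(.water_molecule(wf)),
                                       .blood_molecules(oxygenation, bf),
                                       list(coll)))
    },
    fat = {
      lip <- Molecule("lipid", absorption = spectrumLibrary("fat"),
                      scattering = Spectrum("fat_mus",
                                            .mus_spectrum("fat")@wavelengths,
                                            .mus_spectrum("fat")@values / 0.9),
                      anisotropy = .g_spectrum(), gruneisen = 0.76,
                      speedOfSound = 1435, density = 900,
                      acousticAttenuation = 0.67, volumeFraction = 0.9)
      MolecularComposition("fat", list(lip, .water_molecule(0.1)))
    },
    muscle = {
      bf <- if (is.null(blood_fraction)) 0.02 else blood_fraction
      wf <- 0.70
      df <- 1 - wf - bf
      dry <- .scatterer("muscle_dry_mass", "muscle", df, mua_baseline = 0.2,
                        sos = 1830, rho = 1325, alpha = 2.2,
                        gruneisen = 0.40)
      MolecularComposition("muscle", c(list(.water_molecule(wf)),
                                       .blood_molecules(oxygenation, bf),
                                       list(dry)))
    },
    bone = {
      m <- Molecule("bone_mineral", absorption = .flat_spectrum("bone_mua", 0.25),
                    scattering = .mus_spectrum("bone"),
                    anisotropy = .g_spectrum(), gruneisen = 0.50,
                    speedOfSound = 2800, density = 1908,
                    acousticAttenuation = 3.5, volumeFraction = 1)
      MolecularComposition("bone", list(m))
    },
    water = MolecularComposition("water", list(.water_molecule(1))),
    background = {
      m <- Molecule("generic_soft_tissue",
                    absorption = .flat_spectrum("bg_mua", 0.1),
                    scattering = .mus_spectrum("generic"),
                    anisotropy = .g_spectrum(), gruneisen = 0.20,
                    speedOfSound = 1540, density = 1000,
                    acousticAttenuation = 0.50, volumeFraction = 1)
      MolecularComposition("background", list(m))
    },
    stop("unknown tissue '", name, "'; available: blood, epidermis, ",
         "dermis, fat, muscle, bone, water, background"))
}

#' Read / write spectra as two-column CSV
#'
#' The on-disk format is a plain CSV with columns `wavelength_nm` and
#' `value`.
#'
#' @param path file path.
#' @param name spectrum name to attach on reading.
#' @return `readSpectrumCsv()` returns a [Spectrum-class];
#'   `writeSpectrumCsv()` returns the path invisibly.
#' @export
readSpectrumCsv <- function(path, name = basename(path)) {
  d <- utils::read.csv(path)
  if (!all(c("wavelength_nm", "value") %in% names(d)))
    stop("spectrum CSV needs columns 'wavelength_nm' and 'value'")
  Spectrum(name, d$wavelength_nm, d$value)
}

#' @rdname readSpectrumCsv
#' @param spectrum a [Spectrum-class] to write.
#' @export
writeSpectrumCsv <- function(spectrum, path) {
  utils::write.csv(data.frame(wavelength_nm = spectrum@wavelengths,
                              value = spectrum@values),
                   path, row.names = FALSE)
  invisible(path)
}
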