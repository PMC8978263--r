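#' @include AllClasses.R
NULL

# ---------------------------------------------------------------------------
# Bundled chromophore spectra (library constants)
#
# Knot tables over 650-1000 nm digitized from the public compilations in
# common use: hemoglobin molar extinction after the Prahl/OMLC tabulation
# (converted to whole-blood absorption at 150 g/L, M = 64500 g/mol),
# water absorption after Hale & Querry, melanosome absorption after the
# Jacques power law, lipid absorption after van Veen et al. These are
# library constants representative of the literature, not measurements.
# ---------------------------------------------------------------------------

.SPECTRA_WL <- seq(650, 1000, by = 25)

# molar extinction, cm^-1 / (mol/L)
.EPS_HBO2 <- c(368, 316, 290, 351, 518, 722, 816, 974, 1058, 1154, 1198,
               1263, 1204, 1136, 1058)
.EPS_HB <- c(3750, 2796, 1794, 1244, 1405, 1277, 762, 693, 691, 726, 762,
             854, 925, 930, 916)
# whole blood: mua = ln(10) * eps * C_Hb / M_Hb, C_Hb = 150 g/L
.BLOOD_FACTOR <- log(10) * 150 / 64500

# water absorption, cm^-1 (Hale & Querry interpolation)
.MUA_WATER <- c(0.0032, 0.0044, 0.0060, 0.0159, 0.0260, 0.0242, 0.0200,
                0.0288, 0.0433, 0.0562, 0.0679, 0.1440, 0.3880, 0.4500,
                0.3630)

# lipid absorption, cm^-1 (930 nm band)
.MUA_FAT <- c(0.0060, 0.0050, 0.0045, 0.0050, 0.0055, 0.0058, 0.0060,
              0.0065, 0.0070, 0.0095, 0.0150, 0.0800, 0.0350, 0.0150,
              0.0120)

# melanosome absorption power law, cm^-1
.MUA_MELANOSOME <- 1.7e12 * .SPECTRA_WL^-3.48

# reduced scattering power laws mus'(lambda) = a * (lambda/500)^-b, cm^-1,
# converted to mus with the bundled anisotropy g = 0.9
.SCATTER_LAW <- list(
  skin = c(a = 46.0, b = 1.421),
  blood = c(a = 22.0, b = 0.660),
  fat = c(a = 18.4, b = 0.672),
  muscle = c(a = 13.0, b = 0.926),
  bone = c(a = 22.9, b = 0.716),
  generic = c(a = 10.0, b = 1.000))

.G_DEFAULT <- 0.9

# Wavelength-independent literature values and plausible ranges used to
# validate the bundled tissue compositions: value, min, max.
.LITERATURE <- list(
  blood = list(sos = c(1578, 1520, 1640), rho = c(1050, 1020, 1090),
               alpha = c(0.20, 0.05, 0.50), gruneisen = c(0.20, 0.10, 0.30)),
  epidermis = list(sos = c(1624, 1540, 1700), rho = c(1109, 1050, 1190),
                   alpha = c(0.60, 0.20, 1.20), gruneisen = c(0.20, 0.10, 0.30)),
  dermis = list(sos = c(1624, 1540, 1700), rho = c(1109, 1050, 1190),
                alpha = c(0.60, 0.20, 1.20), gruneisen = c(0.20, 0.10, 0.30)),
  fat = list(sos = c(1440, 1400, 1490), rho = c(911, 880, 960),
             alpha = c(0.60, 0.30, 1.00), gruneisen = c(0.70, 0.50, 0.95)),
  muscle = list(sos = c(1580, 1520, 1630), rho = c(1090, 1040, 1120),
                alpha = c(0.62, 0.30, 1.10), gruneisen = c(0.20, 0.10, 0.30)),
  bone = list(sos = c(2800, 2300, 3600), rho = c(1908, 1700, 2100),
              alpha = c(3.50, 1.00, 8.00), gruneisen = c(0.50, 0.30, 0.80)),
  water = list(sos = c(1480, 1460, 1530), rho = c(997, 980, 1010),
               alpha = c(0.0022, 0.001, 0.01), gruneisen = c(0.12, 0.08, 0.20)),
  background = list(sos = c(1540, 1450, 1640), rho = c(1000, 950, 1120),
                    alpha = c(0.50, 0.10, 1.20), gruneisen = c(0.20, 0.10, 0.30)))

.mus_spectrum <- function(tissue) {
  law <- .SCATTER_LAW[[tissue]]
  musp <- law["a"] * (.SPECTRA_WL / 500)^(-law["b"])
  Spectrum(paste0(tissue, "_scattering"), .SPECTRA_WL,
           as.numeric(musp / (1 - .G_DEFAULT)))
}

.g_spectrum <- function(g = .G_DEFAULT)
  Spectrum("anisotropy", c(650, 1000), c(g, g))

.flat_spectrum <- function(name, value)
  Spectrum(name, c(650, 1000), c(value, value))

#' Bundled chromophore absorption spectra
#'
#' Returns one of the bundled absorption [Spectrum-class] knot tables
#' (cm^-1, 650-1000 nm in 25-nm steps): `"oxyhemoglobin"` and
#' `"deoxyhemoglobin"` are whole-blood absorption at 150 g/L hemoglobin,
#' `"water"`, `"fat"` (lipid) and `"melanin"` (melanosome) are the pure
#' chromophores.
#'
#' @param name chromophore name.
#' @return A [Spectrum-class].
#' @examples
#' interpolateSpectrum(spectrumLibrary("oxyhemoglobin"), 800)
#' @export
spectrumLibrary <- function(name) {
  switch(name,
    oxyhemoglobin = Spectrum("oxyhemoglobin", .SPECTRA_WL,
                             .EPS_HBO2 * .BLOOD_FACTOR),
    deoxyhemoglobin = Spectrum("deoxyhemoglobin", .SPECTRA_WL,
                               .EPS_HB * .BLOOD_FACTOR),
    water = Spectrum("water", .SPECTRA_WL, .MUA_WATER),
    fat = Spectrum("fat", .SPECTRA_WL, .MUA_FAT),
    melanin = Spectrum("melanin", .SPECTRA_WL, .MUA_MELANOSOME),
    stop("unknown chromophore '", name, "'; available: oxyhemoglobin, ",
         "deoxyhemoglobin, water, fat, melanin"))
}

#' Literature reference ranges for tissue properties
#'
#' The wavelength-independent acoustic reference values bundled with the
#' tissue library: for each property (`sos` m/s, `rho` kg/m^3, `alpha`
#' dB/cm/MHz, `gruneisen` unitless) a vector `c(value, min, max)`.
#'
#' @param tissue tissue name (see [tissueLibrary()]).
#' @return Named list of `c(value, min, max)` vectors.
#' @export
literatureRanges <- function(tissue) {
  if (!tissue %in% names(.LITERATURE))
    stop("unknown tissue '", tissue, "'; available: ",
         paste(names(.LITERATURE), collapse = ", "))
  .LITERATURE[[tissue]]
}
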