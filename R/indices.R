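#' Tasseled Cap wetness coefficients per sensor
#'
#' Published reflectance-based wetness coefficient sets (Crist 1985 for TM;
#' Baig et al. 2014 for OLI) over the band order blue, green, red, nir,
#' swir1, swir2. ETM+ uses the TM set; the synthetic sensor defaults to the
#' TM set. The same table ships as a versioned CSV in `extdata`.
#'
#' @param sensor_id one of `"TM"`, `"ETM+"`, `"OLI"`, `"SYNTHETIC"`.
#' @return named numeric vector of 6 coefficients.
#' @export
wetness_coefficients <- function(sensor_id) {
  tabs <- list(
    "TM"        = c(0.0315, 0.2021, 0.3102, 0.1594, -0.6806, -0.6109),
    "ETM+"      = c(0.0315, 0.2021, 0.3102, 0.1594, -0.6806, -0.6109),
    "OLI"       = c(0.1511, 0.1973, 0.3283, 0.3407, -0.7117, -0.4559),
    "SYNTHETIC" = c(0.0315, 0.2021, 0.3102, 0.1594, -0.6806, -0.6109))
  if (!sensor_id %in% names(tabs)) {
    stop("no wetness coefficient set registered for sensor '", sensor_id, "'",
         call. = FALSE)
  }
  stats::setNames(tabs[[sensor_id]], BAND_NAMES)
}

#' Normalized difference of two bands
#'
#' `(a - b) / (a + b)`; pixels with `a + b == 0` become nodata rather than
#' raising an error.
#'
#' @param a,b numeric matrices (or vectors) on one grid.
#' @return numeric array in `[-1, 1]` where valid.
#' @export
normalized_difference <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  s <- a + b
  out <- (a - b) / s
  out[!is.na(s) & s == 0] <- NA_real_
  out
}

#' NDVI, NDMI, NBR and MNDWI from a composite
#'
#' @param composite a `pw_composite`.
#' @param name which index.
#' @return numeric matrix.
#' @export
spectral_index <- function(composite,
                           name = c("NDVI", "NDMI", "NBR", "MNDWI")) {
  name <- match.arg(name)
  b <- composite$bands
  switch(name,
         NDVI  = normalized_difference(b$nir,   b$red),
         NDMI  = normalized_difference(b$nir,   b$swir1),
         NBR   = normalized_difference(b$nir,   b$swir2),
         MNDWI = normalized_difference(b$green, b$swir1))
}

#' Tasseled Cap wetness
#'
#' Per-pixel dot product of the six reflectance bands with the sensor's
#' wetness coefficients.
#'
#' @param composite a `pw_composite`.
#' @param coefficients 6 coefficients; defaults to the registered set for the
#'   composite's sensor.
#' @return numeric matrix.
#' @export
tasseled_cap_wetness <- function(composite,
                                 coefficients =
                                   wetness_coefficients(composite$sensor_id)) {
  stopifnot(length(coefficients) == 6)
  out <- 0
  for (i in seq_along(BAND_NAMES)) {
    out <- out + coefficients[[i]] * composite$bands[[BAND_NAMES[i]]]
  }
  out
}

#' Bare-surface index NDBSI = (SI + IBI) / 2
#'
#' Two SI variants are available. `table_verbatim` (default) follows the
#' printed formula `[(nir + red) - (nir + blue)] / [(nir + red) + (nir +
#' blue)]`, which algebraically collapses to a red-blue contrast
#' `(red - blue) / (2 nir + red + blue)` with no SWIR contribution.
#' `standard_si` is the conventional bare-soil index
#' `[(swir1 + red) - (nir + blue)] / [(swir1 + red) + (nir + blue)]`.
#' IBI is identical in both variants. Zero denominators yield nodata.
#'
#' @param composite a `pw_composite`.
#' @param variant `"table_verbatim"` or `"standard_si"`.
#' @return list with matrices `si`, `ibi`, `ndbsi` and the `variant` used.
#' @export
ndbsi <- function(composite, variant = c("table_verbatim", "standard_si")) {
  variant <- match.arg(variant)
  b <- composite$bands
  si <- if (variant == "table_verbatim") {
    normalized_difference(b$nir + b$red, b$nir + b$blue)
  } else {
    normalized_difference(b$swir1 + b$red, b$nir + b$blue)
  }
  ibi_num <- 2 * b$swir2 / (b$swir1 + b$nir)
  ibi_sub <- b$nir / (b$red + b$nir) + b$green / (b$swir1 + b$green)
  ibi <- (ibi_num - ibi_sub) / (ibi_num + ibi_sub)
  den0 <- !is.na(ibi_num + ibi_sub) & (ibi_num + ibi_sub) == 0
  ibi[den0] <- NA_real_
  list(si = si, ibi = ibi, ndbsi = (si + ibi) / 2, variant = variant)
}

#' Brightness temperature from thermal radiance
#'
#' `T = K2 / ln(K1 / L + 1)` in Kelvin. Non-positive radiance, or radiance
#' above `radiance_cap` (where the logarithm degenerates and T diverges),
#' yields nodata.
#'
#' @param radiance thermal radiance array.
#' @param K1,K2 sensor thermal calibration constants.
#' @param radiance_cap upper radiance bound treated as physically implausible.
#' @return Kelvin array.
#' @export
brightness_temperature <- function(radiance, K1 = 607.76, K2 = 1260.56,
                                   radiance_cap = 1000) {
  stopifnot(K1 > 0, K2 > 0)
  bad <- is.na(radiance) | radiance <= 0 | radiance > radiance_cap
  L <- radiance
  L[bad] <- 1  # placeholder keeps log() quiet; overwritten below
  t <- K2 / log(K1 / L + 1)
  t[bad] <- NA_real_
  t
}

#' Single-channel emissivity-corrected land surface temperature
#'
#' `LST = T / (1 + (lambda * T / rho) * ln(emissivity)) - 273.15` in degrees
#' Celsius. `emissivity <= 0` (or `> 1`) yields nodata; with emissivity 1 the
#' correction vanishes exactly.
#'
#' @param t_kelvin brightness temperature (K).
#' @param emissivity surface emissivity in `(0, 1]` (scalar or array).
#' @param lambda effective thermal wavelength (m), default 11.5e-6.
#' @param rho h*c/sigma constant (m K), default 1.438e-2.
#' @return degrees Celsius.
#' @export
lst_single_channel <- function(t_kelvin, emissivity, lambda = 11.5e-6,
                               rho = 1.438e-2) {
  den <- 1 + (lambda * t_kelvin / rho) * log(emissivity)
  lst <- t_kelvin / den - 273.15
  # emissivities so small that the correction denominator collapses are as
  # unphysical as epsilon <= 0; both become nodata
  bad <- is.na(emissivity) | emissivity <= 0 | emissivity > 1 |
    is.na(t_kelvin) | t_kelvin <= 0 | (!is.na(den) & den <= 0)
  lst[bad] <- NA_real_
  lst
}

#' LST from the Level-2 surface-temperature product
#'
#' Pass-through of the product-scaled temperature with plausibility
#' screening; out-of-bounds values are flagged nodata.
#'
#' @param temperature_c temperature array in degrees Celsius
#'   (from [scale_temperature()]).
#' @param bounds plausible range, default `c(-20, 60)` degrees C.
#' @return screened array.
#' @export
lst_from_product <- function(temperature_c, bounds = c(-20, 60)) {
  temperature_c[temperature_c < bounds[1] | temperature_c > bounds[2]] <-
    NA_real_
  temperature_c
}
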