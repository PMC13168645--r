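# Shared constants: band order of reflectance stacks, land-cover codes and
# the fixed classification predictor set.
BAND_NAMES <- c("blue", "green", "red", "nir", "swir1", "swir2")
CLASS_CODES <- c(forest = 1L, bog = 2L, grassland = 3L)
PREDICTOR_NAMES <- c(BAND_NAMES, "NDVI", "NDMI", "NBR", "MNDWI")
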