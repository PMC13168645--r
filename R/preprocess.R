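#' One year's multi-band scene with QA
#'
#' Container for a single acquisition: six reflectance bands (unitless,
#' nominally in `[0, 1]`), one thermal band (Kelvin unless flagged raw), a
#' QA bit raster and an optional radiometric-saturation raster.
#'
#' @param year calendar year of acquisition.
#' @param doy acquisition day of year.
#' @param sensor_id one of `"TM"`, `"ETM+"`, `"OLI"`, `"SYNTHETIC"`.
#' @param bands named list of the 6 reflectance matrices
#'   (`blue, green, red, nir, swir1, swir2`).
#' @param thermal thermal matrix (Kelvin).
#' @param qa integer matrix of QA bit flags (0 = clear).
#' @param grid a [pw_grid()].
#' @param radsat optional integer matrix; non-zero marks saturated pixels.
#' @return object of class `scene_stack`.
#' @export
scene_stack <- function(year, doy, sensor_id, bands, thermal, qa, grid,
                        radsat = NULL) {
  sensor_id <- match.arg(sensor_id, c("TM", "ETM+", "OLI", "SYNTHETIC"))
  stopifnot(identical(sort(names(bands)), sort(BAND_NAMES)))
  dims <- c(grid$nrow, grid$ncol)
  for (nm in BAND_NAMES) {
    stopifnot(identical(dim(bands[[nm]]), dims))
  }
  stopifnot(identical(dim(thermal), dims), identical(dim(qa), dims))
  structure(list(year = year, doy = doy, sensor_id = sensor_id,
                 bands = bands[BAND_NAMES], thermal = thermal,
                 qa = qa, radsat = radsat, grid = grid),
            class = "scene_stack")
}

#' @export
print.scene_stack <- function(x, ...) {
  cat(sprintf("<scene_stack %d doy %d [%s] %s>\n", x$year, x$doy,
              x$sensor_id, format(x$grid)))
  invisible(x)
}

#' QA bit layout
#'
#' Bit positions of the quality flags decoded by [decode_qa()]. Defaults
#' follow the Collection 2 QA_PIXEL convention (fill bit 0, cirrus 2, cloud
#' 3, shadow 4, snow/ice 5).
#'
#' @param fill,cirrus,cloud,cloud_shadow,snow_ice bit positions (0-based).
#' @return object of class `qa_bit_spec`.
#' @export
qa_bit_spec <- function(fill = 0L, cirrus = 2L, cloud = 3L, cloud_shadow = 4L,
                        snow_ice = 5L) {
  bits <- c(fill = fill, cirrus = cirrus, cloud = cloud,
            cloud_shadow = cloud_shadow, snow_ice = snow_ice)
  if (anyDuplicated(bits)) stop("QA bit positions must be distinct")
  if (any(bits < 0 | bits > 30)) stop("QA bit positions outside word size")
  structure(as.list(bits), class = "qa_bit_spec")
}

#' Decode a QA bit raster to a validity mask
#'
#' A pixel is valid iff none of the flagged bits (fill, cirrus, cloud, cloud
#' shadow, snow/ice) is set.
#'
#' @param qa integer matrix of QA words.
#' @param spec a [qa_bit_spec()].
#' @return logical matrix, `TRUE` = valid.
#' @export
decode_qa <- function(qa, spec = qa_bit_spec()) {
  mask_word <- sum(bitwShiftL(1L, unlist(spec)))
  m <- bitwAnd(as.integer(qa), mask_word) == 0L
  dim(m) <- dim(qa)
  m
}

#' Scale Level-2 style reflectance DN to surface reflectance
#'
#' `reflectance = DN * 2.75e-5 - 0.2`; values outside `[0, 1]` are marked
#' invalid (`NA`), never clipped.
#'
#' @param dn integer matrix (or vector) of digital numbers.
#' @return numeric array of reflectance with `NA` where out of range.
#' @export
scale_reflectance <- function(dn) {
  r <- dn * 2.75e-5 - 0.2
  r[r < 0 | r > 1] <- NA_real_
  r
}

#' Scale Level-2 style surface-temperature DN to degrees Celsius
#'
#' `Kelvin = DN * 0.00341802 + 149.0`, then Celsius = Kelvin - 273.15.
#' No plausibility screening here; see [lst_from_product()].
#'
#' @param dn integer matrix (or vector) of digital numbers.
#' @return temperature in degrees C.
#' @export
scale_temperature <- function(dn) {
  dn * 0.00341802 + 149.0 - 273.15
}

#' Per-scene validity mask
#'
#' Combines QA decoding with whole-pixel saturation drop (any saturated band
#' invalidates the pixel vector) and the out-of-range reflectance rule.
#'
#' @param scene a [scene_stack()].
#' @param spec a [qa_bit_spec()].
#' @return logical matrix, `TRUE` = usable observation.
#' @export
scene_validity <- function(scene, spec = qa_bit_spec()) {
  m <- decode_qa(scene$qa, spec)
  if (!is.null(scene$radsat)) m <- m & (scene$radsat == 0L)
  for (nm in BAND_NAMES) {
    b <- scene$bands[[nm]]
    m <- m & !is.na(b) & b >= 0 & b <= 1
  }
  m
}

#' Select the seasonal scene window for one year
#'
#' June acquisitions are preferred; if the June subset leaves less than
#' `coverage_threshold` of pixels with at least one valid observation the
#' window extends to June-August. A year whose extended window still has no
#' valid observation anywhere is flagged missing rather than fabricated.
#'
#' June is taken as days of year 152-181 (non-leap convention), JJA as
#' 152-243.
#'
#' @param scenes list of [scene_stack()] for one year.
#' @param year calendar year (scenes from other years are ignored).
#' @param coverage_threshold minimum fraction of pixels with >= 1 valid
#'   observation for the June-only window to be accepted (default 0.8).
#' @param spec a [qa_bit_spec()].
#' @return list with `scenes` (the selected subset), `window_used`
#'   (`"JUNE"`, `"JJA"` or `"MISSING"`) and `coverage` (fraction achieved).
#' @export
select_seasonal_scenes <- function(scenes, year, coverage_threshold = 0.8,
                                   spec = qa_bit_spec()) {
  scenes <- Filter(function(s) s$year == year, scenes)
  jja <- Filter(function(s) s$doy >= 152 && s$doy <= 243, scenes)
  if (length(jja) == 0) {
    return(list(scenes = list(), window_used = "MISSING", coverage = 0))
  }
  coverage_of <- function(sub) {
    if (length(sub) == 0) return(0)
    any_valid <- Reduce(`|`, lapply(sub, scene_validity, spec = spec))
    mean(any_valid)
  }
  june <- Filter(function(s) s$doy <= 181, jja)
  cov_june <- coverage_of(june)
  if (length(june) > 0 && cov_june >= coverage_threshold) {
    return(list(scenes = june, window_used = "JUNE", coverage = cov_june))
  }
  cov_jja <- coverage_of(jja)
  if (cov_jja == 0) {
    return(list(scenes = list(), window_used = "MISSING", coverage = 0))
  }
  list(scenes = jja, window_used = "JJA", coverage = cov_jja)
}

#' Medoid composite of a scene set
#'
#' Per pixel, the per-band median over valid observations is computed for the
#' six reflectance bands, and the single valid observation minimising the
#' Euclidean distance to that median vector is copied into all bands
#' including thermal - so every composite spectrum is an observed spectrum,
#' never a per-band mixture. Ties are broken by earliest acquisition date.
#'
#' @param scenes non-empty list of [scene_stack()] on one grid.
#' @param masks optional list of validity masks (as [scene_validity()]);
#'   computed from `spec` when omitted.
#' @param spec a [qa_bit_spec()] used when `masks` is `NULL`.
#' @return object of class `pw_composite`: list with `year`, `bands`,
#'   `thermal`, `valid_count`, `window_used` (filled by callers), `grid`,
#'   `source_index` (which scene each pixel came from).
#' @export
medoid_composite <- function(scenes, masks = NULL, spec = qa_bit_spec()) {
  stopifnot(length(scenes) >= 1)
  grid <- scenes[[1]]$grid
  for (s in scenes) check_same_grid(grid, s$grid, "scenes")
  # earliest-date-first ordering makes which-min tie-breaking deterministic
  ord <- order(vapply(scenes, `[[`, numeric(1), "doy"))
  scenes <- scenes[ord]
  if (is.null(masks)) {
    masks <- lapply(scenes, scene_validity, spec = spec)
  } else {
    masks <- masks[ord]
  }
  k <- length(scenes)
  npix <- grid$nrow * grid$ncol

  refl <- array(NA_real_, c(npix, 6L, k))
  for (j in seq_len(k)) {
    ok <- as.vector(masks[[j]])
    for (b in seq_along(BAND_NAMES)) {
      v <- as.vector(scenes[[j]]$bands[[BAND_NAMES[b]]])
      v[!ok] <- NA_real_
      refl[, b, j] <- v
    }
  }
  med <- matrix(NA_real_, npix, 6L)
  for (b in 1:6) {
    mb <- refl[, b, , drop = FALSE]
    dim(mb) <- c(npix, k)
    med[, b] <- row_medians_cpp(mb)
  }

  d2 <- matrix(Inf, npix, k)
  for (j in seq_len(k)) {
    dj <- (refl[, , j, drop = TRUE] - med)^2
    dim(dj) <- c(npix, 6L)
    s <- rowSums(dj)
    s[is.na(s)] <- Inf
    d2[, j] <- s
  }
  valid_count <- rowSums(matrix(vapply(masks, as.vector, logical(npix)),
                                nrow = npix))
  pick <- max.col(-d2, ties.method = "first")
  pick[valid_count == 0] <- NA_integer_

  bands <- stats::setNames(vector("list", 6), BAND_NAMES)
  for (b in 1:6) {
    v <- refl[cbind(seq_len(npix), b, pick)]
    v[is.na(pick)] <- NA_real_
    bands[[BAND_NAMES[b]]] <- matrix(v, grid$nrow, grid$ncol)
  }
  thermal_stack <- matrix(vapply(scenes, function(s) as.vector(s$thermal),
                                 numeric(npix)), nrow = npix)
  th <- thermal_stack[cbind(seq_len(npix), pick)]
  th[is.na(pick)] <- NA_real_

  structure(list(year = scenes[[1]]$year,
                 sensor_id = scenes[[1]]$sensor_id,
                 bands = bands,
                 thermal = matrix(th, grid$nrow, grid$ncol),
                 valid_count = matrix(valid_count, grid$nrow, grid$ncol),
                 window_used = NA_character_,
                 source_index = matrix(pick, grid$nrow, grid$ncol),
                 grid = grid),
            class = "pw_composite")
}

#' Build one analysis-ready composite for a year
#'
#' Convenience wrapper: seasonal selection then medoid compositing.
#'
#' @inheritParams select_seasonal_scenes
#' @return a `pw_composite`, or `NULL` if the year is missing.
#' @export
composite_year <- function(scenes, year, coverage_threshold = 0.8,
                           spec = qa_bit_spec()) {
  sel <- select_seasonal_scenes(scenes, year, coverage_threshold, spec)
  if (sel$window_used == "MISSING") return(NULL)
  comp <- medoid_composite(sel$scenes, spec = spec)
  comp$window_used <- sel$window_used
  comp
}
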