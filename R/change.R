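#' Pixel-wise RSEI difference (end minus start)
#'
#' @param rsei_end,rsei_start matrices on one grid, values in `[0, 1]`.
#' @return delta matrix; `NA` where either input is missing.
#' @export
delta_rsei <- function(rsei_end, rsei_start) {
  if (!identical(dim(rsei_end), dim(rsei_start))) {
    stop("grids differ", call. = FALSE)
  }
  rsei_end - rsei_start
}

#' Threshold a delta layer into a changed-pixel mask
#'
#' `changed <=> |delta| > threshold` with the threshold either a fixed
#' absolute value (`rule = "abs_value"`, default `k = 0.02`) or a multiple
#' of the delta's standard deviation (`rule = "std_multiple"`, default
#' `m = 0.5`). The resolved threshold is recorded; this is a free parameter
#' of the analysis.
#'
#' @param delta delta matrix.
#' @param rule `"abs_value"` or `"std_multiple"`.
#' @param k absolute threshold for `abs_value`.
#' @param m multiplier for `std_multiple`.
#' @return list `mask` (logical matrix), `threshold_value`, `rule`.
#' @export
threshold_change <- function(delta, rule = c("abs_value", "std_multiple"),
                             k = 0.02, m = 0.5) {
  rule <- match.arg(rule)
  thr <- if (rule == "abs_value") k else m * sd(delta, na.rm = TRUE)
  mask <- !is.na(delta) & abs(delta) > thr
  list(mask = mask, threshold_value = thr, rule = rule)
}

#' Distributional and area summary of a delta layer
#'
#' Mean, median, IQR, percentiles 2/10/90/98, min and max over the valid
#' pixels (linear-interpolation percentiles), plus improved/degraded areas
#' within the changed mask. Improved and degraded hectares partition the
#' changed hectares exactly.
#'
#' @param delta delta matrix.
#' @param changed logical changed mask (from [threshold_change()]).
#' @param pixel_area pixel area in hectares.
#' @return list with `stats` (named vector), `changed_area_ha`,
#'   `improved_area_ha`, `degraded_area_ha`, `improved_percent`,
#'   `degraded_percent` (of changed area).
#' @export
summarize_delta <- function(delta, changed, pixel_area = 0.09) {
  v <- delta[!is.na(delta)]
  stopifnot(length(v) >= 1)
  qs <- quantile(v, c(0.02, 0.10, 0.25, 0.50, 0.75, 0.90, 0.98), type = 7)
  stats <- c(mean = mean(v), median = unname(qs[4]),
             iqr = unname(qs[5] - qs[3]),
             p02 = unname(qs[1]), p10 = unname(qs[2]), p90 = unname(qs[6]),
             p98 = unname(qs[7]), min = min(v), max = max(v))
  n_imp <- sum(changed & delta > 0, na.rm = TRUE)
  n_deg <- sum(changed & delta < 0, na.rm = TRUE)
  n_chg <- sum(changed, na.rm = TRUE)
  # zero-delta pixels cannot be inside a positive-threshold mask, so
  # improved + degraded = changed holds exactly
  list(stats = stats,
       changed_area_ha = n_chg * pixel_area,
       improved_area_ha = n_imp * pixel_area,
       degraded_area_ha = n_deg * pixel_area,
       improved_percent = if (n_chg > 0) 100 * n_imp / n_chg else NA_real_,
       degraded_percent = if (n_chg > 0) 100 * n_deg / n_chg else NA_real_)
}

#' Label contiguous same-sign change patches
#'
#' Connected components (4- or 8-connectivity, default 8) among changed
#' pixels of equal delta sign.
#'
#' @param changed logical changed mask.
#' @param delta delta matrix providing the sign.
#' @param connectivity 4 or 8.
#' @param pixel_area pixel area in hectares.
#' @return list `labels` (integer matrix of patch ids), `table` (data frame
#'   `id`, `sign`, `n_pixels`, `area_ha`), `n_patches`,
#'   `largest_patch_ha`, `connectivity`.
#' @export
label_patches <- function(changed, delta, connectivity = 8,
                          pixel_area = 0.09) {
  stopifnot(connectivity %in% c(4, 8), identical(dim(changed), dim(delta)))
  signs <- matrix(0L, nrow(delta), ncol(delta))
  signs[changed & !is.na(delta) & delta > 0] <- 1L
  signs[changed & !is.na(delta) & delta < 0] <- 2L
  labels <- label_components_cpp(signs, as.integer(connectivity))
  ids <- setdiff(sort(unique(as.vector(labels))), 0L)
  tab <- do.call(rbind, lapply(ids, function(id) {
    sel <- labels == id
    data.frame(id = id, sign = if (signs[which(sel)[1]] == 1L) "+" else "-",
               n_pixels = sum(sel), area_ha = sum(sel) * pixel_area)
  }))
  if (is.null(tab)) {
    tab <- data.frame(id = integer(0), sign = character(0),
                      n_pixels = integer(0), area_ha = numeric(0))
  }
  list(labels = labels, table = tab, n_patches = length(ids),
       largest_patch_ha = if (nrow(tab)) max(tab$area_ha) else 0,
       connectivity = connectivity)
}

#' Complete change analysis between two RSEI layers
#'
#' Convenience wrapper: delta, threshold, distributional summary and patch
#' statistics in one call.
#'
#' @param rsei_end,rsei_start RSEI matrices.
#' @param rule,k,m see [threshold_change()].
#' @param connectivity see [label_patches()].
#' @param pixel_area hectares per pixel.
#' @return list `delta`, `threshold`, `summary`, `patches`.
#' @export
change_analysis <- function(rsei_end, rsei_start,
                            rule = "std_multiple", k = 0.02, m = 0.5,
                            connectivity = 8, pixel_area = 0.09) {
  delta <- delta_rsei(rsei_end, rsei_start)
  thr <- threshold_change(delta, rule, k = k, m = m)
  list(delta = delta, threshold = thr,
       summary = summarize_delta(delta, thr$mask, pixel_area),
       patches = label_patches(thr$mask, delta, connectivity, pixel_area))
}
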