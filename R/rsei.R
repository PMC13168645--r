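#' Min-max normalization to the unit interval
#'
#' `(x - min) / (max - min)` over the valid pixels; affine-invariant by
#' construction. A constant layer is an error naming the component, because
#' the downstream PCA would receive a degenerate column.
#'
#' @param layer numeric matrix (NA = nodata).
#' @param name component name used in error messages.
#' @return matrix in `[0, 1]` with the original `NA` pattern.
#' @export
normalize01 <- function(layer, name = "layer") {
  v <- layer[!is.na(layer)]
  if (length(v) < 2 || max(v) == min(v)) {
    stop("component '", name, "' is constant (or empty); cannot normalize",
         call. = FALSE)
  }
  (layer - min(v)) / (max(v) - min(v))
}

#' Leading principal component of the four condition components
#'
#' Columns (one per component) are centred over the pixels valid in all four
#' layers; PC1 is the leading eigenvector of their 4 x 4 covariance, scores
#' are the projections. A rank-deficient covariance is flagged but the
#' leading eigenvector is still returned.
#'
#' @param layers named list of 4 matrices (order NDVI, WET, NDBSI, LST).
#' @return list: `loadings` (unit 4-vector), `scores` (matrix with `NA`
#'   outside the common valid mask), `variance_share`, `valid` mask,
#'   `rank_deficient` flag.
#' @export
pca_pc1 <- function(layers) {
  stopifnot(length(layers) == 4)
  valid <- Reduce(`&`, lapply(layers, function(l) !is.na(l)))
  if (sum(valid) < 4) stop("fewer than 4 common valid pixels", call. = FALSE)
  V <- vapply(layers, function(l) l[valid], numeric(sum(valid)))
  ctr <- sweep(V, 2, colMeans(V))
  C <- stats::cov(ctr)
  eig <- eigen(C, symmetric = TRUE)
  loadings <- eig$vectors[, 1]
  total <- sum(eig$values)
  variance_share <- if (total > 0) eig$values[1] / total else NA_real_
  scores <- matrix(NA_real_, nrow(layers[[1]]), ncol(layers[[1]]))
  scores[valid] <- as.vector(ctr %*% loadings)
  list(loadings = stats::setNames(loadings, names(layers)),
       scores = scores, variance_share = variance_share, valid = valid,
       rank_deficient = any(eig$values < 1e-12 * max(eig$values)))
}

#' RSEI layer from PCA output
#'
#' Orients PC1 so the index correlates positively with greenness and
#' wetness and negatively with dryness and heat - the "1 - PC1" convention
#' with the eigenvector sign ambiguity resolved: scores are negated when the
#' NDVI loading is negative (falling back to the signed loading sum
#' `+NDVI +WET -NDBSI -LST` when the NDVI loading is exactly zero) - and
#' min-max rescales the oriented scores to `[0, 1]`.
#'
#' @param pca output of [pca_pc1()].
#' @return list: `rsei` matrix in `[0, 1]`, `orientation_flipped`,
#'   `loadings`, `variance_share`.
#' @export
compute_rsei <- function(pca) {
  l <- pca$loadings
  key <- if (abs(l[1]) > 1e-12) l[1] else sum(l * c(1, 1, -1, -1))
  flipped <- key < 0
  raw <- if (flipped) -pca$scores else pca$scores
  v <- raw[!is.na(raw)]
  if (max(v) == min(v)) stop("zero-variance PC1 scores", call. = FALSE)
  list(rsei = (raw - min(v)) / (max(v) - min(v)),
       orientation_flipped = flipped,
       loadings = pca$loadings,
       variance_share = pca$variance_share)
}

#' Five-level RSEI categories
#'
#' Bins `[0, 0.2) [0.2, 0.4) [0.4, 0.6) [0.6, 0.8) [0.8, 1]` coded 1
#' (Poor) to 5 (Excellent); boundaries are left-closed so 0.2 falls in
#' level 2, and 1.0 closes the last bin. Out-of-range values become nodata.
#'
#' @param rsei matrix in `[0, 1]`.
#' @return integer matrix of categories (NA = nodata).
#' @export
classify_rsei <- function(rsei) {
  # findInterval keeps boundary values exact (0.6 stays in level 4)
  cat <- findInterval(rsei, c(0.2, 0.4, 0.6, 0.8)) + 1L
  cat[is.na(rsei) | rsei < 0 | rsei > 1] <- NA_integer_
  matrix(as.integer(cat), nrow(rsei), ncol(rsei))
}

#' Class-stratified RSEI means
#'
#' @param rsei RSEI matrix.
#' @param landcover class matrix on the same grid (0 = nodata).
#' @return data frame `class`, `mean_rsei`, `n_pixels` (empty classes
#'   flagged with `NA` mean).
#' @export
stratified_mean <- function(rsei, landcover) {
  stopifnot(identical(dim(rsei), dim(landcover)))
  out <- lapply(CLASS_CODES, function(cls) {
    v <- rsei[landcover == cls & !is.na(rsei)]
    data.frame(class = cls, mean_rsei = if (length(v)) mean(v) else NA_real_,
               n_pixels = length(v))
  })
  res <- do.call(rbind, out)
  res$class_name <- names(CLASS_CODES)
  rownames(res) <- NULL
  res
}

#' Full per-year RSEI synthesis from a composite
#'
#' Computes the four components (NDVI; Tasseled Cap wetness; NDBSI in the
#' requested variant; LST from the thermal band, Kelvin minus 273.15 with
#' plausibility screening), normalizes each to `[0, 1]`, runs the per-year
#' PCA and returns the oriented, rescaled index with its categories.
#'
#' @param composite a `pw_composite` (thermal in Kelvin).
#' @param variant NDBSI variant, see [ndbsi()].
#' @param lst_bounds plausibility bounds (deg C) for the LST screen.
#' @return object of class `rsei_result`: year, normalized components, PC1
#'   loadings and variance share, `rsei`, `categories`,
#'   `orientation_flipped`.
#' @export
rsei_for_year <- function(composite,
                          variant = c("table_verbatim", "standard_si"),
                          lst_bounds = c(-20, 60)) {
  variant <- match.arg(variant)
  comp <- list(
    NDVI  = spectral_index(composite, "NDVI"),
    WET   = tasseled_cap_wetness(composite),
    NDBSI = ndbsi(composite, variant)$ndbsi,
    LST   = lst_from_product(composite$thermal - 273.15, lst_bounds))
  normed <- mapply(normalize01, comp, names(comp), SIMPLIFY = FALSE)
  pca <- pca_pc1(normed)
  r <- compute_rsei(pca)
  structure(list(year = composite$year,
                 normalized_components = normed,
                 pc1_loadings = r$loadings,
                 pc1_variance_share = r$variance_share,
                 rsei = r$rsei,
                 categories = classify_rsei(r$rsei),
                 orientation_flipped = r$orientation_flipped,
                 variant = variant,
                 grid = composite$grid),
            class = "rsei_result")
}

#' @export
print.rsei_result <- function(x, ...) {
  cat(sprintf(
    "<rsei_result %s: PC1 var share %.3f, flipped %s, mean RSEI %.3f>\n",
    x$year, x$pc1_variance_share, x$orientation_flipped,
    mean(x$rsei, na.rm = TRUE)))
  invisible(x)
}
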