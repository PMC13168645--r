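# Independent oracles and small fixture builders. These deliberately use
# plain, slow R so they stay independent of the package implementation.

band_names <- c("blue", "green", "red", "nir", "swir1", "swir2")

# build a scene with given per-band matrices (defaults: random uniform)
make_scene <- function(grid, year = 2000, doy = 160, bands = NULL,
                       thermal = NULL, qa = NULL, sensor = "SYNTHETIC") {
  nr <- grid$nrow; nc <- grid$ncol
  if (is.null(bands)) {
    bands <- setNames(lapply(band_names, function(b) {
      matrix(runif(nr * nc, 0.01, 0.6), nr, nc)
    }), band_names)
  }
  if (is.null(thermal)) thermal <- matrix(295, nr, nc)
  if (is.null(qa)) qa <- matrix(0L, nr, nc)
  scene_stack(year, doy, sensor, bands, thermal, qa, grid)
}

# exhaustive medoid: per pixel, median per band over valid obs, then argmin
# Euclidean distance, first (earliest-date) scene wins ties
medoid_oracle_pixel <- function(obs, valid) {
  obs_valid <- obs[valid, , drop = FALSE]
  if (nrow(obs_valid) == 0) return(NA_integer_)
  med <- apply(obs_valid, 2, median)
  d <- apply(obs, 1, function(x) sum((x - med)^2))
  d[!valid] <- Inf
  which.min(d)
}

# brute-force Mann-Kendall S via double loop
mk_s_oracle <- function(y) {
  n <- length(y); s <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) s <- s + sign(y[j] - y[i])
  }
  s
}

# brute-force Theil-Sen slope
sen_oracle <- function(t, y) {
  n <- length(y); sl <- c()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) sl <- c(sl, (y[j] - y[i]) / (t[j] - t[i]))
  }
  median(sl)
}

# power-iteration leading eigenvector of a symmetric PSD matrix
power_iteration <- function(C, iters = 2000) {
  v <- rep(1, nrow(C)) / sqrt(nrow(C))
  for (i in seq_len(iters)) {
    v2 <- C %*% v
    v <- v2 / sqrt(sum(v2^2))
  }
  as.vector(v)
}

# full-sort linear-interpolation percentile
percentile_oracle <- function(v, p) {
  v <- sort(v)
  n <- length(v)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  v[lo] + (h - lo) * (v[hi] - v[lo])
}

# BFS connected-component labelling on equal non-zero values
label_oracle <- function(x, connectivity = 8) {
  nr <- nrow(x); nc <- ncol(x)
  lab <- matrix(0L, nr, nc)
  nbrs <- if (connectivity == 8) {
    cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1), dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(dr = c(-1, 0, 0, 1), dc = c(0, -1, 1, 0))
  }
  nid <- 0L
  for (c0 in seq_len(nc)) for (r0 in seq_len(nr)) {
    if (x[r0, c0] == 0 || lab[r0, c0] != 0) next
    nid <- nid + 1L
    queue <- list(c(r0, c0)); lab[r0, c0] <- nid
    while (length(queue) > 0) {
      p <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(nbrs))) {
        r <- p[1] + nbrs[k, 1]; c <- p[2] + nbrs[k, 2]
        if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
            x[r, c] == x[p[1], p[2]] && lab[r, c] == 0) {
          lab[r, c] <- nid
          queue[[length(queue) + 1]] <- c(r, c)
        }
      }
    }
  }
  lab
}

# 8-neighbour dilation used to find eligible bog edge pixels
neighbors8_oracle <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    rs <- max(1, r - 1):min(nr, r + 1)
    cs <- max(1, c - 1):min(nc, c + 1)
    out[r, c] <- any(mask[rs, cs]) &&
      (sum(mask[rs, cs]) > mask[r, c])
  }
  out
}

# quick zero-noise climate config for deterministic climate tests
quiet_climate <- function(trends = list(), sds = list()) {
  pars <- default_climate_params()
  for (v in names(pars)) {
    pars[[v]]$sd <- sds[[v]] %||% 0
    pars[[v]]$trend <- trends[[v]] %||% 0
  }
  pars
}
`%||%` <- function(a, b) if (is.null(a)) b else a
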