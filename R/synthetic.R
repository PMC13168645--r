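#' Configuration for the synthetic raised-bog world
#'
#' Defines the stated world used by the test suite: a three-class landscape
#' (1 Forest, 2 Bog, 3 Grassland) with a contiguous central bog, stochastic
#' bog-to-forest encroachment at the forest edge driven by the annual
#' climatic water balance, Gaussian spectral noise around class-mean spectra,
#' and circular cloud contamination.
#'
#' Initial class shares default to a 52.4/37.2/10.4 forest/bog/grassland
#' split (a forest-dominated mosaic with a large open bog).
#'
#' @param grid_rows,grid_cols landscape dimensions in pixels.
#' @param pixel_size_m pixel edge (m), default 30.
#' @param years strictly increasing calendar years.
#' @param class_spectra 3 x 6 matrix of class-mean reflectances (rows:
#'   forest, bog, grassland; columns in band order).
#' @param thermal_means per-class thermal means (K).
#' @param spectral_noise_sd per-band iid Gaussian noise sd.
#' @param thermal_noise_sd thermal noise sd (K).
#' @param thermal_anomaly_gain K of thermal response per degree C of annual
#'   summer temperature anomaly.
#' @param encroachment_base_rate per-year conversion probability for an
#'   eligible bog edge pixel under neutral water balance.
#' @param deficit_sensitivity multiplier linking conversion probability to
#'   the standardized negative annual climatic water balance.
#' @param grass_encroachment_rate optional grassland-to-forest edge rate
#'   (default 0 = disabled).
#' @param cloud_fraction expected per-scene cloud fraction in `[0, 1]`.
#' @param scenes_per_year acquisitions simulated per year (spread over
#'   June-August, first in June).
#' @param initial_shares named shares (forest, bog, grassland) summing to 1.
#' @param climate list of per-variable cycle parameters
#'   (`mean`, `amp`, `trend`, `sd`), see [simulate_climate()].
#' @param seed master seed; all sub-streams derive from it.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(grid_rows = 100, grid_cols = 100, pixel_size_m = 30,
                       years = 1984:2024,
                       class_spectra = default_class_spectra(),
                       thermal_means = c(forest = 294, bog = 298.5,
                                         grassland = 296),
                       spectral_noise_sd = 0.01,
                       thermal_noise_sd = 0.5,
                       thermal_anomaly_gain = 1.5,
                       encroachment_base_rate = 0.05,
                       deficit_sensitivity = 0.5,
                       grass_encroachment_rate = 0,
                       cloud_fraction = 0.15,
                       scenes_per_year = 3,
                       initial_shares = c(forest = 0.524, bog = 0.372,
                                          grassland = 0.104),
                       climate = default_climate_params(),
                       seed = 1L) {
  if (length(years) < 2 || any(diff(years) <= 0)) {
    stop("years must be >= 2 strictly increasing values", call. = FALSE)
  }
  probs <- c(encroachment_base_rate, grass_encroachment_rate, cloud_fraction)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(initial_shares) - 1) > 1e-9) {
    stop("initial class shares must sum to 1", call. = FALSE)
  }
  stopifnot(is.matrix(class_spectra), nrow(class_spectra) == 3,
            ncol(class_spectra) == 6, deficit_sensitivity >= 0,
            scenes_per_year >= 1)
  structure(list(grid_rows = as.integer(grid_rows),
                 grid_cols = as.integer(grid_cols),
                 pixel_size_m = pixel_size_m, years = years,
                 class_spectra = class_spectra,
                 thermal_means = thermal_means,
                 spectral_noise_sd = spectral_noise_sd,
                 thermal_noise_sd = thermal_noise_sd,
                 thermal_anomaly_gain = thermal_anomaly_gain,
                 encroachment_base_rate = encroachment_base_rate,
                 deficit_sensitivity = deficit_sensitivity,
                 grass_encroachment_rate = grass_encroachment_rate,
                 cloud_fraction = cloud_fraction,
                 scenes_per_year = as.integer(scenes_per_year),
                 initial_shares = initial_shares,
                 climate = climate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Default class-mean spectra
#'
#' Ecologically ordered reflectances: conifer-like forest is dark in the
#' visible and moderate in NIR; open bog is brighter in SWIR (drier moss and
#' exposed peat); grassland has the highest NIR. Only separability matters
#' for the tests; all values are user-configurable.
#'
#' @return 3 x 6 matrix (rows forest, bog, grassland).
#' @export
default_class_spectra <- function() {
  m <- rbind(forest    = c(0.020, 0.040, 0.030, 0.32, 0.14, 0.06),
             bog       = c(0.045, 0.065, 0.075, 0.24, 0.23, 0.15),
             grassland = c(0.035, 0.080, 0.055, 0.42, 0.20, 0.09))
  colnames(m) <- BAND_NAMES
  m
}

#' Default monthly climate-cycle parameters
#'
#' Seasonal cycle + linear trend + Gaussian noise for each monthly variable,
#' loosely emulating a maritime Baltic lowland: ~700 mm annual precipitation
#' with a weak summer maximum, summer-peaking reference evapotranspiration,
#' and a warming, drying tendency. `mean` is the annual mean of the monthly
#' value, `amp` the cosine amplitude peaking in July, `trend` the per-year
#' drift of the monthly value, `sd` the monthly noise standard deviation.
#'
#' @return named list of parameter lists.
#' @export
default_climate_params <- function() {
  list(ppt    = list(mean = 60, amp = 15, trend = -0.30, sd = 18),
       pet    = list(mean = 45, amp = 38, trend = +0.25, sd = 4),
       cwd    = list(mean = 18, amp = 16, trend = +0.15, sd = 5),
       aet    = list(mean = 38, amp = 28, trend = 0.00, sd = 4),
       runoff = list(mean = 18, amp = 10, trend = -0.05, sd = 5),
       tmean  = list(mean = 8.5, amp = 9.5, trend = +0.035, sd = 1.2))
}

#' Simulate a monthly hydroclimate series
#'
#' Every variable is an independent seasonal cycle (July peak) plus linear
#' trend plus Gaussian noise; water fluxes are floored at zero. The climatic
#' water balance `cwb = ppt - pet` is added as a derived column and holds
#' exactly on every row by construction.
#'
#' @param config a [sim_config()] (its `years` and `climate` fields are
#'   used).
#' @param seed integer seed for this operation (defaults to a sub-stream of
#'   the config master seed).
#' @return data frame with columns `year, month, ppt, pet, cwd, aet, runoff,
#'   tmean, cwb`.
#' @export
simulate_climate <- function(config, seed = derive_seed(config$seed, 1L)) {
  years <- config$years
  if (length(years) < 2) stop("need at least 2 years", call. = FALSE)
  pars <- config$climate
  n <- length(years) * 12L
  df <- data.frame(year = rep(years, each = 12L),
                   month = rep(1:12, length(years)))
  set.seed(seed)
  cyc <- cos(2 * pi * (df$month - 7) / 12)
  elapsed <- df$year - years[1]
  gen <- function(p) {
    p$mean + p$amp * cyc + p$trend * elapsed + rnorm(n, 0, p$sd)
  }
  for (v in c("ppt", "pet", "cwd", "aet", "runoff", "tmean")) {
    x <- gen(pars[[v]])
    if (v != "tmean") x <- pmax(x, 0)  # fluxes cannot be negative
    df[[v]] <- x
  }
  df$cwb <- df$ppt - df$pet
  df
}

# 8-neighbour adjacency: TRUE where any 8-neighbour satisfies `mask`
neighbors8_any <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  padded <- matrix(FALSE, nr + 2, nc + 2)
  padded[2:(nr + 1), 2:(nc + 1)] <- mask
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    out <- out | padded[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
  }
  out
}

# Contiguous initial landscape: central elliptical bog sized by share,
# grassland blobs grown from seed points, forest matrix elsewhere.
initial_truth_map <- function(config, seed) {
  nr <- config$grid_rows; nc <- config$grid_cols
  shares <- config$initial_shares
  npix <- nr * nc
  rr <- row(matrix(0, nr, nc)); cc <- col(matrix(0, nr, nc))
  d_center <- ((rr - (nr + 1) / 2) / nr)^2 + ((cc - (nc + 1) / 2) / nc)^2
  map <- matrix(1L, nr, nc)  # forest matrix
  n_bog <- round(shares[["bog"]] * npix)
  if (n_bog > 0) {
    thr <- sort(as.vector(d_center))[n_bog]
    map[d_center <= thr] <- 2L
  }
  # grassland blobs seeded away from the bog, grown by distance rank
  n_grass <- round(shares[["grassland"]] * npix)
  if (n_grass > 0) {
    set.seed(seed)
    forest_idx <- which(map == 1L)
    k <- max(1L, min(4L, length(forest_idx)))
    seeds <- sample(forest_idx, k)
    sr <- (seeds - 1) %% nr + 1; sc <- (seeds - 1) %/% nr + 1
    d_grass <- matrix(Inf, nr, nc)
    for (i in seq_len(k)) {
      d_grass <- pmin(d_grass, (rr - sr[i])^2 + (cc - sc[i])^2)
    }
    d_grass[map != 1L] <- Inf
    ord <- order(as.vector(d_grass))[seq_len(min(n_grass, sum(map == 1L)))]
    map[ord] <- 3L
  }
  map
}

#' Simulate the annual landscape and its scene stacks
#'
#' Year 1 is a contiguous central bog in a forest matrix with grassland
#' patches. Each subsequent year, every bog pixel 8-adjacent to forest
#' converts to forest with probability
#' `p = clamp(base_rate * (1 + deficit_sensitivity * z), 0, 1)` where `z` is
#' the standardized *negative* annual climatic water balance (drier year =
#' larger z = faster encroachment). Per-pixel reflectance is the class mean
#' plus iid Gaussian noise; the thermal band is the class mean plus a scaled
#' summer temperature anomaly plus noise. Each year carries
#' `scenes_per_year` acquisitions (first in June, the rest spread to
#' August), each independently cloud-contaminated via [inject_clouds()].
#'
#' @param config a [sim_config()].
#' @param climate monthly climate from [simulate_climate()] covering
#'   `config$years`.
#' @param seed integer seed for this operation.
#' @return list with one record per year: `year`, `scenes` (list of
#'   [scene_stack()]), `truth` (integer matrix 1/2/3),
#'   `n_converted_pixels`, and attribute-level `grid`.
#' @export
simulate_landscape <- function(config, climate,
                               seed = derive_seed(config$seed, 2L)) {
  years <- config$years
  if (!all(years %in% unique(climate$year))) {
    stop("climate does not cover all requested years", call. = FALSE)
  }
  grid <- pw_grid(config$grid_rows, config$grid_cols,
                  pixel_size_m = config$pixel_size_m)
  nr <- grid$nrow; nc <- grid$ncol; npix <- nr * nc

  ann <- aggregate_climate(climate, window = "annual")
  ann <- ann[match(years, ann$year), ]
  cwb_sd <- sd(ann$cwb)
  z_deficit <- if (is.na(cwb_sd) || cwb_sd == 0) {
    rep(0, length(years))
  } else {
    -(ann$cwb - mean(ann$cwb)) / cwb_sd
  }
  jja <- aggregate_climate(climate, window = "jja")
  jja <- jja[match(years, jja$year), ]
  t_anom <- jja$tmean - mean(jja$tmean)

  truth <- initial_truth_map(config, derive_seed(seed, 0L))
  doys <- round(seq(160, 160 + 35 * (config$scenes_per_year > 1) +
                      (if (config$scenes_per_year > 2) 45 else 0),
                    length.out = config$scenes_per_year))
  # cap DOYs to the JJA window
  doys <- clamp(doys, 152, 243)

  make_scene <- function(truth_map, year, doy, t_anomaly, op_seed) {
    set.seed(op_seed)
    cls <- as.vector(truth_map)
    bands <- stats::setNames(vector("list", 6), BAND_NAMES)
    for (b in 1:6) {
      mu <- config$class_spectra[cls, b]
      bands[[BAND_NAMES[b]]] <-
        matrix(clamp(mu + rnorm(npix, 0, config$spectral_noise_sd), 0, 1),
               nr, nc)
    }
    th <- config$thermal_means[cls] +
      config$thermal_anomaly_gain * t_anomaly +
      rnorm(npix, 0, config$thermal_noise_sd)
    scene_stack(year = year, doy = doy, sensor_id = "SYNTHETIC",
                bands = bands, thermal = matrix(th, nr, nc),
                qa = matrix(0L, nr, nc), grid = grid)
  }

  out <- vector("list", length(years))
  for (i in seq_along(years)) {
    n_conv <- 0L
    if (i > 1) {
      p <- clamp(config$encroachment_base_rate *
                   (1 + config$deficit_sensitivity * z_deficit[i]), 0, 1)
      set.seed(derive_seed(seed, 100L + i))
      eligible <- truth == 2L & neighbors8_any(truth == 1L)
      idx <- which(eligible)
      if (length(idx) > 0 && p > 0) {
        conv <- idx[runif(length(idx)) < p]
        truth[conv] <- 1L
        n_conv <- length(conv)
      }
      if (config$grass_encroachment_rate > 0) {
        gel <- which(truth == 3L & neighbors8_any(truth == 1L))
        if (length(gel) > 0) {
          gconv <- gel[runif(length(gel)) < config$grass_encroachment_rate]
          truth[gconv] <- 1L
        }
      }
    }
    scenes <- vector("list", length(doys))
    for (j in seq_along(doys)) {
      sc <- make_scene(truth, years[i], doys[j], t_anom[i],
                       derive_seed(seed, 1000L + 10L * i + j))
      if (config$cloud_fraction > 0) {
        set.seed(derive_seed(seed, 5000L + 10L * i + j))
        frac <- clamp(config$cloud_fraction * runif(1, 0.4, 1.6), 0, 1)
        sc <- inject_clouds(sc, frac,
                            seed = derive_seed(seed, 9000L + 10L * i + j))
      }
      scenes[[j]] <- sc
    }
    out[[i]] <- list(year = years[i], scenes = scenes, truth = truth,
                     n_converted_pixels = n_conv)
  }
  attr(out, "grid") <- grid
  attr(out, "z_deficit") <- z_deficit
  out
}

#' Contaminate a scene with circular clouds
#'
#' Random circular cloud masks are accumulated until the requested fraction
#' of pixels is flagged; the count is then trimmed to exactly
#' `round(fraction * n_pixels)` flagged pixels. Flagged pixels get the cloud
#' bit set in QA, bright constant reflectance (0.55) and a cold thermal
#' value (285 K).
#'
#' @param scene a [scene_stack()].
#' @param cloud_fraction target flagged fraction in `[0, 1]`.
#' @param seed integer seed.
#' @param spec a [qa_bit_spec()] giving the cloud bit.
#' @return the contaminated scene.
#' @export
inject_clouds <- function(scene, cloud_fraction, seed,
                          spec = qa_bit_spec()) {
  stopifnot(cloud_fraction >= 0, cloud_fraction <= 1)
  nr <- scene$grid$nrow; nc <- scene$grid$ncol
  npix <- nr * nc
  target <- round(cloud_fraction * npix)
  if (target == 0) return(scene)
  set.seed(seed)
  flagged <- matrix(FALSE, nr, nc)
  rr <- row(flagged); cc <- col(flagged)
  guard <- 0L
  while (sum(flagged) < target && guard < 10000L) {
    guard <- guard + 1L
    cy <- runif(1, 1, nr); cx <- runif(1, 1, nc)
    rad <- runif(1, 2, max(4, min(nr, nc) / 6))
    flagged <- flagged | ((rr - cy)^2 + (cc - cx)^2 <= rad^2)
  }
  excess <- sum(flagged) - target
  if (excess > 0) {
    on_idx <- which(flagged)
    flagged[sample(on_idx, excess)] <- FALSE
  }
  cloud_word <- bitwShiftL(1L, spec$cloud)
  scene$qa[flagged] <- bitwOr(scene$qa[flagged], cloud_word)
  for (nm in BAND_NAMES) scene$bands[[nm]][flagged] <- 0.55
  scene$thermal[flagged] <- 285
  scene
}
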