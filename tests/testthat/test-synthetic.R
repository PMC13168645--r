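test_that("degenerate climate: zero noise and trend gives zero anomalies", {
  cfg <- sim_config(years = 1984:1995, climate = quiet_climate(), seed = 3)
  cl <- simulate_climate(cfg)
  jja <- aggregate_climate(cl, "jja")
  an <- anomalies(jja$year, jja$tmean)
  expect_true(all(abs(an$anomaly) < 1e-9))
  expect_equal(cl$cwb, cl$ppt - cl$pet)
})

test_that("imposed linear trends are recovered exactly without noise", {
  cfg <- sim_config(
    years = 1984:2003,
    climate = quiet_climate(trends = list(tmean = 0.05, ppt = -2, pet = 1)),
    seed = 3)
  cl <- simulate_climate(cfg)
  ann_t <- tapply(cl$tmean, cl$year, mean)
  fit <- ols_trend(as.numeric(names(ann_t)), as.numeric(ann_t))
  expect_equal(fit$slope, 0.05, tolerance = 1e-12)
  ann_cwb <- tapply(cl$cwb, cl$year, mean)
  fit2 <- ols_trend(as.numeric(names(ann_cwb)), as.numeric(ann_cwb))
  expect_equal(fit2$slope, -3, tolerance = 1e-9)
})

test_that("climate rejects degenerate year requests", {
  expect_error(sim_config(years = 2000), "years")
  expect_error(sim_config(years = c(2000, 1999)), "years")
  expect_error(sim_config(initial_shares = c(forest = 0.5, bog = 0.5,
                                             grassland = 0.2)), "sum to 1")
})

test_that("landscape: no encroachment means frozen truth maps", {
  cfg <- sim_config(grid_rows = 30, grid_cols = 30, years = 1984:1989,
                    encroachment_base_rate = 0, cloud_fraction = 0,
                    scenes_per_year = 1, seed = 5)
  cl <- simulate_climate(cfg)
  world <- simulate_landscape(cfg, cl)
  truths <- lapply(world, `[[`, "truth")
  for (i in 2:length(truths)) expect_identical(truths[[i]], truths[[1]])
  tm <- transition_matrix(truths)
  expect_equal(as.matrix(tm), diag(3), ignore_attr = TRUE)
  # class shares always sum to 1
  for (tr in truths) {
    expect_equal(sum(class_areas(tr)$percent), 100, tolerance = 1e-9)
  }
})

test_that("zero spectral noise collapses classes to exact spectra", {
  cfg <- sim_config(grid_rows = 20, grid_cols = 20, years = 1984:1985,
                    spectral_noise_sd = 0, thermal_noise_sd = 0,
                    cloud_fraction = 0, scenes_per_year = 1,
                    climate = quiet_climate(), seed = 5)
  cl <- simulate_climate(cfg)
  world <- simulate_landscape(cfg, cl)
  sc <- world[[1]]$scenes[[1]]
  truth <- world[[1]]$truth
  for (cls in 1:3) {
    for (b in seq_along(band_names)) {
      vals <- sc$bands[[band_names[b]]][truth == cls]
      expect_true(all(vals == cfg$class_spectra[cls, b]))
    }
  }
})

test_that("edge conversion frequency matches the base rate (binomial)", {
  # constant p = 0.05, deficit_sensitivity 0: pooled over 500 one-step
  # replicates, the mean converted fraction of eligible edge pixels
  # approaches 0.05
  p_hat <- numeric(500)
  n_elig <- numeric(500)
  for (r in 1:500) {
    cfg <- sim_config(grid_rows = 25, grid_cols = 25, years = 1984:1985,
                      encroachment_base_rate = 0.05,
                      deficit_sensitivity = 0, cloud_fraction = 0,
                      scenes_per_year = 1, climate = quiet_climate(),
                      seed = 1000 + r)
    cl <- simulate_climate(cfg)
    world <- simulate_landscape(cfg, cl)
    t1 <- world[[1]]$truth
    elig <- sum(t1 == 2 & neighbors8_oracle(t1 == 1))
    n_elig[r] <- elig
    p_hat[r] <- world[[2]]$n_converted_pixels / elig
  }
  pooled <- sum(p_hat * n_elig) / sum(n_elig)
  se <- sqrt(0.05 * 0.95 / sum(n_elig))
  expect_lt(abs(pooled - 0.05), 4 * se)
})

test_that("conversions only go bog -> forest under the default process", {
  cfg <- sim_config(grid_rows = 30, grid_cols = 30, years = 1984:1994,
                    encroachment_base_rate = 0.2, cloud_fraction = 0,
                    scenes_per_year = 1, seed = 11)
  cl <- simulate_climate(cfg)
  world <- simulate_landscape(cfg, cl)
  for (i in 2:length(world)) {
    prev <- world[[i - 1]]$truth; cur <- world[[i]]$truth
    changed <- prev != cur
    expect_true(all(prev[changed] == 2L))
    expect_true(all(cur[changed] == 1L))
  }
})

test_that("same master seed gives bit-identical synthetic output", {
  cfg <- sim_config(grid_rows = 20, grid_cols = 20, years = 1984:1987,
                    seed = 99)
  a <- simulate_landscape(cfg, simulate_climate(cfg))
  b <- simulate_landscape(cfg, simulate_climate(cfg))
  expect_identical(a[[4]]$truth, b[[4]]$truth)
  expect_identical(a[[3]]$scenes[[2]]$bands, b[[3]]$scenes[[2]]$bands)
  expect_identical(a[[3]]$scenes[[2]]$qa, b[[3]]$scenes[[2]]$qa)
})

test_that("cloud injection hits the requested fraction exactly", {
  grid <- pw_grid(100, 100)
  set.seed(2)
  sc <- make_scene(grid)
  expect_identical(inject_clouds(sc, 0, seed = 1)$qa, sc$qa)
  full <- inject_clouds(sc, 1, seed = 1)
  expect_true(all(bitwAnd(full$qa, bitwShiftL(1L, 3L)) != 0))
  counts <- vapply(1:50, function(s) {
    out <- inject_clouds(sc, 0.3, seed = s)
    sum(decode_qa(out$qa) == FALSE)
  }, numeric(1))
  expect_true(all(counts == 3000))
})
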