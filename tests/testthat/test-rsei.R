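test_that("min-max normalization: endpoints, values, affine invariance", {
  x <- matrix(c(2, 4, 6), 1, 3)
  expect_equal(normalize01(x), matrix(c(0, 0.5, 1), 1, 3))
  expect_equal(normalize01(10 * x - 3), normalize01(x), tolerance = 1e-12)
  expect_error(normalize01(matrix(5, 2, 2), name = "WET"), "WET")
  # NA pattern preserved
  y <- matrix(c(1, NA, 3, 5), 2, 2)
  ny <- normalize01(y)
  expect_true(is.na(ny[2, 1]))
  expect_equal(range(ny, na.rm = TRUE), c(0, 1))
})

test_that("PC1: closed-form two-variable case and degenerate correlation", {
  set.seed(50)
  x <- matrix(runif(400), 20, 20)
  layers <- list(NDVI = x, WET = x, NDBSI = matrix(0.5, 20, 20),
                 LST = matrix(0.5, 20, 20))
  # two perfectly correlated variables, two constants: share = 1 and the
  # leading eigenvector is (1,1)/sqrt(2) on the correlated pair
  p <- pca_pc1(layers)
  expect_equal(p$variance_share, 1, tolerance = 1e-12)
  expect_equal(abs(unname(p$loadings[1:2])), rep(1 / sqrt(2), 2),
               tolerance = 1e-9)
  expect_equal(unname(p$loadings[3:4]), c(0, 0), tolerance = 1e-9)
  expect_true(p$rank_deficient)
})

test_that("PC1 matches a power-iteration oracle on random layers", {
  set.seed(51)
  for (rep in 1:5) {
    layers <- list(NDVI = matrix(runif(900), 30, 30),
                   WET = matrix(runif(900), 30, 30),
                   NDBSI = matrix(runif(900), 30, 30),
                   LST = matrix(runif(900), 30, 30))
    # correlate them a bit so PC1 is distinct
    layers$WET <- 0.6 * layers$NDVI + 0.4 * layers$WET
    p <- pca_pc1(layers)
    V <- vapply(layers, function(l) as.vector(l), numeric(900))
    C <- cov(sweep(V, 2, colMeans(V)))
    v_or <- power_iteration(C)
    expect_equal(abs(sum(v_or * p$loadings)), 1, tolerance = 1e-9)
    expect_equal(p$variance_share,
                 as.numeric(t(v_or) %*% C %*% v_or) / sum(diag(C)),
                 tolerance = 1e-9)
    expect_equal(sum(p$loadings^2), 1, tolerance = 1e-12)
    # leading eigenvalue is at least the average -> share >= 1/4
    expect_gte(p$variance_share, 0.25)
  }
})

test_that("RSEI orientation and rescale: rank-1 construction", {
  set.seed(52)
  x <- normalize01(matrix(runif(400), 20, 20))
  layers <- list(NDVI = x, WET = x, NDBSI = 1 - x, LST = 1 - x)
  p <- pca_pc1(layers)
  r <- compute_rsei(p)
  expect_equal(r$rsei, normalize01(x), tolerance = 1e-9)
  expect_equal(range(r$rsei), c(0, 1))
  expect_gt(cor(as.vector(r$rsei), as.vector(x)), 0.999)
  # idempotence: recomputing the min-max rescale changes nothing
  expect_equal(normalize01(r$rsei), r$rsei, tolerance = 1e-12)
  # flipping every component flips the eigenvector sign but not the index
  p2 <- pca_pc1(list(NDVI = x, WET = x, NDBSI = 1 - x, LST = 1 - x))
  p2$loadings <- -p2$loadings
  p2$scores <- -p2$scores
  r2 <- compute_rsei(p2)
  expect_equal(r2$rsei, r$rsei, tolerance = 1e-9)
  expect_true(xor(r$orientation_flipped, r2$orientation_flipped))
})

test_that("five-level categorisation uses left-closed 0.2 bins", {
  x <- matrix(c(0, 0.1, 0.2, 0.39, 0.4, 0.6, 0.79, 0.8, 1.0, NA, -0.1, 1.1),
              3, 4)
  cat <- classify_rsei(x)
  expect_equal(as.vector(cat)[1:9], c(1L, 1L, 2L, 2L, 3L, 4L, 4L, 5L, 5L))
  expect_true(all(is.na(as.vector(cat)[10:12])))
  # categories partition the valid area exactly
  set.seed(53)
  r <- matrix(runif(1000), 20, 50)
  cats <- classify_rsei(r)
  expect_equal(sum(!is.na(cats)), 1000)
  expect_equal(sort(unique(as.vector(cats))), 1:5)
})

test_that("stratified means are exact and recombine to the global mean", {
  rsei <- matrix(0.7, 4, 4)
  lc <- matrix(rep(1:3, length.out = 16), 4, 4)
  sm <- stratified_mean(rsei, lc)
  expect_equal(sm$mean_rsei, rep(0.7, 3))
  # two-class toy with known values
  rsei2 <- matrix(c(0.2, 0.4, 0.6, 0.8), 2, 2)
  lc2 <- matrix(c(1L, 1L, 2L, 2L), 2, 2)
  sm2 <- stratified_mean(rsei2, lc2)
  expect_equal(sm2$mean_rsei[1:2], c(0.3, 0.7))
  expect_equal(sm2$n_pixels[1:2], c(2L, 2L))
  expect_true(is.na(sm2$mean_rsei[3]) && sm2$n_pixels[3] == 0)
  # weighted recombination equals the global mean
  set.seed(54)
  rsei3 <- matrix(runif(100), 10, 10)
  lc3 <- matrix(sample(1:3, 100, TRUE), 10, 10)
  sm3 <- stratified_mean(rsei3, lc3)
  expect_equal(sum(sm3$mean_rsei * sm3$n_pixels) / sum(sm3$n_pixels),
               mean(rsei3), tolerance = 1e-12)
})

test_that("full per-year synthesis honours the orientation contract", {
  cfg <- sim_config(grid_rows = 40, grid_cols = 40, years = 1984:1986,
                    cloud_fraction = 0.1, seed = 55)
  world <- simulate_landscape(cfg, simulate_climate(cfg))
  comp <- composite_year(world[[1]]$scenes, 1984)
  rr <- rsei_for_year(comp)
  expect_true(all(rr$rsei >= 0 & rr$rsei <= 1, na.rm = TRUE))
  signs <- c(NDVI = 1, WET = 1, NDBSI = -1, LST = -1)
  for (nm in names(signs)) {
    v <- rr$normalized_components[[nm]]
    ok <- !is.na(v) & !is.na(rr$rsei)
    expect_gte(signs[[nm]] * cor(rr$rsei[ok], v[ok]), 0)
  }
  expect_equal(sum(rr$pc1_loadings^2), 1, tolerance = 1e-9)
})
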