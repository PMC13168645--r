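# Gaussian toy predictors: three classes, 10 dims, configurable separation
make_gauss_training <- function(n_per_class, sep = 4, sd = 1, seed = 1) {
  set.seed(seed)
  mus <- rbind(rep(0, 10), c(rep(sep, 5), rep(0, 5)), rep(sep, 10))
  rows <- lapply(1:3, function(cls) {
    x <- matrix(rnorm(n_per_class * 10, sd = sd), n_per_class, 10)
    x <- sweep(x, 2, mus[cls, ], `+`)
    colnames(x) <- peatwatch:::PREDICTOR_NAMES
    data.frame(class = cls, x, check.names = FALSE)
  })
  do.call(rbind, rows)
}

test_that("maximum likelihood classification matches a density oracle", {
  set.seed(21)
  train <- make_gauss_training(150, sep = 3)
  stats <- class_stats_from_samples(
    as.matrix(train[, peatwatch:::PREDICTOR_NAMES]), train$class,
    n_per_class = 150, seed = 1)
  x <- matrix(rnorm(1000 * 10, mean = 1.5), 1000, 10,
              dimnames = list(NULL, peatwatch:::PREDICTOR_NAMES))
  got <- maximum_likelihood_classify(x, stats)
  oracle <- apply(x, 1, function(px) {
    ll <- vapply(stats, function(st) {
      S <- st$cov
      -0.5 * (mahalanobis(px, st$mean, S) +
                as.numeric(determinant(S)$modulus))
    }, numeric(1))
    as.integer(names(stats))[which.max(ll)]
  })
  expect_equal(got, unname(oracle))
  # pixel exactly at a class mean with shared spherical covariance
  sph <- lapply(stats, function(st) list(mean = st$mean, cov = diag(10)))
  at_mean <- matrix(sph[["2"]]$mean, 1, 10,
                    dimnames = list(NULL, peatwatch:::PREDICTOR_NAMES))
  expect_equal(maximum_likelihood_classify(at_mean, sph), 2L)
  # exact likelihood tie goes to the lowest class code
  tie_stats <- list("1" = list(mean = rep(0, 10), cov = diag(10)),
                    "2" = list(mean = rep(2, 10), cov = diag(10)))
  mid <- matrix(1, 1, 10, dimnames = list(NULL, peatwatch:::PREDICTOR_NAMES))
  expect_equal(maximum_likelihood_classify(mid, tie_stats), 1L)
})

test_that("stable pixel masks are exact class intersections", {
  set.seed(22)
  maps <- lapply(1:4, function(i) matrix(sample(1:3, 64, TRUE), 8, 8))
  masks <- stable_pixel_mask(maps)
  for (cls in 1:3) {
    brute <- Reduce(`&`, lapply(maps, function(m) m == cls))
    expect_identical(masks[[as.character(cls)]], brute)
  }
  # identical maps: stable mask equals the class mask
  same <- stable_pixel_mask(list(maps[[1]], maps[[1]]))
  expect_identical(same[["1"]], maps[[1]] == 1)
  expect_error(stable_pixel_mask(list(maps[[1]], matrix(1L, 4, 4))),
               "grid")
})

test_that("balanced sampling pools reference years and reproduces", {
  cfg <- sim_config(grid_rows = 20, grid_cols = 20, years = 1984:1986,
                    encroachment_base_rate = 0, cloud_fraction = 0,
                    scenes_per_year = 1, seed = 8)
  world <- simulate_landscape(cfg, simulate_climate(cfg))
  comps <- lapply(world, function(w) medoid_composite(w$scenes))
  truth <- world[[1]]$truth
  masks <- list("1" = truth == 1, "2" = truth == 2, "3" = truth == 3)
  ts1 <- sample_balanced_training(masks, 10, 1984:1986, comps, seed = 5)
  expect_equal(nrow(ts1), 10 * 3 * 3)
  expect_equal(unname(table(ts1$class)), rep(30L, 3),
               ignore_attr = TRUE)
  ts2 <- sample_balanced_training(masks, 10, 1984:1986, comps, seed = 5)
  expect_identical(ts1, ts2)
  expect_error(sample_balanced_training(masks, 1e5, 1984:1986, comps),
               "stable pixels")
})

test_that("train/validation split is a disjoint exhaustive partition", {
  ts <- make_gauss_training(100)
  expect_error(split_train_validation(ts, 1.0), "fraction")
  sp <- split_train_validation(ts, 0.75, seed = 3)
  expect_equal(nrow(sp$train) + nrow(sp$validation), nrow(ts))
  expect_length(intersect(rownames(sp$train), rownames(sp$validation)), 0)
  # distribution over seeds: ~75% with binomial spread
  fr <- vapply(1:50, function(s) {
    nrow(split_train_validation(ts, 0.75, seed = s)$train) / nrow(ts)
  }, numeric(1))
  expect_lt(abs(mean(fr) - 0.75), 0.03)
})

test_that("random forest separates separable classes and is deterministic", {
  train <- make_gauss_training(150, sep = 6, seed = 31)
  sp <- split_train_validation(train, 0.75, seed = 1)
  rf <- train_random_forest(sp$train, n_trees = 60, seed = 7)
  pred <- predict(rf, sp$validation)
  oa <- mean(pred == sp$validation$class)
  expect_gt(oa, 0.99)
  rf2 <- train_random_forest(sp$train, n_trees = 60, seed = 7)
  expect_identical(predict(rf2, sp$validation), pred)
  expect_error(train_random_forest(sp$train[sp$train$class == 1, ]),
               "single class")
})

test_that("a constant predictor cannot influence the forest", {
  train <- make_gauss_training(100, sep = 5, seed = 32)
  train$MNDWI <- 0.5  # constant, uninformative
  rf <- train_random_forest(train, n_trees = 40, seed = 2)
  test_x <- make_gauss_training(50, sep = 5, seed = 33)
  p1 <- predict(rf, test_x)
  test_x$MNDWI <- sample(test_x$MNDWI)
  test_x$MNDWI <- rnorm(nrow(test_x))
  expect_identical(predict(rf, test_x), p1)
})

test_that("accuracy metrics: hand-computed kappa, F1 identity, bounds", {
  rep <- accuracy_from_confusion(matrix(c(2, 0, 1, 3), 2, 2))
  expect_equal(rep$overall_accuracy, 5 / 6, tolerance = 1e-12)
  expect_equal(rep$kappa, 2 / 3, tolerance = 1e-3)
  perfect <- accuracy_from_confusion(diag(c(10, 20, 30)))
  expect_equal(perfect$overall_accuracy, 1)
  expect_equal(perfect$kappa, 1)
  expect_true(all(perfect$per_class$f1 == 1))
  set.seed(40)
  for (i in 1:20) {
    cm <- matrix(sample(0:30, 9, TRUE), 3, 3)
    if (any(rowSums(cm) == 0) || any(colSums(cm) == 0)) next
    r <- accuracy_from_confusion(cm)
    expect_lte(r$kappa, r$overall_accuracy + 1e-12)
    with(r$per_class, expect_equal(f1, 2 * ua * pa / (ua + pa),
                                   tolerance = 1e-12))
    expect_true(all(r$per_class$ua >= 0 & r$per_class$ua <= 1, na.rm = TRUE))
  }
})

test_that("stratified assessment draws the requested subset", {
  train <- make_gauss_training(400, sep = 6, seed = 35)
  sp <- split_train_validation(train, 0.75, seed = 1)
  rf <- train_random_forest(sp$train, n_trees = 40, seed = 2)
  rep <- assess_accuracy(rf, sp$validation, n_stratified_per_class = 50)
  expect_equal(unname(rep$n_used), rep(50L, 3), ignore_attr = TRUE)
  expect_equal(sum(rep$confusion), 150)
  expect_error(assess_accuracy(rf, sp$validation[0, ]), "empty class")
})

test_that("temporal majority filter: mode, truncation and tie rules", {
  m <- function(v) matrix(as.integer(v), 1, 1)
  # series F,B,F,F,B with window 5: centre year -> F (3/5)
  maps <- lapply(c(1, 2, 1, 1, 2), m)
  filt <- temporal_majority_filter(maps, 5)
  expect_equal(filt[[3]][1, 1], 1L)
  # constant series unchanged
  const <- lapply(rep(2, 6), m)
  expect_identical(temporal_majority_filter(const, 5), const)
  # truncated edge window: year 1 of B,F,F,... under window 3 sees only
  # years 1:2 = {B, F}, a two-way tie -> centre label B retained
  maps2 <- lapply(c(2, 1, 1, 2, 2), m)
  filt2 <- temporal_majority_filter(maps2, 3)
  expect_equal(filt2[[1]][1, 1], 2L)
  # year 2 window = B,F,F -> mode F
  expect_equal(filt2[[2]][1, 1], 1L)
  # two-way tie retains the centre label: window years 4:5 = B,B for year 5
  maps3 <- lapply(c(1, 1, 2, 2, 1), m)
  filt3 <- temporal_majority_filter(maps3, 3)
  # year 4 window = 2,2,1 -> B; year 5 window = 2,1 tie -> centre label F
  expect_equal(filt3[[4]][1, 1], 2L)
  expect_equal(filt3[[5]][1, 1], 1L)
  # nodata at the centre stays nodata and casts no votes elsewhere
  maps4 <- lapply(c(1, 0, 1), m)
  filt4 <- temporal_majority_filter(maps4, 3)
  expect_equal(filt4[[2]][1, 1], 0L)
  expect_equal(filt4[[1]][1, 1], 1L)
})

test_that("majority filter conserves the classified/nodata partition", {
  set.seed(44)
  maps <- lapply(1:7, function(i) {
    m <- matrix(sample(1:3, 100, TRUE), 10, 10)
    m[sample(100, 10)] <- 0L
    m
  })
  filt <- temporal_majority_filter(maps, 5)
  for (i in seq_along(maps)) {
    expect_identical(filt[[i]] == 0L, maps[[i]] == 0L)
  }
})

test_that("class areas: printed-style arithmetic and exact counting", {
  # single-class map
  solo <- matrix(1L, 5, 5)
  a <- class_areas(solo, 0.09)
  expect_equal(a$percent[1], 100)
  expect_equal(a$area_ha[1], 25 * 0.09)
  # known counts
  m <- matrix(c(rep(1L, 10), rep(2L, 6), rep(3L, 4)), 4, 5)
  a2 <- class_areas(m, 0.09)
  expect_equal(a2$n_pixels, c(10L, 6L, 4L))
  expect_equal(a2$area_ha, c(0.9, 0.54, 0.36))
  expect_equal(sum(a2$percent), 100)
})

test_that("transition matrix: identity, toy counts, row sums", {
  m1 <- matrix(c(2L, 2L, 1L, 3L), 2, 2)
  expect_equal(as.matrix(transition_matrix(list(m1, m1))), diag(3),
               ignore_attr = TRUE)
  # 4-pixel toy: (B,B,F,G) -> (F,B,F,F)
  a <- matrix(c(2L, 2L, 1L, 3L), 1, 4)
  b <- matrix(c(1L, 2L, 1L, 1L), 1, 4)
  tm <- transition_matrix(list(a, b))
  expect_equal(unname(tm["bog", ]), c(0.5, 0.5, 0))
  expect_equal(unname(tm["grassland", ]), c(1, 0, 0))
  expect_equal(unname(rowSums(tm)), rep(1, 3), tolerance = 1e-9)
  # pooled_annual mode pools consecutive pairs
  tm2 <- transition_matrix(list(a, b, b), mode = "pooled_annual")
  expect_equal(unname(tm2["forest", "forest"]), 1)
  expect_equal(unname(rowSums(tm2)), rep(1, 3), tolerance = 1e-9)
  # empty start class is flagged
  onlyf <- matrix(1L, 2, 2)
  tm3 <- transition_matrix(list(onlyf, onlyf))
  expect_true(all(c("bog", "grassland") %in% attr(tm3, "empty_rows")))
  expect_true(all(is.na(tm3["bog", ])))
})

test_that("F1 from printed error rates follows the identity", {
  expect_equal(f1_from_errors(0, 0), 1)
  expect_equal(f1_from_errors(0.5, 0.5), 0.5)
  ua <- 0.9; pa <- 0.8
  expect_equal(f1_from_errors(1 - ua, 1 - pa), 2 * ua * pa / (ua + pa),
               tolerance = 1e-12)
})
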