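#' Predictor stack for classification
#'
#' The 10 classification predictors: the six reflectance bands plus NDVI,
#' NDMI, NBR and MNDWI, as a pixels x 10 matrix (row-major over the grid,
#' column order fixed).
#'
#' @param composite a `pw_composite`.
#' @return numeric matrix `n_pixels x 10` with `NA` rows at nodata.
#' @export
composite_predictors <- function(composite) {
  npix <- composite$grid$nrow * composite$grid$ncol
  x <- matrix(NA_real_, npix, length(PREDICTOR_NAMES),
              dimnames = list(NULL, PREDICTOR_NAMES))
  for (nm in BAND_NAMES) x[, nm] <- as.vector(composite$bands[[nm]])
  for (nm in c("NDVI", "NDMI", "NBR", "MNDWI")) {
    x[, nm] <- as.vector(spectral_index(composite, nm))
  }
  x
}

#' Per-class Gaussian statistics from labelled samples
#'
#' Mean vector and full covariance of the predictors per class, estimated
#' from sampled labelled pixels (the seed stage of two-stage training; in
#' tests the labels come from simulator truth maps).
#'
#' @param predictors `n x p` predictor matrix.
#' @param labels integer class labels (1..3) aligned with rows.
#' @param n_per_class samples drawn per class (without replacement).
#' @param seed integer seed.
#' @return list per class of `mean` and `cov`.
#' @export
class_stats_from_samples <- function(predictors, labels, n_per_class = 200,
                                     seed = 1L) {
  set.seed(seed)
  stats_out <- list()
  ok <- stats::complete.cases(predictors)
  for (cls in sort(unique(labels[ok & labels > 0]))) {
    idx <- which(ok & labels == cls)
    if (length(idx) > n_per_class) idx <- sample(idx, n_per_class)
    xs <- predictors[idx, , drop = FALSE]
    stats_out[[as.character(cls)]] <-
      list(mean = colMeans(xs), cov = stats::cov(xs))
  }
  stats_out
}

#' Maximum-likelihood classification
#'
#' Per-pixel argmax of the Gaussian log-likelihood under per-class mean and
#' full covariance. A singular covariance is ridge-regularised (with a
#' warning); ties go to the lowest class code.
#'
#' @param predictors `n x p` matrix (rows with `NA` become nodata 0).
#' @param class_stats list as from [class_stats_from_samples()], names are
#'   class codes.
#' @param ridge regularisation added to the diagonal when inversion fails.
#' @return integer vector of class codes (0 = nodata).
#' @export
maximum_likelihood_classify <- function(predictors, class_stats,
                                        ridge = 1e-8) {
  classes <- as.integer(names(class_stats))
  n <- nrow(predictors)
  ok <- stats::complete.cases(predictors)
  ll <- matrix(-Inf, n, length(classes))
  for (j in seq_along(classes)) {
    st <- class_stats[[j]]
    S <- st$cov
    chol_S <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(chol_S)) {
      warning("singular covariance for class ", classes[j],
              "; ridge-regularised")
      chol_S <- chol(S + diag(ridge * mean(diag(S)) + ridge, nrow(S)))
    }
    ctr <- sweep(predictors[ok, , drop = FALSE], 2, st$mean)
    z <- backsolve(chol_S, t(ctr), transpose = TRUE)
    maha <- colSums(z^2)
    logdet <- 2 * sum(log(diag(chol_S)))
    ll[ok, j] <- -0.5 * (maha + logdet)
  }
  # ties to the lowest class code: max.col(first) over code-ordered columns
  ordc <- order(classes)
  pick <- max.col(ll[, ordc, drop = FALSE], ties.method = "first")
  out <- classes[ordc][pick]
  out[!ok] <- 0L
  out
}

#' Stable pixels across reference years
#'
#' A pixel is stable for class `c` iff it is classified `c` in every
#' reference-year map.
#'
#' @param maps list of integer class matrices on one grid.
#' @return named list of logical matrices, one per class code present.
#' @export
stable_pixel_mask <- function(maps) {
  stopifnot(length(maps) >= 2)
  d <- dim(maps[[1]])
  for (m in maps) {
    if (!identical(dim(m), d)) stop("maps are not on one grid", call. = FALSE)
  }
  out <- list()
  for (cls in CLASS_CODES) {
    stable <- Reduce(`&`, lapply(maps, function(m) m == cls))
    out[[as.character(cls)]] <- stable
  }
  out
}

#' Balanced training sample from stable pixels
#'
#' Draws `n_per_class` stable pixel locations per class without replacement
#' and extracts the 10 predictors at every reference year, pooling rows, so
#' each class contributes `n_per_class * n_reference_years` rows.
#'
#' @param stable_masks list from [stable_pixel_mask()].
#' @param n_per_class locations per class.
#' @param reference_years vector of years matching `composites`.
#' @param composites list of `pw_composite` for the reference years.
#' @param seed integer seed.
#' @return data frame: `row`, `col`, `year`, `class`, then the 10
#'   predictors.
#' @export
sample_balanced_training <- function(stable_masks, n_per_class,
                                     reference_years, composites, seed = 1L) {
  stopifnot(length(reference_years) == length(composites))
  set.seed(seed)
  nr <- nrow(stable_masks[[1]])
  rows <- list()
  for (cls_name in names(stable_masks)) {
    idx <- which(stable_masks[[cls_name]])
    if (length(idx) < n_per_class) {
      stop("class ", cls_name, " has only ", length(idx),
           " stable pixels (need ", n_per_class, ")", call. = FALSE)
    }
    pts <- sort(sample(idx, n_per_class))
    for (k in seq_along(reference_years)) {
      x <- composite_predictors(composites[[k]])[pts, , drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        row = (pts - 1L) %% nr + 1L,
        col = (pts - 1L) %/% nr + 1L,
        year = reference_years[k],
        class = as.integer(cls_name), x)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Uniform random train/validation split
#'
#' Each row is assigned to the training set by an independent uniform draw
#' below `fraction`; the split is disjoint and exhaustive.
#'
#' @param training_set data frame of pooled samples.
#' @param fraction training fraction in `(0, 1)` (default 0.75).
#' @param seed integer seed.
#' @return list with `train` and `validation` data frames.
#' @export
split_train_validation <- function(training_set, fraction = 0.75, seed = 1L) {
  if (!(fraction > 0 && fraction < 1)) {
    stop("fraction must lie strictly inside (0, 1)", call. = FALSE)
  }
  set.seed(seed)
  u <- runif(nrow(training_set))
  list(train = training_set[u < fraction, , drop = FALSE],
       validation = training_set[u >= fraction, , drop = FALSE])
}

#' Train the Random Forest classifier
#'
#' Bagged CART ensemble with per-node feature subsampling (default
#' `floor(sqrt(p))`), Gini splits and no depth cap by default. Deterministic
#' given `seed`.
#'
#' @param train data frame with a `class` column and the predictor columns.
#' @param n_trees number of trees (default 200).
#' @param mtry features tried per node; default `floor(sqrt(p))`.
#' @param min_node minimum node size (default 1).
#' @param max_depth maximum tree depth (default 30, effectively uncapped).
#' @param seed integer seed.
#' @return object of class `pw_rf`.
#' @export
train_random_forest <- function(train, n_trees = 200, mtry = NULL,
                                min_node = 1, max_depth = 30, seed = 1L) {
  pred_cols <- intersect(PREDICTOR_NAMES, names(train))
  x <- as.matrix(train[, pred_cols, drop = FALSE])
  y <- as.integer(train$class)
  if (length(unique(y)) < 2) {
    stop("training data contain a single class", call. = FALSE)
  }
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  n_classes <- max(y)
  forest <- rf_train_cpp(x, y, n_classes, as.integer(n_trees),
                         as.integer(mtry), as.integer(min_node),
                         as.integer(max_depth), as.integer(seed))
  structure(list(forest = forest, n_classes = n_classes,
                 predictors = pred_cols, n_trees = n_trees, mtry = mtry,
                 seed = seed),
            class = "pw_rf")
}

#' @export
print.pw_rf <- function(x, ...) {
  cat(sprintf("<random forest: %d trees, mtry %d, %d classes>\n",
              x$n_trees, x$mtry, x$n_classes))
  invisible(x)
}

#' Predict classes with a trained forest
#'
#' Majority vote over trees; ties go to the lowest class code. Rows with
#' missing predictors return 0 (nodata).
#'
#' @param object a `pw_rf`.
#' @param newdata data frame or matrix holding the predictor columns.
#' @param ... unused.
#' @return integer class codes.
#' @export
predict.pw_rf <- function(object, newdata, ...) {
  x <- as.matrix(as.data.frame(newdata)[, object$predictors, drop = FALSE])
  ok <- stats::complete.cases(x)
  out <- integer(nrow(x))
  if (any(ok)) {
    votes <- rf_votes_cpp(object$forest, x[ok, , drop = FALSE],
                          object$n_classes)
    out[ok] <- max.col(votes, ties.method = "first")
  }
  out
}

#' Accuracy metrics from a confusion matrix
#'
#' Rows are reference, columns predicted. Returns overall accuracy, Cohen's
#' kappa, and per-class user's/producer's accuracy, Type I = 1 - UA, Type
#' II = 1 - PA, and F1 = 2 UA PA / (UA + PA).
#'
#' @param cm square confusion matrix of counts.
#' @return list with `confusion`, `overall_accuracy`, `kappa`, `per_class`
#'   data frame.
#' @export
accuracy_from_confusion <- function(cm) {
  cm <- as.matrix(cm)
  n <- sum(cm)
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  kappa <- if (abs(1 - pe) < 1e-15) 1 else (po - pe) / (1 - pe)
  ua <- diag(cm) / colSums(cm)  # predicted correct / predicted
  pa <- diag(cm) / rowSums(cm)  # reference captured / reference
  f1 <- ifelse(ua + pa > 0, 2 * ua * pa / (ua + pa), NA_real_)
  list(confusion = cm, overall_accuracy = po, kappa = kappa,
       per_class = data.frame(class = seq_len(nrow(cm)), ua = ua, pa = pa,
                              type1 = 1 - ua, type2 = 1 - pa, f1 = f1))
}

#' F1 score from commission and omission errors
#'
#' `F1 = 2 (1 - type1)(1 - type2) / ((1 - type1) + (1 - type2))` - the
#' harmonic mean of user's and producer's accuracy expressed through the
#' error rates.
#'
#' @param type1 commission error (1 - UA).
#' @param type2 omission error (1 - PA).
#' @return F1 in `[0, 1]`.
#' @export
f1_from_errors <- function(type1, type2) {
  ua <- 1 - type1; pa <- 1 - type2
  2 * ua * pa / (ua + pa)
}

#' Assess classifier accuracy on a stratified validation subset
#'
#' Draws up to `n_stratified_per_class` validation rows per class (all rows,
#' with a message, when a class has fewer), predicts, and summarises the
#' confusion matrix.
#'
#' @param classifier a `pw_rf`.
#' @param validation validation data frame (with `class`).
#' @param n_stratified_per_class target per-class subset size (default 1500).
#' @param seed integer seed for the stratified draw.
#' @return an accuracy report as [accuracy_from_confusion()], plus
#'   `n_used` per class.
#' @export
assess_accuracy <- function(classifier, validation,
                            n_stratified_per_class = 1500, seed = 1L) {
  classes <- sort(unique(validation$class))
  if (length(classes) == 0 || any(table(validation$class) == 0)) {
    stop("validation set has an empty class", call. = FALSE)
  }
  set.seed(seed)
  keep <- integer(0)
  n_used <- stats::setNames(integer(length(classes)), classes)
  for (cls in classes) {
    idx <- which(validation$class == cls)
    if (length(idx) > n_stratified_per_class) {
      idx <- sample(idx, n_stratified_per_class)
    } else if (length(idx) < n_stratified_per_class) {
      message("class ", cls, ": only ", length(idx),
              " validation rows available; using all")
    }
    n_used[as.character(cls)] <- length(idx)
    keep <- c(keep, idx)
  }
  sub <- validation[keep, , drop = FALSE]
  pred <- predict(classifier, sub)
  k <- max(classes, pred)
  cm <- matrix(0L, k, k)
  for (i in seq_len(nrow(sub))) {
    cm[sub$class[i], pred[i]] <- cm[sub$class[i], pred[i]] + 1L
  }
  rep <- accuracy_from_confusion(cm)
  rep$n_used <- n_used
  rep
}

#' Temporal majority filter over annual maps
#'
#' Pixel-wise modal class over a centred moving window of years (default 5),
#' truncated at the series ends. On a tie the centre-year label is retained
#' when it participates in the tie, otherwise the lowest tied class code
#' wins. Nodata (0) at the centre year stays nodata; nodata neighbours cast
#' no vote.
#'
#' @param maps list of integer class matrices, one per year (time order).
#' @param window odd window length.
#' @return list of filtered maps.
#' @export
temporal_majority_filter <- function(maps, window = 5) {
  if (window %% 2 != 1) stop("window must be odd", call. = FALSE)
  ny <- length(maps)
  half <- (window - 1) / 2
  classes <- CLASS_CODES
  out <- vector("list", ny)
  for (t in seq_len(ny)) {
    win <- max(1, t - half):min(ny, t + half)
    counts <- lapply(classes, function(cls) {
      Reduce(`+`, lapply(win, function(j) (maps[[j]] == cls) + 0L))
    })
    maxc <- Reduce(pmax, counts)
    center <- maps[[t]]
    res <- matrix(0L, nrow(center), ncol(center))
    # lowest tied code first...
    for (ci in rev(seq_along(classes))) {
      res[counts[[ci]] == maxc] <- classes[ci]
    }
    # ...then centre label overrides when it ties the maximum
    for (ci in seq_along(classes)) {
      tie_center <- center == classes[ci] & counts[[ci]] == maxc
      res[tie_center] <- classes[ci]
    }
    res[center == 0L] <- 0L
    out[[t]] <- res
  }
  out
}

#' Class areas for one map
#'
#' @param map integer class matrix (0 = nodata).
#' @param pixel_area pixel area in hectares (e.g. [pixel_area_ha()]).
#' @return data frame with `class`, `n_pixels`, `area_ha`, `percent` (of the
#'   classified area).
#' @export
class_areas <- function(map, pixel_area = 0.09) {
  counts <- vapply(CLASS_CODES, function(cls) sum(map == cls), integer(1))
  total <- sum(counts)
  data.frame(class = as.integer(CLASS_CODES),
             class_name = names(CLASS_CODES),
             n_pixels = as.integer(counts),
             area_ha = counts * pixel_area,
             percent = if (total > 0) 100 * counts / total else
               rep(NA_real_, 3))
}

#' Markov class-transition matrix
#'
#' `start_to_end` (default): entry `(i, j)` is the fraction of first-year
#' class-`i` pixels classified `j` in the final year. `pooled_annual`:
#' transition frequencies pooled over all consecutive-year pairs. Rows with
#' an empty start class are `NA` and flagged.
#'
#' @param maps list of class matrices in time order (>= 2).
#' @param mode `"start_to_end"` or `"pooled_annual"`.
#' @return 3 x 3 row-stochastic matrix with attribute `empty_rows`.
#' @export
transition_matrix <- function(maps, mode = c("start_to_end",
                                             "pooled_annual")) {
  mode <- match.arg(mode)
  stopifnot(length(maps) >= 2)
  counts <- matrix(0, 3, 3, dimnames = list(names(CLASS_CODES),
                                            names(CLASS_CODES)))
  pairs <- if (mode == "start_to_end") {
    list(c(1L, length(maps)))
  } else {
    lapply(seq_len(length(maps) - 1L), function(i) c(i, i + 1L))
  }
  for (pr in pairs) {
    a <- maps[[pr[1]]]; b <- maps[[pr[2]]]
    stopifnot(identical(dim(a), dim(b)))
    ok <- a > 0L & b > 0L
    counts <- counts + table(factor(a[ok], levels = 1:3),
                             factor(b[ok], levels = 1:3))
  }
  rs <- rowSums(counts)
  tm <- counts / rs
  tm[rs == 0, ] <- NA_real_
  tm <- as.matrix(tm)
  attr(tm, "empty_rows") <- names(CLASS_CODES)[rs == 0]
  attr(tm, "mode") <- mode
  tm
}
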