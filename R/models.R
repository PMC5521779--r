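# Training protocol: center/scale preprocessing, seeded stratified
# 10-fold cross-validation with grid search, final fit, prediction and
# model persistence.

#' Model configuration
#'
#' @param algorithm One of `"RANDOM_FOREST"`, `"SVM_RBF"`,
#'   `"NAIVE_BAYES"`, `"KNN"`, `"ANN"`, `"PLS_DA"`.
#' @param grid List of hyperparameter lists searched by cross-validation;
#'   `NULL` uses the built-in grid for the algorithm.
#' @param cv_folds Number of cross-validation folds (default 10).
#' @param seed Integer seed controlling fold assignment and any stochastic
#'   fitting.
#' @param decision_threshold Probability above which a site is called
#'   deamidated.
#' @return A `model_config` list.
#' @export
model_config <- function(algorithm = "RANDOM_FOREST", grid = NULL,
                         cv_folds = 10, seed = 20170721,
                         decision_threshold = 0.5) {
  algorithm <- match.arg(algorithm, ALGORITHMS)
  if (is.null(grid)) grid <- default_grid(algorithm)
  stopifnot(cv_folds >= 2, length(grid) >= 1,
            decision_threshold > 0, decision_threshold < 1)
  structure(list(algorithm = algorithm, grid = grid, cv_folds = cv_folds,
                 seed = as.integer(seed),
                 decision_threshold = decision_threshold),
            class = "model_config")
}

#' Fit center/scale preprocessing statistics
#'
#' Per-feature mean and sample standard deviation of the training table.
#' Test rows must be transformed with these training statistics, never
#' with their own.
#'
#' @param X Numeric matrix or data frame of features (rows = sites).
#' @return List with `center`, `scale` and the feature names.
#' @export
fit_preprocessing <- function(X) {
  X <- as_feature_matrix(X)
  if (nrow(X) < 2) stop("need at least 2 rows to fit preprocessing")
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  zero <- scale == 0
  if (any(zero)) {
    warning("constant feature(s) transformed to 0: ",
            paste(colnames(X)[zero], collapse = ", "))
    scale[zero] <- 1
    center[zero] <- center[zero] # centered constant -> all zeros
  }
  list(center = center, scale = scale, features = colnames(X))
}

#' Apply preprocessing statistics to feature rows
#' @param prep Result of [fit_preprocessing()].
#' @param X Feature matrix or data frame.
#' @return Scaled numeric matrix with columns in training order.
#' @export
apply_preprocessing <- function(prep, X) {
  X <- as_feature_matrix(X, required = prep$features)
  X <- X[, prep$features, drop = FALSE]
  scale(X, center = prep$center, scale = prep$scale)[, , drop = FALSE]
}

as_feature_matrix <- function(X, required = NULL) {
  if (is.data.frame(X)) {
    keep <- intersect(c(required %||% FEATURE_NAMES, colnames(X)), colnames(X))
    keep <- keep[vapply(X[keep], is.numeric, logical(1))]
    X <- as.matrix(X[, keep, drop = FALSE])
  }
  if (!is.numeric(X)) stop("features must be numeric")
  if (!is.null(required)) {
    miss <- setdiff(required, colnames(X))
    if (length(miss)) {
      stop("missing feature column(s): ", paste(miss, collapse = ", "))
    }
  }
  X
}

# Seeded stratified fold assignment; folds shrink (with a warning) when
# the positive class has fewer members than folds.
stratified_folds <- function(y, k, seed) {
  npos <- sum(y == 1)
  if (npos < k) {
    warning(sprintf("only %d positives: reducing folds from %d to %d",
                    npos, k, max(2, npos)))
    k <- max(2, npos)
  }
  fold <- integer(length(y))
  rng <- local({ set.seed(seed); NULL })
  set.seed(seed)
  for (cls in c(0, 1)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  list(fold = fold, k = k)
}

#' Cross-validate a classifier with grid search
#'
#' Seeded stratified k-fold split; per grid point, preprocessing is fit
#' inside each training fold (no leakage) and the mean held-out accuracy
#' at the decision threshold is recorded. The best grid point wins, ties
#' going to the first point in grid order.
#'
#' @param X Feature table (matrix or data frame).
#' @param y Binary labels (1 = deamidated).
#' @param config A [model_config()].
#' @return List with `accuracy` (best mean CV accuracy), `best_params`,
#'   `fold` assignment, and `grid_accuracy` per grid point.
#' @export
cross_validate <- function(X, y, config) {
  X <- as_feature_matrix(X)
  y <- as.integer(y)
  stopifnot(length(y) == nrow(X))
  if (length(unique(y)) < 2) stop("both classes must be present for training")
  if (nrow(X) < config$cv_folds) stop("fewer rows than folds")
  sf <- stratified_folds(y, config$cv_folds, config$seed)
  fold <- sf$fold
  k <- sf$k

  grid_acc <- numeric(length(config$grid))
  for (gi in seq_along(config$grid)) {
    pars <- config$grid[[gi]]
    acc <- numeric(k)
    for (f in seq_len(k)) {
      tr <- fold != f
      te <- fold == f
      if (length(unique(y[tr])) < 2) {
        stop("a training fold lost one class entirely; reduce cv_folds")
      }
      prep <- suppressWarnings(fit_preprocessing(X[tr, , drop = FALSE]))
      Xtr <- apply_preprocessing(prep, X[tr, , drop = FALSE])
      Xte <- apply_preprocessing(prep, X[te, , drop = FALSE])
      set.seed(config$seed + 1000L * gi + f)
      fit <- fit_algorithm(config$algorithm, Xtr, y[tr], pars)
      pr <- prob_algorithm(config$algorithm, fit, Xte)
      acc[f] <- mean((pr >= config$decision_threshold) == (y[te] == 1))
    }
    grid_acc[gi] <- mean(acc)
  }
  best <- which.max(grid_acc) # which.max takes the first maximum: tie rule
  list(accuracy = grid_acc[best], best_params = config$grid[[best]],
       fold = fold, grid_accuracy = grid_acc, cv_folds_used = k)
}

#' Train a deamidation classifier
#'
#' Tunes hyperparameters by [cross_validate()], then refits on all rows
#' with preprocessing statistics from the full training table.
#'
#' @inheritParams cross_validate
#' @return An object of class `deam_model`.
#' @export
train_model <- function(X, y, config = model_config()) {
  X <- as_feature_matrix(X)
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("both classes must be present for training")
  cv <- cross_validate(X, y, config)
  prep <- suppressWarnings(fit_preprocessing(X))
  Xs <- apply_preprocessing(prep, X)
  set.seed(config$seed)
  fit <- fit_algorithm(config$algorithm, Xs, y, cv$best_params)
  structure(list(config = config, preprocessing = prep, fit = fit,
                 best_params = cv$best_params, cv = cv,
                 n = nrow(X), class_counts = table(factor(y, c(0, 1)))),
            class = "deam_model")
}

#' @export
print.deam_model <- function(x, ...) {
  cat(sprintf("<deam_model> %s trained on %d sites (%d positive); CV accuracy %.3f\n",
              x$config$algorithm, x$n, x$class_counts[["1"]], x$cv$accuracy))
  invisible(x)
}

#' Predict deamidation probabilities for feature rows
#'
#' @param object A `deam_model`.
#' @param X Feature rows with the 13 descriptor columns of training.
#' @param sites Optional site-identity data frame bound to the output.
#' @param ... Unused.
#' @return Data frame sorted by descending probability with columns
#'   `probability` and `label` (1 at or above the decision threshold).
#' @export
predict.deam_model <- function(object, X, sites = NULL, ...) {
  Xs <- apply_preprocessing(object$preprocessing, X)
  if (anyNA(Xs)) stop("feature rows contain missing values")
  pr <- prob_algorithm(object$config$algorithm, object$fit, Xs)
  out <- data.frame(probability = pr,
                    label = as.integer(pr >= object$config$decision_threshold))
  if (!is.null(sites)) out <- cbind(sites, out)
  out[order(-out$probability), , drop = FALSE]
}

#' Persist a trained model as a versioned JSON archive
#'
#' @param model A `deam_model`.
#' @param path Output file path.
#' @export
save_model <- function(model, path) {
  payload <- list(
    format = "deamidate-model", version = 1L,
    algorithm = model$config$algorithm,
    config = model$config[c("cv_folds", "seed", "decision_threshold")],
    best_params = model$best_params,
    preprocessing = model$preprocessing,
    cv = model$cv[c("accuracy", "grid_accuracy", "cv_folds_used")],
    n = model$n, class_counts = as.list(model$class_counts),
    fit = serialize_fit(model$config$algorithm, model$fit)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Load a model archive written by [save_model()]
#' @param path Archive path.
#' @return A `deam_model`.
#' @export
load_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "deamidate-model")) stop("not a deamidate model archive")
  cfg <- model_config(algorithm = p$algorithm, cv_folds = p$config$cv_folds,
                      seed = p$config$seed,
                      decision_threshold = p$config$decision_threshold)
  prep <- list(center = unlist(p$preprocessing$center),
               scale = unlist(p$preprocessing$scale),
               features = p$preprocessing$features)
  structure(list(config = cfg, preprocessing = prep,
                 fit = deserialize_fit(p$algorithm, p$fit),
                 best_params = p$best_params, cv = p$cv, n = p$n,
                 class_counts = p$class_counts),
            class = "deam_model")
}

serialize_fit <- function(algorithm, fit) {
  if (algorithm == "RANDOM_FOREST") {
    list(trees = lapply(fit$trees, function(m) as.data.frame(m)),
         importance = as.list(fit$importance))
  } else if (algorithm == "KNN") {
    list(X = as.data.frame(fit$X), y = fit$y, k = fit$k)
  } else if (algorithm == "SVM_RBF") {
    list(X = as.data.frame(fit$X), coef = fit$coef, b = fit$b,
         gamma = fit$gamma, platt = fit$platt)
  } else {
    fit
  }
}

deserialize_fit <- function(algorithm, fit) {
  if (algorithm == "RANDOM_FOREST") {
    list(trees = lapply(fit$trees, function(d) as.matrix(as.data.frame(d))),
         importance = unlist(fit$importance))
  } else if (algorithm == "KNN") {
    list(X = as.matrix(fit$X), y = unlist(fit$y), k = fit$k)
  } else if (algorithm == "SVM_RBF") {
    list(X = as.matrix(fit$X), coef = unlist(fit$coef), b = fit$b,
         gamma = fit$gamma, platt = unlist(fit$platt))
  } else if (algorithm == "ANN") {
    list(w = unlist(fit$w), size = fit$size, p = fit$p)
  } else if (algorithm == "PLS_DA") {
    list(B = unlist(fit$B), intercept = fit$intercept, link = unlist(fit$link))
  } else if (algorithm == "NAIVE_BAYES") {
    list(pos = list(mean = unlist(fit$pos$mean), sd = unlist(fit$pos$sd)),
         neg = list(mean = unlist(fit$neg$mean), sd = unlist(fit$neg$sd)),
         prior = fit$prior)
  } else fit
}
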