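# Training protocol: preprocessing, cross-validation, the six classifier
# families, prediction contracts.

# small linearly separable table: feature x1 alone determines the label
# with a wide margin
separable_table <- function(n = 60, seed = 5) {
  set.seed(seed)
  y <- rep(c(1L, 0L), length.out = n)
  X <- cbind(x1 = y * 10 + stats::rnorm(n, 0, 0.3),
             x2 = stats::rnorm(n), x3 = stats::rnorm(n))
  list(X = X, y = y)
}

test_that("preprocessing centers and scales, and never leaks test statistics", {
  d <- separable_table()
  prep <- fit_preprocessing(d$X)
  Xs <- apply_preprocessing(prep, d$X)
  expect_equal(unname(colMeans(Xs)), rep(0, 3), tolerance = 1e-9)
  expect_equal(unname(apply(Xs, 2, stats::sd)), rep(1, 3), tolerance = 1e-9)

  const <- cbind(d$X, x4 = 1)
  expect_warning(prep2 <- fit_preprocessing(const), "constant")
  expect_true(all(apply_preprocessing(prep2, const)[, "x4"] == 0))

  # test rows shifted by +5 must NOT come out centered
  shifted <- d$X + 5
  Zs <- apply_preprocessing(prep, shifted)
  expect_true(all(abs(colMeans(Zs)) > 0.5))

  expect_error(fit_preprocessing(matrix("a", 2, 2)), "numeric")
})

test_that("cross-validation separates separable data and is deterministic", {
  d <- separable_table()
  for (alg in c("RANDOM_FOREST", "KNN")) {
    cfg <- model_config(alg, grid = list(list(mtry = 2, k = 3)),
                        cv_folds = 5, seed = 101)
    cv <- cross_validate(d$X, d$y, cfg)
    expect_gte(cv$accuracy, 0.95)
    cv2 <- cross_validate(d$X, d$y, cfg)
    expect_identical(cv$fold, cv2$fold)
    expect_identical(cv$accuracy, cv2$accuracy)
  }
})

test_that("null tables score at the majority-class rate", {
  null <- build_feature_table(table_spec(n = 194, prevalence = 28 / 194,
                                         effect = 0, seed = 77))
  cfg <- model_config("RANDOM_FOREST", grid = list(list(mtry = 3)),
                      cv_folds = 5, seed = 3)
  cv <- cross_validate(null$features, null$labels, cfg)
  majority <- 166 / 194
  expect_lt(abs(cv$accuracy - majority), 3 * sqrt(majority * (1 - majority) / 194))
})

test_that("fold construction refuses degenerate stratification politely", {
  d <- separable_table(n = 20)
  y <- c(rep(1L, 3), rep(0L, 17))
  cfg <- model_config("KNN", grid = list(list(k = 3)), cv_folds = 10, seed = 1)
  expect_warning(cv <- cross_validate(d$X[1:20, ], y, cfg), "reducing folds")
  expect_equal(cv$cv_folds_used, 3)
  expect_error(cross_validate(d$X[1:20, ], rep(1L, 20), cfg), "both classes")
})

test_that("every family trains, predicts in [0,1] and memorizes separable data", {
  d <- separable_table()
  grids <- list(RANDOM_FOREST = list(list(mtry = 2)),
                SVM_RBF = list(list(cost = 1, gamma_scale = 1)),
                NAIVE_BAYES = list(list()),
                KNN = list(list(k = 3)),
                ANN = list(list(size = 3, decay = 0.01)),
                PLS_DA = list(list(ncomp = 2)))
  for (alg in names(grids)) {
    cfg <- model_config(alg, grid = grids[[alg]], cv_folds = 5, seed = 11)
    m <- train_model(d$X, d$y, cfg)
    pred <- predict(m, d$X)
    expect_true(all(pred$probability >= 0 & pred$probability <= 1),
                label = alg)
    expect_equal(pred$label, as.integer(pred$probability >= 0.5))
    # training positives recovered on this trivially separable table
    ord <- predict(m, d$X[d$y == 1, , drop = FALSE])
    expect_true(all(ord$probability > 0.5), label = alg)
    # determinism on a fixed probe set
    m2 <- train_model(d$X, d$y, cfg)
    expect_identical(predict(m2, d$X)$probability, pred$probability,
                     label = alg)
  }
  expect_error(train_model(d$X, rep(0L, nrow(d$X)), model_config("KNN")),
               "both classes")
})

test_that("prediction output is ranked and threshold-monotone", {
  d <- separable_table()
  cfg5 <- model_config("RANDOM_FOREST", grid = list(list(mtry = 2)),
                       cv_folds = 5, seed = 2, decision_threshold = 0.5)
  m5 <- train_model(d$X, d$y, cfg5)
  p5 <- predict(m5, d$X)
  expect_true(!is.unsorted(rev(p5$probability)))
  n_at <- function(thr) sum(p5$probability >= thr)
  expect_gte(n_at(0.5), n_at(0.9))
  expect_error(predict(m5, d$X[, 1:2]), "missing feature")
})

test_that("PLS-DA probability is monotone in the latent score", {
  d <- separable_table()
  cfg <- model_config("PLS_DA", grid = list(list(ncomp = 2)), cv_folds = 5,
                      seed = 4)
  m <- train_model(d$X, d$y, cfg)
  score <- as.numeric(apply_preprocessing(m$preprocessing, d$X) %*% m$fit$B) +
    m$fit$intercept
  prob <- predict(m, d$X)
  raw <- prob[order(as.integer(rownames(prob))), "probability"]
  expect_equal(order(raw), order(score))
})

test_that("models survive the JSON persistence round trip", {
  d <- separable_table()
  for (alg in c("RANDOM_FOREST", "SVM_RBF", "NAIVE_BAYES", "KNN", "ANN",
                "PLS_DA")) {
    grid <- switch(alg, RANDOM_FOREST = list(list(mtry = 2)),
                   SVM_RBF = list(list(cost = 1, gamma_scale = 1)),
                   KNN = list(list(k = 3)), ANN = list(list(size = 3, decay = 0.01)),
                   PLS_DA = list(list(ncomp = 1)), list(list()))
    m <- train_model(d$X, d$y, model_config(alg, grid = grid, cv_folds = 3,
                                            seed = 12))
    f <- withr::local_tempfile(fileext = ".json")
    save_model(m, f)
    m2 <- load_model(f)
    expect_equal(predict(m2, d$X)$probability, predict(m, d$X)$probability,
                 tolerance = 1e-12, label = alg)
  }
})
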