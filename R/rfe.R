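# Recursive feature elimination over the random-forest model: refit,
# drop the least important descriptor, repeat. The final ranking follows
# elimination order (last survivor first); reported weights are the
# full-model importances rescaled so the top feature is exactly 100.

#' Rank descriptors by recursive feature elimination
#'
#' @param X Feature table (matrix or data frame), at least 2 columns.
#' @param y Binary labels (1 = deamidated).
#' @param config A [model_config()]; the random-forest settings of its
#'   first grid point are used for every refit.
#' @param ntree Trees per forest refit.
#' @return Data frame with columns `feature` and `weight` (top = 100,
#'   non-increasing, clipped at 0), in rank order.
#' @export
rfe_rank <- function(X, y, config = model_config(), ntree = 500) {
  X <- as_feature_matrix(X)
  y <- as.integer(y)
  if (ncol(X) < 2) stop("RFE needs at least 2 features")
  if (length(unique(y)) < 2) stop("both classes must be present")
  prep <- suppressWarnings(fit_preprocessing(X))
  Xs <- apply_preprocessing(prep, X)
  mtry0 <- config$grid[[1]]$mtry %||% max(2, floor(sqrt(ncol(X))))

  # full-model importances define the reported weights
  set.seed(config$seed)
  full <- fit_rf(Xs, y, ntree = ntree, mtry = min(mtry0, ncol(Xs)))
  imp_full <- full$importance

  remaining <- colnames(Xs)
  eliminated <- character(0)
  step <- 0
  while (length(remaining) > 1) {
    step <- step + 1
    set.seed(config$seed + step)
    fit <- fit_rf(Xs[, remaining, drop = FALSE], y, ntree = ntree,
                  mtry = min(mtry0, length(remaining)))
    imp <- fit$importance
    worst <- names(imp)[order(imp, seq_along(imp))][1]
    eliminated <- c(worst, eliminated) # prepend: later eliminations rank higher
    remaining <- setdiff(remaining, worst)
  }
  ranking <- c(remaining, eliminated)

  w <- pmax(imp_full[ranking], 0)
  w <- if (w[1] > 0) 100 * w / w[1] else rep(0, length(w))
  # elimination order defines the rank; displayed weights are made
  # consistent with it (non-increasing) by a running minimum
  w <- cummin(pmin(w, 100))
  data.frame(feature = ranking, weight = unname(w), stringsAsFactors = FALSE)
}

#' Write an RFE ranking as CSV
#' @param ranking Data frame from [rfe_rank()].
#' @param path Output path.
#' @export
write_ranking_csv <- function(ranking, path) {
  utils::write.csv(ranking, path, row.names = FALSE)
  invisible(path)
}
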