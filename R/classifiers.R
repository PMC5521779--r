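# The six classifier families behind a common fit/predict-probability
# interface. Each `fit_*` returns an opaque parameter list; the matching
# `prob_*` returns P(positive) per row. Inputs are already centered and
# scaled by the caller.

## ---- random forest (compiled core) ----------------------------------

fit_rf <- function(X, y, ntree = 500, mtry = 3, min_node = 1) {
  fit <- .rf_fit_cpp(X, as.integer(y), as.integer(ntree), as.integer(mtry),
                     as.integer(min_node))
  names(fit$importance) <- colnames(X)
  fit
}

prob_rf <- function(fit, X) .rf_predict_cpp(fit$trees, X)

## ---- RBF-kernel support vector machine ------------------------------

rbf_kernel <- function(A, B, gamma) {
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * A %*% t(B)
  exp(-gamma * pmax(d2, 0))
}

# Median-heuristic kernel width: gamma = 1 / (2 * median pairwise
# squared distance); the grid scales it by a factor.
svm_gamma_heuristic <- function(X) {
  n <- nrow(X)
  idx <- if (n > 200) seq(1, n, length.out = 200) else seq_len(n)
  D <- as.matrix(stats::dist(X[idx, , drop = FALSE]))^2
  m <- stats::median(D[upper.tri(D)])
  if (!is.finite(m) || m <= 0) m <- 1
  1 / (2 * m)
}

# Soft-margin C-SVM via the dual quadratic program (solve.QP), with a
# logistic (Platt-style) map from decision values to probabilities.
fit_svm <- function(X, y, cost = 1, gamma_scale = 1) {
  gamma <- svm_gamma_heuristic(X) * gamma_scale
  ys <- ifelse(y == 1, 1, -1)
  n <- nrow(X)
  K <- rbf_kernel(X, X, gamma)
  Q <- (ys %o% ys) * K
  diag(Q) <- diag(Q) + 1e-8 # numerical ridge for positive definiteness
  Amat <- cbind(ys, diag(n), -diag(n))
  bvec <- c(0, rep(0, n), rep(-cost, n))
  sol <- quadprog::solve.QP(Dmat = Q, dvec = rep(1, n), Amat = Amat,
                            bvec = bvec, meq = 1)
  alpha <- pmin(pmax(sol$solution, 0), cost)
  sv <- alpha > 1e-6
  margin <- sv & alpha < cost - 1e-6
  f_no_b <- as.numeric(K %*% (alpha * ys))
  b <- if (any(margin)) {
    mean(ys[margin] - f_no_b[margin])
  } else if (any(ys == -1 & sv) && any(ys == 1 & sv)) {
    -(max(f_no_b[ys == -1 & sv]) + min(f_no_b[ys == 1 & sv])) / 2
  } else 0
  decision <- f_no_b + b
  platt <- suppressWarnings(
    stats::glm(y ~ decision, family = stats::binomial())$coefficients)
  if (anyNA(platt)) platt <- c(0, 1)
  list(X = X[sv, , drop = FALSE], coef = (alpha * ys)[sv], b = b,
       gamma = gamma, platt = platt)
}

prob_svm <- function(fit, X) {
  f <- as.numeric(rbf_kernel(X, fit$X, fit$gamma) %*% fit$coef) + fit$b
  1 / (1 + exp(-(fit$platt[1] + fit$platt[2] * f)))
}

## ---- Gaussian naive Bayes -------------------------------------------

fit_nbc <- function(X, y) {
  stats_by <- function(cls) {
    Xi <- X[y == cls, , drop = FALSE]
    s <- apply(Xi, 2, stats::sd)
    s[s < 1e-6] <- 1e-6
    list(mean = colMeans(Xi), sd = s)
  }
  list(pos = stats_by(1), neg = stats_by(0), prior = mean(y == 1))
}

prob_nbc <- function(fit, X) {
  loglik <- function(st) {
    out <- numeric(nrow(X))
    for (j in seq_len(ncol(X))) {
      out <- out + stats::dnorm(X[, j], st$mean[j], st$sd[j], log = TRUE)
    }
    out
  }
  lp <- loglik(fit$pos) + log(fit$prior)
  ln <- loglik(fit$neg) + log(1 - fit$prior)
  1 / (1 + exp(ln - lp))
}

## ---- k-nearest-neighbour --------------------------------------------

fit_knn <- function(X, y, k = 5) list(X = X, y = y, k = min(k, nrow(X)))

# Probability = positive fraction among the k nearest training rows;
# distance ties broken by training-row order (deterministic).
prob_knn <- function(fit, X) {
  apply(X, 1, function(row) {
    d <- sqrt(colSums((t(fit$X) - row)^2))
    nb <- order(d)[seq_len(fit$k)]
    mean(fit$y[nb])
  })
}

## ---- single-hidden-layer neural network -----------------------------

fit_ann <- function(X, y, size = 5, decay = 0.01, maxit = 300) {
  p <- ncol(X)
  npar <- size * (p + 1) + size + 1
  unpack <- function(w) {
    W1 <- matrix(w[seq_len(size * p)], p, size)
    b1 <- w[size * p + seq_len(size)]
    W2 <- w[size * (p + 1) + seq_len(size)]
    b2 <- w[npar]
    list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
  }
  fwd <- function(pars, X) {
    H <- tanh(sweep(X %*% pars$W1, 2, pars$b1, "+"))
    z <- as.numeric(H %*% pars$W2 + pars$b2)
    list(H = H, p = 1 / (1 + exp(-z)))
  }
  loss <- function(w) {
    pars <- unpack(w)
    pr <- pmin(pmax(fwd(pars, X)$p, 1e-12), 1 - 1e-12)
    -mean(y * log(pr) + (1 - y) * log(1 - pr)) + decay * sum(w^2)
  }
  grad <- function(w) {
    pars <- unpack(w)
    f <- fwd(pars, X)
    n <- nrow(X)
    dz <- (f$p - y) / n
    gW2 <- as.numeric(t(f$H) %*% dz)
    gb2 <- sum(dz)
    dH <- (dz %o% pars$W2) * (1 - f$H^2)
    gW1 <- t(X) %*% dH
    gb1 <- colSums(dH)
    c(as.numeric(gW1), gb1, gW2, gb2) + 2 * decay * w
  }
  w0 <- stats::runif(npar, -0.5, 0.5)
  opt <- stats::optim(w0, loss, grad, method = "BFGS",
                      control = list(maxit = maxit))
  list(w = opt$par, size = size, p = p, unpack = NULL)
}

prob_ann <- function(fit, X) {
  size <- fit$size
  p <- fit$p
  w <- fit$w
  W1 <- matrix(w[seq_len(size * p)], p, size)
  b1 <- w[size * p + seq_len(size)]
  W2 <- w[size * (p + 1) + seq_len(size)]
  b2 <- w[length(w)]
  H <- tanh(sweep(X %*% W1, 2, b1, "+"))
  as.numeric(1 / (1 + exp(-(H %*% W2 + b2))))
}

## ---- PLS discriminant analysis --------------------------------------

# PLS1 (NIPALS) regression of the 0/1 label on the descriptors, with a
# logistic map from the latent-score prediction to a probability so the
# regression algorithm can serve as a classifier.
fit_plsda <- function(X, y, ncomp = 2) {
  ncomp <- min(ncomp, ncol(X), nrow(X) - 1)
  ybar <- mean(y)
  E <- X
  f <- y - ybar
  W <- P <- matrix(0, ncol(X), ncomp)
  Q <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    w <- as.numeric(t(E) %*% f)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { ncomp <- a - 1; break }
    w <- w / nw
    t_ <- as.numeric(E %*% w)
    tt <- sum(t_^2)
    p_ <- as.numeric(t(E) %*% t_) / tt
    q_ <- sum(f * t_) / tt
    E <- E - t_ %o% p_
    f <- f - q_ * t_
    W[, a] <- w
    P[, a] <- p_
    Q[a] <- q_
  }
  if (ncomp < 1) stop("PLS-DA: response has no covariance with features")
  W <- W[, seq_len(ncomp), drop = FALSE]
  P <- P[, seq_len(ncomp), drop = FALSE]
  Q <- Q[seq_len(ncomp)]
  B <- W %*% solve(t(P) %*% W, Q)
  score <- as.numeric(X %*% B) + ybar
  link <- suppressWarnings(
    stats::glm(y ~ score, family = stats::binomial())$coefficients)
  if (anyNA(link)) link <- c(0, 1)
  list(B = as.numeric(B), intercept = ybar, link = link)
}

prob_plsda <- function(fit, X) {
  score <- as.numeric(X %*% fit$B) + fit$intercept
  1 / (1 + exp(-(fit$link[1] + fit$link[2] * score)))
}

## ---- dispatch --------------------------------------------------------

ALGORITHMS <- c("RANDOM_FOREST", "SVM_RBF", "NAIVE_BAYES", "KNN", "ANN",
                "PLS_DA")

fit_algorithm <- function(algorithm, X, y, pars) {
  switch(algorithm,
    RANDOM_FOREST = fit_rf(X, y, ntree = pars$ntree %||% 500,
                           mtry = pars$mtry, min_node = pars$min_node %||% 1),
    SVM_RBF = fit_svm(X, y, cost = pars$cost, gamma_scale = pars$gamma_scale),
    NAIVE_BAYES = fit_nbc(X, y),
    KNN = fit_knn(X, y, k = pars$k),
    ANN = fit_ann(X, y, size = pars$size, decay = pars$decay),
    PLS_DA = fit_plsda(X, y, ncomp = pars$ncomp),
    stop("unknown algorithm: ", algorithm)
  )
}

prob_algorithm <- function(algorithm, fit, X) {
  switch(algorithm,
    RANDOM_FOREST = prob_rf(fit, X),
    SVM_RBF = prob_svm(fit, X),
    NAIVE_BAYES = prob_nbc(fit, X),
    KNN = prob_knn(fit, X),
    ANN = prob_ann(fit, X),
    PLS_DA = prob_plsda(fit, X),
    stop("unknown algorithm: ", algorithm)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Hyperparameter search grids at breadth comparable to an automatic
# grid-search default; tie on CV accuracy keeps the first grid point.
default_grid <- function(algorithm) {
  switch(algorithm,
    RANDOM_FOREST = lapply(c(2, 3, 4, 6), function(m) list(mtry = m)),
    SVM_RBF = {
      g <- expand.grid(cost = c(0.25, 0.5, 1, 2, 4),
                       gamma_scale = c(0.5, 1, 2))
      lapply(seq_len(nrow(g)), function(i) as.list(g[i, ]))
    },
    KNN = lapply(c(3, 5, 7, 9, 11), function(k) list(k = k)),
    ANN = {
      g <- expand.grid(size = c(3, 5, 7), decay = c(0, 0.01, 0.1))
      lapply(seq_len(nrow(g)), function(i) as.list(g[i, ]))
    },
    NAIVE_BAYES = list(list()),
    PLS_DA = lapply(1:3, function(nc) list(ncomp = nc)),
    stop("unknown algorithm: ", algorithm)
  )
}
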