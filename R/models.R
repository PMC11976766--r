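# Classifiers behind the ranking interface: weighted logistic ("linear"),
# bagged logistic ensemble ("ensemble"), naive Bayes ("bayes") and a small
# single-hidden-layer perceptron ("mlp"). All share a predict-probability
# contract and an explicit seed.

#' Train a candidate-diagnosis classifier
#'
#' Fits one of four model kinds on the four-feature matrix with
#' inverse-frequency class weights (one causative per thousands of
#' candidates makes unweighted losses degenerate). Deterministic given
#' `seed`.
#'
#' @param features data.frame or matrix with the `FEATURE_NAMES` columns.
#' @param labels Binary vector (1 = causative).
#' @param model_kind "ensemble", "linear", "bayes" or "mlp".
#' @param seed Integer seed for all stochastic steps.
#' @param config `ensemble_members` controls the bag size.
#' @return Object of class `dx_ranker`.
#' @export
train_model <- function(features, labels, model_kind = "ensemble", seed = 1L,
                        config = dxrank_config()) {
  X <- as.matrix(as.data.frame(features)[FEATURE_NAMES])
  y <- as.numeric(labels)
  if (length(unique(y)) < 2L) stopf("single-class training set: cannot fit")
  w <- ifelse(y == 1, 0.5 / mean(y == 1), 0.5 / mean(y == 0))
  fit <- switch(model_kind,
    linear = list(models = list(fit_wlogit(X, y, w))),
    ensemble = withr::with_seed(seed, {
      B <- config$ensemble_members
      models <- vector("list", B)
      n <- nrow(X)
      for (b in seq_len(B)) {
        repeat {
          idx <- sample.int(n, n, replace = TRUE)
          if (length(unique(y[idx])) == 2L) break
        }
        models[[b]] <- fit_wlogit(X[idx, , drop = FALSE], y[idx], w[idx])
      }
      list(models = models)
    }),
    bayes = list(models = list(fit_nbayes(X, y, w))),
    mlp = withr::with_seed(seed, list(models = list(fit_mlp(X, y, w)))),
    stopf("unknown model_kind '%s'", model_kind))
  structure(list(kind = model_kind, members = fit$models, seed = seed),
            class = "dx_ranker")
}

fit_wlogit <- function(X, y, w) {
  # glm.fit avoids the formula/model-frame overhead of glm(): these fits run
  # hundreds of times inside bagged LOPO folds
  Xd <- cbind(`(Intercept)` = 1, X)
  fit <- suppressWarnings(stats::glm.fit(Xd, y, weights = w,
                                         family = stats::binomial()))
  co <- fit$coefficients
  co[is.na(co)] <- 0
  list(type = "logit", coef = co)
}

predict_wlogit <- function(m, X) {
  eta <- m$coef[1] + X %*% m$coef[colnames(X)]
  as.numeric(1 / (1 + exp(-eta)))
}

fit_nbayes <- function(X, y, w) {
  # Gaussian on continuous features, Bernoulli on {0,1} features; weighted
  stats_for <- function(cls) {
    wi <- w * (y == cls)
    mu <- colSums(X * wi) / sum(wi)
    va <- colSums(sweep(X, 2, mu)^2 * wi) / sum(wi)
    list(mu = mu, var = pmax(va, 1e-4))
  }
  binary <- apply(X, 2, function(col) all(col %in% c(0, 1)))
  bern_for <- function(cls) {
    wi <- w * (y == cls)
    (colSums(X * wi) + 1) / (sum(wi) + 2) # Laplace smoothing
  }
  list(type = "bayes", binary = binary,
       g0 = stats_for(0), g1 = stats_for(1),
       b0 = bern_for(0), b1 = bern_for(1),
       prior1 = sum(w * (y == 1)) / sum(w))
}

predict_nbayes <- function(m, X) {
  ll <- function(g, b) {
    out <- rep(0, nrow(X))
    for (j in seq_len(ncol(X))) {
      out <- out + if (m$binary[j]) {
        ifelse(X[, j] > 0.5, log(b[j]), log(1 - b[j]))
      } else {
        stats::dnorm(X[, j], g$mu[j], sqrt(g$var[j]), log = TRUE)
      }
    }
    out
  }
  l1 <- ll(m$g1, m$b1) + log(m$prior1)
  l0 <- ll(m$g0, m$b0) + log(1 - m$prior1)
  1 / (1 + exp(l0 - l1))
}

fit_mlp <- function(X, y, w, hidden = 4L, maxit = 300L) {
  p <- ncol(X)
  n_par <- hidden * (p + 1L) + hidden + 1L
  unpack <- function(theta) {
    W1 <- matrix(theta[seq_len(hidden * p)], p, hidden)
    b1 <- theta[hidden * p + seq_len(hidden)]
    W2 <- theta[hidden * (p + 1L) + seq_len(hidden)]
    b2 <- theta[n_par]
    list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
  }
  fwd <- function(pars, X) {
    H <- tanh(sweep(X %*% pars$W1, 2, pars$b1, "+"))
    as.numeric(1 / (1 + exp(-(H %*% pars$W2 + pars$b2))))
  }
  loss <- function(theta) {
    pr <- fwd(unpack(theta), X)
    pr <- pmin(pmax(pr, 1e-12), 1 - 1e-12)
    -sum(w * (y * log(pr) + (1 - y) * log(1 - pr))) / sum(w) +
      1e-4 * sum(theta^2)
  }
  theta0 <- stats::rnorm(n_par, sd = 0.3)
  opt <- stats::optim(theta0, loss, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-10))
  list(type = "mlp", pars = unpack(opt$par), fwd = NULL)
}

predict_mlp <- function(m, X) {
  H <- tanh(sweep(X %*% m$pars$W1, 2, m$pars$b1, "+"))
  as.numeric(1 / (1 + exp(-(H %*% m$pars$W2 + m$pars$b2))))
}

predict_member <- function(m, X) {
  switch(m$type,
    logit = predict_wlogit(m, X),
    bayes = predict_nbayes(m, X),
    mlp = predict_mlp(m, X))
}

#' Per-member predicted probabilities
#'
#' Matrix of weak-learner probabilities (columns = ensemble members; a
#' single column for non-ensemble kinds), the input of the entropy-based
#' uncertainty decomposition.
#'
#' @param object A `dx_ranker`.
#' @param features Feature data.frame/matrix.
#' @return Numeric matrix, rows = candidates.
#' @export
member_probabilities <- function(object, features) {
  X <- as.matrix(as.data.frame(features)[FEATURE_NAMES])
  P <- vapply(object$members, function(m) predict_member(m, X), numeric(nrow(X)))
  matrix(P, nrow = nrow(X))
}

#' @export
predict.dx_ranker <- function(object, newdata, ...) {
  P <- member_probabilities(object, newdata)
  rowMeans(P)
}

#' @export
print.dx_ranker <- function(x, ...) {
  cat(sprintf("<dx_ranker> kind=%s, members=%d, seed=%d\n",
              x$kind, length(x$members), x$seed))
  invisible(x)
}
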