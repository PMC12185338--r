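## Ridge-regression map from raw features to embedding dimensions (the
## interpretability pipeline), plus the activation-maximisation loss as a
## pure function of a predicted embedding vector.

## closed-form ridge solutions over a lambda grid via one SVD of the centred
## design; returns fitted coefficient array d x k x n_lambda
ridge_path <- function(Xc, Yc, lambdas) {
  sv <- svd(Xc)
  d <- ncol(Xc); k <- ncol(Yc)
  uty <- crossprod(sv$u, Yc)              # r x k
  coefs <- array(0, c(d, k, length(lambdas)))
  for (l in seq_along(lambdas)) {
    shrink <- sv$d / (sv$d^2 + lambdas[l])
    coefs[, , l] <- sv$v %*% (shrink * uty)
  }
  coefs
}

#' Fit an l2-regularised linear map from features to embedding dimensions
#'
#' Each embedding dimension is regressed on the feature matrix with a ridge
#' penalty; the penalty `lambda` is chosen per dimension by k-fold
#' cross-validated R-squared, and the map is refit on all objects at the
#' selected `lambda`. Features and targets are centred internally (the
#' intercept absorbs the means); no scaling is applied.
#'
#' @param features Numeric m x d matrix, same object order as `Y`.
#' @param Y Point embedding, m x k non-negative matrix.
#' @param lambda_grid Candidate penalties (default logarithmic, 1e-3..1e3).
#' @param folds Number of cross-validation folds (default 5).
#' @param seed Seed for the fold shuffle.
#' @return An object of class `linear_map`: `weights` (d x k), `intercept`
#'   (length k), `lambda` (chosen per dimension), `r2_per_dim` (held-out
#'   R-squared at the chosen penalty), `lambda_grid`, `cv_r2` (grid x k).
#' @export
fit_ridge <- function(features, Y, lambda_grid = 10^seq(-3, 3, length.out = 13),
                      folds = 5L, seed = 1L) {
  X <- as.matrix(features); Y <- as.matrix(Y)
  m <- nrow(X)
  stopifnot(nrow(Y) == m, m > folds, folds >= 2, all(lambda_grid >= 0))
  if (any(lambda_grid == 0) && qr(scale(X, scale = FALSE))$rank < ncol(X)) {
    stop("lambda = 0 with a singular design is not identifiable")
  }
  lambda_grid <- sort(lambda_grid)
  set.seed(seed)
  fold_id <- sample(rep_len(seq_len(folds), m))

  k <- ncol(Y)
  press <- matrix(0, length(lambda_grid), k)  # pooled held-out SSE per lambda
  for (f in seq_len(folds)) {
    tr <- fold_id != f; te <- !tr
    xm <- colMeans(X[tr, , drop = FALSE]); ym <- colMeans(Y[tr, , drop = FALSE])
    Xc <- sweep(X[tr, , drop = FALSE], 2, xm)
    Yc <- sweep(Y[tr, , drop = FALSE], 2, ym)
    coefs <- ridge_path(Xc, Yc, lambda_grid)
    Xte <- sweep(X[te, , drop = FALSE], 2, xm)
    for (l in seq_along(lambda_grid)) {
      pred <- sweep(Xte %*% coefs[, , l], 2, ym, `+`)
      press[l, ] <- press[l, ] + colSums((Y[te, , drop = FALSE] - pred)^2)
    }
  }
  sst <- colSums(sweep(Y, 2, colMeans(Y))^2)
  cv_r2 <- 1 - sweep(press, 2, sst, `/`)
  best <- apply(cv_r2, 2, which.max)

  ## refit on all objects at each dimension's chosen lambda
  xm <- colMeans(X); ym <- colMeans(Y)
  coefs <- ridge_path(sweep(X, 2, xm), sweep(Y, 2, ym), lambda_grid)
  W <- vapply(seq_len(k), function(j) coefs[, j, best[j]], numeric(ncol(X)))
  W <- matrix(W, ncol = k)
  intercept <- ym - drop(xm %*% W)
  structure(list(
    weights = W, intercept = intercept, lambda = lambda_grid[best],
    r2_per_dim = cv_r2[cbind(best, seq_len(k))],
    lambda_grid = lambda_grid, cv_r2 = cv_r2,
    dim_ids = colnames(Y)
  ), class = "linear_map")
}

#' @export
print.linear_map <- function(x, ...) {
  cat(sprintf("linear map: %d features -> %d dimensions\n",
              nrow(x$weights), ncol(x$weights)))
  cat(sprintf("  held-out R^2: median %.3f, range [%.3f, %.3f]\n",
              stats::median(x$r2_per_dim), min(x$r2_per_dim), max(x$r2_per_dim)))
  invisible(x)
}

#' Predict embedding dimensions from features
#'
#' Affine prediction through a fitted [fit_ridge()] map, rectified by default
#' so the result satisfies the non-negativity invariant of point embeddings.
#'
#' @param map A `linear_map`.
#' @param features Numeric matrix with the same feature dimensionality the
#'   map was fit on.
#' @param rectified Set `FALSE` for the raw affine predictions.
#' @return Predicted embedding matrix (objects x dimensions).
#' @export
predict_dimensions <- function(map, features, rectified = TRUE) {
  X <- as.matrix(features)
  if (ncol(X) != nrow(map$weights)) stop("feature dimensionality mismatch")
  pred <- sweep(X %*% map$weights, 2, map$intercept, `+`)
  colnames(pred) <- map$dim_ids
  if (rectified) pred <- rectify(pred)
  pred
}

#' Activation-maximisation loss for a predicted embedding vector
#'
#' The score minimised when searching for stimuli that maximise one embedding
#' dimension: `-alpha * y[j] - beta * log p_j`, where the first term rewards
#' the size of dimension `j` and the second rewards specificity —
#' concentration of probability mass on `j`. Specificity defaults to the
#' softmax of the embedding vector across dimensions.
#'
#' @param y_hat Predicted embedding vector (length k).
#' @param j Target dimension index.
#' @param alpha,beta Non-negative trade-off scalars.
#' @param specificity Either `"softmax"` or a function mapping `y_hat` to a
#'   probability vector over dimensions.
#' @return Scalar loss (`Inf`, with a warning, if the specificity probability
#'   of `j` is zero).
#' @export
am_loss <- function(y_hat, j, alpha = 1, beta = 1, specificity = "softmax") {
  stopifnot(alpha >= 0, beta >= 0, j >= 1, j <= length(y_hat))
  if (identical(specificity, "softmax")) {
    log_pj <- y_hat[j] - log(sum(exp(y_hat - max(y_hat)))) - max(y_hat)
  } else {
    p <- specificity(y_hat)
    if (p[j] == 0) {
      warning("specificity probability is zero; loss is +Inf")
      return(Inf)
    }
    log_pj <- log(p[j])
  }
  unname(-alpha * y_hat[j] - beta * log_pj)
}
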