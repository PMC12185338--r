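## Synthetic ground truth: planted sparse non-negative embeddings, feature
## matrices whose dot-product structure mirrors the planted embedding, and
## triplet choice datasets generated from either deterministic (argmax) or
## stochastic (softmax) readout. Every stage of the framework can be
## exercised and validated against a known answer with these generators.

#' Generate a planted sparse non-negative embedding
#'
#' Entries are zero with probability `sparsity` and otherwise exponential
#' with mean `scale` — a positive, heavy-right-tailed weight distribution of
#' the kind sparse similarity embeddings typically exhibit (a few objects
#' load strongly on each dimension, many weakly or not at all). Columns that
#' come out all-zero are resampled so each dimension carries signal.
#'
#' @param m Number of objects.
#' @param k Number of dimensions.
#' @param sparsity Probability of an exact zero, in \[0, 1).
#' @param scale Mean of the exponential for non-zero entries.
#' @param seed Integer seed.
#' @return Non-negative m x k matrix with object/dimension names.
#' @export
generate_embedding <- function(m, k, sparsity = 0.6, scale = 1, seed = 1L) {
  stopifnot(sparsity >= 0, sparsity < 1, m >= 1, k >= 1, scale > 0)
  set.seed(seed)
  draw_col <- function(n) {
    rbinom(n, 1, 1 - sparsity) * rexp(n, rate = 1 / scale)
  }
  Y <- matrix(draw_col(m * k), m, k)
  for (j in seq_len(k)) {
    tries <- 0
    while (all(Y[, j] == 0)) {
      tries <- tries + 1
      if (tries > 100) stop("sparsity too high to plant a non-empty dimension")
      Y[, j] <- draw_col(m)
    }
  }
  dimnames(Y) <- list(default_object_ids(m), default_dim_ids(k))
  Y
}

#' Bundle a planted ground truth
#'
#' @param embedding Planted point embedding (from [generate_embedding()]).
#' @param loading Optional d x k non-negative matrix linking the embedding to
#'   a feature space; generated by [generate_features()] if absent.
#' @param noise_sd Standard deviation of the feature noise.
#' @param seed Seed associated with the ground truth.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(embedding, loading = NULL, noise_sd = 0, seed = 1L) {
  structure(list(embedding = embedding, loading = loading,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "ground_truth")
}

#' Generate a feature matrix mirroring a planted embedding
#'
#' Features are `embedding %*% t(loading)` plus Gaussian noise, rectified.
#' Loading entries are non-negative, and by default each feature is assigned
#' to a single embedding dimension (a block structure), so that feature-space
#' dot products reflect the planted similarity structure; pass an explicit
#' `loading` for full control (e.g. orthogonal columns of equal norm make
#' noise-free feature-space choices coincide exactly with embedding-space
#' choices).
#'
#' @param truth A `ground_truth`.
#' @param d Feature dimensionality (must be >= k; a warning is emitted below
#'   2k, where the random block loading starts to crowd dimensions).
#' @return Rectified m x d feature matrix; the loading actually used is
#'   attached as attribute `"loading"`.
#' @export
generate_features <- function(truth, d) {
  Y <- truth$embedding
  k <- ncol(Y)
  if (d < k) stop("feature dimensionality below embedding dimensionality loses planted structure")
  if (d < 2 * k) warning("d < 2k: feature space may crowd planted dimensions")
  set.seed(truth$seed + 1L)
  L <- truth$loading
  if (is.null(L)) {
    ## block loading: each feature column carries exactly one embedding dim
    L <- matrix(0, d, k)
    owner <- rep_len(seq_len(k), d)
    L[cbind(seq_len(d), owner)] <- 0.5 + runif(d)
  }
  stopifnot(nrow(L) == d, ncol(L) == k, all(L >= 0))
  X <- tcrossprod(Y, L)
  if (truth$noise_sd > 0) X <- X + rnorm(length(X), 0, truth$noise_sd)
  X <- rectify(X)
  rownames(X) <- rownames(Y)
  attr(X, "loading") <- L
  X
}

#' Simulate a triplet choice dataset from a planted embedding
#'
#' Samples random triplets and resolves each choice from the planted
#' embedding's dot products — deterministically (`mode = "argmax"`, the
#' largest pair similarity wins) or stochastically (`mode = "softmax"`, the
#' pair is drawn from the three-way softmax of the dot products divided by
#' `temperature`; temperature 1 is exactly the likelihood the variational
#' model optimises, and temperature -> 0 recovers argmax).
#'
#' @param truth A `ground_truth` (or a bare embedding matrix).
#' @param n Number of trials.
#' @param mode `"argmax"` or `"softmax"`.
#' @param temperature Softmax temperature (> 0).
#' @param seed Integer seed.
#' @return Triplet choice `data.frame` (columns `i`, `j`, `k`, `odd`).
#' @export
simulate_dataset <- function(truth, n, mode = c("argmax", "softmax"),
                             temperature = 1, seed = 1L) {
  mode <- match.arg(mode)
  Y <- if (inherits(truth, "ground_truth")) truth$embedding else as.matrix(truth)
  stopifnot(temperature > 0)
  trips <- sample_triplets(nrow(Y), n, seed = seed)
  if (mode == "argmax") {
    return(simulate_choices(Y, trips))
  }
  odd <- integer(n)
  for (s in seq_len(n)) {
    t <- trips[s, ]
    p <- triplet_choice_probs(Y / sqrt(temperature), t)
    pair <- sample.int(3L, 1L, prob = p)
    odd[s] <- t[4 - pair]
  }
  out <- data.frame(i = trips[, 1], j = trips[, 2], k = trips[, 3], odd = odd)
  validate_triplet_dataset(out)
  out
}

#' Summarise recovery of a planted embedding
#'
#' Matches estimated dimensions to planted dimensions without replacement
#' ([match_dimensions()]) and reports the distribution of matched
#' correlations plus the dimensionality error.
#'
#' @param truth Planted point embedding.
#' @param estimate Recovered point embedding over the same objects.
#' @return A list: `matches` (the match table), `min_r`, `median_r`,
#'   `mean_r` (absolute matched correlations), and `dim_difference`
#'   (estimated k minus planted k).
#' @export
recovery_report <- function(truth, estimate) {
  mt <- match_dimensions(as.matrix(truth), as.matrix(estimate), unique = TRUE)
  r <- abs(mt$r)
  list(matches = mt, min_r = min(r), median_r = stats::median(r),
       mean_r = mean(r),
       dim_difference = ncol(as.matrix(estimate)) - ncol(as.matrix(truth)))
}
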