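## Triplet odd-one-out machinery: representing trials and simulating choices
## from a feature matrix, treating a feature-based model like a participant.

#' Rectify a feature matrix
#'
#' Applies the rectified linear unit elementwise, `max(x, 0)`. All similarity
#' computations in the package assume non-negative features, mirroring the use
#' of ReLU activations as the representational substrate for simulated
#' odd-one-out behaviour.
#'
#' @param x Numeric matrix, one object per row. Row names, if present, are
#'   treated as object identifiers and preserved.
#' @return A matrix of the same shape with all entries >= 0.
#' @examples
#' rectify(matrix(c(-1, 2, 0, 3), 2, 2))
#' @export
rectify <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("features must be numeric")
  if (anyNA(x)) stop("features contain missing values")
  x[x < 0] <- 0
  x
}

#' Dot-product similarity of two objects
#'
#' The similarity between objects `a` and `b` is the inner product of their
#' feature rows, `S_ab = z_a' z_b`. No normalisation or centering is applied:
#' the raw dot product is the similarity currency of the whole framework.
#'
#' @param features Rectified numeric matrix, objects in rows.
#' @param a,b Row indices (1-based).
#' @return Scalar similarity.
#' @export
pair_similarity <- function(features, a, b) {
  m <- nrow(features)
  if (a < 1 || a > m || b < 1 || b > m) stop("object index out of range")
  sum(features[a, ] * features[b, ])
}

#' Canonicalise a triplet
#'
#' Triplets are stored sorted ascending; the three indices must be distinct.
#' @param t Integer vector of length 3 (1-based object indices).
#' @return Sorted integer vector of length 3.
#' @export
as_triplet <- function(t) {
  t <- as.integer(t)
  if (length(t) != 3L || anyNA(t)) stop("a triplet is three object indices")
  if (anyDuplicated(t)) stop("triplet indices must be pairwise distinct")
  sort(t)
}

## The three candidate pairs of a sorted triplet (i, j, k), in canonical order:
## pair 1 = (i, j), pair 2 = (i, k), pair 3 = (j, k). The odd-one-out for each
## pair is the remaining index: k, j, i respectively.
triplet_pairs <- function(t) {
  rbind(c(t[1], t[2]), c(t[1], t[3]), c(t[2], t[3]))
}

#' Resolve a single odd-one-out choice from features
#'
#' Among the three pairs of a triplet, the pair with the largest dot-product
#' similarity is judged "most similar"; the remaining object is the odd one
#' out. Ties are broken deterministically in favour of the lexicographically
#' smallest sorted index pair, i.e. (i,j) before (i,k) before (j,k).
#'
#' @param features Rectified numeric matrix.
#' @param t Triplet (length-3 integer vector, any order).
#' @return A list with elements `triplet` (sorted), `pair` (the chosen
#'   most-similar pair), `odd_one_out` (the remaining index), `similarities`
#'   (the three pair dot products in canonical pair order) and `tie` (logical,
#'   whether the maximum was attained by more than one pair).
#' @export
odd_one_out <- function(features, t) {
  t <- as_triplet(t)
  if (t[3] > nrow(features)) stop("object index out of range")
  prs <- triplet_pairs(t)
  sims <- c(
    pair_similarity(features, prs[1, 1], prs[1, 2]),
    pair_similarity(features, prs[2, 1], prs[2, 2]),
    pair_similarity(features, prs[3, 1], prs[3, 2])
  )
  best <- which.max(sims)  # first maximum = lexicographically smallest pair
  list(
    triplet = t,
    pair = prs[best, ],
    odd_one_out = t[4 - best],
    similarities = sims,
    tie = sum(sims == sims[best]) > 1L
  )
}

#' Sample random triplets
#'
#' Draws `n` triplets of three distinct objects uniformly at random, in
#' canonical sorted form. Triplets are sampled independently, so the same
#' triplet may recur across trials (never within one); set `dedupe = TRUE`
#' to keep only the first occurrence of each distinct triplet.
#'
#' @param m Number of objects (>= 3).
#' @param n Number of trials.
#' @param seed Optional integer seed for reproducibility.
#' @param dedupe Drop repeated triplets (default `FALSE`).
#' @return Integer matrix with `n` rows and columns `i`, `j`, `k`, each row
#'   sorted ascending.
#' @export
sample_triplets <- function(m, n, seed = NULL, dedupe = FALSE) {
  if (m < 3) stop("need at least 3 objects to form a triplet")
  if (n < 1) stop("n must be positive")
  if (!is.null(seed)) set.seed(seed)
  ## vectorised rejection-free draw: one ordered sample of 3 per trial
  out <- matrix(0L, n, 3L)
  for (s in seq_len(n)) {
    out[s, ] <- sort.int(sample.int(m, 3L))
  }
  colnames(out) <- c("i", "j", "k")
  if (dedupe) out <- out[!duplicated(out), , drop = FALSE]
  out
}

#' Simulate odd-one-out choices for a set of triplets
#'
#' Applies [odd_one_out()] to every triplet, preserving order, and returns the
#' resulting choice dataset. The number of trials in which the argmax was tied
#' is recorded in the `n_ties` attribute rather than silently resolved.
#'
#' @param features Rectified numeric matrix.
#' @param triplets Integer matrix (n x 3) of triplets, as from
#'   [sample_triplets()].
#' @return A `data.frame` with columns `i`, `j`, `k` (sorted triplet) and
#'   `odd` (the odd-one-out index); attribute `n_ties` counts tied trials.
#' @export
simulate_choices <- function(features, triplets) {
  triplets <- as.matrix(triplets)
  n <- nrow(triplets)
  odd <- integer(n)
  ties <- 0L
  for (s in seq_len(n)) {
    ch <- odd_one_out(features, triplets[s, ])
    triplets[s, ] <- ch$triplet
    odd[s] <- ch$odd_one_out
    ties <- ties + ch$tie
  }
  out <- data.frame(
    i = as.integer(triplets[, 1]), j = as.integer(triplets[, 2]),
    k = as.integer(triplets[, 3]), odd = odd
  )
  attr(out, "n_ties") <- ties
  out
}

#' Validate a triplet choice dataset
#'
#' Checks the invariants of a choice dataset: sorted distinct indices, the
#' odd-one-out a member of its triplet, and all indices within range.
#'
#' @param data A `data.frame` with columns `i`, `j`, `k`, `odd`.
#' @param m Optional object count to check indices against.
#' @return The validated data, invisibly.
#' @export
validate_triplet_dataset <- function(data, m = NULL) {
  stopifnot(all(c("i", "j", "k", "odd") %in% names(data)))
  if (nrow(data) > 0) {
    if (any(data$i >= data$j | data$j >= data$k)) {
      stop("triplets must be sorted with distinct indices i < j < k")
    }
    if (any(data$odd != data$i & data$odd != data$j & data$odd != data$k)) {
      stop("odd-one-out must be one of the triplet's objects")
    }
    if (any(data$i < 1) || (!is.null(m) && any(data$k > m))) {
      stop("object index out of range")
    }
  }
  invisible(data)
}

## Map a choice dataset to the canonical chosen-pair index (1, 2 or 3) used by
## the likelihood: pair 1 = (i,j) <=> odd k, pair 2 = (i,k) <=> odd j,
## pair 3 = (j,k) <=> odd i.
chosen_pair_index <- function(data) {
  idx <- integer(nrow(data))
  idx[data$odd == data$k] <- 1L
  idx[data$odd == data$j] <- 2L
  idx[data$odd == data$i] <- 3L
  idx
}
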