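## Jackknife dimension relevance: how much each embedding dimension
## contributes to an individual odd-one-out choice, measured by the change in
## the predicted softmax probability when that dimension is removed.

#' Jackknife relevance of each dimension for one triplet choice
#'
#' Computes the softmax probability of the model-predicted most-similar pair
#' under the full embedding, then zeroes out one dimension at a time and
#' records `delta_d = p_full - p_without_d`. A large `|delta_d|` marks a
#' dimension whose removal strongly changes the predicted choice probability.
#'
#' @param Y Point embedding (m x k, k >= 1).
#' @param t Triplet (length-3 integer vector).
#' @return A list of class `relevance_profile`: `triplet`, `base_probs` (the
#'   three pair probabilities under the full embedding), `predicted_pair`
#'   (canonical pair index 1..3 of the argmax, ties to the lowest), `p_full`,
#'   `delta` (length k), and `top_dim` (argmax of `|delta|`, ties to the
#'   lowest index).
#' @export
dimension_relevance <- function(Y, t) {
  Y <- as.matrix(Y)
  stopifnot(ncol(Y) >= 1)
  t <- as_triplet(t)
  base <- triplet_choice_probs(Y, t)
  pred <- which.max(base)
  p_full <- base[[pred]]
  rows <- Y[t, , drop = FALSE]
  delta <- vapply(seq_len(ncol(Y)), function(d) {
    sub <- rows
    sub[, d] <- 0
    p <- triplet_choice_probs(sub, c(1L, 2L, 3L))
    p_full - p[[pred]]
  }, numeric(1))
  names(delta) <- colnames(Y)
  structure(list(
    triplet = t, base_probs = base, predicted_pair = pred,
    p_full = p_full, delta = delta,
    top_dim = which.max(abs(delta))
  ), class = "relevance_profile")
}

#' Most relevant dimension of a relevance profile
#'
#' @param profile A `relevance_profile` from [dimension_relevance()].
#' @return Index of the dimension maximising `|delta|` (ties to the lowest
#'   index).
#' @export
most_relevant_dimension <- function(profile) {
  which.max(abs(profile$delta))
}

#' Aggregate top-dimension categories over a triplet sample
#'
#' Scores every triplet with [dimension_relevance()], takes each triplet's
#' most relevant dimension, and tallies the dimensions' category labels
#' (e.g. semantic / visual / mixed / unclear).
#'
#' @param Y Point embedding.
#' @param triplets Integer matrix of triplets (n x 3).
#' @param dim_labels Character vector of one label per embedding dimension.
#' @return Named integer vector of counts per label category, summing to the
#'   number of triplets.
#' @export
aggregate_relevance <- function(Y, triplets, dim_labels) {
  Y <- as.matrix(Y)
  if (length(dim_labels) != ncol(Y)) {
    stop("every active dimension needs a label")
  }
  if (anyNA(dim_labels)) stop("unlabelled dimension")
  triplets <- as.matrix(triplets)
  levels <- unique(dim_labels)
  counts <- stats::setNames(integer(length(levels)), levels)
  for (s in seq_len(nrow(triplets))) {
    top <- dimension_relevance(Y, triplets[s, ])$top_dim
    counts[dim_labels[top]] <- counts[dim_labels[top]] + 1L
  }
  counts
}

#' Rank triplets by human-model divergence
#'
#' Scores each triplet by how strongly two embeddings disagree about it:
#' zero when both predict the same odd-one-out, otherwise the mean of the two
#' models' own confidences in their (conflicting) predictions. Triplets where
#' both models are confident and contradictory rank first.
#'
#' @param Y_a,Y_b Point embeddings over the same objects in the same order.
#' @param triplets Integer matrix of triplets (n x 3).
#' @param top_n Number of top-ranked triplets to return (default all).
#' @return A `data.frame` sorted by descending `divergence`, with the
#'   triplet, each model's predicted odd-one-out and confidence, and the
#'   divergence score.
#' @export
divergent_triplets <- function(Y_a, Y_b, triplets, top_n = nrow(triplets)) {
  stopifnot(nrow(Y_a) == nrow(Y_b))
  triplets <- as.matrix(triplets)
  n <- nrow(triplets)
  out <- data.frame(i = integer(n), j = integer(n), k = integer(n),
                    odd_a = integer(n), p_a = numeric(n),
                    odd_b = integer(n), p_b = numeric(n),
                    divergence = numeric(n))
  for (s in seq_len(n)) {
    t <- as_triplet(triplets[s, ])
    pa <- triplet_choice_probs(Y_a, t); ba <- which.max(pa)
    pb <- triplet_choice_probs(Y_b, t); bb <- which.max(pb)
    out$i[s] <- t[1]; out$j[s] <- t[2]; out$k[s] <- t[3]
    out$odd_a[s] <- t[4 - ba]; out$p_a[s] <- pa[[ba]]
    out$odd_b[s] <- t[4 - bb]; out$p_b[s] <- pb[[bb]]
    out$divergence[s] <- if (ba == bb) 0 else (pa[[ba]] + pb[[bb]]) / 2
  }
  out <- out[order(-out$divergence), , drop = FALSE]
  rownames(out) <- NULL
  head(out, top_n)
}
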