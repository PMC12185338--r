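## Representational similarity analysis built on context-averaged triplet
## choice probabilities: RSM reconstruction, RSM correlation, dimension
## matching with and without replacement, cumulative RSA, and noise-ceiling
## normalisation.

#' Reconstruct a representational similarity matrix from an embedding
#'
#' The similarity of objects i and j is their probability of being judged the
#' most similar pair in a triplet, averaged over all (or a random subsample
#' of) context objects k:
#' `S_ij = mean_k exp(y_i.y_j) / (exp(y_i.y_j) + exp(y_i.y_k) + exp(y_j.y_k))`.
#' Computation is done on shifted logits (log-sum-exp) so large dot products
#' cannot overflow. The diagonal is set to 1 by convention.
#'
#' @param Y Non-negative embedding matrix (m x k, m >= 3).
#' @param context Either `"all"` (exact enumeration over every context
#'   object) or a positive integer: the number of context objects sampled
#'   uniformly without replacement per pair.
#' @param seed Seed for context subsampling.
#' @return Symmetric m x m matrix with unit diagonal and off-diagonal entries
#'   strictly inside (0, 1).
#' @export
rsm_from_embedding <- function(Y, context = "all", seed = 1L) {
  Y <- as.matrix(Y)
  m <- nrow(Y)
  if (m < 3) stop("an RSM needs at least 3 objects")
  G <- tcrossprod(Y)
  sampled <- !identical(context, "all")
  if (sampled) {
    n_ctx <- as.integer(context)
    stopifnot(n_ctx >= 1)
    set.seed(seed)
  }
  S <- matrix(1, m, m)
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      ks <- setdiff(seq_len(m), c(i, j))
      if (sampled && length(ks) > n_ctx) ks <- sort(sample(ks, n_ctx))
      a <- G[i, j]; b <- G[i, ks]; d <- G[j, ks]
      mx <- pmax(a, b, d)
      p <- exp(a - mx) / (exp(a - mx) + exp(b - mx) + exp(d - mx))
      S[i, j] <- S[j, i] <- mean(p)
    }
  }
  if (!is.null(rownames(Y))) dimnames(S) <- list(rownames(Y), rownames(Y))
  S
}

#' Pearson correlation between two RSMs
#'
#' Correlates the strict upper triangles only (the diagonal and duplicate
#' lower triangle carry no information).
#'
#' @param A,B Square matrices over the same objects in the same order.
#' @return Pearson r.
#' @export
rsm_correlation <- function(A, B) {
  stopifnot(identical(dim(A), dim(B)), nrow(A) == ncol(A))
  ut <- upper.tri(A)
  a <- A[ut]; b <- B[ut]
  if (sd(a) == 0 || sd(b) == 0) stop("RSM upper triangle has zero variance")
  cor(a, b)
}

#' Match dimensions of two embeddings by correlation
#'
#' Pairs each dimension of `A` with its most strongly correlated dimension of
#' `B` (by absolute Pearson r across objects). With replacement, every `A`
#' dimension independently takes its best match, so a `B` dimension can be
#' reused; without replacement (`unique = TRUE`), pairs are formed greedily —
#' repeatedly taking the globally strongest remaining (A, B) pair and
#' retiring both — so each `B` dimension is used at most once.
#'
#' @param A,B Embedding matrices over the same objects in the same order.
#' @param unique Forbid reuse of `B` dimensions.
#' @return A `data.frame` sorted by descending `|r|` with columns `dim_a`,
#'   `dim_b` (column indices), `r` (signed Pearson correlation), and
#'   attribute `unique`. Constant dimensions are skipped with a warning.
#' @export
match_dimensions <- function(A, B, unique = FALSE) {
  A <- as.matrix(A); B <- as.matrix(B)
  stopifnot(nrow(A) == nrow(B))
  cm <- suppressWarnings(cor(A, B))
  if (anyNA(cm)) {
    warning("constant dimensions produced undefined correlations; skipped")
  }
  strength <- abs(cm)
  pairs <- NULL
  if (!unique) {
    for (a in seq_len(ncol(A))) {
      if (all(is.na(strength[a, ]))) next
      b <- which.max(strength[a, ])
      pairs <- rbind(pairs, data.frame(dim_a = a, dim_b = b, r = cm[a, b]))
    }
  } else {
    s <- strength
    repeat {
      if (all(is.na(s))) break
      idx <- arrayInd(which.max(s), dim(s))
      a <- idx[1]; b <- idx[2]
      pairs <- rbind(pairs, data.frame(dim_a = a, dim_b = b, r = cm[a, b]))
      s[a, ] <- NA; s[, b] <- NA
    }
  }
  if (is.null(pairs)) stop("no valid dimension pairs (all correlations undefined)")
  pairs <- pairs[order(-abs(pairs$r)), , drop = FALSE]
  rownames(pairs) <- NULL
  attr(pairs, "unique") <- unique
  pairs
}

#' Cumulative RSA over a ranked list of dimensions
#'
#' Starting from the top-ranked dimension and adding one dimension at a time,
#' rebuilds the RSM from each prefix and correlates it with a reference RSM.
#' `dims_needed` reports, for each requested variance fraction, the smallest
#' prefix whose squared correlation reaches that fraction of the *full*
#' ranking's squared correlation (relative criterion; set
#' `relative = FALSE` to test against an absolute r-squared instead).
#'
#' @param B Embedding matrix.
#' @param reference Reference RSM over the same objects.
#' @param ranking Ordered vector of column indices of `B` (default: all
#'   columns in stored order).
#' @param fractions Variance fractions to report (default 0.95).
#' @param relative Interpret `fractions` relative to the full-prefix
#'   r-squared (default) rather than as absolute r-squared.
#' @param context,seed Passed to [rsm_from_embedding()].
#' @return A list with `r` (correlation per prefix size), `dims_needed`
#'   (named integer vector per fraction; `NA` if never reached), and
#'   `full_r` (the final prefix's correlation).
#' @export
cumulative_rsa <- function(B, reference, ranking = seq_len(ncol(B)),
                           fractions = 0.95, relative = TRUE,
                           context = "all", seed = 1L) {
  B <- as.matrix(B)
  stopifnot(length(ranking) >= 1, all(ranking %in% seq_len(ncol(B))))
  r <- vapply(seq_along(ranking), function(s) {
    rsm_correlation(
      rsm_from_embedding(B[, ranking[seq_len(s)], drop = FALSE],
                         context = context, seed = seed),
      reference)
  }, numeric(1))
  full_r <- r[length(r)]
  target <- if (relative) fractions * full_r^2 else fractions
  dims_needed <- vapply(target, function(tg) {
    hit <- which(r^2 >= tg)
    if (length(hit) == 0) NA_integer_ else hit[1]
  }, integer(1))
  names(dims_needed) <- as.character(fractions)
  list(r = r, dims_needed = dims_needed, full_r = full_r)
}

#' Fraction of explainable variance
#'
#' Normalises a model-to-data RSM correlation by a noise ceiling: returns
#' `r^2 / noise_ceiling_r2`. The ceiling is supplied by the user (it comes
#' from repeat-measurement consistency of the behavioural data, which this
#' package does not estimate). Values above 1 are possible when the model
#' beats the ceiling estimate and are flagged with a warning.
#'
#' @param r Pearson correlation between model RSM and data RSM.
#' @param noise_ceiling_r2 Maximal explainable variance fraction, in (0, 1].
#' @return Fraction of explainable variance.
#' @export
explainable_variance <- function(r, noise_ceiling_r2) {
  if (noise_ceiling_r2 <= 0) stop("noise ceiling must be positive")
  stopifnot(noise_ceiling_r2 <= 1)
  out <- r^2 / noise_ceiling_r2
  if (any(out > 1)) warning("explained variance exceeds the noise ceiling")
  out
}
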