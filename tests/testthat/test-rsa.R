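test_that("choice-probability RSMs match the naive oracle and its identities", {
  Y <- matrix(1, 5, 3)
  S <- rsm_from_embedding(Y)
  expect_equal(S[upper.tri(S)], rep(1 / 3, 10))
  expect_equal(diag(S), rep(1, 5))

  # m = 3, dot products (ln 2, 0, 0): single context gives S12 = 0.5
  Y <- matrix(c(1, log(2), 0), 3, 1)
  expect_equal(rsm_from_embedding(Y)[1, 2], 0.5)

  Y <- random_rectified(12, 5, seed = 71)
  expect_equal(rsm_from_embedding(Y), naive_rsm(Y), tolerance = 1e-12)

  # symmetric, entries in (0,1), column-permutation invariant
  S <- rsm_from_embedding(Y)
  expect_identical(S, t(S))
  expect_true(all(S[upper.tri(S)] > 0 & S[upper.tri(S)] < 1))
  expect_equal(rsm_from_embedding(Y[, c(4, 2, 5, 1, 3)]), S)

  # no overflow with large dot products
  expect_true(all(is.finite(rsm_from_embedding(Y * 40))))
})

test_that("context subsampling converges to exact enumeration", {
  Y <- random_rectified(30, 4, seed = 72)
  S <- rsm_from_embedding(Y)
  expect_equal(rsm_from_embedding(Y, context = 100), S)  # >= m - 2: exact
  err <- function(n_ctx) {
    max(abs(rsm_from_embedding(Y, context = n_ctx, seed = 5) - S))
  }
  expect_lt(err(25), err(4))
})

test_that("RSM correlation uses the upper triangle and detects degeneracy", {
  A <- naive_rsm(random_rectified(7, 3, seed = 73))
  expect_equal(rsm_correlation(A, A), 1)
  expect_equal(rsm_correlation(A, 0.2 + 3 * A), 1)

  # hand Pearson on the 6 upper-triangle values of a 4x4 pair
  ua <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6)
  ub <- c(0.3, 0.1, 0.4, 0.2, 0.6, 0.5)
  A <- diag(4); B <- diag(4)
  A[upper.tri(A)] <- ua; A <- A + t(A) - diag(diag(A))
  B[upper.tri(B)] <- ub; B <- B + t(B) - diag(diag(B))
  hand <- sum((ua - mean(ua)) * (ub - mean(ub))) /
    sqrt(sum((ua - mean(ua))^2) * sum((ub - mean(ub))^2))
  expect_equal(rsm_correlation(A, B), hand)

  expect_error(rsm_correlation(matrix(1, 3, 3), A[1:3, 1:3]), "variance")
})

test_that("dimension matching recovers permutations and honours uniqueness", {
  set.seed(74)
  A <- matrix(rexp(30 * 4), 30, 4)
  B <- A[, c(2, 4, 1, 3)]
  mt <- match_dimensions(A, B, unique = TRUE)
  expect_equal(mt$r, rep(1, 4))
  expect_equal(mt$dim_b[order(mt$dim_a)], c(3, 1, 4, 2))  # inverse permutation

  # duplicated target column: reusable without uniqueness, not with
  B2 <- cbind(A[, 1], A[, 1], A[, 3])
  free <- match_dimensions(A[, c(1, 2)], B2, unique = FALSE)
  expect_true(any(duplicated(free$dim_b)) || nrow(free) < 2 ||
                free$dim_b[1] %in% c(1, 2))
  A12 <- cbind(A[, 1], A[, 1] + rnorm(30, 0, 0.01))
  both_want_1 <- match_dimensions(A12, B2, unique = FALSE)
  expect_true(all(both_want_1$dim_b %in% c(1, 2)))
  uniq <- match_dimensions(A12, B2, unique = TRUE)
  expect_false(any(duplicated(uniq$dim_b)))
})

test_that("greedy matching equals exhaustive search on a small instance", {
  set.seed(75)
  A <- matrix(runif(6 * 4), 6, 4)
  B <- matrix(runif(6 * 5), 6, 5)
  greedy <- match_dimensions(A, B, unique = TRUE)

  # exhaustive: over all injective assignments, the sorted-|r| sequence that
  # is lexicographically maximal
  cm <- abs(cor(A, B))
  best_seq <- NULL
  for (perm in combinat_permn(5, 4)) {
    v <- sort(cm[cbind(1:4, perm)], decreasing = TRUE)
    if (is.null(best_seq) || lex_gt(v, best_seq)) best_seq <- v
  }
  expect_equal(sort(abs(greedy$r), decreasing = TRUE), best_seq,
               tolerance = 1e-12)
})

test_that("unique matching never beats free matching for any source dimension", {
  set.seed(76)
  A <- matrix(rexp(25 * 6), 25, 6)
  B <- matrix(rexp(25 * 4), 25, 4)
  free <- match_dimensions(A, B, unique = FALSE)
  uniq <- match_dimensions(A, B, unique = TRUE)
  merged <- merge(free, uniq, by = "dim_a", suffixes = c("_free", "_uniq"))
  expect_true(all(abs(merged$r_uniq) <= abs(merged$r_free) + 1e-12))
})

test_that("cumulative RSA reaches the full-embedding correlation and counts dims", {
  set.seed(77)
  Y <- matrix(rexp(40 * 6) * rbinom(40 * 6, 1, 0.5), 40, 6)
  ref <- rsm_from_embedding(Y)
  cum <- cumulative_rsa(Y, ref)
  expect_equal(cum$full_r, rsm_correlation(rsm_from_embedding(Y), ref),
               tolerance = 1e-12)
  expect_equal(cum$full_r, 1)

  # reference planted from the single top dimension
  ranking <- order(colSums(Y), decreasing = TRUE)
  ref1 <- rsm_from_embedding(Y[, ranking[1], drop = FALSE])
  cum1 <- cumulative_rsa(Y, ref1, ranking, fractions = 0.95)
  expect_equal(cum1$r[1], 1)
  expect_equal(unname(cum1$dims_needed), 1L)
})

test_that("explainable variance normalises by the noise ceiling", {
  expect_equal(explainable_variance(sqrt(0.8), 0.8), 1)
  expect_equal(explainable_variance(0, 0.5), 0)
  expect_equal(explainable_variance(sqrt(0.5), 0.8), 0.625)
  expect_warning(ev <- explainable_variance(0.95, 0.8), "ceiling")
  expect_gt(ev, 1)
  expect_error(explainable_variance(0.5, 0), "positive")
})
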