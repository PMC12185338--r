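test_that("planted embeddings honour sparsity, positivity and the seed", {
  dense <- generate_embedding(20, 4, sparsity = 0, seed = 91)
  expect_true(all(dense > 0))
  expect_identical(generate_embedding(30, 5, 0.5, seed = 92),
                   generate_embedding(30, 5, 0.5, seed = 92))

  Y <- generate_embedding(1000, 5, sparsity = 0.7, seed = 93)
  p_hat <- mean(Y == 0)
  se <- sqrt(0.7 * 0.3 / length(Y))
  expect_lt(abs(p_hat - 0.7), 3 * se)
  expect_true(all(colSums(Y) > 0))  # no empty dimension
})

test_that("features inherit the planted similarity structure", {
  Y <- generate_embedding(15, 3, sparsity = 0.4, seed = 94)
  tr <- ground_truth(Y, loading = diag(3), noise_sd = 0, seed = 94)
  expect_warning(X <- generate_features(tr, 3), "d < 2k")
  expect_equal(X, Y, ignore_attr = TRUE)

  # orthogonal equal-norm loading: feature-space choices match embedding-space
  L <- rbind(diag(3), diag(3)) * 1.7
  tr <- ground_truth(Y, loading = L, noise_sd = 0, seed = 94)
  X <- generate_features(tr, 6)
  trips <- sample_triplets(15, 300, seed = 95)
  expect_identical(simulate_choices(X, trips)$odd,
                   simulate_choices(Y, trips)$odd)
})

test_that("noise erodes the agreement between features and the planted truth", {
  Y <- generate_embedding(30, 4, sparsity = 0.3, seed = 96)
  trips <- sample_triplets(30, 3000, seed = 97)
  base <- simulate_choices(Y, trips)$odd
  agree <- vapply(c(0, 0.5, 2.5), function(ns) {
    tr <- ground_truth(Y, noise_sd = ns, seed = 96)
    X <- generate_features(tr, 8)
    mean(simulate_choices(X, trips)$odd == base)
  }, numeric(1))
  # block loadings with unequal feature weights flip a few near-tied choices
  # even at zero noise, so agreement starts high but below 1
  expect_true(all(diff(agree) < 0))
  expect_gt(agree[1], 0.85)
})

test_that("softmax choice generation approaches argmax as temperature drops", {
  Y <- generate_embedding(25, 4, sparsity = 0, seed = 98)  # dense: no ties
  hard <- simulate_dataset(ground_truth(Y, seed = 98), 1000, "argmax", seed = 99)
  cold <- simulate_dataset(ground_truth(Y, seed = 98), 1000, "softmax",
                           temperature = 1e-6, seed = 99)
  expect_gt(mean(hard$odd == cold$odd), 0.995)

  # argmax mode IS simulate_choices on the planted embedding
  trips <- sample_triplets(25, 500, seed = 100)
  expect_identical(simulate_dataset(ground_truth(Y, seed = 98), 500,
                                    "argmax", seed = 100)$odd,
                   simulate_choices(Y, trips)$odd)
})

test_that("softmax choices are uniform when all objects are identical", {
  Y <- matrix(1, 6, 3)
  dat <- simulate_dataset(ground_truth(Y, seed = 1), 3000, "softmax", seed = 2)
  freq <- c(mean(dat$odd == dat$i), mean(dat$odd == dat$j),
            mean(dat$odd == dat$k))
  se <- sqrt((1 / 3) * (2 / 3) / 3000)
  expect_true(all(abs(freq - 1 / 3) <= 3 * se))
})

test_that("recovery reports are exact for the truth and null for noise", {
  Y <- generate_embedding(200, 6, sparsity = 0.5, seed = 101)
  self <- recovery_report(Y, Y)
  expect_equal(self$min_r, 1)
  expect_equal(self$dim_difference, 0)

  scrambled <- Y[, c(3, 1, 2, 6, 4, 5)] %*% diag(c(2, 5, 0.1, 1, 3, 9))
  expect_equal(recovery_report(Y, scrambled)$min_r, 1)

  set.seed(102)
  null <- recovery_report(Y, matrix(runif(200 * 6), 200, 6))
  expect_lt(null$median_r, 0.3)
})
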