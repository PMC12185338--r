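test_that("rectification clamps negatives and preserves shape", {
  expect_equal(rectify(matrix(c(-1, 0, 2, 3), 2, 2)),
               matrix(c(0, 0, 2, 3), 2, 2))
  x <- matrix(runif(12), 3, 4)
  expect_identical(rectify(x), x)
  expect_equal(rectify(-x), matrix(0, 3, 4))
  expect_error(rectify(matrix(c(1, NA), 1, 2)), "missing")
})

test_that("pair similarity is the raw dot product", {
  f <- rbind(c(1, 0), c(0, 1), c(1, 2), c(3, 1), c(2, 2))
  expect_equal(pair_similarity(f, 1, 2), 0)
  expect_equal(pair_similarity(f, 3, 4), 5)
  expect_equal(pair_similarity(f, 4, 3), 5)
  expect_equal(pair_similarity(f, 5, 5), 8)
  expect_error(pair_similarity(f, 1, 6), "out of range")
})

test_that("odd-one-out picks the most similar pair, ties lexicographically", {
  f <- rbind(c(1, 0), c(1, 0), c(0, 1))
  ch <- odd_one_out(f, c(1, 2, 3))
  expect_equal(ch$pair, c(1, 2))
  expect_equal(ch$odd_one_out, 3)
  expect_false(ch$tie)

  # S12 = 2, S13 = 0, S23 = 2: tie between pairs (1,2) and (2,3)
  f <- rbind(c(2, 0), c(1, 1), c(0, 2))
  ch <- odd_one_out(f, c(1, 2, 3))
  expect_equal(ch$pair, c(1, 2))
  expect_equal(ch$odd_one_out, 3)
  expect_true(ch$tie)
})

test_that("choices are invariant to triplet permutation and positive scaling", {
  f <- random_rectified(15, 6, seed = 7)
  set.seed(8)
  for (rep in 1:25) {
    t <- sample(15, 3)
    base <- odd_one_out(f, sort(t))
    expect_equal(odd_one_out(f, t)$odd_one_out, base$odd_one_out)
    expect_equal(odd_one_out(f * 3.7, t)$odd_one_out, base$odd_one_out)
  }
})

test_that("triplet sampling is canonical, reproducible and uniform", {
  t5 <- sample_triplets(3, 5, seed = 1)
  expect_equal(unname(t5), matrix(rep(c(1L, 2L, 3L), each = 5), 5, 3))

  a <- sample_triplets(50, 200, seed = 9)
  b <- sample_triplets(50, 200, seed = 9)
  expect_identical(a, b)
  expect_true(all(a[, 1] < a[, 2] & a[, 2] < a[, 3]))

  # per-object inclusion ~ Binomial(n, 3/m): all counts within 3 SE
  m <- 100; n <- 1e5
  trips <- sample_triplets(m, n, seed = 11)
  counts <- tabulate(as.vector(trips), nbins = m)
  p <- 3 / m
  se <- sqrt(n * p * (1 - p))
  expect_true(all(abs(counts - n * p) <= 3 * se))
})

test_that("simulated choices match a brute-force oracle record-by-record", {
  f <- random_rectified(20, 8, seed = 3)
  trips <- sample_triplets(20, 100, seed = 4)
  dat <- simulate_choices(f, trips)
  expect_equal(nrow(dat), 100)
  for (s in seq_len(nrow(dat))) {
    expect_equal(dat$odd[s], brute_force_choice(f, trips[s, ]))
  }
  validate_triplet_dataset(dat, m = 20)
})

test_that("degenerate similarities resolve deterministically and ties are logged", {
  f <- diag(5)  # one-hot rows: every dot product 0
  trips <- sample_triplets(5, 20, seed = 2)
  dat <- simulate_choices(f, trips)
  expect_equal(attr(dat, "n_ties"), 20L)
  expect_equal(dat$odd, dat$k)  # lexicographic rule keeps pair (i, j)
  expect_equal(nrow(simulate_choices(f, trips[0, , drop = FALSE])), 0)
})

test_that("triplet and feature files round-trip with 0-based storage", {
  d <- withr::local_tempdir()
  f <- random_rectified(6, 3, seed = 5)
  rownames(f) <- sprintf("o%d", 1:6)
  p <- file.path(d, "feat.tsv")
  write_features(f, p)
  expect_equal(read_features(p), f)

  dat <- simulate_choices(f, sample_triplets(6, 10, seed = 6))
  tp <- file.path(d, "trips.tsv")
  write_triplets(dat, tp)
  back <- read_triplets(tp)
  expect_equal(back$i, dat$i)
  expect_equal(back$odd, dat$odd)
  raw <- read.delim(tp)
  expect_equal(min(raw$i), min(dat$i) - 1L)  # 0-based on disk

  emb <- matrix(runif(12), 4, 3,
                dimnames = list(paste0("obj", 1:4), paste0("d", 1:3)))
  ep <- file.path(d, "emb.tsv")
  write_embedding(emb, ep)
  expect_equal(read_embedding(ep), emb)
})
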