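# The variational embedding model: likelihood, sampling, objective, pruning,
# training determinism.

make_emb <- function(mu, sigma = matrix(0.5, nrow(mu), ncol(mu))) {
  variational_embedding(mu, sigma)
}

test_that("triplet choice probabilities are a softmax over pair dot products", {
  Y <- rbind(c(1, 1), c(1, 1), c(1, 1))
  expect_equal(unname(triplet_choice_probs(Y, c(1, 2, 3))), rep(1 / 3, 3))

  # dot products (ln 2, 0, 0) -> (0.5, 0.25, 0.25)
  Y <- matrix(c(1, log(2), 0), 3, 1)
  expect_equal(unname(triplet_choice_probs(Y, c(1, 2, 3))),
               c(0.5, 0.25, 0.25))

  # appending a constant column shifts all dot products equally: no change
  Y <- random_rectified(6, 4, seed = 21)
  Y2 <- cbind(Y, 1.3)
  for (t in list(c(1, 2, 3), c(2, 4, 6))) {
    expect_equal(unname(triplet_choice_probs(Y2, t)),
                 unname(triplet_choice_probs(Y, t)))
  }
})

test_that("choice probabilities sum to 1 and permute with the triplet", {
  Y <- random_rectified(10, 5, seed = 22)
  set.seed(23)
  for (rep in 1:20) {
    t <- sample(10, 3)
    p <- triplet_choice_probs(Y, t)
    expect_equal(sum(p), 1)
    expect_equal(p, triplet_choice_probs(Y, rev(t)))
  }
})

test_that("posterior weight samples are reparameterised and rectified", {
  mu <- matrix(c(-1, 0.5, 2, -0.2), 2, 2)
  emb <- variational_embedding(mu, matrix(1e-12, 2, 2))
  expect_equal(sample_weights(emb, seed = 1), rectify(mu),
               ignore_attr = TRUE)

  emb <- make_emb(matrix(runif(20), 4, 5))
  expect_identical(sample_weights(emb, seed = 3), sample_weights(emb, seed = 3))

  # pre-rectification draws are centred on mu (Monte-Carlo, 4 SE)
  n <- 1e5
  emb <- variational_embedding(matrix(0.3, n, 1), matrix(0.7, n, 1))
  w <- sample_weights(emb, seed = 4, rectified = FALSE)
  expect_lt(abs(mean(w) - 0.3), 4 * 0.7 / sqrt(n))
})

test_that("the complexity term vanishes when the posterior equals the prior", {
  # single-Gaussian prior (spike sd = slab sd) matched to q with mu = 0
  prior <- prior_spec(pi = 0.5, sigma_spike = 0.5, sigma_slab = 0.5)
  emb <- variational_embedding(matrix(0, 4, 3), matrix(0.5, 4, 3))
  batch <- data.frame(i = 1, j = 2, k = 3, odd = 3)
  loss <- elbo_loss(emb, prior, batch, n_total = 100)
  expect_equal(loss$complexity, 0)
})

test_that("the likelihood term equals ln 3 under uninformative weights", {
  emb <- variational_embedding(matrix(1, 6, 2), matrix(1e-12, 6, 2))
  batch <- simulate_choices(matrix(1, 6, 2), sample_triplets(6, 30, seed = 5))
  loss <- elbo_loss(emb, prior_spec(), batch, n_total = 30)
  expect_equal(loss$nll, log(3))
})

test_that("Monte-Carlo complexity matches closed-form Gaussian KL", {
  # q = N(mu, s^2), p = N(0, sp^2): KL = log(sp/s) + (s^2 + mu^2)/(2 sp^2) - 1/2
  mu <- 0.4; s <- 0.3; sp <- 0.8
  n <- 1e5
  emb <- variational_embedding(matrix(mu, n, 1), matrix(s, n, 1))
  prior <- prior_spec(pi = 0.5, sigma_spike = sp, sigma_slab = sp)
  batch <- data.frame(i = 1, j = 2, k = 3, odd = 3)
  set.seed(6)
  loss <- elbo_loss(emb, prior, batch, n_total = n)  # mean over n iid entries
  kl <- log(sp / s) + (s^2 + mu^2) / (2 * sp^2) - 0.5
  # SE of a single-sample log-ratio term, computed by direct simulation
  set.seed(7)
  w <- rnorm(n, mu, s)
  terms <- dnorm(w, mu, s, log = TRUE) - dnorm(w, 0, sp, log = TRUE)
  expect_lt(abs(loss$complexity - kl), 3 * sd(terms) / sqrt(n))
})

test_that("posterior positivity probabilities follow the normal CDF", {
  sig <- matrix(c(0.2, 1, 3), 1, 3)
  emb <- variational_embedding(matrix(0, 1, 3), sig)
  expect_equal(unname(posterior_prob_positive(emb)), matrix(0.5, 1, 3))
  emb <- variational_embedding(1.6449 * sig, sig)
  expect_equal(unname(posterior_prob_positive(emb)),
               matrix(0.95, 1, 3), tolerance = 1e-4)
  emb <- variational_embedding(-1.6449 * sig, sig)
  expect_equal(unname(posterior_prob_positive(emb)),
               matrix(0.05, 1, 3), tolerance = 1e-4)
})

test_that("pruning keeps exactly the dimensions with enough posterior support", {
  m <- 20
  sigma <- matrix(0.1, m, 4)
  mu <- matrix(-1, m, 4)
  mu[1:10, 1] <- 1           # 10 supporting objects: kept
  mu[1:5, 2] <- 1            # exactly min_objects: kept (boundary)
  mu[1:4, 3] <- 1            # one short: pruned
  # dim 4: mu << 0 everywhere: pruned
  emb <- variational_embedding(mu, sigma)
  pruned <- prune_dimensions(emb, threshold = 0.05, min_objects = 5)
  expect_equal(pruned$active_dims, c(1L, 2L))
  expect_equal(prune_dimensions(pruned), pruned)  # idempotent

  all_dead <- variational_embedding(matrix(-1, m, 2), matrix(0.1, m, 2))
  expect_error(prune_dimensions(all_dead), "every dimension")
})

test_that("the point estimate is the rectified mean, heaviest column first", {
  mu <- cbind(c(-1, -2, -0.5), c(1, 1, 1), c(0.5, 0, 0))
  emb <- variational_embedding(mu, matrix(1, 3, 3))
  y <- point_estimate(emb)
  expect_true(all(y >= 0))
  expect_equal(unname(y[, 1]), c(1, 1, 1))     # column sum 3 first
  expect_equal(unname(y[, 2]), c(0.5, 0, 0))   # then 0.5
  expect_equal(unname(y[, 3]), c(0, 0, 0))     # all-negative column last
  expect_equal(colnames(y), c("dim_002", "dim_003", "dim_001"))
})

test_that("training is a no-op at zero epochs and bit-reproducible by seed", {
  truth <- generate_embedding(12, 3, sparsity = 0.3, seed = 31)
  dat <- simulate_dataset(ground_truth(truth, seed = 31), 400, seed = 32)

  cfg0 <- train_config(p_init = 5, max_epochs = 0, seed = 99)
  init <- vice_train(dat, cfg0, prior_spec(), m = 12)
  set.seed(99)
  expect_equal(unname(init$mu), matrix(rnorm(12 * 5, 0, cfg0$init_mu_sd), 12, 5))
  expect_true(all(init$sigma == cfg0$init_sigma))

  cfg <- train_config(p_init = 5, max_epochs = 6, stability_epochs = 6,
                      prune_interval = 3, seed = 77)
  f1 <- vice_train(dat, cfg, prior_spec(), m = 12)
  f2 <- vice_train(dat, cfg, prior_spec(), m = 12)
  expect_identical(f1$mu, f2$mu)
  expect_identical(f1$sigma, f2$sigma)
  expect_lte(ncol(f1$mu), 5)
})

test_that("training a planted model beats chance on held-out choices", {
  truth <- generate_embedding(25, 4, sparsity = 0.5, seed = 41)
  dat <- simulate_dataset(ground_truth(truth, seed = 41), 6000, seed = 42)
  cfg <- train_config(p_init = 8, max_epochs = 120, stability_epochs = 80,
                      prune_interval = 20, seed = 43)
  fit <- vice_train(dat, cfg, prior_spec(), m = 25)
  acc <- utils::tail(fit$trajectory$val_accuracy, 1)
  expect_gt(acc, 1 / 3 + 0.15)
  expect_lte(ncol(point_estimate(fit)), 8)
})
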