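# Independent oracles and fixture builders used across the suite.

# brute-force odd-one-out: explicit enumeration of the three pairwise
# comparisons with plain loops, independent of the package's code path
brute_force_choice <- function(features, t) {
  t <- sort(t)
  cand <- list(c(t[1], t[2]), c(t[1], t[3]), c(t[2], t[3]))
  sims <- numeric(3)
  for (p in 1:3) {
    s <- 0
    for (d in seq_len(ncol(features))) {
      s <- s + features[cand[[p]][1], d] * features[cand[[p]][2], d]
    }
    sims[p] <- s
  }
  best <- which.max(sims)
  setdiff(t, cand[[best]])
}

# naive triple-loop choice-probability RSM (no log-sum-exp; fine for the
# small magnitudes used in tests)
naive_rsm <- function(Y) {
  m <- nrow(Y)
  G <- Y %*% t(Y)
  S <- matrix(1, m, m)
  for (i in 1:(m - 1)) for (j in (i + 1):m) {
    acc <- 0; cnt <- 0
    for (k in 1:m) {
      if (k == i || k == j) next
      acc <- acc + exp(G[i, j]) / (exp(G[i, j]) + exp(G[i, k]) + exp(G[j, k]))
      cnt <- cnt + 1
    }
    S[i, j] <- S[j, i] <- acc / cnt
  }
  S
}

random_rectified <- function(m, d, seed) {
  set.seed(seed)
  rectify(matrix(rnorm(m * d), m, d))
}

# all injective assignments of k source dims to n targets
combinat_permn <- function(n, k) {
  res <- list()
  rec <- function(chosen) {
    if (length(chosen) == k) {
      res[[length(res) + 1]] <<- chosen
      return(invisible())
    }
    for (x in setdiff(seq_len(n), chosen)) rec(c(chosen, x))
  }
  rec(integer(0))
  res
}

lex_gt <- function(a, b) {
  d <- a - b
  nz <- which(abs(d) > 1e-15)
  length(nz) > 0 && d[nz[1]] > 0
}
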