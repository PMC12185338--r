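## Split-half reproducibility of embeddings across training runs, and
## selection of the most reproducible run.

#' Fisher z transform and its inverse
#'
#' `fisher_z()` is `atanh(r)`; `inverse_fisher_z()` is `tanh(z)`. Correlations
#' with `|r| >= 1` (exact duplicates) are clipped to `1 - 1e-7` in magnitude
#' before transforming, with a warning, so that averaging stays finite.
#'
#' @param r Pearson correlation(s).
#' @param z Fisher z value(s).
#' @return Transformed numeric vector.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1, na.rm = TRUE)) {
    warning("|r| >= 1 clipped to 1 - 1e-7 before Fisher z")
    r <- pmin(pmax(r, -1 + 1e-7), 1 - 1e-7)
  }
  atanh(r)
}

#' @rdname fisher_z
#' @export
inverse_fisher_z <- function(z) tanh(z)

## Odd/even object masks over stored order: positions 1, 3, 5, ... and
## 2, 4, 6, ... (matching 0-based positions 0,2,4,... and 1,3,5,...).
split_masks <- function(m) {
  list(odd = seq(2L, m, by = 2L), even = seq(1L, m, by = 2L))
}

#' Split-half reliability of embedding dimensions across runs
#'
#' Objects are partitioned into two disjoint halves by position parity. For
#' each run and each of its dimensions, the best-matching dimension among the
#' pooled dimensions of all *other* runs is found on one half (the odd mask),
#' and the matched pair is then correlated on the held-out half (the even
#' mask). Because matching and scoring use disjoint objects, unrelated runs
#' score near zero rather than inheriting selection bias. Per-run Fisher-z
#' averages of these held-out correlations are back-transformed to r.
#'
#' @param runs List of point-embedding matrices over the same objects in the
#'   same order (>= 2 runs).
#' @return A list with `per_run_r` (mean reliability per run, the selection
#'   criterion), and `per_dimension` (a `data.frame`: run, dimension, matched
#'   run/dimension, and the even-mask r; `NA` where a mask half had zero
#'   variance).
#' @export
split_half_reliability <- function(runs) {
  stopifnot(length(runs) >= 2)
  m <- nrow(runs[[1]])
  if (!all(vapply(runs, nrow, 0L) == m)) stop("all runs must cover the same objects")
  masks <- split_masks(m)

  rows <- list()
  for (r_idx in seq_along(runs)) {
    A <- runs[[r_idx]]
    others <- do.call(cbind, runs[-r_idx])
    other_run <- rep(seq_along(runs)[-r_idx],
                     vapply(runs[-r_idx], ncol, 0L))
    other_dim <- unlist(lapply(runs[-r_idx], function(x) seq_len(ncol(x))))
    ## match on odd mask, score on even mask
    c_odd <- suppressWarnings(cor(A[masks$odd, , drop = FALSE],
                                  others[masks$odd, , drop = FALSE]))
    for (d in seq_len(ncol(A))) {
      cand <- c_odd[d, ]
      if (all(is.na(cand))) {
        warning(sprintf("run %d dim %d: no valid match (zero variance); dropped",
                        r_idx, d))
        rows[[length(rows) + 1]] <- data.frame(
          run = r_idx, dim = d, matched_run = NA_integer_,
          matched_dim = NA_integer_, r = NA_real_)
        next
      }
      best <- which.max(cand)
      r_even <- suppressWarnings(
        cor(A[masks$even, d], others[masks$even, best]))
      if (is.na(r_even)) {
        warning(sprintf("run %d dim %d: zero variance on scoring half; dropped",
                        r_idx, d))
      }
      rows[[length(rows) + 1]] <- data.frame(
        run = r_idx, dim = d, matched_run = other_run[best],
        matched_dim = other_dim[best], r = r_even)
    }
  }
  per_dim <- do.call(rbind, rows)
  per_run_r <- vapply(seq_along(runs), function(r_idx) {
    rs <- per_dim$r[per_dim$run == r_idx]
    rs <- rs[!is.na(rs)]
    if (length(rs) == 0) return(NA_real_)
    inverse_fisher_z(mean(suppressWarnings(fisher_z(rs))))
  }, numeric(1))
  list(per_run_r = per_run_r, per_dimension = per_dim)
}

#' Select the most reproducible run
#'
#' @param runs List of point-embedding matrices (as for
#'   [split_half_reliability()]).
#' @param reliability Optional precomputed result of
#'   [split_half_reliability()].
#' @return Index of the run with the highest mean split-half reliability;
#'   ties resolve to the lowest index.
#' @export
select_best_run <- function(runs, reliability = split_half_reliability(runs)) {
  which.max(reliability$per_run_r)
}
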