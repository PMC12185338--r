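// Mean-field variational trainer for sparse non-negative triplet embeddings.
//
// The model: each object i has a p-dimensional weight row w_i with an
// independent Gaussian variational posterior N(mu_ij, sigma_ij^2) per entry
// and a shared spike-and-slab Gaussian-mixture prior. A reparameterised
// sample W = mu + sigma * eps is rectified to max(W, 0) before entering the
// triplet softmax likelihood; the loss is
//   (1/n) * (log q(W) - log p(W))  -  mean_batch log p(chosen pair | W).
// Gradients are exact pathwise derivatives of that one-sample estimator
// (the direct and pathwise derivatives of log q w.r.t. mu cancel; w.r.t.
// sigma they collapse to -1/sigma, the entropy gradient).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double LOG_2PI = 1.8378770664093454836;

// log prior density and its derivative for the two-Gaussian mixture,
// evaluated entrywise on w.
static void mixture_logp(const arma::mat& w, double pi, double s1, double s2,
                         arma::mat& logp, arma::mat& dlogp) {
  const double v1 = s1 * s1, v2 = s2 * s2;
  const double c1 = std::log(pi) - std::log(s1);
  const double c2 = std::log(1.0 - pi) - std::log(s2);
  logp.set_size(arma::size(w));
  dlogp.set_size(arma::size(w));
  for (arma::uword t = 0; t < w.n_elem; ++t) {
    const double x = w[t];
    const double l1 = c1 - 0.5 * x * x / v1;
    const double l2 = c2 - 0.5 * x * x / v2;
    const double mx = std::max(l1, l2);
    const double e1 = std::exp(l1 - mx), e2 = std::exp(l2 - mx);
    const double z = e1 + e2;
    logp[t] = mx + std::log(z) - 0.5 * LOG_2PI;
    dlogp[t] = (e1 * (-x / v1) + e2 * (-x / v2)) / z;
  }
}

static arma::mat draw_std_normal(arma::uword r, arma::uword c) {
  arma::mat e(r, c);
  for (arma::uword t = 0; t < e.n_elem; ++t) e[t] = norm_rand();
  return e;
}

// softmax over the three pair dot products of rows a, b, c of y
static arma::vec3 triplet_softmax(const arma::rowvec& ya, const arma::rowvec& yb,
                                  const arma::rowvec& yc) {
  arma::vec3 u;
  u[0] = arma::dot(ya, yb);
  u[1] = arma::dot(ya, yc);
  u[2] = arma::dot(yb, yc);
  const double mx = u.max();
  arma::vec3 p = arma::exp(u - mx);
  return p / arma::accu(p);
}

// fraction of triplets whose argmax pair under rectified mu matches the data
static double holdout_accuracy(const arma::mat& mu, const arma::imat& trip,
                               const arma::ivec& choice) {
  if (trip.n_rows == 0) return NA_REAL;
  arma::mat y = arma::clamp(mu, 0.0, arma::datum::inf);
  arma::uword hits = 0;
  for (arma::uword s = 0; s < trip.n_rows; ++s) {
    arma::vec3 p = triplet_softmax(y.row(trip(s, 0)), y.row(trip(s, 1)),
                                   y.row(trip(s, 2)));
    if ((int)p.index_max() == choice[s]) ++hits;
  }
  return (double)hits / trip.n_rows;
}

// [[Rcpp::export]]
List vice_train_cpp(const arma::imat& triplets,   // n x 3, 0-based, sorted
                    const arma::ivec& choice,     // 0,1,2 = pair (ij),(ik),(jk)
                    arma::mat mu, arma::mat sigma, // initial state, m x p
                    double n_total, double kl_weight,
                    double lr, int batch_size, int max_epochs,
                    int stability_epochs, int prune_interval,
                    double prune_threshold, int prune_min_objects,
                    double prior_pi, double s_spike, double s_slab,
                    const arma::imat& val_triplets, const arma::ivec& val_choice) {
  const arma::uword n = triplets.n_rows;
  const arma::uword m = mu.n_rows;
  arma::mat lsig = arma::log(sigma);
  arma::uvec active = arma::regspace<arma::uvec>(0, mu.n_cols - 1);

  // Adam state
  arma::mat m_mu(arma::size(mu), arma::fill::zeros), v_mu = m_mu;
  arma::mat m_ls(arma::size(mu), arma::fill::zeros), v_ls = m_ls;
  const double b1 = 0.9, b2 = 0.999, adam_eps = 1e-8;
  double step = 0;

  std::vector<double> loss_epoch, dims_epoch, val_acc_epoch;
  int last_change = 0, epochs_run = 0;
  bool diverged = false;

  const int n_batches = std::max(1, (int)std::ceil((double)n / batch_size));

  for (int epoch = 1; epoch <= max_epochs && !diverged; ++epoch) {
    IntegerVector perm = Rcpp::sample((int)n, (int)n); // 1-based, R RNG
    double loss_sum = 0; int loss_cnt = 0;

    for (int bi = 0; bi < n_batches; ++bi) {
      const arma::uword lo = (arma::uword)bi * batch_size;
      const arma::uword hi = std::min(n, lo + batch_size);
      const arma::uword B = hi - lo;
      if (B == 0) continue;

      arma::mat sig = arma::exp(lsig);
      arma::mat eps = draw_std_normal(m, mu.n_cols);
      arma::mat w = mu + sig % eps;
      arma::mat y = arma::clamp(w, 0.0, arma::datum::inf);

      // complexity term and gradient
      arma::mat logp, dlogp;
      mixture_logp(w, prior_pi, s_spike, s_slab, logp, dlogp);
      // log q(w) at the sample: -0.5*log(2*pi) - log(sigma) - 0.5*eps^2
      const double logq = -0.5 * LOG_2PI * w.n_elem - arma::accu(lsig)
        - 0.5 * arma::accu(eps % eps);
      const double kl_scale = kl_weight / n_total;
      const double complexity = (logq - arma::accu(logp)) * kl_scale;
      arma::mat gmu = -dlogp * kl_scale;
      arma::mat gsig = (-1.0 / sig - dlogp % eps) * kl_scale;

      // likelihood term
      arma::mat gy(m, mu.n_cols, arma::fill::zeros);
      double nll = 0;
      for (arma::uword s = lo; s < hi; ++s) {
        const arma::uword idx = (arma::uword)perm[s] - 1;
        const int a = triplets(idx, 0), b = triplets(idx, 1), c = triplets(idx, 2);
        arma::vec3 p = triplet_softmax(y.row(a), y.row(b), y.row(c));
        const int ch = choice[idx];
        nll -= std::log(std::max(p[ch], 1e-300));
        arma::vec3 g = p; g[ch] -= 1.0;
        gy.row(a) += (g[0] * y.row(b) + g[1] * y.row(c)) / B;
        gy.row(b) += (g[0] * y.row(a) + g[2] * y.row(c)) / B;
        gy.row(c) += (g[1] * y.row(a) + g[2] * y.row(b)) / B;
      }
      nll /= B;

      const double loss = complexity + nll;
      if (!std::isfinite(loss)) { diverged = true; break; }
      loss_sum += loss; ++loss_cnt;

      arma::mat gw = gy % (w > 0);
      gmu += gw;
      gsig += gw % eps;
      arma::mat gls = gsig % sig; // chain rule through sigma = exp(lsig)

      // Adam update
      ++step;
      const double bc1 = 1.0 - std::pow(b1, step);
      const double bc2 = 1.0 - std::pow(b2, step);
      m_mu = b1 * m_mu + (1 - b1) * gmu;
      v_mu = b2 * v_mu + (1 - b2) * (gmu % gmu);
      mu -= lr * (m_mu / bc1) / (arma::sqrt(v_mu / bc2) + adam_eps);
      m_ls = b1 * m_ls + (1 - b1) * gls;
      v_ls = b2 * v_ls + (1 - b2) * (gls % gls);
      lsig -= lr * (m_ls / bc1) / (arma::sqrt(v_ls / bc2) + adam_eps);
    }

    epochs_run = epoch;
    loss_epoch.push_back(loss_cnt ? loss_sum / loss_cnt : NA_REAL);
    dims_epoch.push_back((double)mu.n_cols);
    if (diverged) break;

    // dimension pruning on a fixed cadence: a dimension survives iff at
    // least prune_min_objects objects have Pr(w_ij > 0) >= 1 - threshold
    if (prune_interval > 0 && epoch % prune_interval == 0) {
      arma::mat sig = arma::exp(lsig);
      arma::mat q = 0.5 * arma::erfc(-(mu / sig) / std::sqrt(2.0));
      arma::urowvec support = arma::sum(q >= (1.0 - prune_threshold), 0);
      arma::uvec keep = arma::find(support >= (arma::uword)prune_min_objects);
      // a checkpoint that would remove everything is skipped: early in
      // training no dimension has accumulated support yet
      if (keep.n_elem > 0 && keep.n_elem < mu.n_cols) {
        mu = mu.cols(keep); lsig = lsig.cols(keep);
        m_mu = m_mu.cols(keep); v_mu = v_mu.cols(keep);
        m_ls = m_ls.cols(keep); v_ls = v_ls.cols(keep);
        active = active.elem(keep);
        last_change = epoch;
      }
      val_acc_epoch.push_back(holdout_accuracy(mu, val_triplets, val_choice));
      if (epoch - last_change >= stability_epochs) break;
    }
    Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["mu"] = mu,
    _["sigma"] = arma::exp(lsig),
    _["active_dims"] = arma::conv_to<arma::ivec>::from(active) + 1,
    _["loss"] = loss_epoch,
    _["dims"] = dims_epoch,
    _["val_accuracy"] = val_acc_epoch,
    _["epochs"] = epochs_run,
    _["diverged"] = diverged);
}
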