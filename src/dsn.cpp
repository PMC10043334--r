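// Deep stacking network of adaptive-kernel convolution modules.
//
// One module per input series: n_filters (six) 1 x filter_width filters
// (+bias) are convolved with the input's recent past to produce a
// per-timestep hidden vector, a PReLU (one slope per filter) turns it into
// an input-dependent kernel of length n_filters, and that kernel is dotted
// with the input's past n_filters samples. Module outputs are combined by
// a learned element-wise weighted sum. Trained with minibatch Adam on mean
// squared error with early stopping on a validation split. All randomness
// (init, split, shuffling) comes from one RNG seeded by the caller, so
// results are reproducible bit-for-bit.
//
// The minibatch loop is written with flat preallocated buffers: these
// models are trained once per (region pair, fold), so thousands of runs
// per cohort make allocation churn the dominant cost otherwise.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Module {
  std::vector<double> W;      // nf x fw, row-major [k*fw + j]
  std::vector<double> b;      // nf
  std::vector<double> alpha;  // nf
};

struct Opt {  // Adam first/second moments, same layout as Module
  std::vector<double> mW, vW, mb, vb, ma, va;
};

inline void adam1(double& p, double& m, double& v, double g,
                  double lr, double b1, double b2, double eps,
                  double bc1, double bc2) {
  m = b1 * m + (1.0 - b1) * g;
  v = b2 * v + (1.0 - b2) * g * g;
  p -= lr * (m / bc1) / (std::sqrt(v / bc2) + eps);
}

// predictions for rows [i0, i1) of X (N x L, col-major) without buffers
void predict_block(const std::vector<const double*>& Xcols_all,
                   const std::vector<Module>& ps, int nf, int fw,
                   const std::vector<double>& cw, double c0,
                   const uword* rows, uword n, double* out) {
  const int M = static_cast<int>(ps.size());
  for (uword i = 0; i < n; ++i) out[i] = c0;
  for (int m = 0; m < M; ++m) {
    const double* const* Xc = &Xcols_all[m * 12];  // up to 12 lag columns
    const Module& P = ps[m];
    const double c = cw[m];
    for (uword i = 0; i < n; ++i) {
      const uword r = rows[i];
      double ym = 0.0;
      for (int k = 0; k < nf; ++k) {
        double h = P.b[k];
        for (int j = 0; j < fw; ++j) h += P.W[k * fw + j] * Xc[j][r];
        double a = (h >= 0.0) ? h : P.alpha[k] * h;
        ym += a * Xc[k][r];
      }
      out[i] += c * ym;
    }
  }
}

} // namespace

// Train a DSN mapping M lagged input series to a target; returns MSEs.
// train_lags / eval_lags: list of M matrices (N x L), column j = lag j+1,
// with L >= max(n_filters, filter_width).
// [[Rcpp::export]]
Rcpp::List cpp_dsn_fit(Rcpp::List train_lags, arma::vec train_y,
                       Rcpp::List eval_lags, arma::vec eval_y,
                       int n_filters, int filter_width,
                       double lr, double beta1, double beta2,
                       int n_epochs, int patience, int batch_size,
                       double val_frac, int seed) {
  const int M = train_lags.size();
  const int nf = n_filters, fw = filter_width;
  const int L = std::max(nf, fw);
  if (L > 12) Rcpp::stop("at most 12 lags supported");
  std::vector<mat> Xall(M), Xev(M);
  for (int m = 0; m < M; ++m) {
    Xall[m] = Rcpp::as<mat>(train_lags[m]);
    Xev[m]  = Rcpp::as<mat>(eval_lags[m]);
    if (static_cast<int>(Xall[m].n_cols) < L)
      Rcpp::stop("lag matrices need at least max(n_filters, filter_width) columns");
  }
  const uword N = Xall[0].n_rows;
  if (!train_y.is_finite()) Rcpp::stop("non-finite values in training target");

  // column pointer tables for allocation-free row gathering
  std::vector<const double*> Xcols(M * 12, nullptr), Evcols(M * 12, nullptr);
  for (int m = 0; m < M; ++m)
    for (int j = 0; j < L; ++j) {
      Xcols[m * 12 + j] = Xall[m].colptr(j);
      Evcols[m * 12 + j] = Xev[m].colptr(j);
    }

  std::mt19937 rng(static_cast<uint32_t>(seed));
  std::normal_distribution<double> rnorm(0.0, 1.0);

  // validation split
  std::vector<uword> perm(N);
  for (uword i = 0; i < N; ++i) perm[i] = i;
  std::shuffle(perm.begin(), perm.end(), rng);
  uword n_val = (patience > 0) ? static_cast<uword>(std::floor(val_frac * N)) : 0;
  if (n_val > 0 && n_val < 2) n_val = 2;
  const uword n_tr = N - n_val;
  std::vector<uword> tr_idx(perm.begin(), perm.begin() + n_tr);
  std::vector<uword> va_idx(perm.begin() + n_tr, perm.end());

  // init: small random filters/biases, PReLU slope 0.25, uniform combination
  std::vector<Module> ps(M);
  std::vector<Opt> st(M);
  for (int m = 0; m < M; ++m) {
    ps[m].W.resize(nf * fw); ps[m].b.resize(nf); ps[m].alpha.assign(nf, 0.25);
    for (int k = 0; k < nf; ++k) {
      for (int j = 0; j < fw; ++j) ps[m].W[k * fw + j] = 0.2 * rnorm(rng);
      ps[m].b[k] = 0.2 * rnorm(rng);
    }
    st[m].mW.assign(nf * fw, 0.0); st[m].vW.assign(nf * fw, 0.0);
    st[m].mb.assign(nf, 0.0); st[m].vb.assign(nf, 0.0);
    st[m].ma.assign(nf, 0.0); st[m].va.assign(nf, 0.0);
  }
  std::vector<double> cw(M, 1.0 / M);
  double c0 = 0.0;
  std::vector<double> m_cw(M, 0.0), v_cw(M, 0.0);
  double m_c0 = 0.0, v_c0 = 0.0;
  const double eps = 1e-8;

  std::vector<Module> best_ps = ps;
  std::vector<double> best_cw = cw;
  double best_c0 = c0, best_val = datum::inf;
  int bad_epochs = 0, epochs_run = 0;
  double tstep = 0.0;

  std::vector<uword> order(tr_idx);
  const int B = batch_size;
  // per-batch work buffers, laid out [module][k or sample]
  std::vector<double> yhat(B), g(B);
  std::vector<double> Hbuf(static_cast<size_t>(M) * B * nf);
  std::vector<double> Ybuf(static_cast<size_t>(M) * B);
  std::vector<double> gW(nf * fw), gb(nf), ga(nf);

  for (int ep = 0; ep < n_epochs; ++ep) {
    epochs_run = ep + 1;
    std::shuffle(order.begin(), order.end(), rng);
    for (uword start = 0; start < n_tr; start += B) {
      const uword nb = std::min<uword>(B, n_tr - start);
      const uword* rows = &order[start];

      // forward
      for (uword i = 0; i < nb; ++i) yhat[i] = c0;
      for (int m = 0; m < M; ++m) {
        const double* const* Xc = &Xcols[m * 12];
        const Module& P = ps[m];
        double* H = &Hbuf[static_cast<size_t>(m) * B * nf];
        double* Ym = &Ybuf[static_cast<size_t>(m) * B];
        const double c = cw[m];
        for (uword i = 0; i < nb; ++i) {
          const uword r = rows[i];
          double ym = 0.0;
          for (int k = 0; k < nf; ++k) {
            double h = P.b[k];
            for (int j = 0; j < fw; ++j) h += P.W[k * fw + j] * Xc[j][r];
            H[i * nf + k] = h;
            const double a = (h >= 0.0) ? h : P.alpha[k] * h;
            ym += a * Xc[k][r];
          }
          Ym[i] = ym;
          yhat[i] += c * ym;
        }
      }

      double bad = 0.0;
      for (uword i = 0; i < nb; ++i) {
        g[i] = (2.0 / nb) * (yhat[i] - train_y(rows[i]));
        bad += g[i];
      }
      if (!std::isfinite(bad)) Rcpp::stop("training diverged (non-finite loss)");
      tstep += 1.0;
      const double bc1 = 1.0 - std::pow(beta1, tstep);
      const double bc2 = 1.0 - std::pow(beta2, tstep);

      // backward + updates (modules first: they need the pre-update cw)
      for (int m = 0; m < M; ++m) {
        const double* const* Xc = &Xcols[m * 12];
        Module& P = ps[m];
        Opt& O = st[m];
        const double* H = &Hbuf[static_cast<size_t>(m) * B * nf];
        const double c = cw[m];
        std::fill(gW.begin(), gW.end(), 0.0);
        std::fill(gb.begin(), gb.end(), 0.0);
        std::fill(ga.begin(), ga.end(), 0.0);
        for (uword i = 0; i < nb; ++i) {
          const uword r = rows[i];
          const double dy = c * g[i];
          for (int k = 0; k < nf; ++k) {
            const double h = H[i * nf + k];
            const double dA = dy * Xc[k][r];
            double dH;
            if (h >= 0.0) dH = dA;
            else { dH = dA * P.alpha[k]; ga[k] += dA * h; }
            gb[k] += dH;
            for (int j = 0; j < fw; ++j) gW[k * fw + j] += dH * Xc[j][r];
          }
        }
        for (int k = 0; k < nf; ++k) {
          for (int j = 0; j < fw; ++j)
            adam1(P.W[k * fw + j], O.mW[k * fw + j], O.vW[k * fw + j],
                  gW[k * fw + j], lr, beta1, beta2, eps, bc1, bc2);
          adam1(P.b[k], O.mb[k], O.vb[k], gb[k], lr, beta1, beta2, eps, bc1, bc2);
          adam1(P.alpha[k], O.ma[k], O.va[k], ga[k], lr, beta1, beta2, eps,
                bc1, bc2);
        }
      }
      for (int m = 0; m < M; ++m) {
        const double* Ym = &Ybuf[static_cast<size_t>(m) * B];
        double gc = 0.0;
        for (uword i = 0; i < nb; ++i) gc += g[i] * Ym[i];
        adam1(cw[m], m_cw[m], v_cw[m], gc, lr, beta1, beta2, eps, bc1, bc2);
      }
      double gc0 = 0.0;
      for (uword i = 0; i < nb; ++i) gc0 += g[i];
      adam1(c0, m_c0, v_c0, gc0, lr, beta1, beta2, eps, bc1, bc2);
    }

    if (n_val > 0) {
      std::vector<double> yv(n_val);
      predict_block(Xcols, ps, nf, fw, cw, c0, va_idx.data(), n_val, yv.data());
      double vmse = 0.0;
      for (uword i = 0; i < n_val; ++i) {
        const double d = yv[i] - train_y(va_idx[i]);
        vmse += d * d;
      }
      vmse /= n_val;
      if (!std::isfinite(vmse)) Rcpp::stop("training diverged (non-finite loss)");
      if (vmse < best_val - 1e-12) {
        best_val = vmse; best_ps = ps; best_cw = cw; best_c0 = c0;
        bad_epochs = 0;
      } else if (++bad_epochs >= patience) break;
    }
  }
  if (n_val > 0) { ps = best_ps; cw = best_cw; c0 = best_c0; }

  // final training and held-out evaluation errors
  std::vector<uword> all_tr(tr_idx);
  std::vector<double> yhat_tr(n_tr);
  predict_block(Xcols, ps, nf, fw, cw, c0, all_tr.data(), n_tr, yhat_tr.data());
  double train_mse = 0.0;
  for (uword i = 0; i < n_tr; ++i) {
    const double d = yhat_tr[i] - train_y(all_tr[i]);
    train_mse += d * d;
  }
  train_mse /= n_tr;

  const uword Ne = Xev[0].n_rows;
  std::vector<uword> ev_rows(Ne);
  for (uword i = 0; i < Ne; ++i) ev_rows[i] = i;
  std::vector<double> yhat_ev(Ne);
  predict_block(Evcols, ps, nf, fw, cw, c0, ev_rows.data(), Ne, yhat_ev.data());
  double eval_mse = 0.0;
  for (uword i = 0; i < Ne; ++i) {
    const double d = yhat_ev[i] - eval_y(i);
    eval_mse += d * d;
  }
  eval_mse /= Ne;

  return Rcpp::List::create(
      Rcpp::Named("eval_mse") = eval_mse,
      Rcpp::Named("train_mse") = train_mse,
      Rcpp::Named("val_mse") = (n_val > 0) ? best_val : NA_REAL,
      Rcpp::Named("epochs_run") = epochs_run);
}
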