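// Native training core for the strain-regression CNN.
//
// The network is a stack of "full-height" valid convolutions over the
// temporal axis (each kernel spans every row/channel of its input map),
// followed by flatten -> dropout -> fully connected layers, with rectified
// linear activations everywhere including the output.  Convolutions are
// realized as gather (im2col) + BLAS matrix products; their backward pass is
// the corresponding scatter-add.  Optimization is Adam on mini-batch MSE
// with validation-based early stopping (best weights restored).
//
// Arithmetic is single precision internally (the convention in deep-learning
// training; halves the BLAS cost); weights cross the R boundary as doubles.
// All randomness (mini-batch order, dropout masks) comes from a mt19937
// seeded from R, so runs are reproducible for a given seed.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Geometry {
  int n_conv;
  std::vector<std::vector<uvec>> idx;  // [layer][out position] gather indices
  std::vector<int> out_w;              // output width per conv layer
  std::vector<int> in_len;             // flattened input length per conv layer
  int flatten;
};

Geometry make_geom(const Rcpp::List& idx_list, int n_conv,
                   const std::vector<fmat>& W, int input_len) {
  Geometry g;
  g.n_conv = n_conv;
  int cur = input_len;
  for (int l = 0; l < n_conv; ++l) {
    Rcpp::IntegerMatrix im = idx_list[l];
    const int ow = im.ncol(), patch = im.nrow();
    std::vector<uvec> cols((size_t)ow);
    for (int j = 0; j < ow; ++j) {
      uvec c((uword)patch);
      for (int k = 0; k < patch; ++k) c[(uword)k] = (uword)im(k, j);
      cols[(size_t)j] = std::move(c);
    }
    g.idx.push_back(std::move(cols));
    g.out_w.push_back(ow);
    g.in_len.push_back(cur);
    cur = (int)W[(size_t)(2 * l)].n_rows * ow;  // filters * out_w
  }
  g.flatten = cur;
  return g;
}

std::vector<fmat> as_weights(const Rcpp::List& wl) {
  std::vector<fmat> W;
  W.reserve((size_t)wl.size());
  for (int i = 0; i < wl.size(); ++i) {
    W.push_back(conv_to<fmat>::from(Rcpp::as<mat>(wl[i])));
  }
  return W;
}

struct Cache {
  std::vector<fmat> P;   // per conv layer: gathered patches
  std::vector<fmat> Z;   // per conv layer: pre-activation (filters x ow*B)
  fmat Fd;               // flattened features after dropout
  fmat mask;             // dropout mask (empty => none)
  std::vector<fmat> fcZ; // per fc layer: pre-activation
  std::vector<fmat> fcA; // per fc layer: post-ReLU
};

// gather patches of layer l for a batch stored column-wise (in_len x B)
fmat gather(const fmat& A, const Geometry& g, int l) {
  const int ow = g.out_w[(size_t)l];
  const uword patch = g.idx[(size_t)l][0].n_elem;
  const uword B = A.n_cols;
  fmat P(patch, (uword)ow * B);
  for (uword b = 0; b < B; ++b) {
    const fvec col = A.col(b);
    for (int j = 0; j < ow; ++j) {
      P.col(b * (uword)ow + (uword)j) = col.elem(g.idx[(size_t)l][(size_t)j]);
    }
  }
  return P;
}

// forward pass for a batch; returns 1 x B predictions, fills cache if given
frowvec forward(const std::vector<fmat>& W, const Geometry& g, const fmat& X,
                const fmat* dropout_mask, Cache* cache) {
  const uword B = X.n_cols;
  fmat A = X;  // flattened map, in_len x B
  std::vector<fmat> Ps, Zs;
  for (int l = 0; l < g.n_conv; ++l) {
    fmat P = gather(A, g, l);
    fmat Z = W[(size_t)(2 * l)] * P;
    Z.each_col() += W[(size_t)(2 * l + 1)].col(0);
    fmat Act = clamp(Z, 0.0f, std::numeric_limits<float>::infinity());
    // (filters x ow*B) shares its column-major layout with (filters*ow x B)
    A = reshape(Act, (uword)g.out_w[(size_t)l] * W[(size_t)(2 * l)].n_rows, B);
    if (cache) { Ps.push_back(std::move(P)); Zs.push_back(std::move(Z)); }
  }
  fmat Fd = A;  // flatten x B
  if (dropout_mask) Fd = A % (*dropout_mask);
  const size_t n_fc = W.size() / 2 - (size_t)g.n_conv;
  std::vector<fmat> fcZ, fcA;
  fmat H = Fd;
  for (size_t f = 0; f < n_fc; ++f) {
    const size_t wi = 2 * ((size_t)g.n_conv + f);
    fmat Z = W[wi] * H;
    Z.each_col() += W[wi + 1].col(0);
    fmat Act = clamp(Z, 0.0f, std::numeric_limits<float>::infinity());
    H = Act;
    if (cache) { fcZ.push_back(std::move(Z)); fcA.push_back(std::move(Act)); }
  }
  if (cache) {
    cache->P = std::move(Ps); cache->Z = std::move(Zs);
    cache->Fd = std::move(Fd);
    if (dropout_mask) cache->mask = *dropout_mask; else cache->mask.reset();
    cache->fcZ = std::move(fcZ); cache->fcA = std::move(fcA);
  }
  return H.row(0);
}

// backward pass; returns gradients in the same layout as the weights
std::vector<fmat> backward(const std::vector<fmat>& W, const Geometry& g,
                           const frowvec& y, const Cache& c) {
  const uword B = y.n_elem;
  const size_t n_fc = W.size() / 2 - (size_t)g.n_conv;
  std::vector<fmat> grad(W.size());

  const frowvec pred = c.fcA.back().row(0);
  fmat d = conv_to<fmat>::from((pred - y) * (2.0f / (float)B));
  d %= conv_to<fmat>::from(c.fcZ.back() > 0);

  for (size_t f = n_fc; f-- > 0;) {
    const size_t wi = 2 * ((size_t)g.n_conv + f);
    const fmat& A_prev = (f == 0) ? c.Fd : c.fcA[f - 1];
    grad[wi] = d * A_prev.t();
    grad[wi + 1] = sum(d, 1);
    fmat d_prev = W[wi].t() * d;
    if (f == 0) {
      d = std::move(d_prev);  // gradient w.r.t. Fd, flatten x B
    } else {
      d = d_prev % conv_to<fmat>::from(c.fcZ[f - 1] > 0);
    }
  }
  if (!c.mask.is_empty()) d %= c.mask;

  // into the conv stack: d is flatten x B == (filters*ow) x B of last conv
  for (int l = g.n_conv - 1; l >= 0; --l) {
    const uword filters = W[(size_t)(2 * l)].n_rows;
    const uword ow = (uword)g.out_w[(size_t)l];
    fmat dZ = reshape(d, filters, ow * B);
    dZ %= conv_to<fmat>::from(c.Z[(size_t)l] > 0);
    grad[(size_t)(2 * l)] = dZ * c.P[(size_t)l].t();
    grad[(size_t)(2 * l + 1)] = sum(dZ, 1);
    if (l > 0) {
      fmat dP = W[(size_t)(2 * l)].t() * dZ;
      fmat dA((uword)g.in_len[(size_t)l], B, fill::zeros);
      for (uword b = 0; b < B; ++b) {
        fvec acc(dA.colptr(b), dA.n_rows, false, true);
        for (uword j = 0; j < ow; ++j) {
          acc.elem(g.idx[(size_t)l][(size_t)j]) += dP.col(b * ow + j);
        }
      }
      d = std::move(dA);
    }
  }
  return grad;
}

frowvec predict_chunked(const std::vector<fmat>& W, const Geometry& g,
                        const fmat& X, uword chunk = 256) {
  frowvec out(X.n_cols);
  for (uword s = 0; s < X.n_cols; s += chunk) {
    const uword e = std::min(s + chunk, X.n_cols) - 1;
    out.subvec(s, e) = forward(W, g, X.cols(s, e), nullptr, nullptr);
  }
  return out;
}

struct Rng {
  std::mt19937 g;
  explicit Rng(unsigned s) : g(s) {}
  float unif() { return (float)(g() * (1.0 / 4294967296.0)); }
  void shuffle(std::vector<uword>& v) {
    for (size_t i = v.size(); i > 1; --i) {
      const size_t j = (size_t)(g() % (unsigned long)i);
      std::swap(v[i - 1], v[j]);
    }
  }
};

}  // namespace

// [[Rcpp::export]]
Rcpp::List cnn_train_cpp(Rcpp::List weights_in, const arma::mat& Xtr_in,
                         const arma::vec& ytr_in, const arma::mat& Xval_in,
                         const arma::vec& yval_in, Rcpp::List idx_list,
                         int n_conv, int epochs, double lr, int batch_size,
                         double dropout, int patience, int seed,
                         double beta1, double beta2, double epsilon) {
  std::vector<fmat> W = as_weights(weights_in);
  const fmat Xtr = conv_to<fmat>::from(Xtr_in);
  const fvec ytr = conv_to<fvec>::from(ytr_in);
  const fmat Xval = conv_to<fmat>::from(Xval_in);
  const fvec yval = conv_to<fvec>::from(yval_in);
  Geometry g = make_geom(idx_list, n_conv, W, (int)Xtr.n_rows);
  const uword N = Xtr.n_cols;
  const bool has_val = Xval.n_cols > 0;
  const float flr = (float)lr, b1 = (float)beta1, b2 = (float)beta2,
              eps = (float)epsilon, keep = 1.0f - (float)dropout;

  std::vector<fmat> M(W.size()), V(W.size());
  for (size_t i = 0; i < W.size(); ++i) {
    M[i] = zeros<fmat>(W[i].n_rows, W[i].n_cols);
    V[i] = zeros<fmat>(W[i].n_rows, W[i].n_cols);
  }
  Rng rng((unsigned)seed);
  std::vector<uword> order(N);
  for (uword i = 0; i < N; ++i) order[i] = i;

  std::vector<double> train_hist, val_hist;
  std::vector<fmat> best_W = W;
  double best_val = std::numeric_limits<double>::infinity();
  int best_epoch = 0, wait = 0;
  long t = 0;

  for (int ep = 1; ep <= epochs; ++ep) {
    rng.shuffle(order);
    double ep_loss = 0.0;
    int n_batches = 0;
    for (uword s = 0; s < N; s += (uword)batch_size) {
      const uword e = std::min(s + (uword)batch_size, N);
      uvec ii(e - s);
      for (uword k = s; k < e; ++k) ii[k - s] = order[k];
      const fmat Xb = Xtr.cols(ii);
      frowvec yb(e - s);
      for (uword k = 0; k < e - s; ++k) yb[k] = ytr[ii[k]];

      fmat mask;
      const fmat* maskp = nullptr;
      if (dropout > 0) {
        mask.set_size((uword)g.flatten, e - s);
        for (uword k = 0; k < mask.n_elem; ++k) {
          mask[k] = (rng.unif() < keep) ? 1.0f / keep : 0.0f;
        }
        maskp = &mask;
      }
      Cache cache;
      frowvec pred = forward(W, g, Xb, maskp, &cache);
      const double loss = (double)mean(square(pred - yb));
      if (!std::isfinite(loss)) {
        Rcpp::stop("non-finite training loss at epoch %d, batch %d "
                   "(diverged; lower the learning rate)", ep, n_batches + 1);
      }
      ep_loss += loss;
      ++n_batches;
      std::vector<fmat> grad = backward(W, g, yb, cache);
      ++t;
      const float bc1 = 1.0f - std::pow(b1, (float)t);
      const float bc2 = 1.0f - std::pow(b2, (float)t);
      for (size_t i = 0; i < W.size(); ++i) {
        M[i] = b1 * M[i] + (1.0f - b1) * grad[i];
        V[i] = b2 * V[i] + (1.0f - b2) * square(grad[i]);
        W[i] -= flr * (M[i] / bc1) / (sqrt(V[i] / bc2) + eps);
      }
    }
    train_hist.push_back(ep_loss / n_batches);

    if (has_val) {
      const frowvec pv = predict_chunked(W, g, Xval);
      const double vl = (double)mean(square(pv - yval.t()));
      val_hist.push_back(vl);
      if (vl < best_val) {
        best_val = vl;
        best_W = W;
        best_epoch = ep;
        wait = 0;
      } else if (++wait >= patience) {
        break;
      }
    } else {
      best_W = W;
      best_epoch = ep;
    }
    if (ep % 25 == 0) Rcpp::checkUserInterrupt();
  }

  Rcpp::List wout((int)best_W.size());
  for (size_t i = 0; i < best_W.size(); ++i) {
    wout[(int)i] = conv_to<mat>::from(best_W[i]);
  }
  return Rcpp::List::create(
      Rcpp::Named("weights") = wout,
      Rcpp::Named("train_loss") = train_hist,
      Rcpp::Named("val_loss") = val_hist,
      Rcpp::Named("best_epoch") = best_epoch);
}

// [[Rcpp::export]]
arma::rowvec cnn_predict_cpp(Rcpp::List weights_in, const arma::mat& X,
                             Rcpp::List idx_list, int n_conv) {
  std::vector<fmat> W = as_weights(weights_in);
  Geometry g = make_geom(idx_list, n_conv, W, (int)X.n_rows);
  return conv_to<rowvec>::from(
      predict_chunked(W, g, conv_to<fmat>::from(X)));
}
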