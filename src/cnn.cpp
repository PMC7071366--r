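// Trainable implementation of the context-integrating CNN.
//
// Layer stack: [conv (+ bias, ReLU)] x nconv -> max-pool -> flatten ->
// hidden dense layers (sigmoid/tanh/ReLU) -> softmax, trained by
// mini-batch gradient-descent backpropagation on the cross-entropy.
//
// Convolutions are cuboid convolutions: each filter spans the full
// z-depth of its input, so one filter yields one 2-d map. They are
// evaluated as im2col patch-matrix x filter-matrix products. Flattening
// uses column-major order (row fastest, then column, then slice), the
// same order as R's array vectorisation, so R and C++ agree bit-for-bit.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

struct ConvSpec {
  int K;      // number of filters
  int kh, kw; // filter height/width (odd)
  bool same;  // zero-pad to preserve H x W
};

struct NetSpec {
  int H, W, Z;
  std::vector<ConvSpec> conv;
  bool has_pool;
  int pool_size, pool_stride;
  std::vector<int> fc_sizes; // hidden widths then L
  int act;                   // 0 sigmoid, 1 tanh, 2 relu
  int L;
};

static NetSpec parse_spec(const Rcpp::List& spec) {
  NetSpec s;
  Rcpp::IntegerVector ishape = spec["input_shape"];
  s.H = ishape[0]; s.W = ishape[1]; s.Z = ishape[2];
  Rcpp::List conv = spec["conv_layers"];
  for (int i = 0; i < conv.size(); ++i) {
    Rcpp::List cl = conv[i];
    ConvSpec cs;
    cs.K = Rcpp::as<int>(cl["filters"]);
    cs.kh = Rcpp::as<int>(cl["kh"]);
    cs.kw = Rcpp::as<int>(cl["kw"]);
    cs.same = Rcpp::as<std::string>(cl["mode"]) == "same";
    s.conv.push_back(cs);
  }
  s.has_pool = !Rf_isNull(spec["pool"]);
  if (s.has_pool) {
    Rcpp::List p = spec["pool"];
    s.pool_size = Rcpp::as<int>(p["size"]);
    s.pool_stride = Rcpp::as<int>(p["stride"]);
  } else {
    s.pool_size = s.pool_stride = 1;
  }
  Rcpp::IntegerVector hidden = spec["hidden"];
  for (int i = 0; i < hidden.size(); ++i) s.fc_sizes.push_back(hidden[i]);
  s.L = Rcpp::as<int>(spec["n_classes"]);
  s.fc_sizes.push_back(s.L);
  std::string a = Rcpp::as<std::string>(spec["hidden_activation"]);
  s.act = (a == "sigmoid") ? 0 : (a == "tanh") ? 1 : 2;
  return s;
}

struct Weights {
  std::vector<mat> cW; // (kh*kw*Zin) x K
  std::vector<vec> cb; // K
  std::vector<mat> fW; // out x in
  std::vector<vec> fb; // out
};

static Weights parse_weights(const Rcpp::List& w) {
  Weights W;
  Rcpp::List cW = w["conv_w"], cb = w["conv_b"], fW = w["fc_w"], fb = w["fc_b"];
  for (int i = 0; i < cW.size(); ++i) {
    W.cW.push_back(Rcpp::as<mat>(cW[i]));
    W.cb.push_back(Rcpp::as<vec>(cb[i]));
  }
  for (int i = 0; i < fW.size(); ++i) {
    W.fW.push_back(Rcpp::as<mat>(fW[i]));
    W.fb.push_back(Rcpp::as<vec>(fb[i]));
  }
  return W;
}

static Rcpp::List weights_to_list(const Weights& W) {
  Rcpp::List cW(W.cW.size()), cb(W.cb.size()), fW(W.fW.size()), fb(W.fb.size());
  for (size_t i = 0; i < W.cW.size(); ++i) { cW[i] = W.cW[i]; cb[i] = W.cb[i]; }
  for (size_t i = 0; i < W.fW.size(); ++i) { fW[i] = W.fW[i]; fb[i] = W.fb[i]; }
  return Rcpp::List::create(Rcpp::Named("conv_w") = cW, Rcpp::Named("conv_b") = cb,
                            Rcpp::Named("fc_w") = fW, Rcpp::Named("fc_b") = fb);
}

// Patch matrix of a valid convolution: row r = h + Ho*w holds the
// receptive field at (h, w), columns ordered u (rows) fastest, then v,
// then z -- matching the filter-matrix row order.
static mat im2col(const cube& X, int kh, int kw) {
  const int H = X.n_rows, W = X.n_cols, Z = X.n_slices;
  const int Ho = H - kh + 1, Wo = W - kw + 1;
  mat P(Ho * (sword)Wo, kh * (sword)kw * Z);
  for (int z = 0; z < Z; ++z)
    for (int v = 0; v < kw; ++v)
      for (int u = 0; u < kh; ++u) {
        const int c = u + kh * v + kh * kw * z;
        double* col = P.colptr(c);
        for (int w0 = 0; w0 < Wo; ++w0) {
          const double* src = &X(u, w0 + v, z);
          double* dst = col + (size_t)Ho * w0;
          std::memcpy(dst, src, sizeof(double) * Ho);
        }
      }
  return P;
}

// Adjoint of im2col: scatter patch-gradients back onto the input.
static cube col2im(const mat& dP, int H, int W, int Z, int kh, int kw) {
  const int Ho = H - kh + 1, Wo = W - kw + 1;
  cube dX(H, W, Z, fill::zeros);
  for (int z = 0; z < Z; ++z)
    for (int v = 0; v < kw; ++v)
      for (int u = 0; u < kh; ++u) {
        const int c = u + kh * v + kh * kw * z;
        const double* col = dP.colptr(c);
        for (int w0 = 0; w0 < Wo; ++w0) {
          double* dst = &dX(u, w0 + v, z);
          const double* src = col + (size_t)Ho * w0;
          for (int h0 = 0; h0 < Ho; ++h0) dst[h0] += src[h0];
        }
      }
  return dX;
}

static cube pad_cube(const cube& X, int a, int b) {
  cube P(X.n_rows + 2 * a, X.n_cols + 2 * b, X.n_slices, fill::zeros);
  P.subcube(a, b, 0, a + X.n_rows - 1, b + X.n_cols - 1, X.n_slices - 1) = X;
  return P;
}

struct Cache {
  std::vector<mat> P;     // im2col patches per conv layer (of padded input)
  std::vector<mat> Zm;    // pre-activations (Ho*Wo x K)
  std::vector<cube> A;    // conv activations
  std::vector<int> inH, inW; // unpadded input dims per conv layer
  cube pooled;
  umat poolarg;           // linear index into pre-pool cube per pooled cell
  std::vector<vec> fx;    // dense layer inputs (fx[0] = flattened)
  std::vector<vec> fz;    // dense pre-activations
  std::vector<vec> fa;    // dense activations (last = softmax probs)
};

static vec softmax(const vec& q) {
  vec e = exp(q - q.max());
  return e / accu(e);
}

static vec activate(const vec& z, int act) {
  if (act == 0) return 1.0 / (1.0 + exp(-z));
  if (act == 1) return tanh(z);
  return clamp(z, 0.0, datum::inf);
}

static vec activate_grad(const vec& z, const vec& a, int act) {
  if (act == 0) return a % (1.0 - a);
  if (act == 1) return 1.0 - a % a;
  return conv_to<vec>::from(z > 0);
}

static void forward_one(const NetSpec& s, const Weights& W, const cube& input,
                        Cache& C) {
  cube X = input;
  const size_t nconv = s.conv.size();
  C.P.resize(nconv); C.Zm.resize(nconv); C.A.resize(nconv);
  C.inH.resize(nconv); C.inW.resize(nconv);
  for (size_t l = 0; l < nconv; ++l) {
    const ConvSpec& cs = s.conv[l];
    C.inH[l] = X.n_rows; C.inW[l] = X.n_cols;
    cube Xp = cs.same ? pad_cube(X, (cs.kh - 1) / 2, (cs.kw - 1) / 2) : X;
    C.P[l] = im2col(Xp, cs.kh, cs.kw);
    mat Zm = C.P[l] * W.cW[l];
    Zm.each_row() += W.cb[l].t();
    C.Zm[l] = Zm;
    const int Ho = Xp.n_rows - cs.kh + 1, Wo = Xp.n_cols - cs.kw + 1;
    cube A(Ho, Wo, cs.K);
    for (int k = 0; k < cs.K; ++k) {
      A.slice(k) = reshape(clamp(Zm.col(k), 0.0, datum::inf), Ho, Wo);
    }
    C.A[l] = A;
    X = A;
  }
  if (s.has_pool) {
    const int g = s.pool_size, st = s.pool_stride;
    const int Ho = (X.n_rows - g) / st + 1, Wo = (X.n_cols - g) / st + 1;
    cube Pd(Ho, Wo, X.n_slices);
    C.poolarg.set_size(Ho * (sword)Wo, X.n_slices);
    for (size_t k = 0; k < X.n_slices; ++k) {
      const mat& S = X.slice(k);
      for (int w0 = 0; w0 < Wo; ++w0)
        for (int h0 = 0; h0 < Ho; ++h0) {
          double best = -datum::inf; int bu = 0, bv = 0;
          for (int tv = 0; tv < g; ++tv)
            for (int tu = 0; tu < g; ++tu) {
              double val = S(st * h0 + tu, st * w0 + tv);
              if (val > best) { best = val; bu = tu; bv = tv; }
            }
          Pd(h0, w0, k) = best;
          C.poolarg(h0 + Ho * (sword)w0, k) =
            (st * h0 + bu) + X.n_rows * (size_t)(st * w0 + bv);
        }
    }
    C.pooled = Pd;
    X = Pd;
  } else {
    C.pooled = X;
  }
  vec x = vectorise(X);
  const size_t nfc = W.fW.size();
  C.fx.resize(nfc); C.fz.resize(nfc); C.fa.resize(nfc);
  for (size_t l = 0; l < nfc; ++l) {
    C.fx[l] = x;
    vec z = W.fW[l] * x + W.fb[l];
    C.fz[l] = z;
    vec a = (l == nfc - 1) ? softmax(z) : activate(z, s.act);
    C.fa[l] = a;
    x = a;
  }
}

static void backward_one(const NetSpec& s, const Weights& W, const Cache& C,
                         int label, Weights& G) {
  const size_t nfc = W.fW.size();
  vec delta = C.fa[nfc - 1];
  delta(label - 1) -= 1.0; // softmax + cross-entropy
  for (int l = (int)nfc - 1; l >= 0; --l) {
    G.fW[l] += delta * C.fx[l].t();
    G.fb[l] += delta;
    if (l > 0) {
      vec dx = W.fW[l].t() * delta;
      delta = dx % activate_grad(C.fz[l - 1], C.fa[l - 1], s.act);
    } else {
      delta = W.fW[0].t() * delta;
    }
  }
  // delta now holds the gradient wrt the flattened pooled cube
  const cube& last = C.A.back();
  cube dA(last.n_rows, last.n_cols, last.n_slices, fill::zeros);
  if (s.has_pool) {
    const cube& Pd = C.pooled;
    const int Ho = Pd.n_rows, Wo = Pd.n_cols;
    for (size_t k = 0; k < Pd.n_slices; ++k) {
      mat& dS = dA.slice(k);
      for (int w0 = 0; w0 < Wo; ++w0)
        for (int h0 = 0; h0 < Ho; ++h0) {
          size_t idx = C.poolarg(h0 + Ho * (sword)w0, k);
          dS(idx) += delta(h0 + Ho * (sword)w0 + Ho * (size_t)Wo * k);
        }
    }
  } else {
    dA = cube(delta.memptr(), last.n_rows, last.n_cols, last.n_slices);
  }
  for (int l = (int)s.conv.size() - 1; l >= 0; --l) {
    const ConvSpec& cs = s.conv[l];
    const int Ho = C.A[l].n_rows, Wo = C.A[l].n_cols;
    mat dZ(Ho * (sword)Wo, cs.K);
    for (int k = 0; k < cs.K; ++k) dZ.col(k) = vectorise(dA.slice(k));
    dZ %= conv_to<mat>::from(C.Zm[l] > 0); // ReLU gate
    G.cW[l] += C.P[l].t() * dZ;
    G.cb[l] += sum(dZ, 0).t();
    if (l > 0) {
      mat dP = dZ * W.cW[l].t();
      const int a = cs.same ? (cs.kh - 1) / 2 : 0;
      const int b = cs.same ? (cs.kw - 1) / 2 : 0;
      const int Hp = C.inH[l] + 2 * a, Wp = C.inW[l] + 2 * b;
      cube dXp = col2im(dP, Hp, Wp, W.cW[l].n_rows / (cs.kh * cs.kw), cs.kh, cs.kw);
      dA = cs.same
        ? cube(dXp.subcube(a, b, 0, a + C.inH[l] - 1, b + C.inW[l] - 1,
                           dXp.n_slices - 1))
        : dXp;
    }
  }
}

static Weights zero_like(const Weights& W) {
  Weights G;
  for (size_t i = 0; i < W.cW.size(); ++i) {
    G.cW.push_back(mat(size(W.cW[i]), fill::zeros));
    G.cb.push_back(vec(size(W.cb[i]), fill::zeros));
  }
  for (size_t i = 0; i < W.fW.size(); ++i) {
    G.fW.push_back(mat(size(W.fW[i]), fill::zeros));
    G.fb.push_back(vec(size(W.fb[i]), fill::zeros));
  }
  return G;
}

static std::vector<cube> parse_inputs(const Rcpp::List& inputs) {
  std::vector<cube> X;
  X.reserve(inputs.size());
  for (int i = 0; i < inputs.size(); ++i) X.push_back(Rcpp::as<cube>(inputs[i]));
  return X;
}

// [[Rcpp::export]]
arma::mat cnn_forward_cpp(Rcpp::List inputs, Rcpp::List spec, Rcpp::List weights) {
  NetSpec s = parse_spec(spec);
  Weights W = parse_weights(weights);
  std::vector<cube> X = parse_inputs(inputs);
  mat out(X.size(), s.L);
  Cache C;
  for (size_t i = 0; i < X.size(); ++i) {
    forward_one(s, W, X[i], C);
    out.row(i) = C.fa.back().t();
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List cnn_loss_grad_cpp(Rcpp::List inputs, Rcpp::IntegerVector labels,
                             Rcpp::List spec, Rcpp::List weights) {
  NetSpec s = parse_spec(spec);
  Weights W = parse_weights(weights);
  std::vector<cube> X = parse_inputs(inputs);
  Weights G = zero_like(W);
  double loss = 0.0;
  Cache C;
  for (size_t i = 0; i < X.size(); ++i) {
    forward_one(s, W, X[i], C);
    loss += -std::log(std::max(C.fa.back()(labels[i] - 1), 1e-300));
    backward_one(s, W, C, labels[i], G);
  }
  const double n = (double)X.size();
  loss /= n;
  for (auto& m : G.cW) m /= n;
  for (auto& v : G.cb) v /= n;
  for (auto& m : G.fW) m /= n;
  for (auto& v : G.fb) v /= n;
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grads") = weights_to_list(G));
}

struct Adam {
  std::vector<mat> m_cW, v_cW, m_fW, v_fW;
  std::vector<vec> m_cb, v_cb, m_fb, v_fb;
  double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long t = 0;
  void init(const Weights& W) {
    Weights z1 = zero_like(W), z2 = zero_like(W);
    m_cW = z1.cW; v_cW = z2.cW; m_cb = z1.cb; v_cb = z2.cb;
    m_fW = z1.fW; v_fW = z2.fW; m_fb = z1.fb; v_fb = z2.fb;
  }
  void step_one(mat& w, const mat& g, mat& m, mat& v, double lr) {
    m = b1 * m + (1 - b1) * g;
    v = b2 * v + (1 - b2) * (g % g);
    mat mh = m / (1 - std::pow(b1, (double)t));
    mat vh = v / (1 - std::pow(b2, (double)t));
    w -= lr * mh / (sqrt(vh) + eps);
  }
  void step_one(vec& w, const vec& g, vec& m, vec& v, double lr) {
    m = b1 * m + (1 - b1) * g;
    v = b2 * v + (1 - b2) * (g % g);
    vec mh = m / (1 - std::pow(b1, (double)t));
    vec vh = v / (1 - std::pow(b2, (double)t));
    w -= lr * mh / (sqrt(vh) + eps);
  }
  void step(Weights& W, const Weights& G, double lr) {
    ++t;
    for (size_t i = 0; i < W.cW.size(); ++i) {
      step_one(W.cW[i], G.cW[i], m_cW[i], v_cW[i], lr);
      step_one(W.cb[i], G.cb[i], m_cb[i], v_cb[i], lr);
    }
    for (size_t i = 0; i < W.fW.size(); ++i) {
      step_one(W.fW[i], G.fW[i], m_fW[i], v_fW[i], lr);
      step_one(W.fb[i], G.fb[i], m_fb[i], v_fb[i], lr);
    }
  }
};

// [[Rcpp::export]]
Rcpp::List cnn_train_cpp(Rcpp::List inputs, Rcpp::IntegerVector labels,
                         Rcpp::List spec, Rcpp::List init_weights,
                         double learning_rate, int batch_size, int max_epochs,
                         double loss_threshold, std::string optimizer,
                         double momentum, int seed) {
  NetSpec s = parse_spec(spec);
  Weights W = parse_weights(init_weights);
  std::vector<cube> X = parse_inputs(inputs);
  const int n = (int)X.size();
  std::mt19937 rng((unsigned)seed);
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  const bool use_adam = (optimizer == "adam");
  Adam adam;
  Weights vel = zero_like(W); // SGD momentum buffers
  if (use_adam) adam.init(W);

  std::vector<double> history;
  bool converged = false;
  int epoch = 0;
  double mean_loss = datum::inf;
  Cache C;
  for (epoch = 1; epoch <= max_epochs; ++epoch) {
    std::shuffle(order.begin(), order.end(), rng);
    for (int start = 0; start < n; start += batch_size) {
      const int stop = std::min(start + batch_size, n);
      const double bs = stop - start;
      Weights G = zero_like(W);
      for (int i = start; i < stop; ++i) {
        forward_one(s, W, X[order[i]], C);
        backward_one(s, W, C, labels[order[i]], G);
      }
      for (auto& m : G.cW) m /= bs;
      for (auto& v : G.cb) v /= bs;
      for (auto& m : G.fW) m /= bs;
      for (auto& v : G.fb) v /= bs;
      if (use_adam) {
        adam.step(W, G, learning_rate);
      } else {
        for (size_t i = 0; i < W.cW.size(); ++i) {
          vel.cW[i] = momentum * vel.cW[i] - learning_rate * G.cW[i];
          W.cW[i] += vel.cW[i];
          vel.cb[i] = momentum * vel.cb[i] - learning_rate * G.cb[i];
          W.cb[i] += vel.cb[i];
        }
        for (size_t i = 0; i < W.fW.size(); ++i) {
          vel.fW[i] = momentum * vel.fW[i] - learning_rate * G.fW[i];
          W.fW[i] += vel.fW[i];
          vel.fb[i] = momentum * vel.fb[i] - learning_rate * G.fb[i];
          W.fb[i] += vel.fb[i];
        }
      }
    }
    // epoch-end evaluation of the stopping criterion: mean cross-entropy
    // (and accuracy) over the full training set
    mean_loss = 0.0;
    int n_correct = 0;
    for (int i = 0; i < n; ++i) {
      forward_one(s, W, X[i], C);
      const vec& p = C.fa.back();
      mean_loss += -std::log(std::max(p(labels[i] - 1), 1e-300));
      if ((int)p.index_max() + 1 == labels[i]) ++n_correct;
    }
    mean_loss /= n;
    history.push_back(mean_loss);
    if (!std::isfinite(mean_loss)) {
      Rcpp::stop("training diverged (loss is not finite) at learning rate %g",
                 learning_rate);
    }
    if (mean_loss < loss_threshold) { converged = true; break; }
  }
  // final training accuracy
  int n_correct = 0;
  for (int i = 0; i < n; ++i) {
    forward_one(s, W, X[i], C);
    if ((int)C.fa.back().index_max() + 1 == labels[i]) ++n_correct;
  }
  return Rcpp::List::create(
    Rcpp::Named("weights") = weights_to_list(W),
    Rcpp::Named("loss_history") = history,
    Rcpp::Named("epochs") = std::min(epoch, max_epochs),
    Rcpp::Named("converged") = converged,
    Rcpp::Named("final_loss") = mean_loss,
    Rcpp::Named("train_accuracy") = (double)n_correct / n);
}
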