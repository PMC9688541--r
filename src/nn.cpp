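// Training cores for the two single-trial P300 detectors.
//
// cpp_cnn_fit / cpp_cnn_predict: spatiotemporal CNN. Conv_1 is a spatial
// convolution spanning all channels (kernel C x 1), Conv_2 a temporal
// convolution (1 x k across all Conv_1 maps); each is followed by batch
// normalisation and ReLU, Conv_2 and the hidden linear layer by dropout;
// a 2-unit softmax output gives class probabilities. Adam with L2 weight
// decay, fixed epoch count, seeded minibatch shuffling.
//
// cpp_bnn_fit / cpp_bnn_predict: Bayesian MLP whose weights are sampled on
// every feedforward pass as W = mu + softplus(rho) * eps, eps ~ N(0,1)
// (reparameterisation), trained by minimising cross-entropy plus a
// KL(q || N(0,1)) complexity term weighted by 1/num_batches. Prediction
// averages softmax probabilities over S weight samples.
//
// All randomness comes from a private mt19937_64 stream, so results are
// reproducible from the seed alone.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

// Self-contained, seed-reproducible stream: xorshift128+ for uniforms,
// Marsaglia polar for normals; mt19937_64 only for minibatch shuffling.
struct Rng {
  std::mt19937_64 eng;
  uint64_t s0, s1;
  bool has_spare = false;
  double spare = 0.0;
  explicit Rng(unsigned long long seed) : eng(seed) {
    std::mt19937_64 seeder(seed ^ 0x9E3779B97F4A7C15ULL);
    s0 = seeder();
    s1 = seeder();
  }
  inline uint64_t next() {
    uint64_t x = s0, y = s1;
    s0 = y;
    x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    return s1 + y;
  }
  inline double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  inline double normal() {
    if (has_spare) { has_spare = false; return spare; }
    double u, v, s;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      s = u * u + v * v;
    } while (s >= 1.0 || s == 0.0);
    double f = std::sqrt(-2.0 * std::log(s) / s);
    spare = v * f;
    has_spare = true;
    return u * f;
  }
  mat normal_mat(uword r, uword c) {
    mat m(r, c);
    double* p = m.memptr();
    for (uword i = 0; i < r * c; ++i) p[i] = normal();
    return m;
  }
  mat dropout_mask(uword r, uword c, double p_drop) {
    mat m(r, c);
    double* p = m.memptr();
    double keep = 1.0 / (1.0 - p_drop);
    for (uword i = 0; i < r * c; ++i)
      p[i] = unif() < p_drop ? 0.0 : keep;
    return m;
  }
};

// softplus and logistic sigmoid of the same argument in one pass
void softplus_sig(const mat& rho, mat& sp, mat& sg) {
  sp.set_size(rho.n_rows, rho.n_cols);
  sg.set_size(rho.n_rows, rho.n_cols);
  const double* r = rho.memptr();
  double* a = sp.memptr();
  double* b = sg.memptr();
  for (uword i = 0; i < rho.n_elem; ++i) {
    if (r[i] > 30.0) { a[i] = r[i]; b[i] = 1.0; }
    else {
      double e = std::exp(r[i]);
      a[i] = std::log1p(e);
      b[i] = e / (1.0 + e);
    }
  }
}

struct Adam {
  double lr, b1 = 0.9, b2 = 0.999, eps = 1e-8;
  int t = 0;
  std::vector<mat> m, v;
  std::vector<mat*> params;
  explicit Adam(double lr_) : lr(lr_) {}
  void attach(mat* p) {
    params.push_back(p);
    m.push_back(zeros<mat>(p->n_rows, p->n_cols));
    v.push_back(zeros<mat>(p->n_rows, p->n_cols));
  }
  void step(const std::vector<mat>& grads) {
    ++t;
    double c1 = 1.0 - std::pow(b1, t), c2 = 1.0 - std::pow(b2, t);
    for (size_t i = 0; i < params.size(); ++i) {
      m[i] = b1 * m[i] + (1.0 - b1) * grads[i];
      v[i] = b2 * v[i] + (1.0 - b2) * square(grads[i]);
      *params[i] -= lr * (m[i] / c1) / (sqrt(v[i] / c2) + eps);
    }
  }
};

const double BN_EPS = 1e-5, BN_MOM = 0.1;

// Row-wise batch normalisation over all columns (batch x time pooled).
struct BnCache { mat xhat; vec ivar; };

mat bn_forward_train(const mat& M, const vec& gamma, const vec& beta,
                     vec& run_mean, vec& run_var, BnCache& cache) {
  vec mu = mean(M, 1);
  mat centred = M.each_col() - mu;
  vec var = mean(square(centred), 1);
  cache.ivar = 1.0 / sqrt(var + BN_EPS);
  cache.xhat = centred.each_col() % cache.ivar;
  run_mean = (1.0 - BN_MOM) * run_mean + BN_MOM * mu;
  run_var = (1.0 - BN_MOM) * run_var + BN_MOM * var;
  mat out = cache.xhat.each_col() % gamma;
  out.each_col() += beta;
  return out;
}

mat bn_forward_eval(const mat& M, const vec& gamma, const vec& beta,
                    const vec& run_mean, const vec& run_var) {
  mat out = M.each_col() - run_mean;
  out.each_col() %= gamma / sqrt(run_var + BN_EPS);
  out.each_col() += beta;
  return out;
}

mat bn_backward(const mat& dY, const vec& gamma, const BnCache& cache,
                vec& dgamma, vec& dbeta) {
  double N = (double)dY.n_cols;
  dgamma = sum(dY % cache.xhat, 1);
  dbeta = sum(dY, 1);
  mat dxhat = dY.each_col() % gamma;
  vec s1 = sum(dxhat, 1), s2 = sum(dxhat % cache.xhat, 1);
  mat dX = dxhat * N;
  dX.each_col() -= s1;
  dX -= cache.xhat.each_col() % s2;
  dX.each_col() %= cache.ivar / N;
  return dX;
}

// columns-of-softmax with the usual max shift
mat softmax_cols(const mat& O) {
  mat P = O.each_row() - max(O, 0);
  P = exp(P);
  P.each_row() /= sum(P, 0);
  return P;
}

// gather rows of X (n x d) into a C x (T*B) batch block, sample-major
mat make_batch(const mat& X, const uvec& idx, int C, int T) {
  mat Xb(C, T * idx.n_elem);
  for (uword b = 0; b < idx.n_elem; ++b) {
    // feature row layout: channel-major blocks of T samples
    rowvec r = X.row(idx(b));
    mat m = reshape(r, T, C);  // column c = channel c's segment
    Xb.cols(b * T, (b + 1) * T - 1) = m.t();
  }
  return Xb;
}

mat softplus(const mat& x) {
  mat y = x;
  y.transform([](double v) { return v > 30.0 ? v : std::log1p(std::exp(v)); });
  return y;
}

}  // namespace

// [[Rcpp::export]]
Rcpp::List cpp_cnn_fit(const arma::mat& X, const arma::ivec& y,
                       int n_ch, int n_t, int f1, int f2, int kt, int hidden,
                       double dropout, int batch_size, double weight_decay,
                       double lr, int epochs, int seed) {
  const int n = X.n_rows, C = n_ch, T = n_t, T2 = T - kt + 1;
  if (T2 < 1) Rcpp::stop("temporal kernel longer than the epoch");
  Rng rng((unsigned long long)seed);

  mat W1 = rng.normal_mat(f1, C) * std::sqrt(2.0 / C);
  mat W2 = rng.normal_mat(f2, f1 * kt) * std::sqrt(2.0 / (f1 * kt));
  mat Wh = rng.normal_mat(hidden, f2 * T2) * std::sqrt(2.0 / (f2 * T2));
  mat Wo = rng.normal_mat(2, hidden) * std::sqrt(2.0 / hidden);
  mat bh = zeros<mat>(hidden, 1), bo = zeros<mat>(2, 1);
  mat g1 = ones<mat>(f1, 1), be1 = zeros<mat>(f1, 1);
  mat g2 = ones<mat>(f2, 1), be2 = zeros<mat>(f2, 1);
  vec rm1 = zeros<vec>(f1), rv1 = ones<vec>(f1);
  vec rm2 = zeros<vec>(f2), rv2 = ones<vec>(f2);

  Adam opt(lr);
  opt.attach(&W1); opt.attach(&W2); opt.attach(&Wh); opt.attach(&Wo);
  opt.attach(&bh); opt.attach(&bo);
  opt.attach(&g1); opt.attach(&be1); opt.attach(&g2); opt.attach(&be2);

  std::vector<uword> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::vector<double> loss_hist;

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng.eng);
    double ep_loss = 0.0;
    int n_batches_run = 0;
    for (int start = 0; start < n; start += batch_size) {
      int B = std::min(batch_size, n - start);
      if (B < 2) continue;  // batch norm needs at least two samples
      uvec idx(B);
      for (int b = 0; b < B; ++b) idx(b) = order[start + b];

      mat Xb = make_batch(X, idx, C, T);              // C x T*B
      mat A1 = W1 * Xb;                               // f1 x T*B
      BnCache c1;
      mat N1 = bn_forward_train(A1, g1.col(0), be1.col(0), rm1, rv1, c1);
      mat R1 = clamp(N1, 0.0, datum::inf);

      mat P(f1 * kt, T2 * B);                         // im2col patches
      for (int b = 0; b < B; ++b)
        for (int t = 0; t < T2; ++t)
          P.col(b * T2 + t) =
              vectorise(R1.cols(b * T + t, b * T + t + kt - 1));
      mat A2 = W2 * P;                                // f2 x T2*B
      BnCache c2;
      mat N2 = bn_forward_train(A2, g2.col(0), be2.col(0), rm2, rv2, c2);
      mat R2 = clamp(N2, 0.0, datum::inf);
      mat M2 = rng.dropout_mask(f2, T2 * B, dropout);
      mat D2 = R2 % M2;

      mat h0(f2 * T2, B);                             // flatten per sample
      for (int b = 0; b < B; ++b)
        h0.col(b) = vectorise(D2.cols(b * T2, (b + 1) * T2 - 1));
      mat Zh = Wh * h0;
      Zh.each_col() += bh.col(0);
      mat Rh = clamp(Zh, 0.0, datum::inf);
      mat Mh = rng.dropout_mask(hidden, B, dropout);
      mat Dh = Rh % Mh;
      mat O = Wo * Dh;
      O.each_col() += bo.col(0);
      mat Pr = softmax_cols(O);

      mat Y = zeros<mat>(2, B);
      for (int b = 0; b < B; ++b) Y(y(idx(b)), b) = 1.0;
      ep_loss += -accu(Y % log(Pr + 1e-12)) / B;
      ++n_batches_run;

      // ---- backward ----
      mat dO = (Pr - Y) / B;
      mat dWo = dO * Dh.t() + weight_decay * Wo;
      mat dbo = sum(dO, 1);
      mat dDh = Wo.t() * dO;
      mat dRh = dDh % Mh;
      mat dZh = dRh % conv_to<mat>::from(Zh > 0.0);
      mat dWh = dZh * h0.t() + weight_decay * Wh;
      mat dbh = sum(dZh, 1);
      mat dh0 = Wh.t() * dZh;

      mat dD2(f2, T2 * B);
      for (int b = 0; b < B; ++b)
        dD2.cols(b * T2, (b + 1) * T2 - 1) =
            reshape(dh0.col(b), f2, T2);
      mat dR2 = dD2 % M2;
      mat dN2 = dR2 % conv_to<mat>::from(N2 > 0.0);
      vec dg2, dbe2v;
      mat dA2 = bn_backward(dN2, g2.col(0), c2, dg2, dbe2v);
      mat dW2 = dA2 * P.t() + weight_decay * W2;
      mat dP = W2.t() * dA2;

      mat dR1 = zeros<mat>(f1, T * B);                // col2im
      for (int b = 0; b < B; ++b)
        for (int t = 0; t < T2; ++t)
          dR1.cols(b * T + t, b * T + t + kt - 1) +=
              reshape(dP.col(b * T2 + t), f1, kt);
      mat dN1 = dR1 % conv_to<mat>::from(N1 > 0.0);
      vec dg1, dbe1v;
      mat dA1 = bn_backward(dN1, g1.col(0), c1, dg1, dbe1v);
      mat dW1 = dA1 * Xb.t() + weight_decay * W1;

      std::vector<mat> grads = {dW1, dW2, dWh, dWo, dbh, dbo,
                                mat(dg1), mat(dbe1v), mat(dg2), mat(dbe2v)};
      opt.step(grads);
    }
    loss_hist.push_back(n_batches_run ? ep_loss / n_batches_run : NA_REAL);
  }

  return Rcpp::List::create(
      Rcpp::Named("W1") = W1, Rcpp::Named("W2") = W2,
      Rcpp::Named("Wh") = Wh, Rcpp::Named("Wo") = Wo,
      Rcpp::Named("bh") = bh, Rcpp::Named("bo") = bo,
      Rcpp::Named("g1") = g1, Rcpp::Named("be1") = be1,
      Rcpp::Named("g2") = g2, Rcpp::Named("be2") = be2,
      Rcpp::Named("rm1") = rm1, Rcpp::Named("rv1") = rv1,
      Rcpp::Named("rm2") = rm2, Rcpp::Named("rv2") = rv2,
      Rcpp::Named("loss") = loss_hist);
}

// [[Rcpp::export]]
arma::mat cpp_cnn_predict(const Rcpp::List& par, const arma::mat& X,
                          int n_ch, int n_t, int kt) {
  mat W1 = par["W1"], W2 = par["W2"], Wh = par["Wh"], Wo = par["Wo"];
  mat bh = par["bh"], bo = par["bo"];
  mat g1 = par["g1"], be1 = par["be1"], g2 = par["g2"], be2 = par["be2"];
  vec rm1 = par["rm1"], rv1 = par["rv1"], rm2 = par["rm2"], rv2 = par["rv2"];
  const int n = X.n_rows, C = n_ch, T = n_t, kt_ = kt, T2 = T - kt_ + 1;
  const int f1 = W1.n_rows, f2 = W2.n_rows;
  uvec idx = regspace<uvec>(0, n - 1);
  mat Xb = make_batch(X, idx, C, T);
  mat R1 = clamp(bn_forward_eval(W1 * Xb, g1.col(0), be1.col(0), rm1, rv1),
                 0.0, datum::inf);
  mat P(f1 * kt_, T2 * n);
  for (int b = 0; b < n; ++b)
    for (int t = 0; t < T2; ++t)
      P.col(b * T2 + t) =
          vectorise(R1.cols(b * T + t, b * T + t + kt_ - 1));
  mat R2 = clamp(bn_forward_eval(W2 * P, g2.col(0), be2.col(0), rm2, rv2),
                 0.0, datum::inf);
  mat h0(f2 * T2, n);
  for (int b = 0; b < n; ++b)
    h0.col(b) = vectorise(R2.cols(b * T2, (b + 1) * T2 - 1));
  mat Zh = Wh * h0;
  Zh.each_col() += bh.col(0);
  mat O = Wo * clamp(Zh, 0.0, datum::inf);
  O.each_col() += bo.col(0);
  return softmax_cols(O).t();  // n x 2
}

// [[Rcpp::export]]
Rcpp::List cpp_bnn_fit(const arma::mat& X, const arma::ivec& y, int hidden,
                       int batch_size, double lr, int epochs, int seed) {
  const int n = X.n_rows, d = X.n_cols;
  Rng rng((unsigned long long)seed);
  mat Xt = X.t();  // d x n, column per sample

  mat muW1 = rng.normal_mat(hidden, d) * std::sqrt(1.0 / d);
  mat muW2 = rng.normal_mat(2, hidden) * std::sqrt(1.0 / hidden);
  mat mub1 = zeros<mat>(hidden, 1), mub2 = zeros<mat>(2, 1);
  mat rhoW1 = mat(hidden, d, fill::value(-5.0));
  mat rhoW2 = mat(2, hidden, fill::value(-5.0));
  mat rhob1 = mat(hidden, 1, fill::value(-5.0));
  mat rhob2 = mat(2, 1, fill::value(-5.0));

  Adam opt(lr);
  opt.attach(&muW1); opt.attach(&rhoW1); opt.attach(&mub1); opt.attach(&rhob1);
  opt.attach(&muW2); opt.attach(&rhoW2); opt.attach(&mub2); opt.attach(&rhob2);

  int n_batches = std::max(1, n / batch_size);
  double klw = 1.0 / n_batches;  // complexity weight per minibatch

  std::vector<uword> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::vector<double> loss_hist;

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng.eng);
    double ep_loss = 0.0;
    int nb = 0;
    for (int start = 0; start < n; start += batch_size) {
      int B = std::min(batch_size, n - start);
      uvec idx(B);
      for (int b = 0; b < B; ++b) idx(b) = order[start + b];
      mat Xb = Xt.cols(idx);  // d x B

      // sample weights: W = mu + softplus(rho) * eps  (reparameterisation)
      mat eW1 = rng.normal_mat(hidden, d), eW2 = rng.normal_mat(2, hidden);
      mat eb1 = rng.normal_mat(hidden, 1), eb2 = rng.normal_mat(2, 1);
      mat sW1, gW1, sW2, gW2, sb1, gb1, sb2, gb2;
      softplus_sig(rhoW1, sW1, gW1);
      softplus_sig(rhoW2, sW2, gW2);
      softplus_sig(rhob1, sb1, gb1);
      softplus_sig(rhob2, sb2, gb2);
      mat W1 = muW1 + sW1 % eW1, W2 = muW2 + sW2 % eW2;
      mat b1 = mub1 + sb1 % eb1, b2 = mub2 + sb2 % eb2;

      mat Z1 = W1 * Xb;
      Z1.each_col() += b1.col(0);
      mat H1 = clamp(Z1, 0.0, datum::inf);
      mat O = W2 * H1;
      O.each_col() += b2.col(0);
      mat Pr = softmax_cols(O);
      mat Y = zeros<mat>(2, B);
      for (int b = 0; b < B; ++b) Y(y(idx(b)), b) = 1.0;
      ep_loss += -accu(Y % log(Pr + 1e-12)) / B;
      ++nb;

      mat dO = (Pr - Y) / B;
      mat dW2 = dO * H1.t(), db2 = sum(dO, 1);
      mat dH1 = W2.t() * dO;
      mat dZ1 = dH1 % conv_to<mat>::from(Z1 > 0.0);
      mat dW1 = dZ1 * Xb.t(), db1 = sum(dZ1, 1);

      // KL(q || N(0,1)) gradients: d/dmu = mu, d/dsigma = sigma - 1/sigma
      mat gmuW1 = dW1 + klw * muW1;
      mat gmuW2 = dW2 + klw * muW2;
      mat gmub1 = db1 + klw * mub1;
      mat gmub2 = db2 + klw * mub2;
      mat grhoW1 = (dW1 % eW1 + klw * (sW1 - 1.0 / sW1)) % gW1;
      mat grhoW2 = (dW2 % eW2 + klw * (sW2 - 1.0 / sW2)) % gW2;
      mat grhob1 = (db1 % eb1 + klw * (sb1 - 1.0 / sb1)) % gb1;
      mat grhob2 = (db2 % eb2 + klw * (sb2 - 1.0 / sb2)) % gb2;

      std::vector<mat> grads = {gmuW1, grhoW1, gmub1, grhob1,
                                gmuW2, grhoW2, gmub2, grhob2};
      opt.step(grads);
    }
    loss_hist.push_back(nb ? ep_loss / nb : NA_REAL);
  }

  return Rcpp::List::create(
      Rcpp::Named("muW1") = muW1, Rcpp::Named("rhoW1") = rhoW1,
      Rcpp::Named("mub1") = mub1, Rcpp::Named("rhob1") = rhob1,
      Rcpp::Named("muW2") = muW2, Rcpp::Named("rhoW2") = rhoW2,
      Rcpp::Named("mub2") = mub2, Rcpp::Named("rhob2") = rhob2,
      Rcpp::Named("loss") = loss_hist);
}

// [[Rcpp::export]]
arma::mat cpp_bnn_predict(const Rcpp::List& par, const arma::mat& X,
                          int n_samples, int seed) {
  mat muW1 = par["muW1"], rhoW1 = par["rhoW1"];
  mat mub1 = par["mub1"], rhob1 = par["rhob1"];
  mat muW2 = par["muW2"], rhoW2 = par["rhoW2"];
  mat mub2 = par["mub2"], rhob2 = par["rhob2"];
  const int hidden = muW1.n_rows, d = muW1.n_cols, n = X.n_rows;
  Rng rng((unsigned long long)seed);
  mat Xt = X.t();
  mat sW1 = softplus(rhoW1), sW2 = softplus(rhoW2);
  mat sb1 = softplus(rhob1), sb2 = softplus(rhob2);
  mat acc = zeros<mat>(2, n);
  for (int s = 0; s < n_samples; ++s) {
    mat W1 = muW1 + sW1 % rng.normal_mat(hidden, d);
    mat W2 = muW2 + sW2 % rng.normal_mat(2, hidden);
    mat b1 = mub1 + sb1 % rng.normal_mat(hidden, 1);
    mat b2 = mub2 + sb2 % rng.normal_mat(2, 1);
    mat Z1 = W1 * Xt;
    Z1.each_col() += b1.col(0);
    mat O = W2 * clamp(Z1, 0.0, datum::inf);
    O.each_col() += b2.col(0);
    acc += softmax_cols(O);
  }
  return (acc / n_samples).t();  // n x 2
}
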