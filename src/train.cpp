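// Minibatch trainer for the hierarchical two-output network
// (d -> 16 -> 8 -> 2, SELU hidden activations, sigmoid outputs, inverted
// dropout on the hidden layers, Adam updates). The plain-R forward pass in
// R/net.R is the reference implementation used to cross-check this code in
// the test suite; keep the two in sync.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double SELU_LAMBDA = 1.0507009873554804934193349852946;
static const double SELU_ALPHA  = 1.6732632423543772848170429916717;

static mat selu(const mat& x) {
  mat out = x;
  out.transform([](double v) {
    return v > 0 ? SELU_LAMBDA * v : SELU_LAMBDA * SELU_ALPHA * (std::exp(v) - 1.0);
  });
  return out;
}

static mat selu_grad(const mat& x) {
  mat out = x;
  out.transform([](double v) {
    return v > 0 ? SELU_LAMBDA : SELU_LAMBDA * SELU_ALPHA * std::exp(v);
  });
  return out;
}

static mat sigmoid(const mat& x) {
  return 1.0 / (1.0 + exp(-x));
}

// deterministic RNG helpers (independent of R's RNG state)
static double runif01(std::mt19937& gen) {
  // 53-bit uniform in [0, 1)
  uint64_t a = gen() >> 5, b = gen() >> 6;
  return (a * 67108864.0 + b) * (1.0 / 9007199254740992.0);
}

static double rnorm01(std::mt19937& gen) {
  double u1 = runif01(gen), u2 = runif01(gen);
  if (u1 < 1e-300) u1 = 1e-300;
  return std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2);
}

struct Adam {
  mat m, v;
  Adam(uword r, uword c) : m(r, c, fill::zeros), v(r, c, fill::zeros) {}
  void step(mat& w, const mat& g, double lr, int t) {
    const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
    m = b1 * m + (1 - b1) * g;
    v = b2 * v + (1 - b2) * square(g);
    mat mhat = m / (1 - std::pow(b1, t));
    mat vhat = v / (1 - std::pow(b2, t));
    w -= lr * mhat / (sqrt(vhat) + eps);
  }
};

// [[Rcpp::export]]
Rcpp::List cpp_train_net(const arma::mat& X, const arma::vec& y_any,
                         const arma::vec& y_brca, int epochs, double lr,
                         int batch_size, double dropout, int seed,
                         double tol, int patience) {
  const uword n = X.n_rows, d = X.n_cols;
  const uword h1 = 16, h2 = 8;
  if (n == 0) Rcpp::stop("empty training set");
  if (y_any.n_elem != n || y_brca.n_elem != n)
    Rcpp::stop("label length mismatch");

  std::mt19937 gen(static_cast<uint32_t>(seed));

  // LeCun-normal initialization (variance 1/fan_in), zero biases
  auto init = [&](uword r, uword c) {
    mat w(r, c);
    double s = std::sqrt(1.0 / r);
    for (uword j = 0; j < c; ++j)
      for (uword i = 0; i < r; ++i) w(i, j) = s * rnorm01(gen);
    return w;
  };
  mat W1 = init(d, h1), W2 = init(h1, h2), W3 = init(h2, 2);
  rowvec b1(h1, fill::zeros), b2v(h2, fill::zeros), b3(2, fill::zeros);

  Adam aW1(d, h1), aW2(h1, h2), aW3(h2, 2), ab1(1, h1), ab2(1, h2), ab3(1, 2);
  int t = 0;

  const double keep = 1.0 - dropout;
  std::vector<uword> idx(n);
  for (uword i = 0; i < n; ++i) idx[i] = i;

  std::vector<double> traj;
  double best = datum::inf;
  int stall = 0;
  int epochs_run = 0;

  for (int ep = 0; ep < epochs; ++ep) {
    // Fisher-Yates shuffle
    for (uword i = n - 1; i > 0; --i) {
      uword j = static_cast<uword>(runif01(gen) * (i + 1));
      if (j > i) j = i;
      std::swap(idx[i], idx[j]);
    }
    double ep_loss = 0.0;
    for (uword start = 0; start < n; start += batch_size) {
      uword stop = std::min<uword>(start + batch_size, n);
      uword B = stop - start;
      uvec rows(B);
      for (uword i = 0; i < B; ++i) rows(i) = idx[start + i];
      mat Xb = X.rows(rows);
      vec ya = y_any(rows), yb = y_brca(rows);
      yb.replace(datum::nan, 0.0);  // masked below; any finite value works

      mat Z1 = Xb * W1; Z1.each_row() += b1;
      mat A1 = selu(Z1);
      mat M1(B, h1);
      if (dropout > 0) {
        for (uword j = 0; j < h1; ++j)
          for (uword i = 0; i < B; ++i)
            M1(i, j) = runif01(gen) < keep ? 1.0 / keep : 0.0;
      } else M1.ones();
      mat A1d = A1 % M1;

      mat Z2 = A1d * W2; Z2.each_row() += b2v;
      mat A2 = selu(Z2);
      mat M2(B, h2);
      if (dropout > 0) {
        for (uword j = 0; j < h2; ++j)
          for (uword i = 0; i < B; ++i)
            M2(i, j) = runif01(gen) < keep ? 1.0 / keep : 0.0;
      } else M2.ones();
      mat A2d = A2 % M2;

      mat Z3 = A2d * W3; Z3.each_row() += b3;
      mat P = sigmoid(Z3);
      vec P1 = clamp(P.col(0), 1e-12, 1 - 1e-12);
      vec P2 = clamp(P.col(1), 1e-12, 1 - 1e-12);

      // hierarchical cross-entropy; second term masked for non-carriers
      vec l = -(ya % log(P1) + (1 - ya) % log(1 - P1))
              - ya % (yb % log(P2) + (1 - yb) % log(1 - P2));
      ep_loss += accu(l);

      mat dZ3(B, 2);
      dZ3.col(0) = (P.col(0) - ya) / B;
      dZ3.col(1) = ya % (P.col(1) - yb) / B;

      mat dW3 = A2d.t() * dZ3;
      rowvec db3 = sum(dZ3, 0);
      mat dA2 = (dZ3 * W3.t()) % M2;
      mat dZ2 = dA2 % selu_grad(Z2);
      mat dW2 = A1d.t() * dZ2;
      rowvec db2 = sum(dZ2, 0);
      mat dA1 = (dZ2 * W2.t()) % M1;
      mat dZ1 = dA1 % selu_grad(Z1);
      mat dW1 = Xb.t() * dZ1;
      rowvec db1 = sum(dZ1, 0);

      ++t;
      aW1.step(W1, dW1, lr, t);
      aW2.step(W2, dW2, lr, t);
      aW3.step(W3, dW3, lr, t);
      { mat b = b1;  ab1.step(b, db1, lr, t);  b1 = b.row(0); }
      { mat b = b2v; ab2.step(b, db2, lr, t);  b2v = b.row(0); }
      { mat b = b3;  ab3.step(b, db3, lr, t);  b3 = b.row(0); }
    }
    ep_loss /= n;
    if (!std::isfinite(ep_loss))
      Rcpp::stop("non-finite training loss at epoch %d", ep + 1);
    traj.push_back(ep_loss);
    epochs_run = ep + 1;
    if (best - ep_loss > tol) { best = ep_loss; stall = 0; }
    else if (++stall >= patience) break;
  }

  return Rcpp::List::create(
    Rcpp::Named("W1") = W1, Rcpp::Named("b1") = b1,
    Rcpp::Named("W2") = W2, Rcpp::Named("b2") = b2v,
    Rcpp::Named("W3") = W3, Rcpp::Named("b3") = b3,
    Rcpp::Named("loss") = traj,
    Rcpp::Named("epochs_run") = epochs_run);
}
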