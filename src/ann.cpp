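#include <Rcpp.h>
using namespace Rcpp;

static inline double sigmoid(double z) { return 1.0 / (1.0 + std::exp(-z)); }

// Online (per-example) backpropagation for a p-h-1 sigmoid/sigmoid network
// with squared-error loss. X is n x p (already normalized), t in (0,1).
// `order` is a 0-based presentation order reused each epoch. Weights are
// updated in place conceptually; updated copies are returned.
// [[Rcpp::export]]
List ann_backprop(NumericMatrix X, NumericVector t, NumericMatrix W1,
                  NumericVector b1, NumericVector w2, double b2,
                  double lr, int epochs, IntegerVector order) {
  const int n = X.nrow(), p = X.ncol(), h = W1.nrow();
  NumericMatrix W1c = clone(W1);
  NumericVector b1c = clone(b1), w2c = clone(w2);
  double b2c = b2;
  std::vector<double> hid(h), dh(h);

  for (int e = 0; e < epochs; ++e) {
    for (int k = 0; k < n; ++k) {
      const int i = order[k];
      // forward
      for (int j = 0; j < h; ++j) {
        double z = b1c[j];
        for (int q = 0; q < p; ++q) z += W1c(j, q) * X(i, q);
        hid[j] = sigmoid(z);
      }
      double z2 = b2c;
      for (int j = 0; j < h; ++j) z2 += w2c[j] * hid[j];
      const double o = sigmoid(z2);
      // backward
      const double d2 = (o - t[i]) * o * (1.0 - o);
      for (int j = 0; j < h; ++j) {
        dh[j] = w2c[j] * d2 * hid[j] * (1.0 - hid[j]);
        w2c[j] -= lr * d2 * hid[j];
      }
      b2c -= lr * d2;
      for (int j = 0; j < h; ++j) {
        const double g = lr * dh[j];
        for (int q = 0; q < p; ++q) W1c(j, q) -= g * X(i, q);
        b1c[j] -= g;
      }
    }
  }
  return List::create(_["W1"] = W1c, _["b1"] = b1c, _["w2"] = w2c,
                      _["b2"] = b2c);
}
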