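#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double sigmoid(double z) { return 1.0 / (1.0 + std::exp(-z)); }

// small self-contained PRNG (xorshift32) so per-probe weight initialization
// is reproducible from a derived integer seed without touching R's RNG state
struct XorShift32 {
  uint32_t s;
  explicit XorShift32(uint32_t seed) : s(seed ? seed : 0x9E3779B9u) {}
  double unif() {
    s ^= s << 13; s ^= s >> 17; s ^= s << 5;
    return (s >> 8) * (1.0 / 16777216.0);
  }
};

// RMSE of the network output against 0/1 targets on an index subset
static double rmse_on(const std::vector<double>& w1, const std::vector<double>& b1,
                      const std::vector<double>& w2, double b2, int h,
                      const NumericVector& x, const NumericVector& y,
                      const IntegerVector& idx) {
  double ss = 0.0;
  for (int k = 0; k < idx.size(); ++k) {
    int i = idx[k];
    double net = b2;
    for (int j = 0; j < h; ++j) net += w2[j] * sigmoid(w1[j] * x[i] + b1[j]);
    double e = sigmoid(net) - y[i];
    ss += e * e;
  }
  return std::sqrt(ss / idx.size());
}

// Train a 1-input / h-hidden / 1-output sigmoid network by full-batch
// backpropagation (MSE loss, momentum), early-stopped on a held-out set.
// Returns the blind-validation RMSE of the best restart.
// [[Rcpp::export(name = ".mlp_train_cpp")]]
List mlp_train_cpp(NumericVector x, NumericVector y,
                   IntegerVector itrain, IntegerVector istop, IntegerVector ival,
                   int hidden, double lr, double momentum,
                   int max_epochs, int patience, int n_restarts, int seed) {
  const int h = hidden, ntr = itrain.size();
  double global_best_stop = R_PosInf;
  std::vector<double> gw1(h), gb1(h), gw2(h);
  double gb2 = 0.0;
  int best_restart = -1, best_epochs = 0;

  for (int r = 0; r < n_restarts; ++r) {
    XorShift32 rng((uint32_t)seed ^ (0x9E3779B9u * (uint32_t)(r + 1)));
    std::vector<double> w1(h), b1(h), w2(h);
    double b2 = (rng.unif() * 2.0 - 1.0) / std::sqrt((double)h);
    for (int j = 0; j < h; ++j) {
      w1[j] = (rng.unif() * 2.0 - 1.0) * 0.7;                 // fan-in 1
      b1[j] = (rng.unif() * 2.0 - 1.0) * 0.7;
      w2[j] = (rng.unif() * 2.0 - 1.0) / std::sqrt((double)h); // fan-in h
    }
    std::vector<double> vw1(h, 0.0), vb1(h, 0.0), vw2(h, 0.0);
    double vb2 = 0.0;
    std::vector<double> bw1 = w1, bb1 = b1, bw2 = w2;
    double bb2 = b2;
    double best_stop = rmse_on(w1, b1, w2, b2, h, x, y, istop);
    int wait = 0, epochs_run = 0;

    for (int epoch = 0; epoch < max_epochs; ++epoch) {
      std::vector<double> dw1(h, 0.0), db1(h, 0.0), dw2(h, 0.0);
      double db2 = 0.0;
      for (int k = 0; k < ntr; ++k) {
        int i = itrain[k];
        double hid[8]; // hidden <= 8 enforced on the R side
        double net = b2;
        for (int j = 0; j < h; ++j) {
          hid[j] = sigmoid(w1[j] * x[i] + b1[j]);
          net += w2[j] * hid[j];
        }
        double o = sigmoid(net);
        double dout = 2.0 * (o - y[i]) * o * (1.0 - o) / ntr;
        db2 += dout;
        for (int j = 0; j < h; ++j) {
          dw2[j] += dout * hid[j];
          double dhid = dout * w2[j] * hid[j] * (1.0 - hid[j]);
          dw1[j] += dhid * x[i];
          db1[j] += dhid;
        }
      }
      for (int j = 0; j < h; ++j) {
        vw1[j] = momentum * vw1[j] - lr * dw1[j]; w1[j] += vw1[j];
        vb1[j] = momentum * vb1[j] - lr * db1[j]; b1[j] += vb1[j];
        vw2[j] = momentum * vw2[j] - lr * dw2[j]; w2[j] += vw2[j];
      }
      vb2 = momentum * vb2 - lr * db2; b2 += vb2;
      epochs_run = epoch + 1;

      double stop_rmse = rmse_on(w1, b1, w2, b2, h, x, y, istop);
      if (stop_rmse < best_stop - 1e-9) {
        best_stop = stop_rmse;
        bw1 = w1; bb1 = b1; bw2 = w2; bb2 = b2;
        wait = 0;
      } else if (++wait > patience) {
        break;
      }
    }

    if (best_stop < global_best_stop) {
      global_best_stop = best_stop;
      gw1 = bw1; gb1 = bb1; gw2 = bw2; gb2 = bb2;
      best_restart = r;
      best_epochs = epochs_run;
    }
  }

  double val = rmse_on(gw1, gb1, gw2, gb2, h, x, y, ival);
  NumericVector weights(3 * h + 1);
  for (int j = 0; j < h; ++j) {
    weights[j] = gw1[j];
    weights[h + j] = gb1[j];
    weights[2 * h + j] = gw2[j];
  }
  weights[3 * h] = gb2;
  return List::create(_["validation_rmse"] = val,
                      _["stop_rmse"] = global_best_stop,
                      _["weights"] = weights,
                      _["restart"] = best_restart + 1,
                      _["epochs"] = best_epochs);
}
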