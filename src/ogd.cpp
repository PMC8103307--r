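// Online gradient descent for a binary logistic classifier over hashed
// sparse indicator features (Vowpal-Wabbit style): per-example updates,
// learning rate decaying with the inverse square root of the update
// count, seeded shuffling of the example order each pass.
#include <Rcpp.h>
#include <random>
#include <cmath>
using namespace Rcpp;

static inline double sigmoid(double z) {
  return z >= 0 ? 1.0 / (1.0 + std::exp(-z))
                : std::exp(z) / (1.0 + std::exp(z));
}

// FNV-1a 32-bit hash of "namespace=token" feature strings into
// [0, dim) indices.
// [[Rcpp::export]]
IntegerVector hash_features(CharacterVector feats, int dim) {
  int n = feats.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(feats, i));
    uint32_t h = 2166136261u;
    for (; *s; ++s) {
      h ^= static_cast<uint8_t>(*s);
      h *= 16777619u;
    }
    out[i] = static_cast<int>(h % static_cast<uint32_t>(dim));
  }
  return out;
}

// [[Rcpp::export]]
List ogd_fit(List feat_idx, IntegerVector y, int dim, int passes,
             double lr0, int seed) {
  int n = feat_idx.size();
  NumericVector w(dim);
  double bias = 0.0;
  std::mt19937 rng(seed);
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  long long t = 0;
  NumericVector pass_loss(passes);
  for (int p = 0; p < passes; ++p) {
    std::shuffle(order.begin(), order.end(), rng);
    double loss = 0.0;
    for (int k = 0; k < n; ++k) {
      int i = order[k];
      IntegerVector idx = feat_idx[i];
      double z = bias;
      for (int j = 0; j < idx.size(); ++j) z += w[idx[j]];
      double prob = sigmoid(z);
      double target = y[i];
      loss -= target * std::log(std::max(prob, 1e-12)) +
              (1.0 - target) * std::log(std::max(1.0 - prob, 1e-12));
      double lr = lr0 / std::sqrt(static_cast<double>(++t));
      double g = prob - target;
      for (int j = 0; j < idx.size(); ++j) w[idx[j]] -= lr * g;
      bias -= lr * g;
    }
    pass_loss[p] = n > 0 ? loss / n : 0.0;
  }
  return List::create(_["weights"] = w, _["bias"] = bias,
                      _["pass_loss"] = pass_loss);
}

// Logistic loss of one example; shares the decision function with the
// trainer so finite-difference checks exercise the trained gradient.
// [[Rcpp::export]]
double ogd_example_loss(NumericVector w, double bias, IntegerVector idx,
                        int y) {
  double z = bias;
  for (int j = 0; j < idx.size(); ++j) z += w[idx[j]];
  double prob = sigmoid(z);
  return -(y * std::log(std::max(prob, 1e-12)) +
           (1 - y) * std::log(std::max(1.0 - prob, 1e-12)));
}

// Analytic gradient of ogd_example_loss with respect to w (dense, for
// testing at small dimensions).
// [[Rcpp::export]]
NumericVector ogd_example_grad(NumericVector w, double bias,
                               IntegerVector idx, int y) {
  double z = bias;
  for (int j = 0; j < idx.size(); ++j) z += w[idx[j]];
  double g = sigmoid(z) - y;
  NumericVector out(w.size());
  for (int j = 0; j < idx.size(); ++j) out[idx[j]] += g;
  return out;
}

// [[Rcpp::export]]
NumericVector ogd_decision(List feat_idx, NumericVector w, double bias) {
  int n = feat_idx.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector idx = feat_idx[i];
    double z = bias;
    for (int j = 0; j < idx.size(); ++j) z += w[idx[j]];
    out[i] = sigmoid(z);
  }
  return out;
}
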