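// Bidirectional Elman-style recurrent BIO tagger, trained with the
// Nadam optimizer (adaptive moments + Nesterov momentum) on per-sentence
// cross-entropy. Inputs per token are the concatenation of a trainable
// word-embedding lookup, one trainable embedding per auxiliary BIO
// channel, and fixed (non-learned) feature rows such as hashed
// character-trigram vectors or pretrained word vectors.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct Nadam {
  arma::mat m, v;
  void init(const arma::mat& p) {
    m.zeros(p.n_rows, p.n_cols);
    v.zeros(p.n_rows, p.n_cols);
  }
  void step(arma::mat& p, const arma::mat& g, double lr, double t) {
    const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
    m = b1 * m + (1.0 - b1) * g;
    v = b2 * v + (1.0 - b2) * arma::square(g);
    double c1 = 1.0 - std::pow(b1, t), c2 = 1.0 - std::pow(b2, t);
    arma::mat mhat = b1 * (m / c1) + (1.0 - b1) * (g / c1);
    p -= lr * mhat / (arma::sqrt(v / c2) + eps);
  }
};

arma::mat softmax_cols(arma::mat z) {
  z.each_row() -= arma::max(z, 0);
  z = arma::exp(z);
  arma::rowvec s = arma::sum(z, 0);
  z.each_row() /= s;
  return z;
}

// Assemble the input matrix (D x T) for one sentence.
arma::mat build_input(const arma::mat& Eword, const arma::mat& Echan,
                      int n_chan, int n_chan_labels,
                      const IntegerVector& words, const IntegerMatrix& chans,
                      const arma::mat& fixed) {
  int T = words.size();
  int dw = Eword.n_rows, dc = n_chan > 0 ? Echan.n_rows : 0;
  int dfix = fixed.n_rows;
  arma::mat X(dw + n_chan * dc + dfix, T);
  for (int t = 0; t < T; ++t) {
    X.submat(0, t, dw - 1, t) = Eword.col(words[t] - 1);
    for (int c = 0; c < n_chan; ++c) {
      int col = c * n_chan_labels + (chans(c, t) - 1);
      X.submat(dw + c * dc, t, dw + (c + 1) * dc - 1, t) = Echan.col(col);
    }
    if (dfix > 0)
      X.submat(dw + n_chan * dc, t, X.n_rows - 1, t) = fixed.col(t);
  }
  return X;
}

struct Weights {
  arma::mat Eword, Echan, Wf, Uf, Wb, Ub, Wo;
  arma::vec bf, bb, bo;
};

Weights unpack(const List& w) {
  Weights W;
  W.Eword = as<arma::mat>(w["Eword"]);
  W.Echan = as<arma::mat>(w["Echan"]);
  W.Wf = as<arma::mat>(w["Wf"]); W.Uf = as<arma::mat>(w["Uf"]);
  W.Wb = as<arma::mat>(w["Wb"]); W.Ub = as<arma::mat>(w["Ub"]);
  W.Wo = as<arma::mat>(w["Wo"]);
  W.bf = as<arma::vec>(w["bf"]); W.bb = as<arma::vec>(w["bb"]);
  W.bo = as<arma::vec>(w["bo"]);
  return W;
}

void forward_rnn(const Weights& W, const arma::mat& X,
                 arma::mat& Hf, arma::mat& Hb) {
  int h = W.Wf.n_rows, T = X.n_cols;
  Hf.zeros(h, T); Hb.zeros(h, T);
  arma::vec prev(h, arma::fill::zeros);
  for (int t = 0; t < T; ++t) {
    prev = arma::tanh(W.Wf * X.col(t) + W.Uf * prev + W.bf);
    Hf.col(t) = prev;
  }
  prev.zeros();
  for (int t = T - 1; t >= 0; --t) {
    prev = arma::tanh(W.Wb * X.col(t) + W.Ub * prev + W.bb);
    Hb.col(t) = prev;
  }
}

} // namespace

// [[Rcpp::export]]
List birnn_fit(List word_idx, List chan_idx, List fixed_feats, List labels,
               int vocab_size, int n_chan, int n_chan_labels,
               int d_word, int d_chan, int hidden, int n_labels,
               int d_fixed, int epochs, double dropout, double lr,
               int seed) {
  int n_sent = word_idx.size();
  std::mt19937 rng(seed);
  std::uniform_real_distribution<double> unif(-0.1, 0.1);
  std::uniform_real_distribution<double> u01(0.0, 1.0);

  int D = d_word + n_chan * d_chan + d_fixed;
  Weights W;
  auto init_mat = [&](int r, int c) {
    arma::mat m(r, c);
    for (arma::uword i = 0; i < m.n_elem; ++i) m(i) = unif(rng);
    return m;
  };
  W.Eword = init_mat(d_word, vocab_size);
  W.Echan = n_chan > 0 ? init_mat(d_chan, n_chan * n_chan_labels)
                       : arma::mat(std::max(d_chan, 1), 1, arma::fill::zeros);
  W.Wf = init_mat(hidden, D); W.Uf = init_mat(hidden, hidden);
  W.Wb = init_mat(hidden, D); W.Ub = init_mat(hidden, hidden);
  W.Wo = init_mat(n_labels, 2 * hidden);
  W.bf.zeros(hidden); W.bb.zeros(hidden); W.bo.zeros(n_labels);

  Nadam oEw, oEc, oWf, oUf, obf, oWb, oUb, obb, oWo, obo;
  oEw.init(W.Eword); oEc.init(W.Echan);
  oWf.init(W.Wf); oUf.init(W.Uf); obf.init(W.bf);
  oWb.init(W.Wb); oUb.init(W.Ub); obb.init(W.bb);
  oWo.init(W.Wo); obo.init(W.bo);

  std::vector<int> order(n_sent);
  for (int i = 0; i < n_sent; ++i) order[i] = i;

  NumericVector epoch_loss(epochs);
  double keep = 1.0 - dropout;
  long long step = 0;

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    double total_loss = 0.0;
    long long total_tok = 0;
    for (int si = 0; si < n_sent; ++si) {
      int s = order[si];
      IntegerVector words = word_idx[s];
      int T = words.size();
      if (T == 0) continue;
      IntegerMatrix chans = chan_idx[s];
      arma::mat fixed = as<arma::mat>(fixed_feats[s]);
      IntegerVector y = labels[s];

      arma::mat X = build_input(W.Eword, W.Echan, n_chan, n_chan_labels,
                                words, chans, fixed);
      arma::mat Hf, Hb;
      forward_rnn(W, X, Hf, Hb);

      // per-sentence dropout masks on the recurrent outputs
      arma::vec mf(hidden), mb(hidden);
      if (dropout > 0.0) {
        for (int i = 0; i < hidden; ++i) {
          mf(i) = (u01(rng) < keep) ? 1.0 / keep : 0.0;
          mb(i) = (u01(rng) < keep) ? 1.0 / keep : 0.0;
        }
      } else { mf.ones(); mb.ones(); }

      arma::mat Hfm = Hf.each_col() % mf;
      arma::mat Hbm = Hb.each_col() % mb;
      arma::mat H = arma::join_cols(Hfm, Hbm);
      arma::mat Z = W.Wo * H;
      Z.each_col() += W.bo;
      arma::mat P = softmax_cols(Z);
      for (int t = 0; t < T; ++t) {
        total_loss -= std::log(std::max(P(y[t] - 1, t), 1e-12));
      }
      total_tok += T;

      // backward
      arma::mat dZ = P;
      for (int t = 0; t < T; ++t) dZ(y[t] - 1, t) -= 1.0;
      arma::mat dWo = dZ * H.t();
      arma::vec dbo = arma::sum(dZ, 1);
      arma::mat dH = W.Wo.t() * dZ;
      arma::mat dHf = dH.rows(0, hidden - 1).each_col() % mf;
      arma::mat dHb = dH.rows(hidden, 2 * hidden - 1).each_col() % mb;

      arma::mat dWf(arma::size(W.Wf), arma::fill::zeros);
      arma::mat dUf(arma::size(W.Uf), arma::fill::zeros);
      arma::vec dbf(hidden, arma::fill::zeros);
      arma::mat dWb(arma::size(W.Wb), arma::fill::zeros);
      arma::mat dUb(arma::size(W.Ub), arma::fill::zeros);
      arma::vec dbb(hidden, arma::fill::zeros);
      arma::mat dX(arma::size(X), arma::fill::zeros);

      arma::vec dpre(hidden, arma::fill::zeros);
      for (int t = T - 1; t >= 0; --t) {
        arma::vec dh = dHf.col(t) + W.Uf.t() * dpre;
        dpre = dh % (1.0 - arma::square(Hf.col(t)));
        dWf += dpre * X.col(t).t();
        if (t > 0) dUf += dpre * Hf.col(t - 1).t();
        dbf += dpre;
        dX.col(t) += W.Wf.t() * dpre;
      }
      dpre.zeros();
      for (int t = 0; t < T; ++t) {
        arma::vec dh = dHb.col(t) + W.Ub.t() * dpre;
        dpre = dh % (1.0 - arma::square(Hb.col(t)));
        dWb += dpre * X.col(t).t();
        if (t < T - 1) dUb += dpre * Hb.col(t + 1).t();
        dbb += dpre;
        dX.col(t) += W.Wb.t() * dpre;
      }

      arma::mat dEw(arma::size(W.Eword), arma::fill::zeros);
      arma::mat dEc(arma::size(W.Echan), arma::fill::zeros);
      for (int t = 0; t < T; ++t) {
        dEw.col(words[t] - 1) += dX.submat(0, t, d_word - 1, t);
        for (int c = 0; c < n_chan; ++c) {
          int col = c * n_chan_labels + (chans(c, t) - 1);
          dEc.col(col) += dX.submat(d_word + c * d_chan, t,
                                    d_word + (c + 1) * d_chan - 1, t);
        }
      }

      double t_step = static_cast<double>(++step);
      oEw.step(W.Eword, dEw, lr, t_step);
      if (n_chan > 0) oEc.step(W.Echan, dEc, lr, t_step);
      oWf.step(W.Wf, dWf, lr, t_step);
      oUf.step(W.Uf, dUf, lr, t_step);
      arma::mat bfm(W.bf), dbfm(dbf);
      obf.step(bfm, dbfm, lr, t_step); W.bf = bfm;
      oWb.step(W.Wb, dWb, lr, t_step);
      oUb.step(W.Ub, dUb, lr, t_step);
      arma::mat bbm(W.bb), dbbm(dbb);
      obb.step(bbm, dbbm, lr, t_step); W.bb = bbm;
      oWo.step(W.Wo, dWo, lr, t_step);
      arma::mat bom(W.bo), dbom(dbo);
      obo.step(bom, dbom, lr, t_step); W.bo = bom;
    }
    epoch_loss[ep] = total_tok > 0 ? total_loss / total_tok : 0.0;
  }

  return List::create(
    _["Eword"] = W.Eword, _["Echan"] = W.Echan,
    _["Wf"] = W.Wf, _["Uf"] = W.Uf, _["bf"] = W.bf,
    _["Wb"] = W.Wb, _["Ub"] = W.Ub, _["bb"] = W.bb,
    _["Wo"] = W.Wo, _["bo"] = W.bo,
    _["epoch_loss"] = epoch_loss);
}

// [[Rcpp::export]]
List birnn_predict_cpp(List weights, List word_idx, List chan_idx,
                       List fixed_feats, int n_chan, int n_chan_labels) {
  Weights W = unpack(weights);
  int n_sent = word_idx.size();
  List out(n_sent);
  for (int s = 0; s < n_sent; ++s) {
    IntegerVector words = word_idx[s];
    int T = words.size();
    if (T == 0) { out[s] = IntegerVector(0); continue; }
    IntegerMatrix chans = chan_idx[s];
    arma::mat fixed = as<arma::mat>(fixed_feats[s]);
    arma::mat X = build_input(W.Eword, W.Echan, n_chan, n_chan_labels,
                              words, chans, fixed);
    arma::mat Hf, Hb;
    forward_rnn(W, X, Hf, Hb);
    arma::mat Z = W.Wo * arma::join_cols(Hf, Hb);
    Z.each_col() += W.bo;
    IntegerVector pred(T);
    for (int t = 0; t < T; ++t) {
      pred[t] = static_cast<int>(Z.col(t).index_max()) + 1;
    }
    out[s] = pred;
  }
  return out;
}
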