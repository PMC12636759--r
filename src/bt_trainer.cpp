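// Inner training loop of a Bradley-Terry ranking member: minibatch
// forward/backward through the MLP (linear -> batch-norm -> ReLU ->
// dropout per hidden layer, bias-free final linear), Adam updates, and
// early stopping on validation loss. Semantics mirror the R reference
// implementation in R/mlp.R (which remains the prediction path); all
// randomness (epoch shuffles, dropout masks) is drawn from R's RNG so
// results are reproducible under set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double BN_EPS = 1e-5;
static const double BN_MOMENTUM = 0.1;

struct Hidden {
  mat W; rowvec b, gamma, beta, runMean, runVar;
  // Adam state
  mat mW, vW; rowvec mb, vb, mg, vg, mbt, vbt;
};

struct Net {
  std::vector<Hidden> hidden;
  vec Wout;           // final layer weights (h_last x 1)
  vec mOut, vOut;     // Adam state
  long t = 0;         // Adam step counter
};

static rowvec as_rowvec(SEXP x) { return Rcpp::as<rowvec>(x); }

static Net net_from_list(const Rcpp::List& layers) {
  Net net;
  int nL = layers.size();
  for (int j = 0; j < nL - 1; ++j) {
    Rcpp::List ly = layers[j];
    Hidden h;
    h.W = Rcpp::as<mat>(ly["W"]);
    h.b = as_rowvec(ly["b"]);
    h.gamma = as_rowvec(ly["gamma"]);
    h.beta = as_rowvec(ly["beta"]);
    h.runMean = as_rowvec(ly["runMean"]);
    h.runVar = as_rowvec(ly["runVar"]);
    h.mW = zeros<mat>(size(h.W)); h.vW = zeros<mat>(size(h.W));
    h.mb = zeros<rowvec>(h.b.n_elem); h.vb = h.mb;
    h.mg = h.mb; h.vg = h.mb; h.mbt = h.mb; h.vbt = h.mb;
    net.hidden.push_back(h);
  }
  Rcpp::List fin = layers[nL - 1];
  net.Wout = vectorise(Rcpp::as<mat>(fin["W"]));
  net.mOut = zeros<vec>(net.Wout.n_elem);
  net.vOut = net.mOut;
  return net;
}

static Rcpp::List net_to_list(const Net& net) {
  Rcpp::List out(net.hidden.size() + 1);
  for (size_t j = 0; j < net.hidden.size(); ++j) {
    const Hidden& h = net.hidden[j];
    out[j] = Rcpp::List::create(
      Rcpp::Named("W") = h.W, Rcpp::Named("b") = h.b.t(),
      Rcpp::Named("gamma") = h.gamma.t(), Rcpp::Named("beta") = h.beta.t(),
      Rcpp::Named("runMean") = h.runMean.t(),
      Rcpp::Named("runVar") = h.runVar.t());
  }
  mat Wout(net.Wout);
  out[net.hidden.size()] = Rcpp::List::create(Rcpp::Named("W") = Wout);
  return out;
}

struct Cache {
  mat input, ctr, Zhat, mask; umat relu; rowvec invStd;
  bool hasMask = false;
};

// Training-mode forward; advances running statistics and fills caches.
static vec forward_train(Net& net, const mat& X, double dropout,
                         std::vector<Cache>& caches) {
  mat A = X;
  caches.resize(net.hidden.size());
  for (size_t j = 0; j < net.hidden.size(); ++j) {
    Hidden& h = net.hidden[j];
    mat Z = A * h.W;
    Z.each_row() += h.b;
    double m = (double)Z.n_rows;
    rowvec mu = mean(Z, 0);
    mat ctr = Z.each_row() - mu;
    rowvec v = mean(ctr % ctr, 0);
    rowvec invStd = 1.0 / sqrt(v + BN_EPS);
    mat Zhat = ctr.each_row() % invStd;
    rowvec unb = (m > 1.5) ? rowvec(v * (m / (m - 1.0))) : v;
    h.runMean = (1 - BN_MOMENTUM) * h.runMean + BN_MOMENTUM * mu;
    h.runVar = (1 - BN_MOMENTUM) * h.runVar + BN_MOMENTUM * unb;
    mat B = Zhat.each_row() % h.gamma;
    B.each_row() += h.beta;
    umat relu = B > 0;
    mat A2 = B % conv_to<mat>::from(relu);
    Cache& ca = caches[j];
    ca.input = A; ca.ctr = ctr; ca.Zhat = Zhat; ca.relu = relu;
    ca.invStd = invStd;
    if (dropout > 0) {
      mat mask(A2.n_rows, A2.n_cols);
      // column-major fill, matching R's matrix(runif(n), ...) convention
      for (uword c = 0; c < mask.n_cols; ++c)
        for (uword r = 0; r < mask.n_rows; ++r)
          mask(r, c) = (::unif_rand() >= dropout) ? 1.0 / (1 - dropout) : 0.0;
      A2 %= mask;
      ca.mask = mask; ca.hasMask = true;
    }
    A = A2;
  }
  return A * net.Wout;
}

// Evaluation-mode forward (running statistics, no dropout).
static vec forward_eval(const Net& net, const mat& X) {
  mat A = X;
  for (size_t j = 0; j < net.hidden.size(); ++j) {
    const Hidden& h = net.hidden[j];
    mat Z = A * h.W;
    Z.each_row() += h.b;
    rowvec invStd = 1.0 / sqrt(h.runVar + BN_EPS);
    mat Zhat = (Z.each_row() - h.runMean).each_row() % invStd;
    mat B = Zhat.each_row() % h.gamma;
    B.each_row() += h.beta;
    A = B % conv_to<mat>::from(B > 0);
  }
  return A * net.Wout;
}

static inline void adam_update(mat& p, const mat& g, mat& m, mat& v,
                               double lr, double b1c, double b2c) {
  m = 0.9 * m + 0.1 * g;
  v = 0.999 * v + 0.001 * (g % g);
  p -= lr * (m / b1c) / (sqrt(v / b2c) + 1e-8);
}
static inline void adam_update(rowvec& p, const rowvec& g, rowvec& m,
                               rowvec& v, double lr, double b1c, double b2c) {
  m = 0.9 * m + 0.1 * g;
  v = 0.999 * v + 0.001 * (g % g);
  p -= lr * (m / b1c) / (sqrt(v / b2c) + 1e-8);
}
static inline void adam_update(vec& p, const vec& g, vec& m, vec& v,
                               double lr, double b1c, double b2c) {
  m = 0.9 * m + 0.1 * g;
  v = 0.999 * v + 0.001 * (g % g);
  p -= lr * (m / b1c) / (sqrt(v / b2c) + 1e-8);
}

// Backward + Adam step. dScores: dLoss/dscore, aligned with the chunk rows.
static void backward_step(Net& net, const std::vector<Cache>& caches,
                          const mat& lastA, const vec& dScores,
                          double lr, double wd) {
  net.t += 1;
  double b1c = 1 - std::pow(0.9, (double)net.t);
  double b2c = 1 - std::pow(0.999, (double)net.t);
  vec gOut = lastA.t() * dScores + wd * net.Wout;
  mat dA = dScores * net.Wout.t();
  adam_update(net.Wout, gOut, net.mOut, net.vOut, lr, b1c, b2c);
  for (int j = (int)net.hidden.size() - 1; j >= 0; --j) {
    const Cache& ca = caches[j];
    Hidden& h = net.hidden[j];
    if (ca.hasMask) dA %= ca.mask;
    mat dB = dA % conv_to<mat>::from(ca.relu);
    rowvec dgamma = sum(dB % ca.Zhat, 0);
    rowvec dbeta = sum(dB, 0);
    mat dZhat = dB.each_row() % h.gamma;
    double m = (double)dZhat.n_rows;
    rowvec s1 = sum(dZhat, 0) / m;
    rowvec s2 = sum(dZhat % ca.Zhat, 0) / m;
    mat dZ = dZhat.each_row() - s1;
    dZ -= ca.Zhat.each_row() % s2;
    dZ.each_row() %= ca.invStd;
    mat gW = ca.input.t() * dZ + wd * h.W;
    rowvec gb = sum(dZ, 0);
    dA = dZ * h.W.t();
    adam_update(h.W, gW, h.mW, h.vW, lr, b1c, b2c);
    adam_update(h.b, gb, h.mb, h.vb, lr, b1c, b2c);
    adam_update(h.gamma, dgamma, h.mg, h.vg, lr, b1c, b2c);
    adam_update(h.beta, dbeta, h.mbt, h.vbt, lr, b1c, b2c);
  }
}

static inline double softplus1(double x) {
  return x > 0 ? x + std::log1p(std::exp(-x)) : std::log1p(std::exp(x));
}

// Fisher-Yates shuffle driven by R's RNG.
static void shuffle_r(std::vector<int>& idx) {
  for (int i = (int)idx.size() - 1; i > 0; --i) {
    int j = (int)std::floor(::unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(idx[i], idx[j]);
  }
}

// [[Rcpp::export(name = ".cppTrainBT")]]
Rcpp::List cppTrainBT(const arma::mat& X, Rcpp::IntegerVector trainW,
                      Rcpp::IntegerVector trainL, Rcpp::IntegerVector valW,
                      Rcpp::IntegerVector valL, Rcpp::List layers,
                      int maxEpochs, int patience, int valEvery,
                      int pairBatch, double lr, double weightDecay,
                      double dropout) {
  Net net = net_from_list(layers);
  int nTrain = trainW.size();
  int nVal = valW.size();
  bool hasVal = nVal > 0;
  std::vector<int> order(nTrain);
  for (int i = 0; i < nTrain; ++i) order[i] = i;

  double bestLoss = datum::inf;
  int bestEpoch = 0;
  Net best = net;
  std::vector<double> histTrain, histVal;
  std::vector<int> histEpoch;

  // local (row-compacted) index buffers per chunk
  std::vector<int> uniq; uniq.reserve(2 * pairBatch);
  std::vector<int> mapBuf(X.n_rows);

  for (int epoch = 1; epoch <= maxEpochs; ++epoch) {
    shuffle_r(order);
    double epochLoss = 0;
    for (int start = 0; start < nTrain; start += pairBatch) {
      int stop = std::min(start + pairBatch, nTrain);
      int nP = stop - start;
      uniq.clear();
      std::fill(mapBuf.begin(), mapBuf.end(), -1);
      for (int k = start; k < stop; ++k) {
        for (int rid : {trainW[order[k]], trainL[order[k]]}) {
          if (mapBuf[rid] < 0) {
            mapBuf[rid] = (int)uniq.size();
            uniq.push_back(rid);
          }
        }
      }
      mat Xu((int)uniq.size(), X.n_cols);
      for (size_t r = 0; r < uniq.size(); ++r) Xu.row(r) = X.row(uniq[r]);
      std::vector<Cache> caches;
      vec s = forward_train(net, Xu, dropout, caches);
      vec dScores = zeros<vec>(uniq.size());
      for (int k = start; k < stop; ++k) {
        int iw = mapBuf[trainW[order[k]]];
        int il = mapBuf[trainL[order[k]]];
        double d = s(iw) - s(il);
        epochLoss += softplus1(-d);
        double g = (1.0 / (1.0 + std::exp(-d)) - 1.0) / nP;
        dScores(iw) += g;
        dScores(il) -= g;
      }
      // recover post-dropout activations of the last hidden layer
      mat lastA = caches.back().Zhat.each_row() % net.hidden.back().gamma;
      lastA.each_row() += net.hidden.back().beta;
      lastA %= conv_to<mat>::from(caches.back().relu);
      if (caches.back().hasMask) lastA %= caches.back().mask;
      backward_step(net, caches, lastA, dScores, lr, weightDecay);
    }
    double trainLoss = epochLoss / nTrain;
    double valLoss = NA_REAL;
    if (hasVal && epoch % valEvery == 0) {
      // evaluate on the rows the validation pairs touch
      uniq.clear();
      std::fill(mapBuf.begin(), mapBuf.end(), -1);
      for (int k = 0; k < nVal; ++k) {
        for (int rid : {valW[k], valL[k]}) {
          if (mapBuf[rid] < 0) {
            mapBuf[rid] = (int)uniq.size();
            uniq.push_back(rid);
          }
        }
      }
      mat Xv((int)uniq.size(), X.n_cols);
      for (size_t r = 0; r < uniq.size(); ++r) Xv.row(r) = X.row(uniq[r]);
      vec sv = forward_eval(net, Xv);
      double vl = 0;
      for (int k = 0; k < nVal; ++k)
        vl += softplus1(-(sv(mapBuf[valW[k]]) - sv(mapBuf[valL[k]])));
      valLoss = vl / nVal;
      if (valLoss < bestLoss) {
        bestLoss = valLoss; bestEpoch = epoch; best = net;
      }
      histEpoch.push_back(epoch); histTrain.push_back(trainLoss);
      histVal.push_back(valLoss);
      if (epoch - bestEpoch >= patience) break;
      continue;
    }
    histEpoch.push_back(epoch); histTrain.push_back(trainLoss);
    histVal.push_back(valLoss);
  }
  const Net& fin = (hasVal && std::isfinite(bestLoss)) ? best : net;
  return Rcpp::List::create(
    Rcpp::Named("layers") = net_to_list(fin),
    Rcpp::Named("history") = Rcpp::DataFrame::create(
      Rcpp::Named("epoch") = histEpoch,
      Rcpp::Named("trainLoss") = histTrain,
      Rcpp::Named("valLoss") = histVal),
    Rcpp::Named("bestEpoch") = bestEpoch);
}
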