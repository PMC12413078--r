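// SGD training core for DeepGAM.
//
// The bias-free shape network f(z) = tanh(t3 . relu(T2 relu(t1 z))) is
// positively homogeneous in z on each half-line, so it collapses exactly to
//   f(z) = act(kp * max(z, 0) + km * max(-z, 0)),
//   kp = t3 . relu(T2 relu(t1)),  km = t3 . relu(T2 relu(-t1)).
// Forward and backward passes below use this collapsed form; gradients are
// identical to backpropagation through the direct composition (including
// the relu'(0) = 0 convention), which the R test-suite verifies against
// finite differences and a naive layer-by-layer implementation.
//
// Gate semantics: forward g = 1 iff phi >= 0; backward the gate behaves as
// sigma(phi) (straight-through estimator). The input path z = x * g(phi)
// uses the binary gate in the forward pass, so dead features contribute
// exactly 0 and their shape weights receive no gradient; phi receives the
// sigma-surrogate gradient from the z-path and from the resource
// regularizer R2. Weight decay applies to theta and beta0 only.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static inline arma::vec relu(const arma::vec& v) {
  return arma::clamp(v, 0.0, arma::datum::inf);
}

static inline double sigd(double phi) {
  double s = 1.0 / (1.0 + std::exp(-phi));
  return s * (1.0 - s);
}

// Per-feature half-line slopes and cached intermediates for backward.
struct Chain {
  arma::mat P, Mn, Up, Um, Vp, Vm; // C x M
  arma::vec kp, km;                // M
};

// Dead gates (g = 0) are skipped: their input is identically zero, so
// their contribution, all their gradients, and hence their whole chain
// are zero; their weights stay frozen (death is absorbing, so frozen
// weights are unobservable).
static void forward_chains(const arma::mat& T1, const arma::cube& T2,
                           const arma::mat& T3, const arma::vec& g,
                           Chain& ch) {
  const arma::uword C = T1.n_rows, M = T1.n_cols;
  ch.P.set_size(C, M); ch.Mn.set_size(C, M);
  ch.Up.set_size(C, M); ch.Um.set_size(C, M);
  ch.Vp.set_size(C, M); ch.Vm.set_size(C, M);
  ch.kp.zeros(M); ch.km.zeros(M);
  for (arma::uword j = 0; j < M; ++j) {
    if (g(j) == 0.0) continue;
    ch.P.col(j) = relu(T1.col(j));
    ch.Mn.col(j) = relu(-T1.col(j));
    ch.Up.col(j) = T2.slice(j) * ch.P.col(j);
    ch.Um.col(j) = T2.slice(j) * ch.Mn.col(j);
    ch.Vp.col(j) = relu(ch.Up.col(j));
    ch.Vm.col(j) = relu(ch.Um.col(j));
    ch.kp(j) = arma::dot(T3.col(j), ch.Vp.col(j));
    ch.km(j) = arma::dot(T3.col(j), ch.Vm.col(j));
  }
}

// Batch forward: contributions (B x M) from gated inputs Z.
static arma::mat contributions(const arma::mat& Z, const arma::vec& kp,
                               const arma::vec& km, bool use_tanh) {
  arma::mat Zp = arma::clamp(Z, 0.0, arma::datum::inf);
  arma::mat Zm = arma::clamp(-Z, 0.0, arma::datum::inf);
  arma::mat pre = Zp.each_row() % kp.t() + Zm.each_row() % km.t();
  return use_tanh ? arma::tanh(pre) : pre;
}

// [[Rcpp::export(name = ".deepgam_sgd_cpp")]]
List deepgam_sgd_cpp(const arma::mat& X, const arma::vec& y,
                     const arma::mat& Xval, const arma::vec& yval,
                     bool has_val,
                     const arma::mat& T1in, const arma::cube& T2in,
                     const arma::mat& T3in, const arma::vec& phiin,
                     double beta0,
                     const arma::imat& order, // epochs x N, 1-based rows
                     int batch, double lr, double lambda1, double lambda2,
                     double wd, bool use_R1, bool use_tanh, bool freeze_phi,
                     bool classification) {
  // explicit deep copies: a by-value arma::cube parameter would borrow the
  // R object's memory and the update would mutate the caller's model
  arma::mat T1 = T1in, T3 = T3in;
  arma::cube T2 = T2in;
  arma::vec phi = phiin;
  const arma::uword N = order.n_cols, M = X.n_cols;
  const int epochs = order.n_rows;
  const int steps = (int)((N + batch - 1) / batch);

  arma::vec h_obj(epochs), h_loss(epochs), h_r1(epochs), h_r2(epochs);
  arma::vec h_alive(epochs), h_valf1(epochs);
  h_valf1.fill(arma::datum::nan);

  Chain ch;
  for (int e = 0; e < epochs; ++e) {
    double s_obj = 0, s_loss = 0, s_r1 = 0, s_r2 = 0;
    for (int s = 0; s < steps; ++s) {
      arma::uword lo = (arma::uword)s * batch;
      arma::uword hi = std::min<arma::uword>(lo + batch, N) - 1;
      const arma::uword B = hi - lo + 1;
      arma::uvec idx(B);
      for (arma::uword b = 0; b < B; ++b)
        idx(b) = (arma::uword)order(e, lo + b) - 1;

      arma::mat Xb = X.rows(idx);
      arma::vec yb = y.elem(idx);

      arma::vec g(M);
      for (arma::uword j = 0; j < M; ++j) g(j) = phi(j) >= 0 ? 1.0 : 0.0;
      arma::mat Z = Xb.each_row() % g.t();

      forward_chains(T1, T2, T3, g, ch);
      arma::mat Zp = arma::clamp(Z, 0.0, arma::datum::inf);
      arma::mat Zm = arma::clamp(-Z, 0.0, arma::datum::inf);
      arma::mat pre = Zp.each_row() % ch.kp.t() + Zm.each_row() % ch.km.t();
      arma::mat out = use_tanh ? arma::mat(arma::tanh(pre)) : pre;

      arma::vec score = beta0 + arma::sum(out, 1);
      arma::vec resid = score - yb;
      double loss = arma::mean(arma::square(resid));
      double r1 = arma::accu(arma::square(out)) / (double)B;
      double r2 = arma::accu(g);
      double obj = loss + (use_R1 ? lambda1 * r1 : 0.0) + lambda2 * r2;
      if (!std::isfinite(obj)) {
        stop("non-finite objective at epoch %d, step %d", e + 1, s + 1);
      }
      s_obj += obj; s_loss += loss; s_r1 += r1; s_r2 += r2;

      // ---- backward ----
      arma::mat dout(B, M);
      dout.each_col() = (2.0 / B) * resid;
      if (use_R1) dout += (lambda1 * 2.0 / B) * out;
      arma::mat dpre = use_tanh ? arma::mat(dout % (1.0 - arma::square(out)))
                                : dout;

      arma::vec dkp = arma::sum(dpre % Zp, 0).t();
      arma::vec dkm = arma::sum(dpre % Zm, 0).t();

      if (!freeze_phi) {
        // dz through the half-line slopes, then the sigma surrogate for phi
        arma::mat pos = arma::conv_to<arma::mat>::from(Z > 0);
        arma::mat neg = arma::conv_to<arma::mat>::from(Z < 0);
        arma::mat dz = dpre % (pos.each_row() % ch.kp.t() -
                               neg.each_row() % ch.km.t());
        arma::vec dzx = arma::sum(dz % Xb, 0).t();
        for (arma::uword j = 0; j < M; ++j) {
          double gphi = (dzx(j) + lambda2) * sigd(phi(j));
          phi(j) -= lr * gphi;
        }
      }

      double dbeta0 = (2.0 / B) * arma::accu(resid);
      beta0 -= lr * (dbeta0 + wd * beta0);

      for (arma::uword j = 0; j < M; ++j) {
        if (g(j) == 0.0) continue; // dead: frozen, chain not computed
        if (dkp(j) == 0.0 && dkm(j) == 0.0 && wd == 0.0) continue;
        arma::vec dT3 = dkp(j) * ch.Vp.col(j) + dkm(j) * ch.Vm.col(j);
        arma::vec dup = (dkp(j) * T3.col(j)) %
          arma::conv_to<arma::vec>::from(ch.Up.col(j) > 0);
        arma::vec dum = (dkm(j) * T3.col(j)) %
          arma::conv_to<arma::vec>::from(ch.Um.col(j) > 0);
        arma::vec dp = T2.slice(j).t() * dup;
        arma::vec dm = T2.slice(j).t() * dum;
        arma::vec dT1 = dp % arma::conv_to<arma::vec>::from(T1.col(j) > 0) -
                        dm % arma::conv_to<arma::vec>::from(T1.col(j) < 0);
        T3.col(j) -= lr * (dT3 + wd * T3.col(j));
        T2.slice(j) -= lr * (dup * ch.P.col(j).t() + dum * ch.Mn.col(j).t() +
                             wd * T2.slice(j));
        T1.col(j) -= lr * (dT1 + wd * T1.col(j));
      }
    }
    h_obj(e) = s_obj / steps; h_loss(e) = s_loss / steps;
    h_r1(e) = s_r1 / steps;   h_r2(e) = s_r2 / steps;
    h_alive(e) = arma::accu(phi >= 0);

    if (has_val && classification) {
      arma::vec gv(M);
      for (arma::uword j = 0; j < M; ++j) gv(j) = phi(j) >= 0 ? 1.0 : 0.0;
      forward_chains(T1, T2, T3, gv, ch);
      arma::mat Zv = Xval.each_row() % gv.t();
      arma::mat outv = contributions(Zv, ch.kp, ch.km, use_tanh);
      arma::vec sv = beta0 + arma::sum(outv, 1);
      double tp = 0, fp = 0, fn = 0;
      for (arma::uword i = 0; i < sv.n_elem; ++i) {
        int pred = sv(i) > 0 ? 1 : -1;
        if (pred == 1 && yval(i) == 1) tp++;
        else if (pred == 1 && yval(i) == -1) fp++;
        else if (pred == -1 && yval(i) == 1) fn++;
      }
      double prec = (tp + fp) > 0 ? tp / (tp + fp) : 0.0;
      double rec = (tp + fn) > 0 ? tp / (tp + fn) : 0.0;
      h_valf1(e) = (prec + rec) > 0 ? 2 * prec * rec / (prec + rec) : 0.0;
    }
  }

  return List::create(
    _["theta1"] = T1, _["theta2"] = T2, _["theta3"] = T3,
    _["phi"] = phi, _["beta0"] = beta0,
    _["objective"] = h_obj, _["loss"] = h_loss,
    _["r1"] = h_r1, _["r2"] = h_r2,
    _["alive"] = h_alive, _["val_f1"] = h_valf1);
}
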