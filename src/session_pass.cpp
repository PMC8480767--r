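// Core forward/backward pass of the change-detection network models over one
// session. The three variants share one computation graph:
//
//   r~_t  = relu(r_t * (1 + eps_in))                 multiplicative input noise
//   x_t   = (x_{t-1} + dt/tau_x) / (1 + dt/tau_x + U dt r~_t)   backward Euler
//   u_t   = x_t * r~_t                               depression-gated drive
//   a_t   = W_ad u_t + W_pl r~_t + W_rec h~_{t-1} + b_h
//   h_t   = relu(a_t);  h~_t = relu(h_t * (1 + eps_h))
//   z_t   = w_out . h~_t + b_out
//
// STPNet has only W_ad; RNN has W_pl and W_rec; STPRNN has all three blocks.
// Noise matrices are generated in R (so all randomness follows R's RNG) and
// passed in; gradients are exact backprop-through-time treating the noise and
// the depression trajectory as data (x depends only on inputs, not weights).
// Input-block contributions and gradients are computed as whole-session
// matrix products; only the recurrent pathway runs a sequential loop.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double bce_logit(double z, double y) {
  return std::max(z, 0.0) - z * y + std::log1p(std::exp(-std::fabs(z)));
}

// [[Rcpp::export]]
Rcpp::List cpp_session_pass(const arma::mat& drive,   // T x n_in raw input
                            const arma::mat& eps_in,  // T x n_in noise
                            const arma::mat& eps_h,   // T x n_h noise
                            const arma::uvec& mask,   // T, 1 = in the loss
                            const arma::vec& y,       // T, labels (0/1)
                            const arma::mat& W_ad,    // n_h x n_in or 0 x 0
                            const arma::mat& W_pl,    // n_h x n_in or 0 x 0
                            const arma::mat& W_rec,   // n_h x n_h  or 0 x 0
                            const arma::vec& b_h,     // n_h
                            const arma::vec& w_out,   // n_h
                            double b_out,
                            double U, double tau_x, double dt,
                            double pos_weight, double l2_act,
                            bool grad, bool record) {
  const uword T = drive.n_rows, n_in = drive.n_cols, n_h = b_h.n_elem;
  const bool has_ad = W_ad.n_elem > 0;
  const bool has_pl = W_pl.n_elem > 0;
  const bool has_rec = W_rec.n_elem > 0;
  const double k = dt / tau_x;

  // unit-major storage (units x steps): contiguous per-step columns
  mat Rt = drive.t();          // becomes r~ in place
  const mat Ein = eps_in.t();
  const mat Eh = eps_h.t();
  double* rt = Rt.memptr();
  const double* ein = Ein.memptr();
  for (uword i = 0; i < T * n_in; ++i) {
    double v = rt[i] * (1.0 + ein[i]);
    rt[i] = v > 0.0 ? v : 0.0;
  }

  mat Umat, Xmat;
  if (has_ad) {
    Umat.set_size(n_in, T);
    Xmat.set_size(n_in, T);
    vec x(n_in, fill::ones);
    for (uword t = 0; t < T; ++t) {
      const double* rc = Rt.colptr(t);
      double* xc = Xmat.colptr(t);
      double* uc = Umat.colptr(t);
      for (uword i = 0; i < n_in; ++i) {
        double xn = (x(i) + k) / (1.0 + k + U * dt * rc[i]);
        x(i) = xn;
        xc[i] = xn;
        uc[i] = xn * rc[i];
      }
    }
  }

  // pre-activation from the input blocks (recurrent part added in the loop)
  mat A(n_h, T);
  A.each_col() = b_h;
  if (has_ad) A += W_ad * Umat;
  if (has_pl) A += W_pl * Rt;

  mat Htil(n_h, T);
  vec z(T);
  {
    vec hprev(n_h, fill::zeros);
    for (uword t = 0; t < T; ++t) {
      double* ac = A.colptr(t);
      double* hc = Htil.colptr(t);
      const double* ec = Eh.colptr(t);
      if (has_rec) {
        vec rec = W_rec * hprev;
        for (uword j = 0; j < n_h; ++j) ac[j] += rec(j);
      }
      double zt = b_out;
      for (uword j = 0; j < n_h; ++j) {
        double h = ac[j] > 0.0 ? ac[j] : 0.0;
        double ht = h * (1.0 + ec[j]);
        if (ht < 0.0) ht = 0.0;
        hc[j] = ht;
        zt += w_out(j) * ht;
        if (has_rec) hprev(j) = ht;
      }
      z(t) = zt;
    }
  }
  if (!A.is_finite() || !z.is_finite())
    Rcpp::stop("non-finite network state during the session pass");

  const double M = (double)accu(mask);
  double bce = 0.0;
  for (uword t = 0; t < T; ++t)
    if (mask(t)) bce += (y(t) > 0.5 ? pos_weight : 1.0) * bce_logit(z(t), y(t));
  if (M > 0) bce /= M;
  const double act_pen =
      (T > 0) ? l2_act * accu(square(Htil)) / (double)(T * n_h) : 0.0;

  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("loss") = bce + act_pen, Rcpp::Named("bce") = bce,
      Rcpp::Named("act_penalty") = act_pen, Rcpp::Named("logits") = z);

  if (record) {
    out["hidden"] = mat(Htil.t());
    out["input_raw"] = mat(Rt.t());
    if (has_ad) {
      out["input_gated"] = mat(Umat.t());
      out["x"] = mat(Xmat.t());
    } else {
      out["input_gated"] = mat(Rt.t());
      out["x"] = mat(T, n_in, fill::ones);
    }
  }

  if (grad) {
    vec dz(T, fill::zeros);
    for (uword t = 0; t < T; ++t)
      if (mask(t) && M > 0) {
        double s = 1.0 / (1.0 + std::exp(-z(t)));
        dz(t) = (y(t) > 0.5 ? pos_weight : 1.0) * (s - y(t)) / M;
      }
    const double pen_c = (T > 0) ? 2.0 * l2_act / (double)(T * n_h) : 0.0;

    // dL/dh~ from the output and penalty paths, all steps at once
    mat dHtil = w_out * dz.t() + pen_c * Htil;
    mat dA(n_h, T);
    if (has_rec) {
      vec da_next(n_h, fill::zeros);
      for (uword tt = T; tt-- > 0;) {
        vec dh = dHtil.col(tt) + W_rec.t() * da_next;
        double* dac = dA.colptr(tt);
        const double* hc = Htil.colptr(tt);
        const double* ec = Eh.colptr(tt);
        const double* ac = A.colptr(tt);
        for (uword j = 0; j < n_h; ++j) {
          double g = dh(j) * (1.0 + ec[j]);
          g = (hc[j] > 0.0) ? g : 0.0;
          dac[j] = (ac[j] > 0.0) ? g : 0.0;
          da_next(j) = dac[j];
        }
      }
    } else {
      double* dac = dA.memptr();
      const double* dhc = dHtil.memptr();
      const double* hc = Htil.memptr();
      const double* ec = Eh.memptr();
      const double* ac = A.memptr();
      for (uword i = 0; i < T * n_h; ++i) {
        double g = dhc[i] * (1.0 + ec[i]);
        g = (hc[i] > 0.0) ? g : 0.0;
        dac[i] = (ac[i] > 0.0) ? g : 0.0;
      }
    }
    mat gWad, gWpl, gWrec;
    if (has_ad) gWad = dA * Umat.t(); else gWad.set_size(0, 0);
    if (has_pl) gWpl = dA * Rt.t(); else gWpl.set_size(0, 0);
    if (has_rec && T > 1)
      gWrec = dA.cols(1, T - 1) * Htil.cols(0, T - 2).t();
    else if (has_rec) gWrec.zeros(n_h, n_h);
    else gWrec.set_size(0, 0);
    out["grads"] = Rcpp::List::create(
        Rcpp::Named("W_ad") = gWad, Rcpp::Named("W_pl") = gWpl,
        Rcpp::Named("W_rec") = gWrec, Rcpp::Named("b_h") = vec(sum(dA, 1)),
        Rcpp::Named("w_out") = vec(Htil * dz),
        Rcpp::Named("b_out") = accu(dz));
  }
  return out;
}
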