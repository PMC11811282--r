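// Three-level hierarchical variational RNN: forward generation, free energy,
// and backpropagation-through-time gradients for weights and posterior
// adaptive states.  Level 3 (global) is latent-only and sequence-constant;
// level 2 (network) and level 1 (per-region local) carry leaky deterministic
// units with level-specific time constants.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

struct Cfg {
  int R, C, q1, q2, q3, p1, p2;
  double tau1, tau2, w1, w2, w3, clamp, sclamp;
};

static Cfg read_cfg(const List& cfg) {
  Cfg c;
  c.R = as<int>(cfg["n_regions"]);
  c.C = as<int>(cfg["channels_per_region"]);
  c.q1 = as<int>(cfg["q1"]);
  c.q2 = as<int>(cfg["q2"]);
  c.q3 = as<int>(cfg["q3"]);
  c.p1 = as<int>(cfg["p1"]);
  c.p2 = as<int>(cfg["p2"]);
  c.tau1 = as<double>(cfg["tau1"]);
  c.tau2 = as<double>(cfg["tau2"]);
  c.w1 = as<double>(cfg["w1"]);
  c.w2 = as<double>(cfg["w2"]);
  c.w3 = as<double>(cfg["w3"]);
  c.clamp = as<double>(cfg["clamp"]);
  c.sclamp = as<double>(cfg["sigma_clamp"]);
  return c;
}

// Weight container; theta layout must match theta_layout() on the R side.
struct Par {
  arma::mat A2, B2, B3, P2mu, P2sg;
  arma::vec b2;
  std::vector<arma::mat> A1, B1, C1, P1mu, P1sg, O;
  std::vector<arma::vec> b1;
};

static int theta_length(const Cfg& c) {
  int n2 = c.p2 * c.p2 + c.p2 * c.q2 + c.p2 * c.q3 + c.p2 + 2 * c.q2 * c.p2;
  int n1 = c.p1 * c.p1 + c.p1 * c.q1 + c.p1 * c.p2 + c.p1 +
           2 * c.q1 * c.p1 + c.C * c.p1;
  return n2 + c.R * n1;
}

static arma::mat take_mat(const arma::vec& th, int& off, int nr, int nc) {
  arma::mat m(th.memptr() + off, nr, nc);
  off += nr * nc;
  return m;
}

static Par unpack(const arma::vec& th, const Cfg& c) {
  Par p;
  int off = 0;
  p.A2 = take_mat(th, off, c.p2, c.p2);
  p.B2 = take_mat(th, off, c.p2, c.q2);
  p.B3 = take_mat(th, off, c.p2, c.q3);
  p.b2 = take_mat(th, off, c.p2, 1);
  p.P2mu = take_mat(th, off, c.q2, c.p2);
  p.P2sg = take_mat(th, off, c.q2, c.p2);
  for (int n = 0; n < c.R; ++n) {
    p.A1.push_back(take_mat(th, off, c.p1, c.p1));
    p.B1.push_back(take_mat(th, off, c.p1, c.q1));
    p.C1.push_back(take_mat(th, off, c.p1, c.p2));
    p.b1.push_back(take_mat(th, off, c.p1, 1));
    p.P1mu.push_back(take_mat(th, off, c.q1, c.p1));
    p.P1sg.push_back(take_mat(th, off, c.q1, c.p1));
    p.O.push_back(take_mat(th, off, c.C, c.p1));
  }
  return p;
}

static void put_mat(arma::vec& th, int& off, const arma::mat& m) {
  th.subvec(off, off + m.n_elem - 1) = arma::vectorise(m);
  off += m.n_elem;
}

static arma::vec pack(const Par& p, const Cfg& c) {
  arma::vec th(theta_length(c), arma::fill::zeros);
  int off = 0;
  put_mat(th, off, p.A2); put_mat(th, off, p.B2); put_mat(th, off, p.B3);
  put_mat(th, off, p.b2); put_mat(th, off, p.P2mu); put_mat(th, off, p.P2sg);
  for (int n = 0; n < c.R; ++n) {
    put_mat(th, off, p.A1[n]); put_mat(th, off, p.B1[n]);
    put_mat(th, off, p.C1[n]); put_mat(th, off, p.b1[n]);
    put_mat(th, off, p.P1mu[n]); put_mat(th, off, p.P1sg[n]);
    put_mat(th, off, p.O[n]);
  }
  return th;
}

static Par zero_like(const Cfg& c) {
  Par g;
  g.A2.zeros(c.p2, c.p2); g.B2.zeros(c.p2, c.q2); g.B3.zeros(c.p2, c.q3);
  g.b2.zeros(c.p2); g.P2mu.zeros(c.q2, c.p2); g.P2sg.zeros(c.q2, c.p2);
  for (int n = 0; n < c.R; ++n) {
    g.A1.push_back(arma::mat(c.p1, c.p1, arma::fill::zeros));
    g.B1.push_back(arma::mat(c.p1, c.q1, arma::fill::zeros));
    g.C1.push_back(arma::mat(c.p1, c.p2, arma::fill::zeros));
    g.b1.push_back(arma::vec(c.p1, arma::fill::zeros));
    g.P1mu.push_back(arma::mat(c.q1, c.p1, arma::fill::zeros));
    g.P1sg.push_back(arma::mat(c.q1, c.p1, arma::fill::zeros));
    g.O.push_back(arma::mat(c.C, c.p1, arma::fill::zeros));
  }
  return g;
}

// clamp pre-activation to [-b, b]; mask = 1 inside (gradient passes)
static arma::vec clampv(const arma::vec& v, double b, arma::vec& mask) {
  arma::vec out = v;
  mask.set_size(v.n_elem);
  for (arma::uword i = 0; i < v.n_elem; ++i) {
    if (v(i) > b) { out(i) = b; mask(i) = 0.0; }
    else if (v(i) < -b) { out(i) = -b; mask(i) = 0.0; }
    else mask(i) = 1.0;
  }
  return out;
}

// alpha layout: a3mu (q3) | a3sg (q3) | a2mu (q2*T) | a2sg (q2*T) |
//               a1mu (R*q1*T) | a1sg (R*q1*T); matrices column-major by time
// [[Rcpp::export]]
int pv_alpha_length(List cfg, int T) {
  Cfg c = read_cfg(cfg);
  return 2 * c.q3 + 2 * T * (c.q2 + c.R * c.q1);
}

// [[Rcpp::export]]
int pv_theta_length(List cfg) {
  return theta_length(read_cfg(cfg));
}

// KL(N(qm,qs) || N(pm,ps)) summed over components
static double kl_gauss(const arma::vec& qm, const arma::vec& qs,
                       const arma::vec& pm, const arma::vec& ps) {
  arma::vec term = arma::log(ps) - arma::log(qs) +
    (arma::square(qs) + arma::square(qm - pm)) / (2.0 * arma::square(ps)) - 0.5;
  return arma::accu(term);
}

// Forward pass (+ optional BPTT gradients) over one observed window/sequence.
// x: (R*C) x T observations; eps list with e3 (q3), e2 (q2 x T), e1 (R*q1 x T)
// init: list(h2, d2, h1 (p1 x R), d1 (p1 x R)) or empty for zeros
// first_is_t1: TRUE when column 1 is sequence step 1 (N(0,1) initial prior,
// z3 KL charged); FALSE when the window starts mid-sequence.
// [[Rcpp::export]]
List pv_forward(List cfg, arma::vec theta, arma::vec alpha, arma::mat x,
                List eps, bool first_is_t1, List init, bool want_grad) {
  Cfg c = read_cfg(cfg);
  Par w = unpack(theta, c);
  const int T = x.n_cols;
  const int Ctot = c.R * c.C;
  if ((int)x.n_rows != Ctot) stop("x has %d rows, expected %d", x.n_rows, Ctot);
  if ((int)alpha.n_elem != pv_alpha_length(cfg, T))
    stop("alpha length %d, expected %d", alpha.n_elem, pv_alpha_length(cfg, T));

  // unpack adaptive states
  int off = 0;
  arma::vec a3mu(alpha.memptr() + off, c.q3); off += c.q3;
  arma::vec a3sg(alpha.memptr() + off, c.q3); off += c.q3;
  arma::mat a2mu(alpha.memptr() + off, c.q2, T); off += c.q2 * T;
  arma::mat a2sg(alpha.memptr() + off, c.q2, T); off += c.q2 * T;
  arma::mat a1mu(alpha.memptr() + off, c.R * c.q1, T); off += c.R * c.q1 * T;
  arma::mat a1sg(alpha.memptr() + off, c.R * c.q1, T);

  arma::vec e3 = as<arma::vec>(eps["e3"]);
  arma::mat e2 = as<arma::mat>(eps["e2"]);
  arma::mat e1 = as<arma::mat>(eps["e1"]);

  arma::vec init_h2(c.p2, arma::fill::zeros), init_d2(c.p2, arma::fill::zeros);
  arma::mat init_h1(c.p1, c.R, arma::fill::zeros),
            init_d1(c.p1, c.R, arma::fill::zeros);
  if (init.size() > 0) {
    init_h2 = as<arma::vec>(init["h2"]); init_d2 = as<arma::vec>(init["d2"]);
    init_h1 = as<arma::mat>(init["h1"]); init_d1 = as<arma::mat>(init["d1"]);
  }

  // z3 posterior (sequence-constant)
  arma::vec mmu3, msg3;
  arma::vec qm3 = arma::tanh(clampv(a3mu, c.clamp, mmu3));
  arma::vec qs3 = arma::exp(clampv(a3sg, c.sclamp, msg3));
  arma::vec z3 = qm3 + qs3 % e3;

  // storage
  arma::mat qm2(c.q2, T), qs2(c.q2, T), pm2(c.q2, T), ps2(c.q2, T), z2(c.q2, T);
  arma::mat mmu2(c.q2, T), msg2(c.q2, T), mp2(c.q2, T);
  arma::mat h2(c.p2, T), d2(c.p2, T);
  int Rq = c.R * c.q1;
  arma::mat qm1(Rq, T), qs1(Rq, T), pm1(Rq, T), ps1(Rq, T), z1(Rq, T);
  arma::mat mmu1(Rq, T), msg1(Rq, T), mp1(Rq, T);
  arma::cube h1(c.p1, c.R, T), d1(c.p1, c.R, T);
  arma::mat xhat(Ctot, T);
  arma::vec recon(T), kl1(T), kl2(T), kl3(T, arma::fill::zeros);

  const double l2 = 1.0 / c.tau2, l1 = 1.0 / c.tau1;

  for (int t = 0; t < T; ++t) {
    arma::vec d2prev = (t == 0) ? init_d2 : arma::vec(d2.col(t - 1));
    arma::vec h2prev = (t == 0) ? init_h2 : arma::vec(h2.col(t - 1));
    // level-2 prior
    if (t == 0 && first_is_t1) {
      pm2.col(t).zeros(); ps2.col(t).ones(); mp2.col(t).zeros();
    } else {
      pm2.col(t) = arma::tanh(w.P2mu * d2prev);
      arma::vec msk;
      ps2.col(t) = arma::exp(clampv(w.P2sg * d2prev, c.sclamp, msk));
      mp2.col(t) = msk;
    }
    // level-2 posterior and sample
    arma::vec m1v, m2v;
    qm2.col(t) = arma::tanh(clampv(a2mu.col(t), c.clamp, m1v));
    qs2.col(t) = arma::exp(clampv(a2sg.col(t), c.sclamp, m2v));
    mmu2.col(t) = m1v; msg2.col(t) = m2v;
    z2.col(t) = qm2.col(t) + qs2.col(t) % e2.col(t);
    // level-2 deterministic step
    arma::vec u2 = w.A2 * d2prev + w.B2 * z2.col(t) + w.B3 * z3 + w.b2;
    h2.col(t) = l2 * u2 + (1.0 - l2) * h2prev;
    d2.col(t) = arma::tanh(h2.col(t));
    // level-1 per region
    double klsum1 = 0.0;
    for (int n = 0; n < c.R; ++n) {
      arma::span rs(n * c.q1, (n + 1) * c.q1 - 1);
      arma::vec d1prev = (t == 0) ? arma::vec(init_d1.col(n))
                                  : arma::vec(d1.slice(t - 1).col(n));
      arma::vec h1prev = (t == 0) ? arma::vec(init_h1.col(n))
                                  : arma::vec(h1.slice(t - 1).col(n));
      if (t == 0 && first_is_t1) {
        pm1(rs, arma::span(t)).zeros(); ps1(rs, arma::span(t)).ones();
        mp1(rs, arma::span(t)).zeros();
      } else {
        pm1(rs, arma::span(t)) = arma::tanh(w.P1mu[n] * d1prev);
        arma::vec msk;
        ps1(rs, arma::span(t)) =
          arma::exp(clampv(w.P1sg[n] * d1prev, c.sclamp, msk));
        mp1(rs, arma::span(t)) = msk;
      }
      arma::vec ma, mb;
      qm1(rs, arma::span(t)) =
        arma::tanh(clampv(a1mu(rs, arma::span(t)), c.clamp, ma));
      qs1(rs, arma::span(t)) =
        arma::exp(clampv(a1sg(rs, arma::span(t)), c.sclamp, mb));
      mmu1(rs, arma::span(t)) = ma; msg1(rs, arma::span(t)) = mb;
      z1(rs, arma::span(t)) =
        qm1(rs, arma::span(t)) + qs1(rs, arma::span(t)) % e1(rs, arma::span(t));
      arma::vec u1 = w.A1[n] * d1prev + w.B1[n] * z1(rs, arma::span(t)) +
                     w.C1[n] * d2.col(t) + w.b1[n];
      h1.slice(t).col(n) = l1 * u1 + (1.0 - l1) * h1prev;
      d1.slice(t).col(n) = arma::tanh(h1.slice(t).col(n));
      xhat(arma::span(n * c.C, (n + 1) * c.C - 1), arma::span(t)) =
        arma::tanh(w.O[n] * d1.slice(t).col(n));
      klsum1 += kl_gauss(qm1(rs, arma::span(t)), qs1(rs, arma::span(t)),
                         pm1(rs, arma::span(t)), ps1(rs, arma::span(t)));
    }
    kl1(t) = klsum1;
    kl2(t) = kl_gauss(qm2.col(t), qs2.col(t), pm2.col(t), ps2.col(t));
    if (t == 0 && first_is_t1)
      kl3(t) = kl_gauss(qm3, qs3, arma::vec(c.q3, arma::fill::zeros),
                        arma::vec(c.q3, arma::fill::ones));
    recon(t) = 0.5 * arma::accu(arma::square(xhat.col(t) - x.col(t)));
  }

  double loss = arma::accu(recon) + c.w1 * arma::accu(kl1) +
                c.w2 * arma::accu(kl2) + c.w3 * arma::accu(kl3);

  List out = List::create(
    _["loss"] = loss, _["recon"] = recon, _["kl1"] = kl1, _["kl2"] = kl2,
    _["kl3"] = kl3, _["xhat"] = xhat,
    _["z3"] = z3, _["qm3"] = qm3, _["qs3"] = qs3,
    _["qm2"] = qm2, _["qs2"] = qs2, _["pm2"] = pm2, _["ps2"] = ps2,
    _["z2"] = z2,
    _["qm1"] = qm1, _["qs1"] = qs1, _["pm1"] = pm1, _["ps1"] = ps1,
    _["z1"] = z1,
    _["d2"] = d2, _["h2"] = h2, _["d1"] = d1, _["h1"] = h1);

  if (!want_grad) return out;

  // ---- backward pass ----
  Par g = zero_like(c);
  arma::vec ga3mu(c.q3, arma::fill::zeros), ga3sg(c.q3, arma::fill::zeros);
  arma::mat ga2mu(c.q2, T, arma::fill::zeros),
            ga2sg(c.q2, T, arma::fill::zeros);
  arma::mat ga1mu(Rq, T, arma::fill::zeros), ga1sg(Rq, T, arma::fill::zeros);

  arma::vec gd2carry(c.p2, arma::fill::zeros), gh2carry(c.p2, arma::fill::zeros);
  arma::mat gd1carry(c.p1, c.R, arma::fill::zeros),
            gh1carry(c.p1, c.R, arma::fill::zeros);
  arma::vec gz3acc(c.q3, arma::fill::zeros);

  for (int t = T - 1; t >= 0; --t) {
    bool initial = (t == 0 && first_is_t1);
    arma::vec d2prev = (t == 0) ? init_d2 : arma::vec(d2.col(t - 1));
    arma::vec gx = xhat.col(t) - x.col(t);
    arma::vec gd2v = gd2carry;
    for (int n = 0; n < c.R; ++n) {
      arma::span rs(n * c.q1, (n + 1) * c.q1 - 1);
      arma::span cs(n * c.C, (n + 1) * c.C - 1);
      arma::vec d1prev = (t == 0) ? arma::vec(init_d1.col(n))
                                  : arma::vec(d1.slice(t - 1).col(n));
      arma::vec d1col = d1.slice(t).col(n);
      arma::vec xh = xhat(cs, arma::span(t));
      arma::vec gpo = gx(cs) % (1.0 - arma::square(xh));
      g.O[n] += gpo * d1col.t();
      arma::vec gd1v = gd1carry.col(n) + w.O[n].t() * gpo;
      arma::vec gh1v = gd1v % (1.0 - arma::square(d1col)) + gh1carry.col(n);
      arma::vec gu1 = l1 * gh1v;
      arma::vec z1seg = z1(rs, arma::span(t));
      g.A1[n] += gu1 * d1prev.t();
      g.B1[n] += gu1 * z1seg.t();
      g.C1[n] += gu1 * arma::vec(d2.col(t)).t();
      g.b1[n] += gu1;
      gd2v += w.C1[n].t() * gu1;
      arma::vec gz1 = w.B1[n].t() * gu1;
      arma::vec qm = qm1(rs, arma::span(t)), qs = qs1(rs, arma::span(t));
      arma::vec pm = pm1(rs, arma::span(t)), ps = ps1(rs, arma::span(t));
      arma::vec gqm = c.w1 * (qm - pm) / arma::square(ps) + gz1;
      arma::vec gqs = c.w1 * (-1.0 / qs + qs / arma::square(ps)) +
                      gz1 % e1(rs, arma::span(t));
      ga1mu(rs, arma::span(t)) =
        gqm % (1.0 - arma::square(qm)) % mmu1(rs, arma::span(t));
      ga1sg(rs, arma::span(t)) = gqs % qs % msg1(rs, arma::span(t));
      arma::vec gd1prev_extra(c.p1, arma::fill::zeros);
      if (!initial) {
        arma::vec gpm = c.w1 * (pm - qm) / arma::square(ps);
        arma::vec gps = c.w1 * (1.0 / ps - (arma::square(qs) +
                        arma::square(qm - pm)) / arma::pow(ps, 3));
        arma::vec gprem = gpm % (1.0 - arma::square(pm));
        arma::vec gpres = gps % ps % mp1(rs, arma::span(t));
        g.P1mu[n] += gprem * d1prev.t();
        g.P1sg[n] += gpres * d1prev.t();
        gd1prev_extra = w.P1mu[n].t() * gprem + w.P1sg[n].t() * gpres;
      }
      gd1carry.col(n) = w.A1[n].t() * gu1 + gd1prev_extra;
      gh1carry.col(n) = (1.0 - l1) * gh1v;
    }
    // level 2
    arma::vec d2col = d2.col(t);
    arma::vec gh2v = gd2v % (1.0 - arma::square(d2col)) + gh2carry;
    arma::vec gu2 = l2 * gh2v;
    g.A2 += gu2 * d2prev.t();
    g.B2 += gu2 * arma::vec(z2.col(t)).t();
    g.B3 += gu2 * z3.t();
    g.b2 += gu2;
    gz3acc += w.B3.t() * gu2;
    arma::vec gz2 = w.B2.t() * gu2;
    arma::vec qm = qm2.col(t), qs = qs2.col(t), pm = pm2.col(t),
              ps = ps2.col(t);
    arma::vec gqm = c.w2 * (qm - pm) / arma::square(ps) + gz2;
    arma::vec gqs = c.w2 * (-1.0 / qs + qs / arma::square(ps)) +
                    gz2 % e2.col(t);
    ga2mu.col(t) = gqm % (1.0 - arma::square(qm)) % mmu2.col(t);
    ga2sg.col(t) = gqs % qs % msg2.col(t);
    arma::vec gd2prev_extra(c.p2, arma::fill::zeros);
    if (!initial) {
      arma::vec gpm = c.w2 * (pm - qm) / arma::square(ps);
      arma::vec gps = c.w2 * (1.0 / ps - (arma::square(qs) +
                      arma::square(qm - pm)) / arma::pow(ps, 3));
      arma::vec gprem = gpm % (1.0 - arma::square(pm));
      arma::vec gpres = gps % ps % mp2.col(t);
      g.P2mu += gprem * d2prev.t();
      g.P2sg += gpres * d2prev.t();
      gd2prev_extra = w.P2mu.t() * gprem + w.P2sg.t() * gpres;
    }
    gd2carry = w.A2.t() * gu2 + gd2prev_extra;
    gh2carry = (1.0 - l2) * gh2v;
  }

  arma::vec gqm3 = gz3acc, gqs3 = gz3acc % e3;
  if (first_is_t1) {
    gqm3 += c.w3 * qm3;
    gqs3 += c.w3 * (-1.0 / qs3 + qs3);
  }
  ga3mu = gqm3 % (1.0 - arma::square(qm3)) % mmu3;
  ga3sg = gqs3 % qs3 % msg3;

  arma::vec gtheta = pack(g, c);
  arma::vec galpha(alpha.n_elem);
  off = 0;
  galpha.subvec(off, off + c.q3 - 1) = ga3mu; off += c.q3;
  galpha.subvec(off, off + c.q3 - 1) = ga3sg; off += c.q3;
  galpha.subvec(off, off + c.q2 * T - 1) = arma::vectorise(ga2mu);
  off += c.q2 * T;
  galpha.subvec(off, off + c.q2 * T - 1) = arma::vectorise(ga2sg);
  off += c.q2 * T;
  galpha.subvec(off, off + Rq * T - 1) = arma::vectorise(ga1mu); off += Rq * T;
  galpha.subvec(off, off + Rq * T - 1) = arma::vectorise(ga1sg);

  out["gtheta"] = gtheta;
  out["galpha"] = galpha;
  return out;
}

// Generative rollout: free latent units sample from their priors, clamped
// units replay supplied trajectories.  m3/m2/m1 are 0/1 clamp masks; clamped
// entries of z3c/z2c/z1c are used verbatim.
// [[Rcpp::export]]
List pv_generate(List cfg, arma::vec theta, int T, List eps, bool first_is_t1,
                 List init, arma::vec m3, arma::vec z3c, arma::mat m2,
                 arma::mat z2c, arma::mat m1, arma::mat z1c) {
  Cfg c = read_cfg(cfg);
  Par w = unpack(theta, c);
  const int Ctot = c.R * c.C;
  arma::vec e3 = as<arma::vec>(eps["e3"]);
  arma::mat e2 = as<arma::mat>(eps["e2"]);
  arma::mat e1 = as<arma::mat>(eps["e1"]);

  arma::vec init_h2(c.p2, arma::fill::zeros), init_d2(c.p2, arma::fill::zeros);
  arma::mat init_h1(c.p1, c.R, arma::fill::zeros),
            init_d1(c.p1, c.R, arma::fill::zeros);
  if (init.size() > 0) {
    init_h2 = as<arma::vec>(init["h2"]); init_d2 = as<arma::vec>(init["d2"]);
    init_h1 = as<arma::mat>(init["h1"]); init_d1 = as<arma::mat>(init["d1"]);
  }

  // z3: prior is N(0,1) at sequence start, constant thereafter
  arma::vec z3(c.q3);
  for (int i = 0; i < c.q3; ++i)
    z3(i) = (m3(i) > 0.5) ? z3c(i) : e3(i);

  int Rq = c.R * c.q1;
  arma::mat z2(c.q2, T), z1(Rq, T), pm2(c.q2, T), ps2(c.q2, T),
            pm1(Rq, T), ps1(Rq, T);
  arma::mat h2(c.p2, T), d2(c.p2, T), xhat(Ctot, T);
  arma::cube h1(c.p1, c.R, T), d1(c.p1, c.R, T);
  const double l2 = 1.0 / c.tau2, l1 = 1.0 / c.tau1;
  arma::vec msk;

  for (int t = 0; t < T; ++t) {
    arma::vec d2prev = (t == 0) ? init_d2 : arma::vec(d2.col(t - 1));
    arma::vec h2prev = (t == 0) ? init_h2 : arma::vec(h2.col(t - 1));
    if (t == 0 && first_is_t1) {
      pm2.col(t).zeros(); ps2.col(t).ones();
    } else {
      pm2.col(t) = arma::tanh(w.P2mu * d2prev);
      ps2.col(t) = arma::exp(clampv(w.P2sg * d2prev, c.sclamp, msk));
    }
    for (int i = 0; i < c.q2; ++i)
      z2(i, t) = (m2(i, t) > 0.5) ? z2c(i, t)
                                  : pm2(i, t) + ps2(i, t) * e2(i, t);
    arma::vec u2 = w.A2 * d2prev + w.B2 * z2.col(t) + w.B3 * z3 + w.b2;
    h2.col(t) = l2 * u2 + (1.0 - l2) * h2prev;
    d2.col(t) = arma::tanh(h2.col(t));
    for (int n = 0; n < c.R; ++n) {
      arma::vec d1prev = (t == 0) ? arma::vec(init_d1.col(n))
                                  : arma::vec(d1.slice(t - 1).col(n));
      arma::vec h1prev = (t == 0) ? arma::vec(init_h1.col(n))
                                  : arma::vec(h1.slice(t - 1).col(n));
      arma::span rs(n * c.q1, (n + 1) * c.q1 - 1);
      if (t == 0 && first_is_t1) {
        pm1(rs, arma::span(t)).zeros(); ps1(rs, arma::span(t)).ones();
      } else {
        pm1(rs, arma::span(t)) = arma::tanh(w.P1mu[n] * d1prev);
        ps1(rs, arma::span(t)) =
          arma::exp(clampv(w.P1sg[n] * d1prev, c.sclamp, msk));
      }
      for (int i = 0; i < c.q1; ++i) {
        int r = n * c.q1 + i;
        z1(r, t) = (m1(r, t) > 0.5) ? z1c(r, t)
                                    : pm1(r, t) + ps1(r, t) * e1(r, t);
      }
      arma::vec u1 = w.A1[n] * d1prev + w.B1[n] * z1(rs, arma::span(t)) +
                     w.C1[n] * d2.col(t) + w.b1[n];
      h1.slice(t).col(n) = l1 * u1 + (1.0 - l1) * h1prev;
      d1.slice(t).col(n) = arma::tanh(h1.slice(t).col(n));
      xhat(arma::span(n * c.C, (n + 1) * c.C - 1), arma::span(t)) =
        arma::tanh(w.O[n] * d1.slice(t).col(n));
    }
  }
  return List::create(_["xhat"] = xhat, _["z3"] = z3, _["z2"] = z2,
                      _["z1"] = z1, _["pm2"] = pm2, _["ps2"] = ps2,
                      _["pm1"] = pm1, _["ps1"] = ps1, _["d2"] = d2,
                      _["d1"] = d1, _["h2"] = h2, _["h1"] = h1);
}
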