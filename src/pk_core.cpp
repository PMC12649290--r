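// Analytic kinetics of the depot -> parent central -> metabolite cascade,
// an event-driven simulation engine (doses, observations, time-varying
// covariate on parent clearance), and the FOCE-I inner problem (per-subject
// posterior-mode search and Laplace/Gauss-Newton objective contribution).
//
// Units: amounts ug, volumes L, times h, concentrations ug/L.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double RATE_SEP = 1e-8;   // relative separation below which rates are nudged apart
static const double LOG2PI = 1.8378770664093453;

// Nudge near-equal rate constants apart so the distinct-rate analytic
// solution stays numerically stable (perturbation branch; relative error of
// the nudge is O(1e-7 * k * t), far below the residual noise scale).
static void separate_rates(double &ka, double &k20, double &k30) {
  const double f = 1e-7;
  if (std::fabs(ka - k20) < RATE_SEP * std::max(ka, k20)) k20 *= (1.0 + f);
  if (std::fabs(ka - k30) < RATE_SEP * std::max(ka, k30)) k30 *= (1.0 - f);
  if (std::fabs(k20 - k30) < RATE_SEP * std::max(k20, k30)) k30 *= (1.0 - f);
}

// Advance amounts (A1 depot, A2 parent, A3 metabolite) by dt under constant
// rates; exact solution of the linear cascade.
static void advance_state(double *A, double ka, double k20, double k30,
                          double fm, double dt) {
  separate_rates(ka, k20, k30);
  const double E1 = std::exp(-ka * dt);
  const double E2 = std::exp(-k20 * dt);
  const double E3 = std::exp(-k30 * dt);
  const double A1 = A[0], A2 = A[1], A3 = A[2];
  A[0] = A1 * E1;
  A[1] = A2 * E2 + A1 * ka * (E2 - E1) / (ka - k20);
  double triple = E1 / ((k20 - ka) * (k30 - ka)) +
                  E2 / ((ka - k20) * (k30 - k20)) +
                  E3 / ((ka - k30) * (k20 - k30));
  A[2] = A3 * E3 + A2 * fm * k20 * (E2 - E3) / (k30 - k20) +
         A1 * fm * k20 * ka * triple;
}

// Concentration profile under an arbitrary dose list, both analytes, on a
// sorted time grid. Constant parameters (no covariate switching).
// [[Rcpp::export]]
NumericMatrix cpp_profile(double ka, double vp, double clp, double vm,
                          double clm, double fm,
                          NumericVector dose_time, NumericVector dose_amt,
                          NumericVector times) {
  const double k20 = clp / vp, k30 = clm / vm;
  const int nd = dose_time.size(), nt = times.size();
  NumericMatrix out(nt, 2);
  double A[3] = {0.0, 0.0, 0.0};
  double t = 0.0;
  int id = 0, it = 0;
  if (nt > 0) t = std::min(times[0], nd > 0 ? dose_time[0] : times[0]);
  if (nd > 0) t = std::min(t, dose_time[0]);
  while (it < nt) {
    // next event: dose or output time, doses first on ties (trough sampled
    // via a time infinitesimally before the dose belongs to the caller)
    bool take_dose = (id < nd) && (dose_time[id] <= times[it]);
    double tn = take_dose ? dose_time[id] : times[it];
    if (tn > t) {
      advance_state(A, ka, k20, k30, fm, tn - t);
      t = tn;
    }
    if (take_dose) {
      A[0] += dose_amt[id];
      ++id;
    } else {
      out(it, 0) = A[1] / vp;
      out(it, 1) = A[2] / vm;
      ++it;
    }
  }
  return out;
}

// ---- Event-record engine (NONMEM-style rows) --------------------------------
// times sorted; evid 1 = dose into depot, 0 = observation; cmt for
// observations: 2 = parent, 3 = metabolite; cobi flag switches the parent
// clearance multiplier theta from the event's time onward.
// Returns predicted concentration for each observation row, in row order.
static void sim_events_core(double ka, double vp, double clp, double vm,
                            double clm, double fm, double theta,
                            const double *times, const int *evid,
                            const double *amt, const int *cmt,
                            const int *cobi, int n, double *pred) {
  double A[3] = {0.0, 0.0, 0.0};
  double t = n > 0 ? times[0] : 0.0;
  int cur_cobi = n > 0 ? cobi[0] : 0;
  int iout = 0;
  const double k30 = clm / vm;
  for (int i = 0; i < n; ++i) {
    double k20 = (cur_cobi ? clp * theta : clp) / vp;
    if (times[i] > t) {
      advance_state(A, ka, k20, k30, fm, times[i] - t);
      t = times[i];
    }
    cur_cobi = cobi[i];  // flag effective from this event time onward
    if (evid[i] == 1) {
      A[0] += amt[i];
    } else {
      pred[iout++] = (cmt[i] == 3) ? A[2] / vm : A[1] / vp;
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_sim_events(double ka, double vp, double clp, double vm,
                             double clm, double fm, double theta,
                             NumericVector times, IntegerVector evid,
                             NumericVector amt, IntegerVector cmt,
                             IntegerVector cobi) {
  int n = times.size(), nobs = 0;
  for (int i = 0; i < n; ++i) if (evid[i] == 0) ++nobs;
  NumericVector pred(nobs);
  sim_events_core(ka, vp, clp, vm, clm, fm, theta,
                  REAL(times), INTEGER(evid), REAL(amt), INTEGER(cmt),
                  INTEGER(cobi), n, REAL(pred));
  return pred;
}

// ---- FOCE-I per-subject machinery ------------------------------------------

struct SubjData {
  const double *times;
  const int *evid;
  const double *amt;
  const int *cmt;
  const int *cobi;
  int n;        // event rows
  const double *y;  // observations, length nobs
  int nobs;
  double ka, vp, clp, vm, clm, fm;  // individual base (allometry applied, eta not)
  double theta, sigma;
  double oinv[3];    // omega inverse: [0]=11, [1]=12=21, [2]=22
  bool interaction;
  const double *f0;  // eta = 0 predictions (variance scale when !interaction)
};

static void subj_pred(const SubjData &d, double e0, double e1, double *f) {
  sim_events_core(d.ka, d.vp, d.clp * std::exp(e0), d.vm,
                  d.clm * std::exp(e1), d.fm, d.theta,
                  d.times, d.evid, d.amt, d.cmt, d.cobi, d.n, f);
}

// -2 log p(y | eta): proportional residual error, variance at the
// conditional prediction (interaction) or the population prediction.
static double m2ll_cond(const SubjData &d, const double *f) {
  double s = 0.0;
  for (int j = 0; j < d.nobs; ++j) {
    double fv = d.interaction ? f[j] : d.f0[j];
    double sd = d.sigma * std::max(std::fabs(fv), 1e-12);
    double r = (d.y[j] - f[j]) / sd;
    s += LOG2PI + 2.0 * std::log(sd) + r * r;
  }
  if (!std::isfinite(s)) s = 1e10;
  return s;
}

static double pls_obj(const SubjData &d, double e0, double e1,
                      std::vector<double> &work) {
  subj_pred(d, e0, e1, work.data());
  double quad = d.oinv[0] * e0 * e0 + 2.0 * d.oinv[1] * e0 * e1 +
                d.oinv[2] * e1 * e1;
  return m2ll_cond(d, work.data()) + quad;
}

// Damped-Newton search for the posterior mode of eta (finite-difference
// gradient/Hessian; tolerance 1e-8 on the penalized objective).
static bool find_mode(const SubjData &d, double *eta, double *obj_out) {
  std::vector<double> work(d.nobs);
  const double h = 1e-4;
  double e0 = eta[0], e1 = eta[1];
  double obj = pls_obj(d, e0, e1, work);
  if (!std::isfinite(obj)) { e0 = e1 = 0.0; obj = pls_obj(d, e0, e1, work); }
  double lambda = 1e-4;
  bool ok = false;
  for (int it = 0; it < 100; ++it) {
    double fpp = pls_obj(d, e0 + h, e1, work), fmm = pls_obj(d, e0 - h, e1, work);
    double gpp = pls_obj(d, e0, e1 + h, work), gmm = pls_obj(d, e0, e1 - h, work);
    double fpg = pls_obj(d, e0 + h, e1 + h, work), fmg = pls_obj(d, e0 + h, e1 - h, work);
    double gpf = pls_obj(d, e0 - h, e1 + h, work), gmf = pls_obj(d, e0 - h, e1 - h, work);
    double g0 = (fpp - fmm) / (2 * h), g1 = (gpp - gmm) / (2 * h);
    double H00 = (fpp - 2 * obj + fmm) / (h * h);
    double H11 = (gpp - 2 * obj + gmm) / (h * h);
    double H01 = (fpg - fmg - gpf + gmf) / (4 * h * h);
    double gnorm = std::sqrt(g0 * g0 + g1 * g1);
    if (gnorm < 1e-6) { ok = true; break; }
    bool accepted = false;
    for (int trial = 0; trial < 12; ++trial) {
      double a = H00 + lambda, b = H01, c = H11 + lambda;
      double det = a * c - b * b;
      if (det <= 0 || a <= 0) { lambda = std::max(lambda * 10, 1e-3); continue; }
      double d0 = -(c * g0 - b * g1) / det;
      double d1 = -(-b * g0 + a * g1) / det;
      double no = pls_obj(d, e0 + d0, e1 + d1, work);
      if (std::isfinite(no) && no <= obj + 1e-12) {
        double drop = obj - no;
        e0 += d0; e1 += d1; obj = no;
        lambda = std::max(lambda / 3, 1e-8);
        accepted = true;
        if (drop < 1e-8 && std::sqrt(d0 * d0 + d1 * d1) < 1e-6) {
          ok = true;
        }
        break;
      }
      lambda *= 10;
    }
    if (!accepted) { ok = gnorm < 1e-3; break; }
    if (ok) break;
  }
  eta[0] = e0; eta[1] = e1;
  *obj_out = obj;
  return ok;
}

// FOCE-I -2 log marginal likelihood contribution of one subject:
//   sum_j [log(2 pi R_j) + res_j^2/R_j] + eta' Oinv eta + log|Omega| + log|M|,
// M = G' R^-1 G + Oinv with G = df/deta at the mode (Gauss-Newton curvature).
static double foce_subject(const SubjData &d, double log_det_omega,
                           double *eta, int *flag) {
  *flag = 0;
  if (d.nobs == 0) { eta[0] = eta[1] = 0.0; return 0.0; }
  double obj;
  bool ok = find_mode(d, eta, &obj);
  if (!ok) *flag = 1;
  std::vector<double> fhat(d.nobs), fp(d.nobs), fm_(d.nobs);
  subj_pred(d, eta[0], eta[1], fhat.data());
  const double h = 1e-4;
  std::vector<double> G0(d.nobs), G1(d.nobs);
  subj_pred(d, eta[0] + h, eta[1], fp.data());
  subj_pred(d, eta[0] - h, eta[1], fm_.data());
  for (int j = 0; j < d.nobs; ++j) G0[j] = (fp[j] - fm_[j]) / (2 * h);
  subj_pred(d, eta[0], eta[1] + h, fp.data());
  subj_pred(d, eta[0], eta[1] - h, fm_.data());
  for (int j = 0; j < d.nobs; ++j) G1[j] = (fp[j] - fm_[j]) / (2 * h);
  double M00 = d.oinv[0], M01 = d.oinv[1], M11 = d.oinv[2];
  double ll = 0.0;
  for (int j = 0; j < d.nobs; ++j) {
    double fv = d.interaction ? fhat[j] : d.f0[j];
    double sd = d.sigma * std::max(std::fabs(fv), 1e-12);
    double R = sd * sd;
    double r = d.y[j] - fhat[j];
    ll += LOG2PI + std::log(R) + r * r / R;
    M00 += G0[j] * G0[j] / R;
    M01 += G0[j] * G1[j] / R;
    M11 += G1[j] * G1[j] / R;
  }
  double quad = d.oinv[0] * eta[0] * eta[0] + 2 * d.oinv[1] * eta[0] * eta[1] +
                d.oinv[2] * eta[1] * eta[1];
  double detM = M00 * M11 - M01 * M01;
  if (detM <= 0 || !std::isfinite(detM)) { *flag = 2; return 1e7; }
  double ofv = ll + quad + log_det_omega + std::log(detM);
  if (!std::isfinite(ofv)) { *flag = 2; return 1e7; }
  return ofv;
}

// base: n_subj x 5 matrix (ka, vp, clp, vm, clm), allometry applied.
// Events flattened across subjects; start[i]..start[i+1]-1 rows (0-based) for
// subject i; y holds that subject's observations in row order.
// [[Rcpp::export]]
List cpp_ofv_foce(NumericMatrix base, double fm, double theta, double sigma,
                  NumericMatrix omega, NumericVector times, IntegerVector evid,
                  NumericVector amt, IntegerVector cmt, IntegerVector cobi,
                  NumericVector y, IntegerVector start, IntegerVector ystart,
                  NumericMatrix eta_start, bool interaction) {
  int ns = base.nrow();
  double det_om = omega(0, 0) * omega(1, 1) - omega(0, 1) * omega(1, 0);
  if (det_om <= 0) stop("omega must be positive definite");
  double oinv[3] = {omega(1, 1) / det_om, -omega(0, 1) / det_om,
                    omega(0, 0) / det_om};
  double ldet = std::log(det_om);
  NumericMatrix eta(ns, 2);
  NumericVector ofv_i(ns);
  IntegerVector flags(ns);
  double total = 0.0;
  std::vector<double> f0;
  for (int i = 0; i < ns; ++i) {
    SubjData d;
    int a = start[i], b = start[i + 1];
    d.times = REAL(times) + a; d.evid = INTEGER(evid) + a;
    d.amt = REAL(amt) + a; d.cmt = INTEGER(cmt) + a;
    d.cobi = INTEGER(cobi) + a; d.n = b - a;
    d.y = REAL(y) + ystart[i];
    d.nobs = ystart[i + 1] - ystart[i];
    d.ka = base(i, 0); d.vp = base(i, 1); d.clp = base(i, 2);
    d.vm = base(i, 3); d.clm = base(i, 4);
    d.fm = fm; d.theta = theta; d.sigma = sigma;
    d.oinv[0] = oinv[0]; d.oinv[1] = oinv[1]; d.oinv[2] = oinv[2];
    d.interaction = interaction;
    f0.resize(std::max(1, d.nobs));
    if (!interaction && d.nobs > 0) subj_pred(d, 0.0, 0.0, f0.data());
    d.f0 = f0.data();
    double e[2] = {eta_start(i, 0), eta_start(i, 1)};
    int flag;
    double o = foce_subject(d, ldet, e, &flag);
    eta(i, 0) = e[0]; eta(i, 1) = e[1];
    ofv_i[i] = o; flags[i] = flag;
    total += o;
  }
  return List::create(_["ofv"] = total, _["ofv_i"] = ofv_i, _["eta"] = eta,
                      _["flags"] = flags);
}

// -2 log p(y | eta) at supplied eta values (rows), for one subject; used by
// the adaptive quadrature oracle and the diagnostics expansions.
// [[Rcpp::export]]
NumericVector cpp_m2ll_at_eta(double ka, double vp, double clp, double vm,
                              double clm, double fm, double theta,
                              double sigma, NumericVector times,
                              IntegerVector evid, NumericVector amt,
                              IntegerVector cmt, IntegerVector cobi,
                              NumericVector y, NumericMatrix etas,
                              bool interaction) {
  SubjData d;
  d.times = REAL(times); d.evid = INTEGER(evid); d.amt = REAL(amt);
  d.cmt = INTEGER(cmt); d.cobi = INTEGER(cobi); d.n = times.size();
  d.y = REAL(y); d.nobs = y.size();
  d.ka = ka; d.vp = vp; d.clp = clp; d.vm = vm; d.clm = clm;
  d.fm = fm; d.theta = theta; d.sigma = sigma;
  d.oinv[0] = d.oinv[1] = d.oinv[2] = 0.0;
  d.interaction = interaction;
  std::vector<double> f0(std::max(1, d.nobs));
  if (!interaction && d.nobs > 0) subj_pred(d, 0.0, 0.0, f0.data());
  d.f0 = f0.data();
  int m = etas.nrow();
  NumericVector out(m);
  std::vector<double> f(std::max(1, d.nobs));
  for (int k = 0; k < m; ++k) {
    subj_pred(d, etas(k, 0), etas(k, 1), f.data());
    out[k] = m2ll_cond(d, f.data());
  }
  return out;
}
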