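// Metropolis-within-Gibbs sampler for the hierarchical Wiener diffusion
// model. Participant-level delta/theta/tau nodes are updated one at a time
// with normal random-walk proposals against the cached cell likelihoods;
// group means are drawn exactly from their conjugate normal conditionals
// (truncated at zero for theta/tau by rejection) and group spreads by
// stepping-out slice sampling under the half-normal prior. Participant
// proposal scales adapt in log space during burn-in only and are frozen
// afterwards.

#include <Rcpp.h>
#include "wfpt.h"
using namespace Rcpp;

static const double WFPT_EPS = 1e-7;
static const double Z_FIXED = 0.5;

struct HddmData {
  std::vector<std::vector<int> > tr;   // trial indices per (participant, cell6)
  std::vector<double> minrt;           // min rt per (participant, cell6), Inf if empty
  NumericVector rt;
  IntegerVector correct;
  int P;
};

static double cell_loglik(const HddmData& D, int i, int c6,
                          double d, double th, double tau) {
  const std::vector<int>& idx = D.tr[i * 6 + c6];
  double ll = 0.0;
  for (size_t j = 0; j < idx.size(); ++j) {
    int k = idx[j];
    double f = avddm_wfpt_pdf(D.rt[k], D.correct[k], d, th, tau, Z_FIXED, WFPT_EPS);
    if (f <= 0.0) return R_NegInf;
    ll += std::log(f);
  }
  return ll;
}

// [[Rcpp::export]]
List hddm_mcmc_cpp(NumericVector rt, IntegerVector correct, IntegerVector cell6,
                   IntegerVector pid, int P, IntegerVector agegrp,
                   LogicalVector varies, int n_iter, int burn_in, int thin,
                   NumericVector prior_mu0, NumericVector prior_sd0,
                   double prior_sigma_hn, NumericVector init_scale) {
  HddmData D;
  D.rt = rt; D.correct = correct; D.P = P;
  D.tr.resize(P * 6);
  D.minrt.assign(P * 6, R_PosInf);
  for (int k = 0; k < rt.size(); ++k) {
    int slot = pid[k] * 6 + cell6[k];
    D.tr[slot].push_back(k);
    if (rt[k] < D.minrt[slot]) D.minrt[slot] = rt[k];
  }

  int npc[3], ngc[3];
  for (int p = 0; p < 3; ++p) {
    npc[p] = varies[p] ? 6 : 1;
    ngc[p] = varies[p] ? 12 : 1;
  }
  // group cell of participant i's node k for parameter p
  #define GCELL(p, i, k) (varies[p] ? ((k) * 2 + agegrp[i]) : 0)

  // ---- state ----
  std::vector<std::vector<double> > x(3), mu(3), sg(3);
  std::vector<std::vector<double> > ps(3), gms(3), gss(3);      // proposal scales
  std::vector<std::vector<long> >  pacc(3), patt(3);            // participant acc/att
  std::vector<std::vector<long> >  gacc_mu(3), gatt_mu(3), gacc_sg(3), gatt_sg(3);
  for (int p = 0; p < 3; ++p) {
    x[p].assign(P * npc[p], 0.0);
    mu[p].assign(ngc[p], prior_mu0[p]);
    sg[p].assign(ngc[p], 0.5 * prior_sd0[p] + 0.1);
    ps[p].assign(P * npc[p], init_scale[p]);
    gms[p].assign(ngc[p], init_scale[p] / std::sqrt((double)P));
    gss[p].assign(ngc[p], 0.2);   // log-scale width of the rescaling move
    pacc[p].assign(P * npc[p], 0); patt[p].assign(P * npc[p], 0);
    gacc_mu[p].assign(ngc[p], 0);  gatt_mu[p].assign(ngc[p], 0);
    gacc_sg[p].assign(ngc[p], 0);  gatt_sg[p].assign(ngc[p], 0);
  }

  // tau upper bound for node (i,k): min retained rt over the covered cells
  std::vector<double> tau_ub(P * npc[2]);
  for (int i = 0; i < P; ++i)
    for (int k = 0; k < npc[2]; ++k) {
      double m = R_PosInf;
      if (varies[2]) m = D.minrt[i * 6 + k];
      else for (int c = 0; c < 6; ++c) m = std::min(m, D.minrt[i * 6 + c]);
      tau_ub[i * npc[2] + k] = m;
    }

  // initialise participant nodes near the group means with seeded jitter
  for (int i = 0; i < P; ++i) {
    for (int p = 0; p < 3; ++p)
      for (int k = 0; k < npc[p]; ++k) {
        double v = prior_mu0[p] + 0.05 * norm_rand();
        if (p == 1 && v < 0.2) v = 0.2;
        if (p == 2) {
          double ub = tau_ub[i * npc[2] + k];
          if (!std::isfinite(ub)) ub = 1.0;
          if (v >= 0.8 * ub) v = 0.8 * ub;
          if (v < 0.0) v = 0.01;
        }
        x[p][i * npc[p] + k] = v;
      }
  }

  // cached cell log-likelihoods
  std::vector<double> ll(P * 6);
  bool finite_init = false;
  for (int attempt = 0; attempt < 10 && !finite_init; ++attempt) {
    if (attempt > 0) {   // re-jitter
      for (int p = 0; p < 3; ++p)
        for (size_t j = 0; j < x[p].size(); ++j)
          x[p][j] = std::fabs(x[p][j] * (1.0 + 0.05 * norm_rand()));
    }
    finite_init = true;
    for (int i = 0; i < P && finite_init; ++i)
      for (int c = 0; c < 6; ++c) {
        double d  = x[0][i * npc[0] + (varies[0] ? c : 0)];
        double th = x[1][i * npc[1] + (varies[1] ? c : 0)];
        double ta = x[2][i * npc[2] + (varies[2] ? c : 0)];
        ll[i * 6 + c] = cell_loglik(D, i, c, d, th, ta);
        if (D.tr[i * 6 + c].size() > 0 && !std::isfinite(ll[i * 6 + c])) {
          finite_init = false; break;
        }
      }
  }
  if (!finite_init) stop("could not find a finite-likelihood initialisation");

  // group membership lists: (i) per group cell per parameter
  std::vector<std::vector<std::vector<int> > > members(3);
  for (int p = 0; p < 3; ++p) {
    members[p].resize(ngc[p]);
    for (int i = 0; i < P; ++i)
      for (int k = 0; k < npc[p]; ++k)
        members[p][GCELL(p, i, k)].push_back(i * npc[p] + k);
  }

  // ---- output containers ----
  int n_ret = (n_iter - burn_in) / thin;
  int n_group = 2 * (ngc[0] + ngc[1] + ngc[2]);
  int n_part  = P * (npc[0] + npc[1] + npc[2]);
  NumericMatrix draws(n_ret, n_group + n_part);
  NumericVector deviance(n_ret);
  std::vector<int> adapt_iter;
  std::vector<double> adapt_change;

  const int batch = 25;
  int adapt_n = 0;
  std::vector<std::vector<long> > bacc(3), batt(3);
  std::vector<std::vector<long> > bmacc(3), bmatt(3), bsacc(3), bsatt(3);
  for (int p = 0; p < 3; ++p) {
    bacc[p].assign(P * npc[p], 0); batt[p].assign(P * npc[p], 0);
    bmacc[p].assign(ngc[p], 0); bmatt[p].assign(ngc[p], 0);
    bsacc[p].assign(ngc[p], 0); bsatt[p].assign(ngc[p], 0);
  }

  std::vector<double> newll(6);
  int ret = 0;

  for (int it = 1; it <= n_iter; ++it) {
    // ---- participant-level updates ----
    for (int i = 0; i < P; ++i) {
      for (int p = 0; p < 3; ++p) {
        for (int k = 0; k < npc[p]; ++k) {
          int slot = i * npc[p] + k;
          double cur = x[p][slot];
          double prop = cur + ps[p][slot] * norm_rand();
          batt[p][slot]++; if (it > burn_in) patt[p][slot]++;
          if (p == 1 && prop <= 0.0) continue;
          if (p == 2 && (prop < 0.0 || prop >= tau_ub[slot])) continue;

          int gc = GCELL(p, i, k);
          double dlp = R::dnorm(prop, mu[p][gc], sg[p][gc], 1) -
                       R::dnorm(cur,  mu[p][gc], sg[p][gc], 1);
          int c_lo = varies[p] ? k : 0, c_hi = varies[p] ? k : 5;
          bool ok = true;
          for (int c = c_lo; c <= c_hi && ok; ++c) {
            double d  = (p == 0) ? prop : x[0][i * npc[0] + (varies[0] ? c : 0)];
            double th = (p == 1) ? prop : x[1][i * npc[1] + (varies[1] ? c : 0)];
            double ta = (p == 2) ? prop : x[2][i * npc[2] + (varies[2] ? c : 0)];
            newll[c] = cell_loglik(D, i, c, d, th, ta);
            if (D.tr[i * 6 + c].size() > 0 && !std::isfinite(newll[c])) ok = false;
            dlp += newll[c] - ll[i * 6 + c];
          }
          if (ok && std::log(unif_rand()) < dlp) {
            x[p][slot] = prop;
            for (int c = c_lo; c <= c_hi; ++c) ll[i * 6 + c] = newll[c];
            bacc[p][slot]++; if (it > burn_in) pacc[p][slot]++;
          }
        }
      }
    }

    // ---- group-level updates ----
    // two passes per sweep: group spreads of weakly identified cells mix
    // slowest, and these updates are cheap relative to the participant sweep
    for (int pass = 0; pass < 2; ++pass)
    for (int p = 0; p < 3; ++p) {
      for (int c = 0; c < ngc[p]; ++c) {
        const std::vector<int>& mem = members[p][c];
        int nm = (int)mem.size();
        double s = sg[p][c];
        // mean: conjugate normal conditional, truncated at 0 for theta/tau
        double sum = 0.0;
        for (int j = 0; j < nm; ++j) sum += x[p][mem[j]];
        double prec = 1.0 / (prior_sd0[p] * prior_sd0[p]) + nm / (s * s);
        double mpost = (prior_mu0[p] / (prior_sd0[p] * prior_sd0[p]) +
                        sum / (s * s)) / prec;
        double spost = 1.0 / std::sqrt(prec);
        double mnew = mpost + spost * norm_rand();
        if (p > 0) {                       // positivity by rejection
          int tries = 0;
          while (mnew <= 0.0 && ++tries < 100)
            mnew = mpost + spost * norm_rand();
          if (mnew <= 0.0) mnew = mu[p][c];   // keep current in pathologies
        }
        mu[p][c] = mnew;
        // spread: stepping-out slice sampler on sigma, half-normal prior
        double m = mu[p][c];
        double ssq = 0.0;
        for (int j = 0; j < nm; ++j) {
          double e = x[p][mem[j]] - m;
          ssq += e * e;
        }
        double hn2 = 2.0 * prior_sigma_hn * prior_sigma_hn;
        #define SG_LOGPOST(v) (-(v) * (v) / hn2 - nm * std::log(v) - ssq / (2.0 * (v) * (v)))
        double ly = SG_LOGPOST(s) + std::log(unif_rand());
        double wslice = 0.25 * s + 0.05;
        double L = s - wslice * unif_rand();
        double Rr = L + wslice;
        for (int st = 0; st < 50 && L > 1e-6 && SG_LOGPOST(L) > ly; ++st) L -= wslice;
        if (L < 1e-6) L = 1e-6;
        for (int st = 0; st < 50 && SG_LOGPOST(Rr) > ly; ++st) Rr += wslice;
        for (int st = 0; st < 100; ++st) {
          double cand = L + (Rr - L) * unif_rand();
          if (cand > 1e-6 && SG_LOGPOST(cand) > ly) { sg[p][c] = cand; break; }
          if (cand < s) L = cand; else Rr = cand;
        }
        #undef SG_LOGPOST

        // ---- interweaved joint moves (escape the hierarchical funnel) ----
        // translation: shift the group mean and every member node together;
        // the hierarchical normal terms are invariant, only the data
        // likelihood and the mean's prior change.
        {
          double d = gms[p][c] * norm_rand();
          double mup = mu[p][c] + d;
          bmatt[p][c]++;
          bool ok = !((p == 1 && mup <= 0.0) || (p == 2 && mup < 0.0));
          for (int j = 0; j < nm && ok; ++j) {
            double xn = x[p][mem[j]] + d;
            if (p == 1 && xn <= 0.0) ok = false;
            if (p == 2 && (xn < 0.0 || xn >= tau_ub[mem[j]])) ok = false;
          }
          if (ok) {
            double dlp = R::dnorm(mup, prior_mu0[p], prior_sd0[p], 1) -
                         R::dnorm(mu[p][c], prior_mu0[p], prior_sd0[p], 1);
            std::vector<double> nll;
            nll.reserve(nm * (varies[p] ? 1 : 6));
            for (int j = 0; j < nm && ok; ++j) {
              int slot = mem[j], i = slot / npc[p], k = slot % npc[p];
              double xn = x[p][slot] + d;
              int c_lo = varies[p] ? k : 0, c_hi = varies[p] ? k : 5;
              for (int cc = c_lo; cc <= c_hi; ++cc) {
                double dd = (p == 0) ? xn : x[0][i * npc[0] + (varies[0] ? cc : 0)];
                double th = (p == 1) ? xn : x[1][i * npc[1] + (varies[1] ? cc : 0)];
                double ta = (p == 2) ? xn : x[2][i * npc[2] + (varies[2] ? cc : 0)];
                double l2 = cell_loglik(D, i, cc, dd, th, ta);
                if (D.tr[i * 6 + cc].size() > 0 && !std::isfinite(l2)) { ok = false; break; }
                dlp += l2 - ll[i * 6 + cc];
                nll.push_back(l2);
              }
            }
            if (ok && std::log(unif_rand()) < dlp) {
              mu[p][c] = mup;
              size_t q = 0;
              for (int j = 0; j < nm; ++j) {
                int slot = mem[j], i = slot / npc[p], k = slot % npc[p];
                x[p][slot] += d;
                int c_lo = varies[p] ? k : 0, c_hi = varies[p] ? k : 5;
                for (int cc = c_lo; cc <= c_hi; ++cc) ll[i * 6 + cc] = nll[q++];
              }
              bmacc[p][c]++;
            }
          }
        }
        // rescaling: multiply the spread and every member's deviation from
        // the mean by a common factor (log-scale random walk); the
        // hierarchical terms cancel against the transformation Jacobian,
        // leaving the likelihood, the half-normal prior and log(s'/s).
        {
          double s0 = sg[p][c];
          double sp2 = s0 * std::exp(gss[p][c] * norm_rand());
          double fac = sp2 / s0;
          bsatt[p][c]++;
          bool ok = true;
          for (int j = 0; j < nm && ok; ++j) {
            double xn = mu[p][c] + fac * (x[p][mem[j]] - mu[p][c]);
            if (p == 1 && xn <= 0.0) ok = false;
            if (p == 2 && (xn < 0.0 || xn >= tau_ub[mem[j]])) ok = false;
          }
          if (ok) {
            double dlp = -(sp2 * sp2 - s0 * s0) / hn2 + std::log(fac);
            std::vector<double> nll;
            nll.reserve(nm * (varies[p] ? 1 : 6));
            for (int j = 0; j < nm && ok; ++j) {
              int slot = mem[j], i = slot / npc[p], k = slot % npc[p];
              double xn = mu[p][c] + fac * (x[p][slot] - mu[p][c]);
              int c_lo = varies[p] ? k : 0, c_hi = varies[p] ? k : 5;
              for (int cc = c_lo; cc <= c_hi; ++cc) {
                double dd = (p == 0) ? xn : x[0][i * npc[0] + (varies[0] ? cc : 0)];
                double th = (p == 1) ? xn : x[1][i * npc[1] + (varies[1] ? cc : 0)];
                double ta = (p == 2) ? xn : x[2][i * npc[2] + (varies[2] ? cc : 0)];
                double l2 = cell_loglik(D, i, cc, dd, th, ta);
                if (D.tr[i * 6 + cc].size() > 0 && !std::isfinite(l2)) { ok = false; break; }
                dlp += l2 - ll[i * 6 + cc];
                nll.push_back(l2);
              }
            }
            if (ok && std::log(unif_rand()) < dlp) {
              sg[p][c] = sp2;
              size_t q = 0;
              for (int j = 0; j < nm; ++j) {
                int slot = mem[j], i = slot / npc[p], k = slot % npc[p];
                x[p][slot] = mu[p][c] + fac * (x[p][slot] - mu[p][c]);
                int c_lo = varies[p] ? k : 0, c_hi = varies[p] ? k : 5;
                for (int cc = c_lo; cc <= c_hi; ++cc) ll[i * 6 + cc] = nll[q++];
              }
              bsacc[p][c]++;
            }
          }
        }
      }
    }

    // ---- adaptation (burn-in only) ----
    if (it % batch == 0 && it <= burn_in) {
      adapt_n++;
      double step = std::min(0.25, 1.0 / std::sqrt((double)adapt_n));
      double maxch = 0.0;
      for (int p = 0; p < 3; ++p) {
        for (size_t j = 0; j < ps[p].size(); ++j) {
          if (batt[p][j] > 0) {
            double r = (double)bacc[p][j] / batt[p][j];
            double d = (r > 0.44) ? step : -step;
            ps[p][j] *= std::exp(d);
            maxch = std::max(maxch, std::fabs(d));
          }
          bacc[p][j] = batt[p][j] = 0;
        }
        for (int c = 0; c < ngc[p]; ++c) {
          if (bmatt[p][c] > 0) {
            double r = (double)bmacc[p][c] / bmatt[p][c];
            gms[p][c] *= std::exp((r > 0.44) ? step : -step);
            maxch = std::max(maxch, step);
          }
          if (bsatt[p][c] > 0) {
            double r = (double)bsacc[p][c] / bsatt[p][c];
            gss[p][c] *= std::exp((r > 0.44) ? step : -step);
            maxch = std::max(maxch, step);
          }
          bmacc[p][c] = bmatt[p][c] = bsacc[p][c] = bsatt[p][c] = 0;
        }
      }
      adapt_iter.push_back(it);
      adapt_change.push_back(maxch);
    } else if (it % batch == 0) {
      // post burn-in: log zero change (scales frozen)
      adapt_iter.push_back(it);
      adapt_change.push_back(0.0);
    }

    // ---- retention ----
    if (it > burn_in && (it - burn_in) % thin == 0) {
      int col = 0;
      for (int p = 0; p < 3; ++p)
        for (int c = 0; c < ngc[p]; ++c) draws(ret, col++) = mu[p][c];
      for (int p = 0; p < 3; ++p)
        for (int c = 0; c < ngc[p]; ++c) draws(ret, col++) = sg[p][c];
      for (int p = 0; p < 3; ++p)
        for (int i = 0; i < P; ++i)
          for (int k = 0; k < npc[p]; ++k) draws(ret, col++) = x[p][i * npc[p] + k];
      double tot = 0.0;
      for (int i = 0; i < P; ++i)
        for (int c = 0; c < 6; ++c) tot += ll[i * 6 + c];
      deviance[ret] = -2.0 * tot;
      ret++;
    }
    if (it % 500 == 0) Rcpp::checkUserInterrupt();
  }

  // aggregate post-burn-in acceptance rates
  double pa = 0; long pt = 0;
  for (int p = 0; p < 3; ++p)
    for (size_t j = 0; j < pacc[p].size(); ++j) { pa += pacc[p][j]; pt += patt[p][j]; }
  double ga = 0; long gt = 0;
  for (int p = 0; p < 3; ++p)
    for (int c = 0; c < ngc[p]; ++c) {
      ga += gacc_mu[p][c] + gacc_sg[p][c];
      gt += gatt_mu[p][c] + gatt_sg[p][c];
    }

  return List::create(
    _["draws"] = draws,
    _["deviance"] = deviance,
    _["accept_participant"] = pt > 0 ? pa / pt : NA_REAL,
    _["accept_group"] = gt > 0 ? ga / gt : NA_REAL,
    _["adapt_log"] = DataFrame::create(_["iteration"] = adapt_iter,
                                       _["max_log_scale_change"] = adapt_change));
}
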