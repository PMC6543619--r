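// Discrete-time individual-level step engine.
//
// One call advances a set of individuals through 4-week steps until an
// absorbing state or the horizon. All randomness comes from a counter-based
// generator keyed on (seed, person, replicate, step, slot), so results are
// independent of cohort ordering and of how person-replicates are batched.
// Slots: 1 cancer-death draw, 2 other-death draw, 3 destination draw,
// 4 ordinal category draw, 5 comorbidity-increase draw, 6 increment-size
// draw. The same stream is exposed to R (counter_uniform) so the R-level
// single-step reference implementation consumes identical uniforms.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// label codes, fixed across R and C++:
// AS=1 WW=2 RP=3 RT=4 RTADJ=5 AA=6 GNRH=7 PCA_DEATH=8 OTHER_DEATH=9
static const int LAB_AS = 1, LAB_RTADJ = 5;
static const int N_LAB = 9;

static inline uint64_t mix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

static inline double cb_uniform(uint64_t seed, uint64_t person, uint64_t rep,
                                uint64_t step, uint64_t slot) {
  uint64_t h = mix64(seed ^ 0xD6E8FEB86659FD93ULL);
  h = mix64(h ^ (person * 0x9E3779B97F4A7C15ULL));
  h = mix64(h ^ (rep * 0xC2B2AE3D27D4EB4FULL));
  h = mix64(h ^ (step * 0x165667B19E3779F9ULL) ^ slot);
  return (double)(h >> 11) * (1.0 / 9007199254740992.0); // [0, 1)
}

// [[Rcpp::export(name = ".cpp_counter_uniform")]]
NumericVector cpp_counter_uniform(double seed, IntegerVector person,
                                  IntegerVector rep, IntegerVector step,
                                  IntegerVector slot) {
  int n = person.size();
  NumericVector out(n);
  uint64_t s = (uint64_t)seed;
  for (int i = 0; i < n; ++i) {
    out[i] = cb_uniform(s, (uint64_t)person[i], (uint64_t)rep[i],
                        (uint64_t)step[i], (uint64_t)slot[i]);
  }
  return out;
}

// ---- compiled model structures --------------------------------------------

struct LP {
  std::vector<int> code, arg;
  std::vector<double> beta;
  bool present = false;
};

struct DestModel {
  std::vector<int> dests;
  LP lp; // shared terms; beta stored per destination in `betas`
  std::vector<std::vector<double> > betas;
  bool present = false;
};

struct OrdModel {
  int K = 0;
  std::vector<double> zeta;
  LP lp;
  bool present = false;
};

static LP parse_lp(List m) {
  LP out;
  IntegerMatrix tc = m["tc"];
  NumericVector beta = m["beta"];
  int p = tc.ncol();
  out.code.resize(p); out.arg.resize(p); out.beta.resize(p);
  for (int j = 0; j < p; ++j) {
    out.code[j] = tc(0, j);
    out.arg[j] = tc(1, j);
    out.beta[j] = beta[j];
  }
  out.present = true;
  return out;
}

struct Ctx {
  int label, cat, cci, histmask;
  double age;
  int tis; // steps already spent in current state
};

static inline double term_value(int code, int arg, const Ctx& c) {
  switch (code) {
    case 0: return 1.0;                       // intercept
    case 1: return (c.age - 70.0) / 10.0;     // age per decade, centred
    case 2: return c.cci == arg ? 1.0 : 0.0;  // CCI level indicator
    case 3: return c.label == arg ? 1.0 : 0.0;
    case 4: return c.cat == arg ? 1.0 : 0.0;
    case 5: return (c.histmask >> arg) & 1 ? 1.0 : 0.0;
    case 6: return (double)(c.cat - 1);       // ordinal risk score
    case 7: return (double)c.cci;
    case 8: return (double)c.tis / 13.0;
    default: Rcpp::stop("unhandled term code");
  }
}

static inline double eval_lp(const LP& m, const Ctx& c) {
  double eta = 0.0;
  for (size_t j = 0; j < m.code.size(); ++j) {
    eta += m.beta[j] * term_value(m.code[j], m.arg[j], c);
  }
  return eta;
}

static inline double eval_terms(const LP& m, const std::vector<double>& beta,
                                const Ctx& c) {
  double eta = 0.0;
  for (size_t j = 0; j < m.code.size(); ++j) {
    eta += beta[j] * term_value(m.code[j], m.arg[j], c);
  }
  return eta;
}

static inline double logistic(double eta) { return 1.0 / (1.0 + exp(-eta)); }

// inverse-CDF draw from a zero-truncated Poisson(lambda)
static inline int ztp_draw(double lambda, double u) {
  if (lambda < 1e-12) return 1;
  double denom = expm1(lambda);
  double term = lambda, cum = 0.0;
  for (int k = 1; k <= 100; ++k) {
    cum += term / denom;
    if (u < cum) return k;
    term *= lambda / (double)(k + 1);
  }
  return 100;
}

// ---- main engine ----------------------------------------------------------

// persons: parallel vectors of entry conditions. Replicates r = rep_offset ..
// rep_offset + replicates - 1 give each person-replicate its own substream
// (the registry generator uses replicate stream 0; simulation uses 1..R).
// [[Rcpp::export(name = ".cpp_sim_engine")]]
List cpp_sim_engine(IntegerVector person_id, IntegerVector entry_label,
                    IntegerVector entry_cat, NumericVector age0,
                    IntegerVector cci0, IntegerVector hist0,
                    IntegerVector start_t, List cmodels, int horizon,
                    int replicates, int rep_offset, double seed,
                    bool occupancy) {
  int n = person_id.size();
  uint64_t sd = (uint64_t)seed;

  LP death_pca = parse_lp(cmodels["death_pca"]);
  LP death_other = parse_lp(cmodels["death_other"]);

  List dlist = cmodels["destination"], olist = cmodels["ordinal"],
       clist = cmodels["cci"];
  std::vector<DestModel> dest(N_LAB + 1);
  std::vector<OrdModel> ord(N_LAB + 1);
  std::vector<LP> cci_logit(N_LAB + 1), cci_rate(N_LAB + 1);
  for (int i = 0; i < 7; ++i) {
    if (dlist[i] != R_NilValue) {
      List dm = dlist[i];
      DestModel& d = dest[i + 1];
      IntegerVector dd = dm["dests"];
      d.dests.assign(dd.begin(), dd.end());
      IntegerMatrix tc = dm["tc"];
      NumericMatrix beta = dm["beta"];
      int p = tc.ncol();
      d.lp.code.resize(p); d.lp.arg.resize(p);
      for (int j = 0; j < p; ++j) { d.lp.code[j] = tc(0, j); d.lp.arg[j] = tc(1, j); }
      d.betas.resize(d.dests.size());
      for (size_t k = 0; k < d.dests.size(); ++k) {
        d.betas[k].resize(p);
        for (int j = 0; j < p; ++j) d.betas[k][j] = beta(j, k);
      }
      d.present = true;
    }
    if (olist[i] != R_NilValue) {
      List om = olist[i];
      OrdModel& o = ord[i + 1];
      o.K = as<int>(om["K"]);
      NumericVector z = om["zeta"];
      o.zeta.assign(z.begin(), z.end());
      o.lp = parse_lp(om);
      o.present = true;
    }
    List cm = clist[i];
    cci_logit[i + 1] = parse_lp(cm["logit"]);
    cci_rate[i + 1] = parse_lp(cm["rate"]);
  }
  bool as_ww = as<bool>(cmodels["as_ww_enabled"]);
  NumericVector thr = cmodels["as_ww_thresholds"];

  std::vector<int> ev_person, ev_rep, ev_step, ev_type, ev_a, ev_b;
  std::vector<int> tm_person, tm_rep, tm_end, tm_status;
  size_t guess = (size_t)n * (size_t)replicates;
  tm_person.reserve(guess); tm_rep.reserve(guess);
  tm_end.reserve(guess); tm_status.reserve(guess);
  NumericMatrix occ(occupancy ? horizon : 0, occupancy ? N_LAB : 0);

  const double step_years = 28.0 / 365.25;

  for (int i = 0; i < n; ++i) {
    uint64_t pid = (uint64_t)person_id[i];
    for (int rr = 0; rr < replicates; ++rr) {
      uint64_t rep = (uint64_t)(rep_offset + rr);
      Ctx c;
      c.label = entry_label[i]; c.cat = entry_cat[i];
      c.cci = cci0[i]; c.histmask = hist0[i];
      int entered_at = start_t[i] - 1;
      int status = 0, end_step = horizon;
      for (int t = start_t[i]; t <= horizon; ++t) {
        c.age = age0[i] + (double)t * step_years; // age at end of step
        c.tis = t - entered_at;
        double u1 = cb_uniform(sd, pid, rep, (uint64_t)t, 1);
        if (u1 < logistic(eval_lp(death_pca, c))) {
          status = 8; end_step = t; break;
        }
        double u2 = cb_uniform(sd, pid, rep, (uint64_t)t, 2);
        if (u2 < logistic(eval_lp(death_other, c))) {
          status = 9; end_step = t; break;
        }
        // treatment change: deterministic AS->WW rule first, then the
        // stochastic multinomial draw over the origin's destinations
        int new_label = c.label, new_cat = c.cat;
        if (as_ww && c.label == LAB_AS && c.age >= thr[c.cci]) {
          new_label = 2; // WW
        } else if (dest[c.label].present) {
          const DestModel& d = dest[c.label];
          double u3 = cb_uniform(sd, pid, rep, (uint64_t)t, 3);
          double denom = 1.0;
          std::vector<double> ex(d.dests.size());
          for (size_t k = 0; k < d.dests.size(); ++k) {
            ex[k] = exp(eval_terms(d.lp, d.betas[k], c));
            denom += ex[k];
          }
          double acc = 0.0;
          for (size_t k = 0; k < d.dests.size(); ++k) {
            acc += ex[k] / denom;
            if (u3 < acc) { new_label = d.dests[k]; break; }
          }
        }
        bool changed = new_label != c.label;
        if (changed) {
          if (new_label == LAB_RTADJ) {
            // direct transition: category known and unchanged
            new_cat = c.cat;
          } else {
            const OrdModel& o = ord[new_label];
            if (!o.present) Rcpp::stop("no ordinal entry model for label %d",
                                       new_label);
            Ctx ec = c;             // entry covariates: origin state/category,
            ec.histmask |= (1 << c.label); // history including the origin
            double eta = eval_lp(o.lp, ec);
            double u4 = cb_uniform(sd, pid, rep, (uint64_t)t, 4);
            new_cat = o.K;
            for (int j = 0; j < o.K - 1; ++j) {
              if (u4 < logistic(o.zeta[j] - eta)) { new_cat = j + 1; break; }
            }
          }
          ev_person.push_back(person_id[i]); ev_rep.push_back((int)rep);
          ev_step.push_back(t); ev_type.push_back(1);
          ev_a.push_back(new_label); ev_b.push_back(new_cat);
        }
        // comorbidity update, evaluated on the state occupied during the
        // step (congruent with person-period attribution); takes effect
        // from the next step
        int new_cci = c.cci;
        if (c.cci < 3) {
          double u5 = cb_uniform(sd, pid, rep, (uint64_t)t, 5);
          if (u5 < logistic(eval_lp(cci_logit[c.label], c))) {
            double u6 = cb_uniform(sd, pid, rep, (uint64_t)t, 6);
            int inc = ztp_draw(exp(eval_lp(cci_rate[c.label], c)), u6);
            new_cci = c.cci + inc > 3 ? 3 : c.cci + inc;
            ev_person.push_back(person_id[i]); ev_rep.push_back((int)rep);
            ev_step.push_back(t); ev_type.push_back(2);
            ev_a.push_back(new_cci); ev_b.push_back(NA_INTEGER);
          }
        }
        if (changed) {
          c.histmask |= (1 << c.label);
          c.label = new_label; c.cat = new_cat;
          entered_at = t;
        }
        c.cci = new_cci;
        if (occupancy) occ(t - 1, c.label - 1) += 1.0;
      }
      if (occupancy && status != 0) {
        for (int t = end_step; t <= horizon; ++t) occ(t - 1, status - 1) += 1.0;
      }
      tm_person.push_back(person_id[i]); tm_rep.push_back((int)rep);
      tm_end.push_back(end_step); tm_status.push_back(status);
    }
  }

  List events = List::create(
    _["person_id"] = wrap(ev_person), _["replicate"] = wrap(ev_rep),
    _["step"] = wrap(ev_step), _["type"] = wrap(ev_type),
    _["a"] = wrap(ev_a), _["b"] = wrap(ev_b));
  List terminal = List::create(
    _["person_id"] = wrap(tm_person), _["replicate"] = wrap(tm_rep),
    _["end_step"] = wrap(tm_end), _["status"] = wrap(tm_status));
  return List::create(_["events"] = events, _["terminal"] = terminal,
                      _["occupancy"] = occ);
}
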