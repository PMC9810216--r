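// Simulation core: keyed counter-based random streams, natural-history
// sampling (adenoma-carcinoma sequence) and the screening replay engine.
// Everything here is deterministic given (master seed, person id, attempt):
// every random quantity is a pure function of a (seed, person, attempt,
// purpose, counter) key, so persons can be simulated in any order and the
// same person can be replayed under different screening arms on common
// random numbers.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <cmath>
#include <algorithm>
#include <limits>

using namespace Rcpp;

static const double INF_D = std::numeric_limits<double>::infinity();
static const double TIE_EPS = 1e-9;
// counter fold for (exam ordinal, lesion) detection keys; lesions per
// person are capped at 500 by the sampler
static const uint64_t ORD_FOLD = 512;

// Purpose codes for the keyed streams. Must stay in sync with the R-side
// constants in R/rng.R (purpose_codes()).
enum Purpose {
  P_PSI = 1, P_DEATH = 2, P_NADEN = 3, P_ATIME = 4, P_GROWTH = 5,
  P_TRANS = 6, P_SOJ = 7, P_STAGE = 8, P_SHIFT = 9, P_SURV = 10,
  P_COLDET = 11, P_FITDET = 12, P_COLCRC = 13, P_FITCRC = 14, P_FITFP = 15
};

// splitmix64 finalizer; good avalanche, standard for key hashing.
static inline uint64_t mix64(uint64_t z) {
  z += 0x9E3779B97F4A7C15ULL;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static inline double key_u01(uint64_t seed, uint64_t person, uint64_t attempt,
                             uint64_t purpose, uint64_t counter) {
  uint64_t h = mix64(seed);
  h = mix64(h ^ person);
  h = mix64(h ^ attempt);
  h = mix64(h ^ purpose);
  h = mix64(h ^ counter);
  // 53-bit mantissa, offset by half an ulp so u is never exactly 0 or 1
  return ((h >> 11) + 0.5) * (1.0 / 9007199254740992.0);
}

// ------------------------------------------------------------------
// parameters

struct NHParams {
  bool toy;
  double toy_init, toy_trans, toy_soj;
  double psi_mean, psi_sd;
  // piecewise-linear log-intensity segments on [age_min, age_max]
  std::vector<double> seg_a;   // segment boundaries, size m+1
  std::vector<double> seg_g0;  // log-intensity at left boundary
  std::vector<double> seg_s;   // slope within segment
  std::vector<double> seg_cum; // cumulative \int e^g up to right boundary
  double total_mass;
  double gr_scale, gr_shape, d0, dinf, beta;
  double soj_meanlog, soj_sdlog;
  double stage_cum[4];
  double shift_cum[4][4];
  bool surv_fixed;             // fixed survival years vs exponential rates
  double surv[4];
  std::vector<double> ltH;     // cumulative other-cause hazard, ages 0..110
  double age_min, age_max;
};

static NHParams parse_params(const List& par) {
  NHParams P;
  P.toy = as<bool>(par["toy"]);
  P.toy_init = as<double>(par["toy_init"]);
  P.toy_trans = as<double>(par["toy_trans"]);
  P.toy_soj = as<double>(par["toy_soj"]);
  P.psi_mean = as<double>(par["psi_mean"]);
  P.psi_sd = as<double>(par["psi_sd"]);
  P.gr_scale = as<double>(par["growth_scale"]);
  P.gr_shape = as<double>(par["growth_shape"]);
  P.d0 = as<double>(par["d0"]);
  P.dinf = as<double>(par["d_inf"]);
  P.beta = as<double>(par["beta"]);
  P.soj_meanlog = as<double>(par["soj_meanlog"]);
  P.soj_sdlog = as<double>(par["soj_sdlog"]);
  NumericVector sp = par["stage_probs"];
  double c = 0.0;
  for (int k = 0; k < 4; ++k) { c += sp[k]; P.stage_cum[k] = c; }
  NumericMatrix sh = par["stage_shift"];
  for (int r = 0; r < 4; ++r) {
    c = 0.0;
    for (int k = 0; k < 4; ++k) { c += sh(r, k); P.shift_cum[r][k] = c; }
  }
  P.surv_fixed = as<bool>(par["surv_fixed"]);
  NumericVector sv = par["surv_by_stage"];
  for (int k = 0; k < 4; ++k) P.surv[k] = sv[k];
  NumericVector H = par["lt_cumhaz"];
  P.ltH.assign(H.begin(), H.end());
  P.age_min = as<double>(par["age_min"]);
  P.age_max = as<double>(par["age_max"]);

  // build log-intensity segments from knots, flat extrapolation
  NumericVector ka = par["knot_ages"], kg = par["knot_logint"];
  int nk = ka.size();
  std::vector<double> bp;
  bp.push_back(P.age_min);
  for (int i = 0; i < nk; ++i)
    if (ka[i] > P.age_min + 1e-12 && ka[i] < P.age_max - 1e-12) bp.push_back(ka[i]);
  bp.push_back(P.age_max);
  auto geval = [&](double a) {
    if (a <= ka[0]) return kg[0];
    if (a >= ka[nk - 1]) return kg[nk - 1];
    int i = 0;
    while (i < nk - 1 && ka[i + 1] < a) ++i;
    double w = (a - ka[i]) / (ka[i + 1] - ka[i]);
    return kg[i] + w * (kg[i + 1] - kg[i]);
  };
  int m = (int)bp.size() - 1;
  P.seg_a = bp;
  P.seg_g0.resize(m);
  P.seg_s.resize(m);
  P.seg_cum.resize(m);
  double cum = 0.0;
  for (int i = 0; i < m; ++i) {
    double a1 = bp[i], a2 = bp[i + 1];
    double g1 = geval(a1), g2 = geval(a2);
    double s = (g2 - g1) / (a2 - a1);
    P.seg_g0[i] = g1;
    P.seg_s[i] = s;
    double mass;
    if (std::fabs(s) < 1e-12) mass = std::exp(g1) * (a2 - a1);
    else mass = (std::exp(g2) - std::exp(g1)) / s;
    cum += mass;
    P.seg_cum[i] = cum;
  }
  P.total_mass = cum;
  return P;
}

// invert the (psi-free) integrated intensity at target in (0, total_mass)
static double invert_intensity(const NHParams& P, double target) {
  int m = (int)P.seg_g0.size();
  int i = 0;
  while (i < m - 1 && P.seg_cum[i] < target) ++i;
  double prev = (i == 0) ? 0.0 : P.seg_cum[i - 1];
  double rem = target - prev;
  double a1 = P.seg_a[i], g1 = P.seg_g0[i], s = P.seg_s[i];
  if (std::fabs(s) < 1e-12) return a1 + rem * std::exp(-g1);
  double arg = rem * s * std::exp(-g1) + 1.0;
  if (arg <= 0) return P.seg_a[i + 1];  // numeric guard
  double a = a1 + std::log(arg) / s;
  return std::min(a, P.seg_a[i + 1]);
}

static double invert_lifetable(const NHParams& P, double u) {
  double E = -std::log(u);
  int n = (int)P.ltH.size();       // ages 0..n-1
  double last = (double)(n - 1);
  if (E >= P.ltH[n - 1]) return last;
  // first index with H > E
  int k = (int)(std::upper_bound(P.ltH.begin(), P.ltH.end(), E) - P.ltH.begin());
  // H[k-1] <= E < H[k]
  double h = P.ltH[k] - P.ltH[k - 1];
  return (double)(k - 1) + (E - P.ltH[k - 1]) / h;
}

static int pois_inv(double u, double lambda) {
  if (lambda <= 0) return 0;
  double p = std::exp(-lambda), cum = p;
  int k = 0;
  while (u > cum && k < 500) {
    ++k;
    p *= lambda / k;
    cum += p;
  }
  return k;
}

static inline double diam_at(const NHParams& P, double init, double lam, double age) {
  return P.dinf - (P.dinf - P.d0) * std::exp(-lam * (age - init));
}

// cumulative transition hazard of a lesion t years after initiation
static inline double cumtrans(const NHParams& P, double lam, double t) {
  return P.beta * (P.dinf * t - (P.dinf - P.d0) * (1.0 - std::exp(-lam * t)) / lam);
}

static double solve_transition(const NHParams& P, double lam, double E) {
  double lo = E / (P.beta * P.dinf);
  double hi = E / (P.beta * P.d0);
  if (hi > 1e6) hi = 1e6;             // far beyond any lifespan
  if (cumtrans(P, lam, hi) < E) return 1e6;
  for (int it = 0; it < 100; ++it) {
    double mid = 0.5 * (lo + hi);
    if (cumtrans(P, lam, mid) < E) lo = mid; else hi = mid;
    if (hi - lo < 1e-10) break;
  }
  return 0.5 * (lo + hi);
}

static inline double surv_time(const NHParams& P, int stage0, double u) {
  if (P.surv_fixed) return P.surv[stage0];
  return -std::log(u) / P.surv[stage0];
}

// ------------------------------------------------------------------
// person sampling

struct Person {
  double psi, other_death;
  std::vector<double> init, lam, trans, soj;
  std::vector<int> cstage, sstage;  // 0-based
};

static int draw_stage(const double* cum4, double u) {
  for (int k = 0; k < 4; ++k) if (u < cum4[k]) return k;
  return 3;
}

static void sample_one(const NHParams& P, uint64_t seed, uint64_t pid,
                       uint64_t att, Person& out) {
  out.init.clear(); out.lam.clear(); out.trans.clear(); out.soj.clear();
  out.cstage.clear(); out.sstage.clear();

  out.other_death = invert_lifetable(P, key_u01(seed, pid, att, P_DEATH, 0));

  int N;
  std::vector<double> times;
  if (P.toy) {
    out.psi = 0.0;
    N = 1;
    times.push_back(P.toy_init);
  } else {
    out.psi = P.psi_mean + P.psi_sd *
      R::qnorm(key_u01(seed, pid, att, P_PSI, 0), 0.0, 1.0, 1, 0);
    double lam_tot = std::exp(out.psi) * P.total_mass;
    N = pois_inv(key_u01(seed, pid, att, P_NADEN, 0), lam_tot);
    times.resize(N);
    for (int j = 0; j < N; ++j)
      times[j] = invert_intensity(P, key_u01(seed, pid, att, P_ATIME, j) * P.total_mass);
    std::sort(times.begin(), times.end());
  }

  for (int j = 0; j < N; ++j) {
    double init = times[j];
    double lam, trans;
    if (P.toy) {
      lam = std::log((P.dinf - P.d0) / (P.dinf - 10.0)) / 8.0;
      trans = P.toy_trans;
    } else {
      double ug = key_u01(seed, pid, att, P_GROWTH, j);
      double tau = P.gr_scale * std::pow(-std::log(ug), -1.0 / P.gr_shape);
      lam = std::log((P.dinf - P.d0) / (P.dinf - 10.0)) / tau;
      double E = -std::log(key_u01(seed, pid, att, P_TRANS, j));
      trans = init + solve_transition(P, lam, E);
    }
    double soj;
    if (P.toy) {
      soj = P.toy_soj;
    } else {
      double us = key_u01(seed, pid, att, P_SOJ, j);
      soj = std::exp(P.soj_meanlog + P.soj_sdlog * R::qnorm(us, 0.0, 1.0, 1, 0));
    }
    int cs = draw_stage(P.stage_cum, key_u01(seed, pid, att, P_STAGE, j));
    int ss = draw_stage(P.shift_cum[cs], key_u01(seed, pid, att, P_SHIFT, j));
    out.init.push_back(init);
    out.lam.push_back(lam);
    out.trans.push_back(trans);
    out.soj.push_back(soj);
    out.cstage.push_back(cs);
    out.sstage.push_back(ss);
  }
}

// ------------------------------------------------------------------
// screening replay

struct TestChars { double s_small, s_med, s_large, s_crc, spec; };

static TestChars parse_chars(const List& l) {
  TestChars c;
  c.s_small = as<double>(l["sens_small"]);
  c.s_med = as<double>(l["sens_medium"]);
  c.s_large = as<double>(l["sens_large"]);
  c.s_crc = as<double>(l["sens_preclinical_crc"]);
  c.spec = as<double>(l["specificity"]);
  return c;
}

struct Policy { double int_high, int_low, int_clear, max_surv_age; };

static Policy parse_policy(const List& l) {
  Policy p;
  p.int_high = as<double>(l["interval_high_risk"]);
  p.int_low = as<double>(l["interval_low_risk"]);
  p.int_clear = as<double>(l["interval_clear"]);
  p.max_surv_age = as<double>(l["max_surveillance_age"]);
  return p;
}

struct ReplayOut {
  double ly, death, dx_age;
  int dx_mode;   // 0 none, 1 clinical, 2 screen-detected
  int dx_stage;  // 0-based; -1 if none
};

// Replay one person's life under a given exam schedule. Modality codes:
// 0 = colonoscopy, 1 = FIT. Schedule must be sorted by age.
// surv_delay / allow_post_surv / min_post_exam implement the disruption
// rules for surveillance colonoscopies straddling the pandemic onset.
static ReplayOut replay_one(const NHParams& P, const TestChars& CC, const TestChars& CF,
                            const Policy& pol, uint64_t seed, uint64_t pid,
                            uint64_t att, const Person& pe,
                            const double* sa, const int* sm, int ns,
                            double ref_age, double onset, double surv_delay,
                            bool allow_post_surv, double min_post_exam) {
  int nles = (int)pe.init.size();
  std::vector<char> removed(nles, 0);
  double surv_due = INF_D;
  double resume_at = -INF_D;
  int si = 0, fit_ord = 0, col_ord = 0;
  double dx_age = INF_D, crc_death = INF_D;
  int dx_mode = 0, dx_stage = -1;

  auto clinical_next = [&](int* who) {
    double best = INF_D; int bi = -1;
    for (int j = 0; j < nles; ++j) {
      if (removed[j]) continue;
      double d = pe.trans[j] + pe.soj[j];
      if (d < best) { best = d; bi = j; }
    }
    *who = bi;
    return best;
  };

  // Detection draws are keyed by (lesion, modality, exam ordinal of that
  // modality): ORD_FOLD * ordinal + lesion.  A delayed exam occupies the
  // same ordinal and re-uses the same draw (cross-arm pairing); successive
  // exams of the same lesion draw independently.
  // returns true if the colonoscopy ends in a (screen-detected) diagnosis
  auto do_col = [&](double age) {
    ++col_ord;
    uint64_t base = (uint64_t)col_ord * ORD_FOLD;
    int ndet = 0; bool any_large = false;
    int crc_j = -1; double crc_tr = INF_D;
    for (int j = 0; j < nles; ++j) {
      if (removed[j] || pe.init[j] > age) continue;
      if (pe.trans[j] <= age) {  // preclinical cancer
        if (key_u01(seed, pid, att, P_COLCRC, base + j) < CC.s_crc &&
            pe.trans[j] < crc_tr) {
          crc_tr = pe.trans[j]; crc_j = j;
        }
      } else {                   // adenoma: detect -> polypectomy
        double d = diam_at(P, pe.init[j], pe.lam[j], age);
        double sens = d < 6.0 ? CC.s_small : (d < 10.0 ? CC.s_med : CC.s_large);
        if (key_u01(seed, pid, att, P_COLDET, base + j) < sens) {
          removed[j] = 1; ++ndet;
          if (d >= 10.0) any_large = true;
        }
      }
    }
    if (crc_j >= 0) {
      dx_mode = 2; dx_age = age; dx_stage = pe.sstage[crc_j];
      // survival clock anchored at the would-be clinical diagnosis age
      double anchor = pe.trans[crc_j] + pe.soj[crc_j];
      crc_death = anchor + surv_time(P, dx_stage, key_u01(seed, pid, att, P_SURV, crc_j));
      return true;
    }
    resume_at = age + pol.int_clear - TIE_EPS;
    if (ndet > 0) {
      double interval = (ndet >= 3 || any_large) ? pol.int_high : pol.int_low;
      double due = age + interval;
      if (age < onset && due >= onset) {
        due += surv_delay;
        if (due < min_post_exam) due = min_post_exam;
      }
      bool cancel = (due > pol.max_surv_age) || (due >= onset && !allow_post_surv);
      surv_due = cancel ? INF_D : due;
    } else {
      surv_due = INF_D;
    }
    return false;
  };

  auto do_fit = [&](double age) {
    ++fit_ord;
    uint64_t base = (uint64_t)fit_ord * ORD_FOLD;
    bool pos = false;
    for (int j = 0; j < nles && !pos; ++j) {
      if (removed[j] || pe.init[j] > age) continue;
      if (pe.trans[j] <= age) {
        if (key_u01(seed, pid, att, P_FITCRC, base + j) < CF.s_crc) pos = true;
      } else {
        double d = diam_at(P, pe.init[j], pe.lam[j], age);
        double sens = d < 6.0 ? CF.s_small : (d < 10.0 ? CF.s_med : CF.s_large);
        if (key_u01(seed, pid, att, P_FITDET, base + j) < sens) pos = true;
      }
    }
    if (!pos && key_u01(seed, pid, att, P_FITFP, fit_ord) > CF.spec) pos = true;
    return pos;
  };

  while (true) {
    int cj;
    double cd = clinical_next(&cj);
    while (si < ns && sa[si] < resume_at) ++si;
    double base_age = si < ns ? sa[si] : INF_D;
    double ex_age; int ex_kind;  // 0 base col, 1 base fit, 2 surveillance col
    if (surv_due <= base_age) { ex_age = surv_due; ex_kind = 2; }
    else { ex_age = base_age; ex_kind = (sm[si] == 0) ? 0 : 1; }
    if (!(ex_age < cd && ex_age < pe.other_death)) break;
    if (ex_kind == 2) {
      surv_due = INF_D;
      if (do_col(ex_age)) break;
    } else if (ex_kind == 0) {
      ++si;
      if (do_col(ex_age)) break;
    } else {
      ++si;
      if (do_fit(ex_age) && do_col(ex_age)) break;
    }
  }

  if (dx_mode == 0) {
    int cj;
    double cd = clinical_next(&cj);
    if (cd < pe.other_death) {
      dx_mode = 1; dx_age = cd; dx_stage = pe.cstage[cj];
      crc_death = cd + surv_time(P, dx_stage, key_u01(seed, pid, att, P_SURV, cj));
    }
  }

  ReplayOut out;
  out.death = std::min(pe.other_death, crc_death);
  out.dx_age = dx_mode ? dx_age : NA_REAL;
  out.dx_mode = dx_mode;
  out.dx_stage = dx_mode ? dx_stage : -1;
  out.ly = std::max(0.0, out.death - ref_age);
  return out;
}

// ------------------------------------------------------------------
// exported interface

// [[Rcpp::export]]
NumericVector cpp_keyed_u01(double master_seed, double person,
                            double attempt, double purpose,
                            NumericVector counter) {
  int n = counter.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = key_u01((uint64_t)master_seed, (uint64_t)person,
                     (uint64_t)attempt, (uint64_t)purpose,
                     (uint64_t)counter[i]);
  return out;
}

static List person_to_list(const Person& pe) {
  return List::create(
    _["psi"] = pe.psi,
    _["other_death"] = pe.other_death,
    _["init_age"] = NumericVector(pe.init.begin(), pe.init.end()),
    _["growth_rate"] = NumericVector(pe.lam.begin(), pe.lam.end()),
    _["transition_age"] = NumericVector(pe.trans.begin(), pe.trans.end()),
    _["sojourn"] = NumericVector(pe.soj.begin(), pe.soj.end()),
    _["stage_clinical"] = IntegerVector(pe.cstage.begin(), pe.cstage.end()),
    _["stage_screen"] = IntegerVector(pe.sstage.begin(), pe.sstage.end()));
}

// [[Rcpp::export]]
List cpp_sample_person(List params, double master_seed, double person_id,
                       double attempt) {
  NHParams P = parse_params(params);
  Person pe;
  sample_one(P, (uint64_t)master_seed, (uint64_t)person_id, (uint64_t)attempt, pe);
  return person_to_list(pe);
}

// Sample a conditioned cohort: persons alive, free of CRC diagnosis at
// ref_age, and consistent with their simulated pre-pandemic screening
// history (exams in pre_* with the supplied test characteristics).
// [[Rcpp::export]]
List cpp_sample_cohort(List params, int n, double master_seed, double ref_age,
                       NumericVector pre_ages, IntegerVector pre_mod,
                       List chars_col, List chars_fit, List policy,
                       int max_attempts) {
  NHParams P = parse_params(params);
  TestChars CC = parse_chars(chars_col), CF = parse_chars(chars_fit);
  Policy pol = parse_policy(policy);
  int np = pre_ages.size();
  std::vector<double> sa(pre_ages.begin(), pre_ages.end());
  std::vector<int> sm(pre_mod.begin(), pre_mod.end());

  std::vector<double> psi(n), other_death(n);
  std::vector<int> attempt_used(n), les_count(n);
  std::vector<double> l_init, l_lam, l_trans, l_soj;
  std::vector<int> l_cs, l_ss, l_person;
  long total_attempts = 0, accepted = 0;

  Person pe;
  for (int i = 0; i < n; ++i) {
    uint64_t pid = (uint64_t)(i + 1);
    bool ok = false;
    for (int a = 0; a < max_attempts; ++a) {
      ++total_attempts;
      sample_one(P, (uint64_t)master_seed, pid, (uint64_t)a, pe);
      ReplayOut r = replay_one(P, CC, CF, pol, (uint64_t)master_seed, pid,
                               (uint64_t)a, pe, sa.data(), sm.data(), np,
                               ref_age, ref_age, 0.0, true, 0.0);
      bool alive = pe.other_death > ref_age;
      bool undx = (r.dx_mode == 0) || (r.dx_age > ref_age);
      if (alive && undx) {
        psi[i] = pe.psi;
        other_death[i] = pe.other_death;
        attempt_used[i] = a;
        les_count[i] = (int)pe.init.size();
        for (size_t j = 0; j < pe.init.size(); ++j) {
          l_person.push_back(i + 1);
          l_init.push_back(pe.init[j]);
          l_lam.push_back(pe.lam[j]);
          l_trans.push_back(pe.trans[j]);
          l_soj.push_back(pe.soj[j]);
          l_cs.push_back(pe.cstage[j]);
          l_ss.push_back(pe.sstage[j]);
        }
        ok = true;
        ++accepted;
        break;
      }
    }
    if (!ok)
      stop("cohort conditioning failed: no acceptable history for person %d "
           "within %d attempts (pathological parameter configuration?)",
           i + 1, max_attempts);
    if ((i & 0x3FFF) == 0) Rcpp::checkUserInterrupt();
  }
  double rejection_rate = 1.0 - (double)accepted / (double)total_attempts;
  if (rejection_rate > 0.99)
    stop("cohort conditioning rejection rate exceeds 99%%");

  return List::create(
    _["n"] = n,
    _["psi"] = NumericVector(psi.begin(), psi.end()),
    _["other_death"] = NumericVector(other_death.begin(), other_death.end()),
    _["attempt"] = IntegerVector(attempt_used.begin(), attempt_used.end()),
    _["lesion_count"] = IntegerVector(les_count.begin(), les_count.end()),
    _["lesion_person"] = IntegerVector(l_person.begin(), l_person.end()),
    _["lesion_init"] = NumericVector(l_init.begin(), l_init.end()),
    _["lesion_growth"] = NumericVector(l_lam.begin(), l_lam.end()),
    _["lesion_transition"] = NumericVector(l_trans.begin(), l_trans.end()),
    _["lesion_sojourn"] = NumericVector(l_soj.begin(), l_soj.end()),
    _["lesion_stage_clinical"] = IntegerVector(l_cs.begin(), l_cs.end()),
    _["lesion_stage_screen"] = IntegerVector(l_ss.begin(), l_ss.end()),
    _["total_attempts"] = (double)total_attempts);
}

// Replay a conditioned cohort under one screening arm.
// [[Rcpp::export]]
List cpp_replay_cohort(List cohort, List params, NumericVector sched_ages,
                       IntegerVector sched_mod, List chars_col, List chars_fit,
                       List policy, double ref_age, double onset_age,
                       double surv_delay, bool allow_post_surv,
                       double min_post_exam, double master_seed) {
  NHParams P = parse_params(params);
  TestChars CC = parse_chars(chars_col), CF = parse_chars(chars_fit);
  Policy pol = parse_policy(policy);
  int n = as<int>(cohort["n"]);
  NumericVector other_death = cohort["other_death"];
  IntegerVector attempt = cohort["attempt"];
  IntegerVector les_count = cohort["lesion_count"];
  NumericVector l_init = cohort["lesion_init"];
  NumericVector l_lam = cohort["lesion_growth"];
  NumericVector l_trans = cohort["lesion_transition"];
  NumericVector l_soj = cohort["lesion_sojourn"];
  IntegerVector l_cs = cohort["lesion_stage_clinical"];
  IntegerVector l_ss = cohort["lesion_stage_screen"];
  int ns = sched_ages.size();
  std::vector<double> sa(sched_ages.begin(), sched_ages.end());
  std::vector<int> sm(sched_mod.begin(), sched_mod.end());

  NumericVector ly(n), death(n), dx_age(n);
  IntegerVector dx_mode(n), dx_stage(n);
  Person pe;
  int off = 0;
  for (int i = 0; i < n; ++i) {
    int nl = les_count[i];
    pe.psi = 0.0;
    pe.other_death = other_death[i];
    pe.init.assign(l_init.begin() + off, l_init.begin() + off + nl);
    pe.lam.assign(l_lam.begin() + off, l_lam.begin() + off + nl);
    pe.trans.assign(l_trans.begin() + off, l_trans.begin() + off + nl);
    pe.soj.assign(l_soj.begin() + off, l_soj.begin() + off + nl);
    pe.cstage.assign(l_cs.begin() + off, l_cs.begin() + off + nl);
    pe.sstage.assign(l_ss.begin() + off, l_ss.begin() + off + nl);
    off += nl;
    ReplayOut r = replay_one(P, CC, CF, pol, (uint64_t)master_seed,
                             (uint64_t)(i + 1), (uint64_t)attempt[i], pe,
                             sa.data(), sm.data(), ns, ref_age, onset_age,
                             surv_delay, allow_post_surv, min_post_exam);
    ly[i] = r.ly;
    death[i] = r.death;
    dx_age[i] = r.dx_age;
    dx_mode[i] = r.dx_mode;
    dx_stage[i] = r.dx_mode ? r.dx_stage + 1 : NA_INTEGER;
    if ((i & 0x3FFF) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["ly"] = ly, _["death_age"] = death,
                      _["dx_age"] = dx_age, _["dx_mode"] = dx_mode,
                      _["dx_stage"] = dx_stage);
}
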