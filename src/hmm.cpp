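#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Variable-order signal HMM over a sequence of kmer "slots", each carrying a
// set of variant kmers (canonical plus modification-branch alternatives).
// States: Match(slot, variant) emits one event from the variant's Gaussian;
// Insert(slot, variant) emits from a broad background Gaussian. Skips are
// handled as direct slot j -> j+2 transitions (silent). Variant consistency
// across overlapping slots is enforced by the edge lists supplied from R:
// an edge (u -> v') exists only when the two variants agree on the shared
// reference positions, so per-site character choices follow a single path.
//
// All recursions run in log space. A diagonal band (band_margin slots around
// the linear event->slot interpolation) bounds the DP; band_margin <= 0
// disables banding. The caller retries unbanded if a banded alignment fails.

static const double NEG_INF = -std::numeric_limits<double>::infinity();
static const double LOG_2PI_HALF = 0.9189385332046727; // log(2*pi)/2

static inline double logadd(double a, double b) {
  if (a == NEG_INF) return b;
  if (b == NEG_INF) return a;
  if (a < b) std::swap(a, b);
  return a + std::log1p(std::exp(b - a));
}

static inline double ldnorm(double x, double mu, double sd) {
  double z = (x - mu) / sd;
  return -0.5 * z * z - std::log(sd) - LOG_2PI_HALF;
}

// [[Rcpp::export]]
List hmm_align_cpp(NumericVector events,
                   IntegerVector v_off,   // length S+1, variant offsets per slot
                   NumericVector v_mu, NumericVector v_sd,
                   IntegerVector st_off,  // length S+1, step-edge offsets (slot j -> j+1)
                   IntegerVector st_from, IntegerVector st_to, NumericVector st_lw,
                   IntegerVector sk_off,  // length S+1, skip-edge offsets (slot j -> j+2)
                   IntegerVector sk_from, IntegerVector sk_to, NumericVector sk_lw,
                   NumericVector trans,   // stay, step, skip, insert_open, insert_extend
                   NumericVector bg,      // background mu, sd
                   int band_margin,
                   double gamma_min,
                   bool want_gamma,
                   bool want_mea) {
  const int E = events.size();
  const int S = v_off.size() - 1;
  const int V = v_off[S];
  if (E < 1 || S < 1) stop("empty read or model");

  const double l_stay = std::log(trans[0]);
  const double l_step = std::log(trans[1]);
  const double l_skip = std::log(trans[2]);
  const double l_io   = std::log(trans[3]);
  const double l_ie   = std::log(trans[4]);
  const double l_ic   = std::log1p(-trans[4]); // insert close -> step
  const double bg_mu = bg[0], bg_sd = bg[1];

  // diagonal band over slots per event
  std::vector<int> jlo(E), jhi(E);
  for (int e = 0; e < E; ++e) {
    if (band_margin <= 0) { jlo[e] = 0; jhi[e] = S - 1; continue; }
    double center = (E > 1) ? (double)e * (S - 1) / (E - 1) : 0.0;
    int lo = (int)std::floor(center) - band_margin;
    int hi = (int)std::ceil(center) + band_margin;
    jlo[e] = lo < 0 ? 0 : lo;
    jhi[e] = hi > S - 1 ? S - 1 : hi;
  }

  // emission cache, filled inside the band only
  std::vector<double> em((size_t)E * V, 0.0);
  std::vector<double> em_bg(E);
  for (int e = 0; e < E; ++e) {
    em_bg[e] = ldnorm(events[e], bg_mu, bg_sd);
    for (int f = v_off[jlo[e]]; f < v_off[jhi[e] + 1]; ++f)
      em[(size_t)e * V + f] = ldnorm(events[e], v_mu[f], v_sd[f]);
  }

  auto slot_of = [&](int f) {
    int lo = 0, hi = S - 1;
    while (lo < hi) { int mid = (lo + hi + 1) / 2; if (v_off[mid] <= f) lo = mid; else hi = mid - 1; }
    return lo;
  };

  std::vector<double> aM((size_t)E * V, NEG_INF), aI((size_t)E * V, NEG_INF);
  std::vector<double> bM((size_t)E * V, NEG_INF), bI((size_t)E * V, NEG_INF);

  // --- forward ---
  // start: first event at slot 0 (uniform over variants), or slot 1 with a
  // skip penalty (the first slot silently skipped)
  {
    int nv0 = v_off[1] - v_off[0];
    for (int f = v_off[0]; f < v_off[1]; ++f)
      aM[f] = -std::log((double)nv0) + em[f];
    if (S >= 2 && jhi[0] >= 1) {
      int nv1 = v_off[2] - v_off[1];
      for (int f = v_off[1]; f < v_off[2]; ++f)
        aM[f] = l_skip - std::log((double)nv1) + em[f];
    }
  }
  for (int e = 1; e < E; ++e) {
    double *prevM = &aM[(size_t)(e - 1) * V], *prevI = &aI[(size_t)(e - 1) * V];
    double *curM = &aM[(size_t)e * V], *curI = &aI[(size_t)e * V];
    const int flo = v_off[jlo[e]], fhi = v_off[jhi[e] + 1];
    for (int f = flo; f < fhi; ++f) {
      if (prevM[f] != NEG_INF) curM[f] = prevM[f] + l_stay;
      double ii = logadd(prevM[f] == NEG_INF ? NEG_INF : prevM[f] + l_io,
                         prevI[f] == NEG_INF ? NEG_INF : prevI[f] + l_ie);
      if (ii != NEG_INF) curI[f] = ii + em_bg[e];
    }
    int j0 = jlo[e] > 1 ? jlo[e] - 1 : 0;
    int j1 = jhi[e] - 1; if (j1 > S - 2) j1 = S - 2;
    for (int j = j0; j <= j1; ++j) {
      for (int t = st_off[j]; t < st_off[j + 1]; ++t) {
        int fu = v_off[j] + st_from[t];
        int fv = v_off[j + 1] + st_to[t];
        if (prevM[fu] != NEG_INF)
          curM[fv] = logadd(curM[fv], prevM[fu] + l_step + st_lw[t]);
        if (prevI[fu] != NEG_INF)
          curM[fv] = logadd(curM[fv], prevI[fu] + l_ic + st_lw[t]);
      }
    }
    j0 = jlo[e] > 2 ? jlo[e] - 2 : 0;
    j1 = jhi[e] - 2; if (j1 > S - 3) j1 = S - 3;
    for (int j = j0; j <= j1; ++j) {
      for (int t = sk_off[j]; t < sk_off[j + 1]; ++t) {
        int fu = v_off[j] + sk_from[t];
        int fv = v_off[j + 2] + sk_to[t];
        if (prevM[fu] != NEG_INF)
          curM[fv] = logadd(curM[fv], prevM[fu] + l_skip + sk_lw[t]);
      }
    }
    for (int f = flo; f < fhi; ++f)
      if (curM[f] != NEG_INF) curM[f] += em[(size_t)e * V + f];
  }

  // termination: last event matched at the final slot, or at slot S-2 with
  // the final slot silently skipped
  double ll = NEG_INF;
  {
    double *lastM = &aM[(size_t)(E - 1) * V];
    for (int f = v_off[S - 1]; f < v_off[S]; ++f) ll = logadd(ll, lastM[f]);
    if (S >= 2)
      for (int f = v_off[S - 2]; f < v_off[S - 1]; ++f)
        if (lastM[f] != NEG_INF) ll = logadd(ll, lastM[f] + l_skip);
  }
  if (!R_FINITE(ll)) {
    return List::create(_["loglik"] = ll, _["failed"] = true);
  }

  // --- backward ---
  {
    double *lastB = &bM[(size_t)(E - 1) * V];
    for (int f = v_off[S - 1]; f < v_off[S]; ++f) lastB[f] = 0.0;
    if (S >= 2)
      for (int f = v_off[S - 2]; f < v_off[S - 1]; ++f) lastB[f] = l_skip;
  }
  for (int e = E - 2; e >= 0; --e) {
    double *nextM = &bM[(size_t)(e + 1) * V], *nextI = &bI[(size_t)(e + 1) * V];
    double *curM = &bM[(size_t)e * V], *curI = &bI[(size_t)e * V];
    const double *emn = &em[(size_t)(e + 1) * V];
    const int flo = v_off[jlo[e]], fhi = v_off[jhi[e] + 1];
    for (int f = flo; f < fhi; ++f) {
      double accM = NEG_INF, accI = NEG_INF;
      if (nextM[f] != NEG_INF) accM = l_stay + emn[f] + nextM[f];
      if (nextI[f] != NEG_INF) {
        accM = logadd(accM, l_io + em_bg[e + 1] + nextI[f]);
        accI = l_ie + em_bg[e + 1] + nextI[f];
      }
      curM[f] = accM;
      curI[f] = accI;
    }
    int j0 = jlo[e], j1 = jhi[e]; if (j1 > S - 2) j1 = S - 2;
    for (int j = j0; j <= j1; ++j) {
      for (int t = st_off[j]; t < st_off[j + 1]; ++t) {
        int fu = v_off[j] + st_from[t];
        int fv = v_off[j + 1] + st_to[t];
        if (nextM[fv] == NEG_INF) continue;
        double core = st_lw[t] + emn[fv] + nextM[fv];
        curM[fu] = logadd(curM[fu], l_step + core);
        curI[fu] = logadd(curI[fu], l_ic + core);
      }
    }
    j1 = jhi[e]; if (j1 > S - 3) j1 = S - 3;
    for (int j = j0; j <= j1; ++j) {
      for (int t = sk_off[j]; t < sk_off[j + 1]; ++t) {
        int fu = v_off[j] + sk_from[t];
        int fv = v_off[j + 2] + sk_to[t];
        if (nextM[fv] == NEG_INF) continue;
        curM[fu] = logadd(curM[fu], l_skip + sk_lw[t] + emn[fv] + nextM[fv]);
      }
    }
  }

  // --- posteriors (Match states only) ---
  std::vector<double> gM;
  if (want_gamma || want_mea) gM.assign((size_t)E * V, 0.0);
  std::vector<int> sp_e, sp_f;
  std::vector<double> sp_g;
  for (int e = 0; e < E; ++e) {
    for (int f = v_off[jlo[e]]; f < v_off[jhi[e] + 1]; ++f) {
      double la = aM[(size_t)e * V + f], lb = bM[(size_t)e * V + f];
      if (la == NEG_INF || lb == NEG_INF) continue;
      double g = std::exp(la + lb - ll);
      if (g > 1.0) g = 1.0;
      if (!gM.empty()) gM[(size_t)e * V + f] = g;
      if (want_gamma && g >= gamma_min) {
        sp_e.push_back(e + 1); sp_f.push_back(f); sp_g.push_back(g);
      }
    }
  }
  List out = List::create(_["loglik"] = ll, _["failed"] = false);
  if (want_gamma) {
    int nsp = sp_e.size();
    IntegerVector g_event(nsp), g_slot(nsp), g_variant(nsp);
    NumericVector g_val(nsp);
    for (int i = 0; i < nsp; ++i) {
      int f = sp_f[i];
      int j = slot_of(f);
      g_event[i] = sp_e[i];
      g_slot[i] = j + 1;
      g_variant[i] = f - v_off[j] + 1;
      g_val[i] = sp_g[i];
    }
    out["gamma"] = DataFrame::create(_["event"] = g_event, _["slot"] = g_slot,
                                     _["variant"] = g_variant, _["prob"] = g_val);
  }
  if (!want_mea) return out;

  // --- MEA: monotone admissible path maximizing summed Match posterior ---
  // ptr codes: state*V + flatv, state 0 = Match, 1 = Insert; -1 = start
  std::vector<double> GM((size_t)E * V, NEG_INF), GI((size_t)E * V, NEG_INF);
  std::vector<int> PM((size_t)E * V, -1), PI((size_t)E * V, -1);
  for (int f = v_off[0]; f < v_off[1]; ++f) GM[f] = gM[f];
  if (S >= 2 && jhi[0] >= 1)
    for (int f = v_off[1]; f < v_off[2]; ++f) GM[f] = gM[f];
  for (int e = 1; e < E; ++e) {
    double *prevM = &GM[(size_t)(e - 1) * V], *prevI = &GI[(size_t)(e - 1) * V];
    double *curM = &GM[(size_t)e * V], *curI = &GI[(size_t)e * V];
    int *pm = &PM[(size_t)e * V], *pi = &PI[(size_t)e * V];
    const int flo = v_off[jlo[e]], fhi = v_off[jhi[e] + 1];
    // skip-in predecessors first (smallest predecessor slot), then step-in
    // (Match before Insert), then stay; strict > keeps the first maximum.
    int j0 = jlo[e] > 2 ? jlo[e] - 2 : 0;
    int j1 = jhi[e] - 2; if (j1 > S - 3) j1 = S - 3;
    for (int j = j0; j <= j1; ++j) {
      for (int t = sk_off[j]; t < sk_off[j + 1]; ++t) {
        int fu = v_off[j] + sk_from[t];
        int fv = v_off[j + 2] + sk_to[t];
        if (prevM[fu] > curM[fv]) { curM[fv] = prevM[fu]; pm[fv] = 0 * V + fu; }
      }
    }
    j0 = jlo[e] > 1 ? jlo[e] - 1 : 0;
    j1 = jhi[e] - 1; if (j1 > S - 2) j1 = S - 2;
    for (int j = j0; j <= j1; ++j) {
      for (int t = st_off[j]; t < st_off[j + 1]; ++t) {
        int fu = v_off[j] + st_from[t];
        int fv = v_off[j + 1] + st_to[t];
        if (prevM[fu] > curM[fv]) { curM[fv] = prevM[fu]; pm[fv] = 0 * V + fu; }
        if (prevI[fu] > curM[fv]) { curM[fv] = prevI[fu]; pm[fv] = 1 * V + fu; }
      }
    }
    for (int f = flo; f < fhi; ++f) {
      if (prevM[f] > curM[f]) { curM[f] = prevM[f]; pm[f] = 0 * V + f; }
      if (curM[f] != NEG_INF) curM[f] += gM[(size_t)e * V + f];
      if (prevM[f] > curI[f]) { curI[f] = prevM[f]; pi[f] = 0 * V + f; }
      if (prevI[f] > curI[f]) { curI[f] = prevI[f]; pi[f] = 1 * V + f; }
    }
  }
  double best = NEG_INF; int best_f = -1;
  {
    double *lastM = &GM[(size_t)(E - 1) * V];
    if (S >= 2)
      for (int f = v_off[S - 2]; f < v_off[S - 1]; ++f)
        if (lastM[f] > best) { best = lastM[f]; best_f = f; }
    for (int f = v_off[S - 1]; f < v_off[S]; ++f)
      if (lastM[f] > best) { best = lastM[f]; best_f = f; }
  }
  if (best_f < 0) { out["mea_score"] = NEG_INF; return out; }
  IntegerVector p_event(E), p_slot(E), p_variant(E);
  CharacterVector p_kind(E);
  NumericVector p_prob(E);
  {
    int state = 0, f = best_f;
    for (int e = E - 1; e >= 0; --e) {
      int j = slot_of(f);
      p_event[e] = e + 1;
      p_slot[e] = j + 1;
      p_variant[e] = f - v_off[j] + 1;
      p_kind[e] = (state == 0) ? "match" : "insert";
      p_prob[e] = (state == 0) ? gM[(size_t)e * V + f] : NA_REAL;
      int ptr = (state == 0) ? PM[(size_t)e * V + f] : PI[(size_t)e * V + f];
      if (e > 0) { state = ptr / V; f = ptr % V; }
    }
  }
  out["mea_score"] = best;
  out["mea_path"] = DataFrame::create(_["event"] = p_event, _["slot"] = p_slot,
                                      _["variant"] = p_variant, _["kind"] = p_kind,
                                      _["prob"] = p_prob,
                                      _["stringsAsFactors"] = false);
  return out;
}
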