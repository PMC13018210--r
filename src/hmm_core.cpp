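// Local profile-HMM dynamic programming in bit (log2) space.
//
// State model (see R/hmm.R): match states 1..M, insert states emitting the
// background (log-odds 0), delete states. Local semantics: entry into any
// match state with weight 1/M, free exit from any match state, flanks
// emitted by the background null (cancel in the odds ratio).
//
// Emission log-odds are passed as an M x 21 matrix `lo` whose column j holds
// residue code j-1 (code 0 = unknown residue, log-odds 0); columns are
// contiguous in memory, so scanning a fixed residue code walks a contiguous
// stretch -- this matters for the ungapped prefilter over megabases of
// translated peptide.

#include <Rcpp.h>
#include <cmath>
#include <cstring>
#include <vector>
#include <limits>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline int aa_code_c(char c) {
  switch (c) {
    case 'A': return 1;  case 'C': return 2;  case 'D': return 3;
    case 'E': return 4;  case 'F': return 5;  case 'G': return 6;
    case 'H': return 7;  case 'I': return 8;  case 'K': return 9;
    case 'L': return 10; case 'M': return 11; case 'N': return 12;
    case 'P': return 13; case 'Q': return 14; case 'R': return 15;
    case 'S': return 16; case 'T': return 17; case 'V': return 18;
    case 'W': return 19; case 'Y': return 20;
    default: return 0;
  }
}

static inline double log2addexp(double a, double b) {
  if (a == NEG_INF) return b;
  if (b == NEG_INF) return a;
  if (a < b) std::swap(a, b);
  return a + std::log2(1.0 + std::exp2(b - a));
}

struct Model {
  int M;
  const double *lo;   // M x 21, column-major
  const double *ltr;  // M x 7, column-major: mm mi md im ii dm dd
  double log2_entry;
  inline double e(int k, int code) const { return lo[(size_t)code * M + (k - 1)]; }
  inline double t(int k, int which) const { return ltr[(size_t)which * M + (k - 1)]; }
};

static Model as_model(int M, const NumericMatrix &lo, const NumericMatrix &ltr,
                      double log2_entry) {
  Model m;
  m.M = M;
  m.lo = REAL(lo);
  m.ltr = REAL(ltr);
  m.log2_entry = log2_entry;
  return m;
}

enum { TMM = 0, TMI = 1, TMD = 2, TIM = 3, TII = 4, TDM = 5, TDD = 6 };

// ---------------------------------------------------------------------------
// Ungapped diagonal prefilter: best local run of consecutive match states
// (entry weight + M->M transitions + emission log-odds), a strict lower bound
// on the Viterbi score. One max + two adds per cell.
static double filter_score(const int *seq, int L, const Model &m) {
  const int M = m.M;
  std::vector<double> b1((size_t)M + 1, NEG_INF), b2((size_t)M + 1, NEG_INF);
  double *prev = b1.data(), *cur = b2.data();
  const double *tmm = m.ltr;  // TMM column; transition out of state k at [k-1]
  const double entry = m.log2_entry;
  double best = NEG_INF;
  for (int i = 0; i < L; ++i) {
    const double *ecol = m.lo + (size_t)seq[i] * M;
    cur[1] = entry + ecol[0];
    for (int k = 2; k <= M; ++k)
      cur[k] = std::max(entry, prev[k - 1] + tmm[k - 2]) + ecol[k - 1];
    for (int k = 1; k <= M; ++k) best = std::max(best, cur[k]);
    std::swap(prev, cur);
  }
  return best;
}

struct ViterbiResult {
  double score;
  int env_start, env_end;  // 0-based half-open on the peptide
  int k_start, k_end;      // 1-based inclusive match-state span
};

// Full local Viterbi with envelope/model-span recovery via origin
// propagation (start position and start state carried along the argmax).
static ViterbiResult viterbi_full(const int *seq, int L, const Model &m) {
  const int M = m.M;
  std::vector<double> VM((size_t)M + 1), VI((size_t)M + 1), VD((size_t)M + 1);
  std::vector<int> oMi((size_t)M + 1), oMk((size_t)M + 1),
      oIi((size_t)M + 1), oIk((size_t)M + 1),
      oDi((size_t)M + 1), oDk((size_t)M + 1);
  std::fill(VM.begin(), VM.end(), NEG_INF);
  std::fill(VI.begin(), VI.end(), NEG_INF);
  std::fill(VD.begin(), VD.end(), NEG_INF);
  ViterbiResult best{NEG_INF, 0, 0, 0, 0};

  for (int i = 0; i < L; ++i) {
    const double *ecol = m.lo + (size_t)seq[i] * M;
    double prevM_km1 = NEG_INF, prevI_km1 = NEG_INF;  // row i-1, state k-1
    int prevMo_i = 0, prevMo_k = 0, prevIo_i = 0, prevIo_k = 0;
    // pass 1: M and I states (use previous row for k-1/k dependencies)
    for (int k = 1; k <= M; ++k) {
      double oldM = VM[k]; int oldMi = oMi[k], oldMk = oMk[k];
      double oldI = VI[k]; int oldIi = oIi[k], oldIk = oIk[k];
      // candidates into M_k at position i
      double cand = m.log2_entry; int ci = i, ck = k;
      if (k > 1) {
        if (prevM_km1 != NEG_INF) {
          double v = prevM_km1 + m.t(k - 1, TMM);
          if (v > cand) { cand = v; ci = prevMo_i; ck = prevMo_k; }
        }
        if (prevI_km1 != NEG_INF) {
          double v = prevI_km1 + m.t(k - 1, TIM);
          if (v > cand) { cand = v; ci = prevIo_i; ck = prevIo_k; }
        }
        if (VD[k - 1] != NEG_INF) {
          double v = VD[k - 1] + m.t(k - 1, TDM);
          if (v > cand) { cand = v; ci = oDi[k - 1]; ck = oDk[k - 1]; }
        }
      }
      double vM = cand + ecol[k - 1];
      // I_k at position i: from row i-1's VM[k] or VI[k]
      double vI = NEG_INF; int Ii = 0, Ik = 0;
      if (k < M) {
        if (oldM != NEG_INF) { vI = oldM + m.t(k, TMI); Ii = oldMi; Ik = oldMk; }
        if (oldI != NEG_INF) {
          double v = oldI + m.t(k, TII);
          if (v > vI) { vI = v; Ii = oldIi; Ik = oldIk; }
        }
      }
      prevM_km1 = oldM; prevMo_i = oldMi; prevMo_k = oldMk;
      prevI_km1 = oldI; prevIo_i = oldIi; prevIo_k = oldIk;
      VM[k] = vM; oMi[k] = ci; oMk[k] = ck;
      VI[k] = vI; oIi[k] = Ii; oIk[k] = Ik;
      if (vM > best.score) {
        best.score = vM;
        best.env_start = ci; best.env_end = i + 1;
        best.k_start = ck; best.k_end = k;
      }
    }
    // pass 2: D states (same row, ascending k)
    VD[1] = NEG_INF;
    for (int k = 2; k <= M; ++k) {
      double vD = NEG_INF; int Di = 0, Dk = 0;
      if (VM[k - 1] != NEG_INF) {
        vD = VM[k - 1] + m.t(k - 1, TMD);
        Di = oMi[k - 1]; Dk = oMk[k - 1];
      }
      if (VD[k - 1] != NEG_INF) {
        double v = VD[k - 1] + m.t(k - 1, TDD);
        if (v > vD) { vD = v; Di = oDi[k - 1]; Dk = oDk[k - 1]; }
      }
      VD[k] = vD; oDi[k] = Di; oDk[k] = Dk;
    }
  }
  return best;
}

// Viterbi score only (no origin bookkeeping); used for calibration batches.
static double viterbi_score_only(const int *seq, int L, const Model &m) {
  const int M = m.M;
  std::vector<double> VM((size_t)M + 1, NEG_INF), VI((size_t)M + 1, NEG_INF),
      VD((size_t)M + 1, NEG_INF);
  double best = NEG_INF;
  for (int i = 0; i < L; ++i) {
    const double *ecol = m.lo + (size_t)seq[i] * M;
    double prevM_km1 = NEG_INF, prevI_km1 = NEG_INF;
    for (int k = 1; k <= M; ++k) {
      double oldM = VM[k], oldI = VI[k];
      double cand = m.log2_entry;
      if (k > 1) {
        cand = std::max(cand, prevM_km1 + m.t(k - 1, TMM));
        cand = std::max(cand, prevI_km1 + m.t(k - 1, TIM));
        cand = std::max(cand, VD[k - 1] + m.t(k - 1, TDM));
      }
      double vM = cand + ecol[k - 1];
      double vI = NEG_INF;
      if (k < M)
        vI = std::max(oldM + m.t(k, TMI), oldI + m.t(k, TII));
      prevM_km1 = oldM; prevI_km1 = oldI;
      VM[k] = vM; VI[k] = vI;
      best = std::max(best, vM);
    }
    VD[1] = NEG_INF;
    for (int k = 2; k <= M; ++k)
      VD[k] = std::max(VM[k - 1] + m.t(k - 1, TMD),
                       VD[k - 1] + m.t(k - 1, TDD));
  }
  return best;
}

// Local forward: log2-sum over all local paths of the same path weights.
static double forward_score(const int *seq, int L, const Model &m) {
  const int M = m.M;
  std::vector<double> FM((size_t)M + 1, NEG_INF), FI((size_t)M + 1, NEG_INF),
      FD((size_t)M + 1, NEG_INF);
  double total = NEG_INF;
  for (int i = 0; i < L; ++i) {
    const double *ecol = m.lo + (size_t)seq[i] * M;
    double prevM_km1 = NEG_INF, prevI_km1 = NEG_INF;
    for (int k = 1; k <= M; ++k) {
      double oldM = FM[k], oldI = FI[k];
      double cand = m.log2_entry;
      if (k > 1) {
        if (prevM_km1 != NEG_INF)
          cand = log2addexp(cand, prevM_km1 + m.t(k - 1, TMM));
        if (prevI_km1 != NEG_INF)
          cand = log2addexp(cand, prevI_km1 + m.t(k - 1, TIM));
        if (FD[k - 1] != NEG_INF)
          cand = log2addexp(cand, FD[k - 1] + m.t(k - 1, TDM));
      }
      double vM = cand + ecol[k - 1];
      double vI = NEG_INF;
      if (k < M) {
        if (oldM != NEG_INF) vI = oldM + m.t(k, TMI);
        if (oldI != NEG_INF) vI = log2addexp(vI, oldI + m.t(k, TII));
      }
      prevM_km1 = oldM; prevI_km1 = oldI;
      FM[k] = vM; FI[k] = vI;
      total = log2addexp(total, vM);  // free exit from any match state
    }
    FD[1] = NEG_INF;
    for (int k = 2; k <= M; ++k) {
      double vD = NEG_INF;
      if (FM[k - 1] != NEG_INF) vD = FM[k - 1] + m.t(k - 1, TMD);
      if (FD[k - 1] != NEG_INF)
        vD = log2addexp(vD, FD[k - 1] + m.t(k - 1, TDD));
      FD[k] = vD;
    }
  }
  return total;
}

static std::vector<int> encode(const std::string &pep) {
  std::vector<int> out(pep.size());
  for (size_t i = 0; i < pep.size(); ++i) out[i] = aa_code_c(pep[i]);
  return out;
}

// [[Rcpp::export]]
double cpp_forward_one(std::string peptide, int M, NumericMatrix lo,
                       NumericMatrix ltr, double log2_entry) {
  std::vector<int> seq = encode(peptide);
  return forward_score(seq.data(), (int)seq.size(),
                       as_model(M, lo, ltr, log2_entry));
}

// [[Rcpp::export]]
List cpp_viterbi_one(std::string peptide, int M, NumericMatrix lo,
                     NumericMatrix ltr, double log2_entry) {
  std::vector<int> seq = encode(peptide);
  ViterbiResult r = viterbi_full(seq.data(), (int)seq.size(),
                                 as_model(M, lo, ltr, log2_entry));
  return List::create(_["score"] = r.score, _["env_start"] = r.env_start,
                      _["env_end"] = r.env_end, _["k_start"] = r.k_start,
                      _["k_end"] = r.k_end);
}

// [[Rcpp::export]]
NumericVector cpp_viterbi_batch(CharacterVector peptides, int M,
                                NumericMatrix lo, NumericMatrix ltr,
                                double log2_entry) {
  Model m = as_model(M, lo, ltr, log2_entry);
  NumericVector out(peptides.size());
  for (R_xlen_t i = 0; i < peptides.size(); ++i) {
    std::vector<int> seq = encode(as<std::string>(peptides[i]));
    out[i] = viterbi_score_only(seq.data(), (int)seq.size(), m);
  }
  return out;
}

// [[Rcpp::export]]
double cpp_filter_one(std::string peptide, int M, NumericMatrix lo,
                      NumericMatrix ltr, double log2_entry) {
  std::vector<int> seq = encode(peptide);
  return filter_score(seq.data(), (int)seq.size(),
                      as_model(M, lo, ltr, log2_entry));
}

// Scan every peptide segment against every model. Segments whose ungapped
// prefilter score is below `filter_bits` are skipped (their Viterbi score is
// reported only if computed). Returns one row per (segment, model) pair that
// underwent full Viterbi.
// [[Rcpp::export]]
DataFrame cpp_scan(CharacterVector peptides, List models, double filter_bits) {
  const int n_mod = models.size();
  std::vector<Model> ms;
  std::vector<NumericMatrix> keep_lo, keep_ltr;  // keep SEXPs alive
  ms.reserve(n_mod);
  for (int j = 0; j < n_mod; ++j) {
    List mj = models[j];
    keep_lo.push_back(as<NumericMatrix>(mj["lo"]));
    keep_ltr.push_back(as<NumericMatrix>(mj["ltr"]));
    ms.push_back(as_model(as<int>(mj["M"]), keep_lo.back(), keep_ltr.back(),
                          as<double>(mj["log2_entry"])));
  }
  std::vector<int> r_seg, r_mod, r_es, r_ee, r_ks, r_ke;
  std::vector<double> r_score, r_filter;
  for (R_xlen_t i = 0; i < peptides.size(); ++i) {
    std::vector<int> seq = encode(as<std::string>(peptides[i]));
    const int L = (int)seq.size();
    for (int j = 0; j < n_mod; ++j) {
      double fs = filter_score(seq.data(), L, ms[j]);
      if (fs < filter_bits) continue;
      ViterbiResult r = viterbi_full(seq.data(), L, ms[j]);
      r_seg.push_back((int)i + 1);
      r_mod.push_back(j + 1);
      r_score.push_back(r.score);
      r_filter.push_back(fs);
      r_es.push_back(r.env_start);
      r_ee.push_back(r.env_end);
      r_ks.push_back(r.k_start);
      r_ke.push_back(r.k_end);
    }
  }
  return DataFrame::create(_["seg"] = r_seg, _["model"] = r_mod,
                           _["score"] = r_score, _["filter"] = r_filter,
                           _["env_start"] = r_es, _["env_end"] = r_ee,
                           _["k_start"] = r_ks, _["k_end"] = r_ke);
}
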