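#include <Rcpp.h>
using namespace Rcpp;

// Profile-HMM dynamic programming in bit (log2) space.
//
// Model: single-domain local alignment. A path enters at any match state
// (uniform entry probability 1/K, i.e. a score of -log2(K) bits), moves
// through match/insert/delete states with position-specific transition
// probabilities, and exits for free after any match state. Residues outside
// the aligned span and insert-state residues are emitted at background and
// contribute 0 bits. Delete states cannot start or end a path.
//
// obs: 1-based residue codes 1..21 (21 = X, scored 0 everywhere).
// lod: K x 21 match-emission log-odds. trans vectors have length K-1,
// entry = -log2(K). All scores in bits.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline double lse2(double a, double b) {
  if (a == NEG_INF) return b;
  if (b == NEG_INF) return a;
  double hi = a > b ? a : b, lo = a > b ? b : a;
  return hi + std::log1p(std::exp((lo - hi) * M_LN2)) / M_LN2;
}

struct Tr {
  const double *MM, *MI, *MD, *IM, *II, *DM, *DD;
};

static Tr unpack(const List& trans) {
  Tr t;
  t.MM = REAL(((SEXP)trans["MM"])); t.MI = REAL(((SEXP)trans["MI"]));
  t.MD = REAL(((SEXP)trans["MD"])); t.IM = REAL(((SEXP)trans["IM"]));
  t.II = REAL(((SEXP)trans["II"])); t.DM = REAL(((SEXP)trans["DM"]));
  t.DD = REAL(((SEXP)trans["DD"]));
  return t;
}

// Viterbi fill over one sequence; optionally keep traceback pointers.
// ptr codes: 0 = entry(B), 1 = from M, 2 = from D, 3 = from I.
static double viterbi_fill(const int* obs, int L, const NumericMatrix& lod,
                           const Tr& t, double entry, int K,
                           std::vector<signed char>* pM,
                           std::vector<signed char>* pD,
                           std::vector<signed char>* pI,
                           int* bestI, int* bestK) {
  std::vector<double> VM((L + 1) * (K + 1), NEG_INF);
  std::vector<double> VD((L + 1) * (K + 1), NEG_INF);
  std::vector<double> VI((L + 1) * (K + 1), NEG_INF);
  auto at = [K](int i, int k) { return i * (K + 1) + k; };
  double best = NEG_INF; int bi = -1, bk = -1;
  for (int i = 1; i <= L; ++i) {
    for (int k = 1; k <= K; ++k) {
      // match state: candidates in tie-break order M, D, I, B
      double v = NEG_INF; signed char from = 0;
      if (k > 1 && i > 1) {
        double c = VM[at(i - 1, k - 1)] + t.MM[k - 2];
        if (c > v) { v = c; from = 1; }
        c = VD[at(i - 1, k - 1)] + t.DM[k - 2];
        if (c > v) { v = c; from = 2; }
        c = VI[at(i - 1, k - 1)] + t.IM[k - 2];
        if (c > v) { v = c; from = 3; }
      }
      if (entry > v) { v = entry; from = 0; }
      double e = lod(k - 1, obs[i - 1] - 1);
      VM[at(i, k)] = v + e;
      if (pM) (*pM)[at(i, k)] = from;
      if (VM[at(i, k)] > best) { best = VM[at(i, k)]; bi = i; bk = k; }
      // delete state (internal only, no emission)
      if (k > 1) {
        double dv = VM[at(i, k - 1)] + t.MD[k - 2]; signed char df = 1;
        double c = VD[at(i, k - 1)] + t.DD[k - 2];
        if (c > dv) { dv = c; df = 2; }
        VD[at(i, k)] = dv;
        if (pD) (*pD)[at(i, k)] = df;
      }
      // insert state k (between match k and k+1)
      if (k < K && i > 1) {
        double iv = VM[at(i - 1, k)] + t.MI[k - 1]; signed char inf_ = 1;
        double c = VI[at(i - 1, k)] + t.II[k - 1];
        if (c > iv) { iv = c; inf_ = 3; }
        VI[at(i, k)] = iv;
        if (pI) (*pI)[at(i, k)] = inf_;
      }
    }
  }
  if (bestI) *bestI = bi;
  if (bestK) *bestK = bk;
  return best;
}

// [[Rcpp::export]]
List phmm_viterbi_cpp(IntegerVector obs, NumericMatrix lod, List trans,
                      double entry) {
  int L = obs.size(), K = lod.nrow();
  Tr t = unpack(trans);
  std::vector<signed char> pM((L + 1) * (K + 1), 0),
      pD((L + 1) * (K + 1), 0), pI((L + 1) * (K + 1), 0);
  int bi, bk;
  double score = viterbi_fill(obs.begin(), L, lod, t, entry, K,
                              &pM, &pD, &pI, &bi, &bk);
  auto at = [K](int i, int k) { return i * (K + 1) + k; };
  // traceback from (bi, bk) in state M
  std::string ops; std::vector<int> ks, is;
  int i = bi, k = bk; char st = 'M';
  while (true) {
    ops.push_back(st); ks.push_back(k); is.push_back(st == 'D' ? NA_INTEGER : i);
    signed char from;
    if (st == 'M') { from = pM[at(i, k)]; --i; --k; }
    else if (st == 'D') { from = pD[at(i, k)]; --k; }
    else { from = pI[at(i, k)]; --i; }
    if (st == 'M' && from == 0) break;
    st = from == 1 ? 'M' : (from == 2 ? 'D' : 'I');
  }
  std::reverse(ops.begin(), ops.end());
  std::reverse(ks.begin(), ks.end());
  std::reverse(is.begin(), is.end());
  return List::create(
      _["score"] = score, _["ops"] = ops,
      _["k"] = IntegerVector(ks.begin(), ks.end()),
      _["i"] = IntegerVector(is.begin(), is.end()));
}

// [[Rcpp::export]]
NumericVector phmm_score_many_cpp(IntegerVector obs, IntegerVector starts,
                                  IntegerVector lens, NumericMatrix lod,
                                  List trans, double entry) {
  int n = starts.size(), K = lod.nrow();
  Tr t = unpack(trans);
  NumericVector out(n);
  for (int s = 0; s < n; ++s) {
    out[s] = viterbi_fill(obs.begin() + (starts[s] - 1), lens[s], lod, t,
                          entry, K, nullptr, nullptr, nullptr, nullptr,
                          nullptr);
  }
  return out;
}

// [[Rcpp::export]]
double phmm_forward_cpp(IntegerVector obs, NumericMatrix lod, List trans,
                        double entry) {
  int L = obs.size(), K = lod.nrow();
  Tr t = unpack(trans);
  std::vector<double> FM((L + 1) * (K + 1), NEG_INF);
  std::vector<double> FD((L + 1) * (K + 1), NEG_INF);
  std::vector<double> FI((L + 1) * (K + 1), NEG_INF);
  auto at = [K](int i, int k) { return i * (K + 1) + k; };
  double total = NEG_INF;
  for (int i = 1; i <= L; ++i) {
    for (int k = 1; k <= K; ++k) {
      double v = entry;
      if (k > 1 && i > 1) {
        v = lse2(v, FM[at(i - 1, k - 1)] + t.MM[k - 2]);
        v = lse2(v, FD[at(i - 1, k - 1)] + t.DM[k - 2]);
        v = lse2(v, FI[at(i - 1, k - 1)] + t.IM[k - 2]);
      }
      FM[at(i, k)] = v + lod(k - 1, obs[i - 1] - 1);
      total = lse2(total, FM[at(i, k)]);  // free exit after any match
      if (k > 1) {
        FD[at(i, k)] = lse2(FM[at(i, k - 1)] + t.MD[k - 2],
                            FD[at(i, k - 1)] + t.DD[k - 2]);
      }
      if (k < K && i > 1) {
        FI[at(i, k)] = lse2(FM[at(i - 1, k)] + t.MI[k - 1],
                            FI[at(i - 1, k)] + t.II[k - 1]);
      }
    }
  }
  return total;
}
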