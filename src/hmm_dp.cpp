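// Dynamic-programming kernels for the profile HMM search.
//
// Architecture (Plan-7-like local mode): self-looping flank states N and C
// emit background residues (log-odds 0 per residue) with loop probability
// eta = n/(n+2) for a target of length n; entry N->B->M_k is uniform over
// match columns (1/L); exit M_k->E->C is uniform (1/L). The profile core has
// match, insert and delete states with per-column transition triples. All
// computation is in natural log; scores are returned in bits.
//
// seq: 1-based residue indices into the 20-letter alphabet, 0 = ambiguity
// (scored as background, log-odds 0). mask: positions where match/insert
// emission is forbidden (-Inf), used to find secondary domains.

#include <Rcpp.h>
#include <cfloat>
#include <cmath>
using namespace Rcpp;

static inline double logsumexp2(double a, double b) {
  if (a == R_NegInf) return b;
  if (b == R_NegInf) return a;
  double m = a > b ? a : b;
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}

// core recurrences shared by forward and viterbi; when viterbi is true we
// take maxima and keep traceback pointers.
// [[Rcpp::export]]
List hmm_engine(IntegerVector seq, NumericMatrix match_lodds,
                NumericMatrix ins_lodds, NumericMatrix lt,
                LogicalVector mask, bool viterbi) {
  const int n = seq.size();
  const int L = match_lodds.nrow();
  const double eta = std::log((double)n / (n + 2.0));
  const double leave = std::log(2.0 / (n + 2.0));
  const double entry = -std::log((double)L);
  const double exitp = -std::log((double)L);
  const double NEG = R_NegInf;
  // transition columns: 0 MM, 1 MI, 2 MD, 3 IM, 4 II, 5 DM, 6 DD; row k =
  // transitions out of column k (k = 0..L), natural log.
  NumericMatrix M(L + 1, n + 1), I(L + 1, n + 1), D(L + 1, n + 1);
  NumericVector Nst(n + 1), Cst(n + 1);
  IntegerMatrix pM, pI, pD;
  IntegerVector pC;
  if (viterbi) {
    pM = IntegerMatrix(L + 1, n + 1);
    pI = IntegerMatrix(L + 1, n + 1);
    pD = IntegerMatrix(L + 1, n + 1);
    pC = IntegerVector(n + 1);
  }
  std::fill(M.begin(), M.end(), NEG);
  std::fill(I.begin(), I.end(), NEG);
  std::fill(D.begin(), D.end(), NEG);
  std::fill(Cst.begin(), Cst.end(), NEG);
  Nst[0] = 0.0;
  for (int i = 1; i <= n; ++i) Nst[i] = Nst[i - 1] + eta;

  for (int i = 1; i <= n; ++i) {
    const int x = seq[i - 1];            // 1..20 or 0
    const bool masked = mask[i - 1];
    double best_exit = NEG;
    int best_exit_k = 0;
    for (int k = 1; k <= L; ++k) {
      // match
      double em = masked ? NEG : (x > 0 ? match_lodds(k - 1, x - 1) : 0.0);
      double from_entry = Nst[i - 1] + leave + entry;
      double v, d1 = NEG, d2 = NEG, d3 = NEG;
      if (k > 1) {
        d1 = M(k - 1, i - 1) + lt(k - 1, 0);
        d2 = I(k - 1, i - 1) + lt(k - 1, 3);
        d3 = D(k - 1, i - 1) + lt(k - 1, 5);
      }
      if (viterbi) {
        v = from_entry; int p = 0;
        if (d1 > v) { v = d1; p = 1; }
        if (d2 > v) { v = d2; p = 2; }
        if (d3 > v) { v = d3; p = 3; }
        M(k, i) = em + v;
        pM(k, i) = p;
      } else {
        v = logsumexp2(logsumexp2(from_entry, d1), logsumexp2(d2, d3));
        M(k, i) = em + v;
      }
      // insert after column k (core inserts k = 1..L-1)
      if (k < L) {
        double ei = masked ? NEG : (x > 0 ? ins_lodds(k - 1, x - 1) : 0.0);
        double a = M(k, i - 1) + lt(k, 1);
        double b = I(k, i - 1) + lt(k, 4);
        if (viterbi) {
          if (a >= b) { I(k, i) = ei + a; pI(k, i) = 0; }
          else        { I(k, i) = ei + b; pI(k, i) = 1; }
        } else {
          I(k, i) = ei + logsumexp2(a, b);
        }
      }
      // delete (no emission), uses current i
      if (k > 1) {
        double a = M(k - 1, i) + lt(k - 1, 2);
        double b = D(k - 1, i) + lt(k - 1, 6);
        if (viterbi) {
          if (a >= b) { D(k, i) = a; pD(k, i) = 0; }
          else        { D(k, i) = b; pD(k, i) = 1; }
        } else {
          D(k, i) = logsumexp2(a, b);
        }
      }
      double ex = M(k, i) + exitp;
      if (viterbi) {
        if (ex > best_exit) { best_exit = ex; best_exit_k = k; }
      } else {
        best_exit = logsumexp2(best_exit, ex);
      }
    }
    // C state: loop or accept an exit at position i
    double stay = Cst[i - 1] + eta;
    if (viterbi) {
      if (stay >= best_exit) { Cst[i] = stay; pC[i] = 0; }
      else { Cst[i] = best_exit; pC[i] = best_exit_k; }
    } else {
      Cst[i] = logsumexp2(stay, best_exit);
    }
  }
  double total = Cst[n] + leave;  // C -> T
  double bits = total / std::log(2.0);
  if (!viterbi) {
    return List::create(_["bits"] = bits);
  }
  // traceback for the envelope
  int env_start = NA_INTEGER, env_end = NA_INTEGER;
  int first_col = NA_INTEGER, last_col = NA_INTEGER;
  int i = n;
  while (i >= 1 && pC[i] == 0) --i;     // position where the exit happened
  if (i >= 1) {
    int k = pC[i];
    last_col = k;
    env_end = i;
    // walk back through the core: state 0 = M, 1 = I, 2 = D
    int st = 0;
    while (true) {
      if (st == 0) {
        int p = pM(k, i);
        env_start = i; first_col = k;
        --i;
        if (p == 0) break;               // entered from N here
        if (p == 1) { st = 0; --k; }
        else if (p == 2) { st = 1; --k; }
        else { st = 2; --k; }
      } else if (st == 1) {
        int p = pI(k, i);
        env_start = i;
        --i;
        st = (p == 0) ? 0 : 1;
      } else {
        int p = pD(k, i);
        st = (p == 0) ? 0 : 2;
        --k;
      }
    }
  }
  return List::create(_["bits"] = bits, _["env_start"] = env_start,
                      _["env_end"] = env_end, _["first_col"] = first_col,
                      _["last_col"] = last_col);
}
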