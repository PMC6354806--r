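#include <Rcpp.h>
using namespace Rcpp;

// Bases are encoded A=1, C=2, G=3, U=4 (0 = unknown, never pairs).
// A duplex is an antiparallel ungapped run: query position i pairs with
// window position j, i+1 with j-1. Walking the query 5'->3' against the
// reversed window turns every duplex into a diagonal run of pair matches.

// Pair class: 0 = none, 1 = GU, 2 = AU, 3 = GC.
static inline int pair_class(int a, int b, bool allow_gu) {
  if ((a == 3 && b == 2) || (a == 2 && b == 3)) return 3;
  if ((a == 1 && b == 4) || (a == 4 && b == 1)) return 2;
  if (allow_gu && ((a == 3 && b == 4) || (a == 4 && b == 3))) return 1;
  return 0;
}

// All maximal antiparallel runs of >= min_len contiguous pairs between query
// q (5'->3') and window w (5'->3'). Returns parallel vectors:
//   q_start (1-based index into q), w_hi (1-based index into w of the pair
//   partner of q_start; the run covers w indices w_hi-len+1 .. w_hi),
//   len, energy (sum of pair weights, weights[0]=GU, [1]=AU, [2]=GC).
// [[Rcpp::export]]
List duplex_runs_cpp(IntegerVector q, IntegerVector w, int min_len,
                     NumericVector weights, bool allow_gu) {
  int m = q.size(), n = w.size();
  std::vector<int> qs, wh, ln;
  std::vector<double> en;
  if (m == 0 || n == 0 || min_len < 1) {
    return List::create(_["q_start"] = qs, _["w_hi"] = wh,
                        _["len"] = ln, _["energy"] = en);
  }
  // diagonals: start cells (i, k) with i==0 or k==0, k indexes reversed w
  for (int d = -(n - 1); d <= m - 1; ++d) {
    int i0 = d > 0 ? d : 0;
    int k0 = d > 0 ? 0 : -d;
    int run = 0;
    double e = 0.0;
    for (int t = 0;; ++t) {
      int i = i0 + t, k = k0 + t;
      bool off = (i >= m || k >= n);
      int pc = 0;
      if (!off) pc = pair_class(q[i], w[n - 1 - k], allow_gu);
      if (pc > 0) {
        run += 1;
        e += weights[pc - 1];
      }
      if ((off || pc == 0) && run >= min_len) {
        int is = i - run;          // 0-based q start of the run
        int ks = k - run;          // 0-based start in reversed w
        qs.push_back(is + 1);
        wh.push_back(n - ks);      // 1-based w index of first pair (= w_hi)
        ln.push_back(run);
        en.push_back(e);
      }
      if (off) break;
      if (pc == 0) { run = 0; e = 0.0; }
    }
  }
  return List::create(_["q_start"] = qs, _["w_hi"] = wh,
                      _["len"] = ln, _["energy"] = en);
}

// Minimum (best) run energy over all runs of >= min_len; +Inf when no run
// reaches min_len. Used for the shuffle null, where only the best duplex
// energy per shuffled window is needed.
// [[Rcpp::export]]
double best_duplex_energy_cpp(IntegerVector q, IntegerVector w, int min_len,
                              NumericVector weights, bool allow_gu) {
  int m = q.size(), n = w.size();
  double best = R_PosInf;
  if (m == 0 || n == 0 || min_len < 1) return best;
  for (int d = -(n - 1); d <= m - 1; ++d) {
    int i0 = d > 0 ? d : 0;
    int k0 = d > 0 ? 0 : -d;
    int run = 0;
    double e = 0.0;
    for (int t = 0;; ++t) {
      int i = i0 + t, k = k0 + t;
      bool off = (i >= m || k >= n);
      int pc = 0;
      if (!off) pc = pair_class(q[i], w[n - 1 - k], allow_gu);
      if (pc > 0) {
        run += 1;
        e += weights[pc - 1];
      }
      if ((off || pc == 0) && run >= min_len && e < best) best = e;
      if (off) break;
      if (pc == 0) { run = 0; e = 0.0; }
    }
  }
  return best;
}
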