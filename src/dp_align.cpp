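#include <Rcpp.h>
using namespace Rcpp;

// Dynamic program over monotone matchings of reference labels to molecule
// labels at a fixed global stretch s (molecule-over-reference).
//
// Score of a matching {(i_k, j_k)}, both index sequences strictly increasing:
//
//   sum_k match_reward
//   - sum_{k>1} (dref_k - dmol_k/s)^2 / (2 * sd^2 * dref_k)
//   - miss_penalty  * (reference labels skipped between matched pairs)
//   - false_penalty * (molecule  labels skipped between matched pairs)
//
// with dref_k = ref[i_k]-ref[i_{k-1}], dmol_k = mol[j_k]-mol[j_{k-1}].
// Unmatched labels before the first and after the last pair are free on both
// sides: a fragment is local in the reference, and fused molecules carry
// labels from a second arm distal to the matched one.
//
// max_step bounds i_k - i_{k-1} and j_k - j_{k-1} (so up to max_step-1
// internal skips per transition); set it >= the label counts for an exact,
// unbanded optimum.

static double dp_fill(const double* ref, int n, const double* mol, int m,
                      double s, double match_reward, double miss_penalty,
                      double false_penalty, double sizing_sd, int max_step,
                      double* M, int* Pi, int* Pj, int* best_i, int* best_j) {
  const double inv2sd2 = 1.0 / (2.0 * sizing_sd * sizing_sd);
  double best = R_NegInf;
  int bi = 0, bj = 0;
  for (int i = 0; i < n; ++i) {
    const int di_max = std::min(max_step, i);
    double* Mi = M + (size_t)i * m;
    for (int j = 0; j < m; ++j) {
      double b = match_reward;  // start a new matching at (i, j)
      int pi = -1, pj = -1;
      const int dj_max = std::min(max_step, j);
      for (int di = 1; di <= di_max; ++di) {
        const double dref = ref[i] - ref[i - di];
        const double base = match_reward - miss_penalty * (di - 1);
        const double* Mp = M + (size_t)(i - di) * m;
        for (int dj = 1; dj <= dj_max; ++dj) {
          const double diff = dref - (mol[j] - mol[j - dj]) / s;
          const double cand = Mp[j - dj] + base
            - diff * diff * inv2sd2 / dref
            - false_penalty * (dj - 1);
          if (cand > b) { b = cand; pi = i - di; pj = j - dj; }
        }
      }
      Mi[j] = b;
      if (Pi) { Pi[(size_t)i * m + j] = pi; Pj[(size_t)i * m + j] = pj; }
      if (b > best) { best = b; bi = i; bj = j; }
    }
  }
  *best_i = bi; *best_j = bj;
  return best;
}

// Score only (no traceback): the hot path of arm scanning and stretch search.
// [[Rcpp::export]]
double dp_score_cpp(NumericVector ref, NumericVector mol, double s,
                    double match_reward, double miss_penalty,
                    double false_penalty, double sizing_sd, int max_step) {
  const int n = ref.size(), m = mol.size();
  if (n == 0 || m == 0) return R_NegInf;
  std::vector<double> M((size_t)n * m);
  int bi, bj;
  return dp_fill(REAL(ref), n, REAL(mol), m, s, match_reward, miss_penalty,
                 false_penalty, sizing_sd, max_step, M.data(), NULL, NULL,
                 &bi, &bj);
}

// Full DP with traceback of the optimal matched pairs (1-based indices).
// [[Rcpp::export]]
List dp_align_cpp(NumericVector ref, NumericVector mol, double s,
                  double match_reward, double miss_penalty,
                  double false_penalty, double sizing_sd, int max_step) {
  const int n = ref.size(), m = mol.size();
  if (n == 0 || m == 0)
    return List::create(_["score"] = R_NegInf,
                        _["ref_idx"] = IntegerVector(0),
                        _["mol_idx"] = IntegerVector(0));
  std::vector<double> M((size_t)n * m);
  std::vector<int> Pi((size_t)n * m), Pj((size_t)n * m);
  int bi, bj;
  double best = dp_fill(REAL(ref), n, REAL(mol), m, s, match_reward,
                        miss_penalty, false_penalty, sizing_sd, max_step,
                        M.data(), Pi.data(), Pj.data(), &bi, &bj);
  std::vector<int> mi, mj;
  for (int i = bi, j = bj; i >= 0 && j >= 0;) {
    mi.push_back(i + 1); mj.push_back(j + 1);
    int ni = Pi[(size_t)i * m + j], nj = Pj[(size_t)i * m + j];
    i = ni; j = nj;
  }
  std::reverse(mi.begin(), mi.end());
  std::reverse(mj.begin(), mj.end());
  return List::create(_["score"] = best,
                      _["ref_idx"] = wrap(mi),
                      _["mol_idx"] = wrap(mj));
}
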