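#include <Rcpp.h>
#include <vector>
#include <string>
#include <utility>
#include <cstring>
using namespace Rcpp;

// base codes: A=0 C=1 G=2 U=3, other=4
static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'U': return 3;
    default: return 4;
  }
}

struct PairTable {
  // energy of pairing code a with code b; > 0 means "cannot pair"
  double e[5][5];
  PairTable(double e_gc, double e_au, double e_gu) {
    for (int a = 0; a < 5; ++a)
      for (int b = 0; b < 5; ++b) e[a][b] = 1.0;
    e[2][1] = e[1][2] = e_gc;  // G:C
    e[0][3] = e[3][0] = e_au;  // A:U
    e[2][3] = e[3][2] = e_gu;  // G:U
  }
};

// fill the Nussinov minimisation table (flat, row-major, 0-based):
// E(i,j) = min( E(i,j-1),
//               min over k in [i, j-min_loop-1] with (k,j) pairable of
//                 E(i,k-1) + e(k,j) + E(k+1,j-1) )
// E(i,j) = 0 whenever j < i (empty interval).
static void fill_table(const std::vector<int> &code, const PairTable &pt,
                       int min_loop, std::vector<double> &E) {
  int n = (int)code.size();
  E.assign((size_t)n * n, 0.0);
  for (int span = min_loop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      const double *Ei = &E[(size_t)i * n];
      double best = Ei[j - 1];  // j unpaired
      int cj = code[j];
      // k == i: pair (i, j) closes the whole interval
      {
        double e = pt.e[code[i]][cj];
        if (e < 0.5) {
          double cand = e + E[(size_t)(i + 1) * n + (j - 1)];
          if (cand < best) best = cand;
        }
      }
      for (int k = i + 1; k <= j - min_loop - 1; ++k) {
        double e = pt.e[code[k]][cj];
        if (e < 0.5) {
          double cand = Ei[k - 1] + e + E[(size_t)(k + 1) * n + (j - 1)];
          if (cand < best) best = cand;
        }
      }
      E[(size_t)i * n + j] = best;
    }
  }
}

static std::vector<int> encode(const std::string &s) {
  std::vector<int> code(s.size());
  for (size_t i = 0; i < s.size(); ++i) code[i] = base_code(s[i]);
  return code;
}

// [[Rcpp::export]]
List nussinov_fold_cpp(std::string seq, double e_gc, double e_au,
                       double e_gu, int min_loop, bool traceback) {
  int n = (int)seq.size();
  PairTable pt(e_gc, e_au, e_gu);
  std::vector<int> code = encode(seq);
  std::vector<double> E;
  double energy = 0.0;
  std::vector<std::pair<int, int> > pairs;
  if (n > 0) {
    fill_table(code, pt, min_loop, E);
    energy = E[n - 1];  // E(0, n-1)
    if (traceback) {
      const double eps = 1e-9;
      std::vector<std::pair<int, int> > stack;
      stack.push_back(std::make_pair(0, n - 1));
      while (!stack.empty()) {
        int i = stack.back().first, j = stack.back().second;
        stack.pop_back();
        if (j - i < min_loop + 1) continue;
        double target = E[(size_t)i * n + j];
        if (std::abs(target - E[(size_t)i * n + (j - 1)]) < eps) {
          stack.push_back(std::make_pair(i, j - 1));  // j unpaired first
          continue;
        }
        bool found = false;
        for (int k = i; k <= j - min_loop - 1 && !found; ++k) {
          double e = pt.e[code[k]][code[j]];
          if (e > 0.5) continue;
          double left = (k > i) ? E[(size_t)i * n + (k - 1)] : 0.0;
          double cand = left + e + E[(size_t)(k + 1) * n + (j - 1)];
          if (std::abs(cand - target) < eps) {
            pairs.push_back(std::make_pair(k + 1, j + 1));  // 1-based
            if (k > i) stack.push_back(std::make_pair(i, k - 1));
            stack.push_back(std::make_pair(k + 1, j - 1));
            found = true;
          }
        }
        if (!found) stack.push_back(std::make_pair(i, j - 1));
      }
    }
  }
  IntegerMatrix pm(pairs.size(), 2);
  for (size_t r = 0; r < pairs.size(); ++r) {
    pm(r, 0) = pairs[r].first;
    pm(r, 1) = pairs[r].second;
  }
  return List::create(Named("energy") = energy, Named("pairs") = pm);
}

// [[Rcpp::export]]
NumericVector nussinov_energy_cpp(CharacterVector seqs, double e_gc,
                                  double e_au, double e_gu, int min_loop) {
  int m = seqs.size();
  NumericVector out(m);
  PairTable pt(e_gc, e_au, e_gu);
  std::vector<double> E;
  for (int i = 0; i < m; ++i) {
    if (CharacterVector::is_na(seqs[i])) {
      out[i] = NA_REAL;
      continue;
    }
    std::string s = as<std::string>(seqs[i]);
    if (s.empty()) {
      out[i] = NA_REAL;
      continue;
    }
    std::vector<int> code = encode(s);
    fill_table(code, pt, min_loop, E);
    out[i] = E[s.size() - 1];
  }
  return out;
}
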