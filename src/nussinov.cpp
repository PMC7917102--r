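#include <Rcpp.h>
#include <vector>
#include <string>
#include <stack>

// Maximum base-pair (Nussinov-style) folding used for hairpin screening.
// Pairing rules: Watson-Crick (A:T, G:C) plus the G:U wobble (G:T on the
// DNA-encoded sequence); minimum hairpin loop of 3 unpaired nt.
// Traceback is deterministic: for an interval [i, j] the outermost pair
// (i, j) is taken whenever it is optimal, otherwise j is left unpaired if
// optimal, otherwise j is paired with the leftmost optimal partner.

// base codes: A=0 C=1 G=2 T=3, other=4
static inline int code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return 4;
  }
}

static const bool PAIRS[5][5] = {
  //        A      C      G      T      N
  /*A*/ {false, false, false, true,  false},
  /*C*/ {false, false, true,  false, false},
  /*G*/ {false, true,  false, true,  false},
  /*T*/ {true,  false, true,  false, false},
  /*N*/ {false, false, false, false, false}
};

// [[Rcpp::export(name = ".nussinov_fold_cpp")]]
Rcpp::List nussinov_fold_cpp(std::string seq, int min_loop = 3) {
  const int n = (int) seq.size();
  Rcpp::IntegerVector pair_out(n, 0);  // 1-based partner, 0 = unpaired
  if (n == 0) {
    return Rcpp::List::create(Rcpp::Named("structure") = "",
                              Rcpp::Named("n_pairs") = 0,
                              Rcpp::Named("pairs") = pair_out);
  }
  std::vector<int> b(n);
  for (int i = 0; i < n; ++i) b[i] = code(seq[i]);

  // M[i*n + j] = max pairs in seq[i..j], 0-based inclusive
  std::vector<int> M((size_t) n * n, 0);
  for (int span = min_loop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      const int j = i + span;
      const int bj = b[j];
      int best = M[(size_t) i * n + (j - 1)];   // j unpaired
      const int *Mi = &M[(size_t) i * n];
      for (int k = i; k <= j - min_loop - 1; ++k) {
        if (!PAIRS[b[k]][bj]) continue;
        int v = 1;
        if (k > i)     v += Mi[k - 1];
        if (k + 1 < j) v += M[(size_t) (k + 1) * n + (j - 1)];
        if (v > best) best = v;
      }
      M[(size_t) i * n + j] = best;
    }
  }

  std::string db(n, '.');
  std::stack< std::pair<int,int> > st;
  st.push(std::make_pair(0, n - 1));
  int n_pairs = 0;
  while (!st.empty()) {
    int i = st.top().first, j = st.top().second;
    st.pop();
    if (j - i < min_loop + 1 || M[(size_t) i * n + j] == 0) continue;
    const int target = M[(size_t) i * n + j];
    // prefer the outermost pair (i, j)
    if (PAIRS[b[i]][b[j]]) {
      int v = 1;
      if (i + 1 <= j - 1) v += M[(size_t) (i + 1) * n + (j - 1)];
      if (v == target) {
        db[i] = '('; db[j] = ')';
        pair_out[i] = j + 1; pair_out[j] = i + 1;
        ++n_pairs;
        st.push(std::make_pair(i + 1, j - 1));
        continue;
      }
    }
    if (target == M[(size_t) i * n + (j - 1)]) {  // j unpaired
      st.push(std::make_pair(i, j - 1));
      continue;
    }
    for (int k = i; k <= j - min_loop - 1; ++k) {
      if (!PAIRS[b[k]][b[j]]) continue;
      int v = 1;
      if (k > i)     v += M[(size_t) i * n + (k - 1)];
      if (k + 1 < j) v += M[(size_t) (k + 1) * n + (j - 1)];
      if (v == target) {
        db[k] = '('; db[j] = ')';
        pair_out[k] = j + 1; pair_out[j] = k + 1;
        ++n_pairs;
        if (k > i)     st.push(std::make_pair(i, k - 1));
        if (k + 1 < j) st.push(std::make_pair(k + 1, j - 1));
        break;
      }
    }
  }

  return Rcpp::List::create(Rcpp::Named("structure") = db,
                            Rcpp::Named("n_pairs") = n_pairs,
                            Rcpp::Named("pairs") = pair_out);
}
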