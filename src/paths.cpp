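#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Depth-first backtracking over the sublattice spanned by start and end.
// Genotypes are 0-based integers with bit i = locus i (little-endian).
// A step flips one bit on which the current genotype still differs from
// `end`; admissibility is either strictly increasing fitness (selective
// accessibility) or viability f > 0 (lethal-only blocking).
static double dfs_paths(const double* f, int L, int start, int end,
                        bool lethal, bool early_exit) {
  if (start == end) return (!lethal || f[start] > 0.0) ? 1.0 : 0.0;
  if (lethal && (f[start] <= 0.0 || f[end] <= 0.0)) return 0.0;
  std::vector<int> node(L + 1), nextbit(L + 1);
  int depth = 0;
  node[0] = start;
  nextbit[0] = 0;
  double count = 0.0;
  while (depth >= 0) {
    const int g = node[depth];
    const int diff = g ^ end;
    int b = nextbit[depth];
    while (b < L) {
      if ((diff >> b) & 1) {
        const int h = g ^ (1 << b);
        const bool ok = lethal ? (f[h] > 0.0) : (f[h] > f[g]);
        if (ok) break;
      }
      ++b;
    }
    if (b >= L) {  // all moves exhausted: backtrack
      --depth;
      continue;
    }
    nextbit[depth] = b + 1;
    const int h = g ^ (1 << b);
    if (h == end) {
      count += 1.0;
      if (early_exit) return count;
    } else {
      ++depth;
      node[depth] = h;
      nextbit[depth] = 0;
    }
  }
  return count;
}

static int infer_L(R_xlen_t n) {
  int L = 0;
  while ((R_xlen_t(1) << L) < n) ++L;
  if ((R_xlen_t(1) << L) != n)
    stop("fitness vector length must be a power of two");
  return L;
}

// [[Rcpp::export]]
double cpp_count_paths(NumericVector f, int start, int end, bool lethal) {
  int L = infer_L(f.size());
  return dfs_paths(REAL(f), L, start, end, lethal, false);
}

// [[Rcpp::export]]
bool cpp_has_path(NumericVector f, int start, int end, bool lethal) {
  int L = infer_L(f.size());
  return dfs_paths(REAL(f), L, start, end, lethal, true) > 0.0;
}

// LK/NK fitness assembly: site i contributes contrib(idx, i) where idx is
// built from the genotype's alleles at site i and its K partner loci.
// partners: L x (K+1) matrix of 0-based locus indices, column 0 = the site
// itself; contrib: 2^(K+1) x L matrix of i.i.d. contributions.
// [[Rcpp::export]]
NumericVector cpp_lk_fitness(IntegerMatrix partners, NumericMatrix contrib) {
  const int L = partners.nrow();
  const int Kp1 = partners.ncol();
  const int n = 1 << L;
  if (contrib.nrow() != (1 << Kp1) || contrib.ncol() != L)
    stop("contribution table has wrong dimensions");
  NumericVector out(n);
  for (int g = 0; g < n; ++g) {
    double fit = 0.0;
    for (int i = 0; i < L; ++i) {
      int idx = 0;
      for (int j = 0; j < Kp1; ++j)
        idx |= ((g >> partners(i, j)) & 1) << j;
      fit += contrib(idx, i);
    }
    out[g] = fit;
  }
  return out;
}
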