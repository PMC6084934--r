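// Hot-path kernels for the evolutionary algorithm: population evaluation
// of the squared polarity-difference cost, codon-exchange mutation and the
// codon-reassignment crossover (NUM/GEN representation: one amino-acid
// index per sense codon), and the position-based block crossover (DEG/BLO
// representation: one amino-acid index per synonymous block).  All
// randomness flows through R's RNG so runs are reproducible via set.seed.

#include <Rcpp.h>
using namespace Rcpp;

static inline int runif_int(int n) {
  // uniform integer in [0, n)
  int k = (int)(unif_rand() * n);
  return (k >= n) ? n - 1 : k;
}

// cost of each row of A (1-based amino-acid indices, one column per sense
// codon) over the pair list (pi, pj: 0-based column indices)
// [[Rcpp::export]]
NumericVector eval_pop_cpp(IntegerMatrix A, NumericVector p,
                           IntegerVector pi, IntegerVector pj) {
  const int n = A.nrow(), m = pi.size();
  NumericVector out(n);
  const int *a = A.begin();
  const double *pp = p.begin();
  double *o = out.begin();
  for (int t = 0; t < m; ++t) {
    const int *ci = a + (R_xlen_t)pi[t] * n;
    const int *cj = a + (R_xlen_t)pj[t] * n;
    for (int r = 0; r < n; ++r) {
      double d = pp[ci[r] - 1] - pp[cj[r] - 1];
      o[r] += d * d;
    }
  }
  return out;
}

// pick the k-th codon (0-based target drawn uniformly) carrying amino
// acid aa in row r of A; returns the column index
static int random_codon_of(IntegerMatrix &A, int r, int aa) {
  int cnt = 0;
  for (int c = 0; c < A.ncol(); ++c) if (A(r, c) == aa) ++cnt;
  int k = runif_int(cnt);
  for (int c = 0; c < A.ncol(); ++c) {
    if (A(r, c) == aa && k-- == 0) return c;
  }
  return -1; // unreachable for valid rows
}

static void mutate_codon_row(IntegerMatrix &A, int r, int naa) {
  // two distinct amino acids, one codon of each, exchanged
  int a1 = runif_int(naa) + 1;
  int a2 = runif_int(naa - 1) + 1;
  if (a2 >= a1) ++a2;
  int c1 = random_codon_of(A, r, a1);
  int c2 = random_codon_of(A, r, a2);
  A(r, c1) = a2;
  A(r, c2) = a1;
}

// [[Rcpp::export]]
IntegerMatrix mutate_codon_pop_cpp(IntegerMatrix A, LogicalVector sel,
                                   int naa) {
  IntegerMatrix B = clone(A);
  for (int r = 0; r < B.nrow(); ++r)
    if (sel[r]) mutate_codon_row(B, r, naa);
  return B;
}

// [[Rcpp::export]]
IntegerVector mutate_codon_one_cpp(IntegerVector a, int naa) {
  IntegerMatrix B(1, a.size());
  for (int c = 0; c < a.size(); ++c) B(0, c) = a[c];
  mutate_codon_row(B, 0, naa);
  return B(0, _);
}

// Codon-reassignment crossover on rows r1 (offspring of parent 1) and r2
// (offspring of parent 2) of B, which enters as a copy of the parents.
// An amino acid a1 is drawn; codons private to one parent's a1 set are
// exchanged pairwise between the offspring.  Surplus private codons are
// moved to a1 from a donor amino acid in one offspring and away from a1
// to a recipient in the other; an amino acid's last codon is never moved.
// With keepCounts (NUM) every move is replaced by a two-codon swap so the
// per-amino-acid counts are preserved exactly.
static void cross_codon_rows(IntegerMatrix &B, int r1, int r2, int naa,
                             bool keepCounts) {
  const int nc = B.ncol();
  int a1 = runif_int(naa) + 1;
  // private codons of a1 in each parent, canonical codon order
  std::vector<int> d1, d2;
  for (int c = 0; c < nc; ++c) {
    bool in1 = B(r1, c) == a1, in2 = B(r2, c) == a1;
    if (in1 && !in2) d1.push_back(c);
    if (in2 && !in1) d2.push_back(c);
  }
  const int m = (int)std::min(d1.size(), d2.size());
  for (int t = 0; t < m; ++t) {
    std::swap(B(r1, d1[t]), B(r1, d2[t]));
    std::swap(B(r2, d1[t]), B(r2, d2[t]));
  }
  // surplus: one parent still has private a1-codons the other lacks
  int rGain, rLose;             // rGain: a1 grows (or swaps in) at codon c
  std::vector<int> *rest;
  if ((int)d2.size() > m) { rest = &d2; rGain = r1; rLose = r2; }
  else                    { rest = &d1; rGain = r2; rLose = r1; }
  std::vector<int> counts1(naa + 1, 0), counts2(naa + 1, 0);
  for (int c = 0; c < nc; ++c) {
    ++counts1[B(rGain, c)];
    ++counts2[B(rLose, c)];
  }
  for (size_t t = m; t < rest->size(); ++t) {
    int c = (*rest)[t];
    int a2 = B(rGain, c);       // donor amino acid in the gaining offspring
    if (keepCounts) {
      // swap codon c with a random a1-codon: counts unchanged
      int c2 = random_codon_of(B, rGain, a1);
      std::swap(B(rGain, c), B(rGain, c2));
      int a3 = runif_int(naa - 1) + 1;
      if (a3 >= a1) ++a3;
      int c3 = random_codon_of(B, rLose, a3);
      std::swap(B(rLose, c), B(rLose, c3));
    } else {
      if (a2 != a1 && counts1[a2] >= 2) {     // never strand an amino acid
        B(rGain, c) = a1;
        --counts1[a2]; ++counts1[a1];
      }
      if (B(rLose, c) == a1 && counts2[a1] >= 2) {
        int a3 = runif_int(naa - 1) + 1;
        if (a3 >= a1) ++a3;
        B(rLose, c) = a3;
        --counts2[a1]; ++counts2[a3];
      }
    }
  }
}

// [[Rcpp::export]]
IntegerMatrix crossover_codon_pop_cpp(IntegerMatrix A, IntegerVector r1,
                                      IntegerVector r2, int naa,
                                      bool keepCounts) {
  IntegerMatrix B = clone(A);
  for (int t = 0; t < r1.size(); ++t)
    cross_codon_rows(B, r1[t] - 1, r2[t] - 1, naa, keepCounts);
  return B;
}

// [[Rcpp::export]]
List crossover_codon_pair_cpp(IntegerVector a, IntegerVector b, int naa,
                              bool keepCounts) {
  IntegerMatrix B(2, a.size());
  for (int c = 0; c < a.size(); ++c) { B(0, c) = a[c]; B(1, c) = b[c]; }
  cross_codon_rows(B, 0, 1, naa, keepCounts);
  return List::create(B(0, _), B(1, _));
}

// Position-based crossover on block permutations p1, p2 (block -> amino
// acid, both 1-based).  Amino acids in the keep set stay on their
// own-parent blocks; the remaining blocks are filled with the unused
// amino acids of the other parent in that parent's block order,
// restricted to the matching exchange class (classId per amino acid /
// block; a single class reproduces the unrestricted BLO behaviour).
static void pos_fill(const IntegerVector &own, const IntegerVector &donor,
                     const IntegerVector &classId, const LogicalVector &keep,
                     IntegerVector &out) {
  const int n = own.size();
  std::vector<bool> used(n + 1, false);
  for (int b = 0; b < n; ++b) {
    if (keep[own[b] - 1]) {
      out[b] = own[b];
      used[own[b]] = true;
    } else out[b] = 0;
  }
  std::vector<int> ptr(n + 1, 0);   // per-class scan position in donor
  for (int b = 0; b < n; ++b) {
    if (out[b] != 0) continue;
    int cls = classId[b];           // class of block b
    int &q = ptr[cls];
    while (q < n && (used[donor[q]] || classId[donor[q] - 1] != cls)) ++q;
    out[b] = donor[q];
    used[donor[q]] = true;
    ++q;
  }
}

// [[Rcpp::export]]
List pos_crossover_pair_cpp(IntegerVector p1, IntegerVector p2,
                            IntegerVector classId,
                            Nullable<LogicalVector> keepSet = R_NilValue) {
  const int n = p1.size();
  LogicalVector keep(n);
  if (keepSet.isNotNull()) keep = LogicalVector(keepSet);
  else for (int a = 0; a < n; ++a) keep[a] = unif_rand() < 0.5;
  IntegerVector o1(n), o2(n);
  pos_fill(p1, p2, classId, keep, o1);
  pos_fill(p2, p1, classId, keep, o2);
  return List::create(o1, o2);
}

// [[Rcpp::export]]
IntegerMatrix pos_crossover_pop_cpp(IntegerMatrix P, IntegerVector r1,
                                    IntegerVector r2, IntegerVector classId) {
  IntegerMatrix B = clone(P);
  const int n = P.ncol();
  IntegerVector p1(n), p2(n), o1(n), o2(n);
  LogicalVector keep(n);
  for (int t = 0; t < r1.size(); ++t) {
    int i = r1[t] - 1, j = r2[t] - 1;
    for (int b = 0; b < n; ++b) { p1[b] = B(i, b); p2[b] = B(j, b); }
    for (int a = 0; a < n; ++a) keep[a] = unif_rand() < 0.5;
    pos_fill(p1, p2, classId, keep, o1);
    pos_fill(p2, p1, classId, keep, o2);
    for (int b = 0; b < n; ++b) { B(i, b) = o1[b]; B(j, b) = o2[b]; }
  }
  return B;
}
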