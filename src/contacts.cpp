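#include "rbd_common.h"
#include <algorithm>
using namespace Rcpp;

// Candidate cross-protein contact pairs (atom centers closer than dc),
// sorted by ascending distance.
struct CandPair { int ia, ib; double d; };

static std::vector<CandPair> candidate_pairs(const NumericMatrix& A,
                                             const NumericMatrix& B,
                                             double dc) {
  std::vector<CandPair> out;
  double dc2 = dc * dc;
  for (int i = 0; i < A.nrow(); ++i) {
    for (int j = 0; j < B.nrow(); ++j) {
      double dx = A(i, 0) - B(j, 0), dy = A(i, 1) - B(j, 1),
             dz = A(i, 2) - B(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < dc2) out.push_back({i, j, std::sqrt(d2)});
    }
  }
  std::sort(out.begin(), out.end(),
            [](const CandPair& a, const CandPair& b) { return a.d < b.d; });
  return out;
}

// Conflict matrix: pairs p and q conflict when their atoms on the same
// protein are within d_min of each other (contacts not independent).
static std::vector<std::vector<bool>> conflicts(const std::vector<CandPair>& P,
                                                const NumericMatrix& A,
                                                const NumericMatrix& B,
                                                double dmin) {
  int k = (int)P.size();
  double dmin2 = dmin * dmin;
  std::vector<std::vector<bool>> C(k, std::vector<bool>(k, false));
  auto close = [&](const NumericMatrix& M, int i, int j) {
    double dx = M(i, 0) - M(j, 0), dy = M(i, 1) - M(j, 1), dz = M(i, 2) - M(j, 2);
    return dx * dx + dy * dy + dz * dz <= dmin2;
  };
  for (int p = 0; p < k; ++p)
    for (int q = p + 1; q < k; ++q) {
      bool c = close(A, P[p].ia, P[q].ia) || close(B, P[p].ib, P[q].ib);
      C[p][q] = C[q][p] = c;
    }
  return C;
}

static int greedy_count(const std::vector<CandPair>& P,
                        const std::vector<std::vector<bool>>& C) {
  int k = (int)P.size(), n = 0;
  std::vector<int> chosen;
  for (int p = 0; p < k; ++p) {
    bool ok = true;
    for (int c : chosen) if (C[p][c]) { ok = false; break; }
    if (ok) { chosen.push_back(p); ++n; }
  }
  return n;
}

struct BnB {
  const std::vector<std::vector<bool>>* C;
  int k;
  long nodes = 0, cap;
  int best = 0;
  bool capped = false;
  void rec(int p, int count, std::vector<bool>& blocked) {
    if (++nodes > cap) { capped = true; return; }
    if (count + (k - p) <= best) return;   // bound
    if (p == k) { if (count > best) best = count; return; }
    if (!blocked[p]) {
      std::vector<int> newly;
      for (int q = p + 1; q < k; ++q)
        if (!blocked[q] && (*C)[p][q]) { blocked[q] = true; newly.push_back(q); }
      rec(p + 1, count + 1, blocked);
      for (int q : newly) blocked[q] = false;
      if (capped) return;
    }
    rec(p + 1, count, blocked);
  }
};

// Maximum number of mutually independent cross-protein contacts. Exact
// branch-and-bound for realistic interface sizes; if the search exceeds
// `node_cap` nodes, falls back to the greedy ascending-distance selection
// (a lower bound, always >= the greedy count).
// [[Rcpp::export]]
int cpp_max_indep_contacts(NumericMatrix A, NumericMatrix B, double dc,
                           double dmin, double node_cap) {
  std::vector<CandPair> P = candidate_pairs(A, B, dc);
  if (P.empty()) return 0;
  if (P.size() == 1) return 1;
  std::vector<std::vector<bool>> C = conflicts(P, A, B, dmin);
  int g = greedy_count(P, C);
  BnB bnb;
  bnb.C = &C; bnb.k = (int)P.size(); bnb.cap = (long)node_cap; bnb.best = g;
  std::vector<bool> blocked(P.size(), false);
  bnb.rec(0, 0, blocked);
  return bnb.best;
}

// [[Rcpp::export]]
int cpp_greedy_indep_contacts(NumericMatrix A, NumericMatrix B, double dc,
                              double dmin) {
  std::vector<CandPair> P = candidate_pairs(A, B, dc);
  if (P.size() < 2) return (int)P.size();
  std::vector<std::vector<bool>> C = conflicts(P, A, B, dmin);
  return greedy_count(P, C);
}

// Fast encounter test: do at least n_ind mutually independent contacts exist?
// For n_ind = 2 this is an O(k^2) scan over candidate pairs.
// [[Rcpp::export]]
bool cpp_has_encounter(NumericMatrix A, NumericMatrix B, double dc,
                       double dmin, int n_ind) {
  std::vector<CandPair> P = candidate_pairs(A, B, dc);
  if ((int)P.size() < n_ind) return false;
  if (n_ind <= 1) return !P.empty();
  if (n_ind == 2) {
    double dmin2 = dmin * dmin;
    int k = (int)P.size();
    for (int p = 0; p < k; ++p)
      for (int q = p + 1; q < k; ++q) {
        double dxa = A(P[p].ia, 0) - A(P[q].ia, 0),
               dya = A(P[p].ia, 1) - A(P[q].ia, 1),
               dza = A(P[p].ia, 2) - A(P[q].ia, 2);
        if (dxa * dxa + dya * dya + dza * dza <= dmin2) continue;
        double dxb = B(P[p].ib, 0) - B(P[q].ib, 0),
               dyb = B(P[p].ib, 1) - B(P[q].ib, 1),
               dzb = B(P[p].ib, 2) - B(P[q].ib, 2);
        if (dxb * dxb + dyb * dyb + dzb * dzb > dmin2) return true;
      }
    return false;
  }
  return cpp_max_indep_contacts(A, B, dc, dmin, 2e6) >= n_ind;
}

// Which atoms of A lie within dc of any atom of B (for contact probabilities).
// [[Rcpp::export]]
LogicalVector cpp_atoms_in_contact(NumericMatrix A, NumericMatrix B, double dc) {
  int na = A.nrow(), nb = B.nrow();
  double dc2 = dc * dc;
  LogicalVector out(na);
  for (int i = 0; i < na; ++i) {
    bool hit = false;
    for (int j = 0; j < nb && !hit; ++j) {
      double dx = A(i, 0) - B(j, 0), dy = A(i, 1) - B(j, 1), dz = A(i, 2) - B(j, 2);
      hit = dx * dx + dy * dy + dz * dz < dc2;
    }
    out[i] = hit;
  }
  return out;
}

// Minimum cross distance between two atom sets (bounding prefilter helper).
// [[Rcpp::export]]
double cpp_min_cross_dist(NumericMatrix A, NumericMatrix B) {
  double best = R_PosInf;
  for (int i = 0; i < A.nrow(); ++i)
    for (int j = 0; j < B.nrow(); ++j) {
      double dx = A(i, 0) - B(j, 0), dy = A(i, 1) - B(j, 1), dz = A(i, 2) - B(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
  return std::sqrt(best);
}
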