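// Core numerics for blockwise pattern probabilities and block simulation
// under the two-population structured coalescent.
//
// The mutation-augmented chain tracks (lineage configuration, per-class
// mutation count).  Counts live on an "active" down-closed subset of a
// 4-dimensional box; a mutation that would leave the active set can never
// return (counts only grow), so its probability mass is simply dropped.
// The pre-split phase [0, T) is integrated by uniformization; the
// panmictic phase after T is absorbed through level-wise linear solves.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Gaussian elimination solve of (I - A) X = B in place, small dense n
static void solve_small(std::vector<double>& M, std::vector<double>& B,
                        int n, int nrhs) {
  for (int col = 0; col < n; ++col) {
    int piv = col;
    double best = std::fabs(M[col * n + col]);
    for (int r = col + 1; r < n; ++r) {
      double v = std::fabs(M[col * n + r]);
      if (v > best) { best = v; piv = r; }
    }
    if (best == 0.0) stop("singular system in panmictic phase");
    if (piv != col) {
      for (int c = 0; c < n; ++c) std::swap(M[c * n + col], M[c * n + piv]);
      for (int c = 0; c < nrhs; ++c) std::swap(B[c * n + col], B[c * n + piv]);
    }
    double d = M[col * n + col];
    for (int r = col + 1; r < n; ++r) {
      double f = M[col * n + r] / d;
      if (f == 0.0) continue;
      for (int c = col; c < n; ++c) M[c * n + r] -= f * M[c * n + col];
      for (int c = 0; c < nrhs; ++c) B[c * n + r] -= f * B[c * n + col];
    }
  }
  for (int col = n - 1; col >= 0; --col) {
    double d = M[col * n + col];
    for (int c = 0; c < nrhs; ++c) {
      double s = B[c * n + col];
      for (int k = col + 1; k < n; ++k) s -= M[k * n + col] * B[c * n + k];
      B[c * n + col] = s / d;
    }
  }
}

// [[Rcpp::export]]
NumericVector patternprob_cpp(double T, NumericVector lambda,
                              int n1, int init1,
                              IntegerVector t1_from, IntegerVector t1_to,
                              NumericVector t1_rate, IntegerMatrix nclass1,
                              int n2, int abs2,
                              IntegerVector t2_from, IntegerVector t2_to,
                              NumericVector t2_rate, IntegerMatrix nclass2,
                              IntegerVector map12,
                              IntegerVector dims, IntegerVector cell_lookup,
                              IntegerMatrix cells, IntegerVector query,
                              double tol) {
  const int nact = cells.nrow();
  int strides[4];
  strides[0] = 1;
  for (int c = 1; c < 4; ++c) strides[c] = strides[c - 1] * dims[c - 1];

  // full-box index and up/down neighbours (active index or -1) per cell
  std::vector<int> up(nact * 4), down(nact * 4);
  for (int i = 0; i < nact; ++i) {
    int fidx = 0;
    for (int c = 0; c < 4; ++c) fidx += cells(i, c) * strides[c];
    for (int c = 0; c < 4; ++c) {
      up[i * 4 + c] = (cells(i, c) + 1 < dims[c]) ?
        cell_lookup[fidx + strides[c]] : -1;
      down[i * 4 + c] = (cells(i, c) > 0) ? cell_lookup[fidx - strides[c]] : -1;
    }
  }

  const int nt1 = t1_from.size(), nt2 = t2_from.size();

  // ---------- phase 1: [0, T), uniformization --------------------------
  // The uniformised kernel P = I + G/Lambda over (state, cell) is built
  // once as a CSR matrix (incoming edges per row), so each Poisson term
  // is a single sparse matrix-vector product.
  std::vector<double> alpha(static_cast<size_t>(n2) * nact, 0.0);
  if (T > 0.0 && n1 > 0) {
    std::vector<double> qout(n1, 0.0);
    for (int t = 0; t < nt1; ++t) qout[t1_from[t]] += t1_rate[t];
    std::vector<double> mrate(n1 * 4);
    for (int s = 0; s < n1; ++s)
      for (int c = 0; c < 4; ++c) {
        double r = lambda[c] * nclass1(s, c);
        mrate[s * 4 + c] = r;
        qout[s] += r;
      }
    double Lam = 0.0;
    for (int s = 0; s < n1; ++s) if (qout[s] > Lam) Lam = qout[s];
    if (Lam <= 0.0) Lam = 1.0;
    const double LT = Lam * T;

    // incoming lineage transitions grouped by target state
    std::vector<std::vector<int>> into(n1);
    for (int t = 0; t < nt1; ++t) into[t1_to[t]].push_back(t);

    const size_t N = static_cast<size_t>(n1) * nact;
    std::vector<int> rowptr(N + 1, 0);
    size_t nnz = 0;
    for (int b = 0; b < nact; ++b)
      for (int s = 0; s < n1; ++s) {
        size_t i = static_cast<size_t>(b) * n1 + s;
        int cnt = 1 + static_cast<int>(into[s].size());
        for (int c = 0; c < 4; ++c)
          if (mrate[s * 4 + c] > 0.0 && down[b * 4 + c] >= 0) ++cnt;
        nnz += cnt;
        rowptr[i + 1] = static_cast<int>(nnz);
      }
    std::vector<int> colidx(nnz);
    std::vector<double> val(nnz);
    {
      size_t k = 0;
      for (int b = 0; b < nact; ++b)
        for (int s = 0; s < n1; ++s) {
          colidx[k] = b * n1 + s;
          val[k++] = 1.0 - qout[s] / Lam;
          for (int t : into[s]) {
            colidx[k] = b * n1 + t1_from[t];
            val[k++] = t1_rate[t] / Lam;
          }
          for (int c = 0; c < 4; ++c) {
            double r = mrate[s * 4 + c];
            int db = down[b * 4 + c];
            if (r > 0.0 && db >= 0) {
              colidx[k] = db * n1 + s;
              val[k++] = r / Lam;
            }
          }
        }
    }

    std::vector<double> w(N, 0.0), w2(N), res(N, 0.0);
    w[init1] = 1.0; // cell 0 has active index 0 (down-closed, sorted)
    double lpois = -LT; // log Poisson(0; LT)
    double cum = std::exp(lpois);
    for (size_t i = 0; i < N; ++i) res[i] += cum * w[i];
    long n = 0;
    const long nmax = static_cast<long>(LT + 12.0 * std::sqrt(LT + 1.0) + 50.0);
    while (n < nmax && (n < static_cast<long>(LT) || cum < 1.0 - tol)) {
      ++n;
      lpois += std::log(LT) - std::log(static_cast<double>(n));
      const double w_pois = std::exp(lpois);
      cum += w_pois;
      const int* ci = colidx.data();
      const double* vv = val.data();
      for (size_t i = 0; i < N; ++i) {
        double acc = 0.0;
        const int end = rowptr[i + 1];
        for (int p = rowptr[i]; p < end; ++p) acc += vv[p] * w[ci[p]];
        w2[i] = acc;
        res[i] += w_pois * acc;
      }
      w.swap(w2);
    }
    for (int b = 0; b < nact; ++b)
      for (int s = 0; s < n1; ++s)
        alpha[static_cast<size_t>(b) * n2 + map12[s]] +=
          res[static_cast<size_t>(b) * n1 + s];
  } else {
    alpha[map12[init1]] = 1.0;
  }

  // ---------- phase 2: panmictic until absorption ----------------------
  std::vector<double> q2(n2, 0.0), absrate(n2, 0.0);
  for (int t = 0; t < nt2; ++t) {
    q2[t2_from[t]] += t2_rate[t];
    if (t2_to[t] == abs2) absrate[t2_from[t]] += t2_rate[t];
  }
  std::vector<int> live, pos(n2, -1);
  for (int s = 0; s < n2; ++s)
    if (s != abs2) { pos[s] = live.size(); live.push_back(s); }
  const int nl = live.size();
  for (int li = 0; li < nl; ++li) {
    int s = live[li];
    for (int c = 0; c < 4; ++c) q2[s] += lambda[c] * nclass2(s, c);
  }
  // IA = I - A (column-major), A[s,s'] = rate(s->s')/q2[s], s' live
  std::vector<double> IA(nl * nl, 0.0);
  for (int li = 0; li < nl; ++li) IA[li * nl + li] = 1.0;
  for (int t = 0; t < nt2; ++t) {
    int s = t2_from[t], sp = t2_to[t];
    if (sp == abs2) continue;
    IA[pos[sp] * nl + pos[s]] -= t2_rate[t] / q2[s];
  }

  // g[s, r] = P(exactly r further mutations, then absorb | state s)
  std::vector<double> g(static_cast<size_t>(n2) * nact, 0.0);
  std::vector<double> rhs(nl);
  std::vector<double> IAcopy(nl * nl);
  for (int b = 0; b < nact; ++b) { // cells sorted by increasing total count
    bool is_zero = true;
    for (int c = 0; c < 4; ++c) if (cells(b, c) > 0) is_zero = false;
    for (int li = 0; li < nl; ++li) {
      int s = live[li];
      double v = is_zero ? absrate[s] / q2[s] : 0.0;
      for (int c = 0; c < 4; ++c) {
        int db = down[b * 4 + c];
        if (db >= 0) {
          double r = lambda[c] * nclass2(s, c);
          if (r > 0.0) v += r / q2[s] * g[static_cast<size_t>(db) * n2 + s];
        }
      }
      rhs[li] = v;
    }
    IAcopy = IA;
    solve_small(IAcopy, rhs, nl, 1);
    for (int li = 0; li < nl; ++li)
      g[static_cast<size_t>(b) * n2 + live[li]] = rhs[li];
    g[static_cast<size_t>(b) * n2 + abs2] = is_zero ? 1.0 : 0.0;
  }

  // ---------- convolution over the split time --------------------------
  const int nq = query.size();
  NumericVector out(nq);
  for (int qi = 0; qi < nq; ++qi) {
    int k = query[qi];
    double p = 0.0;
    for (int v = 0; v < nact; ++v) {
      bool le = true;
      int rem = 0;
      for (int c = 0; c < 4; ++c) {
        int d = cells(k, c) - cells(v, c);
        if (d < 0) { le = false; break; }
        rem += d * strides[c];
      }
      if (!le) continue;
      int rb = cell_lookup[rem];
      const size_t va = static_cast<size_t>(v) * n2;
      const size_t ra = static_cast<size_t>(rb) * n2;
      for (int s = 0; s < n2; ++s) p += alpha[va + s] * g[ra + s];
    }
    out[qi] = p;
  }
  return out;
}

// Gillespie simulation of per-class branch lengths and Poisson mutation
// counts for independent blocks.  Uses the R random number generator.
// [[Rcpp::export]]
IntegerMatrix simulate_blocks_cpp(int n_blocks, double T, NumericVector lambda,
                                  int n1, int init1,
                                  IntegerVector t1_from, IntegerVector t1_to,
                                  NumericVector t1_rate, IntegerMatrix nclass1,
                                  int n2, int abs2,
                                  IntegerVector t2_from, IntegerVector t2_to,
                                  NumericVector t2_rate, IntegerMatrix nclass2,
                                  IntegerVector map12) {
  const int nt1 = t1_from.size(), nt2 = t2_from.size();
  std::vector<std::vector<int>> adj1(n1), adj2(n2);
  std::vector<double> q1(n1, 0.0), q2(n2, 0.0);
  for (int t = 0; t < nt1; ++t) { adj1[t1_from[t]].push_back(t); q1[t1_from[t]] += t1_rate[t]; }
  for (int t = 0; t < nt2; ++t) { adj2[t2_from[t]].push_back(t); q2[t2_from[t]] += t2_rate[t]; }

  IntegerMatrix out(n_blocks, 4);
  for (int b = 0; b < n_blocks; ++b) {
    double tc[4] = {0.0, 0.0, 0.0, 0.0};
    int s = init1;
    double now = 0.0;
    while (now < T) {
      double dt = (q1[s] > 0.0) ? R::exp_rand() / q1[s] : (T - now);
      if (now + dt >= T || q1[s] <= 0.0) {
        for (int c = 0; c < 4; ++c) tc[c] += nclass1(s, c) * (T - now);
        now = T;
        break;
      }
      for (int c = 0; c < 4; ++c) tc[c] += nclass1(s, c) * dt;
      now += dt;
      double u = unif_rand() * q1[s], acc = 0.0;
      int chosen = adj1[s].back();
      for (int ti : adj1[s]) {
        acc += t1_rate[ti];
        if (u <= acc) { chosen = ti; break; }
      }
      s = t1_to[chosen];
    }
    int s2 = map12[s];
    while (s2 != abs2) {
      double dt = R::exp_rand() / q2[s2];
      for (int c = 0; c < 4; ++c) tc[c] += nclass2(s2, c) * dt;
      double u = unif_rand() * q2[s2], acc = 0.0;
      int chosen = adj2[s2].back();
      for (int ti : adj2[s2]) {
        acc += t2_rate[ti];
        if (u <= acc) { chosen = ti; break; }
      }
      s2 = t2_to[chosen];
    }
    for (int c = 0; c < 4; ++c)
      out(b, c) = static_cast<int>(R::rpois(lambda[c] * tc[c]));
  }
  return out;
}
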