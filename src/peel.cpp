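// Felsenstein pruning over weighted site patterns, with per-node scaling,
// and in-place branch-length optimization by exact coordinate ascent
// (Gauss-Seidel over edges, safeguarded Newton per edge).
//
// A persistent engine object (held from R as an external pointer) carries
// the tree indexing, tip partials and all work buffers for one mixture
// class, so repeated likelihood evaluations during optimization allocate
// nothing.
//
// Conventions shared with the R side:
//  - nodes are 1-based in the edge matrix (ape): tips 1..ntip, internals
//    ntip+1..; the edge matrix is in ape "postorder" (child edges precede
//    the edge above them), root = parent of the last postorder edge;
//  - the rate matrix enters through its eigensystem (U, Uinv, lam) and the
//    stationary frequencies pi; P(t) = U diag(exp(lam t)) Uinv;
//  - gamma categories have equal probability 1/K with rates 'rates'.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstring>
using namespace Rcpp;

static const double SCALE_EPS = 1e-150;
static const double TINY = 1e-300;

struct Peeler {
  int ntip, nnode, npat, K, E, root;
  std::vector<int> par, chi;          // edge endpoints, 0-based
  std::vector<double> tipP;           // [tip][x][pat]
  std::vector<double> down;           // [ni][k][x][pat] internal nodes
  std::vector<double> dscale;         // [ni][k][pat]
  std::vector<char>   dinit;          // [ni][k] first-child-seen flag
  std::vector<std::vector<std::pair<int,int> > > kids; // node -> (child, edge)
  // transient model pointers (valid during one entry from R)
  const double *U, *Uinv, *lam, *pi, *rates, *bl;
  // optimizer state/buffers
  std::vector<double> obl;            // working branch lengths
  std::vector<double> up, upscale;    // [ni][k][x][pat], [ni][k][pat]
  std::vector<double> A, Ascale;      // [k][x][pat], [k][pat]
  std::vector<double> esk, mpat;      // [k][pat], [pat]
  std::vector<double> V, V1, V2, lk;  // per-pattern temporaries
  const double* wt;
  double min_bl, max_bl;

  Peeler(const IntegerMatrix& edge_, int ntip_, const NumericVector& tipp_,
         int npat_, int K_)
    : ntip(ntip_), npat(npat_), K(K_), E(edge_.nrow()) {
    par.resize(E); chi.resize(E);
    int maxnode = 0;
    for (int e = 0; e < E; e++) {
      par[e] = edge_(e, 0) - 1;
      chi[e] = edge_(e, 1) - 1;
      if (par[e] + 1 > maxnode) maxnode = par[e] + 1;
      if (chi[e] + 1 > maxnode) maxnode = chi[e] + 1;
    }
    root = par[E - 1];
    nnode = maxnode - ntip;
    tipP.assign((size_t)ntip * 4 * npat, 0.0);
    for (int tip = 0; tip < ntip; tip++)
      for (int pat = 0; pat < npat; pat++)
        for (int x = 0; x < 4; x++)
          tipP[((size_t)tip * 4 + x) * npat + pat] =
            tipp_[x + 4 * (size_t)pat + 4 * (size_t)npat * tip];
    down.assign((size_t)nnode * K * 4 * npat, 0.0);
    dscale.assign((size_t)nnode * K * npat, 0.0);
    dinit.assign((size_t)nnode * K, 0);
    kids.assign(ntip + nnode, std::vector<std::pair<int,int> >());
    for (int e = 0; e < E; e++)
      kids[par[e]].push_back(std::make_pair(chi[e], e));
    up.assign((size_t)nnode * K * 4 * npat, 0.0);
    upscale.assign((size_t)nnode * K * npat, 0.0);
    A.assign((size_t)K * 4 * npat, 0.0);
    Ascale.assign((size_t)K * npat, 0.0);
    esk.assign((size_t)K * npat, 1.0);
    mpat.assign(npat, 0.0);
    V.resize(npat); V1.resize(npat); V2.resize(npat);
    lk.resize((size_t)K * npat);
  }

  inline double* downp(int node, int k) {
    return &down[(((size_t)(node - ntip) * K + k) * 4) * npat];
  }
  inline double* dscalep(int node, int k) {
    return &dscale[((size_t)(node - ntip) * K + k) * npat];
  }
  inline const double* childp(int node, int k) {
    if (node < ntip) return &tipP[(size_t)node * 4 * npat];
    return downp(node, k);
  }
  inline const double* childscale(int node, int k) {
    if (node < ntip) return 0;
    return dscalep(node, k);
  }
  inline double* upp(int node, int k) {
    return &up[(((size_t)(node - ntip) * K + k) * 4) * npat];
  }
  inline double* upscalep(int node, int k) {
    return &upscale[((size_t)(node - ntip) * K + k) * npat];
  }
  inline double* Ak(int k) { return &A[(size_t)k * 4 * npat]; }

  void pmat(double t, double r, double* P, double* P1 = 0, double* P2 = 0) const {
    double el[4], el1[4], el2[4];
    for (int i = 0; i < 4; i++) {
      double lr = lam[i] * r;
      el[i] = std::exp(lr * t);
      if (P1) el1[i] = lr * el[i];
      if (P2) el2[i] = lr * lr * el[i];
    }
    for (int x = 0; x < 4; x++)
      for (int y = 0; y < 4; y++) {
        double s = 0, s1 = 0, s2 = 0;
        for (int i = 0; i < 4; i++) {
          double uy = Uinv[i + 4 * y], ux = U[x + 4 * i];
          s += ux * el[i] * uy;
          if (P1) s1 += ux * el1[i] * uy;
          if (P2) s2 += ux * el2[i] * uy;
        }
        P[x * 4 + y] = s > 0 ? s : 0;
        if (P1) P1[x * 4 + y] = s1;
        if (P2) P2[x * 4 + y] = s2;
      }
  }

  // acc[x][] (*)= sum_y P[x][y] child[y][]; 'first' writes instead of
  // multiplying; child scale is added and underflow-prone patterns rescaled.
  void mult_msg(double* acc, double* accscale, const double* P,
                const double* cp, const double* cs, bool first) {
    for (int x = 0; x < 4; x++) {
      double p0 = P[x * 4], p1 = P[x * 4 + 1], p2 = P[x * 4 + 2], p3 = P[x * 4 + 3];
      double* a = acc + (size_t)x * npat;
      const double *c0 = cp, *c1 = cp + npat, *c2 = cp + 2 * (size_t)npat,
                   *c3 = cp + 3 * (size_t)npat;
      if (first)
        for (int pat = 0; pat < npat; pat++)
          a[pat] = p0 * c0[pat] + p1 * c1[pat] + p2 * c2[pat] + p3 * c3[pat];
      else
        for (int pat = 0; pat < npat; pat++)
          a[pat] *= p0 * c0[pat] + p1 * c1[pat] + p2 * c2[pat] + p3 * c3[pat];
    }
    if (first) {
      if (cs) std::memcpy(accscale, cs, sizeof(double) * npat);
      else    std::memset(accscale, 0, sizeof(double) * npat);
    } else if (cs) {
      for (int pat = 0; pat < npat; pat++) accscale[pat] += cs[pat];
    }
    for (int pat = 0; pat < npat; pat++) {
      double mx = acc[pat];
      double v1 = acc[(size_t)npat + pat], v2 = acc[2 * (size_t)npat + pat],
             v3 = acc[3 * (size_t)npat + pat];
      if (v1 > mx) mx = v1;
      if (v2 > mx) mx = v2;
      if (v3 > mx) mx = v3;
      if (mx < SCALE_EPS && mx > 0) {
        double inv = 1.0 / mx;
        for (int x = 0; x < 4; x++) acc[(size_t)x * npat + pat] *= inv;
        accscale[pat] += std::log(mx);
      }
    }
  }

  void update_down(int u) {
    double P[16];
    for (int k = 0; k < K; k++) {
      double* d = downp(u, k);
      double* s = dscalep(u, k);
      for (size_t c = 0; c < kids[u].size(); c++) {
        int v = kids[u][c].first, e = kids[u][c].second;
        pmat(bl[e], rates[k], P);
        mult_msg(d, s, P, childp(v, k), childscale(v, k), c == 0);
      }
    }
  }

  void fill_down() {
    std::fill(dinit.begin(), dinit.end(), 0);
    double P[16];
    for (int k = 0; k < K; k++) {
      for (int e = 0; e < E; e++) {
        int u = par[e], v = chi[e];
        char& init = dinit[(size_t)(u - ntip) * K + k];
        pmat(bl[e], rates[k], P);
        mult_msg(downp(u, k), dscalep(u, k), P, childp(v, k),
                 childscale(v, k), !init);
        init = 1;
      }
    }
  }

  void site_loglik(double* out) {
    for (int k = 0; k < K; k++) {
      const double* d = downp(root, k);
      const double* s = dscalep(root, k);
      double* o = &lk[(size_t)k * npat];
      for (int pat = 0; pat < npat; pat++) {
        double v = pi[0] * d[pat] + pi[1] * d[(size_t)npat + pat] +
                   pi[2] * d[2 * (size_t)npat + pat] + pi[3] * d[3 * (size_t)npat + pat];
        o[pat] = std::log(v > TINY ? v : TINY) + s[pat];
      }
    }
    double lK = std::log((double)K);
    for (int pat = 0; pat < npat; pat++) {
      double m = lk[pat];
      for (int k = 1; k < K; k++) {
        double v = lk[(size_t)k * npat + pat];
        if (v > m) m = v;
      }
      double acc = 0;
      for (int k = 0; k < K; k++) acc += std::exp(lk[(size_t)k * npat + pat] - m);
      out[pat] = m + std::log(acc) - lK;
    }
  }

  // ---- branch-length optimization --------------------------------------

  void set_scales() {
    bool any = false;
    for (int k = 0; k < K && !any; k++) {
      const double* as = &Ascale[(size_t)k * npat];
      const double* ds = dvscale[k];
      for (int pat = 0; pat < npat; pat++)
        if (as[pat] != 0 || (ds && ds[pat] != 0)) { any = true; break; }
    }
    if (!any) {
      std::fill(esk.begin(), esk.end(), 1.0);
      std::fill(mpat.begin(), mpat.end(), 0.0);
      return;
    }
    for (int pat = 0; pat < npat; pat++) {
      double m = -1e308;
      for (int k = 0; k < K; k++) {
        double s = Ascale[(size_t)k * npat + pat] +
                   (dvscale[k] ? dvscale[k][pat] : 0.0);
        esk[(size_t)k * npat + pat] = s;       // stash raw scale
        if (s > m) m = s;
      }
      mpat[pat] = m;
      for (int k = 0; k < K; k++) {
        double s = esk[(size_t)k * npat + pat];
        esk[(size_t)k * npat + pat] = (s == m) ? 1.0 : std::exp(s - m);
      }
    }
  }

  const double* dvp[8];       // down partial of the pruned-side node, per k
  const double* dvscale[8];

  double edge_obj(double t) {
    double P[16];
    std::fill(V.begin(), V.end(), 0.0);
    for (int k = 0; k < K; k++) {
      pmat(t, rates[k], P);
      const double* a = Ak(k);
      const double* d = dvp[k];
      const double* es = &esk[(size_t)k * npat];
      for (int pat = 0; pat < npat; pat++) {
        double dd0 = d[pat], dd1 = d[(size_t)npat + pat],
               dd2 = d[2 * (size_t)npat + pat], dd3 = d[3 * (size_t)npat + pat];
        double tot = 0;
        for (int x = 0; x < 4; x++) {
          double ax = a[(size_t)x * npat + pat];
          const double* Px = &P[x * 4];
          tot += ax * (Px[0] * dd0 + Px[1] * dd1 + Px[2] * dd2 + Px[3] * dd3);
        }
        V[pat] += tot * es[pat];
      }
    }
    double f = 0;
    for (int pat = 0; pat < npat; pat++)
      if (wt[pat] != 0)
        f += wt[pat] * (std::log(V[pat] > TINY ? V[pat] : TINY) + mpat[pat]);
    return f;
  }

  void edge_derivs(double t, double& d1, double& d2) {
    double P[16], P1[16], P2[16];
    std::fill(V.begin(), V.end(), 0.0);
    std::fill(V1.begin(), V1.end(), 0.0);
    std::fill(V2.begin(), V2.end(), 0.0);
    for (int k = 0; k < K; k++) {
      pmat(t, rates[k], P, P1, P2);
      const double* a = Ak(k);
      const double* d = dvp[k];
      const double* es = &esk[(size_t)k * npat];
      for (int pat = 0; pat < npat; pat++) {
        double dd0 = d[pat], dd1 = d[(size_t)npat + pat],
               dd2 = d[2 * (size_t)npat + pat], dd3 = d[3 * (size_t)npat + pat];
        double t0 = 0, t1 = 0, t2 = 0;
        for (int x = 0; x < 4; x++) {
          double ax = a[(size_t)x * npat + pat];
          if (ax == 0) continue;
          t0 += ax * (P[x*4] * dd0 + P[x*4+1] * dd1 + P[x*4+2] * dd2 + P[x*4+3] * dd3);
          t1 += ax * (P1[x*4] * dd0 + P1[x*4+1] * dd1 + P1[x*4+2] * dd2 + P1[x*4+3] * dd3);
          t2 += ax * (P2[x*4] * dd0 + P2[x*4+1] * dd1 + P2[x*4+2] * dd2 + P2[x*4+3] * dd3);
        }
        double e = es[pat];
        V[pat] += t0 * e; V1[pat] += t1 * e; V2[pat] += t2 * e;
      }
    }
    d1 = 0; d2 = 0;
    for (int pat = 0; pat < npat; pat++) {
      if (wt[pat] == 0) continue;
      double v = V[pat] > TINY ? V[pat] : TINY;
      double r1 = V1[pat] / v;
      d1 += wt[pat] * r1;
      d2 += wt[pat] * (V2[pat] / v - r1 * r1);
    }
  }

  double optimize_edge(double t0) {
    double t = t0 < min_bl ? min_bl : (t0 > max_bl ? max_bl : t0);
    double f0 = edge_obj(t), tstart = t;
    double lo = min_bl, hi = max_bl;
    for (int it = 0; it < 12; it++) {
      double d1, d2;
      edge_derivs(t, d1, d2);
      if (d1 > 0) lo = t; else hi = t;
      double tn;
      if (d2 < 0) {
        tn = t - d1 / d2;
        if (!(tn > lo && tn < hi)) tn = 0.5 * (lo + hi);
      } else tn = 0.5 * (lo + hi);
      if (std::fabs(tn - t) < 1e-6 * (t + 1e-3)) { t = tn; break; }
      t = tn;
      if (hi - lo < 1e-9) break;
    }
    double f1 = edge_obj(t);
    if (!(f1 >= f0 - 1e-9) || !R_finite(t)) return tstart;
    return t;
  }

  void dfs(int u) {
    double P[16];
    for (size_t c = 0; c < kids[u].size(); c++) {
      int v = kids[u][c].first, e = kids[u][c].second;
      for (int k = 0; k < K; k++) {
        double* a = Ak(k);
        double* as = &Ascale[(size_t)k * npat];
        std::memcpy(a, upp(u, k), sizeof(double) * 4 * (size_t)npat);
        std::memcpy(as, upscalep(u, k), sizeof(double) * npat);
        for (size_t c2 = 0; c2 < kids[u].size(); c2++) {
          if (c2 == c) continue;
          int v2 = kids[u][c2].first, e2 = kids[u][c2].second;
          pmat(obl[e2], rates[k], P);
          mult_msg(a, as, P, childp(v2, k), childscale(v2, k), false);
        }
        dvp[k] = childp(v, k);
        dvscale[k] = childscale(v, k);
      }
      set_scales();
      obl[e] = optimize_edge(obl[e]);
      if (v >= ntip) {
        for (int k = 0; k < K; k++) {
          pmat(obl[e], rates[k], P);
          const double* a = Ak(k);
          double* uv = upp(v, k);
          double* uvs = upscalep(v, k);
          for (int y = 0; y < 4; y++) {
            double* o = uv + (size_t)y * npat;
            double py0 = P[y], py1 = P[4 + y], py2 = P[8 + y], py3 = P[12 + y];
            const double *a0 = a, *a1 = a + npat, *a2 = a + 2 * (size_t)npat,
                         *a3 = a + 3 * (size_t)npat;
            for (int pat = 0; pat < npat; pat++)
              o[pat] = py0 * a0[pat] + py1 * a1[pat] + py2 * a2[pat] + py3 * a3[pat];
          }
          std::memcpy(uvs, &Ascale[(size_t)k * npat], sizeof(double) * npat);
          for (int pat = 0; pat < npat; pat++) {
            double mx = uv[pat];
            for (int y = 1; y < 4; y++) {
              double w = uv[(size_t)y * npat + pat];
              if (w > mx) mx = w;
            }
            if (mx < SCALE_EPS && mx > 0) {
              double inv = 1.0 / mx;
              for (int y = 0; y < 4; y++) uv[(size_t)y * npat + pat] *= inv;
              uvs[pat] += std::log(mx);
            }
          }
        }
        dfs(v);
        bl = &obl[0];
        update_down(v);
      }
    }
  }

  List optimize(NumericVector bl_in, double minb, double maxb,
                int max_sweeps, double tol) {
    obl.assign(bl_in.begin(), bl_in.end());
    min_bl = minb; max_bl = maxb;
    bl = &obl[0];
    fill_down();
    std::vector<double> sl(npat);
    site_loglik(&sl[0]);
    double f = 0;
    for (int pat = 0; pat < npat; pat++) f += wt[pat] * sl[pat];
    double f_init = f;
    for (int s = 0; s < max_sweeps; s++) {
      for (int k = 0; k < K; k++) {
        double* u = upp(root, k);
        for (int x = 0; x < 4; x++)
          std::fill(u + (size_t)x * npat, u + (size_t)(x + 1) * npat, pi[x]);
        std::memset(upscalep(root, k), 0, sizeof(double) * npat);
      }
      dfs(root);
      bl = &obl[0];
      fill_down();
      site_loglik(&sl[0]);
      double f_new = 0;
      for (int pat = 0; pat < npat; pat++) f_new += wt[pat] * sl[pat];
      double gain = f_new - f;
      f = f_new;
      if (gain < tol) break;
    }
    if (f < f_init)
      return List::create(_["bl"] = bl_in, _["loglik"] = f_init,
                          _["improved"] = false);
    return List::create(_["bl"] = NumericVector(obl.begin(), obl.end()),
                        _["loglik"] = f, _["improved"] = true);
  }
};

// Eigensystem of a normalized GTR rate matrix via cyclic Jacobi on the
// symmetrized matrix diag(sqrt(pi)) Q diag(1/sqrt(pi)).  Returns U (4x4),
// Uinv (4x4) and eigenvalues lam such that Q = U diag(lam) Uinv.
// [[Rcpp::export]]
List gtr_eigen_cpp(NumericVector rates, NumericVector pi) {
  double Q[4][4] = {{0}};
  int ia[6] = {0, 0, 0, 1, 1, 2}, ja[6] = {1, 2, 3, 2, 3, 3};
  for (int k = 0; k < 6; k++) {
    int i = ia[k], j = ja[k];
    Q[i][j] = rates[k] * pi[j];
    Q[j][i] = rates[k] * pi[i];
  }
  double mu = 0;
  for (int i = 0; i < 4; i++) {
    double rs = 0;
    for (int j = 0; j < 4; j++) if (j != i) rs += Q[i][j];
    Q[i][i] = -rs;
    mu += pi[i] * rs;
  }
  if (!(mu > 0)) stop("degenerate rate matrix");
  double sp[4];
  for (int i = 0; i < 4; i++) sp[i] = std::sqrt(pi[i]);
  double S[4][4], V[4][4] = {{1,0,0,0},{0,1,0,0},{0,0,1,0},{0,0,0,1}};
  for (int i = 0; i < 4; i++)
    for (int j = 0; j < 4; j++)
      S[i][j] = Q[i][j] / mu * sp[i] / sp[j];
  for (int i = 0; i < 4; i++)
    for (int j = i + 1; j < 4; j++) {
      double a = 0.5 * (S[i][j] + S[j][i]);
      S[i][j] = S[j][i] = a;
    }
  for (int sweep = 0; sweep < 50; sweep++) {
    double off = 0;
    for (int i = 0; i < 4; i++)
      for (int j = i + 1; j < 4; j++) off += S[i][j] * S[i][j];
    if (off < 1e-26) break;
    for (int p = 0; p < 4; p++)
      for (int q = p + 1; q < 4; q++) {
        if (std::fabs(S[p][q]) < 1e-30) continue;
        double theta = (S[q][q] - S[p][p]) / (2.0 * S[p][q]);
        double t = (theta >= 0 ? 1.0 : -1.0) /
                   (std::fabs(theta) + std::sqrt(theta * theta + 1.0));
        double c = 1.0 / std::sqrt(t * t + 1.0), s = t * c;
        for (int k = 0; k < 4; k++) {
          double skp = S[k][p], skq = S[k][q];
          S[k][p] = c * skp - s * skq;
          S[k][q] = s * skp + c * skq;
        }
        for (int k = 0; k < 4; k++) {
          double spk = S[p][k], sqk = S[q][k];
          S[p][k] = c * spk - s * sqk;
          S[q][k] = s * spk + c * sqk;
        }
        for (int k = 0; k < 4; k++) {
          double vkp = V[k][p], vkq = V[k][q];
          V[k][p] = c * vkp - s * vkq;
          V[k][q] = s * vkp + c * vkq;
        }
      }
  }
  NumericMatrix U(4, 4), Uinv(4, 4);
  NumericVector lam(4);
  for (int i = 0; i < 4; i++) lam[i] = S[i][i];
  for (int i = 0; i < 4; i++)
    for (int j = 0; j < 4; j++) {
      U(i, j) = V[i][j] / sp[i];
      Uinv(j, i) = V[i][j] * sp[i];
    }
  return List::create(_["vectors"] = U, _["inv_vectors"] = Uinv,
                      _["values"] = lam);
}

// [[Rcpp::export]]
SEXP peeler_create(IntegerMatrix edge, int ntip, NumericVector tipp,
                   int npat, int ncat) {
  if (ncat > 8) stop("at most 8 rate categories are supported");
  XPtr<Peeler> xp(new Peeler(edge, ntip, tipp, npat, ncat), true);
  return xp;
}

// [[Rcpp::export]]
NumericVector peeler_loglik(SEXP xp_, NumericVector bl, NumericVector rates,
                            NumericMatrix U, NumericMatrix Uinv,
                            NumericVector lam, NumericVector pi) {
  XPtr<Peeler> xp(xp_);
  Peeler& p = *xp;
  if ((int)rates.size() != p.K) stop("rate category count mismatch");
  if ((int)bl.size() != p.E) stop("branch length count mismatch");
  p.U = &U[0]; p.Uinv = &Uinv[0]; p.lam = &lam[0]; p.pi = &pi[0];
  p.rates = &rates[0]; p.bl = &bl[0];
  p.fill_down();
  NumericVector out(p.npat);
  p.site_loglik(&out[0]);
  return out;
}

// [[Rcpp::export]]
List peeler_optimize(SEXP xp_, NumericVector bl, NumericVector rates,
                     NumericMatrix U, NumericMatrix Uinv,
                     NumericVector lam, NumericVector pi,
                     NumericVector wt, double min_bl, double max_bl,
                     int max_sweeps, double tol) {
  XPtr<Peeler> xp(xp_);
  Peeler& p = *xp;
  if ((int)rates.size() != p.K) stop("rate category count mismatch");
  if ((int)wt.size() != p.npat) stop("pattern weight count mismatch");
  p.U = &U[0]; p.Uinv = &Uinv[0]; p.lam = &lam[0]; p.pi = &pi[0];
  p.rates = &rates[0]; p.wt = &wt[0];
  return p.optimize(bl, min_bl, max_bl, max_sweeps, tol);
}
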