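#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Vertex-model force/energy kernel.
//
// The mesh is passed as flat arrays: edge endpoints (0-based tail/head), a
// CSR layout of cell -> (edge, sign) with sign +1 when the edge's stored
// direction agrees with the cell's counter-clockwise traversal, and per-cell
// material parameters.  The energy is
//   E = sum_c sigma_c [A ln(A/A0) - A + A0]
//     + sum_c sigma_c Gamma [L ln(L/L0) - L + L0]
//     + P_ext * sum_c A
// so dE/dA = sigma ln(A/A0) + P_ext and dE/dL = sigma Gamma ln(L/L0), and
// F = -grad E assembles edge-wise: area terms through the shoelace gradient,
// perimeter terms along unit edge tangents.

struct MeshArrays {
  int nv, ne, nc;
  const int *tail, *head;
  const int *cptr, *cedge, *csign;
  const double *sigma, *A0;
  double gamma, L0, Pext;
};

// Returns energy (NaN on degenerate geometry: non-positive area/perimeter or
// zero-length edge).  If Fx/Fy are non-null they receive -grad E.  If
// eligible is non-null, *minlen/*minedge get the shortest eligible edge.
static double energy_forces(const MeshArrays &m, const double *x,
                            const double *y, double *Fx, double *Fy,
                            const int *eligible, double *minlen, int *minedge,
                            int *badedge) {
  std::vector<double> ex(m.ne), ey(m.ne), len(m.ne), crs(m.ne);
  double ml = R_PosInf;
  int me = -1;
  for (int e = 0; e < m.ne; ++e) {
    const int t = m.tail[e], h = m.head[e];
    ex[e] = x[h] - x[t];
    ey[e] = y[h] - y[t];
    len[e] = std::sqrt(ex[e] * ex[e] + ey[e] * ey[e]);
    crs[e] = x[t] * y[h] - y[t] * x[h];
    if (len[e] <= 0.0) {
      if (badedge) *badedge = e;
      return NA_REAL;
    }
    if (eligible && eligible[e] && len[e] < ml) {
      ml = len[e];
      me = e;
    }
  }
  if (minlen) *minlen = ml;
  if (minedge) *minedge = me;

  const bool wantF = (Fx != nullptr);
  std::vector<double> ue, ge;
  if (wantF) {
    ue.assign(m.ne, 0.0);
    ge.assign(m.ne, 0.0);
  }
  double E = 0.0;
  for (int c = 0; c < m.nc; ++c) {
    double A = 0.0, L = 0.0;
    for (int k = m.cptr[c]; k < m.cptr[c + 1]; ++k) {
      const int e = m.cedge[k];
      A += 0.5 * m.csign[k] * crs[e];
      L += len[e];
    }
    if (!(A > 0.0) || !(L > 0.0)) return NA_REAL;
    const double la = std::log(A / m.A0[c]);
    const double ll = std::log(L / m.L0);
    E += m.sigma[c] * (A * la - A + m.A0[c]);
    E += m.sigma[c] * m.gamma * (L * ll - L + m.L0);
    E += m.Pext * A;
    if (wantF) {
      const double W = m.sigma[c] * la + m.Pext;        // dE/dA_c
      const double tau = m.sigma[c] * m.gamma * ll;     // dE/dL_c
      for (int k = m.cptr[c]; k < m.cptr[c + 1]; ++k) {
        const int e = m.cedge[k];
        ue[e] += m.csign[k] * W;
        ge[e] += tau;
      }
    }
  }
  if (wantF) {
    for (int e = 0; e < m.ne; ++e) {
      const int t = m.tail[e], h = m.head[e];
      // area (shoelace) gradient, weighted by signed dE/dA
      Fx[t] -= 0.5 * ue[e] * y[h];
      Fy[t] += 0.5 * ue[e] * x[h];
      Fx[h] += 0.5 * ue[e] * y[t];
      Fy[h] -= 0.5 * ue[e] * x[t];
      // perimeter gradient along unit tangent
      const double ux = ex[e] / len[e], uy = ey[e] / len[e];
      Fx[h] -= ge[e] * ux;
      Fy[h] -= ge[e] * uy;
      Fx[t] += ge[e] * ux;
      Fy[t] += ge[e] * uy;
    }
  }
  return E;
}

static MeshArrays make_arrays(const NumericMatrix &V, const IntegerVector &tail,
                              const IntegerVector &head,
                              const IntegerVector &cptr,
                              const IntegerVector &cedge,
                              const IntegerVector &csign,
                              const NumericVector &sigma,
                              const NumericVector &A0, double gamma, double L0,
                              double Pext) {
  MeshArrays m;
  m.nv = V.nrow();
  m.ne = tail.size();
  m.nc = cptr.size() - 1;
  m.tail = INTEGER(tail);
  m.head = INTEGER(head);
  m.cptr = INTEGER(cptr);
  m.cedge = INTEGER(cedge);
  m.csign = INTEGER(csign);
  m.sigma = REAL(sigma);
  m.A0 = REAL(A0);
  m.gamma = gamma;
  m.L0 = L0;
  m.Pext = Pext;
  return m;
}

// [[Rcpp::export]]
double mesh_energy_cpp(NumericMatrix V, IntegerVector tail, IntegerVector head,
                       IntegerVector cptr, IntegerVector cedge,
                       IntegerVector csign, NumericVector sigma,
                       NumericVector A0, double gamma, double L0, double Pext) {
  MeshArrays m =
      make_arrays(V, tail, head, cptr, cedge, csign, sigma, A0, gamma, L0, Pext);
  int bad = -1;
  double E = energy_forces(m, &V(0, 0), &V(0, 1), nullptr, nullptr, nullptr,
                           nullptr, nullptr, &bad);
  if (ISNAN(E) && bad >= 0)
    stop("degenerate (zero-length) edge %d", bad + 1);
  return E;
}

// [[Rcpp::export]]
List mesh_forces_cpp(NumericMatrix V, IntegerVector tail, IntegerVector head,
                     IntegerVector cptr, IntegerVector cedge,
                     IntegerVector csign, NumericVector sigma, NumericVector A0,
                     double gamma, double L0, double Pext) {
  MeshArrays m =
      make_arrays(V, tail, head, cptr, cedge, csign, sigma, A0, gamma, L0, Pext);
  NumericMatrix F(m.nv, 2);
  std::fill(F.begin(), F.end(), 0.0);
  int bad = -1;
  double E = energy_forces(m, &V(0, 0), &V(0, 1), &F(0, 0), &F(0, 1),
                           nullptr, nullptr, nullptr, &bad);
  if (ISNAN(E) && bad >= 0)
    stop("degenerate (zero-length) edge %d", bad + 1);
  return List::create(_["force"] = F, _["energy"] = E);
}

// Overdamped explicit Euler with adaptive step: halve dt when a trial step
// raises the energy, grow dt by 1.1 after 10 consecutive accepted steps.
// Stops when max |F| < force_tol (converged), when an eligible edge drops
// below t1_len (caller performs the T1 and resumes), at max_steps, or when
// dt underflows (stalled).
// [[Rcpp::export]]
List relax_cpp(NumericMatrix V, IntegerVector tail, IntegerVector head,
               IntegerVector cptr, IntegerVector cedge, IntegerVector csign,
               NumericVector sigma, NumericVector A0, double gamma, double L0,
               double Pext, double eta, double dt0, double force_tol,
               int max_steps, double t1_len, IntegerVector eligible) {
  MeshArrays m =
      make_arrays(V, tail, head, cptr, cedge, csign, sigma, A0, gamma, L0, Pext);
  const int nv = m.nv;
  NumericMatrix X = clone(V);
  std::vector<double> Fx(nv), Fy(nv), xn(nv), yn(nv);
  double *x = &X(0, 0), *y = &X(0, 1);

  const int *elig = (t1_len > 0.0) ? INTEGER(eligible) : nullptr;
  double dt = dt0, minlen = R_PosInf, max_inc = 0.0;
  int minedge = -1, bad = -1, accepts = 0, steps = 0;
  std::string status = "max_steps";
  int t1_edge = -1;

  std::fill(Fx.begin(), Fx.end(), 0.0);
  std::fill(Fy.begin(), Fy.end(), 0.0);
  double E = energy_forces(m, x, y, Fx.data(), Fy.data(), elig, &minlen,
                           &minedge, &bad);
  if (ISNAN(E)) stop("degenerate geometry at entry (edge %d)", bad + 1);

  for (steps = 0; steps < max_steps; ++steps) {
    double maxF = 0.0;
    for (int v = 0; v < nv; ++v) {
      const double f = std::sqrt(Fx[v] * Fx[v] + Fy[v] * Fy[v]);
      if (f > maxF) maxF = f;
    }
    if (maxF < force_tol) {
      status = "converged";
      break;
    }
    if (elig && minedge >= 0 && minlen < t1_len) {
      status = "t1";
      t1_edge = minedge;
      break;
    }
    // trial step
    for (int v = 0; v < nv; ++v) {
      xn[v] = x[v] + (dt / eta) * Fx[v];
      yn[v] = y[v] + (dt / eta) * Fy[v];
    }
    double En = energy_forces(m, xn.data(), yn.data(), nullptr, nullptr,
                              nullptr, nullptr, nullptr, &bad);
    if (!ISNAN(En) && En <= E + 1e-12 * (std::fabs(E) + 1.0)) {
      if (En > E) max_inc = std::max(max_inc, En - E);
      std::copy(xn.begin(), xn.end(), x);
      std::copy(yn.begin(), yn.end(), y);
      std::fill(Fx.begin(), Fx.end(), 0.0);
      std::fill(Fy.begin(), Fy.end(), 0.0);
      E = energy_forces(m, x, y, Fx.data(), Fy.data(), elig, &minlen, &minedge,
                        &bad);
      if (++accepts >= 10) {
        dt *= 1.1;
        accepts = 0;
      }
    } else {
      dt *= 0.5;
      accepts = 0;
      if (dt < 1e-14) {
        status = "stalled";
        break;
      }
    }
  }
  double maxF = 0.0;
  for (int v = 0; v < nv; ++v) {
    const double f = std::sqrt(Fx[v] * Fx[v] + Fy[v] * Fy[v]);
    if (f > maxF) maxF = f;
  }
  return List::create(_["vertices"] = X, _["steps"] = steps,
                      _["status"] = status, _["energy"] = E,
                      _["max_force"] = maxF, _["t1_edge"] = t1_edge + 1,
                      _["max_energy_increase"] = max_inc, _["dt"] = dt);
}
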