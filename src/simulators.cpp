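#include <Rcpp.h>
using namespace Rcpp;

// Periodic 4-neighbour Laplacian helpers operate on column-major n x n grids.
// All simulators draw from R's RNG stream so results are reproducible under
// set.seed() on the R side.

static inline int wrap(int i, int n) { return (i + n) % n; }

// precomputed periodic neighbour indices avoid a modulo per lookup
struct Wrap {
  std::vector<int> up, dn;
  explicit Wrap(int n) : up(n), dn(n) {
    for (int i = 0; i < n; ++i) { up[i] = wrap(i - 1, n); dn[i] = wrap(i + 1, n); }
  }
};

static inline double lap4w(const double* m, int i, int j, int n,
                           const Wrap& w) {
  return m[w.up[i] + j * n] + m[w.dn[i] + j * n] +
         m[i + w.up[j] * n] + m[i + w.dn[j] * n] - 4.0 * m[i + j * n];
}

// ---------------------------------------------------------------------------
// Data set 1: local positive feedback lattice.
// Biomass V grows logistically at a rate set by local water W (replenished by
// rainfall R, depleted by uptake), is lost to saturating grazing, diffuses to
// neighbours, and is forced by multiplicative noise. Fold bifurcation in R.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List sim_local_cpp(int n, NumericVector drivers, List params, double dt,
                   double t_first, double t_next) {
  double rw = params["rw"], lambda = params["lambda"], rho = params["rho"],
         K = params["K"], c = params["c"], h2 = params["h2"],
         Dv = params["Dv"], Dw = params["Dw"], sigma = params["sigma"],
         v0 = params["v0"];
  int nd = drivers.size();
  NumericMatrix V(n, n), W(n, n), Vn(n, n), Wn(n, n);
  Wrap wr(n);
  double sqdt = std::sqrt(dt);
  // start near the vegetated state of the first (most benign) driver
  for (int k = 0; k < n * n; ++k) {
    V[k] = v0 * (0.9 + 0.2 * unif_rand());
    W[k] = drivers[0] / rw;
  }
  List out(nd);
  for (int di = 0; di < nd; ++di) {
    double R = drivers[di];
    int steps = (int)std::ceil((di == 0 ? t_first : t_next) / dt);
    for (int s = 0; s < steps; ++s) {
      const double* Vp = &V[0];
      const double* Wp = &W[0];
      for (int j = 0; j < n; ++j) {
        for (int i = 0; i < n; ++i) {
          double v = V(i, j), w = W(i, j);
          double dw = R - rw * w - lambda * w * v + Dw * lap4w(Wp, i, j, n, wr);
          double grow = rho * w * v * (1.0 - v / K);
          double graze = c * v * v / (v * v + h2);
          double dv = grow - graze + Dv * lap4w(Vp, i, j, n, wr);
          double nw = w + dt * dw;
          double nv = v + dt * dv + sigma * v * sqdt * norm_rand();
          if (nv < 0) nv = 0;
          if (nw < 0) nw = 0;
          Wn(i, j) = nw;
          Vn(i, j) = nv;
        }
      }
      std::swap(V, Vn);
      std::swap(W, Wn);
      if (s % 200 == 0) {
        for (int k = 0; k < n * n; ++k) {
          if (!R_FINITE(V[k]) || !R_FINITE(W[k]))
            stop("Numerical instability at driver %f, step %d", R, s);
        }
      }
    }
    out[di] = clone(V);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Data set 2: three-state facilitation cellular automaton.
// States: 1 = vegetated (+), 0 = empty (o), -1 = degraded (-).
// Transitions per update step (synchronous on the previous state, or
// asynchronous single-cell updates):
//   empty -> vegetated    : (delta*rho_v + (1-delta)*q_v) * max(0, b - c*rho_v)
//   empty -> degraded     : d
//   vegetated -> empty    : m
//   degraded -> empty     : r + f*q_v         (local facilitation)
// with rho_v the global vegetated fraction and q_v the local vegetated
// fraction among the 4 neighbours. b is environmental quality (driver;
// harsher = lower b).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List sim_ca_cpp(int n, NumericVector b_values, List params,
                int steps_first, int steps_next, bool async) {
  double m = params["m"], d = params["d"], r = params["r"],
         f = params["f"], delta = params["delta"], c = params["c"];
  int nd = b_values.size();
  IntegerMatrix S(n, n), Sn(n, n);
  Wrap wr(n);
  // initial mix: 40% vegetated, 40% empty, 20% degraded
  for (int k = 0; k < n * n; ++k) {
    double u = unif_rand();
    S[k] = (u < 0.4) ? 1 : (u < 0.8 ? 0 : -1);
  }
  List out(nd);
  for (int di = 0; di < nd; ++di) {
    double b = b_values[di];
    int steps = (di == 0) ? steps_first : steps_next;
    for (int s = 0; s < steps; ++s) {
      int nveg = 0;
      for (int k = 0; k < n * n; ++k) if (S[k] == 1) ++nveg;
      double rho_v = (double)nveg / (n * n);
      double recol = b - c * rho_v;
      if (recol < 0) recol = 0;
      int sweeps = async ? n * n : 1;
      for (int sw = 0; sw < sweeps; ++sw) {
        int i0 = 0, i1 = n, j0 = 0, j1 = n;
        if (async) {
          int cell = (int)(unif_rand() * n * n);
          if (cell >= n * n) cell = n * n - 1;
          i0 = cell % n; i1 = i0 + 1; j0 = cell / n; j1 = j0 + 1;
        }
        for (int j = j0; j < j1; ++j) {
          for (int i = i0; i < i1; ++i) {
            int st = S(i, j);
            double qv = (double)((S(wr.up[i], j) == 1) +
                                 (S(wr.dn[i], j) == 1) +
                                 (S(i, wr.up[j]) == 1) +
                                 (S(i, wr.dn[j]) == 1)) / 4.0;
            int ns = st;
            double u = unif_rand();
            if (st == 0) {
              double pcol = (delta * rho_v + (1.0 - delta) * qv) * recol;
              if (pcol > 1.0 || pcol + d > 1.0)
                stop("Transition probability outside [0,1] (colonization %f + degradation %f)",
                     pcol, d);
              if (u < pcol) ns = 1;
              else if (u < pcol + d) ns = -1;
            } else if (st == 1) {
              if (m > 1.0) stop("Mortality probability above 1");
              if (u < m) ns = 0;
            } else {
              double preg = r + f * qv;
              if (preg > 1.0)
                stop("Regeneration probability %f above 1", preg);
              if (u < preg) ns = 0;
            }
            if (async) S(i, j) = ns; else Sn(i, j) = ns;
          }
        }
      }
      if (!async) std::swap(S, Sn);
    }
    out[di] = clone(S);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Data set 3: scale-dependent feedback (Turing) model; three coupled PDEs for
// plant biomass P, soil water W and surface water O on a periodic lattice,
// explicit Euler with 5-point Laplacian. Driver is rainfall Rn.
//   dP/dt = cg * gmax * W/(W+k1) * P - dd * P            + Dp lap P (+ noise)
//   dW/dt = al * O * (P + k2*W0)/(P + k2)
//           - gmax * W/(W+k1) * P - rw * W               + Dw lap W
//   dO/dt = Rn - al * O * (P + k2*W0)/(P + k2)           + Do lap O
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List sim_turing_cpp(int n, NumericVector R_values, List params, double dx,
                    double dt, double t_first, double t_next) {
  double cg = params["c"], gmax = params["gmax"], k1 = params["k1"],
         dd = params["d"], Dp = params["Dp"], al = params["alpha"],
         W0 = params["W0"], k2 = params["k2"], rw = params["rw"],
         Dw = params["Dw"], Do = params["Do"], sigma = params["sigma"],
         p0 = params["p0"];
  int nd = R_values.size();
  double idx2 = 1.0 / (dx * dx);
  NumericMatrix P(n, n), W(n, n), O(n, n), Pn(n, n), Wn(n, n), On(n, n);
  Wrap wr(n);
  double R1 = R_values[0];
  for (int k = 0; k < n * n; ++k) {
    P[k] = p0 * (0.5 + unif_rand());      // heterogeneous seed
    W[k] = R1 / rw;
    O[k] = R1 / al;
  }
  double sqdt = std::sqrt(dt);
  List out(nd);
  for (int di = 0; di < nd; ++di) {
    double Rn = R_values[di];
    int steps = (int)std::ceil((di == 0 ? t_first : t_next) / dt);
    for (int s = 0; s < steps; ++s) {
      const double* Pp = &P[0];
      const double* Wp = &W[0];
      const double* Op = &O[0];
      for (int j = 0; j < n; ++j) {
        for (int i = 0; i < n; ++i) {
          double p = P(i, j), w = W(i, j), o = O(i, j);
          double uptake = gmax * w / (w + k1) * p;
          double infil = al * o * (p + k2 * W0) / (p + k2);
          double dp = cg * uptake - dd * p + Dp * idx2 * lap4w(Pp, i, j, n, wr);
          double dw2 = infil - uptake - rw * w + Dw * idx2 * lap4w(Wp, i, j, n, wr);
          double do2 = Rn - infil + Do * idx2 * lap4w(Op, i, j, n, wr);
          double np = p + dt * dp + sigma * p * sqdt * norm_rand();
          double nw = w + dt * dw2;
          double no = o + dt * do2;
          if (np < 0) {
            if (np < -1e-3) stop("Negative biomass beyond tolerance at rainfall %f, step %d", Rn, s);
            np = 0;
          }
          if (nw < 0) nw = 0;
          if (no < 0) no = 0;
          Pn(i, j) = np;
          Wn(i, j) = nw;
          On(i, j) = no;
        }
      }
      std::swap(P, Pn);
      std::swap(W, Wn);
      std::swap(O, On);
      if (s % 1000 == 0) {
        for (int k = 0; k < n * n; ++k) {
          if (!R_FINITE(P[k]) || !R_FINITE(W[k]) || !R_FINITE(O[k]))
            stop("Numerical instability at rainfall %f, step %d", Rn, s);
        }
      }
    }
    out[di] = clone(P);
  }
  return out;
}
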