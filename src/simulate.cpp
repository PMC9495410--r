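#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Chemical-noise amplitude: sqrt(z), replaced by z/4 for z <= 16 so that the
// relative noise stops growing as abundance drops (continuous at z = 16).
static inline double ampf(double z)  { return z > 16.0 ? std::sqrt(z) : 0.25 * z; }
static inline double amppf(double z) { return z > 16.0 ? 0.5 / std::sqrt(z) : 0.25; }

static inline int lowest_bit_index(int m) {
  int j = 0;
  while (!((m >> j) & 1)) ++j;
  return j;
}

// Thermodynamic promoter-occupancy activation for one gene.
// Subset weights w_S = r_S * prod_{j in S} v_j with v_j = (y_j / k_j)^{h_j},
// computed in log space and rescaled by the maximum weight so that products of
// very large intensities (v up to ~1e15 per TF) never overflow.
// Fills w with the rescaled weights, returns f = sum(alpha_S w_S) / sum(w_S).
static double gene_activation(int n, int nmask, const double* y,
                              const double* krow, const double* hrow,
                              const double* arow, const double* rrow,
                              const int* rcol,
                              std::vector<double>& lw, std::vector<double>& w,
                              double& Dout)
{
  double lv[32];
  for (int j = 0; j < n; ++j) {
    double hj = hrow[j];
    if (hj == 0.0) lv[j] = 0.0;                       // (y/k)^0 = 1
    else if (y[j] <= 0.0) lv[j] = R_NegInf;           // v = 0
    else lv[j] = hj * (std::log(y[j]) - std::log(krow[j]));
  }
  lw[0] = 0.0;                                        // empty subset: w = 1
  for (int mask = 1; mask < nmask; ++mask) {
    int low = mask & (-mask);
    lw[mask] = lw[mask ^ low] + lv[lowest_bit_index(low)];
  }
  for (int mask = 0; mask < nmask; ++mask)
    if (rcol[mask] >= 0) lw[mask] += std::log(rrow[rcol[mask]]);
  double M = lw[0];
  for (int mask = 1; mask < nmask; ++mask) if (lw[mask] > M) M = lw[mask];
  double D = 0.0, N = 0.0;
  for (int mask = 0; mask < nmask; ++mask) {
    double wv = std::exp(lw[mask] - M);
    w[mask] = wv;
    D += wv;
    N += arow[mask] * wv;
  }
  Dout = D;
  return N / D;
}

// Forward simulation of the TF circuit by fixed-step Euler(-Maruyama), with an
// optional reverse pass that backpropagates the squared-deviation trajectory
// loss through every unrolled step (discretize-then-optimize).
//
//   x_{t+dt,i} = x_i + dt (m_i f_i(y) - delta_i x_i) + ns sqrt(dt) amp(x_i) Wx_i
//   y_{t+dt,i} = y_i + dt (s_i x_i - gamma_i y_i + drive_i(t)) + ns sqrt(dt) amp(y_i) Wy_i
//
// followed by flooring at zero. Rates are per day; dt in days. driveAdd holds
// the precomputed light boost (molecules/day) added to dy of driveGene at each
// step. W is the pre-drawn standard-normal noise (2n x nsteps) when
// noiseScale != 0. Loss: sum over lossSteps (state indices, 0-based) of
// (ytilde - target)^2 with ytilde = y^2/(yHalf^2 + y^2) for gene lossGene.
// [[Rcpp::export]]
List cpp_simulate(int n,
                  NumericVector m, NumericVector delta,
                  NumericVector s, NumericVector gamma_,
                  NumericVector x0, NumericVector y0,
                  NumericMatrix k, NumericMatrix h,
                  NumericMatrix alpha, NumericMatrix rsyn, IntegerVector rcol,
                  double dt, int nsteps, int saveEvery,
                  NumericVector driveAdd, int driveGene,
                  double noiseScale, NumericMatrix W,
                  int lossGene, IntegerVector lossSteps, NumericVector lossTarget,
                  double yHalf, bool wantGrad)
{
  if (n < 1 || n > 31) stop("n out of supported range");
  const int nmask = 1 << n;
  const int nr = rsyn.ncol();
  const bool noise = (noiseScale != 0.0);
  const double sq = std::sqrt(dt);
  if (noise && (W.nrow() != 2 * n || W.ncol() < nsteps))
    stop("noise matrix must be 2n x nsteps");
  if (driveGene >= 0 && (int)driveAdd.size() < nsteps)
    stop("driveAdd must have one entry per step");

  // per-gene contiguous copies of the regulation parameters
  std::vector<std::vector<double> > krow(n), hrow(n), arow(n), rrow(n);
  for (int i = 0; i < n; ++i) {
    krow[i].resize(n); hrow[i].resize(n);
    for (int j = 0; j < n; ++j) { krow[i][j] = k(i, j); hrow[i][j] = h(i, j); }
    arow[i].resize(nmask);
    for (int mask = 0; mask < nmask; ++mask) arow[i][mask] = alpha(i, mask);
    rrow[i].resize(nr);
    for (int c = 0; c < nr; ++c) rrow[i][c] = rsyn(i, c);
  }
  std::vector<int> rc(nmask);
  for (int mask = 0; mask < nmask; ++mask) rc[mask] = rcol[mask];

  std::vector<double> X((size_t)(nsteps + 1) * n), Y((size_t)(nsteps + 1) * n);
  for (int i = 0; i < n; ++i) { X[i] = x0[i]; Y[i] = y0[i]; }

  std::vector<double> lw(nmask), wbuf(nmask), f(n);
  double D;

  for (int step = 0; step < nsteps; ++step) {
    const double* xs = &X[(size_t)step * n];
    const double* ys = &Y[(size_t)step * n];
    double* xn = &X[(size_t)(step + 1) * n];
    double* yn = &Y[(size_t)(step + 1) * n];
    for (int i = 0; i < n; ++i)
      f[i] = gene_activation(n, nmask, ys, krow[i].data(), hrow[i].data(),
                             arow[i].data(), rrow[i].data(), rc.data(),
                             lw, wbuf, D);
    for (int i = 0; i < n; ++i) {
      double xv = xs[i] + dt * (m[i] * f[i] - delta[i] * xs[i]);
      if (noise) xv += noiseScale * sq * ampf(xs[i]) * W(i, step);
      xn[i] = xv > 0.0 ? xv : 0.0;
      double dy = s[i] * xs[i] - gamma_[i] * ys[i];
      if (i == driveGene) dy += driveAdd[step];
      double yv = ys[i] + dt * dy;
      if (noise) yv += noiseScale * sq * ampf(ys[i]) * W(n + i, step);
      yn[i] = yv > 0.0 ? yv : 0.0;
    }
  }

  // loss on the requested grid of state indices
  const int nl = lossSteps.size();
  const double H2 = yHalf * yHalf;
  double loss = 0.0;
  std::vector<double> lres(nl);
  std::vector<int> lossAt((size_t)nsteps + 1, -1);
  for (int li = 0; li < nl; ++li) {
    int st = lossSteps[li];
    if (st < 0 || st > nsteps) stop("loss step index out of range");
    double yv = Y[(size_t)st * n + lossGene];
    double yt = yv * yv / (H2 + yv * yv);
    double e = yt - lossTarget[li];
    lres[li] = e;
    loss += e * e;
    lossAt[st] = li;
  }

  // thinned trajectory output
  int nsave = nsteps / saveEvery + 1;
  NumericMatrix Xo(nsave, n), Yo(nsave, n);
  for (int sdx = 0; sdx < nsave; ++sdx) {
    size_t st = (size_t)sdx * saveEvery;
    for (int i = 0; i < n; ++i) { Xo(sdx, i) = X[st * n + i]; Yo(sdx, i) = Y[st * n + i]; }
  }

  List out = List::create(_["loss"] = loss, _["x"] = Xo, _["y"] = Yo);
  if (!wantGrad) return out;

  // reverse pass: adjoints of the loss with respect to the state, propagated
  // backwards through floor -> Euler update -> activation function
  NumericVector gm(n), gdelta(n), gs(n), ggamma(n), gx0(n), gy0(n);
  NumericMatrix gk(n, n), gh(n, n), galpha(n, nmask), grsyn(n, nr);
  std::vector<double> Ax(n, 0.0), Ay(n, 0.0), bx(n), by(n), nAx(n), nAy(n);
  std::vector<double> Sy(n);

  // direct loss gradient at a stored state
  const int lg = lossGene;
  // at final state
  {
    int li = lossAt[nsteps];
    if (li >= 0) {
      double yv = Y[(size_t)nsteps * n + lg];
      double den = H2 + yv * yv;
      Ay[lg] += 2.0 * lres[li] * (2.0 * yv * H2 / (den * den));
    }
  }

  for (int step = nsteps - 1; step >= 0; --step) {
    const double* xs = &X[(size_t)step * n];
    const double* ys = &Y[(size_t)step * n];
    const double* xs1 = &X[(size_t)(step + 1) * n];
    const double* ys1 = &Y[(size_t)(step + 1) * n];
    for (int i = 0; i < n; ++i) {
      bx[i] = (xs1[i] > 0.0) ? Ax[i] : 0.0;   // floor kills the gradient
      by[i] = (ys1[i] > 0.0) ? Ay[i] : 0.0;
    }
    for (int i = 0; i < n; ++i) {
      double ax = bx[i] * (1.0 - dt * delta[i]) + by[i] * dt * s[i];
      double ay = by[i] * (1.0 - dt * gamma_[i]);
      if (noise) {
        ax += bx[i] * noiseScale * sq * amppf(xs[i]) * W(i, step);
        ay += by[i] * noiseScale * sq * amppf(ys[i]) * W(n + i, step);
      }
      nAx[i] = ax;
      nAy[i] = ay;
    }
    for (int i = 0; i < n; ++i) {
      if (bx[i] == 0.0 && by[i] == 0.0) continue;
      gs[i]     += by[i] * dt * xs[i];
      ggamma[i] -= by[i] * dt * ys[i];
      if (bx[i] == 0.0) continue;
      double fi = gene_activation(n, nmask, ys, krow[i].data(), hrow[i].data(),
                                  arow[i].data(), rrow[i].data(), rc.data(),
                                  lw, wbuf, D);
      gm[i]     += bx[i] * dt * fi;
      gdelta[i] -= bx[i] * dt * xs[i];
      double A = bx[i] * dt * m[i];              // dL/df_i at this step
      if (A == 0.0) continue;
      for (int j = 0; j < n; ++j) Sy[j] = 0.0;
      for (int mask = 0; mask < nmask; ++mask) {
        double wD = wbuf[mask] / D;
        galpha(i, mask) += A * wD;
        double c = (arow[i][mask] - fi) * wD;    // dlogw coefficient
        if (rc[mask] >= 0 && c != 0.0)
          grsyn(i, rc[mask]) += A * c / rrow[i][rc[mask]];
        int mm = mask;
        while (mm) {
          int j = lowest_bit_index(mm & (-mm));
          Sy[j] += c;
          mm &= mm - 1;
        }
      }
      for (int j = 0; j < n; ++j) {
        if (Sy[j] == 0.0) continue;
        double hij = hrow[i][j], kij = krow[i][j], yj = ys[j];
        gk(i, j) -= A * Sy[j] * hij / kij;
        if (yj > 0.0) {
          nAy[j] += A * Sy[j] * hij / yj;
          gh(i, j) += A * Sy[j] * std::log(yj / kij);
        }
      }
    }
    for (int i = 0; i < n; ++i) { Ax[i] = nAx[i]; Ay[i] = nAy[i]; }
    int li = lossAt[step];
    if (li >= 0) {
      double yv = ys[lg];
      double den = H2 + yv * yv;
      Ay[lg] += 2.0 * lres[li] * (2.0 * yv * H2 / (den * den));
    }
  }
  for (int i = 0; i < n; ++i) { gx0[i] = Ax[i]; gy0[i] = Ay[i]; }

  out["grad"] = List::create(
    _["m"] = gm, _["delta"] = gdelta, _["s"] = gs, _["gamma"] = ggamma,
    _["x0"] = gx0, _["y0"] = gy0, _["k"] = gk, _["h"] = gh,
    _["alpha"] = galpha, _["r"] = grsyn);
  return out;
}

// n-TF activation for a block of abundance vectors (rows of Ymat), one gene.
// Used by the logic-surface grid evaluator.
// [[Rcpp::export]]
NumericVector cpp_activation_grid(int n, NumericMatrix Ymat,
                                  NumericVector krow, NumericVector hrow,
                                  NumericVector arow, NumericVector rrow,
                                  IntegerVector rcol)
{
  const int nmask = 1 << n;
  std::vector<int> rc(nmask);
  for (int mask = 0; mask < nmask; ++mask) rc[mask] = rcol[mask];
  std::vector<double> lw(nmask), wbuf(nmask), yv(n);
  double D;
  int npt = Ymat.nrow();
  NumericVector out(npt);
  for (int p = 0; p < npt; ++p) {
    for (int j = 0; j < n; ++j) yv[j] = Ymat(p, j);
    out[p] = gene_activation(n, nmask, yv.data(), krow.begin(), hrow.begin(),
                             arow.begin(), rrow.begin(), rc.data(), lw, wbuf, D);
  }
  return out;
}
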