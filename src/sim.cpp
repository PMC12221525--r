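#include <Rcpp.h>
using namespace Rcpp;

// Temperature at (x, y) mm for the analytic thermoscape:
// plate baseline plus peak-normalized Gaussian bumps at each source.
static inline double field_analytic(double x, double y,
                                    const double* sx, const double* sy,
                                    const double* sC, int nsrc,
                                    double plate, double spread_mm) {
  double T = plate;
  double two_s2 = 2.0 * spread_mm * spread_mm;
  for (int j = 0; j < nsrc; ++j) {
    double dx = x - sx[j], dy = y - sy[j];
    T += (sC[j] - plate) * std::exp(-(dx * dx + dy * dy) / two_s2);
  }
  return T;
}

// Run-and-turn agents with cross-inhibition thermosensing.
//
// Draw order per step, per agent (must match the R reference stepper):
//   u ~ unif; if turning, ang ~ norm.  Uses R's RNG stream so results are
//   reproducible under set.seed() in R.
//
// field_type: 0 = analytic thermoscape, 1 = thermal-frame lookup.
// frame_vals: (nrow_f * ncol_f) x nframes matrix, frames flattened
// column-major (row index = y pixel, col index = x pixel).
// Occupancy is accumulated in fine temperature bins [bin_lo + i*bin_w)
// for steps strictly after burn_steps.
// [[Rcpp::export]]
List cpp_sim_agents(int n, double dt, int n_steps, int burn_steps,
                    double speed, double r0, double k, double sigma,
                    double c_o, double s, double thsp,
                    double arena_w, double arena_h,
                    int field_type,
                    NumericVector src_x, NumericVector src_y,
                    NumericVector src_C, double plate, double spread_mm,
                    NumericMatrix frame_vals, IntegerVector frame_of_step,
                    int nrow_f, int ncol_f,
                    NumericVector x0, NumericVector y0, NumericVector th0,
                    double bin_lo, double bin_w, int nbins,
                    bool record) {
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> th(th0.begin(), th0.end());
  std::vector<double> A(n, 0.0), Tprev(n), p(n);
  NumericMatrix occ(n, nbins);
  NumericMatrix rx, ry, rth;
  if (record) {
    rx = NumericMatrix(n, n_steps + 1);
    ry = NumericMatrix(n, n_steps + 1);
    rth = NumericMatrix(n, n_steps + 1);
  }
  const int nsrc = src_x.size();
  const double* psx = src_x.begin();
  const double* psy = src_y.begin();
  const double* psC = src_C.begin();
  const double* fv = frame_vals.begin();
  const int npix = nrow_f * ncol_f;

  double p0 = dt * r0;
  if (p0 < 0) p0 = 0; if (p0 > 1) p0 = 1;
  for (int i = 0; i < n; ++i) {
    double T0;
    if (field_type == 0) {
      T0 = field_analytic(x[i], y[i], psx, psy, psC, nsrc, plate, spread_mm);
    } else {
      int cx = (int)std::floor(x[i] / arena_w * (ncol_f - 1) + 0.5);
      int cy = (int)std::floor(y[i] / arena_h * (nrow_f - 1) + 0.5);
      if (cx < 0) cx = 0; if (cx > ncol_f - 1) cx = ncol_f - 1;
      if (cy < 0) cy = 0; if (cy > nrow_f - 1) cy = nrow_f - 1;
      T0 = fv[(size_t)(frame_of_step[0] - 1) * npix + cx * nrow_f + cy];
    }
    Tprev[i] = T0;
    p[i] = p0;
    if (record) { rx(i, 0) = x[i]; ry(i, 0) = y[i]; rth(i, 0) = th[i]; }
  }

  GetRNGstate();
  for (int m = 1; m <= n_steps; ++m) {
    int fidx = 0;
    if (field_type == 1) fidx = frame_of_step[m - 1] - 1;
    for (int i = 0; i < n; ++i) {
      // turning decision uses the probability from the previous step
      double u = unif_rand();
      if (u < p[i]) th[i] += norm_rand() * sigma;
      // advance and reflect at the walls
      double nx = x[i] + speed * dt * std::cos(th[i]);
      double ny = y[i] + speed * dt * std::sin(th[i]);
      if (nx < 0) { nx = -nx; th[i] = M_PI - th[i]; }
      else if (nx > arena_w) { nx = 2 * arena_w - nx; th[i] = M_PI - th[i]; }
      if (ny < 0) { ny = -ny; th[i] = -th[i]; }
      else if (ny > arena_h) { ny = 2 * arena_h - ny; th[i] = -th[i]; }
      x[i] = nx; y[i] = ny;
      // sense
      double T;
      if (field_type == 0) {
        T = field_analytic(nx, ny, psx, psy, psC, nsrc, plate, spread_mm);
      } else {
        int cx = (int)std::floor(nx / arena_w * (ncol_f - 1) + 0.5);
        int cy = (int)std::floor(ny / arena_h * (nrow_f - 1) + 0.5);
        if (cx < 0) cx = 0; if (cx > ncol_f - 1) cx = ncol_f - 1;
        if (cy < 0) cy = 0; if (cy > nrow_f - 1) cy = nrow_f - 1;
        T = fv[(size_t)fidx * npix + cx * nrow_f + cy];
      }
      // Weber-Fechner perception with exponential decay (forward Euler)
      double G = 2.0 * s * (thsp - T);
      A[i] += dt * (-c_o * A[i] + G * (T - Tprev[i]) / (dt * T));
      Tprev[i] = T;
      double pi_ = dt * r0 * (1.0 - k * A[i]);
      if (pi_ < 0) pi_ = 0; if (pi_ > 1) pi_ = 1;
      p[i] = pi_;
      if (m > burn_steps) {
        int b = (int)std::floor((T - bin_lo) / bin_w);
        if (b < 0) b = 0; if (b > nbins - 1) b = nbins - 1;
        occ(i, b) += dt;
      }
      if (record) { rx(i, m) = x[i]; ry(i, m) = y[i]; rth(i, m) = th[i]; }
    }
  }
  PutRNGstate();

  List out = List::create(_["occ"] = occ);
  if (record) {
    out["x"] = rx; out["y"] = ry; out["theta"] = rth;
  }
  return out;
}
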