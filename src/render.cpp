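// Image-formation renderers for synthetic membrane scenes.
//
// Particles diffuse on a periodic box (minimum-image convention); a scanned
// confocal beam or a camera samples them through a 2D Gaussian detection
// profile with 1/e^2 radius omega.  All randomness goes through R's RNG so
// renders are reproducible under set.seed().

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double min_image(double d, double L) {
  if (d > 0.5 * L) d -= L;
  else if (d < -0.5 * L) d += L;
  return d;
}

static inline double wrap(double x, double L) {
  x -= L * std::floor(x / L);
  if (x >= L) x -= L;   // guard the floor rounding edge case
  return x;
}

static void advance(std::vector<double>& x, std::vector<double>& y,
                    const NumericVector& D, double dt, double L) {
  if (dt <= 0) return;
  int n = x.size();
  for (int i = 0; i < n; ++i) {
    double s = std::sqrt(2.0 * D[i] * dt);
    if (s > 0) {
      x[i] = wrap(x[i] + R::rnorm(0.0, s), L);
      y[i] = wrap(y[i] + R::rnorm(0.0, s), L);
    }
  }
}

// Add eps * exp(-2 r^2 / omega^2) of one particle to the rate of every pixel
// in one scan line (pixel centers at (c + 0.5) * dr), honoring periodicity.
static void add_line_rates(std::vector<double>& rates, double px, double py,
                           double y_line, double eps, double omega,
                           double dr, int ncol, double L) {
  double cut = 4.0 * omega;
  double dy = min_image(py - y_line, L);
  if (std::fabs(dy) > cut) return;
  double gy = std::exp(-2.0 * dy * dy / (omega * omega));
  for (int rep = -1; rep <= 1; ++rep) {
    double x0 = px + rep * L;
    int cmin = (int)std::floor((x0 - cut) / dr - 0.5);
    int cmax = (int)std::ceil((x0 + cut) / dr - 0.5);
    if (cmin < 0) cmin = 0;
    if (cmax > ncol - 1) cmax = ncol - 1;
    for (int c = cmin; c <= cmax; ++c) {
      double dx = (c + 0.5) * dr - x0;
      rates[c] += eps * gy * std::exp(-2.0 * dx * dx / (omega * omega));
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_render_confocal(NumericMatrix pos0, NumericVector D,
                                  NumericVector eps, double boxL,
                                  double bg_khz, int nframes, int nrow,
                                  int ncol, double dr, double tau_p,
                                  double tau_l, double frame_time,
                                  double omega, bool per_pixel) {
  int n = pos0.nrow();
  std::vector<double> x(n), y(n);
  for (int i = 0; i < n; ++i) { x[i] = pos0(i, 0); y[i] = pos0(i, 1); }
  NumericVector out((R_xlen_t)nframes * nrow * ncol);
  std::vector<double> rates(ncol);
  double cut = 4.0 * omega;
  for (int f = 0; f < nframes; ++f) {
    for (int r = 0; r < nrow; ++r) {
      double y_line = (r + 0.5) * dr;
      if (!per_pixel) {
        std::fill(rates.begin(), rates.end(), bg_khz);
        for (int i = 0; i < n; ++i)
          add_line_rates(rates, x[i], y[i], y_line, eps[i], omega, dr,
                         ncol, boxL);
        for (int c = 0; c < ncol; ++c) {
          double mu = rates[c] * 1000.0 * tau_p;
          out[f + (R_xlen_t)nframes * (r + (R_xlen_t)nrow * c)] =
            R::rpois(mu);
        }
        advance(x, y, D, tau_l, boxL);
      } else {
        for (int c = 0; c < ncol; ++c) {
          double rate = bg_khz;
          double xc = (c + 0.5) * dr;
          for (int i = 0; i < n; ++i) {
            double dx = min_image(x[i] - xc, boxL);
            double dy = min_image(y[i] - y_line, boxL);
            if (std::fabs(dx) > cut || std::fabs(dy) > cut) continue;
            rate += eps[i] *
              std::exp(-2.0 * (dx * dx + dy * dy) / (omega * omega));
          }
          out[f + (R_xlen_t)nframes * (r + (R_xlen_t)nrow * c)] =
            R::rpois(rate * 1000.0 * tau_p);
          advance(x, y, D, tau_p, boxL);
        }
        advance(x, y, D, tau_l - ncol * tau_p, boxL);
      }
    }
    advance(x, y, D, frame_time - nrow * tau_l, boxL);
  }
  return out;
}

// Mean of exp(-2 (u - u0)^2 / omega^2) over one pixel [u, u + dr]
// (integrated Gaussian point spread function along one axis).
static inline double pix_integral(double lo, double u0, double dr,
                                  double omega) {
  double s = omega / 2.0;                       // Gaussian sigma
  double a = (lo - u0) / (s * std::sqrt(2.0));
  double b = (lo + dr - u0) / (s * std::sqrt(2.0));
  return s * std::sqrt(M_PI / 2.0) * (std::erf(b) - std::erf(a)) / dr;
}

// [[Rcpp::export]]
List cpp_render_camera(NumericMatrix pos0, NumericVector D,
                       NumericMatrix bright, NumericVector bg_khz,
                       double boxL, int nframes, int nrow, int ncol,
                       double dr, double frame_time, double exposure,
                       NumericVector ch_offsets, NumericVector omega,
                       double read_noise_sd, NumericMatrix reg_offset_px) {
  int n = pos0.nrow(), n_ch = bright.ncol();
  std::vector<double> x(n), y(n);
  for (int i = 0; i < n; ++i) { x[i] = pos0(i, 0); y[i] = pos0(i, 1); }
  List out(n_ch);
  std::vector<NumericVector> chan;
  for (int c = 0; c < n_ch; ++c)
    chan.push_back(NumericVector((R_xlen_t)nframes * nrow * ncol));
  double t_now = 0.0;
  for (int f = 0; f < nframes; ++f) {
    double t0 = f * frame_time;
    for (int ch = 0; ch < n_ch; ++ch) {
      double t_mid = t0 + ch_offsets[ch] + exposure / 2.0;
      // advance to the mid-exposure time of this channel
      if (t_mid > t_now) {
        // distribute across particles in one step
        double dt = t_mid - t_now;
        advance(x, y, D, dt, boxL);
        t_now = t_mid;
      }
      double om = omega[ch];
      double cut = 4.0 * om;
      std::vector<double> signal((size_t)nrow * ncol,
                                 bg_khz[ch] * 1000.0 * exposure);
      double offx = reg_offset_px(ch, 1) * dr;   // column shift
      double offy = reg_offset_px(ch, 0) * dr;   // row shift
      for (int i = 0; i < n; ++i) {
        double b = bright(i, ch);
        if (b <= 0) continue;
        double amp = b * 1000.0 * exposure;
        for (int repx = -1; repx <= 1; ++repx) {
          double x0 = x[i] + offx + repx * boxL;
          int cmin = (int)std::floor((x0 - cut) / dr);
          int cmax = (int)std::floor((x0 + cut) / dr);
          if (cmax < 0 || cmin > ncol - 1) continue;
          if (cmin < 0) cmin = 0;
          if (cmax > ncol - 1) cmax = ncol - 1;
          for (int repy = -1; repy <= 1; ++repy) {
            double y0 = y[i] + offy + repy * boxL;
            int rmin = (int)std::floor((y0 - cut) / dr);
            int rmax = (int)std::floor((y0 + cut) / dr);
            if (rmax < 0 || rmin > nrow - 1) continue;
            if (rmin < 0) rmin = 0;
            if (rmax > nrow - 1) rmax = nrow - 1;
            for (int r = rmin; r <= rmax; ++r) {
              double iy = pix_integral(r * dr, y0, dr, om);
              for (int c = cmin; c <= cmax; ++c) {
                double ix = pix_integral(c * dr, x0, dr, om);
                signal[(size_t)r * ncol + c] += amp * ix * iy;
              }
            }
          }
        }
      }
      NumericVector& arr = chan[ch];
      for (int r = 0; r < nrow; ++r) {
        for (int c = 0; c < ncol; ++c) {
          double v = R::rpois(signal[(size_t)r * ncol + c]);
          if (read_noise_sd > 0) v += R::rnorm(0.0, read_noise_sd);
          if (v < 0) v = 0;
          arr[f + (R_xlen_t)nframes * (r + (R_xlen_t)nrow * c)] = v;
        }
      }
    }
    double t_next = t0 + frame_time;
    if (t_next > t_now) {
      advance(x, y, D, t_next - t_now, boxL);
      t_now = t_next;
    }
  }
  for (int c = 0; c < n_ch; ++c) out[c] = chan[c];
  return out;
}
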