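// Core numerical kernels for the Fresnel-Kirchhoff layered forward model.
//
// Geometry convention: x lateral, z depth increasing away from the array;
// sensors at z = 0, the aberrator occupies 0 <= z <= z_j(x), sources lie in
// water beyond the layer.  Interface normals point toward the array.
//
// All three kernels share the same per-(source, interface) and
// (interface, sensor) geometry so that the gather is the exact adjoint of the
// deposit and the gradient is the exact derivative of the discrete loss.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct Geometry {
  // per (s,j): r1, cos_in and their z-derivatives; tau1
  // per (j,n): r2, cos_out and their z-derivatives; tau2
  int S, J, N;
  std::vector<double> r1, e1z, cosin, dcosin_dz, dcosin_dg;  // S*J
  std::vector<double> r2, e2z, cosout, dcosout_dz, dcosout_dg; // J*N
};

// variant codes: 0 kirchhoff, 1 sommerfeld1, 2 sommerfeld2, 3 unity
inline void build_geometry(Geometry &G,
                           const NumericVector &sx, const NumericVector &sz,
                           const NumericVector &ix, const NumericVector &iz,
                           const NumericVector &nx, const NumericVector &nz,
                           const NumericVector &gx, // slope g_j
                           const NumericVector &ax, const NumericVector &az,
                           double min_dist) {
  const int S = sx.size(), J = ix.size(), N = ax.size();
  G.S = S; G.J = J; G.N = N;
  G.r1.resize((size_t)S * J); G.e1z.resize((size_t)S * J);
  G.cosin.resize((size_t)S * J); G.dcosin_dz.resize((size_t)S * J);
  G.dcosin_dg.resize((size_t)S * J);
  G.r2.resize((size_t)J * N); G.e2z.resize((size_t)J * N);
  G.cosout.resize((size_t)J * N); G.dcosout_dz.resize((size_t)J * N);
  G.dcosout_dg.resize((size_t)J * N);

  for (int j = 0; j < J; ++j) {
    const double g = gx[j];
    const double s3 = std::pow(1.0 + g * g, 1.5);
    // source -> interface
    for (int s = 0; s < S; ++s) {
      const double ux = ix[j] - sx[s], uz = iz[j] - sz[s];
      const double r1 = std::sqrt(ux * ux + uz * uz);
      if (r1 < min_dist) stop("degenerate geometry: source too close to interface");
      const double e1x = ux / r1, e1z = uz / r1;
      const double ci = nx[j] * e1x + nz[j] * e1z;
      const size_t k = (size_t)s * J + j;
      G.r1[k] = r1; G.e1z[k] = e1z; G.cosin[k] = ci;
      G.dcosin_dz[k] = (nz[j] - ci * e1z) / r1;
      G.dcosin_dg[k] = (e1x + g * e1z) / s3;
    }
    // interface -> sensor
    for (int n = 0; n < N; ++n) {
      const double vx = ax[n] - ix[j], vz = az[n] - iz[j];
      const double r2 = std::sqrt(vx * vx + vz * vz);
      if (r2 < min_dist) stop("degenerate geometry: sensor too close to interface");
      const double e2x = vx / r2, e2z = vz / r2;
      const double co = nx[j] * e2x + nz[j] * e2z;
      const size_t k = (size_t)j * N + n;
      G.r2[k] = r2; G.e2z[k] = e2z; G.cosout[k] = co;
      G.dcosout_dz[k] = (-nz[j] + co * e2z) / r2;
      G.dcosout_dg[k] = (e2x + g * e2z) / s3;
    }
  }
}

inline double psi_value(int variant, double cosin, double cosout,
                        double cw, double ca) {
  switch (variant) {
    case 0: return cosin / cw + cosout / ca;
    case 1: return cosout;
    case 2: return cosin;
    default: return 1.0;
  }
}

} // namespace

// Deposit the delta train of Eq.-(1)-style wavelets onto the time grid
// (linear interpolation between the two nearest samples).  Convolution with
// the sensor impulse response is applied afterwards in R via FFT.
// [[Rcpp::export]]
List cpp_deposit(NumericVector sx, NumericVector sz, NumericVector amp,
                 NumericVector ix, NumericVector iz,
                 NumericVector nx, NumericVector nz, NumericVector slope,
                 NumericVector ax, NumericVector az,
                 double cw, double ca, int variant, double quad,
                 double alpha_w, double alpha_a,
                 double fs, double t0, int nt, double min_dist) {
  Geometry G;
  build_geometry(G, sx, sz, ix, iz, nx, nz, slope, ax, az, min_dist);
  NumericMatrix D(nt, G.N);
  long long clipped = 0, total = 0;
  for (int s = 0; s < G.S; ++s) {
    const double a = amp[s];
    if (a == 0.0) { total += (long long)G.J * G.N; continue; }
    for (int j = 0; j < G.J; ++j) {
      const size_t k1 = (size_t)s * G.J + j;
      const double r1 = G.r1[k1], ci = G.cosin[k1];
      const double tau1 = r1 / cw;
      const double att1 = alpha_w > 0 ? std::exp(-alpha_w * r1) : 1.0;
      for (int n = 0; n < G.N; ++n) {
        ++total;
        const size_t k2 = (size_t)j * G.N + n;
        const double r2 = G.r2[k2], co = G.cosout[k2];
        const double psi = psi_value(variant, ci, co, cw, ca);
        double w = quad * psi / (r1 * r2);
        if (alpha_w > 0 || alpha_a > 0)
          w *= att1 * (alpha_a > 0 ? std::exp(-alpha_a * r2) : 1.0);
        const double tau = tau1 + r2 / ca;
        const double pos = (tau - t0) * fs;
        const int i0 = (int)std::floor(pos);
        if (i0 < 0 || i0 + 1 >= nt) { ++clipped; continue; }
        const double f = pos - i0;
        D(i0, n)     += a * w * (1.0 - f);
        D(i0 + 1, n) += a * w * f;
      }
    }
  }
  return List::create(_["deposits"] = D, _["clipped"] = (double)clipped,
                      _["total"] = (double)total);
}

// Gather (beamforming) kernel: image[s] = sum_{j,n} weight * P_n(tau_sjn),
// with P read by linear interpolation in time.
// mode 0: "paper" weights r1*r2*psi (Eq. 2); mode 1: "adjoint" weights
// quad*psi/(r1*r2) (exact transpose of cpp_deposit).
// [[Rcpp::export]]
List cpp_gather(NumericMatrix P,
                NumericVector sx, NumericVector sz,
                NumericVector ix, NumericVector iz,
                NumericVector nx, NumericVector nz, NumericVector slope,
                NumericVector ax, NumericVector az,
                double cw, double ca, int variant, double quad, int mode,
                double alpha_w, double alpha_a,
                double fs, double t0, double min_dist) {
  Geometry G;
  build_geometry(G, sx, sz, ix, iz, nx, nz, slope, ax, az, min_dist);
  const int nt = P.nrow();
  if (P.ncol() != G.N) stop("trace matrix does not match the array");
  NumericVector img(G.S);
  long long clipped = 0, total = 0;
  for (int s = 0; s < G.S; ++s) {
    double acc = 0.0;
    for (int j = 0; j < G.J; ++j) {
      const size_t k1 = (size_t)s * G.J + j;
      const double r1 = G.r1[k1], ci = G.cosin[k1];
      const double tau1 = r1 / cw;
      const double att1 = alpha_w > 0 ? std::exp(-alpha_w * r1) : 1.0;
      for (int n = 0; n < G.N; ++n) {
        ++total;
        const size_t k2 = (size_t)j * G.N + n;
        const double r2 = G.r2[k2], co = G.cosout[k2];
        const double psi = psi_value(variant, ci, co, cw, ca);
        double w = mode == 0 ? r1 * r2 * psi : quad * psi / (r1 * r2);
        if (alpha_w > 0 || alpha_a > 0)
          w *= att1 * (alpha_a > 0 ? std::exp(-alpha_a * r2) : 1.0);
        const double pos = ((tau1 + r2 / ca) - t0) * fs;
        const int i0 = (int)std::floor(pos);
        if (i0 < 0 || i0 + 1 >= nt) { ++clipped; continue; }
        const double f = pos - i0;
        acc += w * ((1.0 - f) * P(i0, n) + f * P(i0 + 1, n));
      }
    }
    img[s] = acc;
  }
  return List::create(_["image"] = img, _["clipped"] = (double)clipped,
                      _["total"] = (double)total);
}

// Gradient of the data-consistency term D = sum residual^2 with respect to
// the source amplitudes a_s and the interface thicknesses z_j.
//
// q is the residual back-propagated through the convolution (correlation of
// the residual with the impulse-response kernel); for deposit weight W = a*w
// at delay tau the chain rule gives
//   dD/da    = 2 * w * Q(tau)
//   dD/dz_j  = 2 * a * (dw/dz * Q(tau) + w * dtau/dz * Q'(tau))
// plus a slope channel dD/dg_j (normals depend on neighbouring z through the
// finite-difference slope; mapped back to z in R via the slope Jacobian).
// Q is the linear interpolant of q; Q' its in-cell derivative.
// [[Rcpp::export]]
List cpp_grad(NumericMatrix q,
              NumericVector sx, NumericVector sz, NumericVector amp,
              NumericVector ix, NumericVector iz,
              NumericVector nx, NumericVector nz, NumericVector slope,
              NumericVector ax, NumericVector az,
              double cw, double ca, int variant, double quad,
              double alpha_w, double alpha_a,
              double fs, double t0, double min_dist) {
  Geometry G;
  build_geometry(G, sx, sz, ix, iz, nx, nz, slope, ax, az, min_dist);
  const int nt = q.nrow();
  if (q.ncol() != G.N) stop("trace matrix does not match the array");
  NumericVector ga(G.S), gz(G.J), gg(G.J);
  for (int s = 0; s < G.S; ++s) {
    const double a = amp[s];
    double acc_a = 0.0;
    for (int j = 0; j < G.J; ++j) {
      const size_t k1 = (size_t)s * G.J + j;
      const double r1 = G.r1[k1], ci = G.cosin[k1], e1z = G.e1z[k1];
      const double dr1 = e1z;                     // dr1/dz_j
      const double tau1 = r1 / cw;
      const double att1 = alpha_w > 0 ? std::exp(-alpha_w * r1) : 1.0;
      double acc_z = 0.0, acc_g = 0.0;
      for (int n = 0; n < G.N; ++n) {
        const size_t k2 = (size_t)j * G.N + n;
        const double r2 = G.r2[k2], co = G.cosout[k2], e2z = G.e2z[k2];
        const double dr2 = -e2z;                  // dr2/dz_j
        const double psi = psi_value(variant, ci, co, cw, ca);
        double dpsi_dz, dpsi_dg;
        switch (variant) {
          case 0:
            dpsi_dz = G.dcosin_dz[k1] / cw + G.dcosout_dz[k2] / ca;
            dpsi_dg = G.dcosin_dg[k1] / cw + G.dcosout_dg[k2] / ca;
            break;
          case 1: dpsi_dz = G.dcosout_dz[k2]; dpsi_dg = G.dcosout_dg[k2]; break;
          case 2: dpsi_dz = G.dcosin_dz[k1];  dpsi_dg = G.dcosin_dg[k1];  break;
          default: dpsi_dz = 0.0; dpsi_dg = 0.0;
        }
        double att = 1.0;
        if (alpha_w > 0 || alpha_a > 0)
          att = att1 * (alpha_a > 0 ? std::exp(-alpha_a * r2) : 1.0);
        const double inv = 1.0 / (r1 * r2);
        const double w = quad * att * psi * inv;
        double dw = quad * att * inv *
          (dpsi_dz - psi * (dr1 / r1 + dr2 / r2) - psi * (alpha_w * dr1 + alpha_a * dr2));
        const double dwg = quad * att * dpsi_dg * inv;
        const double dtau = dr1 / cw + dr2 / ca;
        const double pos = ((tau1 + r2 / ca) - t0) * fs;
        const int i0 = (int)std::floor(pos);
        if (i0 < 0 || i0 + 1 >= nt) continue;
        const double f = pos - i0;
        const double Q = (1.0 - f) * q(i0, n) + f * q(i0 + 1, n);
        const double Qp = (q(i0 + 1, n) - q(i0, n)) * fs;
        acc_a += w * Q;
        acc_z += dw * Q + w * dtau * Qp;
        acc_g += dwg * Q;
      }
      gz[j] += 2.0 * a * acc_z;
      gg[j] += 2.0 * a * acc_g;
    }
    ga[s] = 2.0 * acc_a;
  }
  return List::create(_["grad_a"] = ga, _["grad_z"] = gz, _["grad_slope"] = gg);
}
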