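#include <Rcpp.h>
using namespace Rcpp;

// Expected photon counts (above background) for one shoebox with explicit
// mosaic domains. For pixel p, channel e, domain d:
//   q_p(e)   = dirs[p,] * invlam[e] - (0, 0, invlam[e])
//   eps^2    = | q_p(e) - qdom[d,] |^2
//   counts_p = omega[p] * sum_e w[e] * f2[e] * sum_d peak * exp(-eps^2 / (2 s2))
// `peak` already carries the (N_a N_b N_c)^2 / n_domains normalization and
// any overall flux/scale factor is applied by the caller.
// [[Rcpp::export(name = ".shoebox_expected_cpp")]]
NumericVector shoebox_expected_cpp(NumericMatrix dirs, NumericVector omega,
                                   NumericVector invlam, NumericVector w,
                                   NumericVector f2, NumericMatrix qdom,
                                   double s2, double peak) {
  const int np = dirs.nrow(), ne = invlam.size(), nd = qdom.nrow();
  NumericVector out(np);
  const double inv2s2 = 1.0 / (2.0 * s2);
  for (int p = 0; p < np; ++p) {
    const double dx = dirs(p, 0), dy = dirs(p, 1), dz = dirs(p, 2);
    double acc = 0.0;
    for (int e = 0; e < ne; ++e) {
      const double il = invlam[e];
      const double qx = dx * il, qy = dy * il, qz = (dz - 1.0) * il;
      double dsum = 0.0;
      for (int d = 0; d < nd; ++d) {
        const double ex = qx - qdom(d, 0);
        const double ey = qy - qdom(d, 1);
        const double ez = qz - qdom(d, 2);
        dsum += std::exp(-(ex * ex + ey * ey + ez * ez) * inv2s2);
      }
      acc += w[e] * f2[e] * dsum;
    }
    out[p] = omega[p] * acc * peak;
  }
  return out;
}

// Poisson NLL of all pixels of one shot under the smooth-mosaic model,
// for a trial orientation/width (per-shot refinement inner objective).
// dirs/omega/k/bpix are the concatenated pixels of the shot's shoeboxes,
// pix_sb maps each pixel to its shoebox (0-based); qcen (nsb x 3) are the
// trial reciprocal peak centers; f2 (nsb x ne) the channel intensities;
// wflux = flux * spectrum weight.
// [[Rcpp::export(name = ".shot_nll_cpp")]]
double shot_nll_cpp(NumericMatrix dirs, NumericVector omega,
                    IntegerVector pix_sb, NumericVector invlam,
                    NumericVector wflux, NumericMatrix f2,
                    NumericMatrix qcen, NumericVector sr2,
                    NumericVector st2, NumericVector amp,
                    double g, NumericVector bpix, NumericVector k) {
  const int np = dirs.nrow(), ne = invlam.size(), nsb = qcen.nrow();
  std::vector<double> hx(nsb), hy(nsb), hz(nsb), invr(nsb), invt(nsb);
  for (int s = 0; s < nsb; ++s) {
    const double qn = std::sqrt(qcen(s, 0) * qcen(s, 0) +
                                qcen(s, 1) * qcen(s, 1) +
                                qcen(s, 2) * qcen(s, 2));
    hx[s] = qn > 0 ? qcen(s, 0) / qn : 0;
    hy[s] = qn > 0 ? qcen(s, 1) / qn : 0;
    hz[s] = qn > 0 ? qcen(s, 2) / qn : 1;
    invr[s] = 1.0 / sr2[s];
    invt[s] = 1.0 / st2[s];
  }
  double nll = 0.0;
  for (int p = 0; p < np; ++p) {
    const int s = pix_sb[p];
    double m = 0.0;
    for (int e = 0; e < ne; ++e) {
      const double il = invlam[e];
      const double dx = dirs(p, 0) * il - qcen(s, 0);
      const double dy = dirs(p, 1) * il - qcen(s, 1);
      const double dz = (dirs(p, 2) - 1.0) * il - qcen(s, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      const double dpar = dx * hx[s] + dy * hy[s] + dz * hz[s];
      const double par2 = dpar * dpar;
      m += wflux[e] * f2(s, e) *
        std::exp(-0.5 * (par2 * invr[s] + (d2 - par2) * invt[s]));
    }
    double lam = g * omega[p] * amp[s] * m + bpix[p];
    if (lam < 1e-12) lam = 1e-12;
    nll += lam - k[p] * std::log(lam);
  }
  return nll;
}

// Row-wise weighted contraction m[p] = sum_e Pw(p, e) * f2(sb[p], e),
// the per-pixel model intensity given per-shoebox channel intensities.
// [[Rcpp::export(name = ".pixel_model_cpp")]]
NumericVector pixel_model_cpp(NumericMatrix pw, NumericMatrix f2,
                              IntegerVector sb0) {
  const int np = pw.nrow(), ne = pw.ncol();
  NumericVector out(np);
  for (int e = 0; e < ne; ++e) {
    const double *pc = &pw(0, e);
    for (int p = 0; p < np; ++p)
      out[p] += pc[p] * f2(sb0[p], e);
  }
  return out;
}

// Smooth-mosaic profile matrix. Mosaic misorientations smear the
// reciprocal peak only tangentially (perpendicular to q), while the
// domain-size broadening is isotropic, so the smooth limit of the
// incoherent domain sum is an anisotropic Gaussian: variance sr2 along
// q-hat (the energy-selecting radial direction) and st2 >= sr2 in the
// tangential plane. P[p, e] = omega[p] * amp *
//   exp(-(dpar^2 / sr2 + dperp^2 / st2) / 2),
// with d = q_p(e) - qcen, dpar = d . q-hat.
// [[Rcpp::export(name = ".design_profile_cpp")]]
NumericMatrix design_profile_cpp(NumericMatrix dirs, NumericVector omega,
                                 NumericVector invlam, NumericVector qcen,
                                 double sr2, double st2, double amp) {
  const int np = dirs.nrow(), ne = invlam.size();
  NumericMatrix out(np, ne);
  const double qn = std::sqrt(qcen[0] * qcen[0] + qcen[1] * qcen[1] +
                              qcen[2] * qcen[2]);
  double hx = 0, hy = 0, hz = 1;
  if (qn > 0) { hx = qcen[0] / qn; hy = qcen[1] / qn; hz = qcen[2] / qn; }
  const double invr = 1.0 / sr2, invt = 1.0 / st2;
  for (int e = 0; e < ne; ++e) {
    const double il = invlam[e];
    for (int p = 0; p < np; ++p) {
      const double dx = dirs(p, 0) * il - qcen[0];
      const double dy = dirs(p, 1) * il - qcen[1];
      const double dz = (dirs(p, 2) - 1.0) * il - qcen[2];
      const double d2 = dx * dx + dy * dy + dz * dz;
      const double dpar = dx * hx + dy * hy + dz * hz;
      const double par2 = dpar * dpar;
      out(p, e) = omega[p] * amp *
        std::exp(-0.5 * (par2 * invr + (d2 - par2) * invt));
    }
  }
  return out;
}
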