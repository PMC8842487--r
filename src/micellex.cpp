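// Simulation kernels: Kuhn-rod chain sampling, exact intramolecular
// energetics, spherical-shell projections, and the dynamic SCMF Monte Carlo
// engine.  All lengths in bead diameters (sigma), energies in kBT.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double HC_TOL = 1e-9;     // hard-core tolerance (sigma)

static inline void rand_unit_vec(double &x, double &y, double &z) {
  // Marsaglia (1972) uniform direction on the sphere, using R's RNG
  double u, v, s;
  do {
    u = 2.0 * unif_rand() - 1.0;
    v = 2.0 * unif_rand() - 1.0;
    s = u * u + v * v;
  } while (s >= 1.0 || s == 0.0);
  double f = 2.0 * std::sqrt(1.0 - s);
  x = u * f;
  y = v * f;
  z = 1.0 - 2.0 * s;
}

static inline double dist2(const double *a, const double *b) {
  double dx = a[0] - b[0], dy = a[1] - b[1], dz = a[2] - b[2];
  return dx * dx + dy * dy + dz * dz;
}

// any non-bonded pair closer than the hard core?
static bool has_overlap(const std::vector<double> &p, int n) {
  const double lim = (1.0 - HC_TOL) * (1.0 - HC_TOL);
  for (int i = 0; i < n; ++i)
    for (int j = i + 2; j < n; ++j)
      if (dist2(&p[3 * i], &p[3 * j]) < lim) return true;
  return false;
}

// build one freely-jointed chain of rigid rods; bead 0 at the origin.
// Rejection is immediate at the first hard-core violation, which leaves the
// accepted-sample distribution identical to whole-chain rejection but skips
// the doomed remainder of the build.
static bool build_chain(const IntegerVector &seg_len, std::vector<double> &p) {
  int n = 0;
  for (int s = 0; s < seg_len.size(); ++s) n += seg_len[s];
  p.assign(3 * n, 0.0);
  const double lim = (1.0 - HC_TOL) * (1.0 - HC_TOL);
  int b = 0;
  double last[3] = {0.0, 0.0, 0.0};
  for (int s = 0; s < seg_len.size(); ++s) {
    double ux, uy, uz;
    rand_unit_vec(ux, uy, uz);
    int m = seg_len[s];
    double start[3];
    if (s == 0) {
      start[0] = 0.0; start[1] = 0.0; start[2] = 0.0;
    } else {
      start[0] = last[0] + ux; start[1] = last[1] + uy; start[2] = last[2] + uz;
    }
    for (int j = 0; j < m; ++j) {
      p[3 * b + 0] = start[0] + j * ux;
      p[3 * b + 1] = start[1] + j * uy;
      p[3 * b + 2] = start[2] + j * uz;
      for (int k = 0; k < b - 1; ++k) {
        if (dist2(&p[3 * b], &p[3 * k]) < lim) return false;
      }
      ++b;
    }
    last[0] = p[3 * (b - 1) + 0];
    last[1] = p[3 * (b - 1) + 1];
    last[2] = p[3 * (b - 1) + 2];
  }
  return true;
}

// [[Rcpp::export]]
NumericMatrix cpp_sample_chain(IntegerVector seg_len, int max_attempts) {
  std::vector<double> p;
  int n = 0;
  for (int s = 0; s < seg_len.size(); ++s) {
    if (seg_len[s] < 1) stop("segment lengths must be >= 1");
    n += seg_len[s];
  }
  for (int a = 0; a < max_attempts; ++a) {
    if (build_chain(seg_len, p)) {
      NumericMatrix out(n, 3);
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < 3; ++k) out(i, k) = p[3 * i + k];
      return out;
    }
  }
  stop("no self-avoiding conformation found after %d attempts", max_attempts);
}

// [[Rcpp::export]]
double cpp_intra_energy(NumericMatrix pos, IntegerVector block,
                        double eps_contact, double rc_outer) {
  int n = pos.nrow();
  std::vector<double> p(3 * n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) p[3 * i + k] = pos(i, k);
  const double hc2 = (1.0 - HC_TOL) * (1.0 - HC_TOL);
  const double rc2 = rc_outer * rc_outer;
  double e = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 2; j < n; ++j) {
      double d2 = dist2(&p[3 * i], &p[3 * j]);
      if (d2 < hc2) return R_PosInf;
      if (d2 <= rc2 && block[i] != block[j]) e += eps_contact;
    }
  }
  return e;
}

// Rodrigues rotation of rows [from, n) about unit axis through point c
static void rotate_tail(std::vector<double> &p, int from, int n,
                        const double *c, const double *ax, double theta) {
  double ct = std::cos(theta), st = std::sin(theta);
  for (int i = from; i < n; ++i) {
    double vx = p[3 * i + 0] - c[0];
    double vy = p[3 * i + 1] - c[1];
    double vz = p[3 * i + 2] - c[2];
    double dot = ax[0] * vx + ax[1] * vy + ax[2] * vz;
    double cx = ax[1] * vz - ax[2] * vy;
    double cy = ax[2] * vx - ax[0] * vz;
    double cz = ax[0] * vy - ax[1] * vx;
    p[3 * i + 0] = c[0] + vx * ct + cx * st + ax[0] * dot * (1 - ct);
    p[3 * i + 1] = c[1] + vy * ct + cy * st + ax[1] * dot * (1 - ct);
    p[3 * i + 2] = c[2] + vz * ct + cz * st + ax[2] * dot * (1 - ct);
  }
}

// symmetric local move: pivot of one side about a random inter-segment joint,
// or rigid whole-chain translation; amplitude sets the max angle (rad) and
// max step (sigma)
static bool propose_move(std::vector<double> &p, int n,
                         const IntegerVector &seg_end, double amplitude) {
  if (amplitude <= 0.0) return false;
  int njoint = seg_end.size() - 1;  // joints between consecutive segments
  bool do_pivot = njoint > 0 && unif_rand() < 0.5;
  if (do_pivot) {
    int j = (int)std::floor(unif_rand() * njoint);
    if (j >= njoint) j = njoint - 1;
    int pivot = seg_end[j];          // 0-based index of the joint bead
    double c[3] = {p[3 * pivot], p[3 * pivot + 1], p[3 * pivot + 2]};
    double ax[3];
    rand_unit_vec(ax[0], ax[1], ax[2]);
    double theta = amplitude * (2.0 * unif_rand() - 1.0);
    if (unif_rand() < 0.5) {
      rotate_tail(p, pivot + 1, n, c, ax, theta);
    } else {
      // rotate the head side: beads [0, pivot)
      double ct = std::cos(theta), st = std::sin(theta);
      for (int i = 0; i < pivot; ++i) {
        double vx = p[3 * i + 0] - c[0];
        double vy = p[3 * i + 1] - c[1];
        double vz = p[3 * i + 2] - c[2];
        double dot = ax[0] * vx + ax[1] * vy + ax[2] * vz;
        double cx = ax[1] * vz - ax[2] * vy;
        double cy = ax[2] * vx - ax[0] * vz;
        double cz = ax[0] * vy - ax[1] * vx;
        p[3 * i + 0] = c[0] + vx * ct + cx * st + ax[0] * dot * (1 - ct);
        p[3 * i + 1] = c[1] + vy * ct + cy * st + ax[1] * dot * (1 - ct);
        p[3 * i + 2] = c[2] + vz * ct + cz * st + ax[2] * dot * (1 - ct);
      }
    }
  } else {
    double ux, uy, uz;
    rand_unit_vec(ux, uy, uz);
    double step = amplitude * unif_rand();
    for (int i = 0; i < n; ++i) {
      p[3 * i + 0] += step * ux;
      p[3 * i + 1] += step * uy;
      p[3 * i + 2] += step * uz;
    }
    return true;
  }
  return false;
}

// [[Rcpp::export]]
NumericMatrix cpp_perturb(NumericMatrix pos, IntegerVector seg_end,
                          double amplitude) {
  int n = pos.nrow();
  std::vector<double> p(3 * n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) p[3 * i + k] = pos(i, k);
  propose_move(p, n, seg_end, amplitude);
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) out(i, k) = p[3 * i + k];
  return out;
}

// volume of ball(origin, R) \cap ball(center at distance s, rho)
static double sphere_cap_vol(double R, double rho, double s) {
  if (R <= 0.0 || rho <= 0.0) return 0.0;
  if (s >= R + rho) return 0.0;
  double rmin = std::min(R, rho);
  if (s <= std::fabs(R - rho))
    return 4.0 / 3.0 * M_PI * rmin * rmin * rmin;
  double t = R + rho - s;
  return M_PI * t * t *
         (s * s + 2.0 * s * rho - 3.0 * rho * rho + 2.0 * s * R +
          6.0 * rho * R - 3.0 * R * R) /
         (12.0 * s);
}

// square-well shell {win <= |x - b| <= wout} volume inside lattice shell
// [R1, R2], for a bead at radius s
static double well_in_shell(double s, double R1, double R2, double win,
                            double wout) {
  double v = sphere_cap_vol(R2, wout, s) - sphere_cap_vol(R2, win, s) -
             (sphere_cap_vol(R1, wout, s) - sphere_cap_vol(R1, win, s));
  return v > 0.0 ? v : 0.0;
}

struct Projection {
  std::vector<double> cntEO, cntPO;   // bead counts per shell
  std::vector<double> wEO, wPO;       // well volume per shell
  bool outside;
};

// fraction of each bead's square-well shell accessible to solvent and
// neighbouring molecules, i.e. not excluded by the chain's own beads
// (pairwise overlap approximation)
static void intra_screening(const std::vector<double> &p, int n, double win,
                            double wout, std::vector<double> &s) {
  double vwell = 4.0 / 3.0 * M_PI * (wout * wout * wout - win * win * win);
  s.assign(n, 1.0);
  for (int i = 0; i < n; ++i) {
    double blocked = 0.0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double d = std::sqrt(dist2(&p[3 * i], &p[3 * j]));
      if (d >= wout + 1.0) continue;
      blocked += sphere_cap_vol(wout, 1.0, d) - sphere_cap_vol(win, 1.0, d);
    }
    // independent-overlap closure for the union of the exclusion spheres:
    // exact to first order in the blocked fraction, saturating below 1
    s[i] = std::exp(-blocked / vwell);
  }
}

static void project_chain(const std::vector<double> &p, int n,
                          const IntegerVector &block,
                          const std::vector<double> &edges, double win,
                          double wout, Projection &pr, bool screen,
                          const std::vector<double> *scr_pre = 0) {
  int R = (int)edges.size() - 1;
  pr.cntEO.assign(R, 0.0);
  pr.cntPO.assign(R, 0.0);
  pr.wEO.assign(R, 0.0);
  pr.wPO.assign(R, 0.0);
  pr.outside = false;
  double Rmax = edges[R];
  std::vector<double> scr_own;
  const std::vector<double> *scr = 0;
  if (screen) {
    if (scr_pre) {
      scr = scr_pre;
    } else {
      intra_screening(p, n, win, wout, scr_own);
      scr = &scr_own;
    }
  }
  for (int i = 0; i < n; ++i) {
    double s = std::sqrt(p[3 * i] * p[3 * i] + p[3 * i + 1] * p[3 * i + 1] +
                         p[3 * i + 2] * p[3 * i + 2]);
    if (s > Rmax) {
      pr.outside = true;
      continue;
    }
    int sh = R - 1;
    for (int r = 0; r < R; ++r) {
      if (s < edges[r + 1]) { sh = r; break; }
    }
    bool eo = block[i] == 0;
    if (eo) pr.cntEO[sh] += 1.0; else pr.cntPO[sh] += 1.0;
    // apportion the square-well shell around this bead to lattice shells
    int lo = 0;
    while (lo < R && edges[lo + 1] < s - wout) ++lo;
    for (int r = lo; r < R; ++r) {
      if (edges[r] > s + wout) break;
      double v = well_in_shell(s, edges[r], edges[r + 1], win, wout);
      if (screen) v *= (*scr)[i];
      if (eo) pr.wEO[r] += v; else pr.wPO[r] += v;
    }
  }
}

// [[Rcpp::export]]
List cpp_project(NumericMatrix pos, IntegerVector block, NumericVector edges,
                 double well_inner, double well_outer, bool screen_intra) {
  int n = pos.nrow();
  std::vector<double> p(3 * n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) p[3 * i + k] = pos(i, k);
  std::vector<double> ed(edges.begin(), edges.end());
  Projection pr;
  project_chain(p, n, block, ed, well_inner, well_outer, pr, screen_intra);
  return List::create(_["count_EO"] = wrap(pr.cntEO),
                      _["count_PO"] = wrap(pr.cntPO),
                      _["well_EO"] = wrap(pr.wEO),
                      _["well_PO"] = wrap(pr.wPO),
                      _["outside"] = pr.outside);
}

// [[Rcpp::export]]
List cpp_project_ensemble(List chains, IntegerVector block,
                          NumericVector edges, double well_inner,
                          double well_outer, bool screen_intra) {
  int M = chains.size();
  int R = edges.size() - 1;
  NumericMatrix cEO(M, R), cPO(M, R), wEO(M, R), wPO(M, R);
  LogicalVector outside(M);
  std::vector<double> ed(edges.begin(), edges.end());
  Projection pr;
  for (int m = 0; m < M; ++m) {
    NumericMatrix pos = chains[m];
    int n = pos.nrow();
    std::vector<double> p(3 * n);
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 3; ++k) p[3 * i + k] = pos(i, k);
    project_chain(p, n, block, ed, well_inner, well_outer, pr, screen_intra);
    for (int r = 0; r < R; ++r) {
      cEO(m, r) = pr.cntEO[r];
      cPO(m, r) = pr.cntPO[r];
      wEO(m, r) = pr.wEO[r];
      wPO(m, r) = pr.wPO[r];
    }
    outside[m] = pr.outside;
  }
  return List::create(_["count_EO"] = cEO, _["count_PO"] = cPO,
                      _["well_EO"] = wEO, _["well_PO"] = wPO,
                      _["outside"] = outside);
}

// ---------------------------------------------------------------------------
// dynamic SCMF Monte Carlo engine

struct ChainState {
  std::vector<double> p;  // 3n coordinates
  Projection proj;
  std::vector<double> scr;  // accessible well fractions (screening cache)
  double uintra;
  bool member;            // inside the micelle (with hysteresis)
};

static double intra_energy_vec(const std::vector<double> &p, int n,
                               const IntegerVector &block, double eps_contact,
                               double rc_outer) {
  const double hc2 = (1.0 - HC_TOL) * (1.0 - HC_TOL);
  const double rc2 = rc_outer * rc_outer;
  double e = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 2; j < n; ++j) {
      double d2 = dist2(&p[3 * i], &p[3 * j]);
      if (d2 < hc2) return R_PosInf;
      if (d2 <= rc2 && block[i] != block[j]) e += eps_contact;
    }
  return e;
}

// interchain + solvent + incompressibility part of the single-chain
// Hamiltonian, given this chain's projection and the minus-self fields
static double h_inter(const Projection &pr, int R,
                      const std::vector<double> &cntEO,
                      const std::vector<double> &cntPO,
                      const std::vector<double> &wEOt,
                      const std::vector<double> &wPOt,
                      const std::vector<double> &cs,
                      const std::vector<double> &pi,
                      const std::vector<double> &Vr, double eps_eopo,
                      double eps_eos, double eps_pos, double v_p) {
  double h = 0.0;
  for (int r = 0; r < R; ++r) {
    double cEO_mi = (cntEO[r] - pr.cntEO[r]) / Vr[r];
    double cPO_mi = (cntPO[r] - pr.cntPO[r]) / Vr[r];
    double wEO_mi = wEOt[r] - pr.wEO[r];
    double wPO_mi = wPOt[r] - pr.wPO[r];
    h += 0.5 * eps_eopo *
         (pr.wEO[r] * cPO_mi + pr.cntPO[r] * wEO_mi / Vr[r] +
          pr.wPO[r] * cEO_mi + pr.cntEO[r] * wPO_mi / Vr[r]);
    h += (eps_eos * pr.wEO[r] + eps_pos * pr.wPO[r]) * cs[r];
    h += pi[r] * v_p * (pr.cntEO[r] + pr.cntPO[r]);
  }
  return h;
}

static void solve_fields(int R, const std::vector<double> &cntEO,
                         const std::vector<double> &cntPO,
                         const std::vector<double> &wEOt,
                         const std::vector<double> &wPOt,
                         const std::vector<double> &Vr, double v_p,
                         double v_s, double eps_eos, double eps_pos,
                         std::vector<double> &cs, std::vector<double> &pi) {
  const double phimin = 1e-10;
  for (int r = 0; r < R; ++r) {
    double phi_ch = (cntEO[r] + cntPO[r]) * v_p / Vr[r];
    double phis = 1.0 - phi_ch;
    if (phis < phimin) phis = phimin;
    cs[r] = phis / v_s;
    double hs = (eps_eos * wEOt[r] + eps_pos * wPOt[r]) / Vr[r];
    pi[r] = -(std::log(phis) + hs) / v_s;
  }
  double ref = pi[R - 1];
  for (int r = 0; r < R; ++r) pi[r] -= ref;
}

static void po_shape(const std::vector<double> &p, int n,
                     const IntegerVector &block, double &r_po, double &rg_po,
                     double &angle) {
  double cpo[3] = {0, 0, 0}, ce1[3] = {0, 0, 0}, ce2[3] = {0, 0, 0};
  int npo = 0, ne1 = 0, ne2 = 0;
  bool seen_po = false;
  for (int i = 0; i < n; ++i) {
    if (block[i] == 1) {
      seen_po = true;
      for (int k = 0; k < 3; ++k) cpo[k] += p[3 * i + k];
      ++npo;
    } else if (!seen_po) {
      for (int k = 0; k < 3; ++k) ce1[k] += p[3 * i + k];
      ++ne1;
    } else {
      for (int k = 0; k < 3; ++k) ce2[k] += p[3 * i + k];
      ++ne2;
    }
  }
  for (int k = 0; k < 3; ++k) cpo[k] /= npo;
  r_po = std::sqrt(cpo[0] * cpo[0] + cpo[1] * cpo[1] + cpo[2] * cpo[2]);
  double s = 0.0;
  for (int i = 0; i < n; ++i)
    if (block[i] == 1) s += dist2(&p[3 * i], cpo);
  rg_po = std::sqrt(s / npo);
  angle = NA_REAL;
  if (ne1 > 0 && ne2 > 0) {
    double v1[3], v2[3];
    double n1 = 0, n2 = 0, dot = 0;
    for (int k = 0; k < 3; ++k) {
      v1[k] = ce1[k] / ne1 - cpo[k];
      v2[k] = ce2[k] / ne2 - cpo[k];
      n1 += v1[k] * v1[k];
      n2 += v2[k] * v2[k];
      dot += v1[k] * v2[k];
    }
    if (n1 > 1e-24 && n2 > 1e-24) {
      double c = dot / std::sqrt(n1 * n2);
      if (c > 1.0) c = 1.0;
      if (c < -1.0) c = -1.0;
      angle = std::acos(c) * 180.0 / M_PI;
    }
  }
}

// [[Rcpp::export]]
List cpp_mc_run(List chains0, IntegerVector block, IntegerVector seg_end,
                NumericVector edges, NumericVector shell_vol,
                double eps_eopo, double eps_eos, double eps_pos,
                double well_inner, double well_outer, double v_p, double v_s,
                double amplitude, int n_cycles, int stride,
                LogicalVector tagged0, double r_bound, double hyst,
                bool freeze_fields, NumericVector ext_cs, NumericVector ext_pi,
                NumericVector ext_cEO, NumericVector ext_cPO,
                int profile_every, double prof_bin, int n_prof_bins,
                bool screen_intra) {
  int NC = chains0.size();
  int R = edges.size() - 1;
  std::vector<double> ed(edges.begin(), edges.end());
  std::vector<double> Vr(shell_vol.begin(), shell_vol.end());
  std::vector<ChainState> ch(NC);
  int nb = 0;
  for (int i = 0; i < NC; ++i) {
    NumericMatrix pos = chains0[i];
    nb = pos.nrow();
    ch[i].p.resize(3 * nb);
    for (int b = 0; b < nb; ++b)
      for (int k = 0; k < 3; ++k) ch[i].p[3 * b + k] = pos(b, k);
    if (screen_intra)
      intra_screening(ch[i].p, nb, well_inner, well_outer, ch[i].scr);
    project_chain(ch[i].p, nb, block, ed, well_inner, well_outer, ch[i].proj,
                  screen_intra, screen_intra ? &ch[i].scr : 0);
    ch[i].uintra = intra_energy_vec(ch[i].p, nb, block, eps_eopo, well_outer);
    double r_po, rg, ang;
    po_shape(ch[i].p, nb, block, r_po, rg, ang);
    ch[i].member = r_po < r_bound;
  }

  // totals
  std::vector<double> cntEO(R, 0.0), cntPO(R, 0.0), wEOt(R, 0.0), wPOt(R, 0.0);
  for (int i = 0; i < NC; ++i)
    for (int r = 0; r < R; ++r) {
      cntEO[r] += ch[i].proj.cntEO[r];
      cntPO[r] += ch[i].proj.cntPO[r];
      wEOt[r] += ch[i].proj.wEO[r];
      wPOt[r] += ch[i].proj.wPO[r];
    }
  std::vector<double> cs(R), pi(R);
  if (freeze_fields) {
    cs.assign(ext_cs.begin(), ext_cs.end());
    pi.assign(ext_pi.begin(), ext_pi.end());
  } else {
    solve_fields(R, cntEO, cntPO, wEOt, wPOt, Vr, v_p, v_s, eps_eos, eps_pos,
                 cs, pi);
  }

  int n_rec = n_cycles / stride;
  IntegerVector rec_cycle(n_rec);
  IntegerVector rec_f(n_rec);
  NumericVector rec_acc(n_rec);

  // profile accumulators
  NumericVector prof_rg(n_prof_bins), prof_angle(n_prof_bins);
  IntegerVector prof_n(n_prof_bins), prof_n_angle(n_prof_bins);
  // occupancy of the chain-0 PO-com shell (used by frozen-field checks)
  NumericVector occupancy(R);
  // time-averaged concentration fields
  NumericVector avg_cEO(R), avg_cPO(R);
  long n_avg = 0;

  std::vector<double> cntEO_snap, cntPO_snap, wEO_snap, wPO_snap;
  std::vector<double> pnew(3 * nb);
  std::vector<double> scrnew;
  Projection prnew;
  long accepted = 0, proposed = 0, acc_win = 0, prop_win = 0;
  double Rmax = ed[R];

  for (int cyc = 1; cyc <= n_cycles; ++cyc) {
    cntEO_snap = cntEO; cntPO_snap = cntPO; wEO_snap = wEOt; wPO_snap = wPOt;
    for (int i = 0; i < NC; ++i) {
      pnew = ch[i].p;
      bool translated = propose_move(pnew, nb, seg_end, amplitude);
      // reject beads leaving the cell
      bool out = false;
      for (int b = 0; b < nb && !out; ++b) {
        double s2 = pnew[3 * b] * pnew[3 * b] + pnew[3 * b + 1] * pnew[3 * b + 1] +
                    pnew[3 * b + 2] * pnew[3 * b + 2];
        if (s2 > Rmax * Rmax) out = true;
      }
      ++proposed; ++prop_win;
      if (out) continue;
      double unew;
      if (translated) {
        // rigid translation: internal geometry (energy, screening) unchanged
        unew = ch[i].uintra;
        scrnew = ch[i].scr;
      } else {
        unew = intra_energy_vec(pnew, nb, block, eps_eopo, well_outer);
        if (!R_FINITE(unew)) continue;
        if (screen_intra)
          intra_screening(pnew, nb, well_inner, well_outer, scrnew);
      }
      project_chain(pnew, nb, block, ed, well_inner, well_outer, prnew,
                    screen_intra, screen_intra ? &scrnew : 0);
      double hold, hnew;
      if (freeze_fields && ext_cEO.size() == R) {
        // fully external fields: couple to supplied concentrations
        hold = 0.0; hnew = 0.0;
        for (int r = 0; r < R; ++r) {
          hold += eps_eopo * (ch[i].proj.wEO[r] * ext_cPO[r] +
                              ch[i].proj.wPO[r] * ext_cEO[r]) +
                  (eps_eos * ch[i].proj.wEO[r] + eps_pos * ch[i].proj.wPO[r]) * cs[r] +
                  pi[r] * v_p * (ch[i].proj.cntEO[r] + ch[i].proj.cntPO[r]);
          hnew += eps_eopo * (prnew.wEO[r] * ext_cPO[r] +
                              prnew.wPO[r] * ext_cEO[r]) +
                  (eps_eos * prnew.wEO[r] + eps_pos * prnew.wPO[r]) * cs[r] +
                  pi[r] * v_p * (prnew.cntEO[r] + prnew.cntPO[r]);
        }
      } else {
        hold = h_inter(ch[i].proj, R, cntEO_snap, cntPO_snap, wEO_snap,
                       wPO_snap, cs, pi, Vr, eps_eopo, eps_eos, eps_pos, v_p);
        hnew = h_inter(prnew, R, cntEO_snap, cntPO_snap, wEO_snap, wPO_snap,
                       cs, pi, Vr, eps_eopo, eps_eos, eps_pos, v_p);
      }
      double dh = (unew + hnew) - (ch[i].uintra + hold);
      if (dh <= 0.0 || unif_rand() < std::exp(-dh)) {
        // update live totals
        for (int r = 0; r < R; ++r) {
          cntEO[r] += prnew.cntEO[r] - ch[i].proj.cntEO[r];
          cntPO[r] += prnew.cntPO[r] - ch[i].proj.cntPO[r];
          wEOt[r] += prnew.wEO[r] - ch[i].proj.wEO[r];
          wPOt[r] += prnew.wPO[r] - ch[i].proj.wPO[r];
        }
        ch[i].p = pnew;
        ch[i].proj = prnew;
        ch[i].scr = scrnew;
        ch[i].uintra = unew;
        ++accepted; ++acc_win;
      }
    }
    if (!freeze_fields) {
      solve_fields(R, cntEO, cntPO, wEOt, wPOt, Vr, v_p, v_s, eps_eos,
                   eps_pos, cs, pi);
    }
    // per-cycle occupancy of the first chain (frozen-field diagnostics)
    if (freeze_fields) {
      double r_po, rg, ang;
      po_shape(ch[0].p, nb, block, r_po, rg, ang);
      int sh = R - 1;
      for (int r = 0; r < R; ++r)
        if (r_po < ed[r + 1]) { sh = r; break; }
      occupancy[sh] += 1.0;
    }
    bool do_profile = profile_every > 0 && cyc % profile_every == 0;
    bool do_record = cyc % stride == 0;
    if (do_profile || do_record) {
      int f = 0;
      for (int i = 0; i < NC; ++i) {
        double r_po, rg, ang;
        po_shape(ch[i].p, nb, block, r_po, rg, ang);
        if (ch[i].member && r_po > r_bound + hyst) ch[i].member = false;
        else if (!ch[i].member && r_po < r_bound) ch[i].member = true;
        if (ch[i].member && tagged0[i]) ++f;
        if (do_profile) {
          int bin = (int)std::floor(r_po / prof_bin);
          if (bin >= 0 && bin < n_prof_bins) {
            prof_rg[bin] += rg;
            prof_n[bin] += 1;
            if (R_FINITE(ang)) {
              prof_angle[bin] += ang;
              prof_n_angle[bin] += 1;
            }
          }
        }
      }
      if (do_record) {
        int k = cyc / stride - 1;
        rec_cycle[k] = cyc;
        rec_f[k] = f;
        rec_acc[k] = prop_win > 0 ? (double)acc_win / prop_win : NA_REAL;
        acc_win = 0; prop_win = 0;
      }
      for (int r = 0; r < R; ++r) {
        avg_cEO[r] += cntEO[r] / Vr[r];
        avg_cPO[r] += cntPO[r] / Vr[r];
      }
      ++n_avg;
    }
  }
  for (int r = 0; r < R; ++r) {
    avg_cEO[r] /= n_avg;
    avg_cPO[r] /= n_avg;
  }
  List final_chains(NC);
  LogicalVector member(NC);
  for (int i = 0; i < NC; ++i) {
    NumericMatrix pos(nb, 3);
    for (int b = 0; b < nb; ++b)
      for (int k = 0; k < 3; ++k) pos(b, k) = ch[i].p[3 * b + k];
    final_chains[i] = pos;
    member[i] = ch[i].member;
  }
  return List::create(
      _["cycle"] = rec_cycle, _["f"] = rec_f, _["acceptance"] = rec_acc,
      _["accept_rate"] = proposed > 0 ? (double)accepted / proposed : NA_REAL,
      _["chains"] = final_chains, _["member"] = member,
      _["prof_rg_sum"] = prof_rg, _["prof_angle_sum"] = prof_angle,
      _["prof_n"] = prof_n, _["prof_n_angle"] = prof_n_angle,
      _["occupancy"] = occupancy, _["avg_cEO"] = avg_cEO,
      _["avg_cPO"] = avg_cPO, _["cs"] = wrap(cs), _["pi"] = wrap(pi));
}

// free-space Monte Carlo for the centre-of-mass diffusion constant
// [[Rcpp::export]]
List cpp_msd_run(List chains0, IntegerVector block, IntegerVector seg_end,
                 double eps_eopo, double well_outer, double amplitude,
                 int n_cycles, int stride) {
  int NC = chains0.size();
  std::vector<std::vector<double> > p(NC);
  int nb = 0;
  for (int i = 0; i < NC; ++i) {
    NumericMatrix pos = chains0[i];
    nb = pos.nrow();
    p[i].resize(3 * nb);
    for (int b = 0; b < nb; ++b)
      for (int k = 0; k < 3; ++k) p[i][3 * b + k] = pos(b, k);
  }
  std::vector<double> u(NC);
  std::vector<double> com0(3 * NC);
  for (int i = 0; i < NC; ++i) {
    u[i] = intra_energy_vec(p[i], nb, block, eps_eopo, well_outer);
    double c[3] = {0, 0, 0};
    for (int b = 0; b < nb; ++b)
      for (int k = 0; k < 3; ++k) c[k] += p[i][3 * b + k];
    for (int k = 0; k < 3; ++k) com0[3 * i + k] = c[k] / nb;
  }
  int n_rec = n_cycles / stride;
  IntegerVector rec_cycle(n_rec);
  NumericVector rec_msd(n_rec);
  std::vector<double> pnew(3 * nb);
  long accepted = 0, proposed = 0;
  for (int cyc = 1; cyc <= n_cycles; ++cyc) {
    for (int i = 0; i < NC; ++i) {
      pnew = p[i];
      propose_move(pnew, nb, seg_end, amplitude);
      ++proposed;
      double unew = intra_energy_vec(pnew, nb, block, eps_eopo, well_outer);
      if (!R_FINITE(unew)) continue;
      double dh = unew - u[i];
      if (dh <= 0.0 || unif_rand() < std::exp(-dh)) {
        p[i] = pnew;
        u[i] = unew;
        ++accepted;
      }
    }
    if (cyc % stride == 0) {
      double msd = 0.0;
      for (int i = 0; i < NC; ++i) {
        double c[3] = {0, 0, 0};
        for (int b = 0; b < nb; ++b)
          for (int k = 0; k < 3; ++k) c[k] += p[i][3 * b + k];
        double d2 = 0.0;
        for (int k = 0; k < 3; ++k) {
          double d = c[k] / nb - com0[3 * i + k];
          d2 += d * d;
        }
        msd += d2;
      }
      int krec = cyc / stride - 1;
      rec_cycle[krec] = cyc;
      rec_msd[krec] = msd / NC;
    }
  }
  return List::create(_["cycle"] = rec_cycle, _["msd"] = rec_msd,
                      _["accept_rate"] =
                          proposed > 0 ? (double)accepted / proposed : NA_REAL);
}
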