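// Metropolis Monte Carlo kernel and batch reduced-potential evaluation for
// the lambda-coupled toy Hamiltonian. The energy model mirrors the plain R
// evaluator in R/alchemy.R term by term (validated against it in the test
// suite): harmonic bonds/angles, always-on proper dihedrals, switched
// truncated-harmonic torsion profiles, Beutler soft-core LJ+Coulomb pairs,
// and lambda-scaled harmonic restraints (torsion, distance, angle,
// center-of-mass pseudodihedral).

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double wrap_rad(double x) {
  double y = x - 2.0 * M_PI * std::round(x / (2.0 * M_PI));
  if (y <= -M_PI) y += 2.0 * M_PI;
  return y;
}

struct Vec3 { double x, y, z; };
static inline Vec3 vsub(const Vec3 &a, const Vec3 &b) { return {a.x-b.x, a.y-b.y, a.z-b.z}; }
static inline Vec3 vcross(const Vec3 &a, const Vec3 &b) {
  return {a.y*b.z - a.z*b.y, a.z*b.x - a.x*b.z, a.x*b.y - a.y*b.x};
}
static inline double vdot(const Vec3 &a, const Vec3 &b) { return a.x*b.x + a.y*b.y + a.z*b.z; }
static inline double vnorm(const Vec3 &a) { return std::sqrt(vdot(a, a)); }

static inline Vec3 getp(const double *xyz, int i) { // i 0-based
  return {xyz[3*i], xyz[3*i+1], xyz[3*i+2]};
}

static inline double dist(const double *xyz, int i, int j) {
  Vec3 d = vsub(getp(xyz, i), getp(xyz, j));
  return vnorm(d);
}

static inline double angle3(const Vec3 &p1, const Vec3 &p2, const Vec3 &p3) {
  Vec3 v1 = vsub(p1, p2), v2 = vsub(p3, p2);
  double c = vdot(v1, v2) / (vnorm(v1) * vnorm(v2));
  if (c > 1.0) c = 1.0; if (c < -1.0) c = -1.0;
  return std::acos(c);
}

// signed torsion, radians; NaN when degenerate
static inline double torsion4(const Vec3 &p1, const Vec3 &p2, const Vec3 &p3,
                              const Vec3 &p4) {
  Vec3 b1 = vsub(p2, p1), b2 = vsub(p3, p2), b3 = vsub(p4, p3);
  Vec3 n1 = vcross(b1, b2), n2 = vcross(b2, b3);
  double n1n = vnorm(n1), n2n = vnorm(n2), b2n = vnorm(b2);
  if (n1n < 1e-12 || n2n < 1e-12 || b2n < 1e-12) return NAN;
  double x = vdot(n1, n2);
  double y = vdot(vcross(n1, n2), b2) / b2n;
  return std::atan2(y, x);
}

// Flattened topology + restraint tables (built by topology_tables() in R)
struct Tables {
  int n;
  NumericMatrix bonds, angles, dihedrals, prof_terms, prof_wells, pairs;
  NumericMatrix rt, rd, ra, rp_off, rp_par;
  IntegerVector rp_idx;
  NumericVector rp_w;
  double sc_alpha, sc_sigma6; int sc_power;
  double fcoul;
  IntegerVector rot_idx, rot_off;
  IntegerMatrix rot_axis;
  Tables(List t)
    : n(as<int>(t["n"])),
      bonds(as<NumericMatrix>(t["bonds"])),
      angles(as<NumericMatrix>(t["angles"])),
      dihedrals(as<NumericMatrix>(t["dihedrals"])),
      prof_terms(as<NumericMatrix>(t["prof_terms"])),
      prof_wells(as<NumericMatrix>(t["prof_wells"])),
      pairs(as<NumericMatrix>(t["pairs"])),
      rt(as<NumericMatrix>(t["rt"])),
      rd(as<NumericMatrix>(t["rd"])),
      ra(as<NumericMatrix>(t["ra"])),
      rp_off(as<NumericMatrix>(t["rp_off"])),
      rp_par(as<NumericMatrix>(t["rp_par"])),
      rp_idx(as<IntegerVector>(t["rp_idx"])),
      rp_w(as<NumericVector>(t["rp_w"])) {
    NumericVector sc = as<NumericVector>(t["sc"]);
    sc_alpha = sc[0]; sc_power = (int)sc[1];
    double s = sc[2]; sc_sigma6 = s*s*s*s*s*s;
    fcoul = as<double>(t["fcoul"]);
    rot_idx = as<IntegerVector>(t["rot_idx"]);
    rot_off = as<IntegerVector>(t["rot_off"]);
    rot_axis = as<IntegerMatrix>(t["rot_axis"]);
  }
};

// state: lc, lv, m_rv, m_vr, m_single
static double total_energy(const double *xyz, const Tables &tb,
                           const double *st) {
  const double lc = st[0], lv = st[1];
  const double mult[3] = {st[4], st[2], st[3]}; // single, rv, vr
  double e = 0.0;

  for (int i = 0; i < tb.bonds.nrow(); ++i) {
    double r = dist(xyz, (int)tb.bonds(i,0)-1, (int)tb.bonds(i,1)-1);
    double d = r - tb.bonds(i,3);
    e += 0.5 * tb.bonds(i,2) * d * d;
  }
  for (int i = 0; i < tb.angles.nrow(); ++i) {
    double th = angle3(getp(xyz,(int)tb.angles(i,0)-1),
                       getp(xyz,(int)tb.angles(i,1)-1),
                       getp(xyz,(int)tb.angles(i,2)-1));
    double d = th - tb.angles(i,4);
    e += 0.5 * tb.angles(i,3) * d * d;
  }
  for (int i = 0; i < tb.dihedrals.nrow(); ++i) {
    double phi = torsion4(getp(xyz,(int)tb.dihedrals(i,0)-1),
                          getp(xyz,(int)tb.dihedrals(i,1)-1),
                          getp(xyz,(int)tb.dihedrals(i,2)-1),
                          getp(xyz,(int)tb.dihedrals(i,3)-1));
    if (std::isnan(phi)) return INFINITY;
    e += tb.dihedrals(i,5) * (1.0 + std::cos(tb.dihedrals(i,4) * phi - tb.dihedrals(i,6)));
  }
  // switched torsion profiles: coupling = wv of the term's group
  int nprof = tb.prof_terms.nrow();
  std::vector<double> chi(nprof);
  for (int i = 0; i < nprof; ++i) {
    int g = (int)tb.prof_terms(i,4);
    double w = (g == 0) ? 1.0 : (g == 1 ? 1.0 - lv : lv);
    chi[i] = NAN;
    if (w == 0.0) continue;
    chi[i] = torsion4(getp(xyz,(int)tb.prof_terms(i,0)-1),
                      getp(xyz,(int)tb.prof_terms(i,1)-1),
                      getp(xyz,(int)tb.prof_terms(i,2)-1),
                      getp(xyz,(int)tb.prof_terms(i,3)-1));
    if (std::isnan(chi[i])) return INFINITY;
  }
  for (int w = 0; w < tb.prof_wells.nrow(); ++w) {
    int term = (int)tb.prof_wells(w,0) - 1;
    int g = (int)tb.prof_terms(term,4);
    double cpl = (g == 0) ? 1.0 : (g == 1 ? 1.0 - lv : lv);
    if (cpl == 0.0) continue;
    double D = tb.prof_wells(w,2), cc = tb.prof_wells(w,3);
    double reach2 = 2.0 * D / cc;
    double d = wrap_rad(chi[term] - tb.prof_wells(w,1));
    if (d * d <= reach2) e += cpl * (0.5 * cc * d * d - D);
  }
  // soft-core nonbonded
  for (int i = 0; i < tb.pairs.nrow(); ++i) {
    int g = (int)tb.pairs(i,5);
    double wv, wc, off;
    if (g == 0) { wv = 1.0; wc = 1.0; off = 0.0; }
    else if (g == 1) { wv = 1.0 - lv; wc = 1.0 - lc; off = lv; }
    else { wv = lv; wc = lc; off = 1.0 - lv; }
    if (wv == 0.0 && wc == 0.0) continue;
    double r = dist(xyz, (int)tb.pairs(i,0)-1, (int)tb.pairs(i,1)-1);
    double offp = off;
    for (int p = 1; p < tb.sc_power; ++p) offp *= off;
    double r6 = tb.sc_alpha * tb.sc_sigma6 * offp + std::pow(r, 6.0);
    double sig = tb.pairs(i,4);
    double s6 = sig*sig*sig*sig*sig*sig / r6;
    e += wv * 4.0 * tb.pairs(i,3) * (s6 * s6 - s6);
    double qq = tb.pairs(i,2);
    if (qq != 0.0) e += wc * tb.fcoul * qq / std::pow(r6, 1.0/6.0);
  }
  // restraints
  for (int i = 0; i < tb.rt.nrow(); ++i) {
    double m = mult[(int)tb.rt(i,6)];
    if (m == 0.0) continue;
    double phi = torsion4(getp(xyz,(int)tb.rt(i,0)-1), getp(xyz,(int)tb.rt(i,1)-1),
                          getp(xyz,(int)tb.rt(i,2)-1), getp(xyz,(int)tb.rt(i,3)-1));
    if (std::isnan(phi)) return INFINITY;
    double d = wrap_rad(phi - tb.rt(i,4));
    e += m * 0.5 * tb.rt(i,5) * d * d;
  }
  for (int i = 0; i < tb.rd.nrow(); ++i) {
    double m = mult[(int)tb.rd(i,4)];
    if (m == 0.0) continue;
    double r = dist(xyz, (int)tb.rd(i,0)-1, (int)tb.rd(i,1)-1);
    double d = r - tb.rd(i,2);
    e += m * 0.5 * tb.rd(i,3) * d * d;
  }
  for (int i = 0; i < tb.ra.nrow(); ++i) {
    double m = mult[(int)tb.ra(i,5)];
    if (m == 0.0) continue;
    double th = angle3(getp(xyz,(int)tb.ra(i,0)-1), getp(xyz,(int)tb.ra(i,1)-1),
                       getp(xyz,(int)tb.ra(i,2)-1));
    double d = wrap_rad(th - tb.ra(i,3));
    e += m * 0.5 * tb.ra(i,4) * d * d;
  }
  for (int i = 0; i < tb.rp_off.nrow(); ++i) {
    double m = mult[(int)tb.rp_par(i,2)];
    if (m == 0.0) continue;
    Vec3 c[4];
    for (int g = 0; g < 4; ++g) {
      int lo = (int)tb.rp_off(i,g), hi = (int)tb.rp_off(i,g+1);
      double sx=0, sy=0, sz=0, sw=0;
      for (int k = lo; k < hi; ++k) {
        int idx = tb.rp_idx[k] - 1;
        double w = tb.rp_w[k];
        sx += w * xyz[3*idx]; sy += w * xyz[3*idx+1]; sz += w * xyz[3*idx+2];
        sw += w;
      }
      c[g] = {sx/sw, sy/sw, sz/sw};
    }
    double phi = torsion4(c[0], c[1], c[2], c[3]);
    if (std::isnan(phi)) return INFINITY;
    double d = wrap_rad(phi - tb.rp_par(i,0));
    e += m * 0.5 * tb.rp_par(i,1) * d * d;
  }
  return e;
}

// [[Rcpp::export]]
double cpp_total_energy(NumericVector coords, List tables, NumericVector state) {
  Tables tb(tables);
  return total_energy(REAL(coords), tb, REAL(state));
}

// [[Rcpp::export]]
NumericMatrix cpp_eval_states(NumericMatrix frames, List tables,
                              NumericMatrix states, double beta) {
  Tables tb(tables);
  int nf = frames.nrow(), K = states.nrow();
  NumericMatrix u(K, nf);
  std::vector<double> xyz(3 * tb.n);
  for (int f = 0; f < nf; ++f) {
    for (int j = 0; j < 3 * tb.n; ++j) xyz[j] = frames(f, j);
    for (int k = 0; k < K; ++k) {
      double st[5] = {states(k,0), states(k,1), states(k,2), states(k,3), states(k,4)};
      u(k, f) = beta * total_energy(xyz.data(), tb, st);
    }
  }
  return u;
}

static void rotate_about(double *xyz, const int *idx, int nidx,
                         const Vec3 &a, const Vec3 &b, double angle) {
  Vec3 ax = vsub(b, a);
  double n = vnorm(ax);
  if (n < 1e-12) return;
  ax.x /= n; ax.y /= n; ax.z /= n;
  double c = std::cos(angle), s = std::sin(angle);
  for (int k = 0; k < nidx; ++k) {
    int i = idx[k] - 1;
    Vec3 p = {xyz[3*i] - a.x, xyz[3*i+1] - a.y, xyz[3*i+2] - a.z};
    Vec3 axp = vcross(ax, p);
    double ad = vdot(ax, p);
    Vec3 q = {p.x*c + axp.x*s + ax.x*ad*(1-c),
              p.y*c + axp.y*s + ax.y*ad*(1-c),
              p.z*c + axp.z*s + ax.z*ad*(1-c)};
    xyz[3*i] = q.x + a.x; xyz[3*i+1] = q.y + a.y; xyz[3*i+2] = q.z + a.z;
  }
}

// [[Rcpp::export]]
List cpp_metropolis(NumericVector coords0, List tables, NumericVector state,
                    double beta, int n_sweeps, int burn_sweeps, int stride,
                    double step_disp, double step_tor, bool adapt,
                    int n_log) {
  Tables tb(tables);
  const double *st = REAL(state);
  std::vector<double> xyz(coords0.begin(), coords0.end());
  std::vector<double> trial(xyz);
  int n = tb.n;
  int ncopies = tb.rot_axis.nrow();
  int n_frames = (n_sweeps > burn_sweeps && stride > 0)
                   ? (n_sweeps - burn_sweeps) / stride : 0;
  NumericMatrix frames(n_frames, 3 * n);
  NumericMatrix prop_log(std::max(n_log, 0), 3);
  int logged = 0;

  double ucur = total_energy(xyz.data(), tb, st);
  long acc_d = 0, tot_d = 0, acc_t = 0, tot_t = 0;       // post-burn-in
  long blk_acc_d = 0, blk_tot_d = 0, blk_acc_t = 0, blk_tot_t = 0;
  bool adapt_fail = false;
  int frame = 0;

  const double disp_min = 1e-4, disp_max = 1.0, tor_min = 1e-3, tor_max = 1.5;

  for (int s = 0; s < n_sweeps; ++s) {
    bool in_burn = s < burn_sweeps;
    // single-particle Cartesian displacements
    for (int p = 0; p < n; ++p) {
      std::copy(xyz.begin(), xyz.end(), trial.begin());
      trial[3*p]   += norm_rand() * step_disp;
      trial[3*p+1] += norm_rand() * step_disp;
      trial[3*p+2] += norm_rand() * step_disp;
      double unew = total_energy(trial.data(), tb, st);
      double du = beta * (unew - ucur);
      double r = unif_rand();
      bool accept = std::isfinite(unew) && (r < std::exp(-du));
      if (!in_burn && logged < n_log) {
        prop_log(logged, 0) = du; prop_log(logged, 1) = r;
        prop_log(logged, 2) = accept ? 1.0 : 0.0; ++logged;
      }
      if (accept) { std::swap(xyz, trial); ucur = unew; }
      if (in_burn) { blk_tot_d++; if (accept) blk_acc_d++; }
      else { tot_d++; if (accept) acc_d++; }
    }
    // collective torsion rotations of each conformer rotor
    for (int cidx = 0; cidx < ncopies; ++cidx) {
      std::copy(xyz.begin(), xyz.end(), trial.begin());
      int lo = tb.rot_off[cidx], hi = tb.rot_off[cidx + 1];
      Vec3 a = getp(trial.data(), tb.rot_axis(cidx,0) - 1);
      Vec3 b = getp(trial.data(), tb.rot_axis(cidx,1) - 1);
      double ang = norm_rand() * step_tor;
      std::vector<int> idx(tb.rot_idx.begin() + lo, tb.rot_idx.begin() + hi);
      rotate_about(trial.data(), idx.data(), hi - lo, a, b, ang);
      double unew = total_energy(trial.data(), tb, st);
      double du = beta * (unew - ucur);
      double r = unif_rand();
      bool accept = std::isfinite(unew) && (r < std::exp(-du));
      if (!in_burn && logged < n_log) {
        prop_log(logged, 0) = du; prop_log(logged, 1) = r;
        prop_log(logged, 2) = accept ? 1.0 : 0.0; ++logged;
      }
      if (accept) { std::swap(xyz, trial); ucur = unew; }
      if (in_burn) { blk_tot_t++; if (accept) blk_acc_t++; }
      else { tot_t++; if (accept) acc_t++; }
    }
    // step-size adaptation toward 30-50% acceptance during burn-in
    if (adapt && in_burn && (s + 1) % 50 == 0) {
      if (blk_tot_d > 0) {
        double ar = (double)blk_acc_d / blk_tot_d;
        if (blk_acc_d == 0 && step_disp <= disp_min * 1.0001) adapt_fail = true;
        if (ar > 0.5) step_disp *= 1.2; else if (ar < 0.3) step_disp /= 1.2;
        if (step_disp < disp_min) step_disp = disp_min;
        if (step_disp > disp_max) step_disp = disp_max;
      }
      if (blk_tot_t > 0) {
        double ar = (double)blk_acc_t / blk_tot_t;
        if (blk_acc_t == 0 && step_tor <= tor_min * 1.0001) adapt_fail = true;
        if (ar > 0.5) step_tor *= 1.2; else if (ar < 0.3) step_tor /= 1.2;
        if (step_tor < tor_min) step_tor = tor_min;
        if (step_tor > tor_max) step_tor = tor_max;
      }
      blk_acc_d = blk_tot_d = blk_acc_t = blk_tot_t = 0;
    }
    if (!in_burn && stride > 0 && (s - burn_sweeps + 1) % stride == 0 &&
        frame < n_frames) {
      for (int j = 0; j < 3 * n; ++j) frames(frame, j) = xyz[j];
      ++frame;
    }
  }

  return List::create(
    _["frames"] = frames,
    _["acceptance"] = NumericVector::create(
      _["displacement"] = tot_d > 0 ? (double)acc_d / tot_d : NA_REAL,
      _["torsion"] = tot_t > 0 ? (double)acc_t / tot_t : NA_REAL),
    _["steps"] = NumericVector::create(_["displacement"] = step_disp,
                                       _["torsion"] = step_tor),
    _["adapt_fail"] = adapt_fail,
    _["proposal_log"] = prop_log,
    _["final_coords"] = NumericVector(xyz.begin(), xyz.end()),
    _["final_energy"] = ucur);
}
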