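// Langevin / BMD integration engine.
//
// Units: length A, time ps, mass amu, energy kcal/mol.
// Forces in kcal/mol/A are converted to accelerations with
// KCAL_TO_AKMA = 418.4 amu A^2 ps^-2 per kcal/mol.
//
// Integrator: BAOAB splitting (B: half kick, A: half drift, O: exact
// Ornstein-Uhlenbeck velocity update), chosen for its accuracy in the
// high-friction regime (friction of order 60 ps^-1).

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <string>

using namespace Rcpp;

static const double KCAL_TO_AKMA = 418.4;
static const double KB_KCAL = 1.987204e-3; // kcal mol^-1 K^-1

enum TermKind {
  HARMONIC_WELL,
  FLAT_BOTTOM_PAIR,
  FUNNEL_RADIAL,
  DOUBLE_WELL_1D,
  VECTOR_BOND
};

struct Term {
  TermKind kind;
  int a1, a2;        // 0-based atom indices (a2 unused for single-atom terms)
  int dim;           // for double_well_1d
  double p1, p2, p3; // scalar parameters
  double ref[3];     // reference point / vector / per-dim k
  std::vector<double> wpos, wdepth, wwidth; // funnel wells
};

static std::vector<Term> parse_potential(List potential, int natom) {
  List terms;
  if (potential.containsElementNamed("terms"))
    terms = potential["terms"];
  else
    terms = potential;
  std::vector<Term> out;
  for (int t = 0; t < terms.size(); ++t) {
    List tl = terms[t];
    std::string kind = as<std::string>(tl["kind"]);
    Term tm;
    tm.a1 = tm.a2 = -1;
    tm.dim = 0;
    tm.p1 = tm.p2 = tm.p3 = 0.0;
    tm.ref[0] = tm.ref[1] = tm.ref[2] = 0.0;
    if (kind == "harmonic_well") {
      tm.kind = HARMONIC_WELL;
      tm.a1 = as<int>(tl["atom"]) - 1;
      NumericVector ref = tl["ref"];
      NumericVector k = tl["k"];
      for (int d = 0; d < 3; ++d) {
        tm.ref[d] = ref[d];
        // per-dimension spring constants; a scalar k applies isotropically
        tm.wpos.push_back(k.size() == 3 ? k[d] : k[0]);
      }
    } else if (kind == "flat_bottom_pair") {
      tm.kind = FLAT_BOTTOM_PAIR;
      tm.a1 = as<int>(tl["i"]) - 1;
      tm.a2 = as<int>(tl["j"]) - 1;
      tm.p1 = as<double>(tl["rmin"]);
      tm.p2 = as<double>(tl["rmax"]);
      tm.p3 = as<double>(tl["k"]);
    } else if (kind == "funnel_radial") {
      tm.kind = FUNNEL_RADIAL;
      tm.a1 = as<int>(tl["i"]) - 1;
      tm.a2 = as<int>(tl["j"]) - 1;
      NumericMatrix w = tl["wells"];
      for (int r = 0; r < w.nrow(); ++r) {
        tm.wpos.push_back(w(r, 0));
        tm.wdepth.push_back(w(r, 1));
        tm.wwidth.push_back(w(r, 2));
      }
      tm.p1 = as<double>(tl["wall_r"]);
      tm.p2 = as<double>(tl["wall_k"]);
    } else if (kind == "double_well_1d") {
      tm.kind = DOUBLE_WELL_1D;
      tm.a1 = as<int>(tl["atom"]) - 1;
      tm.dim = as<int>(tl["dim"]) - 1;
      tm.p1 = as<double>(tl["a"]);
      tm.p2 = as<double>(tl["b"]);
    } else if (kind == "vector_bond") {
      tm.kind = VECTOR_BOND;
      tm.a1 = as<int>(tl["i"]) - 1;
      tm.a2 = as<int>(tl["j"]) - 1;
      NumericVector d0 = tl["d0"];
      for (int d = 0; d < 3; ++d) tm.ref[d] = d0[d];
      tm.p3 = as<double>(tl["k"]);
    } else {
      stop("unknown potential term kind '%s'", kind.c_str());
    }
    if (tm.a1 < 0 || tm.a1 >= natom ||
        (tm.a2 != -1 && (tm.a2 < 0 || tm.a2 >= natom)))
      stop("potential term %d ('%s') references an atom outside the system",
           t + 1, kind.c_str());
    out.push_back(tm);
  }
  return out;
}

static const char *kind_name(TermKind k) {
  switch (k) {
  case HARMONIC_WELL:    return "harmonic_well";
  case FLAT_BOTTOM_PAIR: return "flat_bottom_pair";
  case FUNNEL_RADIAL:    return "funnel_radial";
  case DOUBLE_WELL_1D:   return "double_well_1d";
  case VECTOR_BOND:      return "vector_bond";
  }
  return "?";
}

// Flat-bottom half-harmonic: zero inside [rmin, rmax], 0.5 k (d - edge)^2
// outside; C1-continuous at both edges.
static inline double flat_bottom_e(double d, double rmin, double rmax,
                                   double k, double *dEdd) {
  if (d > rmax) {
    *dEdd = k * (d - rmax);
    return 0.5 * k * (d - rmax) * (d - rmax);
  }
  if (d < rmin) {
    *dEdd = -k * (rmin - d);
    return 0.5 * k * (rmin - d) * (rmin - d);
  }
  *dEdd = 0.0;
  return 0.0;
}

// Radial profile of a funnel term: Gaussian wells plus a half-harmonic
// inner wall; flat (zero) in the unbound region.
static inline double funnel_e(const Term &tm, double d, double *dEdd) {
  double e = 0.0, g = 0.0;
  for (size_t w = 0; w < tm.wpos.size(); ++w) {
    double dx = d - tm.wpos[w];
    double s2 = tm.wwidth[w] * tm.wwidth[w];
    double gauss = tm.wdepth[w] * std::exp(-0.5 * dx * dx / s2);
    e -= gauss;
    g += gauss * dx / s2;
  }
  if (d < tm.p1) { // inner repulsive wall
    e += 0.5 * tm.p2 * (tm.p1 - d) * (tm.p1 - d);
    g += -tm.p2 * (tm.p1 - d);
  }
  *dEdd = g;
  return e;
}

// Evaluate energy and accumulate forces (-gradient) in f (natom x 3,
// row-major [i*3+d]).
static double eval_potential(const std::vector<Term> &terms,
                             const double *x, int natom, double *f) {
  double energy = 0.0;
  for (size_t t = 0; t < terms.size(); ++t) {
    const Term &tm = terms[t];
    double e = 0.0;
    switch (tm.kind) {
    case HARMONIC_WELL: {
      for (int d = 0; d < 3; ++d) {
        double dx = x[tm.a1 * 3 + d] - tm.ref[d];
        double k = tm.wpos[d];
        e += 0.5 * k * dx * dx;
        f[tm.a1 * 3 + d] -= k * dx;
      }
      break;
    }
    case FLAT_BOTTOM_PAIR:
    case FUNNEL_RADIAL: {
      double dv[3], d2 = 0.0;
      for (int d = 0; d < 3; ++d) {
        dv[d] = x[tm.a1 * 3 + d] - x[tm.a2 * 3 + d];
        d2 += dv[d] * dv[d];
      }
      double dist = std::sqrt(d2);
      if (dist < 1e-10)
        stop("zero interatomic distance in potential term '%s'",
             kind_name(tm.kind));
      double dEdd;
      e = (tm.kind == FLAT_BOTTOM_PAIR)
              ? flat_bottom_e(dist, tm.p1, tm.p2, tm.p3, &dEdd)
              : funnel_e(tm, dist, &dEdd);
      for (int d = 0; d < 3; ++d) {
        double fc = -dEdd * dv[d] / dist;
        f[tm.a1 * 3 + d] += fc;
        f[tm.a2 * 3 + d] -= fc;
      }
      break;
    }
    case DOUBLE_WELL_1D: {
      double xv = x[tm.a1 * 3 + tm.dim];
      double q = xv * xv - tm.p2 * tm.p2;
      e = tm.p1 * q * q;
      f[tm.a1 * 3 + tm.dim] -= 4.0 * tm.p1 * q * xv;
      break;
    }
    case VECTOR_BOND: {
      for (int d = 0; d < 3; ++d) {
        double dx = x[tm.a1 * 3 + d] - x[tm.a2 * 3 + d] - tm.ref[d];
        e += 0.5 * tm.p3 * dx * dx;
        f[tm.a1 * 3 + d] -= tm.p3 * dx;
        f[tm.a2 * 3 + d] += tm.p3 * dx;
      }
      break;
    }
    }
    if (!std::isfinite(e))
      stop("non-finite energy in potential term '%s'", kind_name(tm.kind));
    energy += e;
  }
  for (int i = 0; i < natom * 3; ++i)
    if (!std::isfinite(f[i]))
      stop("non-finite force produced by the potential");
  return energy;
}

// [[Rcpp::export]]
List engine_energy_forces(NumericMatrix x, List potential) {
  int natom = x.nrow();
  if (x.ncol() != 3) stop("coordinates must be an N x 3 matrix");
  std::vector<Term> terms = parse_potential(potential, natom);
  std::vector<double> xv(natom * 3), fv(natom * 3, 0.0);
  for (int i = 0; i < natom; ++i)
    for (int d = 0; d < 3; ++d) xv[i * 3 + d] = x(i, d);
  double e = eval_potential(terms, xv.data(), natom, fv.data());
  NumericMatrix f(natom, 3);
  for (int i = 0; i < natom; ++i)
    for (int d = 0; d < 3; ++d) f(i, d) = fv[i * 3 + d];
  return List::create(_["energy"] = e, _["forces"] = f);
}

static inline double pair_dist(const double *x, int i, int j) {
  double d2 = 0.0;
  for (int d = 0; d < 3; ++d) {
    double dv = x[i * 3 + d] - x[j * 3 + d];
    d2 += dv * dv;
  }
  return std::sqrt(d2);
}

// Ratchet bias force magnitude along increasing rho (zero when at or above
// the watermark), and its energy.
static inline double bias_force_mag(double rho, double rho_max, double alpha) {
  return (rho < rho_max) ? alpha * (rho_max - rho) : 0.0;
}
static inline double bias_energy_c(double rho, double rho_max, double alpha) {
  if (rho < rho_max) {
    double d = rho_max - rho;
    return 0.5 * alpha * d * d;
  }
  return 0.0;
}

// [[Rcpp::export]]
List engine_run(NumericMatrix x0, NumericMatrix v0, NumericVector mass,
                List potential, double dt, double friction,
                double temperature, int nsteps, int save_every,
                List bias, double unbound_rho) {
  int natom = x0.nrow();
  if (x0.ncol() != 3 || v0.nrow() != natom || v0.ncol() != 3)
    stop("x0 and v0 must be N x 3 matrices of equal size");
  if ((int)mass.size() != natom) stop("mass length must equal atom count");
  if (dt <= 0 || friction <= 0 || temperature < 0)
    stop("require dt > 0, friction > 0, temperature >= 0");
  std::vector<Term> terms = parse_potential(potential, natom);

  bool bias_on = as<bool>(bias["enabled"]);
  int bi = -1, bj = -1;
  double alpha = 0.0, rho_max = 0.0;
  if (bias_on) {
    bi = as<int>(bias["i"]) - 1;
    bj = as<int>(bias["j"]) - 1;
    alpha = as<double>(bias["alpha"]); // kcal mol^-1 A^-2
    if (alpha < 0) stop("negative bias force constant");
    if (bi < 0 || bi >= natom || bj < 0 || bj >= natom || bi == bj)
      stop("invalid reaction-coordinate atom pair");
  }

  std::vector<double> x(natom * 3), v(natom * 3), f(natom * 3, 0.0);
  for (int i = 0; i < natom; ++i)
    for (int d = 0; d < 3; ++d) {
      x[i * 3 + d] = x0(i, d);
      v[i * 3 + d] = v0(i, d);
    }

  double kT = KB_KCAL * temperature * KCAL_TO_AKMA; // amu A^2 ps^-2
  double c1 = std::exp(-friction * dt);
  double c2 = std::sqrt(1.0 - c1 * c1);
  std::vector<double> sdv(natom), invm(natom);
  for (int i = 0; i < natom; ++i) {
    if (mass[i] <= 0) stop("atom masses must be positive");
    sdv[i] = std::sqrt(kT / mass[i]);
    invm[i] = KCAL_TO_AKMA / mass[i];
  }

  double rho = 0.0;
  if (bias_on) {
    rho = pair_dist(x.data(), bi, bj);
    if (rho < 1e-10) stop("reaction-coordinate atoms are coincident");
    double rm0 = as<double>(bias["rho_max0"]);
    rho_max = ISNA(rm0) ? rho : rm0;
    if (rho > rho_max) rho_max = rho;
  }

  // force at the initial state
  double fb = 0.0;
  std::fill(f.begin(), f.end(), 0.0);
  eval_potential(terms, x.data(), natom, f.data());
  if (bias_on) {
    fb = bias_force_mag(rho, rho_max, alpha);
    for (int d = 0; d < 3; ++d) {
      double u = (x[bi * 3 + d] - x[bj * 3 + d]) / rho;
      f[bi * 3 + d] += fb * u;
      f[bj * 3 + d] -= fb * u;
    }
  }

  int max_saved = nsteps / save_every + 2;
  NumericVector frames(std::size_t(max_saved) * natom * 3);
  NumericVector t_out(max_saved), rho_out(max_saved), rhomax_out(max_saved),
      ebias_out(max_saved);
  int nsaved = 0;
  double work = 0.0;
  std::string stopped = "time_limit";

  auto save_frame = [&](int step) {
    std::size_t off = std::size_t(nsaved) * natom * 3;
    for (int i = 0; i < natom * 3; ++i) frames[off + i] = x[i];
    t_out[nsaved] = step * dt;
    rho_out[nsaved] = bias_on ? rho : NA_REAL;
    rhomax_out[nsaved] = bias_on ? rho_max : NA_REAL;
    ebias_out[nsaved] = bias_on ? bias_energy_c(rho, rho_max, alpha) : 0.0;
    ++nsaved;
  };
  save_frame(0);

  int step;
  for (step = 1; step <= nsteps; ++step) {
    // B: half kick
    for (int i = 0; i < natom; ++i)
      for (int d = 0; d < 3; ++d)
        v[i * 3 + d] += 0.5 * dt * f[i * 3 + d] * invm[i];
    // A: half drift
    for (int i = 0; i < natom * 3; ++i) x[i] += 0.5 * dt * v[i];
    // O: Ornstein-Uhlenbeck
    for (int i = 0; i < natom; ++i)
      for (int d = 0; d < 3; ++d)
        v[i * 3 + d] = c1 * v[i * 3 + d] + c2 * sdv[i] * R::norm_rand();
    // A: half drift
    for (int i = 0; i < natom * 3; ++i) x[i] += 0.5 * dt * v[i];

    // new forces; ratchet bookkeeping
    std::fill(f.begin(), f.end(), 0.0);
    eval_potential(terms, x.data(), natom, f.data());
    if (bias_on) {
      double rho_new = pair_dist(x.data(), bi, bj);
      if (rho_new < 1e-10) stop("reaction-coordinate atoms are coincident");
      work += fb * (rho_new - rho); // bias force applied over rc displacement
      rho = rho_new;
      if (rho > rho_max) rho_max = rho; // pawl advances
      fb = bias_force_mag(rho, rho_max, alpha);
      for (int d = 0; d < 3; ++d) {
        double u = (x[bi * 3 + d] - x[bj * 3 + d]) / rho;
        f[bi * 3 + d] += fb * u;
        f[bj * 3 + d] -= fb * u;
      }
    }

    // B: trailing half kick with the new forces
    for (int i = 0; i < natom; ++i)
      for (int d = 0; d < 3; ++d)
        v[i * 3 + d] += 0.5 * dt * f[i * 3 + d] * invm[i];

    if (step % save_every == 0) save_frame(step);
    if (bias_on && rho >= unbound_rho) {
      if (step % save_every != 0) save_frame(step);
      stopped = "unbound";
      break;
    }
  }

  NumericMatrix xf(natom, 3), vf(natom, 3);
  for (int i = 0; i < natom; ++i)
    for (int d = 0; d < 3; ++d) {
      xf(i, d) = x[i * 3 + d];
      vf(i, d) = v[i * 3 + d];
    }

  // trim saved series
  NumericVector fr(std::size_t(nsaved) * natom * 3);
  for (std::size_t i = 0; i < fr.size(); ++i) fr[i] = frames[i];
  fr.attr("dim") = IntegerVector::create(3, natom, nsaved);

  return List::create(
      _["frames"] = fr, _["times"] = head(t_out, nsaved),
      _["rho"] = head(rho_out, nsaved),
      _["rho_max"] = head(rhomax_out, nsaved),
      _["bias_energy"] = head(ebias_out, nsaved), _["bias_work"] = work,
      _["x_final"] = xf, _["v_final"] = vf, _["stopped"] = stopped,
      _["n_saved"] = nsaved);
}
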