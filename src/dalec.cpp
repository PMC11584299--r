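// Compiled forward engine for the six-pool weekly carbon mass-balance model.
// Mirrors the reference R implementation (.step_core) exactly; the two are
// cross-tested. Parameter order is the registry order (param_registry()).
#include <Rcpp.h>
using namespace Rcpp;

namespace {

enum Par {
  F_AUTO, F_FOL, F_LAB, F_ROOT, D_ONSET, R_ONSET, BIG_F_ONSET,
  D_FALL, R_FALL, BIG_F_FALL, T_ROOT, T_WOOD, R_LIT, D_LIT2SOM, R_SOM,
  THETA, C_EFF, LMA, THETA_LIT, DL_COEF, LAB_LAG, F_WOOD2SOM,
  C_LAB0, C_FOL0, C_ROOT0, C_WOOD0, C_LIT0, C_SOM0
};

const int NDAYS = 365;

// weekly sums of the wrapped-Gaussian daily phenology weights
void week_sums(double center, double width, double* out52) {
  std::vector<double> w(NDAYS, 0.0);
  double tot = 0.0;
  for (int d = 1; d <= NDAYS; ++d) {
    double s = 0.0;
    for (int k = -2; k <= 2; ++k) {
      double z = (d - center + k * (double)NDAYS) / width;
      s += std::exp(-0.5 * z * z);
    }
    w[d - 1] = s;
    tot += s;
  }
  for (int wk = 0; wk < 52; ++wk) {
    int d0 = wk * 7;          // 0-based first day
    int d1 = (wk < 51) ? d0 + 7 : NDAYS; // week 52 absorbs days 358-365
    double s = 0.0;
    for (int d = d0; d < d1; ++d) s += w[d] / tot;
    out52[wk] = s;
  }
}

double acm_gpp_c(double lai, double tmin, double tmax, double swrad,
                 double co2, double dayl, double ceff, double dl_coef,
                 const double* e /* e1..e10, psi_d, r_tot */) {
  if (lai <= 0.0 || swrad <= 0.0 || ceff <= 0.0) return 0.0;
  double trange = tmax - tmin;
  double gc = std::pow(std::fabs(e[10]), e[9]) / (e[5] * e[11] + 0.5 * trange);
  double pp = lai * ceff * e[0] * std::exp(e[7] * tmax) / gc;
  double qq = e[2] - e[3];
  double b = co2 + qq - pp;
  double disc = b * b - 4.0 * (co2 * qq - pp * e[2]);
  if (disc < 0.0) disc = 0.0;
  double ci = 0.5 * (b + std::sqrt(disc));
  double e0 = e[6] * lai * lai / (lai * lai + e[8]);
  double draw = gc * (co2 - ci);
  double denom = e0 * swrad + draw;
  double core = denom > 0.0 ? e0 * swrad * draw / denom : 0.0;
  double gpp = core * (dl_coef * dayl + e[4]);
  return gpp > 0.0 ? gpp : 0.0;
}

} // namespace

// [[Rcpp::export]]
List dalec_run_cpp(NumericVector pars, NumericMatrix drivers,
                   NumericVector init, NumericVector consts, double dt) {
  const int n = drivers.nrow();
  NumericMatrix pools(n, 6);
  NumericMatrix fluxes(n, 18);
  const double* e = consts.begin();

  double shift = pars[D_ONSET] + pars[LAB_LAG] - 1.0;
  double on_center = shift - std::floor(shift / NDAYS) * NDAYS + 1.0;
  double ws_on[52], ws_fall[52];
  week_sums(on_center, pars[R_ONSET], ws_on);
  week_sums(pars[D_FALL], pars[R_FALL], ws_fall);

  double rel_on[52], rel_fall[52];
  for (int w = 0; w < 52; ++w) {
    rel_on[w] = 1.0 - std::pow(1.0 - pars[BIG_F_ONSET], ws_on[w]);
    rel_fall[w] = 1.0 - std::pow(1.0 - pars[BIG_F_FALL], ws_fall[w]);
  }

  double c_lab = init[0], c_fol = init[1], c_root = init[2],
         c_wood = init[3], c_lit = init[4], c_som = init[5];
  bool clamped = false;

  for (int i = 0; i < n; ++i) {
    int w = (int)drivers(i, 0) - 1;
    double tmin = drivers(i, 1), tmax = drivers(i, 2), swrad = drivers(i, 3),
           co2 = drivers(i, 4), dayl = drivers(i, 5);
    double t_mean = 0.5 * (tmin + tmax);
    double f_t = std::exp(pars[THETA] * t_mean);
    double f_t_lit = std::exp(pars[THETA_LIT] * t_mean);

    double lai0 = c_fol / pars[LMA];
    double gpp = acm_gpp_c(lai0, tmin, tmax, swrad, co2, dayl,
                           pars[C_EFF], pars[DL_COEF], e);
    double ra = pars[F_AUTO] * gpp;
    double npp = gpp - ra;

    double a_lab = pars[F_LAB] * npp * dt;
    double a_fol = pars[F_FOL] * npp * dt;
    double a_root = pars[F_ROOT] * npp * dt;
    double a_wood = (1.0 - pars[F_FOL] - pars[F_LAB] - pars[F_ROOT]) * npp * dt;

    double release = rel_on[w] * c_lab;
    double fall = rel_fall[w] * c_fol;

    double root_mort = std::min(1.0, pars[T_ROOT] * dt) * c_root;
    double wood_mort = std::min(1.0, pars[T_WOOD] * dt) * c_wood;
    double wood2som = pars[F_WOOD2SOM] * wood_mort;
    double wood2lit = wood_mort - wood2som;

    double fr_rh = pars[R_LIT] * f_t_lit * dt;
    double fr_dec = pars[D_LIT2SOM] * f_t_lit * dt;
    double tot = fr_rh + fr_dec;
    if (tot > 1.0) { fr_rh /= tot; fr_dec /= tot; }
    double rh_lit = fr_rh * c_lit;
    double dec = fr_dec * c_lit;
    double rh_som = std::min(1.0, pars[R_SOM] * f_t * dt) * c_som;

    c_lab = c_lab + a_lab - release;
    c_fol = c_fol + a_fol + release - fall;
    c_root = c_root + a_root - root_mort;
    c_wood = c_wood + a_wood - wood_mort;
    c_lit = c_lit + fall + root_mort + wood2lit - rh_lit - dec;
    c_som = c_som + dec + wood2som - rh_som;

    if (c_lab < 0) { c_lab = 0; clamped = true; }
    if (c_fol < 0) { c_fol = 0; clamped = true; }
    if (c_root < 0) { c_root = 0; clamped = true; }
    if (c_wood < 0) { c_wood = 0; clamped = true; }
    if (c_lit < 0) { c_lit = 0; clamped = true; }
    if (c_som < 0) { c_som = 0; clamped = true; }

    pools(i, 0) = c_lab; pools(i, 1) = c_fol; pools(i, 2) = c_root;
    pools(i, 3) = c_wood; pools(i, 4) = c_lit; pools(i, 5) = c_som;

    double rh = (rh_lit + rh_som) / dt;
    fluxes(i, 0) = gpp; fluxes(i, 1) = ra; fluxes(i, 2) = npp;
    fluxes(i, 3) = a_lab / dt; fluxes(i, 4) = a_fol / dt;
    fluxes(i, 5) = a_root / dt; fluxes(i, 6) = a_wood / dt;
    fluxes(i, 7) = release / dt; fluxes(i, 8) = fall / dt;
    fluxes(i, 9) = root_mort / dt; fluxes(i, 10) = wood_mort / dt;
    fluxes(i, 11) = dec / dt; fluxes(i, 12) = rh_lit / dt;
    fluxes(i, 13) = rh_som / dt; fluxes(i, 14) = rh;
    fluxes(i, 15) = ra + rh; fluxes(i, 16) = ra + rh - gpp;
    fluxes(i, 17) = ra + rh - gpp;
  }

  return List::create(_["pools"] = pools, _["fluxes"] = fluxes,
                      _["clamped"] = clamped);
}
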