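#include <Rcpp.h>
using namespace Rcpp;

// MEND carbon-pool model: fixed-step explicit integration with adaptive
// sub-stepping and per-substep flux limiting so that pools never go negative
// and the carbon budget closes exactly (inputs - Rh = delta storage, up to
// floating-point rounding).
//
// State layout (mg C per g soil):
//   0 p_ox   oxidative-degradable POM
//   1 p_hyd  hydrolytic-degradable POM
//   2 mom    mineral-associated OM
//   3 qom    adsorbed DOM (Langmuir surface)
//   4 dom    dissolved OM
//   5 b_act  active microbial biomass
//   6 b_dor  dormant microbial biomass
//   7 e_ox   oxidative enzyme pool
//   8 e_hyd  hydrolytic enzyme pool
//   9 e_mom  MOM enzyme pool

static const int NPOOL = 10;

struct MendPar {
  double q10, t_ref;
  double vmax_ox, k_ox, vmax_hyd, k_hyd, vmax_mom, k_mom;
  double v_uptake, k_uptake, cue, cue_slope, frac_to_dom;
  double k_ads, k_des, q_max;
  double p_enz_ox, p_enz_hyd, p_enz_mom, r_enz;
  double k_mortality, mort_to_dom;
  double k_maint, dormancy_beta, k_dorm, k_resusc;
  double w_fc, w_exp;
  double ph_opt, ph_sigma;
  double in_pox, in_phyd; // input allocation; remainder to DOM
};

static MendPar unpack(const NumericVector& p) {
  MendPar q;
  q.q10 = p["q10"];             q.t_ref = p["t_ref"];
  q.vmax_ox = p["vmax_ox"];     q.k_ox = p["k_ox"];
  q.vmax_hyd = p["vmax_hyd"];   q.k_hyd = p["k_hyd"];
  q.vmax_mom = p["vmax_mom"];   q.k_mom = p["k_mom"];
  q.v_uptake = p["v_uptake"];   q.k_uptake = p["k_uptake"];
  q.cue = p["cue"];             q.cue_slope = p["cue_slope"];
  q.frac_to_dom = p["frac_to_dom"];
  q.k_ads = p["k_ads"];         q.k_des = p["k_des"];  q.q_max = p["q_max"];
  q.p_enz_ox = p["p_enz_ox"];   q.p_enz_hyd = p["p_enz_hyd"];
  q.p_enz_mom = p["p_enz_mom"]; q.r_enz = p["r_enz"];
  q.k_mortality = p["k_mortality"]; q.mort_to_dom = p["mort_to_dom"];
  q.k_maint = p["k_maint"];     q.dormancy_beta = p["dormancy_beta"];
  q.k_dorm = p["k_dorm"];       q.k_resusc = p["k_resusc"];
  q.w_fc = p["w_fc"];           q.w_exp = p["w_exp"];
  q.ph_opt = p["ph_opt"];       q.ph_sigma = p["ph_sigma"];
  q.in_pox = p["in_pox"];       q.in_phyd = p["in_phyd"];
  return q;
}

static inline double f_temp(double T, double q10, double t_ref) {
  return std::pow(q10, (T - t_ref) / 10.0);
}
static inline double f_moist(double W, double w_fc, double w_exp) {
  double s = std::pow(W / w_fc, w_exp);
  return s > 1.0 ? 1.0 : s;
}
static inline double f_ph(double ph, double opt, double sigma) {
  double z = (ph - opt) / sigma;
  return std::exp(-0.5 * z * z);
}

// 16 component fluxes, all >= 0 (mg C g-1 d-1)
enum Flux {
  F_DEC_OX = 0, F_DEC_HYD, F_DEC_MOM, F_ADS, F_DES, F_UPTAKE,
  F_GROW_RESP, F_MAINT_A, F_MAINT_D, F_EP_OX, F_EP_HYD, F_EP_MOM,
  F_ETO_OX, F_ETO_HYD, F_ETO_MOM, F_MORT, F_DORM, F_RESUSC, NFLUX
};

static void mend_flux(const double* x, const MendPar& p,
                      double T, double W, double ph, double* f) {
  double ft = f_temp(T, p.q10, p.t_ref);
  double fw = f_moist(W, p.w_fc, p.w_exp);
  double fp = f_ph(ph, p.ph_opt, p.ph_sigma);
  double env = ft * fw * fp;

  f[F_DEC_OX]  = p.vmax_ox  * x[7] * x[0] / (p.k_ox  + x[0]) * env;
  f[F_DEC_HYD] = p.vmax_hyd * x[8] * x[1] / (p.k_hyd + x[1]) * env;
  f[F_DEC_MOM] = p.vmax_mom * x[9] * x[2] / (p.k_mom + x[2]) * env;
  double site = 1.0 - x[3] / p.q_max;
  if (site < 0.0) site = 0.0;
  f[F_ADS] = p.k_ads * x[4] * site;
  f[F_DES] = p.k_des * x[3] / p.q_max;
  double upt = p.v_uptake * x[5] * x[4] / (p.k_uptake + x[4]) * env;
  // optional linear temperature dependence of carbon use efficiency
  double cue = p.cue + p.cue_slope * (T - p.t_ref);
  if (cue < 0.01) cue = 0.01;
  if (cue > 0.99) cue = 0.99;
  f[F_UPTAKE]    = upt;
  f[F_GROW_RESP] = (1.0 - cue) * upt;       // respired share of uptake
  f[F_MAINT_A]   = p.k_maint * ft * x[5];
  f[F_MAINT_D]   = p.dormancy_beta * p.k_maint * ft * x[6];
  f[F_EP_OX]  = p.p_enz_ox  * x[5];
  f[F_EP_HYD] = p.p_enz_hyd * x[5];
  f[F_EP_MOM] = p.p_enz_mom * x[5];
  f[F_ETO_OX]  = p.r_enz * x[7];
  f[F_ETO_HYD] = p.r_enz * x[8];
  f[F_ETO_MOM] = p.r_enz * x[9];
  f[F_MORT] = p.k_mortality * x[5];
  // moisture stress drives dormancy; wet conditions drive resuscitation
  f[F_DORM]   = p.k_dorm   * (1.0 - fw) * x[5];
  f[F_RESUSC] = p.k_resusc * fw * x[6];
}

// total outflow per pool, used by the non-negativity limiter
static void pool_outflow(const double* f, double* out) {
  out[0] = f[F_DEC_OX];
  out[1] = f[F_DEC_HYD];
  out[2] = f[F_DEC_MOM];
  out[3] = f[F_DES];
  out[4] = f[F_ADS] + f[F_UPTAKE];
  // b_act outflows: maintenance, enzyme production, mortality, dormancy
  // (growth is an inflow; gross uptake is charged to DOM)
  out[5] = f[F_MAINT_A] + f[F_EP_OX] + f[F_EP_HYD] + f[F_EP_MOM]
         + f[F_MORT] + f[F_DORM];
  out[6] = f[F_MAINT_D] + f[F_RESUSC];
  out[7] = f[F_ETO_OX];
  out[8] = f[F_ETO_HYD];
  out[9] = f[F_ETO_MOM];
}

// scale factor per flux given limiter per source pool
static void apply_limiter(double* f, const double* lim) {
  f[F_DEC_OX]  *= lim[0];
  f[F_DEC_HYD] *= lim[1];
  f[F_DEC_MOM] *= lim[2];
  f[F_DES]     *= lim[3];
  f[F_ADS]     *= lim[4];
  f[F_UPTAKE]  *= lim[4];
  f[F_GROW_RESP] *= lim[4]; // rides on uptake
  f[F_MAINT_A] *= lim[5];
  f[F_EP_OX]   *= lim[5];
  f[F_EP_HYD]  *= lim[5];
  f[F_EP_MOM]  *= lim[5];
  f[F_MORT]    *= lim[5];
  f[F_DORM]    *= lim[5];
  f[F_MAINT_D] *= lim[6];
  f[F_RESUSC]  *= lim[6];
  f[F_ETO_OX]  *= lim[7];
  f[F_ETO_HYD] *= lim[8];
  f[F_ETO_MOM] *= lim[9];
}

// net derivative per pool from (possibly limited) fluxes + input rate
static void derivs(const double* f, const MendPar& p, double input,
                   double* dx, double* rh) {
  double cue_in = f[F_UPTAKE] - f[F_GROW_RESP]; // growth share of uptake
  double in_dom = 1.0 - p.in_pox - p.in_phyd;
  dx[0] = p.in_pox * input - f[F_DEC_OX];
  dx[1] = p.in_phyd * input - f[F_DEC_HYD]
        + (1.0 - p.mort_to_dom) * f[F_MORT];
  dx[2] = (1.0 - p.frac_to_dom) * (f[F_DEC_OX] + f[F_DEC_HYD]) - f[F_DEC_MOM];
  dx[3] = f[F_ADS] - f[F_DES];
  dx[4] = in_dom * input
        + p.frac_to_dom * (f[F_DEC_OX] + f[F_DEC_HYD]) + f[F_DEC_MOM]
        + f[F_ETO_OX] + f[F_ETO_HYD] + f[F_ETO_MOM]
        + p.mort_to_dom * f[F_MORT]
        - f[F_ADS] + f[F_DES] - f[F_UPTAKE];
  dx[5] = cue_in - f[F_MAINT_A] - f[F_EP_OX] - f[F_EP_HYD] - f[F_EP_MOM]
        - f[F_MORT] - f[F_DORM] + f[F_RESUSC];
  dx[6] = f[F_DORM] - f[F_RESUSC] - f[F_MAINT_D];
  dx[7] = f[F_EP_OX] - f[F_ETO_OX];
  dx[8] = f[F_EP_HYD] - f[F_ETO_HYD];
  dx[9] = f[F_EP_MOM] - f[F_ETO_MOM];
  *rh = f[F_GROW_RESP] + f[F_MAINT_A] + f[F_MAINT_D];
}

// [[Rcpp::export]]
NumericVector mend_flux_cpp(NumericVector state, NumericVector params,
                            double soil_temp, double moisture, double ph) {
  MendPar p = unpack(params);
  double f[NFLUX];
  mend_flux(REAL(state), p, soil_temp, moisture, ph, f);
  NumericVector out(NFLUX);
  for (int i = 0; i < NFLUX; ++i) out[i] = f[i];
  out.attr("names") = CharacterVector::create(
    "dec_ox", "dec_hyd", "dec_mom", "ads", "des", "uptake",
    "growth_resp", "maint_active", "maint_dormant",
    "enz_prod_ox", "enz_prod_hyd", "enz_prod_mom",
    "enz_turn_ox", "enz_turn_hyd", "enz_turn_mom",
    "mortality", "to_dormant", "resuscitation");
  return out;
}

// [[Rcpp::export]]
List mend_core_cpp(NumericVector init, NumericVector params,
                   NumericVector soil_temp, NumericVector moisture,
                   NumericVector ph, NumericVector c_input,
                   double dt, bool keep_daily = true) {
  const int ndays = soil_temp.size();
  MendPar p = unpack(params);
  double x[NPOOL];
  for (int i = 0; i < NPOOL; ++i) x[i] = init[i];

  int nsub = (int) std::ceil(1.0 / dt - 1e-9);
  if (nsub < 1) nsub = 1;
  double h0 = 1.0 / nsub;

  NumericVector daily_rh(ndays);
  NumericMatrix pools(keep_daily ? ndays : 1, NPOOL);
  double cum_rh = 0.0, cum_in = 0.0;
  double total0 = 0.0;
  for (int i = 0; i < NPOOL; ++i) total0 += x[i];
  double max_resid = 0.0;
  int limited_steps = 0;

  double f[NFLUX], outfl[NPOOL], lim[NPOOL], dx[NPOOL], rh;

  for (int d = 0; d < ndays; ++d) {
    double T = soil_temp[d], W = moisture[d], PH = ph[d], I = c_input[d];
    double day_rh = 0.0;
    for (int s = 0; s < nsub; ++s) {
      // adaptive halving: retry with smaller h if a pool would go negative,
      // at the floor clamp outflows proportionally (exactly conservative)
      double remaining = h0;
      while (remaining > 1e-12) {
        double h = remaining;
        int tries = 0;
        for (;;) {
          mend_flux(x, p, T, W, PH, f);
          pool_outflow(f, outfl);
          bool neg = false;
          for (int i = 0; i < NPOOL; ++i) {
            double nx = x[i]; // projected
            lim[i] = 1.0;
            if (outfl[i] * h > x[i] && outfl[i] > 0.0) neg = true;
            (void)nx;
          }
          if (!neg || tries >= 20 || h <= h0 / 1048576.0) {
            if (neg) {
              ++limited_steps;
              for (int i = 0; i < NPOOL; ++i)
                if (outfl[i] * h > x[i] && outfl[i] > 0.0)
                  lim[i] = x[i] / (outfl[i] * h);
              apply_limiter(f, lim);
            }
            derivs(f, p, I, dx, &rh);
            for (int i = 0; i < NPOOL; ++i) {
              x[i] += dx[i] * h;
              if (x[i] < 0.0 && x[i] > -1e-13) x[i] = 0.0;
            }
            day_rh += rh * h;
            cum_rh += rh * h;
            cum_in += I * h;
            remaining -= h;
            break;
          }
          h *= 0.5;
          ++tries;
        }
      }
    }
    daily_rh[d] = day_rh;
    if (keep_daily)
      for (int i = 0; i < NPOOL; ++i) pools(d, i) = x[i];
    double total = 0.0;
    for (int i = 0; i < NPOOL; ++i) total += x[i];
    double resid = std::fabs((total - total0) - (cum_in - cum_rh));
    if (resid > max_resid) max_resid = resid;
  }
  if (!keep_daily)
    for (int i = 0; i < NPOOL; ++i) pools(0, i) = x[i];

  return List::create(
    _["daily_rh"] = daily_rh,
    _["pools"] = pools,
    _["cum_rh"] = cum_rh,
    _["cum_input"] = cum_in,
    _["balance_residual"] = max_resid,
    _["limited_steps"] = limited_steps);
}

// First-order multi-pool (TECO/CENTURY-type) core.
// dX/dt = A * xi(T, W) * K * X + B * I(t); Rh = respired complement of the
// transfers out of the environment-sensitive (litter/SOM) pools.
// xi applies only to pools flagged env_sensitive.
// [[Rcpp::export]]
List teco_core_cpp(NumericVector init, NumericMatrix transfer,
                   NumericVector turnover, LogicalVector env_sensitive,
                   NumericVector alloc, double q10, double t_ref,
                   double w_fc, double w_exp,
                   NumericVector soil_temp, NumericVector moisture,
                   NumericVector c_input, double dt,
                   bool keep_daily = true) {
  const int np = init.size();
  const int ndays = soil_temp.size();
  std::vector<double> x(np);
  for (int i = 0; i < np; ++i) x[i] = init[i];

  int nsub = (int) std::ceil(1.0 / dt - 1e-9);
  if (nsub < 1) nsub = 1;
  double h = 1.0 / nsub;

  NumericVector daily_rh(ndays);
  NumericMatrix pools(keep_daily ? ndays : 1, np);
  double cum_rh = 0.0, cum_in = 0.0, total0 = 0.0, max_resid = 0.0;
  for (int i = 0; i < np; ++i) total0 += x[i];

  std::vector<double> outflow(np), dx(np);

  for (int d = 0; d < ndays; ++d) {
    double ft = std::pow(q10, (soil_temp[d] - t_ref) / 10.0);
    double fw = std::pow(moisture[d] / w_fc, w_exp);
    if (fw > 1.0) fw = 1.0;
    double xi = ft * fw;
    double I = c_input[d];
    double day_rh = 0.0;
    for (int s = 0; s < nsub; ++s) {
      double rh = 0.0;
      for (int j = 0; j < np; ++j) {
        double k = turnover[j] * (env_sensitive[j] ? xi : 1.0);
        double out = k * x[j];
        if (out * h > x[j]) out = x[j] / h; // non-negativity clamp
        outflow[j] = out;
      }
      for (int i = 0; i < np; ++i) dx[i] = alloc[i] * I - outflow[i];
      for (int j = 0; j < np; ++j) {
        double transferred = 0.0;
        for (int i = 0; i < np; ++i) {
          double a = transfer(i, j);
          if (a > 0.0) { dx[i] += a * outflow[j]; transferred += a; }
        }
        // respired complement; for plant pools the default transfers sum to
        // 1 so their complement is zero and Rh is purely heterotrophic
        rh += (1.0 - transferred) * outflow[j];
      }
      for (int i = 0; i < np; ++i) {
        x[i] += dx[i] * h;
        if (x[i] < 0.0 && x[i] > -1e-13) x[i] = 0.0;
      }
      day_rh += rh * h;
      cum_rh += rh * h;
      cum_in += I * h;
    }
    daily_rh[d] = day_rh;
    if (keep_daily)
      for (int i = 0; i < np; ++i) pools(d, i) = x[i];
    double total = 0.0;
    for (int i = 0; i < np; ++i) total += x[i];
    double resid = std::fabs((total - total0) - (cum_in - cum_rh));
    if (resid > max_resid) max_resid = resid;
  }
  if (!keep_daily)
    for (int i = 0; i < np; ++i) pools(0, i) = x[i];

  return List::create(
    _["daily_rh"] = daily_rh,
    _["pools"] = pools,
    _["cum_rh"] = cum_rh,
    _["cum_input"] = cum_in,
    _["balance_residual"] = max_resid);
}
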