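// Forward-Euler integrators for the three ionic cell models.
// All state updates are explicit Euler at a fixed step dt (ms); stimulus
// pulses are half-open intervals [onset, onset + duration) on the grid.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

// Square-pulse stimulus evaluated on a uniform grid, walking the sorted
// onset list once (onsets strictly increasing).
struct PulseTrain {
  const std::vector<double>& onsets;
  double duration, amplitude;
  std::size_t next = 0;

  PulseTrain(const std::vector<double>& on, double dur, double amp)
      : onsets(on), duration(dur), amplitude(amp) {}

  double at(double t) {
    while (next < onsets.size() && t >= onsets[next] + duration) ++next;
    if (next < onsets.size() && t >= onsets[next] && t < onsets[next] + duration)
      return amplitude;
    return 0.0;
  }
};

inline double heav(double x) { return x >= 0.0 ? 1.0 : 0.0; }

}  // namespace

// Fenton-Karma three-variable model (Fenton & Karma 1998, Chaos 8:20;
// parameters supplied from R, default set 3 / Beeler-Reuter fit of
// Fenton et al. 2002, Chaos 12:852, Table 1).
// du/dt = -(J_fi + J_so + J_si) + J_stim
// [[Rcpp::export(name = ".fk_integrate")]]
List fk_integrate(List pars, std::vector<double> onsets, double duration,
                  double amplitude, double t_end, double dt,
                  NumericVector init) {
  const double tau_d   = pars["tau_d"],   tau_r   = pars["tau_r"];
  const double tau_si  = pars["tau_si"],  tau_0   = pars["tau_0"];
  const double tau_vp  = pars["tau_v_plus"];
  const double tau_v1m = pars["tau_v1_minus"], tau_v2m = pars["tau_v2_minus"];
  const double tau_wp  = pars["tau_w_plus"],   tau_wm  = pars["tau_w_minus"];
  const double u_c = pars["u_c"], u_v = pars["u_v"], u_csi = pars["u_c_si"];
  const double k = pars["k"];

  const std::size_t n = static_cast<std::size_t>(std::floor(t_end / dt)) + 1;
  NumericVector time(n), volt(n), stim(n);
  double u = init[0], v = init[1], w = init[2];
  PulseTrain pulse(onsets, duration, amplitude);

  for (std::size_t i = 0; i < n; ++i) {
    const double t = i * dt;
    const double Istim = pulse.at(t);
    time[i] = t; volt[i] = u; stim[i] = Istim;

    const double p = heav(u - u_c);          // active-phase switch
    const double q = heav(u - u_v);          // two-timescale v recovery
    const double tau_vm = q * tau_v1m + (1.0 - q) * tau_v2m;

    const double J_fi = -v * p * (1.0 - u) * (u - u_c) / tau_d;
    const double J_so = u * (1.0 - p) / tau_0 + p / tau_r;
    const double J_si = -w * (1.0 + std::tanh(k * (u - u_csi))) / (2.0 * tau_si);

    u += dt * (-(J_fi + J_so + J_si) + Istim);
    v += dt * ((1.0 - p) * (1.0 - v) / tau_vm - p * v / tau_vp);
    w += dt * ((1.0 - p) * (1.0 - w) / tau_wm - p * w / tau_wp);

    if (!std::isfinite(u) || u < -0.5 || u > 2.0 || v < -1e-6 ||
        v > 1.0 + 1e-6 || w < -1e-6 || w > 1.0 + 1e-6)
      stop("Fenton-Karma integration diverged at t = %f ms", t);
  }
  return List::create(_["time"] = time, _["voltage"] = volt,
                      _["stimulus"] = stim);
}

// Corrado-Niederer variant of the Mitchell-Schaeffer two-variable model.
// Inward current uses the cubic gated form h*v*(v - v_gate)*(1 - v)/tau_in,
// which keeps the rest state non-self-oscillatory.
// [[Rcpp::export(name = ".ms_integrate")]]
List ms_integrate(List pars, std::vector<double> onsets, double duration,
                  double amplitude, double t_end, double dt,
                  NumericVector init) {
  const double tau_in = pars["tau_in"], tau_out = pars["tau_out"];
  const double tau_open = pars["tau_open"], tau_close = pars["tau_close"];
  const double v_gate = pars["v_gate"];

  const std::size_t n = static_cast<std::size_t>(std::floor(t_end / dt)) + 1;
  NumericVector time(n), volt(n), stim(n);
  double v = init[0], h = init[1];
  PulseTrain pulse(onsets, duration, amplitude);

  for (std::size_t i = 0; i < n; ++i) {
    const double t = i * dt;
    const double Istim = pulse.at(t);
    time[i] = t; volt[i] = v; stim[i] = Istim;

    const double J_in = h * v * (v - v_gate) * (1.0 - v) / tau_in;
    const double dv = J_in - v / tau_out + Istim;
    const double dh = (v < v_gate) ? (1.0 - h) / tau_open : -h / tau_close;

    v += dt * dv;
    h += dt * dh;

    if (!std::isfinite(v) || v < -0.5 || v > 2.0 || h < -1e-6 || h > 1.0 + 1e-6)
      stop("Mitchell-Schaeffer integration diverged at t = %f ms", t);
  }
  return List::create(_["time"] = time, _["voltage"] = volt,
                      _["stimulus"] = stim);
}

// Noble 1962 Purkinje-fibre model co-integrated with the Lorenz system.
// The three Lorenz equations are multiplied by `lorenz_time_factor` so the
// chaotic forcing evolves on the millisecond scale; the anionic conductance
// is slaved to the Lorenz z variable through a linear map clipped at zero.
// [[Rcpp::export(name = ".noble_lorenz_integrate")]]
List noble_lorenz_integrate(double t_end, double dt, NumericVector noble_init,
                            NumericVector lorenz_init, double rho, double b,
                            double sigma, double lorenz_time_factor,
                            double g_an_slope, double keep_every,
                            double burn_in) {
  const double C_m = 12.0;       // membrane capacitance, uF/cm^2
  const double g_na_bar = 400.0; // mmho/cm^2
  const double E_na = 40.0, E_an = -60.0;

  const std::size_t n_steps = static_cast<std::size_t>(std::floor(t_end / dt));
  const std::size_t stride = static_cast<std::size_t>(keep_every);

  double V = noble_init[0], m = noble_init[1], h = noble_init[2],
         nn = noble_init[3];
  double x = lorenz_init[0], y = lorenz_init[1], z = lorenz_init[2];

  std::vector<double> time, volt, zs;
  time.reserve(n_steps / stride + 1);
  volt.reserve(n_steps / stride + 1);
  zs.reserve(n_steps / stride + 1);

  for (std::size_t i = 0; i <= n_steps; ++i) {
    const double t = i * dt;
    if (t >= burn_in && (i % stride == 0)) {
      time.push_back(t - burn_in);
      volt.push_back(V);
      zs.push_back(z);
    }

    // Lorenz subsystem, time-rescaled
    const double dx = lorenz_time_factor * sigma * (y - x);
    const double dy = lorenz_time_factor * (x * (rho - z) - y);
    const double dz = lorenz_time_factor * (x * y - b * z);

    // Noble 1962 rate constants (ms^-1); guarded against 0/0 removable
    // singularities of the linear-over-expm1 forms.
    const double Vm = V;
    // a * s / (exp(s) - 1), with the removable singularity at s = 0
    auto lin_expm1 = [](double a, double s) {
      return std::fabs(s) < 1e-7 ? a * (1.0 - s / 2.0) : a * s / std::expm1(s);
    };
    // alpha_m = 0.1 (-V - 48) / (exp((-V-48)/15) - 1)
    const double am = lin_expm1(0.1 * 15.0, (-Vm - 48.0) / 15.0);
    const double bm = lin_expm1(0.12 * 5.0, (Vm + 8.0) / 5.0);
    const double ah = 0.17 * std::exp((-Vm - 90.0) / 20.0);
    const double bh = 1.0 / (1.0 + std::exp((-Vm - 42.0) / 10.0));
    const double an = lin_expm1(0.0001 * 10.0, (-Vm - 50.0) / 10.0);
    const double bn = 0.002 * std::exp((-Vm - 90.0) / 80.0);

    const double g_na = g_na_bar * m * m * m * h + 0.14;
    const double g_k1 = 1.2 * std::exp((-Vm - 90.0) / 50.0) +
                        0.015 * std::exp((Vm + 90.0) / 60.0);
    const double g_k2 = 1.2 * std::pow(nn, 4.0);
    const double g_an = std::max(0.0, g_an_slope * z);

    const double I_na = g_na * (Vm - E_na);
    const double I_k = (g_k1 + g_k2) * (Vm + 100.0);
    const double I_an = g_an * (Vm - E_an);

    V += dt * (-(I_na + I_k + I_an) / C_m);
    m += dt * (am * (1.0 - m) - bm * m);
    h += dt * (ah * (1.0 - h) - bh * h);
    nn += dt * (an * (1.0 - nn) - bn * nn);
    x += dt * dx; y += dt * dy; z += dt * dz;

    if (!std::isfinite(V) || V < -150.0 || V > 100.0 || m < -1e-6 ||
        m > 1.0 + 1e-6 || h < -1e-6 || h > 1.0 + 1e-6 || nn < -1e-6 ||
        nn > 1.0 + 1e-6)
      stop("Noble-Lorenz integration diverged at t = %f ms", t);
  }

  return List::create(_["time"] = wrap(time), _["voltage"] = wrap(volt),
                      _["lorenz_z"] = wrap(zs));
}
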