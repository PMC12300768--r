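#include <Rcpp.h>
using namespace Rcpp;

// Stationary damped-oscillator (complex Ornstein-Uhlenbeck) sample paths.
//
// z_{n+1} = exp(-(gamma + i*omega)*dt) * z_n + xi_n with circularly
// symmetric Gaussian innovations gives, for the real part,
//   <Re z(0) Re z(k dt)> = sd^2 * exp(-gamma*k*dt) * cos(omega*k*dt)
// exactly at the sample times (no integrator drift at any dt).  Draws come
// from R's RNG, so paths are reproducible under set.seed().

// [[Rcpp::export]]
NumericMatrix damped_osc_paths(int n_steps, int n_series, double gamma,
                               double omega, double dt, double sd) {
    if (n_steps < 1 || n_series < 1)
        stop("n_steps and n_series must be positive");
    if (gamma <= 0.0) stop("damping rate must be positive");
    double s2 = 2.0 * sd * sd;               // <|z|^2> of the complex process
    double decay = std::exp(-gamma * dt);
    double ar = decay * std::cos(omega * dt);
    double ai = -decay * std::sin(omega * dt);
    double innov = std::sqrt(s2 * (1.0 - decay * decay) / 2.0);
    double init = std::sqrt(s2 / 2.0);

    NumericMatrix out(n_steps, n_series);
    for (int j = 0; j < n_series; ++j) {
        double zr = init * norm_rand();
        double zi = init * norm_rand();
        for (int i = 0; i < n_steps; ++i) {
            out(i, j) = zr;
            double nr = ar * zr - ai * zi + innov * norm_rand();
            double ni = ar * zi + ai * zr + innov * norm_rand();
            zr = nr;
            zi = ni;
        }
    }
    return out;
}
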