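#' @useDynLib thzwater, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Internal unit system: lengths in Angstrom, times in ps, charges in e,
# dipoles in Debye (conversion owned by .EA2D), fields in e/A^2 so that
# mu[e A] = alpha[A^3] * E[e/A^2].  Spectra in cm^-1.

.EA2D <- 4.80321                 # 1 e*Angstrom in Debye
.DEBYE_SI <- 3.33564e-30         # 1 Debye in C m
.KB_SI <- 1.380649e-23           # J/K
.EPS0_SI <- 8.8541878128e-12     # A s / (V m)
.C_SI <- 2.99792458e8            # m/s
.C_CM_PS <- 2.99792458e-2        # cm/ps

# omega[rad/ps] = .OMEGA_PER_CM * nu[cm^-1]
.OMEGA_PER_CM <- 2 * pi * .C_CM_PS

# alpha*n' prefactor: multiplies a cosine-transformed current correlation in
# D^2/ps (i.e. integral of D^2/ps^2 over ps) divided by (V[A^3] T[K]);
# result is in cm^-1.
.K_SPECTRUM <- .DEBYE_SI^2 / 1e-12 / (3 * 1e-30 * .KB_SI * .C_SI * .EPS0_SI) / 100

# permittivity prefactor: eps(0)-eps_inf = .K_EPS * <M^2>[D^2] / (V[A^3] T[K])
.K_EPS <- .DEBYE_SI^2 / (3 * 1e-30 * .KB_SI * .EPS0_SI)

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalize a (near-)zero vector")
  v / n
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
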