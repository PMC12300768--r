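# Transforms correlation functions into alpha(omega) * n'(omega) and the
# complex permittivity, applies the Savitzky-Golay smoothing / max-scaling
# spectral conventions, and classifies the low-frequency (~200 cm^-1)
# feature.
#
# Convention: one-sided (Laplace) cosine transforms throughout.  The common
# alternative Fourier route differs by a factor of two (the autocorrelation
# is even); that factor is owned here and nowhere else.

#' Spectrum container
#'
#' @param wavenumber strictly increasing grid in cm^-1.
#' @param value alpha * n' values in cm^-1.
#' @param channel decomposition tag (total/self/cross/perm/ind).
#' @param volume,temperature system metadata (A^3, K).
#' @param smoothing smoothing record (NULL until [smooth_and_scale()]).
#' @return a \code{thz_spectrum}.
#' @export
thz_spectrum <- function(wavenumber, value, channel = "total",
                         volume = NA_real_, temperature = NA_real_,
                         smoothing = NULL) {
  stopifnot(length(wavenumber) == length(value))
  if (any(diff(wavenumber) <= 0))
    stop("wavenumber grid must be strictly increasing")
  structure(list(wavenumber = as.numeric(wavenumber),
                 value = as.numeric(value), channel = channel,
                 volume = volume, temperature = temperature,
                 smoothing = smoothing),
            class = "thz_spectrum")
}

#' @export
print.thz_spectrum <- function(x, ...) {
  cat("<thz_spectrum>", x$channel, "channel,", length(x$wavenumber),
      "points over", round(min(x$wavenumber), 2), "-",
      round(max(x$wavenumber), 2), "cm^-1\n")
  if (!is.null(x$smoothing))
    cat("  smoothing:", paste(names(x$smoothing), unlist(x$smoothing),
                              sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' @export
plot.thz_spectrum <- function(x, ...,
                              xlab = expression(bar(nu) ~ (cm^-1)),
                              ylab = expression(alpha %.% n * minute ~ (cm^-1)),
                              type = "l") {
  graphics::plot(x$wavenumber, x$value, type = type, xlab = xlab,
                 ylab = ylab, ...)
  invisible(x)
}

# One-sided cosine transform integral_0^T f(t) cos(omega t) dt by trapezoid
# quadrature with Euler-Maclaurin end correction:
#   int = trap + (dt^2/12) * (g'(0) - g'(T)),  g(t) = f(t) cos(omega t),
# with the end-slopes estimated by one-sided O(dt^2) differences.  Accurate
# to ~ (omega dt)^4 relative for decayed integrands.
.cos_transform <- function(lag, val, omega) {
  dt <- lag[2] - lag[1]
  if (max(abs(diff(lag) - dt)) > 1e-9)
    stop("non-uniform lag spacing")
  n <- length(lag)
  w <- rep(dt, n); w[1] <- w[n] <- dt / 2
  trap <- drop(cos(outer(omega, lag)) %*% (w * val))
  fp0 <- (-3 * val[1] + 4 * val[2] - val[3]) / (2 * dt)
  fpT <- (3 * val[n] - 4 * val[n - 1] + val[n - 2]) / (2 * dt)
  gp0 <- fp0                                       # cos(0)=1, sin(0)=0
  gpT <- fpT * cos(omega * lag[n]) - omega * val[n] * sin(omega * lag[n])
  trap + dt^2 / 12 * (gp0 - gpT)
}

.default_grid <- function(lag) {
  dt <- lag[2] - lag[1]
  nyquist <- 1 / (2 * .C_CM_PS * dt)
  seq(0, nyquist, length.out = length(lag))
}

#' Absorption spectrum from the current correlation (preferred route)
#'
#' \deqn{\alpha(\omega) n'(\omega) = \frac{1}{3 V k_B T c \epsilon_0}
#'   \int_0^\infty \langle J_D(0) \cdot J_D(t)\rangle \cos(\omega t)\, dt}
#' evaluated by discrete cosine quadrature with trapezoidal end correction.
#' Because the \eqn{\omega^2} amplification of the moment route is absent,
#' no baseline correction is needed.
#'
#' @param cjj current autocorrelation ([corrfun()], D^2/ps^2, uniform lags).
#' @param volume system volume in A^3.
#' @param temperature temperature in K.
#' @param wavenumber output grid in cm^-1 (default: up to the Nyquist limit
#'   with as many points as lags).
#' @param channel decomposition tag carried into the spectrum.
#' @return a [thz_spectrum()] in cm^-1.
#' @export
spectrum_from_current <- function(cjj, volume, temperature,
                                  wavenumber = NULL, channel = "total") {
  stopifnot(inherits(cjj, "corrfun"))
  if (is.null(wavenumber)) wavenumber <- .default_grid(cjj$lag)
  omega <- .OMEGA_PER_CM * wavenumber
  val <- .K_SPECTRUM / (volume * temperature) *
    .cos_transform(cjj$lag, cjj$value, omega)
  thz_spectrum(wavenumber, val, channel, volume, temperature)
}

#' Absorption spectrum from the moment correlation
#'
#' \deqn{\alpha(\omega) n'(\omega) = \frac{\omega^2}{3 V k_B T c \epsilon_0}
#'   \int_0^\infty \Phi_D(t) \cos(\omega t)\, dt}
#' The \eqn{\omega^2} term acts as a parabolic amplifier of any baseline in
#' the transform, so the current route is preferred; on smooth, fully
#' decayed correlation functions the two agree (integration by parts).
#'
#' @param phi collective-moment autocorrelation ([corrfun()], D^2).
#' @inheritParams spectrum_from_current
#' @return a [thz_spectrum()]; exactly zero at \eqn{\omega = 0}.
#' @export
spectrum_from_moment <- function(phi, volume, temperature,
                                 wavenumber = NULL, channel = "total") {
  stopifnot(inherits(phi, "corrfun"))
  if (is.null(wavenumber)) wavenumber <- .default_grid(phi$lag)
  omega <- .OMEGA_PER_CM * wavenumber
  val <- omega^2 * .K_SPECTRUM / (volume * temperature) *
    .cos_transform(phi$lag, phi$value, omega)
  thz_spectrum(wavenumber, val, channel, volume, temperature)
}

#' Complex permittivity from the moment correlation
#'
#' \deqn{\hat\epsilon(\omega) - \epsilon_\infty = \frac{\langle M_D^2\rangle
#'   + i \omega \int_0^\infty \Phi_D(t) e^{i\omega t} dt}{3 V k_B T
#'   \epsilon_0}}
#' The static value comes from the \eqn{\langle M_D^2\rangle} term alone
#' (taken as \eqn{\Phi_D(0)}).  A correlation function that has not decayed
#' inside the lag window (tail above 1\% of \eqn{\Phi_D(0)}) produces a
#' warning and a flagged estimate.
#'
#' @param phi collective-moment autocorrelation (D^2).
#' @param volume,temperature system metadata (A^3, K).
#' @param wavenumber output grid (cm^-1).
#' @param eps_inf high-frequency permittivity added back to the real part
#'   metadata (an input; default 1).
#' @return a \code{permittivity} object: grid, complex
#'   \eqn{\hat\epsilon - \epsilon_\infty}, static value, decay flag.
#' @export
permittivity <- function(phi, volume, temperature, wavenumber = NULL,
                         eps_inf = 1) {
  stopifnot(inherits(phi, "corrfun"))
  if (is.null(wavenumber)) wavenumber <- .default_grid(phi$lag)
  decayed <- abs(phi$value[length(phi$value)]) < 0.01 * abs(phi$value[1])
  if (!decayed)
    warning("correlation tail has not decayed below 1% of Phi(0); ",
            "permittivity estimate flagged")
  omega <- .OMEGA_PER_CM * wavenumber
  K <- .K_EPS / (volume * temperature)
  m2 <- phi$value[1]
  C <- .cos_transform(phi$lag, phi$value, omega)
  S <- .sin_transform(phi$lag, phi$value, omega)
  eps <- complex(real = K * (m2 - omega * S), imaginary = K * omega * C)
  structure(list(wavenumber = wavenumber, eps = eps,
                 static = K * m2, eps_inf = eps_inf,
                 volume = volume, temperature = temperature,
                 decayed = decayed),
            class = "permittivity")
}

# one-sided sine transform with the same end-correction scheme
.sin_transform <- function(lag, val, omega) {
  dt <- lag[2] - lag[1]
  n <- length(lag)
  w <- rep(dt, n); w[1] <- w[n] <- dt / 2
  trap <- drop(sin(outer(omega, lag)) %*% (w * val))
  fpT <- (3 * val[n] - 4 * val[n - 1] + val[n - 2]) / (2 * dt)
  gp0 <- omega * val[1]                            # d/dt [f sin] at 0
  gpT <- fpT * sin(omega * lag[n]) + omega * val[n] * cos(omega * lag[n])
  trap + dt^2 / 12 * (gp0 - gpT)
}

#' @export
print.permittivity <- function(x, ...) {
  cat("<permittivity>", length(x$wavenumber), "points; eps(0) - eps_inf =",
      format(x$static, digits = 5),
      if (!x$decayed) "(FLAGGED: tail not decayed)" else "", "\n")
  invisible(x)
}

#' Savitzky-Golay smoothing and maximum scaling
#'
#' Applies the spectral presentation conventions: local polynomial
#' least-squares (Savitzky-Golay) smoothing, which preserves peak shapes,
#' followed optionally by division by the channel maximum so that spectra of
#' different models can be compared on one scale.
#'
#' @param spec a [thz_spectrum()].
#' @param window_pts odd filter window length (> \code{poly_order}).
#' @param poly_order polynomial order of the filter.
#' @param scale \code{"none"} or \code{"max"} (divide by the maximum).
#' @return the smoothed (and possibly scaled) [thz_spectrum()] with its
#'   smoothing record updated.
#' @export
smooth_and_scale <- function(spec, window_pts = 21, poly_order = 3,
                             scale = c("none", "max")) {
  scale <- match.arg(scale)
  stopifnot(inherits(spec, "thz_spectrum"))
  if (window_pts %% 2 != 1 || window_pts <= poly_order)
    stop("window_pts must be odd and greater than poly_order")
  if (window_pts > length(spec$wavenumber))
    stop("smoothing window exceeds the spectral grid")
  v <- signal::sgolayfilt(spec$value, p = poly_order, n = window_pts)
  sc <- 1
  if (scale == "max") {
    sc <- max(v)
    if (sc <= 0) stop("cannot max-scale a non-positive spectrum")
    v <- v / sc
  }
  thz_spectrum(spec$wavenumber, v, spec$channel, spec$volume,
               spec$temperature,
               smoothing = list(window_pts = window_pts,
                                poly_order = poly_order, scale = scale,
                                scale_factor = sc))
}

#' Classify the low-frequency (~200 cm^-1) spectral feature
#'
#' Operationalizes the yes/shoulder/no classification of the intermolecular
#' peak: \code{"yes"} if the spectrum has a strict local maximum inside the
#' band; \code{"shoulder"} if there is no local maximum but the first
#' derivative has a strict local minimum there (an inflection plateau on the
#' rising flank of the libration band); \code{"no"} otherwise.
#'
#' @param spec a [thz_spectrum()] whose grid covers at least 100-400 cm^-1.
#' @param band search band in cm^-1 (default 150-300).
#' @return \code{"yes"}, \code{"shoulder"}, or \code{"no"}.
#' @export
classify_200cm_peak <- function(spec, band = c(150, 300)) {
  stopifnot(inherits(spec, "thz_spectrum"))
  nu <- spec$wavenumber
  if (min(nu) > 100 || max(nu) < 400)
    stop("insufficient coverage: grid must span 100-400 cm^-1")
  v <- spec$value
  n <- length(v)
  inband <- function(i) nu[i] >= band[1] & nu[i] <= band[2]
  idx <- 2:(n - 1)
  is_max <- v[idx] > v[idx - 1] & v[idx] > v[idx + 1]
  if (any(is_max & inband(idx))) return("yes")
  dv <- (v[3:n] - v[1:(n - 2)]) / (nu[3:n] - nu[1:(n - 2)])  # centered d/dnu
  m <- length(dv)
  jdx <- 2:(m - 1)
  is_min <- dv[jdx] < dv[jdx - 1] & dv[jdx] < dv[jdx + 1]
  if (any(is_min & inband(jdx + 1))) return("shoulder")
  "no"
}

#' Write / read a spectrum as two-column text
#'
#' Two-column plain text (wavenumber cm^-1, alpha*n' cm^-1) with a
#' \code{#}-prefixed metadata header.  [read_spectrum()] also ingests
#' third-party reference spectra in the same two-column shape (e.g.
#' experimental overlays); header lines are optional on read.
#'
#' @param spec a [thz_spectrum()].
#' @param path file path.
#' @return \code{path} (write) or a [thz_spectrum()] (read).
#' @export
write_spectrum <- function(spec, path) {
  hdr <- c("# thzwater spectrum",
           paste0("# channel: ", spec$channel),
           paste0("# volume_A3: ", format(spec$volume)),
           paste0("# temperature_K: ", format(spec$temperature)),
           if (!is.null(spec$smoothing))
             paste0("# smoothing: window=", spec$smoothing$window_pts,
                    " order=", spec$smoothing$poly_order,
                    " scale=", spec$smoothing$scale),
           "# columns: wavenumber_cm-1 alpha_n_cm-1")
  writeLines(c(hdr, sprintf("%.10g %.10g", spec$wavenumber, spec$value)),
             path)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  dat <- utils::read.table(text = lines[!startsWith(lines, "#")])
  channel <- sub("^# channel: ", "", grep("^# channel: ", hdr, value = TRUE))
  vol <- suppressWarnings(as.numeric(
    sub("^# volume_A3: ", "", grep("^# volume_A3: ", hdr, value = TRUE))))
  tem <- suppressWarnings(as.numeric(
    sub("^# temperature_K: ", "",
        grep("^# temperature_K: ", hdr, value = TRUE))))
  thz_spectrum(dat[[1]], dat[[2]],
               channel = if (length(channel)) channel else "total",
               volume = if (length(vol)) vol else NA_real_,
               temperature = if (length(tem)) tem else NA_real_)
}
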