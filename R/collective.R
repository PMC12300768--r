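# Collective rotational dipole moments, rotational currents, and the
# correlation-function machinery with its self/cross and permanent/induced
# decompositions.

#' Per-molecule dipole time series
#'
#' Container for per-molecule, per-frame permanent and induced dipole
#' vectors on a uniform time grid.
#'
#' @param times frame times in ps (uniform spacing).
#' @param perm numeric array \code{[frame, molecule, 3]} of permanent
#'   molecular dipoles (Debye).
#' @param induced optional array of the same shape for the induced channel
#'   (defaults to zero: non-polarizable model).
#' @return a \code{dipole_series}.
#' @export
dipole_series <- function(times, perm, induced = NULL) {
  stopifnot(is.array(perm), length(dim(perm)) == 3, dim(perm)[3] == 3,
            length(times) == dim(perm)[1])
  if (is.null(induced)) induced <- array(0, dim(perm))
  stopifnot(all(dim(induced) == dim(perm)))
  dt <- diff(times)
  if (length(dt) && (any(dt <= 0) || max(abs(dt - dt[1])) > 1e-9))
    stop("frame times must be uniformly increasing (to 1e-9 ps)")
  structure(list(times = as.numeric(times), perm = perm, induced = induced,
                 n_molecules = dim(perm)[2],
                 dt = if (length(dt)) dt[1] else NA_real_),
            class = "dipole_series")
}

#' @export
print.dipole_series <- function(x, ...) {
  cat("<dipole_series>", dim(x$perm)[1], "frames x", x$n_molecules,
      "molecules, dt =", x$dt, "ps\n")
  invisible(x)
}

# central differences along the first (time) axis; one-sided at the ends.
# Endpoints are excluded from correlation estimation downstream.
.time_derivative <- function(x, dt) {
  n <- dim(x)[1]
  d <- x
  d[2:(n - 1), , ] <- (x[3:n, , , drop = FALSE] -
                       x[1:(n - 2), , , drop = FALSE]) / (2 * dt)
  d[1, , ] <- (x[2, , ] - x[1, , ]) / dt
  d[n, , ] <- (x[n, , ] - x[n - 1, , ]) / dt
  d
}

.deriv_mat <- function(m, dt) {
  n <- nrow(m)
  d <- m
  d[2:(n - 1), ] <- (m[3:n, , drop = FALSE] - m[1:(n - 2), , drop = FALSE]) /
    (2 * dt)
  d[1, ] <- (m[2, ] - m[1, ]) / dt
  d[n, ] <- (m[n, ] - m[n - 1, ]) / dt
  d
}

#' Collective rotational dipole moment and rotational current
#'
#' Sums the molecular dipoles of each channel into the collective moment
#' \eqn{M_D(t)} and differentiates it (central differences, one-sided at the
#' endpoints, which are excluded from correlation estimation) into the
#' rotational current \eqn{J_D(t) = dM_D/dt}.
#'
#' @param series a [dipole_series()] with at least 3 frames.
#' @return a \code{collective_series} with \code{M} and \code{J} lists
#'   (components \code{total}, \code{perm}, \code{ind}; each a frames x 3
#'   matrix in D and D/ps respectively).
#' @export
collective_moment <- function(series) {
  stopifnot(inherits(series, "dipole_series"))
  n <- dim(series$perm)[1]
  if (n < 3) stop("insufficient frames for derivative (need >= 3)")
  sum_mol <- function(a) apply(a, c(1, 3), sum)
  Mp <- sum_mol(series$perm)
  Mi <- sum_mol(series$induced)
  M <- list(total = Mp + Mi, perm = Mp, ind = Mi)
  J <- lapply(M, .deriv_mat, dt = series$dt)
  structure(list(times = series$times, M = M, J = J, dt = series$dt,
                 n_molecules = series$n_molecules,
                 derivative = "central", interior = c(2L, n - 1L)),
            class = "collective_series")
}

#' @export
print.collective_series <- function(x, ...) {
  cat("<collective_series>", nrow(x$M$total), "frames,", x$n_molecules,
      "molecules, dt =", x$dt, "ps (", x$derivative, "derivative )\n")
  invisible(x)
}

#' Correlation function container
#'
#' @param lag lag times (ps), starting at zero with uniform spacing.
#' @param value correlation values (units of A.B).
#' @param n effective number of sample pairs per lag (unbiased
#'   normalization), if known.
#' @return a \code{corrfun}.
#' @export
corrfun <- function(lag, value, n = NULL) {
  stopifnot(length(lag) == length(value))
  structure(list(lag = as.numeric(lag), value = as.numeric(value), n = n),
            class = "corrfun")
}

#' @export
print.corrfun <- function(x, ...) {
  cat("<corrfun>", length(x$lag), "lags, dt =",
      if (length(x$lag) > 1) x$lag[2] - x$lag[1] else NA,
      "ps, C(0) =", format(x$value[1], digits = 6), "\n")
  invisible(x)
}

# FFT cross-correlation sum_t a_t . b_{t+k} (linear, via zero padding),
# unbiased per-lag normalization; a, b are n x k matrices (vector series).
.xcorr_fft <- function(a, b, max_lag) {
  n <- nrow(a)
  nf <- stats::nextn(2 * n, 2)
  total <- numeric(max_lag + 1)
  for (j in seq_len(ncol(a))) {
    fa <- stats::fft(c(a[, j], numeric(nf - n)))
    fb <- stats::fft(c(b[, j], numeric(nf - n)))
    s <- Re(stats::fft(fb * Conj(fa), inverse = TRUE)) / nf
    total <- total + s[1:(max_lag + 1)]
  }
  total / (n - 0:max_lag)
}

#' Autocorrelation of a vector time series
#'
#' FFT-based estimate of \eqn{\langle A(0) \cdot A(t) \rangle} with unbiased
#' per-lag normalization; lags are restricted to a fraction of the series
#' (cross terms get noisy at large lag, so long lags are excluded by
#' default).
#'
#' @param x numeric matrix (frames x components) on a uniform grid, or a
#'   \code{collective_series} channel extracted by the caller.
#' @param dt time step in ps.
#' @param max_lag_fraction largest lag as a fraction of the series length.
#' @return a [corrfun()].
#' @export
autocorrelation <- function(x, dt, max_lag_fraction = 0.5) {
  x <- as.matrix(x)
  n <- nrow(x)
  max_lag <- max(1L, floor(n * max_lag_fraction) - 1L)
  v <- .xcorr_fft(x, x, max_lag)
  corrfun((0:max_lag) * dt, v, n = n - 0:max_lag)
}

#' Cross-correlation of two vector time series
#'
#' Estimates \eqn{\langle A(0) \cdot B(t) \rangle} with the same estimator
#' conventions as [autocorrelation()].
#'
#' @param a,b numeric matrices (frames x components), same shape.
#' @param dt time step in ps.
#' @param max_lag_fraction largest lag as a fraction of the series length.
#' @return a [corrfun()].
#' @export
crosscorrelation <- function(a, b, dt, max_lag_fraction = 0.5) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(all(dim(a) == dim(b)))
  n <- nrow(a)
  max_lag <- max(1L, floor(n * max_lag_fraction) - 1L)
  corrfun((0:max_lag) * dt, .xcorr_fft(a, b, max_lag), n = n - 0:max_lag)
}

#' Self/cross decomposition of the current correlation
#'
#' Splits the collective current autocorrelation into the same-molecule
#' (self) and distinct-molecule (cross) parts,
#' \eqn{C_{total} = C_{self} + C_{cross}}.  The self term is the sum over
#' molecules of each molecule's current autocorrelation (molecules being
#' statistically equivalent, this is the molecule-averaged correlation times
#' N); the cross term is obtained by subtraction rather than the O(N^2)
#' double sum, which is retained as a test oracle.  With \code{via =
#' "moments"} the same split is applied to the dipole moments instead of the
#' currents.
#'
#' @param series a [dipole_series()].
#' @param via correlate \code{"currents"} (derivatives; the spectral route)
#'   or \code{"moments"}.
#' @param max_lag_fraction largest lag as a fraction of the usable series.
#' @return list with components \code{self}, \code{cross}, \code{total}
#'   ([corrfun()]s).
#' @export
self_cross_split <- function(series, via = c("currents", "moments"),
                             max_lag_fraction = 0.5) {
  via <- match.arg(via)
  stopifnot(inherits(series, "dipole_series"))
  mol <- series$perm + series$induced
  n <- dim(mol)[1]
  if (via == "currents") {
    if (n < 3) stop("insufficient frames for derivative (need >= 3)")
    x <- .time_derivative(mol, series$dt)
    keep <- 2:(n - 1)             # one-sided endpoints excluded
  } else {
    x <- mol
    keep <- seq_len(n)
  }
  x <- x[keep, , , drop = FALSE]
  nk <- length(keep)
  max_lag <- max(1L, floor(nk * max_lag_fraction) - 1L)
  lag <- (0:max_lag) * series$dt

  coll <- apply(x, c(1, 3), sum)
  c_total <- .xcorr_fft(coll, coll, max_lag)
  c_self <- numeric(max_lag + 1)
  for (m in seq_len(dim(x)[2])) {
    xm <- x[, m, ]
    c_self <- c_self + .xcorr_fft(xm, xm, max_lag)
  }
  counts <- nk - 0:max_lag
  list(self = corrfun(lag, c_self, counts),
       cross = corrfun(lag, c_total - c_self, counts),
       total = corrfun(lag, c_total, counts))
}

#' Permanent/induced decomposition of the current correlation
#'
#' Correlates the total rotational current against its permanent and induced
#' parts: \eqn{C_{perm}(t) = \langle J_D(0) \cdot J_D^{perm}(t) \rangle},
#' \eqn{C_{ind}(t) = \langle J_D(0) \cdot J_D^{ind}(t) \rangle}, so that
#' \eqn{C_{perm} + C_{ind} = C_{total}} exactly (linearity of the
#' estimator).  A missing induced channel yields an identically zero
#' \eqn{C_{ind}} with a warning (non-polarizable model).
#'
#' @param collective a \code{collective_series} from [collective_moment()].
#' @param max_lag_fraction largest lag as a fraction of the usable series.
#' @return list with components \code{perm}, \code{ind}, \code{total}.
#' @export
perm_ind_split <- function(collective, max_lag_fraction = 0.5) {
  stopifnot(inherits(collective, "collective_series"))
  keep <- collective$interior[1]:collective$interior[2]
  J <- collective$J$total[keep, , drop = FALSE]
  Jp <- collective$J$perm[keep, , drop = FALSE]
  Ji <- collective$J$ind[keep, , drop = FALSE]
  if (all(Ji == 0))
    warning("induced channel is zero (non-polarizable model); C_ind == 0")
  nk <- length(keep)
  max_lag <- max(1L, floor(nk * max_lag_fraction) - 1L)
  lag <- (0:max_lag) * collective$dt
  counts <- nk - 0:max_lag
  list(perm = corrfun(lag, .xcorr_fft(J, Jp, max_lag), counts),
       ind = corrfun(lag, .xcorr_fft(J, Ji, max_lag), counts),
       total = corrfun(lag, .xcorr_fft(J, J, max_lag), counts))
}

#' Write / read a correlation function as two-column text
#'
#' Plain-text exchange format: a \code{#}-prefixed metadata header followed
#' by lag (ps) and value columns.
#'
#' @param cf a [corrfun()].
#' @param path output file.
#' @param meta named character vector merged into the header.
#' @return \code{path}, invisibly.
#' @export
write_corrfun <- function(cf, path, meta = c()) {
  hdr <- c("# thzwater correlation function",
           "# columns: lag_ps value",
           if (length(meta)) paste0("# ", names(meta), ": ", meta))
  writeLines(c(hdr, sprintf("%.10g %.10g", cf$lag, cf$value)), path)
  invisible(path)
}

#' @rdname write_corrfun
#' @export
read_corrfun <- function(path) {
  lines <- readLines(path)
  dat <- utils::read.table(text = lines[!startsWith(lines, "#")])
  corrfun(dat[[1]], dat[[2]])
}
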