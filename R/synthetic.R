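# Synthetic inputs with known statistical structure: a rigid-water librator
# trajectory generator whose collective dipole autocorrelation is known in
# closed form, random non-overlapping clusters for polarization-solver
# oracles, and a constructed hydrogen-bonded dimer.

#' Librator model parameters
#'
#' Defines the stochastic dipole-fluctuation model the generator samples
#' from: each molecular dipole component is an independent superposition of
#' exactly discretized damped-oscillator (complex Ornstein-Uhlenbeck)
#' processes plus an exponential orientational-diffusion mode, so the
#' collective dipole autocorrelation is exactly
#' \deqn{\Phi_D(t) = N \mu_0^2 \left[\sum_k a_k e^{-\gamma_k t}
#'   \cos(\omega_k t) + a_0 e^{-t/\tau_r}\right]}
#' at the sample times.  Defaults emulate the liquid-water line-shape
#' regimes: an intermolecular mode near 200 cm^-1, a librational mode near
#' 650 cm^-1 (both with ~53 cm^-1 half-widths), and a slow Debye-like
#' diffusive remainder.
#'
#' @param n_molecules number of (dynamically independent) molecules.
#' @param box_edge cubic box edge in Angstrom.
#' @param mu0 root-mean-square molecular dipole magnitude (D).
#' @param modes data frame with columns \code{amplitude} (fraction of the
#'   dipole variance), \code{center_cm} (cm^-1), \code{damping_ps}
#'   (ps^-1).  Amplitudes must sum to < 1; the remainder goes into the
#'   diffusive mode.
#' @param tau_r diffusive reorientation time (ps).
#' @param dt time step (ps); rejected if any mode would alias
#'   (\eqn{\omega_k \Delta t > 0.5}).
#' @param n_frames number of frames.
#' @param shared_mode_amplitude variance fraction of an extra mode (the
#'   first row of \code{modes}) driven identically in all molecules, to
#'   produce nonzero cross-correlations; 0 (default) keeps molecules
#'   independent so cross terms vanish in expectation.
#' @param seed RNG seed (integer) or NULL to use the current RNG state.
#' @return a \code{librator_params} list.
#' @export
librator_params <- function(n_molecules = 64, box_edge = 12.42, mu0 = 2.35,
                            modes = data.frame(
                              amplitude = c(0.65, 0.10),
                              center_cm = c(200, 650),
                              damping_ps = c(10, 10)),
                            tau_r = 8, dt = 0.001, n_frames = 32768,
                            shared_mode_amplitude = 0, seed = NULL) {
  stopifnot(n_molecules >= 1, mu0 > 0, dt > 0, n_frames >= 3, tau_r > 0,
            all(modes$amplitude >= 0), all(modes$damping_ps > 0),
            shared_mode_amplitude >= 0)
  if (sum(modes$amplitude) + shared_mode_amplitude > 1)
    stop("mode amplitude fractions must sum to <= 1")
  omega <- .OMEGA_PER_CM * modes$center_cm
  if (length(omega) && max(omega) * dt > 0.5)
    stop("aliasing guard: omega_k * dt = ", format(max(omega) * dt),
         " > 0.5; reduce dt")
  structure(list(n_molecules = n_molecules, box_edge = box_edge, mu0 = mu0,
                 modes = modes, tau_r = tau_r, dt = dt, n_frames = n_frames,
                 shared_mode_amplitude = shared_mode_amplitude, seed = seed),
            class = "librator_params")
}

#' Generate a librator dipole trajectory
#'
#' Samples the dipole-fluctuation model of [librator_params()] and returns
#' the per-molecule dipole series together with the exact parametric
#' autocorrelation for oracle comparison.  Identical seeds give identical
#' output.
#'
#' @param params a [librator_params()].
#' @return a \code{librator_sim}: \code{dipoles} ([dipole_series()]),
#'   \code{params}, and \code{phi}, a function of lag time returning the
#'   exact collective \eqn{\Phi_D(t)} in D^2.
#' @export
generate_librator <- function(params) {
  stopifnot(inherits(params, "librator_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  n <- params$n_frames
  nm <- params$n_molecules
  v_axis <- params$mu0^2 / 3            # per-axis dipole variance
  perm <- array(0, c(n, nm, 3))
  for (k in seq_len(nrow(params$modes))) {
    sd_k <- sqrt(params$modes$amplitude[k] * v_axis)
    if (sd_k == 0) next
    paths <- damped_osc_paths(n, nm * 3, params$modes$damping_ps[k],
                              .OMEGA_PER_CM * params$modes$center_cm[k],
                              params$dt, sd_k)
    perm <- perm + array(paths, c(n, nm, 3))
  }
  a0 <- 1 - sum(params$modes$amplitude) - params$shared_mode_amplitude
  if (a0 > 0) {
    paths <- damped_osc_paths(n, nm * 3, 1 / params$tau_r, 0, params$dt,
                              sqrt(a0 * v_axis))
    perm <- perm + array(paths, c(n, nm, 3))
  }
  if (params$shared_mode_amplitude > 0) {
    shared <- damped_osc_paths(n, 3, params$modes$damping_ps[1],
                               .OMEGA_PER_CM * params$modes$center_cm[1],
                               params$dt,
                               sqrt(params$shared_mode_amplitude * v_axis))
    for (m in seq_len(nm)) perm[, m, ] <- perm[, m, ] + shared
  }
  structure(list(
    dipoles = dipole_series((seq_len(n) - 1) * params$dt, perm),
    params = params,
    phi = function(t) librator_phi(params, t)
  ), class = "librator_sim")
}

#' Exact collective dipole autocorrelation of the librator model
#'
#' @param params a [librator_params()].
#' @param t lag times (ps).
#' @return \eqn{\Phi_D(t)} in D^2 (cross terms included for the shared
#'   mode, which contributes \eqn{N^2}-fold).
#' @export
librator_phi <- function(params, t) {
  t <- abs(t)
  v <- params$mu0^2
  a0 <- 1 - sum(params$modes$amplitude) - params$shared_mode_amplitude
  per_mol <- a0 * exp(-t / params$tau_r)
  for (k in seq_len(nrow(params$modes)))
    per_mol <- per_mol + params$modes$amplitude[k] *
      exp(-params$modes$damping_ps[k] * t) *
      cos(.OMEGA_PER_CM * params$modes$center_cm[k] * t)
  tot <- params$n_molecules * v * per_mol
  if (params$shared_mode_amplitude > 0)
    tot <- tot + params$n_molecules^2 * v * params$shared_mode_amplitude *
      exp(-params$modes$damping_ps[1] * t) *
      cos(.OMEGA_PER_CM * params$modes$center_cm[1] * t)
  tot
}

#' Expected current correlation under the central-difference estimator
#'
#' The rotational current is estimated by central differences, so its exact
#' expected autocorrelation under the librator model is the second central
#' difference of \eqn{\Phi_D},
#' \deqn{C_{JJ}(t) = \frac{2\Phi_D(t) - \Phi_D(t + 2\Delta t)
#'   - \Phi_D(t - 2\Delta t)}{4 \Delta t^2}}
#' This is the closed-form oracle to compare pipeline output against
#' (it converges to \eqn{-\ddot\Phi_D} as \eqn{\Delta t \to 0}).
#'
#' @param params a [librator_params()].
#' @param t lag times (ps).
#' @param dt sampling interval used by the difference scheme (defaults to
#'   the model's own).
#' @return expected \eqn{C_{JJ}(t)} in D^2/ps^2.
#' @export
librator_cjj <- function(params, t, dt = params$dt) {
  (2 * librator_phi(params, t) - librator_phi(params, t + 2 * dt) -
     librator_phi(params, abs(t - 2 * dt))) / (4 * dt^2)
}

#' Emit rigid-water coordinates for a librator simulation
#'
#' Places the molecules on a cubic sublattice and orients a rigid reference
#' molecule so its dipole (bisector) axis follows the instantaneous
#' direction of each sampled molecular dipole.  Because a rigid molecule has
#' a fixed dipole magnitude, the coordinate route carries the direction but
#' not the magnitude fluctuations of the underlying model; it is intended
#' for exercising trajectory I/O and dipole extraction, while statistical
#' tests use the dipole series itself.
#'
#' @param sim a \code{librator_sim}.
#' @param spec a rigid \code{water_model} used for the site geometry.
#' @param frames which frames to emit (default: all; keep small).
#' @return a \code{wtraj} trajectory object (see [load_trajectory()]).
#' @export
librator_trajectory <- function(sim, spec = water_model("spce"),
                                frames = seq_len(dim(sim$dipoles$perm)[1])) {
  stopifnot(inherits(sim, "librator_sim"))
  nm <- sim$params$n_molecules
  ref <- build_reference_molecule(spec)
  nsite <- nrow(ref$coords)
  per_edge <- ceiling(nm^(1 / 3))
  spacing <- sim$params$box_edge / per_edge
  centers <- as.matrix(expand.grid(x = 1:per_edge, y = 1:per_edge,
                                   z = 1:per_edge))[seq_len(nm), , drop = FALSE]
  centers <- (centers - 0.5) * spacing
  coords <- array(0, c(length(frames), nm * nsite, 3))
  for (fi in seq_along(frames)) {
    f <- frames[fi]
    for (m in seq_len(nm)) {
      mu <- sim$dipoles$perm[f, m, ] + sim$dipoles$induced[f, m, ]
      R <- .rotation_z_to(mu)
      xyz <- t(R %*% t(ref$coords)) +
        matrix(centers[m, ], nsite, 3, byrow = TRUE)
      coords[fi, ((m - 1) * nsite + 1):(m * nsite), ] <- xyz
    }
  }
  wtraj(coords,
        atoms = data.frame(molecule = rep(seq_len(nm), each = nsite),
                           site = rep(rownames(ref$coords), nm)),
        dt = sim$params$dt * if (length(frames) > 1) frames[2] - frames[1] else 1,
        box = sim$params$box_edge, model = spec$name)
}

# minimal rotation taking +z to the direction of v
.rotation_z_to <- function(v) {
  z <- c(0, 0, 1)
  u <- .unit(v)
  c_ <- sum(z * u)
  ax <- .cross3(z, u)
  s <- sqrt(sum(ax^2))
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    return(diag(c(1, -1, -1)))               # 180 degrees about x
  }
  ax <- ax / s
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  diag(3) + s * K + (1 - c_) * K %*% K
}

#' Random non-overlapping water cluster
#'
#' Rejection-samples molecular centers in a cubic box subject to a minimum
#' O-O distance and draws orientations uniformly (random rotations); used
#' as input for the polarization-solver oracles.
#'
#' @param n_molecules cluster size.
#' @param spec a rigid \code{water_model}.
#' @param box_edge cubic box edge (Angstrom).
#' @param min_oo minimum O-O distance (Angstrom).
#' @param max_attempts rejection-sampling cap per molecule.
#' @param seed optional RNG seed.
#' @return list of \code{molecule_geometry}, one per molecule.
#' @export
generate_cluster <- function(n_molecules, spec = water_model("swm4-ndp"),
                             box_edge = 12, min_oo = 2.6,
                             max_attempts = 2000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  centers <- matrix(NA_real_, n_molecules, 3)
  for (m in seq_len(n_molecules)) {
    ok <- FALSE
    for (a in seq_len(max_attempts)) {
      p <- stats::runif(3, 0, box_edge)
      if (m == 1 ||
          min(sqrt(rowSums((centers[seq_len(m - 1), , drop = FALSE] -
                            matrix(p, m - 1, 3, byrow = TRUE))^2))) >= min_oo) {
        centers[m, ] <- p; ok <- TRUE; break
      }
    }
    if (!ok)
      stop("packing failure: placed ", m - 1, " of ", n_molecules,
           " molecules at min O-O ", min_oo, " A")
  }
  lapply(seq_len(n_molecules), function(m)
    build_reference_molecule(spec,
      rigid_transform(.random_rotation(), centers[m, ])))
}

# uniform random rotation (normalized quaternion)
.random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

#' Construct a linear hydrogen-bonded water dimer
#'
#' Builds a donor molecule with one O-H bond pointing along the O-O axis at
#' the acceptor oxygen, and an acceptor tilted out of that axis (the
#' "linear" dimer motif).  The geometry is a constructed stand-in --
#' convenient, plausible, and fully specified by its arguments -- not an
#' optimized quantum-chemical structure.  With the \code{"water-dimer"}
#' charge set, the six CHELPG charges are assigned to the donor
#' (O1/H11/H12, H11 the bonding hydrogen) and acceptor (O2/H21/H22) sites.
#'
#' @param r_oo O-O distance in Angstrom (> 2).
#' @param spec a rigid \code{water_model} providing the monomer geometry
#'   (default SPC/E).
#' @param tilt acceptor bisector tilt from the O-O axis, degrees.
#' @param charges \code{"model"} (use \code{spec}'s charges) or
#'   \code{"dimer"} (attach the water-dimer CHELPG set).
#' @return a list with the two \code{molecule_geometry} objects
#'   (\code{donor}, \code{acceptor}) and the charge map used.
#' @export
build_dimer <- function(r_oo, spec = water_model("spce"), tilt = 57,
                        charges = c("model", "dimer")) {
  charges <- match.arg(charges)
  stopifnot(r_oo > 2)
  th <- spec$geometry$hoh_angle * pi / 180
  # donor: rotate the reference so H1's bond axis lies along +x
  beta <- pi / 2 - th / 2
  Ry <- function(b) matrix(c(cos(b), 0, -sin(b), 0, 1, 0,
                             sin(b), 0, cos(b)), 3, 3)
  donor <- build_reference_molecule(spec, rigid_transform(Ry(beta)))
  # acceptor: bisector in the xz plane at `tilt` degrees from the O-O axis,
  # hydrogens pointing away from the donor
  ta <- tilt * pi / 180
  acc <- build_reference_molecule(
    spec, rigid_transform(Ry(pi / 2 - ta), c(r_oo, 0, 0)))
  qmap <- NULL
  if (charges == "dimer") {
    dim_spec <- water_model("water-dimer")
    qmap <- list(donor = dim_spec$charges[c("O1", "H11", "H12")],
                 acceptor = dim_spec$charges[c("O2", "H21", "H22")])
  }
  list(donor = donor, acceptor = acc, r_oo = r_oo, charges = qmap)
}
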