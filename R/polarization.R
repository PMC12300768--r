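# Induced dipoles: direct Drude-pair evaluation, and self-consistent-field
# solution of mutually interacting point polarizabilities in the permanent
# electric field (used for multipole models and for post-trajectory
# polarization of non-polarizable trajectories).
#
# Gaussian-style units: fields in e/A^2, polarizabilities in A^3, so that
# mu[e A] = alpha * E; conversion to Debye happens at the interface.

#' Polarization solver options
#'
#' @param interaction \code{"bare_tensor"} (the dipole-dipole tensor as such,
#'   divergent at short range) or \code{"thole_damped"} (exponential damping
#'   of the r^-3 and r^-5 terms with factor \code{a/(alpha_i alpha_j)^{1/6}},
#'   recommended for dense-liquid post-trajectory polarization).
#' @param thole_a Thole damping factor (used when
#'   \code{interaction = "thole_damped"}).
#' @param solver \code{"fixed_point"} or \code{"direct_linear"}.
#' @param max_iter,mixing,tol fixed-point controls: iteration cap, mixing
#'   parameter in (0, 1], convergence tolerance in Debye.
#' @param boundary \code{"open_cluster"} or \code{"minimum_image"}.
#' @param cutoff,switch_width minimum-image real-space cutoff and smooth
#'   switching width (Angstrom).
#' @param field_sources logical flags naming which permanent sources enter
#'   the field: partial charges (default), lab-frame atomic dipoles, atomic
#'   quadrupoles.
#' @param intramolecular_induction include mutual induction between
#'   polarizable sites of the same molecule (off for rigid 3/4-site models;
#'   a single molecule must be field-free).
#' @return a \code{polar_options} list.
#' @export
polar_options <- function(interaction = c("bare_tensor", "thole_damped"),
                          thole_a = 0.39,
                          solver = c("fixed_point", "direct_linear"),
                          max_iter = 200, mixing = 0.7, tol = 1e-6,
                          boundary = c("open_cluster", "minimum_image"),
                          cutoff = 9, switch_width = 1,
                          field_sources = c(charges = TRUE,
                                            atomic_dipoles = FALSE,
                                            atomic_quadrupoles = FALSE),
                          intramolecular_induction = FALSE) {
  stopifnot(tol > 0, mixing > 0, mixing <= 1, max_iter >= 1)
  opts <- list(interaction = match.arg(interaction), thole_a = thole_a,
               solver = match.arg(solver), max_iter = max_iter,
               mixing = mixing, tol = tol, boundary = match.arg(boundary),
               cutoff = cutoff, switch_width = switch_width,
               field_sources = field_sources,
               intramolecular_induction = intramolecular_induction)
  class(opts) <- "polar_options"
  opts
}

#' Induced dipole of a Drude oscillator pair
#'
#' The physical induced dipole \eqn{\mu = q_D d} where \eqn{d} is the
#' displacement from the fixed (-q_D) particle at the host atom toward the
#' mobile (+q_D) particle.
#'
#' @param host_position,drude_position positions in Angstrom.
#' @param q_d Drude charge in e (nonzero).
#' @return induced dipole vector in Debye.
#' @examples
#' drude_induced(c(0, 0, 0), c(0.1, 0, 0), 1)     # (0.480321, 0, 0) D
#' @export
drude_induced <- function(host_position, drude_position, q_d) {
  if (q_d == 0) stop("Drude charge must be nonzero")
  q_d * (as.numeric(drude_position) - as.numeric(host_position)) * .EA2D
}

#' Dipole-dipole interaction tensor
#'
#' The point-dipole tensor \eqn{T(r) = (3 \hat r \hat r^T - I)/r^3}
#' (Angstrom^-3), optionally Thole-damped: the r^-3 and r^-5 terms are
#' multiplied by \eqn{1 - e^{-a u^3}} and \eqn{1 - (1 + a u^3) e^{-a u^3}}
#' with \eqn{u = r/(\alpha_i \alpha_j)^{1/6}}.  The bare tensor is symmetric
#' and traceless.
#'
#' @param r separation vector (Angstrom), nonzero.
#' @param interaction \code{"bare_tensor"} or \code{"thole_damped"}.
#' @param thole_a damping factor.
#' @param alpha_i,alpha_j polarizabilities of the coupled sites (A^3),
#'   needed for Thole damping.
#' @return 3x3 tensor in Angstrom^-3.
#' @export
dipole_tensor <- function(r, interaction = "bare_tensor", thole_a = 0.39,
                          alpha_i = NULL, alpha_j = NULL) {
  r <- as.numeric(r)
  d <- sqrt(sum(r^2))
  if (d < 1e-6) stop("coincident sites: |r| = ", format(d), " A")
  rh <- r / d
  l3 <- 1; l5 <- 1
  if (identical(interaction, "thole_damped")) {
    if (is.null(alpha_i) || is.null(alpha_j))
      stop("Thole damping needs both site polarizabilities")
    u3 <- thole_a * (d / (alpha_i * alpha_j)^(1 / 6))^3
    e <- exp(-u3)
    l3 <- 1 - e
    l5 <- 1 - (1 + u3) * e
  }
  (3 * l5 * tcrossprod(rh) - l3 * diag(3)) / d^3
}

#' Assemble an interacting site configuration
#'
#' Flattens a list of molecule geometries that share a water model into the
#' per-site table the field and SCF routines operate on: coordinates,
#' charges, polarizabilities, and (when present) lab-frame atomic dipoles
#' (e A) and quadrupoles (e A^2, with the model's scale convention applied).
#'
#' @param geoms list of \code{molecule_geometry} objects.
#' @param spec the shared \code{water_model}.
#' @param box optional cubic box edge (Angstrom) for minimum-image boundaries.
#' @return a \code{site_config}.
#' @export
assemble_configuration <- function(geoms, spec, box = NULL) {
  if (inherits(geoms, "molecule_geometry")) geoms <- list(geoms)
  alphas <- .model_alphas(spec)
  n <- vapply(geoms, function(g) nrow(g$coords), integer(1))
  coords <- do.call(rbind, lapply(geoms, function(g) g$coords))
  site <- unlist(lapply(geoms, function(g) rownames(g$coords)))
  molecule <- rep(seq_along(geoms), n)
  charge <- unname(spec$charges[site])
  charge[is.na(charge)] <- 0
  alpha <- unname(alphas[site])
  alpha[is.na(alpha)] <- 0
  mu_perm <- NULL; theta <- NULL
  if (length(spec$atomic_dipoles) || length(spec$atomic_quadrupoles)) {
    mu_perm <- matrix(0, length(site), 3)
    theta <- vector("list", length(site))
    off <- 0
    for (g in geoms) {
      fr <- local_frames(g)
      for (j in seq_len(nrow(g$coords))) {
        lab <- rownames(g$coords)[j]
        if (lab %in% names(spec$atomic_dipoles))
          mu_perm[off + j, ] <-
            drop(fr[[lab]] %*% spec$atomic_dipoles[[lab]]) / .EA2D
      }
      if (length(spec$atomic_quadrupoles)) {
        ql <- quadrupole_lab(g, spec)
        for (j in seq_len(nrow(g$coords))) {
          lab <- rownames(g$coords)[j]
          if (lab %in% names(ql)) theta[[off + j]] <- ql[[lab]] / .EA2D
        }
      }
      off <- off + nrow(g$coords)
    }
  }
  structure(list(coords = unname(coords), site = site, molecule = molecule,
                 charge = charge, alpha = alpha, mu_perm = mu_perm,
                 theta = theta, box = box, model = spec$name,
                 thole = spec$thole),
            class = "site_config")
}

# minimum-image displacement (cubic box) and smooth switching weight
.mi_disp <- function(dr, box) dr - box * round(dr / box)

.switch_weight <- function(d, cutoff, width) {
  if (d >= cutoff) return(0)
  if (d <= cutoff - width) return(1)
  cos(pi * (d - (cutoff - width)) / (2 * width))^2
}

#' Electric field of the permanent sources
#'
#' Sums, at each polarizable site, the Coulomb fields of the permanent
#' partial charges of all *other* molecules (intramolecular sources are
#' excluded), plus point-dipole and point-quadrupole fields when the model
#' carries atomic multipoles and the corresponding \code{field_sources} flags
#' are set.  The quadrupole convention is the potential
#' \eqn{V = r^T \Theta r / r^5} with the stored (already scale-converted)
#' tensor.  Units: e/A^2.
#'
#' @param config a \code{site_config}.
#' @param opts [polar_options()].
#' @param targets integer indices of target sites; defaults to all
#'   polarizable sites.
#' @return matrix (length(targets) x 3) of fields.
#' @export
permanent_field <- function(config, opts = polar_options(),
                            targets = which(config$alpha > 0)) {
  fs <- opts$field_sources
  mi <- identical(opts$boundary, "minimum_image")
  if (mi) {
    if (is.null(config$box)) stop("minimum_image boundary needs a box")
    if (opts$cutoff >= config$box / 2 + 1e-9)
      stop("cutoff must be below half the box edge")
  }
  out <- matrix(0, length(targets), 3)
  for (k in seq_along(targets)) {
    i <- targets[k]
    E <- c(0, 0, 0)
    for (j in seq_along(config$site)) {
      if (config$molecule[j] == config$molecule[i]) next
      dr <- config$coords[i, ] - config$coords[j, ]
      if (mi) dr <- .mi_disp(dr, config$box)
      d <- sqrt(sum(dr^2))
      if (d < 1e-6) stop("singular field: overlapping intermolecular sites ",
                         i, " and ", j)
      w <- if (mi) .switch_weight(d, opts$cutoff, opts$switch_width) else 1
      if (w == 0) next
      if (isTRUE(fs[["charges"]]) && config$charge[j] != 0)
        E <- E + w * config$charge[j] * dr / d^3
      if (isTRUE(fs[["atomic_dipoles"]]) && !is.null(config$mu_perm)) {
        mu <- config$mu_perm[j, ]
        if (any(mu != 0))
          E <- E + w * (3 * sum(mu * dr) * dr / d^2 - mu) / d^3
      }
      if (isTRUE(fs[["atomic_quadrupoles"]]) && !is.null(config$theta) &&
          !is.null(config$theta[[j]])) {
        th <- config$theta[[j]]
        thr <- drop(th %*% dr)
        E <- E + w * (5 * sum(dr * thr) * dr / d^7 - 2 * thr / d^5)
      }
    }
    out[k, ] <- E
  }
  out
}

# block dipole-dipole coupling matrix over polarizable sites (3p x 3p),
# honoring interaction type, boundary and intramolecular mask
.coupling_matrix <- function(config, opts, pol) {
  p <- length(pol)
  Tm <- matrix(0, 3 * p, 3 * p)
  mi <- identical(opts$boundary, "minimum_image")
  for (a in seq_len(p)) {
    for (b in seq_len(p)) {
      if (a == b) next
      i <- pol[a]; j <- pol[b]
      if (!opts$intramolecular_induction &&
          config$molecule[i] == config$molecule[j]) next
      dr <- config$coords[i, ] - config$coords[j, ]
      if (mi) dr <- .mi_disp(dr, config$box)
      d <- sqrt(sum(dr^2))
      w <- if (mi) .switch_weight(d, opts$cutoff, opts$switch_width) else 1
      if (w == 0) next
      Tm[(3 * a - 2):(3 * a), (3 * b - 2):(3 * b)] <-
        w * dipole_tensor(dr, opts$interaction, thole_a = opts$thole_a,
                          alpha_i = config$alpha[i], alpha_j = config$alpha[j])
    }
  }
  Tm
}

#' Self-consistent induced dipoles
#'
#' Solves \eqn{\mu_i = \alpha_i (E^0_i + \sum_{j \ne i} T_{ij} \mu_j)} over
#' all polarizable sites, either by damped fixed-point iteration or by the
#' direct linear solve \eqn{(I - A T)\mu = A E^0}.  Fixed-point divergence
#' (residual growth over 10 consecutive iterations) and singular linear
#' systems raise a polarization-catastrophe error naming the closest pair of
#' polarizable sites.
#'
#' @param config a \code{site_config} with at least one polarizable site.
#' @param opts [polar_options()].
#' @param external_field optional uniform external field (e/A^2) added to the
#'   permanent field.
#' @param mu0 optional warm-start induced dipoles in Debye (matrix p x 3).
#' @return an \code{induced_dipoles} object: matrix \code{mu} (p x 3, Debye),
#'   site indices, iteration count, final residual (D), solver tag and
#'   convergence status.
#' @export
scf_induced_dipoles <- function(config, opts = polar_options(),
                                external_field = c(0, 0, 0), mu0 = NULL) {
  pol <- which(config$alpha > 0)
  if (!length(pol)) stop("no polarizable sites in configuration")
  if (any(config$alpha[pol] <= 0)) stop("polarizabilities must be positive")
  p <- length(pol)
  alpha <- config$alpha[pol]
  E0 <- permanent_field(config, opts, targets = pol) +
    matrix(as.numeric(external_field), p, 3, byrow = TRUE)
  Tm <- .coupling_matrix(config, opts, pol)
  A <- rep(alpha, each = 3)

  catastrophe <- function(reason) {
    dd <- Inf; pair <- c(NA, NA)
    for (a in seq_len(p - 1)) for (b in (a + 1):p) {
      dr <- config$coords[pol[a], ] - config$coords[pol[b], ]
      if (identical(opts$boundary, "minimum_image"))
        dr <- .mi_disp(dr, config$box)
      d <- sqrt(sum(dr^2))
      if (d < dd) { dd <- d; pair <- pol[c(a, b)] }
    }
    stop("polarization catastrophe (", reason, "); closest polarizable pair: ",
         "sites ", pair[1], " and ", pair[2], " at ",
         format(round(dd, 3)), " A", call. = FALSE)
  }

  if (identical(opts$solver, "direct_linear")) {
    K <- diag(3 * p) - A * Tm
    mu_vec <- tryCatch(solve(K, A * as.vector(t(E0))),
                       error = function(e) catastrophe("singular linear system"))
    mu <- matrix(mu_vec, p, 3, byrow = TRUE)
    resid <- max(abs(A * (as.vector(t(E0)) + Tm %*% mu_vec) - mu_vec)) * .EA2D
    iters <- 0L
  } else {
    mu <- if (is.null(mu0)) matrix(0, p, 3) else unname(mu0) / .EA2D
    mu_vec <- as.vector(t(mu))
    E0_vec <- as.vector(t(E0))
    resid_prev <- Inf; grow <- 0L; iters <- 0L; resid <- Inf
    repeat {
      iters <- iters + 1L
      target <- A * (E0_vec + drop(Tm %*% mu_vec))
      resid <- max(abs(target - mu_vec)) * .EA2D
      if (resid <= opts$tol) { mu_vec <- target; break }
      if (resid > resid_prev) grow <- grow + 1L else grow <- 0L
      if (grow >= 10L) catastrophe("fixed-point divergence")
      if (iters >= opts$max_iter)
        stop("SCF did not converge in ", opts$max_iter,
             " iterations (residual ", format(resid), " D)")
      resid_prev <- resid
      mu_vec <- (1 - opts$mixing) * mu_vec + opts$mixing * target
    }
    mu <- matrix(mu_vec, p, 3, byrow = TRUE)
  }
  structure(list(mu = mu * .EA2D, sites = pol, iterations = iters,
                 residual = resid, solver = opts$solver,
                 converged = resid <= max(opts$tol, 1e-8)),
            class = "induced_dipoles")
}

#' @export
print.induced_dipoles <- function(x, ...) {
  cat("<induced_dipoles>", nrow(x$mu), "site(s),", x$solver,
      "solver,", x$iterations, "iteration(s), residual",
      format(x$residual, digits = 3), "D\n")
  invisible(x)
}

#' Post-trajectory polarization of a trajectory
#'
#' Runs the self-consistent induced-dipole solver on every frame of a
#' trajectory whose model assigns a polarizability to the oxygen site
#' (hydrogens unpolarized), warm-starting each frame from the previous
#' solution, and aggregates per-molecule induced dipoles
#' \eqn{\mu_i^{ind} = \sum_\beta \mu_{i\beta}^{ind}}.  This is how induced
#' dipoles are attached to trajectories produced with a non-polarizable
#' model (e.g. SPC/E with an elevated oxygen polarizability).
#'
#' @param traj a trajectory (see [load_trajectory()] or
#'   [librator_trajectory()]).
#' @param spec a \code{water_model} with at least one polarizable site (use
#'   [set_site_polarizability()] for non-polarizable models).
#' @param opts [polar_options()].
#' @param on_error \code{"abort"} (default; error names the frame) or
#'   \code{"skip"} (frame's induced dipoles set to NA with a warning).
#' @return a [dipole_series()] with both permanent and induced channels.
#' @export
post_trajectory_polarization <- function(traj, spec, opts = polar_options(),
                                         on_error = c("abort", "skip")) {
  on_error <- match.arg(on_error)
  alphas <- .model_alphas(spec)
  if (!length(alphas))
    stop("model '", spec$name, "' has no polarizable sites")
  series <- molecular_dipoles(traj, spec)
  nfr <- dim(series$perm)[1]
  nmol <- dim(series$perm)[2]
  ind <- array(0, dim(series$perm))
  warm <- NULL
  for (f in seq_len(nfr)) {
    cfg <- .frame_config(traj, spec, f)
    res <- tryCatch(scf_induced_dipoles(cfg, opts, mu0 = warm),
                    error = function(e) e)
    if (inherits(res, "error")) {
      if (on_error == "abort")
        stop("SCF failed at frame ", f, ": ", conditionMessage(res))
      warning("SCF failed at frame ", f, "; induced dipoles set to NA")
      ind[f, , ] <- NA_real_
      warm <- NULL
      next
    }
    warm <- res$mu
    mol_of <- cfg$molecule[res$sites]
    for (m in seq_len(nmol))
      ind[f, m, ] <- colSums(res$mu[mol_of == m, , drop = FALSE])
  }
  dipole_series(series$times, series$perm, ind)
}

# site_config for one trajectory frame (charges + polarizabilities only;
# atomic multipole sources would need per-frame frames and are attached the
# same way as in assemble_configuration when present)
.frame_config <- function(traj, spec, frame) {
  geoms <- .frame_geometries(traj, frame)
  assemble_configuration(geoms, spec, box = traj$box)
}
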