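# Electrostatic parameterizations of rigid water models and the geometric
# machinery (reference geometries, virtual sites, local atomic frames) needed
# to evaluate permanent molecular dipoles and lab-frame multipoles.

#' Load a water model parameter set
#'
#' Reads one of the bundled electrostatic parameter files (or a user file via
#' [read_water_model()]) describing a water model: site charges, rigid
#' reference geometry, virtual sites, optional Drude pair, and optional
#' atomic permanent dipoles/quadrupoles in local atomic frames.
#'
#' Bundled models: \code{"spce"}, \code{"swm4-ndp"}, \code{"ipol-013"},
#' \code{"opc3-pol"}, \code{"amoeba14"}, and the \code{"water-dimer"} CHELPG
#' charge set.
#'
#' @param name model name (file stem of a bundled parameter file).
#' @return an object of class \code{water_model}.
#' @examples
#' m <- water_model("spce")
#' m$charges
#' @export
water_model <- function(name) {
  path <- system.file("extdata", "water_models", paste0(name, ".yaml"),
                      package = "thzwater")
  if (!nzchar(path)) {
    avail <- sub("\\.yaml$", "", dir(system.file("extdata", "water_models",
                                                 package = "thzwater")))
    stop("unknown water model '", name, "'; bundled models: ",
         paste(avail, collapse = ", "))
  }
  read_water_model(path)
}

#' Read and validate a water model parameter file
#'
#' @param path path to a YAML parameter file mirroring the bundled ones.
#' @return an object of class \code{water_model}.
#' @export
read_water_model <- function(path) {
  raw <- yaml::read_yaml(path)
  spec <- list(
    name = raw$name,
    geometry = raw$geometry,
    charges = vapply(raw$charges, as.numeric, numeric(1)),
    virtual_sites = raw$virtual_sites,
    drude = raw$drude,
    atomic_dipoles = lapply(raw$atomic_dipoles, as.numeric),
    atomic_quadrupoles = lapply(raw$atomic_quadrupoles, .quad_from_yaml),
    quadrupole_scale_convention =
      if (is.null(raw$quadrupole_scale_convention)) "as_printed"
      else raw$quadrupole_scale_convention,
    polarizability = if (is.null(raw$polarizability)) NULL
                     else vapply(raw$polarizability, as.numeric, numeric(1)),
    thole = raw$thole
  )
  class(spec) <- "water_model"
  validate_water_model(spec)
  spec
}

.quad_from_yaml <- function(q) {
  m <- matrix(0, 3, 3, dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  get0 <- function(k) if (is.null(q[[k]])) 0 else as.numeric(q[[k]])
  m[1, 1] <- get0("xx"); m[2, 2] <- get0("yy"); m[3, 3] <- get0("zz")
  m[1, 2] <- m[2, 1] <- get0("xy")
  m[1, 3] <- m[3, 1] <- get0("xz")
  m[2, 3] <- m[3, 2] <- get0("yz")
  m
}

#' Validate a water model parameter set
#'
#' Checks the structural invariants: charge neutrality of the full site set
#' (to 1e-12 e), near-tracelessness of every atomic quadrupole (printed
#' tabulations round-trip to |trace| <= 1.5e-3 D A), and, if a Drude block is
#' present, a positive polarizability and nonzero Drude charge.
#'
#' @param spec a \code{water_model}.
#' @return \code{spec}, invisibly; errors on violation.
#' @export
validate_water_model <- function(spec) {
  stopifnot(inherits(spec, "water_model"))
  if (abs(sum(spec$charges)) > 1e-12)
    stop("water model '", spec$name, "' is not charge neutral: sum q = ",
         format(sum(spec$charges)))
  for (lab in names(spec$atomic_quadrupoles)) {
    th <- spec$atomic_quadrupoles[[lab]]
    if (max(abs(th - t(th))) > 1e-12)
      stop("atomic quadrupole for site ", lab, " is not symmetric")
    if (abs(sum(diag(th))) > 1.5e-3)
      stop("atomic quadrupole for site ", lab, " is not traceless: trace = ",
           format(sum(diag(th))))
  }
  if (!is.null(spec$drude)) {
    if (!(spec$drude$alpha > 0)) stop("Drude polarizability must be > 0")
    if (spec$drude$charge == 0) stop("Drude charge must be nonzero")
  }
  if (!spec$quadrupole_scale_convention %in% c("as_printed", "one_third"))
    stop("unknown quadrupole_scale_convention: ",
         spec$quadrupole_scale_convention)
  invisible(spec)
}

#' @export
print.water_model <- function(x, ...) {
  cat("<water_model>", x$name, "\n")
  cat("  sites:", paste(names(x$charges), collapse = " "), "\n")
  if (identical(x$geometry$kind, "rigid"))
    cat("  rigid: r_OH =", x$geometry$r_oh, "A, H-O-H =",
        x$geometry$hoh_angle, "deg\n")
  else cat("  flexible geometry\n")
  if (!is.null(x$drude))
    cat("  Drude on", x$drude$host, ": q_D =", x$drude$charge,
        "e, alpha =", x$drude$alpha, "A^3\n")
  if (length(x$atomic_dipoles))
    cat("  atomic multipoles up to quadrupole (",
        x$quadrupole_scale_convention, " convention )\n")
  invisible(x)
}

#' Rigid-body placement
#'
#' A rotation + translation used to place reference molecules in the lab
#' frame.
#'
#' @param rotation 3x3 rotation matrix (orthonormal, det +1).
#' @param translation length-3 translation vector (Angstrom).
#' @return a \code{rigid_transform}.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  stopifnot(is.matrix(rotation), all(dim(rotation) == c(3, 3)))
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8 ||
      abs(det(rotation) - 1) > 1e-8)
    stop("rotation must be orthonormal with determinant +1")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Build a reference molecule from a rigid water model
#'
#' Places one molecule with the oxygen at the transform origin and the H-O-H
#' bisector along the transform z axis (hydrogens in the transform xz plane,
#' H1 on the +x side).  Virtual sites are constructed per their rule; the
#' bisector rule places the site at the stated displacement from O toward the
#' hydrogen midpoint (e.g. the SWM4-NDP OM site at 0.24 A).
#'
#' @param spec a rigid \code{water_model}.
#' @param placement a [rigid_transform()].
#' @return a \code{molecule_geometry}: data frame of site labels and lab
#'   coordinates (Angstrom), carrying the model name.
#' @export
build_reference_molecule <- function(spec, placement = rigid_transform()) {
  stopifnot(inherits(spec, "water_model"))
  if (!identical(spec$geometry$kind, "rigid"))
    stop("geometry required: model '", spec$name,
         "' is flexible; supply explicit coordinates")
  r <- spec$geometry$r_oh
  half <- spec$geometry$hoh_angle * pi / 360
  coords <- rbind(
    O  = c(0, 0, 0),
    H1 = r * c(sin(half), 0, cos(half)),
    H2 = r * c(-sin(half), 0, cos(half))
  )
  for (vs in spec$virtual_sites) {
    if (identical(vs$rule, "bisector")) {
      p <- c(0, 0, vs$displacement)   # along the bisector toward the H midpoint
    } else stop("unknown virtual site rule: ", vs$rule)
    coords <- rbind(coords, p)
    rownames(coords)[nrow(coords)] <- vs$label
  }
  lab <- t(placement$rotation %*% t(coords)) +
    matrix(placement$translation, nrow(coords), 3, byrow = TRUE)
  molecule_geometry(lab, model = spec$name)
}

#' Construct a molecule geometry from explicit coordinates
#'
#' @param coords numeric matrix with one row per site and rownames giving the
#'   site labels (must include O, H1, H2 for frame construction).
#' @param model optional model name tag.
#' @return a \code{molecule_geometry}.
#' @export
molecule_geometry <- function(coords, model = NULL) {
  stopifnot(is.matrix(coords), ncol(coords) == 3, !is.null(rownames(coords)))
  structure(list(coords = coords, model = model), class = "molecule_geometry")
}

#' @export
print.molecule_geometry <- function(x, ...) {
  cat("<molecule_geometry>", if (!is.null(x$model)) x$model else "", "\n")
  print(round(x$coords, 4))
  invisible(x)
}

#' Local atomic frames of a water molecule
#'
#' Builds the local frames in which AMOEBA-style atomic multipoles are
#' defined.  Oxygen: z along the bisector from O toward the hydrogen
#' midpoint, x in the molecular plane perpendicular to z (along the H1-H2
#' direction).  Hydrogens: z from the hydrogen toward the oxygen, x in-plane
#' pointing inward (toward the molecular interior).  y completes each
#' right-handed frame, which makes y point "up" for O and H1 and "down" for
#' H2.  These conventions are pinned down uniquely by the reconstruction of
#' the AMOEBA14 monomer dipole magnitude (see [permanent_dipole()]).
#'
#' @param geom a \code{molecule_geometry} resolving sites O, H1, H2.
#' @return named list of 3x3 rotation matrices whose columns are the local
#'   x, y, z axes expressed in lab coordinates (so \code{R \%*\% v_local}
#'   is the lab-frame vector).
#' @export
local_frames <- function(geom) {
  co <- geom$coords
  need <- c("O", "H1", "H2")
  if (!all(need %in% rownames(co)))
    stop("local frames need resolvable O, H1, H2 sites")
  O <- co["O", ]; H1 <- co["H1", ]; H2 <- co["H2", ]
  b1 <- H1 - O; b2 <- H2 - O
  if (sqrt(sum(.cross3(b1, b2)^2)) < 1e-8 * sqrt(sum(b1^2)) * sqrt(sum(b2^2)))
    stop("degenerate frame: collinear atoms")
  frame_from <- function(z, inplane) {
    z <- .unit(z)
    x <- .unit(inplane - sum(inplane * z) * z)
    y <- .cross3(z, x)
    cbind(x = x, y = y, z = z)
  }
  list(
    O  = frame_from((H1 + H2) / 2 - O, H1 - H2),
    H1 = frame_from(O - H1, H2 - H1),
    H2 = frame_from(O - H2, H1 - H2)
  )
}

#' Permanent molecular dipole moment
#'
#' Sums the point-charge dipole \eqn{\sum_\beta q_\beta r_\beta} (converted
#' with 1 e A = 4.80321 D) and, when the model carries atomic permanent
#' dipoles, their lab-frame rotations via [local_frames()].  For a neutral
#' site set the result is origin independent; a non-neutral set is rejected
#' unless an explicit \code{origin} is supplied (the dipole is then reported
#' about that origin).
#'
#' @param geom a \code{molecule_geometry} with all sites (including virtual
#'   sites) present.
#' @param spec the matching \code{water_model}.
#' @param origin optional length-3 origin (Angstrom) for charged site sets.
#' @return length-3 dipole vector in Debye.
#' @examples
#' m <- water_model("spce")
#' mu <- permanent_dipole(build_reference_molecule(m), m)
#' sqrt(sum(mu^2))   # 2.35 D
#' @export
permanent_dipole <- function(geom, spec, origin = NULL) {
  co <- geom$coords
  labs <- intersect(names(spec$charges), rownames(co))
  if (!setequal(labs, names(spec$charges)))
    stop("geometry is missing charged sites: ",
         paste(setdiff(names(spec$charges), rownames(co)), collapse = ", "))
  q <- spec$charges[labs]
  if (abs(sum(q)) > 1e-9 && is.null(origin))
    stop("origin-dependent dipole: site set carries net charge ",
         format(sum(q)), " e; supply an explicit origin")
  if (is.null(origin)) origin <- c(0, 0, 0)
  r <- co[labs, , drop = FALSE] - matrix(origin, length(labs), 3, byrow = TRUE)
  mu <- colSums(q * r) * .EA2D
  if (length(spec$atomic_dipoles)) {
    fr <- local_frames(geom)
    for (lab in names(spec$atomic_dipoles)) {
      if (!lab %in% names(fr))
        stop("no local frame for site ", lab)
      mu <- mu + drop(fr[[lab]] %*% spec$atomic_dipoles[[lab]])
    }
  }
  unname(mu)
}

#' Lab-frame atomic quadrupoles
#'
#' Rotates each atomic quadrupole from its local frame to the lab frame
#' (\eqn{R \Theta R^T}), optionally applying the one-third scale convention
#' used when the printed tensor values are consumed by a simulation engine.
#' The trace is preserved under rotation.
#'
#' @param geom a \code{molecule_geometry}.
#' @param spec a \code{water_model} carrying atomic quadrupoles.
#' @param convention \code{"as_printed"} or \code{"one_third"}; defaults to
#'   the model's own convention.
#' @return named list of lab-frame 3x3 tensors (D A).
#' @export
quadrupole_lab <- function(geom, spec,
                           convention = spec$quadrupole_scale_convention) {
  if (!length(spec$atomic_quadrupoles))
    stop("model '", spec$name, "' carries no atomic quadrupoles")
  convention <- match.arg(convention, c("as_printed", "one_third"))
  scale <- if (convention == "one_third") 1 / 3 else 1
  fr <- local_frames(geom)
  out <- list()
  for (lab in names(spec$atomic_quadrupoles)) {
    th <- spec$atomic_quadrupoles[[lab]]
    if (max(abs(th - t(th))) > 1e-12)
      stop("non-symmetric quadrupole tensor for site ", lab)
    R <- fr[[lab]]
    out[[lab]] <- scale * R %*% th %*% t(R)
  }
  out
}

#' Scale the polarizability of a water model
#'
#' Returns a copy of the model with every polarizability multiplied by
#' \code{factor}.  For Drude models this rescales the stored effective
#' polarizability \eqn{\alpha = q_D^2 / k_D} (the analysis pipeline consumes
#' \eqn{\alpha}, not the force constant).
#'
#' @param spec a \code{water_model}.
#' @param factor multiplicative factor (> 0).
#' @return the rescaled \code{water_model}.
#' @examples
#' sw <- water_model("swm4-ndp")
#' scale_polarizability(sw, 1.2)$drude$alpha
#' @export
scale_polarizability <- function(spec, factor) {
  stopifnot(inherits(spec, "water_model"), factor > 0)
  if (!is.null(spec$drude)) spec$drude$alpha <- spec$drude$alpha * factor
  if (!is.null(spec$polarizability))
    spec$polarizability <- spec$polarizability * factor
  spec
}

#' Assign a site polarizability
#'
#' Attaches (or overrides) an isotropic polarizability on one site, e.g. to
#' add post-trajectory polarization to a non-polarizable model such as SPC/E
#' (oxygen-only polarization; hydrogens stay unpolarized).
#'
#' @param spec a \code{water_model}.
#' @param site site label.
#' @param alpha polarizability in Angstrom^3 (> 0), or 0 to remove.
#' @return the modified \code{water_model}.
#' @examples
#' spce_pol <- set_site_polarizability(water_model("spce"), "O", 1.14)
#' @export
set_site_polarizability <- function(spec, site, alpha) {
  stopifnot(inherits(spec, "water_model"), alpha >= 0)
  pol <- spec$polarizability
  if (is.null(pol)) pol <- numeric(0)
  pol[site] <- alpha
  spec$polarizability <- pol[pol > 0]
  if (!length(spec$polarizability)) spec$polarizability <- NULL
  spec
}

# polarizable sites of a model as a named alpha vector (Drude host included)
.model_alphas <- function(spec) {
  pol <- spec$polarizability
  if (is.null(pol)) pol <- numeric(0)
  if (!is.null(spec$drude) && !spec$drude$host %in% names(pol))
    pol[spec$drude$host] <- spec$drude$alpha
  pol
}
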