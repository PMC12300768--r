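# Independent brute-force oracles the FFT / solver / field code is checked
# against, plus small fixture builders.

# naive O(n^2) correlation estimator, unbiased per-lag normalization
naive_xcorr <- function(a, b, max_lag) {
  a <- as.matrix(a); b <- as.matrix(b)
  n <- nrow(a)
  vapply(0:max_lag, function(k) {
    idx <- seq_len(n - k)
    sum(a[idx, , drop = FALSE] * b[idx + k, , drop = FALSE]) / (n - k)
  }, numeric(1))
}

# explicit double-sum cross term over distinct molecule pairs
naive_cross_sum <- function(j_arr, max_lag) {
  nm <- dim(j_arr)[2]
  out <- numeric(max_lag + 1)
  for (i in seq_len(nm)) for (j in seq_len(nm)) {
    if (i == j) next
    out <- out + naive_xcorr(j_arr[, i, ], j_arr[, j, ], max_lag)
  }
  out
}

# naive pairwise Coulomb field (charges only, open cluster)
naive_charge_field <- function(config, target) {
  E <- c(0, 0, 0)
  for (j in seq_along(config$site)) {
    if (config$molecule[j] == config$molecule[target]) next
    dr <- config$coords[target, ] - config$coords[j, ]
    d <- sqrt(sum(dr^2))
    E <- E + config$charge[j] * dr / d^3
  }
  E
}

# electrostatic potential of one source site (charge + point dipole +
# quadrupole with the V = r' Theta r / r^5 convention), used to check fields
# against a numerical gradient
source_potential <- function(r_eval, r_src, q, mu, theta) {
  dr <- r_eval - r_src
  d <- sqrt(sum(dr^2))
  v <- q / d
  if (!is.null(mu)) v <- v + sum(mu * dr) / d^3
  if (!is.null(theta)) v <- v + drop(dr %*% theta %*% dr) / d^5
  v
}

numerical_field <- function(r_eval, r_src, q, mu, theta, h = 1e-5) {
  -vapply(1:3, function(k) {
    e <- c(0, 0, 0); e[k] <- h
    (source_potential(r_eval + e, r_src, q, mu, theta) -
       source_potential(r_eval - e, r_src, q, mu, theta)) / (2 * h)
  }, numeric(1))
}

# bare site configuration with no charges: p polarizable points in an
# external field (dipole-only SCF test bed)
bare_polarizable_config <- function(coords, alpha) {
  p <- nrow(coords)
  structure(list(coords = coords, site = rep("X", p), molecule = seq_len(p),
                 charge = rep(0, p), alpha = rep(alpha, length.out = p),
                 mu_perm = NULL, theta = NULL, box = NULL,
                 model = "toy", thole = NULL),
            class = "site_config")
}

# direct (I - alpha T) mu = alpha E solve built independently of the package
oracle_two_site <- function(coords, alpha, E_ext) {
  T12 <- {
    dr <- coords[1, ] - coords[2, ]
    d <- sqrt(sum(dr^2)); rh <- dr / d
    (3 * tcrossprod(rh) - diag(3)) / d^3
  }
  K <- rbind(cbind(diag(3), -alpha[1] * T12),
             cbind(-alpha[2] * T12, diag(3)))
  rhs <- c(alpha[1] * E_ext, alpha[2] * E_ext)
  matrix(solve(K, rhs), 2, 3, byrow = TRUE)
}

lorentzian <- function(nu, nu0, w, A) A * w^2 / ((nu - nu0)^2 + w^2)
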