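# Induced dipoles: Drude pairs, interaction tensors, permanent fields, and
# the self-consistent solver (fixed point vs direct linear algebra).

test_that("Drude pair displacement gives the physical induced dipole", {
  expect_equal(drude_induced(c(0, 0, 0), c(0.1, 0, 0), 1),
               c(0.480321, 0, 0), tolerance = 1e-12)
  expect_equal(drude_induced(c(1, 2, 3), c(1, 2, 3), -1.71636), c(0, 0, 0))
  expect_equal(drude_induced(c(0, 0, 0), c(0, 0, -0.05), -1.71636),
               c(0, 0, 0.0858180) * 4.80321, tolerance = 1e-6)
  expect_error(drude_induced(c(0, 0, 0), c(1, 0, 0), 0), "nonzero")
})

test_that("bare dipole tensor matches its closed forms and is traceless", {
  expect_equal(dipole_tensor(c(1, 0, 0)), diag(c(2, -1, -1)),
               tolerance = 1e-14)
  expect_equal(dipole_tensor(c(0, 2, 0)), diag(c(-1, 2, -1) / 8),
               tolerance = 1e-14)
  set.seed(3)
  for (rep in 1:1000) {
    Tm <- dipole_tensor(rnorm(3))
    expect_lt(abs(sum(diag(Tm))), 1e-12 * max(abs(Tm)))
    expect_equal(Tm, t(Tm))
  }
  expect_error(dipole_tensor(c(0, 0, 0)), "coincident")
})

test_that("Thole damping suppresses short range and vanishes at long range", {
  a <- 0.39; al <- 1.47
  far <- dipole_tensor(c(8, 0, 0), "thole_damped", a, al, al)
  expect_equal(far, dipole_tensor(c(8, 0, 0)), tolerance = 1e-6)
  near_d <- dipole_tensor(c(0.5, 0, 0), "thole_damped", a, al, al)
  near_b <- dipole_tensor(c(0.5, 0, 0))
  expect_lt(max(abs(near_d)), max(abs(near_b)))
  expect_error(dipole_tensor(c(1, 0, 0), "thole_damped", a), "polarizabilit")
})

test_that("permanent charge field matches Coulomb law and the naive sum", {
  spce <- water_model("spce")
  # single unit charge at 1 A along x: field (1,0,0) e/A^2 at the target
  cfg <- bare_polarizable_config(rbind(c(0, 0, 0), c(-1, 0, 0)), c(1, 0))
  cfg$charge <- c(0, 1)
  expect_equal(permanent_field(cfg, targets = 1)[1, ], c(1, 0, 0),
               tolerance = 1e-14)
  # two opposite charges symmetric about the target: transverse cancellation
  cfg2 <- bare_polarizable_config(rbind(c(0, 0, 0), c(0, 2, 1), c(0, -2, 1)),
                                  c(1, 0, 0))
  cfg2$charge <- c(0, 1, -1)
  E <- permanent_field(cfg2, targets = 1)[1, ]
  expect_equal(E[1], 0, tolerance = 1e-14)
  expect_equal(E[3], 0, tolerance = 1e-14)
  # random three-molecule configuration vs independent double loop
  set.seed(21)
  cl <- generate_cluster(3, spce, box_edge = 9, min_oo = 2.8, seed = 21)
  cfg3 <- assemble_configuration(cl, set_site_polarizability(spce, "O", 1.14))
  for (t in which(cfg3$alpha > 0)) {
    expect_equal(permanent_field(cfg3, targets = t)[1, ],
                 naive_charge_field(cfg3, t), tolerance = 1e-12)
  }
})

test_that("dipole and quadrupole fields match a numerical potential gradient", {
  am <- water_model("amoeba14")
  g1 <- build_reference_molecule(am)
  g2 <- build_reference_molecule(
    am, rigid_transform(thzwater:::.random_rotation(), c(3.1, 0.4, -0.2)))
  set.seed(5)
  cfg <- assemble_configuration(list(g1, g2), am)
  opts <- polar_options(field_sources = c(charges = TRUE,
                                          atomic_dipoles = TRUE,
                                          atomic_quadrupoles = TRUE))
  target <- 1                                  # molecule 1 oxygen
  E <- permanent_field(cfg, opts, targets = target)[1, ]
  E_num <- c(0, 0, 0)
  for (j in which(cfg$molecule == 2)) {
    E_num <- E_num + numerical_field(cfg$coords[target, ], cfg$coords[j, ],
                                     cfg$charge[j], cfg$mu_perm[j, ],
                                     cfg$theta[[j]])
  }
  expect_equal(E, E_num, tolerance = 1e-6)
})

test_that("an isolated polarizable site obeys mu = alpha E exactly", {
  cfg <- bare_polarizable_config(matrix(c(0, 0, 0), 1), 0.97825)
  res <- scf_induced_dipoles(cfg, external_field = c(0.02, -0.01, 0.005))
  expect_equal(res$mu, 0.97825 * matrix(c(0.02, -0.01, 0.005), 1) * 4.80321,
               tolerance = 1e-9)
  expect_true(res$converged)
})

test_that("two-site SCF equals the independent 6x6 linear solve", {
  set.seed(8)
  for (rep in 1:5) {
    co <- rbind(c(0, 0, 0), c(0, 0, 0) + runif(3, 2, 4))
    al <- runif(2, 0.5, 1.5)
    cfg <- bare_polarizable_config(co, al)
    Eext <- rnorm(3, sd = 0.05)
    mu_fp <- scf_induced_dipoles(cfg, polar_options(tol = 1e-9),
                                 external_field = Eext)$mu
    mu_or <- oracle_two_site(co, al, Eext) * 4.80321
    expect_equal(mu_fp, mu_or, tolerance = 1e-6)
  }
})

test_that("fixed-point and direct solvers agree on random clusters", {
  sw <- water_model("swm4-ndp")
  set.seed(31)
  for (rep in 1:10) {
    n <- sample(2:8, 1)
    cl <- generate_cluster(n, sw, box_edge = 11, min_oo = 2.7)
    cfg <- assemble_configuration(cl, sw)
    fp <- scf_induced_dipoles(cfg, polar_options(solver = "fixed_point",
                                                 tol = 1e-7))
    dl <- scf_induced_dipoles(cfg, polar_options(solver = "direct_linear",
                                                 tol = 1e-7))
    expect_lt(max(abs(fp$mu - dl$mu)), 10 * 1e-7)
    expect_lt(fp$iterations, 50)
  }
})

test_that("induced dipoles are linear in the driving field", {
  set.seed(9)
  co <- rbind(c(0, 0, 0), c(3, 0.5, 0), c(1, 3, 1))
  for (inter in c("bare_tensor", "thole_damped")) {
    cfg <- bare_polarizable_config(co, c(1.0, 1.2, 0.8))
    opts <- polar_options(interaction = inter, tol = 1e-10)
    E1 <- c(0.01, 0.02, -0.015)
    mu1 <- scf_induced_dipoles(cfg, opts, external_field = E1)$mu
    mu2 <- scf_induced_dipoles(cfg, opts, external_field = 2 * E1)$mu
    expect_equal(mu2, 2 * mu1, tolerance = 1e-6)
  }
})

test_that("close polarizable pairs trigger the polarization catastrophe", {
  # alpha*T largest eigenvalue = 2*alpha/r^3 >= 1 inside the divergence radius
  cfg <- bare_polarizable_config(rbind(c(0, 0, 0), c(1.0, 0, 0)), 1.47)
  expect_error(
    scf_induced_dipoles(cfg, polar_options(solver = "fixed_point"),
                        external_field = c(0.01, 0, 0)),
    "polarization catastrophe")
  # outside the radius (typical O-O distances) the bare tensor converges
  cfg2 <- bare_polarizable_config(rbind(c(0, 0, 0), c(2.6, 0, 0)), 1.47)
  res <- scf_induced_dipoles(cfg2, external_field = c(0.01, 0, 0))
  expect_true(res$converged)
})

test_that("mirror-symmetric dimers give mirror-symmetric induced dipoles", {
  sw <- water_model("swm4-ndp")
  set.seed(14)
  gA <- build_reference_molecule(
    sw, rigid_transform(thzwater:::.random_rotation(), c(-1.6, 0.3, 0.2)))
  coB <- gA$coords
  coB[, 1] <- -coB[, 1]
  gB <- molecule_geometry(coB)
  cfg <- assemble_configuration(list(gA, gB), sw)
  res <- scf_induced_dipoles(cfg, polar_options(tol = 1e-10))
  muA <- res$mu[1, ]; muB <- res$mu[2, ]
  expect_equal(muB, muA * c(-1, 1, 1), tolerance = 1e-8)
})

test_that("minimum image with a wide cutoff reduces to the open cluster", {
  sw <- water_model("swm4-ndp")
  cl <- generate_cluster(5, sw, box_edge = 8, min_oo = 2.7, seed = 44)
  cfg <- assemble_configuration(cl, sw, box = 40)
  open <- scf_induced_dipoles(cfg, polar_options(boundary = "open_cluster",
                                                 tol = 1e-9))
  mi <- scf_induced_dipoles(cfg,
    polar_options(boundary = "minimum_image", cutoff = 19.9,
                  switch_width = 0.1, tol = 1e-9))
  expect_equal(mi$mu, open$mu, tolerance = 1e-8)
  expect_error(
    permanent_field(cfg, polar_options(boundary = "minimum_image",
                                       cutoff = 25)),
    "half the box")
})

test_that("post-trajectory polarization matches cold-start SCF per frame", {
  spce_pol <- set_site_polarizability(water_model("spce"), "O", 1.14)
  cl <- generate_cluster(3, water_model("spce"), box_edge = 8, min_oo = 2.8,
                         seed = 77)
  nsite <- 3
  coords <- array(0, c(2, 3 * nsite, 3))
  for (m in 1:3) {
    co <- cl[[m]]$coords
    coords[1, ((m - 1) * nsite + 1):(m * nsite), ] <- co
    co2 <- co; co2[, 3] <- co2[, 3] + 0.15 * m   # second frame: shifted
    coords[2, ((m - 1) * nsite + 1):(m * nsite), ] <- co2
  }
  traj <- wtraj(coords,
                data.frame(molecule = rep(1:3, each = nsite),
                           site = rep(c("O", "H1", "H2"), 3)),
                dt = 0.001, box = 8)
  series <- post_trajectory_polarization(traj, spce_pol)
  # frame-by-frame cold-start recomputation
  for (f in 1:2) {
    cfg <- thzwater:::.frame_config(traj, spce_pol, f)
    res <- scf_induced_dipoles(cfg, polar_options())
    for (m in 1:3)
      expect_equal(series$induced[f, m, ], unname(res$mu[m, ]),
                   tolerance = 1e-5, ignore_attr = TRUE)
  }
  # a lone molecule feels no field: induced channel identically zero
  traj1 <- wtraj(coords[, 1:nsite, , drop = FALSE],
                 data.frame(molecule = rep(1, nsite),
                            site = c("O", "H1", "H2")),
                 dt = 0.001)
  s1 <- post_trajectory_polarization(traj1, spce_pol)
  expect_equal(max(abs(s1$induced)), 0)
})
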