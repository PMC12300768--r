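# Collective moments/currents, correlation estimators, and the self/cross
# and permanent/induced decompositions.

random_series <- function(n, nm, seed, walk = FALSE) {
  set.seed(seed)
  perm <- array(rnorm(n * nm * 3), c(n, nm, 3))
  if (walk) perm <- array(apply(perm, c(2, 3), cumsum), c(n, nm, 3))
  ind <- array(rnorm(n * nm * 3, sd = 0.3), c(n, nm, 3))
  dipole_series((seq_len(n) - 1) * 0.002, perm, ind)
}

test_that("collective moment sums channels and differentiates accurately", {
  s <- random_series(50, 3, 1)
  cs <- collective_moment(s)
  expect_equal(cs$M$total, cs$M$perm + cs$M$ind, tolerance = 1e-12)
  expect_equal(cs$M$perm[10, ], colSums(s$perm[10, , ]), tolerance = 1e-12)
  # one molecule: M_D equals the molecular dipole
  s1 <- dipole_series(s$times, s$perm[, 1, , drop = FALSE])
  expect_equal(collective_moment(s1)$M$total, s$perm[, 1, ],
               tolerance = 1e-12, ignore_attr = TRUE)
  # constant M -> zero current
  sc <- dipole_series(s$times, array(2.5, c(50, 3, 3)))
  expect_equal(max(abs(collective_moment(sc)$J$total)), 0)
  expect_error(collective_moment(dipole_series((0:1) * 0.1,
                                               array(1, c(2, 1, 3)))),
               "insufficient frames")
  # sampled sinusoid: central difference matches the analytic derivative
  # to its O(dt^2) Taylor bound
  dt <- 0.002; om <- 40; tt <- (0:499) * dt
  arr <- array(0, c(500, 1, 3)); arr[, 1, 1] <- sin(om * tt)
  J <- collective_moment(dipole_series(tt, arr))$J$total
  interior <- 2:499
  err <- max(abs(J[interior, 1] - om * cos(om * tt[interior])))
  expect_lt(err, 1.01 * om^3 * dt^2 / 6)
})

test_that("FFT correlation estimators equal the naive double loop", {
  set.seed(10)
  for (n in c(37, 200)) {
    x <- matrix(rnorm(n * 3), n, 3)
    y <- matrix(rnorm(n * 3), n, 3)
    max_lag <- floor(n / 2) - 1
    cf <- autocorrelation(x, dt = 0.01)
    expect_equal(cf$value, naive_xcorr(x, x, max_lag), tolerance = 1e-10)
    cc <- crosscorrelation(x, y, dt = 0.01)
    expect_equal(cc$value, naive_xcorr(x, y, max_lag), tolerance = 1e-10)
  }
})

test_that("autocorrelation reproduces known statistical structure", {
  # deterministic constant vector: flat correlation |c|^2
  cst <- matrix(rep(c(1, -2, 3), each = 300), 300, 3)
  cf <- autocorrelation(cst, dt = 0.1)
  expect_equal(cf$value, rep(14, length(cf$lag)), tolerance = 1e-12)
  # white noise: lag0 ~ 3 sigma^2, others ~ 0, within 5 standard errors
  set.seed(77)
  n <- 6000; sig <- 1.3
  w <- matrix(rnorm(n * 3, sd = sig), n, 3)
  cf <- autocorrelation(w, dt = 0.1)
  expect_lt(abs(cf$value[1] - 3 * sig^2), 5 * sig^2 * sqrt(2 / (3 * n)))
  se_k <- sig^2 * sqrt(3 / (n - seq_along(cf$value) + 1))
  expect_true(all(abs(cf$value[-1]) < 5 * se_k[-1]))
  # lag 0 of an autocorrelation is never negative
  expect_gte(cf$value[1], 0)
})

test_that("self + cross equals total, and the cross term matches the
           explicit double sum", {
  s <- random_series(60, 3, 5, walk = TRUE)
  sp <- self_cross_split(s, via = "currents")
  expect_equal(sp$self$value + sp$cross$value, sp$total$value,
               tolerance = 1e-9 * max(abs(sp$total$value)))
  # oracle: explicit pair double sum on the interior currents
  mol <- s$perm + s$induced
  j <- thzwater:::.time_derivative(mol, s$dt)[2:59, , , drop = FALSE]
  expect_equal(sp$cross$value,
               naive_cross_sum(j, length(sp$cross$value) - 1),
               tolerance = 1e-9 * max(abs(sp$total$value)))
  # moments route obeys the same closure
  spm <- self_cross_split(s, via = "moments")
  expect_equal(spm$self$value + spm$cross$value, spm$total$value,
               tolerance = 1e-9 * max(abs(spm$total$value)))
})

test_that("self/cross split degenerate and antisymmetric cases", {
  # N = 1: cross is exactly zero
  s1 <- random_series(40, 1, 2)
  sp1 <- self_cross_split(s1)
  expect_equal(max(abs(sp1$cross$value)), 0, tolerance = 1e-12)
  # two molecules with mu2 = -mu1: total vanishes, cross = -self
  set.seed(3)
  a <- array(rnorm(80 * 1 * 3), c(80, 1, 3))
  perm <- array(0, c(80, 2, 3)); perm[, 1, ] <- a[, 1, ]
  perm[, 2, ] <- -a[, 1, ]
  s2 <- dipole_series((0:79) * 0.01, perm)
  sp2 <- self_cross_split(s2)
  expect_equal(max(abs(sp2$total$value)), 0,
               tolerance = 1e-12 * max(abs(sp2$self$value)))
  expect_equal(sp2$cross$value, -sp2$self$value,
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("cross terms of dynamically independent molecules vanish
           statistically", {
  p <- librator_params(n_molecules = 50, n_frames = 4096, seed = 19)
  sim <- generate_librator(p)
  sp <- self_cross_split(sim$dipoles, max_lag_fraction = 0.1)
  # the self term carries the signal; cross fluctuates about zero
  expect_lt(max(abs(sp$cross$value)), 0.2 * sp$self$value[1])
  expect_gt(sp$self$value[1], 0)
})

test_that("permanent/induced split closes and swaps symmetrically", {
  s <- random_series(80, 4, 11)
  cs <- collective_moment(s)
  sp <- perm_ind_split(cs)
  expect_equal(sp$perm$value + sp$ind$value, sp$total$value,
               tolerance = 1e-9 * max(abs(sp$total$value)))
  # swapping the channel labels swaps the outputs
  s_sw <- dipole_series(s$times, s$induced, s$perm)
  sp_sw <- perm_ind_split(collective_moment(s_sw))
  expect_equal(sp_sw$perm$value, sp$ind$value, tolerance = 1e-10)
  expect_equal(sp_sw$ind$value, sp$perm$value, tolerance = 1e-10)
  # zero induced channel: C_perm = C_total, with a warning
  s0 <- dipole_series(s$times, s$perm)
  expect_warning(sp0 <- perm_ind_split(collective_moment(s0)),
                 "induced channel is zero")
  expect_equal(sp0$perm$value, sp0$total$value, tolerance = 1e-12)
  expect_equal(max(abs(sp0$ind$value)), 0)
})

test_that("Phi(0) equals the frame average of |M_D|^2", {
  s <- random_series(300, 5, 23)
  cs <- collective_moment(s)
  phi <- autocorrelation(cs$M$total, dt = s$dt)
  expect_equal(phi$value[1], mean(rowSums(cs$M$total^2)), tolerance = 1e-10)
})

test_that("correlation functions round-trip through two-column text", {
  cf <- corrfun((0:50) * 0.01, exp(-(0:50) * 0.05))
  path <- tempfile(fileext = ".dat")
  write_corrfun(cf, path, meta = c(channel = "total"))
  back <- read_corrfun(path)
  expect_equal(back$lag, cf$lag, tolerance = 1e-9)
  expect_equal(back$value, cf$value, tolerance = 1e-9)
})
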