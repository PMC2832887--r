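# Eigendecomposition, autocorrelation, power spectra, coherence,
# eigenvalue trajectories and population relaxation.

test_that("decomposition recovers known spectra and reconstructs M", {
  dec <- decompose_generator(matrix(c(-1, 1, 3, -3), 2, 2))
  expect_equal(sort(Re(dec$values)), c(-4, 0), tolerance = 1e-12)
  expect_lt(dec$reconstruction_error, 1e-8)
  # biorthonormality and normalization of the stationary pair
  B <- dec$left %*% dec$right
  expect_equal(Mod(B), diag(2), tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(Re(dec$right[, 1]), c(0.75, 0.25), tolerance = 1e-10)
  expect_equal(Re(dec$left[1, ]), c(1, 1), tolerance = 1e-10)
  # irreversible 4-cycle: {0, -1+i, -2, -1-i}
  dec4 <- decompose_generator(build_generator(homogeneous_cycle_system(4, 1)))
  expect_lt(complex_set_distance(dec4$values,
                                 c(0, -1 + 1i, -2, -1 - 1i)), 1e-10)
})

test_that("closed systems have purely real relaxation spectra", {
  for (seed in 1:100) {
    N <- 2 + seed %% 2
    M <- build_generator(random_closed_system(N, seed)$system)
    dec <- decompose_generator(M)
    expect_lt(max(abs(Im(dec$values))), 1e-8 * max(abs(dec$values)))
  }
})

test_that("autocorrelation matches closed form and matrix-exponential oracle", {
  dec <- decompose_generator(matrix(c(-1, 1, 3, -3), 2, 2))
  taus <- c(0, 0.2, 1)
  expect_equal(autocorrelation(dec, c(0, 1), taus), 0.1875 * exp(-4 * taus),
               tolerance = 1e-12)
  # constant observable carries no fluctuation
  expect_equal(autocorrelation(dec, c(5, 5), taus), rep(0, 3),
               tolerance = 1e-12)
  # random systems against expm
  for (seed in 1:10) {
    sys <- random_promoter_system(1 + seed %% 3, seed)
    M <- build_generator(sys)
    d <- decompose_generator(M)
    for (tau in c(0, 2, 10)) {
      expect_equal(autocorrelation(d, sys$rho, tau),
                   expm_autocov(M, sys$rho, tau, d$pi), tolerance = 1e-8)
    }
  }
})

test_that("power spectra are nonnegative and integrate to the variance", {
  dec <- decompose_generator(matrix(c(-1, 1, 3, -3), 2, 2))
  expect_equal(power_spectrum(dec, c(0, 1), omega = 0)$value,
               2 * 4 * 0.1875 / 16, tolerance = 1e-12)
  for (seed in 1:20) {
    sys <- random_promoter_system(1 + seed %% 4, seed + 100)
    dec <- decompose_generator(build_generator(sys))
    sp <- power_spectrum(dec, sys$rho)
    expect_true(all(sp$value >= -1e-12 * max(abs(sp$value))))
    f <- promodyn:::.spectrum_fun(dec, sys$rho)
    v <- stats::integrate(f, 0, Inf, rel.tol = 1e-9,
                          subdivisions = 2000L)$value / pi
    expect_equal(v, autocorrelation(dec, sys$rho, 0), tolerance = 1e-3)
  }
})

test_that("closed systems cannot show a spectral peak above S(0)", {
  for (seed in 1:20) {
    sys <- random_closed_system(2 + seed %% 2, seed + 300)$system
    dec <- decompose_generator(build_generator(sys))
    sp <- power_spectrum(dec, sys$rho)
    s0 <- power_spectrum(dec, sys$rho, omega = 0)$value
    expect_lte(max(sp$value), s0 * (1 + 1e-8))
  }
})

test_that("coherence factor counts oscillations per decay time", {
  expect_equal(coherence_factor(-0.01 + 0.628319i), 10, tolerance = 1e-4)
  expect_equal(coherence_factor(-5), 0)
  expect_error(coherence_factor(0.1), "Re lambda")
  # slowest mode of the irreversible 22-cycle, from the closed form
  th <- 2 * pi / 22
  lam <- cycle_eigenvalues(22, 1)[2]
  expect_equal(coherence_factor(lam), sin(th) / (2 * pi * (1 - cos(th))),
               tolerance = 1e-12)
  expect_equal(coherence_factor(lam), 1.1069469, tolerance = 1e-6)
})

test_that("cycle eigenvalues lie on the analytic circle/ellipse", {
  expect_lt(complex_set_distance(cycle_eigenvalues(4, 1, 0),
                                 c(0, -1 + 1i, -2, -1 - 1i)), 1e-12)
  # symmetric cycle: real spectrum 2k(cos - 1)
  lam <- cycle_eigenvalues(6, 0.7, 0.7)
  expect_lt(max(abs(Im(lam))), 1e-12)
  expect_equal(sort(Re(lam)),
               sort(2 * 0.7 * (cos(2 * pi * (0:5) / 6) - 1)),
               tolerance = 1e-12)
  # irreversible cycle: points on |lambda + kf| = kf
  lam22 <- cycle_eigenvalues(22, 3)
  expect_equal(Mod(lam22 + 3), rep(3, 22), tolerance = 1e-12)
  # closed form agrees with the dense eigensolver on the explicit generator
  for (n in c(3, 5, 22)) for (r in c(0, 0.1, 1)) {
    kf <- 0.5; kb <- kf * r
    dec <- decompose_generator(build_generator(homogeneous_cycle_system(n, kf, kb)))
    expect_lt(complex_set_distance(dec$values, cycle_eigenvalues(n, kf, kb)),
              1e-10)
  }
})

test_that("cycle coherence grows with length and directionality", {
  zmax <- function(n, kf, kb) {
    lam <- cycle_eigenvalues(n, kf, kb)
    lam <- lam[Re(lam) < 0 & abs(Im(lam)) > 1e-14]
    if (length(lam) == 0) return(0)
    max(abs(Im(lam)) / (2 * pi * abs(Re(lam))))
  }
  z_by_n <- vapply(c(4, 8, 16, 32), zmax, numeric(1), kf = 1, kb = 0)
  expect_true(all(diff(z_by_n) > 0))
  z_by_dir <- vapply(c(1, 0.3, 0.1, 0), function(kb) zmax(12, 1, kb),
                     numeric(1))
  expect_true(all(diff(z_by_dir) > 0))
})

test_that("eigenvalue trajectories track concentration sweeps", {
  sys <- two_state_system(kon0 = 0.2, conc = 1, koff = 3)
  grid <- c(1, 2, 5, 10, 20)
  tr <- eigenvalue_trajectories(sys, "A", grid)
  nz <- tr[abs(tr$re) > 1e-12, ]
  expect_equal(nz$re, -(0.2 * grid + 3), tolerance = 1e-10)
  expect_equal(nz$im, rep(0, length(grid)))
  # conjugate-pair paths stay mutually conjugate along the sweep
  cyc_sys <- random_promoter_system(3, 11, log_rate_sd = 1.5)
  tr2 <- eigenvalue_trajectories(cyc_sys, "F1", c(0.5, 1, 2, 4))
  for (cc in unique(tr2$conc)) {
    lam <- complex(real = tr2$re[tr2$conc == cc],
                   imaginary = tr2$im[tr2$conc == cc])
    expect_lt(complex_set_distance(lam, Conj(lam)), 1e-9 * max(Mod(lam)))
  }
})

test_that("synchronized populations relax to the stationary mean", {
  M <- matrix(c(-1, 1, 3, -3), 2, 2)
  t <- c(0, 0.1, 0.5, 2)
  expect_equal(population_relaxation(M, c(0, 1), 2, t),
               0.25 + 0.75 * exp(-4 * t), tolerance = 1e-10)
  # cycle released from state 1: damped oscillation checked against expm
  cyc <- build_generator(homogeneous_cycle_system(8, 1))
  obs <- c(1, rep(0, 7))
  dec <- decompose_generator(cyc)
  for (tt in c(0.5, 4, 9)) {
    E <- as.matrix(Matrix::expm(Matrix::Matrix(unclass(cyc) * tt)))
    expect_equal(population_relaxation(dec, obs, 1, tt),
                 sum(obs * E[, 1]), tolerance = 1e-9)
  }
  expect_equal(population_relaxation(dec, obs, 1, 500), 1 / 8,
               tolerance = 1e-6)
})
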