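# Example-system builders, barrier randomization and the coherence
# optimizer.

test_that("two-state builder matches its analytic solution", {
  sys <- two_state_system(0.2, 5, 3, 0, 8)
  M <- build_generator(sys)
  expect_equal(unname(stationary_distribution(M)), c(0.75, 0.25),
               tolerance = 1e-12)
  dec <- decompose_generator(M)
  expect_lt(complex_set_distance(dec$values, c(0, -(0.2 * 5 + 3))), 1e-10)
  expect_equal(sum(stationary_distribution(M) * sys$rho), 2, tolerance = 1e-12)
  # instant unbinding pins expression at the free-state rate
  fast <- two_state_system(0.2, 5, 1e7, rho_off = 0.5, rho_on = 8)
  mx <- sum(stationary_distribution(build_generator(fast)) * fast$rho)
  expect_equal(mx, 0.5, tolerance = 1e-4)
})

test_that("gate concentration controls noise but not means", {
  lo <- gated_activator_system(1e-2)
  hi <- gated_activator_system(1e3)
  nv_lo <- normalized_variances(lo$system, lo$cascade)
  nv_hi <- normalized_variances(hi$system, hi$cascade)
  m_lo <- attr(nv_lo, "means"); m_hi <- attr(nv_hi, "means")
  # the gate rescales both B directions equally: means are [A]-independent
  expect_equal(m_hi$mean_P, m_lo$mean_P, tolerance = 1e-10)
  expect_equal(m_lo$mean_R, 30, tolerance = 1e-6)
  # but high gate concentration amplifies the noise
  expect_gt(nv_hi$cv2_P, nv_lo$cv2_P)
  expect_gt(nv_hi$cv2_R, nv_lo$cv2_R)
  # and splits the RNA distribution
  expect_equal(count_modes(rna_marginal(joint_steady_state(lo$system, lo$cascade$gamma)))$n_modes, 1)
  expect_equal(count_modes(rna_marginal(joint_steady_state(hi$system, hi$cascade$gamma)))$n_modes, 2)
  # the gate never obeys a directed cycle (closed kinetics)
  expect_false(detect_directed_cycles(build_generator(hi$system))$has_cycle)
})

test_that("promoter dynamics slow as the gate saturates", {
  sys <- gated_activator_system(1)$system
  tr <- eigenvalue_trajectories(sys, "A", 10^seq(-2, 3, length.out = 41))
  slowest <- vapply(split(tr, tr$conc), function(d) {
    lam <- abs(complex(real = d$re, imaginary = d$im))
    min(lam[lam > 1e-12])
  }, numeric(1))
  expect_lt(slowest[length(slowest)], 0.1 * slowest[1])
  expect_true(all(diff(slowest) < 1e-12))
})

test_that("noise increase at high gate concentration is robust to parameter perturbations", {
  perturb <- list(conc_B = 5, dE = 2.5, rho_B = 0.2, residence_A = 30,
                  residence_B = 60, K_A = 0.5, K_B = 5)
  for (p in names(perturb)) for (fac in c(0.5, 1.5)) {
    args <- list(); args[[p]] <- perturb[[p]] * fac
    lo <- do.call(gated_activator_system, c(list(conc_A = 1e-2), args))
    hi <- do.call(gated_activator_system, c(list(conc_A = 1e3), args))
    cv_lo <- normalized_variances(lo$system, lo$cascade,
                                  check_quadrature = FALSE)$cv2_P
    cv_hi <- normalized_variances(hi$system, hi$cascade,
                                  check_quadrature = FALSE)$cv2_P
    expect_gt(cv_hi, cv_lo)
  }
  # RNA/protein lifetimes perturbed through the cascade
  base <- gated_activator_system(1e-2)
  for (fac in c(0.5, 1.5)) {
    cas <- cascade_params(base$cascade$gamma * fac, base$cascade$beta,
                          base$cascade$gamma_p / fac)
    hi <- gated_activator_system(1e3)
    expect_gt(normalized_variances(hi$system, cas,
                                   check_quadrature = FALSE)$cv2_P,
              normalized_variances(base$system, cas,
                                   check_quadrature = FALSE)$cv2_P)
  }
})

test_that("looped promoter is energetically closed with a Boltzmann steady state", {
  lp <- looped_promoter_system(10, 10)
  expect_true(is_closed_system(lp$energetic_model))
  M <- build_generator(lp$system)
  expect_lt(energy_consumption_rate(M)$edot_kBT_s, 1e-10)
  pi <- stationary_distribution(M)
  pb <- boltzmann_distribution(lp$energetic_model,
                               c(A1 = 10, A2 = 10, C = 10, L = 1))
  expect_lt(max(abs(pi - pb)), 1e-9)
  dec <- decompose_generator(M)
  expect_lt(max(abs(Im(dec$values))), 1e-8 * max(abs(dec$values)))
})

test_that("mean RNA surface shows four Hill-like plateaus within 10-70 copies", {
  grid <- 10^seq(-2, 3, length.out = 6)
  mean_R <- outer(grid, grid, Vectorize(function(a, c) {
    lp <- looped_promoter_system(a, c)
    mean_levels(lp$system, lp$cascade)$mean_R
  }))
  expect_true(all(mean_R >= 10 & mean_R <= 70))
  # monotone staircase: decreasing in [A] (loop represses), increasing in [C]
  expect_true(all(apply(mean_R, 2, diff) < 1e-9))
  expect_true(all(apply(mean_R, 1, diff) > -1e-9))
  # four distinct corner plateaus
  corners <- c(mean_R[1, 1], mean_R[1, 6], mean_R[6, 1], mean_R[6, 6])
  expect_equal(length(unique(round(corners, 1))), 4)
  rel <- abs(outer(corners, corners, "-")) / outer(corners, corners, pmax)
  expect_true(all(rel[upper.tri(rel)] > 0.1))
  # flat in the corner neighborhoods (plateaus, not slopes)
  expect_lt(abs(mean_R[2, 1] / mean_R[1, 1] - 1), 0.05)
  expect_lt(abs(mean_R[6, 5] / mean_R[6, 6] - 1), 0.05)
})

test_that("randomizing shared barriers preserves means but reshapes noise", {
  lp <- looped_promoter_system(1, 1)
  em2 <- randomize_barriers(lp$energetic_model, sd_kcal = 3, seed = 99)
  expect_true(is_closed_system(em2))
  expect_identical(em2$G0, lp$energetic_model$G0)
  em0 <- randomize_barriers(lp$energetic_model, sd_kcal = 0, seed = 99)
  expect_equal(em0$E0, lp$energetic_model$E0)
  grid <- 10^seq(-2, 3, length.out = 3)
  rel_mean <- rel_cv2 <- 0
  for (a in grid) for (cc in grid) {
    base <- looped_promoter_system(a, cc)
    conc <- c(A1 = a, A2 = a, C = cc, L = 1)
    pert <- system_from_energies(em2, conc, base$system$rho)
    m1 <- mean_levels(base$system, base$cascade)$mean_R
    m2 <- mean_levels(pert, base$cascade)$mean_R
    rel_mean <- max(rel_mean, abs(m2 / m1 - 1))
    n1 <- suppressWarnings(normalized_variances(base$system, base$cascade,
                                                check_quadrature = FALSE))$cv2_R
    n2 <- suppressWarnings(normalized_variances(pert, base$cascade,
                                                check_quadrature = FALSE))$cv2_R
    rel_cv2 <- max(rel_cv2, abs(n2 / n1 - 1))
  }
  expect_lt(rel_mean, 1e-8)
  expect_gt(rel_cv2, 0.1)
})

test_that("random systems are reproducible and pass structural validation", {
  a <- random_promoter_system(3, 123)
  b <- random_promoter_system(3, 123)
  expect_identical(a$k0, b$k0)
  expect_identical(a$rho, b$rho)
  M <- build_generator(a)
  expect_true(attr(M, "irreducible"))
  expect_lt(max(abs(colSums(unclass(M)))), 1e-12)
})

test_that("coherence optimization never loses ground and logs dissipation", {
  sys <- random_promoter_system(3, 1, log_rate_sd = 1.5)
  tr0 <- optimize_coherence(sys, iterations = 0, seed = 1)
  expect_equal(nrow(tr0), 1)
  tr <- optimize_coherence(sys, iterations = 40, seed = 1)
  expect_true(all(diff(tr$best_coherence) >= 0))
  expect_true(all(diff(tr$objective) >= 0))
  expect_gte(tr$coherence[nrow(tr)], tr$coherence[1])
  expect_true(all(is.finite(tr$edot_kBT_s)))
  final <- attr(tr, "system")
  expect_s3_class(final, "promoter_system")
})
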