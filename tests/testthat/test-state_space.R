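# State enumeration, generator construction and the kinetic/energetic dual.

test_that("state enumeration follows bitmask order and rejects duplicates", {
  expect_equal(enumerate_states("A"), list(character(0), "A"))
  s2 <- enumerate_states(c("A", "B"))
  expect_length(s2, 4)
  expect_equal(s2[[1]], character(0))
  expect_equal(s2[[2]], "A")
  expect_equal(s2[[3]], "B")
  expect_equal(s2[[4]], c("A", "B"))
  expect_error(enumerate_states(c("A", "A")), "duplicate")
})

test_that("generator assembly weights association by concentration", {
  sys <- promoter_system("A", k0 = rbind(c(0.2, 3)),
                         concentrations = c(A = 5), rho = c(0, 8))
  M <- build_generator(sys)
  expect_equal(unclass(M), matrix(c(-1, 1, 3, -3), 2, 2),
               ignore_attr = TRUE)
  # all rates zero -> zero matrix
  z <- promoter_system(c("A", "B"), k0 = matrix(0, 2, 4),
                       concentrations = c(A = 1, B = 1), rho = rep(0, 4))
  expect_true(all(unclass(build_generator(z)) == 0))
})

test_that("every constructed generator conserves probability", {
  for (seed in 1:20) {
    N <- 1 + seed %% 4
    M <- build_generator(random_promoter_system(N, seed))
    expect_lt(max(abs(colSums(unclass(M)))), 1e-12 * max(abs(M)))
    offdiag <- unclass(M); diag(offdiag) <- 0
    expect_true(all(offdiag >= 0))
  }
})

test_that("raw generators are validated and take precedence over k0", {
  # explicit homogeneous 4-cycle
  A <- matrix(0, 4, 4)
  for (s in 1:4) A[s %% 4 + 1, s] <- 1
  diag(A) <- -1
  sys <- promoter_system(c("A", "B"), k0 = matrix(9, 2, 4),
                         concentrations = c(A = 1, B = 1),
                         rho = rep(0, 4), raw_M = A)
  M <- build_generator(sys)
  expect_equal(max(abs(colSums(unclass(M)))), 0)
  expect_equal(unclass(M)[2, 1], 1)   # k0 was ignored
  # non-conservative raw_M rejected
  B <- A; B[1, 1] <- 0
  expect_error(promoter_system(c("A", "B"), concentrations = c(A = 1, B = 1),
                               rho = rep(0, 4), raw_M = B), "sum to zero")
  expect_error(raw_system(matrix(c(0, -1, 0, 1), 2, 2), c(0, 0)),
               "nonnegative")
})

test_that("flat energy landscape gives unit rates and concentration enters only association", {
  em <- energetic_model(c("A", "B"), G0 = rep(0, 4), E0 = matrix(0, 2, 4))
  k0 <- kinetics_from_energies(em, c(A = 1, B = 1))
  expect_equal(k0, matrix(1, 2, 4))
  sys1 <- system_from_energies(em, c(A = 1, B = 1), rep(0, 4))
  sys2 <- system_from_energies(em, c(A = 2, B = 1), rep(0, 4))
  M1 <- unclass(build_generator(sys1)); M2 <- unclass(build_generator(sys2))
  # A-association edges double (states 1 and 3 lack A: targets 2 and 4)
  expect_equal(M2[2, 1], 2 * M1[2, 1])
  expect_equal(M2[4, 3], 2 * M1[4, 3])
  # A-dissociation and B edges untouched
  expect_equal(M2[1, 2], M1[1, 2])
  expect_equal(M2[3, 1], M1[3, 1])
})

test_that("closed two-state systems satisfy the equilibrium-constant identity", {
  for (seed in 1:100) {
    set.seed(seed)
    G0 <- rnorm(2, 0, 2)
    E0 <- matrix(max(G0) + runif(1, 0.5, 3), 1, 2)
    em <- energetic_model("A", G0, E0)
    k0 <- kinetics_from_energies(em, c(A = runif(1, 0.1, 10)))
    expect_equal(k0[1, 1] / k0[1, 2], exp((G0[1] - G0[2]) / em$kBT),
                 tolerance = 1e-12)
  }
})

test_that("prefactor rescales time but not the stationary law", {
  rcs <- random_closed_system(3, 42)
  em2 <- rcs$em; em2$prefactor <- 2
  M1 <- build_generator(system_from_energies(rcs$em, rcs$conc, rcs$system$rho))
  M2 <- build_generator(system_from_energies(em2, rcs$conc, rcs$system$rho))
  expect_equal(unclass(M2), 2 * unclass(M1), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(stationary_distribution(M1), stationary_distribution(M2),
               tolerance = 1e-9)
})

test_that("barrier symmetry defines closedness", {
  rcs <- random_closed_system(2, 7)
  expect_true(is_closed_system(rcs$em))
  em2 <- rcs$em
  em2$E0[1, 2] <- em2$E0[1, 2] + 2   # one direction only
  expect_false(is_closed_system(em2))
})

test_that("Kolmogorov criterion detects directed cycles", {
  # a single reversible edge cannot break detailed balance
  two <- as_generator(matrix(c(-1, 1, 3, -3), 2, 2))
  expect_false(detect_directed_cycles(two)$has_cycle)
  # driven 3-cycle: forward 2, backward 1 -> product ratio 8
  cyc <- build_generator(homogeneous_cycle_system(3, 2, 1))
  res <- detect_directed_cycles(cyc)
  expect_true(res$has_cycle)
  expect_equal(abs(res$log_ratio), log(8), tolerance = 1e-12)
  expect_length(res$witness, 3)
  # closed energetic systems never contain directed cycles
  for (seed in 1:100) {
    N <- 2 + seed %% 2
    M <- build_generator(random_closed_system(N, seed)$system)
    expect_false(detect_directed_cycles(M)$has_cycle)
  }
})

test_that("stationary distributions solve the balance equations", {
  pi2 <- stationary_distribution(matrix(c(-1, 1, 3, -3), 2, 2))
  expect_equal(unname(pi2), c(0.75, 0.25), tolerance = 1e-12)
  # uniform irreversible cycle is uniform
  pin <- stationary_distribution(build_generator(homogeneous_cycle_system(7, 0.3)))
  expect_equal(unname(pin), rep(1 / 7, 7), tolerance = 1e-10)
  # reducible chain is refused with a diagnostic
  D <- matrix(0, 2, 2)
  expect_error(stationary_distribution(D), "reducible")
})

test_that("closed systems relax to the Boltzmann distribution", {
  worst <- 0
  for (seed in 1:100) {
    N <- 2 + seed %% 2
    rcs <- random_closed_system(N, seed)
    pi <- stationary_distribution(build_generator(rcs$system))
    pb <- boltzmann_distribution(rcs$em, rcs$conc)
    worst <- max(worst, max(abs(pi - pb) / pb))
  }
  expect_lt(worst, 1e-8)
})
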