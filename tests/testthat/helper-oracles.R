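# Independent oracles and small utilities shared across the test files.

# stationary covariance of an observable at lag tau via the matrix
# exponential (Matrix::expm), independent of the eigendecomposition path
expm_autocov <- function(M, obs, tau, pi = NULL) {
  M <- unclass(M)
  if (is.null(pi)) pi <- stationary_distribution(M)
  E <- as.matrix(Matrix::expm(Matrix::Matrix(M * tau)))
  mu <- sum(pi * obs)
  sum(obs * (E %*% (pi * obs))) - mu^2
}

# greedy matching of two complex sets; returns max matched distance
complex_set_distance <- function(a, b) {
  stopifnot(length(a) == length(b))
  d <- 0
  b <- as.complex(b)
  for (x in a) {
    k <- which.min(Mod(b - x))
    d <- max(d, Mod(b[k] - x))
    b <- b[-k]
  }
  d
}

total_variation <- function(p, q) {
  n <- max(length(p), length(q))
  p <- c(p, rep(0, n - length(p)))
  q <- c(q, rep(0, n - length(q)))
  0.5 * sum(abs(p - q))
}

# empirical pmf of sampled integer copy numbers
empirical_pmf <- function(x, rmax = max(x)) {
  tabulate(x + 1L, nbins = rmax + 1L) / length(x)
}

# random closed system assembled from a random energetic model
random_closed_system <- function(N, seed) {
  em <- random_energetic_model(N, seed, closed = TRUE)
  set.seed(seed + 10000L)
  conc <- stats::runif(N, 0.5, 2)
  names(conc) <- em$tf_names
  rho <- stats::runif(2^N, 0, 0.2)
  list(em = em, conc = conc,
       system = system_from_energies(em, conc, rho))
}
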