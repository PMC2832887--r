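# Spectral analysis of the promoter generator: eigendecomposition,
# autocorrelation and modal power spectra of any promoter observable,
# coherence of oscillatory modes, eigenvalue trajectories along
# concentration sweeps, and relaxation of a synchronized population.

#' Eigendecomposition of a promoter generator
#'
#' Diagonalizes `M` into eigenvalues `lambda_i` and biorthonormal
#' right/left eigenvectors (`L_i . R_j = delta_ij`). Eigenvalues are sorted
#' by `|Re lambda|` ascending so the stationary mode comes first; its right
#' vector is normalized to the stationary distribution `pi` and its left
#' vector to the all-ones vector. All other modes have `Re lambda < 0` and
#' decay; complex pairs correspond to stochastic oscillations at angular
#' frequency `|Im lambda|`.
#'
#' @param M Generator matrix (coerced with [as_generator()]).
#' @param tol Relative tolerance used to identify the zero eigenvalue.
#' @return An object of class `spectral_decomposition` with elements
#'   `values` (complex eigenvalues), `right` and `left` (complex matrices,
#'   modes in columns resp. rows), `pi`, `reconstruction_error` and
#'   `ill_conditioned` (TRUE when the eigenvector basis has condition
#'   number above 1e8 and mode coefficients are unreliable).
#' @export
decompose_generator <- function(M, tol = 1e-9) {
  M <- as_generator(M)
  ns <- nrow(M)
  A <- unclass(M)
  e <- eigen(A)
  V <- e$vectors
  if (!is.complex(V)) { V <- V + 0i }
  sv <- svd(V, nu = 0, nv = 0)$d
  kappa <- max(sv) / max(min(sv), .Machine$double.xmin)
  ill <- !is.finite(kappa) || kappa > 1e8
  if (ill)
    warning("eigenvector basis is ill-conditioned (condition ~ ",
            signif(kappa, 2), "); mode coefficients may be unreliable")
  W <- solve(V)                         # rows are left eigenvectors
  scale <- max(abs(e$values), 1)
  ord <- order(abs(Re(e$values)), abs(Im(e$values)))
  lam <- e$values[ord]; V <- V[, ord, drop = FALSE]; W <- W[ord, , drop = FALSE]
  nzero <- sum(abs(lam) < tol * scale)
  if (nzero != 1)
    warning(nzero, " near-zero eigenvalues found (irreducible chains have exactly one)")
  lam[1] <- 0 + 0i
  # normalize the stationary mode: R_0 = pi, L_0 = 1
  s0 <- sum(V[, 1])
  V[, 1] <- V[, 1] / s0
  W[1, ] <- W[1, ] * s0
  pi <- Re(V[, 1])
  pi <- pmax(pi, 0); pi <- pi / sum(pi)
  recon <- V %*% (lam * W)
  rerr <- max(abs(recon - A)) / max(abs(A), .Machine$double.eps)
  structure(list(values = lam, right = V, left = W, pi = pi,
                 reconstruction_error = rerr, ill_conditioned = ill,
                 M = A),
            class = "spectral_decomposition")
}

#' @export
print.spectral_decomposition <- function(x, ...) {
  cat("Spectral decomposition:", length(x$values), "modes\n")
  nz <- x$values[-1]
  cat("  slowest relaxation: ", signif(-1 / max(Re(nz)), 4), " s; ",
      sum(Im(nz) > 0), " oscillatory pair(s)\n", sep = "")
  if (x$ill_conditioned) cat("  WARNING: ill-conditioned eigenbasis\n")
  invisible(x)
}

# mode coefficients c_i = (obs . R_i) * (L_i . (pi * obs)), i >= 2;
# sum_i c_i = Var(obs) under pi
.mode_coefficients <- function(dec, observable) {
  obs <- as.numeric(observable)
  if (length(obs) != length(dec$pi))
    stop("observable must have one value per promoter state")
  as.vector(obs %*% dec$right) * as.vector(dec$left %*% (dec$pi * obs))
}

#' Stationary autocorrelation of a promoter observable
#'
#' For an observable taking value `obs[s]` in state `s` (e.g. the
#' transcription rates `rho`, or a 0/1 occupancy indicator), the
#' covariance function is a sum of decaying (possibly oscillating)
#' exponentials over the non-stationary modes:
#' `C(tau) = sum_i c_i exp(lambda_i tau)`, with
#' `C(0) = Var(obs)` under the stationary law.
#'
#' @param dec A [decompose_generator()] result.
#' @param observable Numeric vector of length `2^N`.
#' @param tau Nonnegative lag grid (s).
#' @return Numeric vector `C(tau)`.
#' @export
autocorrelation <- function(dec, observable, tau) {
  stopifnot(inherits(dec, "spectral_decomposition"))
  if (any(tau < 0)) stop("lags must be nonnegative")
  cc <- .mode_coefficients(dec, observable)[-1]
  lam <- dec$values[-1]
  out <- vapply(tau, function(t) sum(cc * exp(lam * t)), complex(1))
  if (length(cc) > 0) {
    scale <- max(sum(abs(cc)), .Machine$double.eps)
    if (max(abs(Im(out))) > 1e-8 * scale)
      warning("imaginary residue ", signif(max(abs(Im(out))) / scale, 3),
              " in autocorrelation (conjugate modes should cancel)")
  }
  Re(out)
}

#' Default angular-frequency grid for spectra
#'
#' 400 log-spaced points from two decades below the slowest nonzero
#' relaxation rate to two decades above the fastest eigenvalue.
#'
#' @param dec A `spectral_decomposition`.
#' @param n Number of grid points.
#' @return Numeric vector of angular frequencies (rad/s).
#' @export
default_omega_grid <- function(dec, n = 400) {
  lam <- dec$values[-1]
  if (length(lam) == 0 || all(abs(lam) == 0)) return(10^seq(-3, 1, length.out = n))
  lo <- 1e-2 * min(abs(Re(lam[abs(Re(lam)) > 0])))
  hi <- 1e2 * max(abs(lam))
  exp(seq(log(lo), log(hi), length.out = n))
}

# closed-form two-sided spectral density as a function of omega
.spectrum_fun <- function(dec, observable) {
  cc <- .mode_coefficients(dec, observable)[-1]
  lam <- dec$values[-1]
  function(omega) {
    vapply(omega, function(w)
      Re(sum(cc * (1 / (-lam + 1i * w) + 1 / (-lam - 1i * w)))), numeric(1))
  }
}

#' Modal power spectrum of a promoter observable
#'
#' Fourier transform of the stationary autocovariance: a sum of `2^N - 1`
#' elementary modes. A real eigenvalue `lambda` contributes a Lorentzian of
#' half-width `-lambda`; a conjugate pair contributes a peak near
#' `omega = |Im lambda|`. The two-sided convention is used, so
#' `integral S(omega) domega / 2pi = Var(obs)`; only `omega >= 0` is stored.
#'
#' @inheritParams autocorrelation
#' @param omega Angular-frequency grid (rad/s); defaults to
#'   [default_omega_grid()].
#' @return A `spectrum` object: data.frame with columns `omega` and `value`
#'   (units observable^2 s).
#' @export
power_spectrum <- function(dec, observable, omega = NULL) {
  stopifnot(inherits(dec, "spectral_decomposition"))
  if (is.null(omega)) omega <- default_omega_grid(dec)
  if (any(omega < 0)) stop("omega grid must be nonnegative")
  v <- .spectrum_fun(dec, observable)(omega)
  mx <- max(abs(v), .Machine$double.eps)
  v[v < 0 & v > -1e-12 * mx] <- 0
  new_spectrum(omega, v)
}

#' Construct a spectrum object
#' @param omega Nonnegative angular frequencies (rad/s).
#' @param value Spectral density values (observable^2 s), two-sided
#'   convention stored on the half-line.
#' @return A data.frame of class `spectrum`.
#' @export
new_spectrum <- function(omega, value) {
  structure(data.frame(omega = as.numeric(omega), value = as.numeric(value)),
            class = c("spectrum", "data.frame"))
}

#' Coherence factor of an eigenvalue
#'
#' `Z = |Im lambda| / (2 pi |Re lambda|)`: the oscillation frequency times
#' the decay time, i.e. roughly the number of oscillations a synchronized
#' population completes before desynchronizing. Real eigenvalues have
#' `Z = 0` (aperiodic relaxation).
#'
#' @param lambda Complex eigenvalue(s) with negative real part.
#' @return Nonnegative numeric.
#' @export
coherence_factor <- function(lambda) {
  if (any(Re(lambda) >= 0)) stop("coherence is defined for decaying modes (Re lambda < 0)")
  abs(Im(lambda)) / (2 * pi * abs(Re(lambda)))
}

#' Eigenvalues of a homogeneous directed cycle
#'
#' Closed form for the `n`-state cycle with uniform forward rate `kf` and
#' backward rate `kb`:
#' `lambda_j = kf (e^{2 pi i j / n} - 1) + kb (e^{-2 pi i j / n} - 1)`.
#' For `kb = 0` the spectrum is `n` points regularly spaced on the circle of
#' radius `kf` tangent to the imaginary axis at 0; increasing `kb` flattens
#' it into an ellipse toward the real axis (less coherent oscillation).
#'
#' @param n Number of cycle states (>= 2).
#' @param kf Forward rate (> 0, per s).
#' @param kb Backward rate (>= 0, per s).
#' @return Complex vector of length `n` (j = 0 .. n-1).
#' @export
cycle_eigenvalues <- function(n, kf, kb = 0) {
  if (n < 2) stop("a cycle needs at least 2 states")
  if (kf <= 0 || kb < 0) stop("rates must satisfy kf > 0, kb >= 0")
  j <- seq_len(n) - 1
  w <- exp(2i * pi * j / n)
  kf * (w - 1) + kb * (Conj(w) - 1)
}

#' Eigenvalue trajectories along a concentration sweep
#'
#' Rebuilds and decomposes the generator at each concentration of one TF
#' and tracks individual eigenvalues across the sweep by greedy
#' nearest-neighbor matching in the complex plane (a heuristic: paths may
#' swap labels at genuine crossings; large matching distances are flagged).
#'
#' @param system A [promoter_system()] built from `k0` (not `raw_M`).
#' @param tf Label of the factor to sweep.
#' @param conc_grid Increasing positive concentrations (nM).
#' @return A data.frame with columns `conc`, `path`, `re`, `im`,
#'   `coherence`, `frequency_hz`, plus attribute `ambiguity` (max matching
#'   distance relative to eigenvalue scale).
#' @export
eigenvalue_trajectories <- function(system, tf, conc_grid) {
  stopifnot(inherits(system, "promoter_system"))
  if (!is.null(system$raw_M)) stop("sweeps need a kinetic (k0) system")
  if (!(tf %in% system$tf_names)) stop("unknown TF: ", tf)
  if (any(diff(conc_grid) <= 0) || any(conc_grid <= 0))
    stop("conc_grid must be positive and strictly increasing")
  ns <- 2^length(system$tf_names)
  prev <- NULL
  ambiguity <- 0
  rows <- vector("list", length(conc_grid))
  for (k in seq_along(conc_grid)) {
    sys_k <- system
    sys_k$concentrations[tf] <- conc_grid[k]
    dec <- decompose_generator(build_generator(sys_k))
    lam <- dec$values
    if (is.null(prev)) {
      ordk <- seq_len(ns)
    } else {
      ordk <- .match_eigs(prev, lam)
      d <- abs(lam[ordk] - prev)
      ambiguity <- max(ambiguity, max(d) / max(abs(lam), .Machine$double.eps))
    }
    lam <- lam[ordk]
    prev <- lam
    z <- ifelse(Re(lam) < 0, abs(Im(lam)) / (2 * pi * abs(Re(lam))), 0)
    rows[[k]] <- data.frame(conc = conc_grid[k], path = seq_len(ns),
                            re = Re(lam), im = Im(lam), coherence = z,
                            frequency_hz = abs(Im(lam)) / (2 * pi))
  }
  out <- do.call(rbind, rows)
  if (ambiguity > 0.5)
    warning("eigenvalue matching is ambiguous (relative jump ",
            signif(ambiguity, 2), "); refine the grid")
  attr(out, "ambiguity") <- ambiguity
  out
}

# greedy assignment: sort all pairwise distances, take compatible pairs
.match_eigs <- function(prev, cur) {
  n <- length(prev)
  d <- outer(prev, cur, function(a, b) abs(a - b))
  ord <- order(d)
  asg <- integer(n); used_p <- logical(n); used_c <- logical(n)
  for (k in ord) {
    i <- (k - 1) %% n + 1
    j <- (k - 1) %/% n + 1
    if (!used_p[i] && !used_c[j]) {
      asg[i] <- j; used_p[i] <- TRUE; used_c[j] <- TRUE
      if (all(used_p)) break
    }
  }
  asg
}

#' Relaxation of a synchronized promoter population
#'
#' Expected observable at time `t` for a population started synchronously
#' in one state: `obs . exp(M t) . delta_s0`, evaluated through the
#' spectral decomposition. Mirrors population-average measurements (e.g.
#' ChIP time courses after synchronized induction): damped oscillations
#' reflect desynchronization of individually cycling promoters. Converges
#' to the stationary mean.
#'
#' @param dec A `spectral_decomposition` (or generator matrix).
#' @param observable Numeric vector of length `2^N`.
#' @param initial_state State index (1-based).
#' @param t Nonnegative time grid (s).
#' @return Numeric vector of expected values.
#' @export
population_relaxation <- function(dec, observable, initial_state, t) {
  if (!inherits(dec, "spectral_decomposition"))
    dec <- decompose_generator(dec)
  ns <- length(dec$pi)
  if (initial_state < 1 || initial_state > ns) stop("invalid initial state")
  obs <- as.numeric(observable)
  if (length(obs) != ns) stop("observable must have one value per state")
  a <- as.vector(obs %*% dec$right) * dec$left[, initial_state]
  out <- vapply(t, function(tt) sum(a * exp(dec$values * tt)), complex(1))
  Re(out)
}
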