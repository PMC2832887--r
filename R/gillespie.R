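# Exact stochastic simulation (direct-method Gillespie) of the full
# promoter + RNA + protein system. Serves as the independent oracle for
# the analytic spectra, variances and distributions.

#' Simulate a full trajectory
#'
#' Exact direct-method simulation of the coupled system: promoter
#' transitions from the generator, RNA birth at the state rate `rho_s` and
#' death at `gamma R`, protein birth at `beta R` and death at `gamma_p P`.
#' Identical seeds give bitwise-identical trajectories.
#'
#' @param system A [promoter_system()].
#' @param cascade A [cascade_params()], or `NULL` to simulate the promoter
#'   alone.
#' @param duration Total simulated time (s).
#' @param seed Integer seed.
#' @param burn_in Time discarded at the start (s); must be `< duration`.
#' @param init Optional list with `state` (1-based), `R`, `P`; defaults to
#'   state 1 with copy numbers at their deterministic means.
#' @param max_events Guard against runaway simulations.
#' @return An object of class `ssa_trajectory`: event times and the
#'   piecewise-constant state/RNA/protein paths after each event, plus the
#'   initial condition, seed and duration.
#' @export
simulate_trajectory <- function(system, cascade, duration, seed,
                                burn_in = 0, init = NULL, max_events = 2e8) {
  res <- .run_ssa(system, cascade, duration, seed, burn_in, dt = 0,
                  record_events = TRUE, init = init, max_events = max_events)
  structure(list(time = res$raw$event_t, state = res$raw$event_state + 1L,
                 R = res$raw$event_R, P = res$raw$event_P,
                 init = res$init, seed = seed, duration = duration,
                 burn_in = burn_in, n_events = res$raw$n_events),
            class = "ssa_trajectory")
}

#' Simulate and sample on a regular grid
#'
#' Runs the same exact simulation but records only left-continuous samples
#' every `dt` seconds, keeping memory bounded for long oracle runs.
#'
#' @inheritParams simulate_trajectory
#' @param dt Sampling interval (s).
#' @param promoter_only Skip RNA/protein reactions (promoter path only).
#' @return A data.frame with columns `t`, `state` (1-based), `R`, `P` and
#'   attributes `seed`, `dt`.
#' @export
simulate_sampled <- function(system, cascade, duration, dt, seed,
                             burn_in = 0, promoter_only = is.null(cascade),
                             init = NULL, max_events = 2e8) {
  if (dt <= 0) stop("dt must be positive")
  res <- .run_ssa(system, cascade, duration, seed, burn_in, dt = dt,
                  record_events = FALSE, promoter_only = promoter_only,
                  init = init, max_events = max_events)
  n <- length(res$raw$sample_state)
  out <- data.frame(t = burn_in + (seq_len(n) - 1) * dt,
                    state = res$raw$sample_state + 1L,
                    R = res$raw$sample_R, P = res$raw$sample_P)
  attr(out, "seed") <- seed; attr(out, "dt") <- dt
  out
}

.run_ssa <- function(system, cascade, duration, seed, burn_in, dt,
                     record_events, promoter_only = is.null(cascade),
                     init = NULL, max_events = 2e8) {
  stopifnot(inherits(system, "promoter_system"))
  if (duration <= burn_in || burn_in < 0)
    stop("need duration > burn_in >= 0")
  M <- build_generator(system)
  if (is.null(cascade)) {
    gamma <- 1; beta <- 0; gamma_p <- 1
    promoter_only <- TRUE
  } else {
    stopifnot(inherits(cascade, "cascade_params"))
    gamma <- cascade$gamma; beta <- cascade$beta; gamma_p <- cascade$gamma_p
  }
  if (is.null(init)) {
    pi <- stationary_distribution(M)
    mx <- sum(pi * system$rho)
    init <- list(state = 1L, R = round(mx / gamma),
                 P = round(beta * mx / (gamma * gamma_p)))
  }
  if (promoter_only) init$R <- init$P <- 0
  set.seed(as.integer(seed))
  raw <- .ssa_cpp(unclass(M), system$rho, gamma, beta, gamma_p,
                  duration, burn_in, dt, record_events, promoter_only,
                  as.integer(init$state) - 1L, init$R, init$P, max_events)
  list(raw = raw, init = init)
}

#' @export
print.ssa_trajectory <- function(x, ...) {
  cat("SSA trajectory:", format(x$n_events, big.mark = ","), "events over",
      x$duration, "s (seed", x$seed, ")\n")
  invisible(x)
}

#' Sample a trajectory on a regular grid
#'
#' Left-continuous sampling of the piecewise-constant paths: the value at a
#' grid time is the value just before/at that time.
#'
#' @param traj An [simulate_trajectory()] result.
#' @param dt Sampling interval (s).
#' @return A data.frame with columns `t`, `state`, `R`, `P`.
#' @export
sampled_series <- function(traj, dt) {
  stopifnot(inherits(traj, "ssa_trajectory"))
  if (dt <= 0) stop("dt must be positive")
  tgrid <- seq(traj$burn_in, traj$duration, by = dt)
  # index of the last event at or before each grid time; 0 = initial condition
  k <- findInterval(tgrid + 1e-12, traj$time)
  state <- c(traj$init$state, traj$state)[k + 1L]
  R <- c(traj$init$R, traj$R)[k + 1L]
  P <- c(traj$init$P, traj$P)[k + 1L]
  data.frame(t = tgrid, state = state, R = R, P = P)
}

#' Welch-averaged periodogram
#'
#' Power spectral density estimate matching the two-sided analytic
#' convention (`integral S domega / 2 pi = Var`): the series is split into
#' overlapping Hann-windowed segments whose scaled periodograms are
#' averaged; only `omega >= 0` is returned.
#'
#' @param x Numeric series sampled every `dt` seconds.
#' @param dt Sampling interval (s).
#' @param segments Number of Welch segments (default 16).
#' @param overlap Fractional overlap between segments (default 0.5).
#' @return A `spectrum` (omega in rad/s) with attribute `n_segments`.
#' @export
periodogram <- function(x, dt, segments = 16, overlap = 0.5) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 16) stop("series too short")
  L <- floor(n / (1 + (segments - 1) * (1 - overlap)))
  L <- .smooth_length(L)   # keep the FFT on fast (2,3,5-smooth) lengths
  step <- max(1, floor(L * (1 - overlap)))
  starts <- seq(1, n - L + 1, by = step)
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(L) - 1) / (L - 1)))  # Hann
  U <- mean(w^2)
  acc <- numeric(L)
  for (s0 in starts) {
    seg <- x[s0:(s0 + L - 1)]
    seg <- (seg - mean(seg)) * w
    acc <- acc + Mod(stats::fft(seg))^2
  }
  S <- dt * acc / (L * U * length(starts))
  half <- seq_len(floor(L / 2))
  omega <- 2 * pi * (half - 1) / (L * dt)
  structure(new_spectrum(omega, S[half]), n_segments = length(starts))
}

# largest integer <= n whose prime factors are all in {2, 3, 5}
.smooth_length <- function(n) {
  for (m in n:2) {
    k <- m
    for (p in c(2, 3, 5)) while (k %% p == 0) k <- k / p
    if (k == 1) return(m)
  }
  n
}

#' Log-binned average of a spectrum
#'
#' Averages spectral values in logarithmically spaced frequency bins;
#' useful for comparing a noisy periodogram with an analytic spectrum.
#'
#' @param spec A `spectrum`.
#' @param omega_min,omega_max Band limits (rad/s).
#' @param bins Number of log bins.
#' @return A data.frame with `omega` (bin geometric center), `value`
#'   (mean in bin) and `n` (points per bin); empty bins dropped.
#' @export
bin_spectrum <- function(spec, omega_min, omega_max, bins = 12) {
  stopifnot(inherits(spec, "spectrum"))
  edges <- exp(seq(log(omega_min), log(omega_max), length.out = bins + 1))
  idx <- findInterval(spec$omega, edges, rightmost.closed = TRUE)
  keep <- idx >= 1 & idx <= bins
  agg <- tapply(spec$value[keep], idx[keep], mean)
  cnt <- tapply(spec$value[keep], idx[keep], length)
  b <- as.integer(names(agg))
  data.frame(omega = sqrt(edges[b] * edges[b + 1]),
             value = as.numeric(agg), n = as.integer(cnt))
}
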