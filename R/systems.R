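# Ready-made example systems, random-system generators and a stochastic
# coherence optimizer.
#
# The two worked regulatory systems mirror experimentally grounded
# scenarios from the quantitative literature on bacterial regulation:
# (i) a minimal two-TF promoter in which one factor only gates the
# binding kinetics of the transcription-controlling factor, producing
# *more* expression noise at *higher* gate concentration; and (ii) a
# prokaryotic-like promoter with cooperative double binding, competitive
# binding and DNA looping, specified entirely by state free energies and
# shared activation barriers (an energetically closed system).

#' Two-state promoter
#'
#' Single factor A; analytic eigenvalues are `{0, -(kon0 conc + koff)}`.
#'
#' @param kon0 Association constant (per nM per s).
#' @param conc Concentration of A (nM).
#' @param koff Dissociation rate (per s).
#' @param rho_off,rho_on Transcription rates of the free and bound states.
#' @return A [promoter_system()].
#' @export
two_state_system <- function(kon0 = 0.2, conc = 5, koff = 3,
                             rho_off = 0, rho_on = 8) {
  promoter_system("A", k0 = rbind(c(kon0, koff)),
                  concentrations = c(A = conc), rho = c(rho_off, rho_on))
}

#' Homogeneous directed reaction cycle
#'
#' `n` states connected in a ring with uniform forward rate `kf` and
#' backward rate `kb`. The idealized model of sequential recruitment:
#' its generator spectrum is the circle/ellipse given by
#' [cycle_eigenvalues()], and for `kb << kf` the promoter progresses
#' around the cycle as a strongly coherent stochastic clock.
#'
#' @param n Number of states (>= 3).
#' @param kf Forward rate (per s).
#' @param kb Backward rate (per s).
#' @param rho Per-state transcription rates; default: active in state 1
#'   only.
#' @return A `promoter_system` built on a raw generator.
#' @export
homogeneous_cycle_system <- function(n, kf, kb = 0,
                                     rho = c(1, rep(0, n - 1))) {
  if (n < 3) stop("need at least 3 states")
  M <- matrix(0, n, n)
  for (s in seq_len(n)) {
    M[s %% n + 1L, s] <- kf                      # forward s -> s+1
    M[(s - 2L) %% n + 1L, s] <- M[(s - 2L) %% n + 1L, s] + kb  # backward
  }
  diag(M) <- -colSums(M)
  raw_system(M, rho, state_names = paste0("c", seq_len(n)))
}

#' Minimal system with noise induced by high TF concentration
#'
#' Two factors: B controls transcription (rate `rho_B` when bound), while
#' the gate A does not touch transcription at all -- its only effect is to
#' slow both association and dissociation of B by the Arrhenius factor
#' `exp(-dE/kBT)` while bound. Parameters follow quantitative bacterial
#' measurements: residence times 30 s (A) and 60 s (B), equilibrium
#' constants `K_A = 0.5` nM and `K_B = 5` nM, `[B] = 5` nM, barrier shift
#' `dE = 2.5` kcal/mol, RNA lifetime 5 min, protein lifetime 20 min.
#' Because the gate rescales both directions equally, the stationary law --
#' hence every mean level -- is independent of `[A]`; but at high `[A]`
#' the B-switching slows far below the RNA lifetime and expression noise
#' grows, splitting the RNA distribution into two modes.
#'
#' @param conc_A Gate concentration (nM), typically swept over
#'   `[1e-2, 1e3]`.
#' @param conc_B Activator concentration (nM).
#' @param dE Barrier shift applied to B's kinetics when A is bound
#'   (kcal/mol).
#' @param rho_B Transcription rate of B-bound states (per s); the default
#'   0.2 puts the mean RNA level near 30 copies.
#' @param residence_A,residence_B Residence times `1/koff` (s).
#' @param K_A,K_B Equilibrium dissociation constants (nM).
#' @param temperature Kelvin.
#' @return List with `system` (a [promoter_system()]) and `cascade`
#'   (a [cascade_params()]).
#' @export
gated_activator_system <- function(conc_A, conc_B = 5, dE = 2.5,
                                   rho_B = 0.2, residence_A = 30,
                                   residence_B = 60, K_A = 0.5, K_B = 5,
                                   temperature = 298.15) {
  kBT <- .kB * temperature
  eps <- exp(-dE / kBT)
  koff_A <- 1 / residence_A; kon_A <- koff_A / K_A
  koff_B <- 1 / residence_B; kon_B <- koff_B / K_B
  # states (A = bit 1, B = bit 2): 0, A, B, AB
  k0 <- rbind(
    A = c(kon_A, koff_A, kon_A, koff_A),
    B = c(kon_B, kon_B * eps, koff_B, koff_B * eps))
  sys <- promoter_system(c("A", "B"), k0 = k0,
                         concentrations = c(A = conc_A, B = conc_B),
                         rho = c(0, 0, rho_B, rho_B))
  cas <- cascade_params(gamma = 1 / 300, beta = 1000 / 1200,
                        gamma_p = 1 / 1200)
  list(system = sys, cascade = cas)
}

#' Prokaryotic-like looped promoter (energetically closed)
#'
#' Sixteen states over two binding sites for activator-repressor A, one
#' site for factor C and a DNA-loop pseudo-factor L (concentration fixed
#' at 1, so it contributes no chemical-potential term). State free
#' energies are assembled additively (kcal/mol): per-site binding
#' `kBT log K` with `K_A = 20` nM, `K_C = 1` nM; cooperativity between the
#' two A sites `dG_AA = -2`; competition between C and one A site
#' `dG_AC = +1.5`; loop formation `dG_loop = +9`, overcompensated by
#' `dG_loopA = -5.5` per occupied A site. Kinetics: residence times 20 s
#' (A sites) and 60 s (C); looping time 1 s once both A sites are
#' occupied (the loop cannot form otherwise, and with its shared barrier
#' it then cannot open either, so closedness is exact); the loop slows C
#' exchange by a shared barrier shift `dE_loopC = +2.5`. All barriers are
#' direction-symmetric: the system consumes no free energy, its
#' stationary law is the Boltzmann distribution in the assembled G and
#' its relaxation spectrum is purely real.
#'
#' Transcription is promoted by the unlooped conformation, by bound C and
#' slightly by A occupying exactly one site:
#' `rho = rho0 * 0.4^[looped] * 2.0^[C bound] * 1.15^[one A]`, keeping the
#' mean RNA level between roughly 10 and 70 copies over the swept
#' concentration ranges for `gamma = 1/300` (5-min RNA lifetime).
#'
#' @param conc_A,conc_C Concentrations (nM), physiological range
#'   `[1e-2, 1e3]`.
#' @param competing_site Which A site carries the A/C competition (1 or
#'   2); the caption-level description does not fix it.
#' @param rho0 Basal transcription rate (per s).
#' @param temperature Kelvin.
#' @return List with `system`, `energetic_model` and `cascade`.
#' @export
looped_promoter_system <- function(conc_A, conc_C, competing_site = 2,
                                   rho0 = 0.1, temperature = 298.15) {
  stopifnot(competing_site %in% c(1, 2))
  kBT <- .kB * temperature
  tf <- c("A1", "A2", "C", "L")
  ns <- 16L
  K_A <- 20; K_C <- 1
  dG_AA <- -2; dG_AC <- 1.5; dG_loop <- 9; dG_loopA <- -5.5
  dE_loopC <- 2.5
  koff_A <- 1 / 20; koff_C <- 1 / 60; k_close <- 1
  has <- function(s, bit) bitwAnd(s, bitwShiftL(1L, bit - 1L)) > 0L
  G0 <- vapply(seq_len(ns) - 1L, function(s) {
    a1 <- has(s, 1); a2 <- has(s, 2); cc <- has(s, 3); lp <- has(s, 4)
    g <- kBT * log(K_A) * (a1 + a2) + kBT * log(K_C) * cc
    if (a1 && a2) g <- g + dG_AA
    if (cc && (if (competing_site == 1) a1 else a2)) g <- g + dG_AC
    if (lp) g <- g + dG_loop + dG_loopA * (a1 + a2)
    g
  }, numeric(1))
  E0 <- matrix(Inf, 4, ns)
  for (s in seq_len(ns) - 1L) {
    a1 <- has(s, 1); a2 <- has(s, 2); cc <- has(s, 3); lp <- has(s, 4)
    # A-site and C barriers, set from the dissociation side (f bound in s)
    for (f in 1:3) {
      if (!has(s, f)) next
      koff <- if (f == 3) koff_C else koff_A
      e <- G0[s + 1L] + kBT * log(1 / koff)
      if (f == 3 && lp) e <- e + dE_loopC
      E0[f, s + 1L] <- e
      E0[f, bitwXor(s, bitwShiftL(1L, f - 1L)) + 1L] <- e
    }
    # loop closing, defined from the unlooped side, only with both A bound
    if (!lp && a1 && a2) {
      e <- G0[s + 1L] + kBT * log(1 / k_close)
      E0[4, s + 1L] <- e
      E0[4, s + 8L + 1L] <- e
    }
  }
  em <- energetic_model(tf, G0, E0, temperature = temperature, prefactor = 1)
  rho <- vapply(seq_len(ns) - 1L, function(s) {
    a1 <- has(s, 1); a2 <- has(s, 2); cc <- has(s, 3); lp <- has(s, 4)
    rho0 * (if (lp) 0.4 else 1) * (if (cc) 2.0 else 1) *
      (if (xor(a1, a2)) 1.15 else 1)
  }, numeric(1))
  conc <- c(A1 = conc_A, A2 = conc_A, C = conc_C, L = 1)
  sys <- system_from_energies(em, conc, rho)
  cas <- cascade_params(gamma = 1 / 300, beta = 1000 / 1200,
                        gamma_p = 1 / 1200)
  list(system = sys, energetic_model = em, cascade = cas)
}

#' Randomize activation barriers
#'
#' Adds one zero-mean Gaussian energy per reaction to the *shared* barrier
#' (both directions equally), leaving state energies `G0` untouched.
#' Closed models stay closed, so the stationary law -- and therefore every
#' mean level -- is exactly unchanged, while the kinetics (hence all
#' fluctuation properties) can change drastically.
#'
#' @param em An [energetic_model()].
#' @param sd_kcal Standard deviation of the added energy (kcal/mol).
#' @param seed Integer seed.
#' @return A perturbed `energetic_model`.
#' @export
randomize_barriers <- function(em, sd_kcal, seed) {
  stopifnot(inherits(em, "energetic_model"))
  if (sd_kcal < 0) stop("sd must be nonnegative")
  set.seed(as.integer(seed))
  n <- length(em$tf_names); ns <- 2^n
  E0 <- em$E0
  for (f in seq_len(n)) {
    bit <- bitwShiftL(1L, f - 1L)
    for (s in seq_len(ns) - 1L) {
      if (bitwAnd(s, bit) == 0L) next          # visit each reaction once
      if (is.infinite(E0[f, s + 1L])) next
      d <- stats::rnorm(1, 0, sd_kcal)
      E0[f, s + 1L] <- E0[f, s + 1L] + d
      E0[f, bitwXor(s, bit) + 1L] <- E0[f, bitwXor(s, bit) + 1L] + d
    }
  }
  energetic_model(em$tf_names, em$G0, E0, em$temperature, em$prefactor)
}

#' Random promoter system
#'
#' Log-normal standard-condition rates over the full binding hypercube
#' (hence irreducible), uniform transcription rates; reproducible by seed.
#' Used as a property-test and consistency-check fixture.
#'
#' @param N Number of factors (1..8).
#' @param seed Integer seed.
#' @param log_rate_sd Standard deviation of log rates.
#' @param rate_scale Median rate (per s).
#' @param rho_max Upper bound of the uniform transcription rates.
#' @return A [promoter_system()].
#' @export
random_promoter_system <- function(N, seed, log_rate_sd = 1,
                                   rate_scale = 0.05, rho_max = 0.2) {
  if (N < 1 || N > 8) stop("N must be between 1 and 8")
  set.seed(as.integer(seed))
  ns <- 2^N
  k0 <- matrix(exp(stats::rnorm(N * ns, log(rate_scale), log_rate_sd)), N, ns)
  conc <- stats::runif(N, 0.5, 2)
  names(conc) <- paste0("F", seq_len(N))
  rho <- stats::runif(ns, 0, rho_max)
  promoter_system(paste0("F", seq_len(N)), k0 = k0, concentrations = conc,
                  rho = rho)
}

#' Random energetic model
#'
#' State energies `G0 ~ N(0, g_sd)`; each reaction barrier sits a uniform
#' amount above the higher of its two end states. Closed models share the
#' barrier across directions; open models add a Gaussian asymmetry.
#'
#' @param N Number of factors.
#' @param seed Integer seed.
#' @param closed Share barriers (detailed balance) or not.
#' @param g_sd Spread of state energies (kcal/mol).
#' @param asym_sd Barrier asymmetry for open models (kcal/mol).
#' @return An [energetic_model()].
#' @export
random_energetic_model <- function(N, seed, closed = TRUE, g_sd = 1.5,
                                   asym_sd = 1) {
  set.seed(as.integer(seed))
  ns <- 2^N
  G0 <- stats::rnorm(ns, 0, g_sd)
  E0 <- matrix(NA_real_, N, ns)
  for (f in seq_len(N)) {
    bit <- bitwShiftL(1L, f - 1L)
    for (s in seq_len(ns) - 1L) {
      if (bitwAnd(s, bit) == 0L) next
      sp <- bitwXor(s, bit)
      e <- max(G0[s + 1L], G0[sp + 1L]) + stats::runif(1, 0.5, 2.5)
      if (closed) {
        E0[f, s + 1L] <- E0[f, sp + 1L] <- e
      } else {
        E0[f, s + 1L] <- e
        E0[f, sp + 1L] <- e + stats::rnorm(1, 0, asym_sd)
      }
    }
  }
  energetic_model(paste0("F", seq_len(N)), G0, E0)
}

#' Stochastic optimization of oscillation coherence
#'
#' Hill-climb on the log-rates of a kinetic promoter system: propose
#' Gaussian perturbations of all `log k0` entries, accept whenever the
#' objective does not decrease. The objective is the largest coherence
#' factor over the eigenvalue pairs, damped by a penalty unless the
#' oscillation period is at least `period_factor` times the fastest
#' relaxation time (so the oscillation is slow relative to the rest of
#' the dynamics). The free-energy consumption rate is logged at each
#' accepted step; driving a promoter toward a coherent cycle makes its
#' transitions more directed and therefore more dissipative.
#'
#' @param system Initial kinetic [promoter_system()] (not raw).
#' @param iterations Number of proposals.
#' @param seed Integer seed.
#' @param move_sd Standard deviation of the log-rate perturbations.
#' @param period_factor Required ratio of oscillation period to fastest
#'   relaxation time.
#' @return A data.frame trace with one row per accepted state (including
#'   the start): `iteration`, `objective`, `coherence`, `best_coherence`,
#'   `edot_kBT_s`. The final system is attached as attribute `system`.
#' @export
optimize_coherence <- function(system, iterations, seed, move_sd = 0.3,
                               period_factor = 10) {
  stopifnot(inherits(system, "promoter_system"))
  if (is.null(system$k0)) stop("optimization needs a kinetic (k0) system")
  set.seed(as.integer(seed))
  score <- function(sys) {
    dec <- suppressWarnings(decompose_generator(build_generator(sys)))
    lam <- dec$values[-1]
    osc <- lam[Im(lam) > 1e-12]
    if (length(osc) == 0) return(list(obj = 0, Z = 0))
    Z <- abs(Im(osc)) / (2 * pi * abs(Re(osc)))
    k <- which.max(Z)
    period <- 2 * pi / abs(Im(osc[k]))
    tfast <- 1 / max(abs(Re(lam)))
    pen <- min(1, period / (period_factor * tfast))
    list(obj = Z[k] * pen, Z = max(Z))
  }
  edot <- function(sys)
    energy_consumption_rate(build_generator(sys))$edot_kBT_s
  cur <- system
  sc <- score(cur)
  best_Z <- sc$Z
  trace <- data.frame(iteration = 0L, objective = sc$obj, coherence = sc$Z,
                      best_coherence = best_Z, edot_kBT_s = edot(cur))
  if (iterations > 0) for (it in seq_len(iterations)) {
    prop <- cur
    pos <- prop$k0 > 0
    prop$k0[pos] <- exp(log(prop$k0[pos]) +
                          stats::rnorm(sum(pos), 0, move_sd))
    sc_new <- score(prop)
    if (sc_new$obj >= sc$obj) {
      cur <- prop; sc <- sc_new
      best_Z <- max(best_Z, sc$Z)
      trace <- rbind(trace,
                     data.frame(iteration = it, objective = sc$obj,
                                coherence = sc$Z, best_coherence = best_Z,
                                edot_kBT_s = edot(cur)))
    }
  }
  attr(trace, "system") <- cur
  trace
}
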