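# Exact steady-state distributions of the joint promoter/RNA master
# equation, mode counting for RNA histograms, and the steady-state
# entropy-production (free-energy consumption) rate of the promoter chain.

#' Joint promoter-RNA steady-state distribution
#'
#' Solves the stationary master equation of the coupled system
#' `0 = M phi_r + D_rho (phi_{r-1} - phi_r) + gamma ((r+1) phi_{r+1} - r phi_r)`
#' where `phi_r[s]` is the probability of `r` RNA molecules with the
#' promoter in state `s`. The copy-number axis is truncated at `rmax`
#' (reflecting: no synthesis out of the top level) and solved as one sparse
#' linear system with a normalization row replacing one redundant balance
#' equation; `rmax` is doubled until the mass at the boundary falls below
#' `1e-8`.
#'
#' @param system A [promoter_system()].
#' @param gamma RNA degradation rate (per s).
#' @param rmax_hint Optional starting truncation; defaults to
#'   `ceil(mean + 12 sqrt(mean) + 20)`.
#' @return An object of class `joint_distribution`: list with `probs`
#'   (`(rmax+1) x 2^N` matrix), `rmax`, `tail_mass` and `gamma`.
#' @export
joint_steady_state <- function(system, gamma, rmax_hint = NULL) {
  stopifnot(inherits(system, "promoter_system"))
  if (gamma <= 0) stop("gamma must be positive")
  M <- build_generator(system)
  if (!isTRUE(attr(M, "irreducible"))) stop("promoter chain must be irreducible")
  pi <- stationary_distribution(M)
  mean_R <- sum(pi * system$rho) / gamma
  rmax <- if (is.null(rmax_hint)) ceiling(mean_R + 12 * sqrt(mean_R) + 20)
          else as.integer(rmax_hint)
  repeat {
    if (rmax > 1e5) stop("truncation did not converge by rmax = 1e5")
    probs <- .solve_joint(unclass(M), system$rho, gamma, rmax)
    tail_mass <- sum(probs[rmax + 1, ])
    if (tail_mass < 1e-8) break
    rmax <- 2 * rmax
  }
  structure(list(probs = probs, rmax = rmax, tail_mass = tail_mass,
                 gamma = gamma, pi = pi),
            class = "joint_distribution")
}

# sparse solve of the truncated joint CME; unknowns ordered r-major
# (all states of r = 0, then r = 1, ...): block tridiagonal, small bandwidth
.solve_joint <- function(M, rho, gamma, rmax) {
  ns <- ncol(M)
  nr <- rmax + 1L
  ntot <- ns * nr
  idx <- function(r, s) r * ns + s      # r in 0..rmax, s in 1..ns
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  add <- function(i, j, x) {
    keep <- x != 0
    ii <<- c(ii, i[keep]); jj <<- c(jj, j[keep]); xx <<- c(xx, x[keep])
  }
  s_seq <- seq_len(ns)
  nzM <- which(M != 0, arr.ind = TRUE)
  for (r in 0:rmax) {
    base <- idx(r, s_seq)
    # promoter transitions within level r
    add(idx(r, nzM[, 1]), idx(r, nzM[, 2]), M[nzM])
    # birth: inflow from r-1 at rate rho_s; outflow -rho_s (suppressed at rmax)
    if (r > 0) add(base, idx(r - 1L, s_seq), rho)
    if (r < rmax) add(base, base, -rho)
    # death: inflow from r+1 at rate gamma (r+1); outflow -gamma r
    if (r < rmax) add(base, idx(r + 1L, s_seq), rep(gamma * (r + 1), ns))
    add(base, base, rep(-gamma * r, ns))
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(ntot, ntot))
  # replace the last balance row (redundant) with normalization
  A[ntot, ] <- 1
  b <- c(rep(0, ntot - 1), 1)
  sol <- as.numeric(Matrix::solve(A, b))
  sol[sol < 0 & sol > -1e-12] <- 0
  probs <- matrix(sol, nrow = nr, ncol = ns, byrow = TRUE)
  probs / sum(probs)
}

#' @export
print.joint_distribution <- function(x, ...) {
  cat("Joint promoter-RNA distribution: rmax =", x$rmax,
      "; tail mass", signif(x$tail_mass, 3), "\n")
  invisible(x)
}

#' RNA marginal distribution
#'
#' Sums the joint distribution over promoter states.
#'
#' @param jd A [joint_steady_state()] result.
#' @return Numeric probability vector over `r = 0 .. rmax`.
#' @export
rna_marginal <- function(jd) {
  stopifnot(inherits(jd, "joint_distribution"))
  rowSums(jd$probs)
}

#' Promoter marginal of the joint distribution
#'
#' @param jd A [joint_steady_state()] result.
#' @return Probability vector over promoter states (should match
#'   [stationary_distribution()]).
#' @export
promoter_marginal <- function(jd) {
  stopifnot(inherits(jd, "joint_distribution"))
  colSums(jd$probs)
}

#' Count modes of a discrete distribution
#'
#' Number of strict local maxima of the pmf after merging flat plateaus;
#' maxima whose height is below `min_height` are ignored.
#'
#' @param pmf Nonnegative vector summing to ~1.
#' @param min_height Ignore maxima lower than this.
#' @return List with `n_modes` and `modes` (0-based copy-number locations).
#' @export
count_modes <- function(pmf, min_height = 1e-6) {
  p <- as.numeric(pmf)
  if (length(p) == 0 || any(p < 0)) stop("pmf must be nonnegative")
  # collapse runs of equal values, remember representative positions
  r <- rle(p)
  v <- r$values
  pos_end <- cumsum(r$lengths)
  pos_start <- pos_end - r$lengths + 1
  k <- length(v)
  modes <- integer(0)
  for (i in seq_len(k)) {
    left <- if (i == 1) -Inf else v[i - 1]
    right <- if (i == k) -Inf else v[i + 1]
    if (v[i] > left && v[i] > right && v[i] >= min_height) {
      at <- floor((pos_start[i] + pos_end[i]) / 2) - 1L  # 0-based copy number
      modes <- c(modes, at)
    }
  }
  list(n_modes = length(modes), modes = modes)
}

#' Steady-state free-energy consumption rate
#'
#' Entropy production of the stationary promoter chain:
#' `Edot = sum over ordered pairs s != s' of pi_s M[s', s]
#' log(M[s', s] / M[s, s'])` in units of kBT per second. It is nonnegative
#' and vanishes exactly when detailed balance holds (closed systems). A
#' one-way reaction used at stationarity makes the rate infinite (the
#' idealized irreversible step would dissipate unbounded free energy); the
#' offending edge is reported in that case.
#'
#' @param M Generator matrix (coerced with [as_generator()]).
#' @param temperature Kelvin, used only for the kcal/mol conversion.
#' @return List with `edot_kBT_s`, `edot_kcal_mol_s` and, when infinite,
#'   `one_way_edge` (source/target state indices).
#' @export
energy_consumption_rate <- function(M, temperature = 298.15) {
  M <- as_generator(M)
  pi <- stationary_distribution(M)
  ns <- nrow(M)
  A <- unclass(M)
  edot <- 0
  for (s in seq_len(ns)) for (sp in seq_len(ns)) {
    if (s == sp) next
    fwd <- A[sp, s]
    if (fwd == 0) next
    bwd <- A[s, sp]
    if (bwd == 0)
      return(list(edot_kBT_s = Inf, edot_kcal_mol_s = Inf,
                  one_way_edge = c(source = s, target = sp)))
    edot <- edot + pi[s] * fwd * log(fwd / bwd)
  }
  edot <- as.numeric(edot)
  list(edot_kBT_s = edot, edot_kcal_mol_s = edot * .kB * temperature)
}

#' ATP equivalents dissipated per oscillation cycle
#'
#' Converts a free-energy consumption rate into hydrolysis equivalents per
#' oscillation period: `Edot * period / atp_kBT`.
#'
#' @param edot_kBT_s Consumption rate (kBT/s).
#' @param period_s Oscillation period (s).
#' @param atp_kBT Free energy of one ATP hydrolysis in kBT (default 20,
#'   physiological conditions).
#' @return Numeric.
#' @examples
#' atp_equivalent_per_cycle(0.05, 40 * 60, 20)  # 6 ATP per 40-min cycle
#' @export
atp_equivalent_per_cycle <- function(edot_kBT_s, period_s, atp_kBT = 20) {
  if (period_s <= 0 || atp_kBT <= 0) stop("period and ATP energy must be positive")
  if (edot_kBT_s < 0) stop("consumption rate must be nonnegative")
  edot_kBT_s * period_s / atp_kBT
}
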