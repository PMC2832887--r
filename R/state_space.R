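# Promoter state space, generator matrix and the kinetic/energetic duality.
#
# A promoter with N transcription factors (TFs, or more generally binary
# epigenetic marks) has 2^N states indexed by the bitmask over the declared
# TF order: bit f set <=> factor f bound; state index 0 is the empty promoter.
# The generator M is column-indexed by the source state (dphi/dt = M phi),
# so every column sums to zero.

#' Boltzmann constant in kcal/(mol K)
#' @keywords internal
.kB <- 0.0019872

#' Enumerate promoter states
#'
#' Lists all `2^N` combinations of bound factors in bitmask order: the state
#' at index `i + 1` contains factor `f` iff bit `f - 1` of `i` is set, so the
#' first state is the empty promoter.
#'
#' @param tf_names Character vector of distinct factor labels, in the order
#'   defining the bitmask.
#' @return A list of length `2^N` of character vectors (subsets of
#'   `tf_names`); element 1 is `character(0)`.
#' @examples
#' enumerate_states(c("A", "B"))
#' @export
enumerate_states <- function(tf_names) {
  tf_names <- as.character(tf_names)
  n <- length(tf_names)
  if (n < 1) stop("at least one TF label is required")
  if (n > 20) stop("more than 20 factors (", n, ") is not supported")
  if (anyDuplicated(tf_names)) stop("duplicate TF labels: ",
    paste(unique(tf_names[duplicated(tf_names)]), collapse = ", "))
  if (n > 12) warning("N = ", n, ": the 2^N state space is very large")
  lapply(seq_len(2^n) - 1L, function(i) tf_names[bitwAnd(i, bitwShiftL(1L, seq_len(n) - 1L)) > 0L])
}

#' Human-readable state labels
#'
#' @param tf_names Factor labels as in [enumerate_states()].
#' @param empty Label used for the empty promoter.
#' @return Character vector of length `2^N`.
#' @export
state_labels <- function(tf_names, empty = "0") {
  vapply(enumerate_states(tf_names),
         function(s) if (length(s) == 0) empty else paste(s, collapse = "+"),
         character(1))
}

#' Construct a promoter system
#'
#' Bundles the combinatorial kinetic description of a promoter: factor
#' labels, the standard-condition rate matrix `k0`, free concentrations and
#' the per-state transcription initiation rates `rho`. Entry `k0[f, s]`
#' governs the reaction from state `s` to `s XOR f`: it is an association
#' constant (per nM per s) when `f` is absent from `s` and a dissociation
#' rate (per s) when `f` is present. Alternatively a full generator `raw_M`
#' may be supplied for systems whose transitions move several molecules at
#' once; it then takes precedence over `k0`.
#'
#' @param tf_names Ordered factor labels.
#' @param k0 `N x 2^N` matrix of nonnegative rate constants (ignored when
#'   `raw_M` is given).
#' @param concentrations Positive vector of length `N` (nM), named or in
#'   `tf_names` order.
#' @param rho Nonnegative vector of length `2^N`: transcription initiation
#'   rate of each state (per s).
#' @param raw_M Optional `2^N x 2^N` generator with nonnegative
#'   off-diagonal entries and zero column sums.
#' @return An object of class `promoter_system`.
#' @examples
#' sys <- promoter_system("A", k0 = rbind(c(0.2, 3)),
#'                        concentrations = c(A = 5), rho = c(0, 8))
#' build_generator(sys)
#' @export
promoter_system <- function(tf_names, k0 = NULL, concentrations, rho,
                            raw_M = NULL) {
  states <- enumerate_states(tf_names)
  n <- length(tf_names)
  ns <- 2^n
  concentrations <- .match_conc(concentrations, tf_names)
  if (any(concentrations <= 0)) stop("all concentrations must be positive")
  rho <- as.numeric(rho)
  if (length(rho) != ns) stop("rho must have length 2^N = ", ns)
  if (any(rho < 0)) stop("rho entries must be nonnegative")
  if (is.null(raw_M)) {
    if (is.null(k0)) stop("either k0 or raw_M must be supplied")
    k0 <- as.matrix(k0)
    if (!all(dim(k0) == c(n, ns))) stop("k0 must be ", n, " x ", ns)
    if (any(k0 < 0)) stop("k0 entries must be nonnegative")
  } else {
    raw_M <- as.matrix(raw_M)
    if (!all(dim(raw_M) == c(ns, ns))) stop("raw_M must be ", ns, " x ", ns)
    offdiag <- raw_M - diag(diag(raw_M))
    if (any(offdiag < 0)) stop("raw_M off-diagonal entries must be nonnegative")
    cs <- colSums(raw_M)
    if (any(abs(cs) > 1e-12 * max(abs(raw_M), 1)))
      stop("raw_M columns must sum to zero (non-conservative generator)")
  }
  structure(list(tf_names = as.character(tf_names), states = states,
                 k0 = k0, concentrations = concentrations, rho = rho,
                 raw_M = raw_M),
            class = "promoter_system")
}

#' Promoter system from a raw generator
#'
#' Wraps an arbitrary `n x n` generator (e.g. an n-state reaction cycle or a
#' rate table for transitions that move several molecules at once) together
#' with per-state transcription rates. State count need not be a power of
#' two; no factor bookkeeping is attached.
#'
#' @param raw_M `n x n` generator: nonnegative off-diagonals, zero column
#'   sums (columns = source state).
#' @param rho Nonnegative per-state transcription rates (length `n`).
#' @param state_names Optional state labels.
#' @return A `promoter_system` (with `tf_names = NULL`).
#' @export
raw_system <- function(raw_M, rho, state_names = NULL) {
  M <- as_generator(raw_M)
  ns <- nrow(M)
  rho <- as.numeric(rho)
  if (length(rho) != ns) stop("rho must have length ", ns)
  if (any(rho < 0)) stop("rho entries must be nonnegative")
  if (is.null(state_names)) state_names <- paste0("s", seq_len(ns))
  structure(list(tf_names = NULL, states = as.list(state_names),
                 k0 = NULL, concentrations = NULL, rho = rho,
                 raw_M = unclass(M)),
            class = "promoter_system")
}

.match_conc <- function(concentrations, tf_names) {
  concentrations <- unlist(concentrations)
  if (length(concentrations) != length(tf_names))
    stop("concentrations must have length N = ", length(tf_names))
  if (!is.null(names(concentrations))) {
    if (!setequal(names(concentrations), tf_names))
      stop("concentration names do not match TF labels")
    concentrations <- concentrations[tf_names]
  }
  v <- as.numeric(concentrations)
  names(v) <- tf_names
  v
}

#' @export
print.promoter_system <- function(x, ...) {
  if (is.null(x$tf_names)) {
    cat("Promoter system (raw generator):", length(x$rho), "states\n")
    return(invisible(x))
  }
  n <- length(x$tf_names)
  cat("Promoter system:", n, "factor(s),", 2^n, "states\n")
  cat("  factors:", paste(sprintf("%s (%g nM)", x$tf_names, x$concentrations),
                          collapse = ", "), "\n")
  cat("  rho range: [", min(x$rho), ",", max(x$rho), "] /s",
      if (!is.null(x$raw_M)) "  [raw generator supplied]", "\n")
  invisible(x)
}

#' Build the promoter generator matrix
#'
#' Assembles the `2^N x 2^N` generator `M` of the promoter-state Markov
#' chain from the concentration-weighted rates: the rate of `s -> s XOR f`
#' is `k0[f, s] * [f]` when `f` binds and `k0[f, s]` when it unbinds.
#' Columns index the source state and are made to sum to zero exactly. When
#' the system carries a `raw_M` it is validated and used directly.
#'
#' @param system A [promoter_system()].
#' @return A `generator_matrix`: the matrix `M` with attributes
#'   `irreducible` (logical) and `tf_names`.
#' @export
build_generator <- function(system) {
  stopifnot(inherits(system, "promoter_system"))
  if (!is.null(system$raw_M)) {
    M <- system$raw_M
    diag(M) <- 0
    diag(M) <- -colSums(M)
    labels <- if (is.null(system$tf_names)) paste0("s", seq_len(nrow(M)))
              else state_labels(system$tf_names)
    dimnames(M) <- list(labels, labels)
    return(structure(M, class = c("generator_matrix", "matrix"),
                     irreducible = .is_irreducible(M),
                     tf_names = system$tf_names))
  }
  n <- length(system$tf_names)
  ns <- 2^n
  {
    M <- matrix(0, ns, ns)
    for (s in seq_len(ns) - 1L) {
      for (f in seq_len(n)) {
        bit <- bitwShiftL(1L, f - 1L)
        target <- bitwXor(s, bit)
        rate <- if (bitwAnd(s, bit) == 0L)
          system$k0[f, s + 1L] * system$concentrations[f]
        else system$k0[f, s + 1L]
        M[target + 1L, s + 1L] <- rate
      }
    }
    diag(M) <- -colSums(M)
  }
  dimnames(M) <- list(state_labels(system$tf_names),
                      state_labels(system$tf_names))
  structure(M, class = c("generator_matrix", "matrix"),
            irreducible = .is_irreducible(M),
            tf_names = system$tf_names)
}

#' Validate an arbitrary generator matrix
#'
#' Wraps a plain square matrix as a `generator_matrix`, checking that
#' off-diagonal entries are nonnegative and column sums vanish.
#'
#' @param M Square matrix, columns indexed by source state.
#' @return A `generator_matrix`.
#' @export
as_generator <- function(M) {
  if (inherits(M, "generator_matrix")) return(M)
  M <- as.matrix(M)
  if (nrow(M) != ncol(M)) stop("M must be square")
  offdiag <- M - diag(diag(M), nrow(M))
  if (any(offdiag < 0)) stop("off-diagonal entries of M must be nonnegative")
  cs <- colSums(M)
  if (any(abs(cs) > 1e-12 * max(abs(M), 1)))
    stop("columns of M must sum to zero")
  diag(M) <- diag(M) - cs   # enforce exact conservation
  structure(M, class = c("generator_matrix", "matrix"),
            irreducible = .is_irreducible(M))
}

.is_irreducible <- function(M) {
  g <- igraph::graph_from_adjacency_matrix(t(M) > 0, mode = "directed",
                                           diag = FALSE)
  igraph::is_connected(g, mode = "strong")
}

#' Construct an energetic promoter model
#'
#' The thermodynamic dual of the kinetic description: a standard-condition
#' Gibbs free energy `G0[s]` per state and an absolute activation barrier
#' `E0[f, s]` per reaction `s -> s XOR f` (all kcal/mol). A model is
#' *closed* (no energy input; e.g. pure TF/DNA binding) when each barrier is
#' shared by the two directions of its reaction; asymmetric barriers encode
#' energy-driven steps such as ATP-dependent remodeling.
#'
#' @param tf_names Ordered factor labels.
#' @param G0 Numeric vector of length `2^N` (kcal/mol at unit concentration).
#' @param E0 `N x 2^N` matrix of barriers (kcal/mol); `Inf` disables a
#'   reaction in both directions.
#' @param temperature Kelvin (default 298.15, giving kBT = 0.5925 kcal/mol).
#' @param prefactor Attempt frequency `nu` in per s. The energies only fix
#'   rate ratios; `nu` sets the overall timescale and defaults to 1.
#' @return An object of class `energetic_model`.
#' @export
energetic_model <- function(tf_names, G0, E0, temperature = 298.15,
                            prefactor = 1) {
  states <- enumerate_states(tf_names)
  n <- length(tf_names); ns <- 2^n
  G0 <- as.numeric(G0)
  if (length(G0) != ns) stop("G0 must have length 2^N = ", ns)
  E0 <- as.matrix(E0)
  if (!all(dim(E0) == c(n, ns))) stop("E0 must be ", n, " x ", ns)
  if (temperature <= 0) stop("temperature must be positive")
  if (prefactor <= 0) stop("prefactor must be positive")
  structure(list(tf_names = as.character(tf_names), G0 = G0, E0 = E0,
                 temperature = temperature, prefactor = prefactor,
                 kBT = .kB * temperature),
            class = "energetic_model")
}

#' @export
print.energetic_model <- function(x, ...) {
  cat("Energetic promoter model:", length(x$tf_names), "factor(s), kBT =",
      signif(x$kBT, 4), "kcal/mol\n")
  cat("  closed (barrier-symmetric):", is_closed_system(x), "\n")
  invisible(x)
}

#' Test whether an energetic model is closed
#'
#' A model is closed when the activation barrier of every reaction is the
#' same in both directions (`E0[f, s] == E0[f, s XOR f]`), i.e. no reaction
#' injects free energy. Closed models obey detailed balance, have a
#' Boltzmann stationary law and purely real relaxation spectra.
#'
#' @param em An [energetic_model()].
#' @param tol Symmetry tolerance in kcal/mol.
#' @return Logical.
#' @export
is_closed_system <- function(em, tol = 1e-9) {
  stopifnot(inherits(em, "energetic_model"))
  n <- length(em$tf_names); ns <- 2^n
  for (f in seq_len(n)) {
    bit <- bitwShiftL(1L, f - 1L)
    for (s in seq_len(ns) - 1L) {
      e1 <- em$E0[f, s + 1L]
      e2 <- em$E0[f, bitwXor(s, bit) + 1L]
      if (is.infinite(e1) && is.infinite(e2)) next
      if (!isTRUE(abs(e1 - e2) <= tol)) return(FALSE)
    }
  }
  TRUE
}

#' Convert energies to standard-condition kinetic constants
#'
#' Arrhenius-type rate law: the standard-condition constant of reaction
#' `s -> s XOR f` is `nu * exp(-(E0[f, s] - G0[s]) / kBT)`. Association
#' entries are in the standard-condition convention, so
#' [build_generator()] reproduces the concentration-weighted rates
#' `k0 * [f]`. With the concentration term `kBT * sum_{f' free} log[f']`
#' included in the state energy `G_s`, the ratio of the two directions of
#' any reaction equals `exp((G_s - G_{s XOR f}) / kBT)`, so closed models
#' relax to the Boltzmann law in `G`.
#'
#' @param em An [energetic_model()].
#' @param concentrations Positive concentrations (nM), length `N`.
#' @return `N x 2^N` matrix `k0` usable in [promoter_system()].
#' @export
kinetics_from_energies <- function(em, concentrations) {
  stopifnot(inherits(em, "energetic_model"))
  concentrations <- .match_conc(concentrations, em$tf_names)
  if (any(concentrations <= 0)) stop("all concentrations must be positive")
  n <- length(em$tf_names); ns <- 2^n
  k0 <- matrix(0, n, ns)
  for (s in seq_len(ns) - 1L)
    for (f in seq_len(n))
      k0[f, s + 1L] <- em$prefactor *
        exp(-(em$E0[f, s + 1L] - em$G0[s + 1L]) / em$kBT)
  k0[!is.finite(k0)] <- 0   # infinite barriers disable the reaction
  k0
}

#' Promoter system from an energetic model
#'
#' Convenience wrapper: converts energies to kinetics and assembles a
#' [promoter_system()].
#'
#' @inheritParams kinetics_from_energies
#' @param rho Per-state transcription rates (length `2^N`).
#' @return A `promoter_system`.
#' @export
system_from_energies <- function(em, concentrations, rho) {
  promoter_system(em$tf_names, k0 = kinetics_from_energies(em, concentrations),
                  concentrations = concentrations, rho = rho)
}

#' State free energies at given concentrations
#'
#' `G_s = G0_s + kBT * sum over free factors of log [f]`; only unbound
#' factors contribute their chemical-potential term.
#'
#' @inheritParams kinetics_from_energies
#' @return Numeric vector of length `2^N` (kcal/mol).
#' @export
state_energies <- function(em, concentrations) {
  stopifnot(inherits(em, "energetic_model"))
  concentrations <- .match_conc(concentrations, em$tf_names)
  n <- length(em$tf_names); ns <- 2^n
  vapply(seq_len(ns) - 1L, function(s) {
    free <- bitwAnd(s, bitwShiftL(1L, seq_len(n) - 1L)) == 0L
    em$G0[s + 1L] + em$kBT * sum(log(concentrations[free]))
  }, numeric(1))
}

#' Boltzmann distribution of a closed model
#'
#' `pi_s` proportional to `exp(-G_s / kBT)`; the exact stationary law of any
#' closed (detailed-balance) promoter.
#'
#' @inheritParams kinetics_from_energies
#' @return Probability vector of length `2^N`.
#' @export
boltzmann_distribution <- function(em, concentrations) {
  g <- state_energies(em, concentrations)
  w <- exp(-(g - min(g)) / em$kBT)
  w / sum(w)
}

#' Detect directed cycles (detailed-balance violation)
#'
#' Applies the Kolmogorov cycle criterion to the transition-support graph:
#' the chain is reversible iff around every cycle the product of rates
#' clockwise equals the product counterclockwise. Checking the fundamental
#' cycles of a spanning forest suffices. A one-way reaction (zero reverse
#' rate) lying on a cycle violates the criterion outright.
#'
#' @param M A generator matrix (coerced with [as_generator()]).
#' @param tol Relative tolerance on the cycle product ratio.
#' @return A list with `has_cycle` (logical: TRUE when detailed balance is
#'   broken), `witness` (state indices of one offending cycle, or NULL) and
#'   `log_ratio` (log of the worst clockwise/counterclockwise rate-product
#'   ratio; `Inf` for a one-way cycle edge).
#' @export
detect_directed_cycles <- function(M, tol = 1e-8) {
  M <- as_generator(M)
  ns <- nrow(M)
  sup <- (M > 0); diag(sup) <- FALSE
  und <- sup | t(sup)
  g <- igraph::graph_from_adjacency_matrix(und, mode = "undirected",
                                           diag = FALSE)
  if (igraph::ecount(g) == 0)
    return(list(has_cycle = FALSE, witness = NULL, log_ratio = 0))
  # spanning forest; each non-tree edge closes one fundamental cycle
  forest <- igraph::mst(g)
  fe <- igraph::as_edgelist(forest, names = FALSE)
  in_forest <- matrix(FALSE, ns, ns)
  if (nrow(fe) > 0) {
    in_forest[fe] <- TRUE
    in_forest[fe[, c(2, 1), drop = FALSE]] <- TRUE
  }
  worst <- 0; witness <- NULL
  el <- igraph::as_edgelist(g, names = FALSE)
  for (k in seq_len(nrow(el))) {
    a <- el[k, 1]; b <- el[k, 2]
    if (in_forest[a, b]) next
    path <- igraph::shortest_paths(forest, from = a, to = b)$vpath[[1]]
    if (length(path) == 0) next     # different components (cannot happen for mst of g)
    cyc <- as.integer(path)         # a ... b, closed by edge b->a
    lr <- .cycle_log_ratio(M, cyc)
    if (is.infinite(lr) || abs(lr) > abs(worst)) {
      worst <- lr; witness <- cyc
      if (is.infinite(lr)) break
    }
  }
  has <- is.infinite(worst) || abs(worst) > log1p(tol)
  list(has_cycle = has, witness = if (has) witness else NULL,
       log_ratio = worst)
}

# log of (product of forward rates / product of backward rates) around the
# closed walk v1 -> v2 -> ... -> vk -> v1
.cycle_log_ratio <- function(M, cyc) {
  k <- length(cyc)
  nxt <- c(cyc[-1], cyc[1])
  lr <- 0
  for (i in seq_len(k)) {
    fwd <- M[nxt[i], cyc[i]]
    bwd <- M[cyc[i], nxt[i]]
    if (fwd == 0 && bwd == 0) return(0)   # support edge missing: not a cycle of the chain
    if (fwd == 0 || bwd == 0) return(Inf)
    lr <- lr + log(fwd) - log(bwd)
  }
  lr
}

#' Stationary distribution of the promoter chain
#'
#' Solves `M pi = 0`, `sum pi = 1` by replacing one redundant balance row
#' with the normalization constraint, followed by one step of iterative
#' refinement.
#'
#' @param M Generator matrix (coerced with [as_generator()]).
#' @return Probability vector `pi` with `max|M pi| < 1e-10 * max|M|`.
#' @export
stationary_distribution <- function(M) {
  M <- as_generator(M)
  ns <- nrow(M)
  if (ns == 1) return(stats::setNames(1, rownames(M)))
  if (!isTRUE(attr(M, "irreducible"))) {
    g <- igraph::graph_from_adjacency_matrix(t(unclass(M)) > 0,
                                             mode = "directed", diag = FALSE)
    comp <- igraph::components(g, mode = "strong")
    stop("promoter chain is reducible; strongly connected components: ",
         paste(tapply(seq_len(ns), comp$membership, paste, collapse = ","),
               collapse = " | "))
  }
  A <- unclass(M)
  A[ns, ] <- 1
  b <- c(rep(0, ns - 1), 1)
  pi <- solve(A, b)
  # one refinement step against the full (unmodified) system
  r <- unclass(M) %*% pi
  pi <- pi - solve(A, c(r[-ns], sum(pi) - 1))
  pi <- pmax(pi, 0); pi <- pi / sum(pi)
  resid <- max(abs(unclass(M) %*% pi))
  if (resid > 1e-10 * max(abs(M)))
    warning("stationary residual ", signif(resid, 3), " exceeds tolerance")
  stats::setNames(as.numeric(pi), rownames(M))
}
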