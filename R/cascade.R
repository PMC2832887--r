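# Propagation of promoter fluctuations through the RNA and protein stages.
#
# RNA is born at the state-dependent rate rho_s (an inhomogeneous Poisson
# process driven by the promoter) and degrades at rate gamma per molecule;
# protein is translated at rate beta per RNA and degrades at rate gamma_p.
# Each stage adds a shot-noise floor 2 * (degradation) * (mean) and
# low-pass filters the incoming spectrum at its degradation rate.

#' Cascade parameters
#'
#' @param gamma RNA degradation rate (per s; lifetime `1/gamma`).
#' @param beta Translation rate per RNA molecule (per s).
#' @param gamma_p Protein degradation rate (per s).
#' @return An object of class `cascade_params`.
#' @examples
#' cascade_params(gamma = 1/300, beta = 1, gamma_p = 1/1200)
#' @export
cascade_params <- function(gamma, beta, gamma_p) {
  if (any(c(gamma, beta, gamma_p) <= 0))
    stop("all cascade rates must be positive")
  structure(list(gamma = gamma, beta = beta, gamma_p = gamma_p),
            class = "cascade_params")
}

#' Stationary means of transcription, RNA and protein
#'
#' `<X> = pi . rho` (mean initiation rate), `<R> = <X> / gamma`,
#' `<P> = beta <R> / gamma_p`.
#'
#' @param system A [promoter_system()].
#' @param cascade A [cascade_params()].
#' @return Named list `mean_X`, `mean_R`, `mean_P`.
#' @export
mean_levels <- function(system, cascade) {
  stopifnot(inherits(system, "promoter_system"),
            inherits(cascade, "cascade_params"))
  pi <- stationary_distribution(build_generator(system))
  mx <- sum(pi * system$rho)
  mr <- mx / cascade$gamma
  list(mean_X = mx, mean_R = mr, mean_P = cascade$beta * mr / cascade$gamma_p)
}

#' RNA-level power spectrum
#'
#' `S_R(omega) = (2 gamma <R> + S_X(omega)) / (gamma^2 + omega^2)`:
#' the promoter spectrum plus the transcription/degradation shot-noise
#' floor, low-pass filtered by the RNA lifetime.
#'
#' @param sx Promoter spectrum (a `spectrum` from [power_spectrum()]).
#' @param mean_R Stationary mean RNA copy number.
#' @param gamma RNA degradation rate (per s).
#' @return A `spectrum`.
#' @export
rna_spectrum <- function(sx, mean_R, gamma) {
  stopifnot(inherits(sx, "spectrum"))
  new_spectrum(sx$omega, (2 * gamma * mean_R + sx$value) /
                           (gamma^2 + sx$omega^2))
}

#' Protein-level power spectrum
#'
#' `S_P(omega) = (2 gamma_p <P> + beta^2 S_R(omega)) / (gamma_p^2 + omega^2)`.
#'
#' @param sr RNA spectrum (a `spectrum`).
#' @param mean_P Stationary mean protein copy number.
#' @param beta Translation rate (per s).
#' @param gamma_p Protein degradation rate (per s).
#' @return A `spectrum`.
#' @export
protein_spectrum <- function(sr, mean_P, beta, gamma_p) {
  stopifnot(inherits(sr, "spectrum"))
  new_spectrum(sr$omega, (2 * gamma_p * mean_P + beta^2 * sr$value) /
                           (gamma_p^2 + sr$omega^2))
}

# exact integral over the real line, divided by 2 pi, of
# [1/(a + i w) + 1/(a - i w)] / prod_k (g_k^2 + w^2), Re(a) > 0, g_k > 0.
# Obtained by partial fractions; with no filter the value is 1.
.lorentz_filter_integral <- function(a, filters) {
  if (length(filters) == 0) return(1)      # integral of the bare mode = c_i
  if (length(filters) == 1) return(1 / (filters * (a + filters)))
  g1 <- filters[1]; g2 <- filters[2]
  # the partial-fraction form has removable singularities at coincident
  # poles; a relative nudge of 1e-6 keeps the error far below the 0.1%
  # quadrature cross-check
  if (abs(g1 - g2) < 1e-8 * g1) g2 <- g2 * (1 + 1e-6)
  if (abs(a - g1) < 1e-8 * g1) a <- a * (1 + 1e-6)
  if (abs(a - g2) < 1e-8 * g2) a <- a * (1 + 1e-6)
  # 1/((a^2+w^2)(g1^2+w^2)(g2^2+w^2)) expansion, times 2a, integrated
  A <- 1 / ((g1^2 - a^2) * (g2^2 - a^2))
  B <- 1 / ((a^2 - g1^2) * (g2^2 - g1^2))
  C <- 1 / ((a^2 - g2^2) * (g1^2 - g2^2))
  A + a * B / g1 + a * C / g2
}

#' Normalized variances of transcription, RNA and protein
#'
#' Exact stationary noise levels `CV^2 = sigma^2 / mean^2` at the three
#' stages, obtained by closed-form integration (partial fractions over the
#' promoter eigenvalues) of the cascade spectra, cross-checked against
#' adaptive quadrature of the same spectra:
#' * `sigma_X^2 = sum_i c_i` (promoter modes),
#' * `sigma_R^2 = <R> + sum_i c_i / (gamma (gamma - lambda_i))`,
#' * `sigma_P^2 = <P> + beta^2 [ <R> / (gamma_p (gamma + gamma_p))
#'     + sum_i c_i I(-lambda_i; gamma, gamma_p) ]`,
#' where `I` is the two-filter Lorentzian integral. RNA and protein noise
#' are bounded below by their Poisson floors `1/<R>`, `1/<P>`.
#'
#' @param system A [promoter_system()].
#' @param cascade A [cascade_params()].
#' @param check_quadrature Cross-check the closed forms by numerical
#'   integration (error if they disagree by more than 0.1%).
#' @return Named list `cv2_X`, `cv2_R`, `cv2_P` (plus means as attribute).
#' @export
normalized_variances <- function(system, cascade, check_quadrature = TRUE) {
  stopifnot(inherits(system, "promoter_system"),
            inherits(cascade, "cascade_params"))
  M <- build_generator(system)
  dec <- decompose_generator(M)
  g <- cascade$gamma; b <- cascade$beta; gp <- cascade$gamma_p
  mx <- sum(dec$pi * system$rho)
  if (mx <= 0) stop("mean transcription rate is zero; variances undefined")
  mr <- mx / g; mp <- b * mr / gp
  cc <- .mode_coefficients(dec, system$rho)[-1]
  lam <- dec$values[-1]
  a <- -lam
  var_X <- Re(sum(cc))
  var_R <- mr + Re(sum(cc / (g * (g + a))))
  int2 <- vapply(a, .lorentz_filter_integral, complex(1), filters = c(g, gp))
  var_P <- mp + b^2 * (mr / (gp * (g + gp)) + Re(sum(cc * int2)))
  if (check_quadrature) {
    sxf <- .spectrum_fun(dec, system$rho)
    srf <- function(w) (2 * g * mr + sxf(w)) / (g^2 + w^2)
    spf <- function(w) (2 * gp * mp + b^2 * srf(w)) / (gp^2 + w^2)
    qr <- stats::integrate(srf, 0, Inf, rel.tol = 1e-9,
                           subdivisions = 2000L)$value / pi
    qp <- stats::integrate(spf, 0, Inf, rel.tol = 1e-9,
                           subdivisions = 2000L)$value / pi
    if (abs(qr - var_R) > 1e-3 * var_R || abs(qp - var_P) > 1e-3 * var_P)
      stop("closed-form and quadrature variances disagree beyond 0.1% ",
           "(RNA: ", signif(var_R, 6), " vs ", signif(qr, 6),
           "; protein: ", signif(var_P, 6), " vs ", signif(qp, 6), ")")
  }
  out <- list(cv2_X = var_X / mx^2, cv2_R = var_R / mr^2, cv2_P = var_P / mp^2)
  attr(out, "means") <- list(mean_X = mx, mean_R = mr, mean_P = mp)
  out
}
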