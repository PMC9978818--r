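#' Sum-of-exponentials dissociation model
#'
#' Evaluates the multi-component dissociation model
#' \deqn{R(t) = \sum_i \alpha_i e^{-k_{d,i} t} + R_\infty}
#' where each component represents a group of antibodies sharing a similar
#' dissociation rate constant, \eqn{\alpha_i} is that group's bound response
#' at the window start and the optional \eqn{R_\infty} absorbs
#' non-dissociating residual signal.
#'
#' @param times Times in seconds (>= 0).
#' @param alpha Component amplitudes in response units (>= 0).
#' @param kd Component dissociation rate constants in 1/s (> 0), same
#'   length as `alpha`.
#' @param r_inf Residual response at infinite time (default 0).
#' @return Numeric vector of responses at `times`.
#' @examples
#' sum_exp_response(c(0, 69.31), alpha = 1, kd = 0.01)  # ~c(1, 0.5)
#' @export
sum_exp_response <- function(times, alpha, kd, r_inf = 0) {
  stopifnot(length(alpha) == length(kd), length(alpha) >= 1L)
  if (any(!is.finite(kd)) || any(kd <= 0))
    stop("'kd' must be finite and positive", call. = FALSE)
  if (any(!is.finite(alpha)) || any(alpha < 0))
    stop("'alpha' must be finite and non-negative", call. = FALSE)
  if (any(times < 0)) stop("'times' must be non-negative", call. = FALSE)
  drop(exp(-outer(as.numeric(times), kd)) %*% alpha) + r_inf
}

#' 1:1 Langmuir association time-course
#'
#' Closed-form solution of single-site reversible binding during the
#' association phase at constant analyte concentration `conc`:
#' \deqn{R(t) = R_{eq}\,(1 - e^{-k_{obs} t}),\quad
#'       k_{obs} = k_a C + k_d,\quad
#'       R_{eq} = \frac{k_a C\, R_{max}}{k_{obs}}.}
#'
#' @param times Times in seconds from the association start.
#' @param ka Association rate constant, 1/(M s).
#' @param kd Dissociation rate constant, 1/s.
#' @param conc Analyte concentration in M (0 gives all-zero response).
#' @param rmax Surface binding capacity in response units.
#' @return Numeric vector of responses at `times`.
#' @export
langmuir_association <- function(times, ka, kd, conc, rmax) {
  stopifnot(ka > 0, kd >= 0, rmax > 0, conc >= 0)
  if (conc == 0) return(numeric(length(times)) * 0 + 0 * times)
  kobs <- ka * conc + kd
  req <- ka * conc * rmax / kobs
  req * (1 - exp(-kobs * as.numeric(times)))
}

#' Equilibrium dissociation constant from rate constants
#'
#' @param ka Association rate constant, 1/(M s), > 0.
#' @param kd Dissociation rate constant, 1/s.
#' @return K_D = kd / ka in molar.
#' @examples
#' binding_KD(8.2e4, 5.6e-5) * 1e9  # ~0.68 nM
#' @export
binding_KD <- function(ka, kd) {
  if (any(ka <= 0) || any(!is.finite(ka)))
    stop("'ka' must be positive and finite", call. = FALSE)
  kd / ka
}

#' Fold ratio of two dissociation rate constants
#'
#' Avidity differences between antibody components are conventionally
#' quoted as the fold difference of their dissociation rates.
#'
#' @param kd_a,kd_b Dissociation rate constants, 1/s; `kd_b` > 0.
#' @return `kd_a / kd_b`.
#' @examples
#' kd_fold_ratio(3.7e-2, 5.6e-5)  # ~660.7
#' @export
kd_fold_ratio <- function(kd_a, kd_b) {
  if (any(kd_b <= 0)) stop("denominator kd must be positive", call. = FALSE)
  kd_a / kd_b
}
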