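#' Heterogeneous-analyte (competing reactions) system
#'
#' Describes N analytes (e.g. monoclonal antibodies of differing kinetics)
#' competing in solution for one immobilized ligand population of capacity
#' `rmax`. During association each bound response R_j obeys the mass-action
#' law
#' \deqn{dR_j/dt = k_{a,j} C_j (R_{max} - \sum_k w_{jk} R_k) - k_{d,j} R_j}
#' with the molecular-weight scaling \eqn{w_{jk} = mw_j / mw_k} converting
#' the surface occupied by analyte k into the response scale of analyte j
#' (w = 1 when weights are equal or unspecified, as for IgG mixtures).
#' During dissociation the solution concentrations are zero and each
#' component decays as a pure exponential — rebinding is neglected, which
#' makes the simulated dissociation exactly multi-exponential.
#'
#' @param ka,kd Per-analyte rate constants (1/(M s) and 1/s).
#' @param conc Per-analyte molar concentrations (>= 0).
#' @param labels Optional analyte labels.
#' @param mw Optional molecular weights in g/mol (default: all equal).
#' @param rmax Shared surface capacity in response units.
#' @return An object of class `"competing_system"`.
#' @seealso [simulate_competing()], [fit_competing()]
#' @export
competing_system <- function(ka, kd, conc, labels = NULL, mw = NULL,
                             rmax = 1) {
  n <- length(ka)
  stopifnot(n >= 1L, length(kd) == n, length(conc) == n)
  if (any(ka < 0) || any(kd < 0) || any(conc < 0))
    stop("rates and concentrations must be non-negative", call. = FALSE)
  if (rmax <= 0) stop("'rmax' must be positive", call. = FALSE)
  if (is.null(labels)) labels <- paste0("analyte", seq_len(n))
  if (is.null(mw)) mw <- rep(1, n)
  stopifnot(length(labels) == n, length(mw) == n, all(mw > 0))
  structure(list(ka = as.numeric(ka), kd = as.numeric(kd),
                 conc = as.numeric(conc), labels = as.character(labels),
                 mw = as.numeric(mw), rmax = as.numeric(rmax)),
            class = "competing_system")
}

#' @export
print.competing_system <- function(x, ...) {
  cat(sprintf("<competing system> %d analyte(s), rmax = %g\n",
              length(x$ka), x$rmax))
  for (j in seq_along(x$ka))
    cat(sprintf("  %-10s ka %.3g 1/(M s), kd %.3g 1/s, conc %.3g M\n",
                x$labels[j], x$ka[j], x$kd[j], x$conc[j]))
  invisible(x)
}

# System matrix and forcing of the association-phase linear ODE.
.competing_matrices <- function(sys) {
  n <- length(sys$ka)
  w <- outer(sys$mw, sys$mw, "/")
  A <- -sys$ka * sys$conc * w
  diag(A) <- diag(A) - sys$kd
  list(A = A, b = sys$ka * sys$conc * sys$rmax)
}

# Solve dR/dt = A R + b, R(0) = r0, at the given times, by eigendecomposition
# (the system is linear with constant coefficients). Falls back to lsoda when
# the eigenbasis is degenerate or complex.
.solve_linear_binding <- function(A, b, r0, times, rtol = 1e-9) {
  n <- nrow(A)
  rp <- tryCatch(solve(A, -b), error = function(e) NULL)
  sol <- NULL
  if (!is.null(rp)) {
    eg <- eigen(A)
    ok <- max(abs(Im(eg$values))) < 1e-12 &&
      is.finite(rcond(Re(eg$vectors))) && rcond(Re(eg$vectors)) > 1e-10
    if (ok) {
      V <- Re(eg$vectors)
      lam <- Re(eg$values)
      c0 <- solve(V, r0 - rp)
      e_lt <- exp(outer(times, lam))          # nt x n
      sol <- e_lt * rep(c0, each = length(times))
      sol <- sol %*% t(V) + rep(rp, each = length(times))
    }
  }
  if (is.null(sol)) {
    deriv <- function(t, y, p) list(drop(A %*% y) + b)
    out <- deSolve::lsoda(y = r0, times = times, func = deriv, parms = NULL,
                          rtol = rtol, atol = rtol * 1e-3)
    if (nrow(out) < length(times))
      stop("ODE integration failed to reach relative tolerance ", rtol,
           call. = FALSE)
    sol <- unname(out[, -1L, drop = FALSE])
  }
  matrix(sol, nrow = length(times), ncol = n)
}

#' Simulate a competing-analyte binding experiment
#'
#' Forward-simulates association followed by dissociation for a
#' [competing_system], returning per-analyte component time-courses and the
#' total observed response. The association phase is solved exactly via the
#' eigendecomposition of the constant-coefficient linear system (adaptive
#' ODE integration as fallback); the dissociation phase sets all solution
#' concentrations to zero so each component decays as
#' \eqn{R_j(t_{assoc}) e^{-k_{d,j}\tau}}.
#'
#' @param sys A [competing_system].
#' @param t_assoc,t_dissoc Phase durations in seconds (> 0).
#' @param dt Sampling interval in seconds (> 0).
#' @return An object of class `"competing_sim"`: lists `assoc` and `dissoc`,
#'   each with `times` (phase-local, from 0), a `components` matrix (one
#'   column per analyte) and `total`.
#' @examples
#' sys <- competing_system(ka = 8.2e4, kd = 5.6e-5, conc = 3.33e-8)
#' sim <- simulate_competing(sys, t_assoc = 300, t_dissoc = 600, dt = 1)
#' max(abs(sim$assoc$total -
#'   langmuir_association(sim$assoc$times, 8.2e4, 5.6e-5, 3.33e-8, 1)))
#' @export
simulate_competing <- function(sys, t_assoc, t_dissoc, dt) {
  stopifnot(inherits(sys, "competing_system"),
            t_assoc > 0, t_dissoc > 0, dt > 0)
  m <- .competing_matrices(sys)
  t_a <- seq(0, t_assoc, by = dt)
  if (abs(t_a[length(t_a)] - t_assoc) > 1e-9) t_a <- c(t_a, t_assoc)
  comp_a <- .solve_linear_binding(m$A, m$b, numeric(length(sys$ka)), t_a)
  r_end <- comp_a[nrow(comp_a), ]
  t_d <- seq(0, t_dissoc, by = dt)
  if (abs(t_d[length(t_d)] - t_dissoc) > 1e-9) t_d <- c(t_d, t_dissoc)
  comp_d <- exp(-outer(t_d, sys$kd)) * rep(r_end, each = length(t_d))
  colnames(comp_a) <- colnames(comp_d) <- sys$labels
  structure(list(system = sys, t_assoc = t_assoc, t_dissoc = t_dissoc,
                 dt = dt,
                 assoc = list(times = t_a, components = comp_a,
                              total = rowSums(comp_a)),
                 dissoc = list(times = t_d, components = comp_d,
                               total = rowSums(comp_d))),
            class = "competing_sim")
}

#' @export
print.competing_sim <- function(x, ...) {
  cat(sprintf(
    "<competing simulation> %d analyte(s), %g s association + %g s dissociation (dt = %g s)\n",
    length(x$system$ka), x$t_assoc, x$t_dissoc, x$dt))
  fr <- occupancy_fractions(x, x$t_assoc)
  cat("  end-of-association occupancy fractions:\n")
  for (j in seq_along(fr))
    cat(sprintf("    %-10s %.3f\n", names(fr)[j], fr[j]))
  invisible(x)
}

#' Per-analyte occupancy fractions at a time point
#'
#' Fraction of the total bound response contributed by each analyte at time
#' `t` on the combined assay clock (association start = 0; dissociation
#' spans `t_assoc` to `t_assoc + t_dissoc`). The end-of-association value
#' (`t = t_assoc`) is what the avidity-binning fractions estimate.
#'
#' @param sim A `competing_sim` from [simulate_competing()].
#' @param t Time in seconds within the simulated range.
#' @return Named numeric vector of fractions summing to 1.
#' @export
occupancy_fractions <- function(sim, t) {
  stopifnot(inherits(sim, "competing_sim"))
  if (t < 0 || t > sim$t_assoc + sim$t_dissoc + 1e-9)
    stop("'t' outside the simulated range [0, ",
         sim$t_assoc + sim$t_dissoc, "] s", call. = FALSE)
  if (t <= sim$t_assoc) {
    times <- sim$assoc$times; comp <- sim$assoc$components; tt <- t
  } else {
    times <- sim$dissoc$times; comp <- sim$dissoc$components
    tt <- t - sim$t_assoc
  }
  vals <- vapply(seq_len(ncol(comp)), function(j)
    stats::approx(times, comp[, j], xout = tt)$y, numeric(1L))
  total <- sum(vals)
  if (total <= 0)
    stop("total bound response is zero at t = ", t, " s", call. = FALSE)
  stats::setNames(vals / total, colnames(comp))
}

#' Equilibrium occupancy ratio of a two-analyte competition
#'
#' At equilibrium the occupancy ratio of two analytes competing for one
#' ligand is set purely by their concentrations relative to their K_D:
#' \eqn{(C_1/K_{D,1}) / (C_2/K_{D,2})}. Useful as a closed-form check on
#' long simulations.
#'
#' @param sys A [competing_system] with exactly two analytes, both at
#'   positive concentration.
#' @return The dimensionless occupancy ratio analyte1 : analyte2.
#' @export
equilibrium_occupancy_ratio <- function(sys) {
  stopifnot(inherits(sys, "competing_system"))
  if (length(sys$ka) != 2L)
    stop("exactly two analytes required", call. = FALSE)
  if (any(sys$conc <= 0))
    stop("both concentrations must be positive", call. = FALSE)
  kD <- binding_KD(sys$ka, sys$kd)
  (sys$conc[1L] / kD[1L]) / (sys$conc[2L] / kD[2L])
}

#' Convert a competing-analyte simulation to sensorgrams
#'
#' Returns the total trace as one [sensorgram] plus one per component
#' (sample ids `"<label>__component"`), ready for [write_sensorgrams()].
#'
#' @param sim A `competing_sim`.
#' @param sample_id Sample id for the total trace.
#' @param unit Response unit label.
#' @return A list of [sensorgram] objects (total first).
#' @export
competing_sim_sensorgrams <- function(sim, sample_id = "mixture",
                                      unit = "nm") {
  stopifnot(inherits(sim, "competing_sim"))
  mk <- function(assoc_y, dissoc_y, id) {
    sensorgram(list(
      association = timecourse(sim$assoc$times, assoc_y, unit),
      dissociation = timecourse(sim$dissoc$times, dissoc_y, unit)),
      sample_id = id)
  }
  out <- list(mk(sim$assoc$total, sim$dissoc$total, sample_id))
  for (j in seq_along(sim$system$labels)) {
    lab <- paste0(sim$system$labels[j], "__component")
    out[[j + 1L]] <- mk(sim$assoc$components[, j],
                        sim$dissoc$components[, j], lab)
  }
  out
}
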