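#' Control parameters for avidity-binning fits
#'
#' Collects every tunable of the sum-of-exponentials fitting and
#' model-order selection. Defaults are chosen for BLI/SPR dissociation
#' phases of a few hundred seconds sampled at ~1-5 Hz.
#'
#' @param max_components Largest number of exponential components tried.
#' @param aic `"aic"` or `"aicc"` (small-sample corrected) for model-order
#'   selection.
#' @param include_r_inf Add a constant term for non-dissociating residual
#'   signal. It counts as a parameter in the AIC penalty and is excluded
#'   from fraction normalization.
#' @param kd_bounds Lower/upper bounds on dissociation rate constants, 1/s.
#' @param multistart Number of screened starting points refined by full
#'   nonlinear least squares per model order.
#' @param seed Integer seed recorded with results and used by
#'   [simulate.paart()]; the fit itself is deterministic.
#' @param tol Relative convergence tolerance on the residual sum of squares.
#' @param min_points_per_param Minimum data points required per fitted
#'   parameter.
#' @param report_fraction_threshold Default fraction below which a component
#'   is not counted by [count_components()].
#' @return A list of class `"paart_control"`.
#' @export
paart_control <- function(max_components = 4L,
                          aic = c("aic", "aicc"),
                          include_r_inf = FALSE,
                          kd_bounds = c(1e-6, 1),
                          multistart = 24L,
                          seed = 1L,
                          tol = 1e-10,
                          min_points_per_param = 10L,
                          report_fraction_threshold = 0.05) {
  aic <- match.arg(aic)
  stopifnot(max_components >= 1L, length(kd_bounds) == 2L,
            kd_bounds[1L] > 0, kd_bounds[1L] < kd_bounds[2L],
            multistart >= 1L, tol > 0, min_points_per_param >= 1L,
            report_fraction_threshold >= 0, report_fraction_threshold <= 1)
  structure(list(max_components = as.integer(max_components), aic = aic,
                 include_r_inf = isTRUE(include_r_inf),
                 kd_bounds = as.numeric(kd_bounds),
                 multistart = as.integer(multistart),
                 seed = as.integer(seed), tol = tol,
                 min_points_per_param = as.integer(min_points_per_param),
                 report_fraction_threshold = report_fraction_threshold),
            class = "paart_control")
}

#' Akaike information criterion for least-squares fits
#'
#' Gaussian-likelihood form for a least-squares fit:
#' \deqn{AIC = n \ln(RSS/n) + 2K}
#' with `K = k_params + 1` (the noise variance is a fitted parameter). The
#' small-sample correction adds `2K(K+1)/(n - K - 1)`.
#'
#' @param rss Residual sum of squares (> 0).
#' @param n_obs Number of observations.
#' @param k_params Number of fitted model parameters (excluding the noise
#'   variance).
#' @param variant `"aic"` or `"aicc"`.
#' @return The criterion value (smaller is better).
#' @examples
#' aic_ls(1.0, 100, 2)  # 100 * log(0.01) + 6
#' @export
aic_ls <- function(rss, n_obs, k_params, variant = c("aic", "aicc")) {
  variant <- match.arg(variant)
  if (rss <= 0) stop("'rss' must be positive", call. = FALSE)
  k_tot <- k_params + 1
  if (n_obs <= k_tot + 1)
    stop("need n_obs > k_params + 2", call. = FALSE)
  out <- n_obs * log(rss / n_obs) + 2 * k_tot
  if (variant == "aicc")
    out <- out + 2 * k_tot * (k_tot + 1) / (n_obs - k_tot - 1)
  out
}

# Log-spaced kd seed grid covering the rates the window can resolve:
# from ~1/(10 * span) (barely-decaying) to ~10/dt (decayed within a few
# samples), clipped to the configured bounds.
.kd_seed_grid <- function(times, bounds, size = 10L) {
  span <- max(times) - min(times)
  dt_min <- min(diff(times))
  lo <- max(bounds[1L], 1 / (10 * span))
  hi <- min(bounds[2L], 10 / dt_min)
  if (hi <= lo) { lo <- bounds[1L]; hi <- bounds[2L] }
  exp(seq(log(lo), log(hi), length.out = size))
}

# Non-negative least squares on precomputed normal equations (tiny systems:
# iteratively drop the most negative coefficient).
.nnls_normal <- function(G, b) {
  p <- length(b)
  active <- rep(TRUE, p)
  a <- numeric(p)
  for (it in seq_len(p + 1L)) {
    idx <- which(active)
    if (!length(idx)) break
    sol <- tryCatch(solve(G[idx, idx, drop = FALSE], b[idx]),
                    error = function(e) NULL)
    if (is.null(sol)) { # singular subset: ridge-stabilize
      sol <- solve(G[idx, idx, drop = FALSE] +
                     diag(1e-10 * max(diag(G)[idx]), length(idx)), b[idx])
    }
    if (all(sol >= -1e-12)) { a[idx] <- pmax(sol, 0); break }
    active[idx[which.min(sol)]] <- FALSE
  }
  a
}

# Joint Levenberg-Marquardt refinement of (log kd, alpha, [r_inf]).
.refine_sumexp <- function(times, y, kd0, alpha0, r_inf0, control) {
  n <- length(kd0)
  lb <- log(control$kd_bounds)
  include_ri <- control$include_r_inf
  par0 <- c(pmin(pmax(log(kd0), lb[1L]), lb[2L]),
            pmax(alpha0, 1e-8 * max(abs(y))),
            if (include_ri) max(r_inf0, 0))
  lower <- c(rep(lb[1L], n), rep(0, n), if (include_ri) 0)
  upper <- c(rep(lb[2L], n), rep(Inf, n), if (include_ri) Inf)
  resid_fn <- function(par) {
    k <- exp(par[seq_len(n)]); a <- par[n + seq_len(n)]
    m <- drop(exp(-outer(times, k)) %*% a)
    if (include_ri) m <- m + par[2L * n + 1L]
    m - y
  }
  jac_fn <- function(par) {
    k <- exp(par[seq_len(n)]); a <- par[n + seq_len(n)]
    E <- exp(-outer(times, k))
    J <- cbind(E * rep(-a * k, each = length(times)) * times, E)
    if (include_ri) J <- cbind(J, 1)
    J
  }
  fit <- tryCatch(
    suppressWarnings( # convergence status is read from fit$info instead
      minpack.lm::nls.lm(par = par0, lower = lower, upper = upper,
                         fn = resid_fn, jac = jac_fn,
                         control = minpack.lm::nls.lm.control(
                           ftol = control$tol, ptol = 1e-12,
                           maxiter = 200))),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  par <- fit$par
  list(kd = exp(par[seq_len(n)]), alpha = par[n + seq_len(n)],
       r_inf = if (include_ri) par[2L * n + 1L] else 0,
       rss = sum(resid_fn(par)^2),
       converged = fit$info %in% c(1L, 2L, 3L, 4L))
}

#' Fit a fixed-order sum of exponentials to a dissociation phase
#'
#' Least-squares fit of `n` exponential components (plus an optional
#' constant) to a windowed dissociation phase. Because exponential fitting
#' is highly initialization-sensitive, a variable-projection multistart is
#' used: candidate rate constants are taken as size-`n` subsets of a
#' log-spaced seed grid, amplitudes are solved by non-negative linear least
#' squares for each subset, and the best-screening subsets are refined
#' jointly by Levenberg-Marquardt under bound constraints (kd within
#' `kd_bounds`, amplitudes non-negative). Ties break by lowest residual sum
#' of squares, then lowest seed index; the procedure is deterministic.
#'
#' @param phase A [dissociation_phase] (see [dissociation_window()]).
#' @param n Number of exponential components (>= 1).
#' @param control A [paart_control()] list.
#' @return An object of class `"sumexp_fit"` with elements `kd`, `alpha`
#'   (ascending kd), `r_inf`, standard errors, `fraction`, `rss`,
#'   `chi2` (= rss), `aic`, `converged`, `restarts_used`, `fitted`,
#'   `warnings`.
#' @export
fit_sum_exp <- function(phase, n, control = paart_control()) {
  stopifnot(inherits(phase, "timecourse"), n >= 1L)
  times <- phase$times - phase$times[1L]
  y <- phase$responses
  npts <- length(y)
  k_params <- 2L * n + as.integer(control$include_r_inf)
  if (npts < control$min_points_per_param * k_params)
    stop("only ", npts, " points for ", k_params, " parameters; need >= ",
         control$min_points_per_param * k_params, call. = FALSE)
  if (y[1L] <= 0)
    stop("non-positive response at the window start; nothing to fit",
         call. = FALSE)
  warnings <- character()

  grid <- .kd_seed_grid(times, control$kd_bounds)
  E <- exp(-outer(times, grid))
  basis <- if (control$include_r_inf) cbind(E, 1) else E
  G <- crossprod(basis)
  gy <- drop(crossprod(basis, y))
  yty <- sum(y * y)
  combos <- utils::combn(length(grid), n)
  ri_col <- ncol(basis)
  screen <- apply(combos, 2L, function(S) {
    cols <- if (control$include_r_inf) c(S, ri_col) else S
    a <- .nnls_normal(G[cols, cols, drop = FALSE], gy[cols])
    rss <- yty - 2 * sum(a * gy[cols]) +
      drop(t(a) %*% G[cols, cols, drop = FALSE] %*% a)
    list(rss = max(rss, 0), alpha = a)
  })
  ord <- order(vapply(screen, `[[`, numeric(1L), "rss"))

  best <- NULL
  used <- 0L
  for (i in ord[seq_len(min(control$multistart, length(ord)))]) {
    S <- combos[, i]
    a_full <- screen[[i]]$alpha
    ri0 <- if (control$include_r_inf) a_full[length(a_full)] else 0
    ref <- .refine_sumexp(times, y, grid[S], a_full[seq_len(n)], ri0, control)
    used <- used + 1L
    if (is.null(ref)) next
    if (is.null(best) || ref$rss < best$rss * (1 - 1e-12)) best <- ref
    if (!is.null(best) && best$rss <= control$tol * yty * 1e-4) break
  }
  if (is.null(best)) {
    return(structure(list(n = n, kd = rep(NA_real_, n),
                          alpha = rep(NA_real_, n), r_inf = NA_real_,
                          se_kd = rep(NA_real_, n),
                          se_alpha = rep(NA_real_, n), se_r_inf = NA_real_,
                          fraction = rep(NA_real_, n), rss = Inf, chi2 = Inf,
                          aic = Inf, converged = FALSE, restarts_used = used,
                          fitted = rep(NA_real_, npts), npts = npts,
                          warnings = "no restart converged"),
                     class = "sumexp_fit"))
  }
  o <- order(best$kd)
  kd <- best$kd[o]; alpha <- best$alpha[o]
  if (any(kd <= control$kd_bounds[1L] * 1.0001) ||
      any(kd >= control$kd_bounds[2L] * 0.9999)) {
    warnings <- c(warnings, "kd pinned at a configured bound")
    warning("kd estimate pinned at a configured bound", call. = FALSE)
  }
  if (n > 1L && any(kd[-1L] / kd[-n] < 2)) {
    warnings <- c(warnings,
                  "components closer than 2-fold in kd; poorly separated")
    warning("fitted components closer than 2-fold in kd; ",
            "estimates may be poorly separated", call. = FALSE)
  }
  se <- .sumexp_se(times, kd, alpha, best$r_inf, best$rss,
                   control$include_r_inf, npts)
  warnings <- c(warnings, se$warnings)
  rss <- max(best$rss, .Machine$double.xmin)
  fitted <- sum_exp_response(times, alpha, kd, best$r_inf)
  structure(list(n = n, kd = kd, alpha = alpha, r_inf = best$r_inf,
                 se_kd = se$se_kd, se_alpha = se$se_alpha,
                 se_r_inf = se$se_r_inf,
                 fraction = if (sum(alpha) > 0) alpha / sum(alpha)
                            else rep(NA_real_, n),
                 rss = rss, chi2 = rss,
                 aic = if (best$converged)
                   aic_ls(rss, npts, k_params, control$aic) else Inf,
                 converged = best$converged, restarts_used = used,
                 fitted = fitted, npts = npts, warnings = warnings),
            class = "sumexp_fit")
}

# Linearized (Gauss-Newton) standard errors at the optimum:
# cov = sigma^2 (J'J)^-1 with sigma^2 = rss / (n_obs - k).
.sumexp_se <- function(times, kd, alpha, r_inf, rss, include_ri, npts) {
  n <- length(kd)
  E <- exp(-outer(times, kd))
  J <- cbind(E * rep(-alpha, each = npts) * times, E)
  if (include_ri) J <- cbind(J, 1)
  k <- ncol(J)
  na_out <- list(se_kd = rep(NA_real_, n), se_alpha = rep(NA_real_, n),
                 se_r_inf = NA_real_)
  JtJ <- crossprod(J)
  # assess conditioning on the unit-scaled (correlation-like) matrix so
  # that disparate parameter units do not masquerade as collinearity
  d <- sqrt(diag(JtJ))
  if (any(d <= 0)) {
    warning("ill-conditioned Jacobian; standard errors unavailable",
            call. = FALSE)
    return(c(na_out, list(warnings = "ill-conditioned")))
  }
  Cm <- JtJ / tcrossprod(d)
  rc <- tryCatch(rcond(Cm), error = function(e) 0)
  if (!is.finite(rc) || rc < 1e-10) {
    warning("ill-conditioned Jacobian; standard errors unavailable",
            call. = FALSE)
    return(c(na_out, list(warnings = "ill-conditioned")))
  }
  sigma2 <- rss / max(npts - k, 1L)
  cv <- tryCatch(solve(Cm) * sigma2 / tcrossprod(d),
                 error = function(e) NULL)
  if (is.null(cv)) {
    warning("ill-conditioned Jacobian; standard errors unavailable",
            call. = FALSE)
    return(c(na_out, list(warnings = "ill-conditioned")))
  }
  se <- sqrt(pmax(diag(cv), 0))
  list(se_kd = se[seq_len(n)], se_alpha = se[n + seq_len(n)],
       se_r_inf = if (include_ri) se[2L * n + 1L] else NA_real_,
       warnings = character())
}

#' @export
print.sumexp_fit <- function(x, ...) {
  cat(sprintf("<sum-of-exponentials fit> n = %d, rss = %.4g, AIC = %.4g%s\n",
              x$n, x$rss, x$aic,
              if (!x$converged) " (not converged)" else ""))
  for (i in seq_len(x$n))
    cat(sprintf("  kd %.4g 1/s (se %.2g), alpha %.4g (fraction %.3f)\n",
                x$kd[i], x$se_kd[i], x$alpha[i], x$fraction[i]))
  invisible(x)
}

#' Fractional contributions of exponential components
#'
#' \eqn{f_i = \alpha_i / \sum_j \alpha_j}: each component's share of the
#' total bound response at the start of the fitted dissociation window (its
#' antigen-occupancy share there — not its abundance in solution). Any
#' constant `r_inf` term is excluded from the normalization.
#'
#' @param alpha Non-negative component amplitudes.
#' @return Fractions summing to 1.
#' @examples
#' compute_fractions(c(0.4, 0.1))  # 0.8 0.2
#' @export
compute_fractions <- function(alpha) {
  if (any(alpha < 0)) stop("'alpha' must be non-negative", call. = FALSE)
  s <- sum(alpha)
  if (s <= 0) stop("all amplitudes are zero", call. = FALSE)
  alpha / s
}
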