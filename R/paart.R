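#' Avidity binning of a dissociation phase by parsimonious
#' multi-exponential fitting
#'
#' Fits a biosensor dissociation phase to sums of exponentials of
#' increasing order and selects the minimal number of antibody avidity
#' components by the Akaike information criterion. Order `n = 1, 2, ...` is
#' fit sequentially ([fit_sum_exp()]); the loop stops as soon as the
#' `n + 1`-component model has a larger AIC than the `n`-component model
#' (or `max_components` is reached, or too few points remain for more
#' parameters), and the candidate with the minimal AIC among all fitted
#' orders is returned. Each component is reported with its dissociation
#' rate constant, standard error and fractional contribution to the bound
#' response at the window start.
#'
#' @param phase A [dissociation_phase], or a [sensorgram] (its dissociation
#'   phase is windowed via [dissociation_window()] with `t_start`/`t_end`).
#' @param control A [paart_control()] list of fitting options.
#' @param t_start,t_end Analysis window used when `phase` is a sensorgram.
#' @return An object of class `"paart"` with components table
#'   (`kd, se_kd, alpha, se_alpha, fraction`, ascending kd), `selected_n`,
#'   `r_inf`, `chi2` (residual sum of squares over the window),
#'   `aic_trace`, `residuals`, `fitted`, the analysis `window`, the
#'   `control` used and accumulated `warnings`. Methods: `print`,
#'   `summary`, `coef`, `predict`, `fitted`, `residuals`, `plot`,
#'   `simulate`.
#' @examples
#' ph <- simulate_polyclonal_dissociation(alpha = c(0.4, 0.1),
#'                                        kd = c(5.6e-5, 3.7e-2),
#'                                        sigma = 0)$phase
#' fit <- paart(ph)
#' fit
#' @export
paart <- function(phase, control = paart_control(), t_start = 5,
                  t_end = NULL) {
  if (inherits(phase, "sensorgram"))
    phase <- dissociation_window(phase, t_start = t_start, t_end = t_end)
  stopifnot(inherits(phase, "timecourse"))
  window <- if (inherits(phase, "dissociation_phase")) phase$window
            else c(0, max(phase$times) - phase$times[1L])

  candidates <- list()
  n <- 1L
  repeat {
    # warnings raised while probing candidate orders are muffled here and
    # re-emitted below only for the selected model
    cand <- tryCatch(
      withCallingHandlers(fit_sum_exp(phase, n, control),
                          warning = function(w) invokeRestart("muffleWarning")),
      error = function(e) e)
    if (inherits(cand, "error")) {
      if (n == 1L) stop(conditionMessage(cand), call. = FALSE)
      break # not enough points for a larger model: stop growing
    }
    candidates[[n]] <- cand
    if (n > 1L && cand$aic > candidates[[n - 1L]]$aic) break
    if (n >= control$max_components) break
    # numerically exact fit: any further "improvement" would only chase
    # floating-point noise, where the Gaussian AIC is meaningless
    if (is.finite(cand$rss) &&
        cand$rss <= 1e-16 * sum(phase$responses^2)) break
    n <- n + 1L
  }
  aics <- vapply(candidates, `[[`, numeric(1L), "aic")
  if (!any(is.finite(aics)))
    stop("no candidate model converged", call. = FALSE)
  sel <- which.min(aics) # ties resolve to the smaller order
  best <- candidates[[sel]]
  for (w in best$warnings) warning(w, call. = FALSE)
  comp <- data.frame(kd = best$kd, se_kd = best$se_kd, alpha = best$alpha,
                     se_alpha = best$se_alpha, fraction = best$fraction)
  structure(list(
    selected_n = best$n,
    components = comp,
    r_inf = best$r_inf, se_r_inf = best$se_r_inf,
    rss = best$rss, chi2 = best$chi2, aic = best$aic,
    aic_trace = data.frame(
      n = vapply(candidates, `[[`, integer(1L), "n"),
      aic = aics,
      rss = vapply(candidates, `[[`, numeric(1L), "rss"),
      converged = vapply(candidates, `[[`, logical(1L), "converged"),
      restarts_used = vapply(candidates, `[[`, integer(1L),
                             "restarts_used")),
    fitted_values = best$fitted,
    residuals = phase$responses - best$fitted,
    phase = phase, window = window, control = control,
    warnings = best$warnings,
    candidates = candidates),
    class = "paart")
}

#' Standard 1:1 Langmuir dissociation fit
#'
#' The conventional single-exponential ("standard") analysis of a
#' dissociation phase, provided as the named baseline for side-by-side
#' comparison with the multi-component analysis. On heterogeneous samples
#' its single kd is weighted toward the slower-dissociating antibodies and
#' its residuals reveal the model inadequacy.
#'
#' @inheritParams paart
#' @return A `"paart"` object with `selected_n = 1` (no model selection).
#' @export
fit_langmuir_dissociation <- function(phase, control = paart_control(),
                                      t_start = 5, t_end = NULL) {
  control$max_components <- 1L
  paart(phase, control = control, t_start = t_start, t_end = t_end)
}

#' Count antibody components above a reporting threshold
#'
#' Components whose fractional contribution falls below `min_fraction`
#' (default 5%) are typically not counted when summarizing how many avidity
#' components a sample shows.
#'
#' @param fit A `"paart"` object.
#' @param min_fraction Minimum fraction for a component to count.
#' @return Integer number of components with `fraction >= min_fraction`.
#' @export
count_components <- function(fit,
                             min_fraction = fit$control$report_fraction_threshold) {
  stopifnot(inherits(fit, "paart"))
  sum(fit$components$fraction >= min_fraction)
}

#' @export
print.paart <- function(x, digits = 4, ...) {
  cat(sprintf(
    "Avidity binning fit: %d component(s) selected (AIC), window %g-%g s\n",
    x$selected_n, x$window[1L], x$window[2L]))
  comp <- x$components
  for (i in seq_len(nrow(comp)))
    cat(sprintf("  component %d: kd = %.*g 1/s (se %.2g), fraction = %.3f\n",
                i, digits, comp$kd[i], comp$se_kd[i], comp$fraction[i]))
  if (x$control$include_r_inf)
    cat(sprintf("  r_inf = %.4g (se %.2g)\n", x$r_inf, x$se_r_inf))
  cat(sprintf("  chi^2 (RSS) = %.4g over %d points\n", x$chi2,
              length(x$residuals)))
  if (length(x$warnings))
    cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' @export
summary.paart <- function(object, ...) {
  structure(list(fit = object), class = "summary.paart")
}

#' @export
print.summary.paart <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\nModel-order trace:\n")
  print(f$aic_trace, row.names = FALSE)
  cat(sprintf("\nResiduals: min %.3g, median %.3g, max %.3g\n",
              min(f$residuals), stats::median(f$residuals),
              max(f$residuals)))
  invisible(x)
}

#' @export
coef.paart <- function(object, ...) {
  comp <- object$components
  out <- as.matrix(comp[, c("kd", "se_kd", "alpha", "se_alpha", "fraction")])
  rownames(out) <- paste0("component", seq_len(nrow(comp)))
  out
}

#' @export
fitted.paart <- function(object, ...) object$fitted_values

#' @export
residuals.paart <- function(object, ...) object$residuals

#' Predict responses from a fitted avidity-binning model
#'
#' @param object A `"paart"` fit.
#' @param times Times in seconds from the window start; defaults to the
#'   fitted time grid.
#' @param ... Unused.
#' @return Predicted responses.
#' @export
predict.paart <- function(object, times = NULL, ...) {
  if (is.null(times)) times <- object$phase$times
  sum_exp_response(times, object$components$alpha, object$components$kd,
                   object$r_inf)
}

#' Simulate noisy replicates from a fitted model
#'
#' Draws `nsim` synthetic dissociation traces from the fitted
#' multi-exponential model with i.i.d. Gaussian noise at the residual
#' standard deviation (or a supplied `sigma`).
#'
#' @param object A `"paart"` fit.
#' @param nsim Number of replicates.
#' @param seed Integer seed (default: the seed recorded in the control).
#' @param sigma Noise standard deviation; default is estimated from the
#'   fit residuals.
#' @param ... Unused.
#' @return A matrix with one column per replicate.
#' @export
simulate.paart <- function(object, nsim = 1, seed = object$control$seed,
                           sigma = NULL, ...) {
  if (is.null(sigma)) {
    k <- 2L * object$selected_n + as.integer(object$control$include_r_inf)
    sigma <- sqrt(object$rss / max(length(object$residuals) - k, 1L))
  }
  mu <- object$fitted_values
  with_seed(seed, {
    matrix(stats::rnorm(length(mu) * nsim, mean = mu, sd = sigma),
           ncol = nsim)
  })
}

#' Diagnostic plot: fit overlay and residuals
#'
#' Two-panel base-graphics plot: the dissociation data with the selected
#' model overlaid, and the fit residuals (structure in the residuals is the
#' classic sign that more components are needed).
#'
#' @param x A `"paart"` fit.
#' @param ... Passed to the top-panel `plot()`.
#' @return `x`, invisibly.
#' @export
plot.paart <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  t <- x$phase$times
  graphics::plot(t, x$phase$responses, type = "l", col = "grey40",
                 xlab = "time (s)",
                 ylab = paste0("response (", x$phase$unit, ")"),
                 main = sprintf("%d-component dissociation fit",
                                x$selected_n), ...)
  graphics::lines(t, x$fitted_values, col = "red", lwd = 2)
  graphics::plot(t, x$residuals, type = "l", col = "grey40",
                 xlab = "time (s)", ylab = "residual")
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}
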