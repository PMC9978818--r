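# Global kinetics fits used for validation: the 1:1 Langmuir model fit
# across a concentration series, and the heterogeneous-analyte (competing
# reactions) decomposition of mixture sensorgrams with known concentrations.

# Unit-capacity (rmax = 1) 1:1 model over one sensorgram's association +
# dissociation grids; the full model is rmax * this, so rmax is profiled
# linearly during screening and fitting.
.langmuir_unit_curve <- function(ka, kd, conc, t_assoc, t_dissoc) {
  a <- langmuir_association(t_assoc, ka, kd, conc, 1)
  r_end <- a[length(a)]
  c(a, r_end * exp(-kd * t_dissoc))
}

.series_unit_curve <- function(ka, kd, series) {
  unlist(lapply(series, function(s)
    .langmuir_unit_curve(ka, kd, s$analyte_conc,
                         s$phases$association$times -
                           s$phases$association$times[1L],
                         s$phases$dissociation$times -
                           s$phases$dissociation$times[1L])))
}

# Central-difference Jacobian of a residual function.
.num_jacobian <- function(fn, par, h_rel = 1e-6) {
  r0 <- fn(par)
  J <- matrix(0, length(r0), length(par))
  for (j in seq_along(par)) {
    h <- h_rel * max(abs(par[j]), 1e-8)
    pp <- par; pp[j] <- pp[j] + h
    pm <- par; pm[j] <- pm[j] - h
    J[, j] <- (fn(pp) - fn(pm)) / (2 * h)
  }
  J
}

#' Global 1:1 Langmuir fit over a concentration series
#'
#' Fits a single set of rate constants (ka, kd) and a shared surface
#' capacity rmax to the pooled association + dissociation phases of
#' sensorgrams recorded at known analyte concentrations — the standard
#' global kinetics analysis for a monoclonal analyte. Screening over a
#' log-spaced (ka, kd) grid with rmax profiled linearly is followed by
#' joint Levenberg-Marquardt refinement.
#'
#' @param series A list of [sensorgram]s, each with association and
#'   dissociation phases and a declared `analyte_conc` (molar).
#' @param control A [paart_control()]; `kd_bounds` and `tol` are honored.
#' @param ka_bounds Association rate bounds, 1/(M s).
#' @return An object of class `"langmuir_global_fit"`: `ka`, `kd`, `rmax`,
#'   derived `KD`, standard errors (`se_ka`, `se_kd`, `se_rmax`), `rss`
#'   and per-sensorgram `residuals`.
#' @export
fit_global_langmuir <- function(series, control = paart_control(),
                                ka_bounds = c(1e3, 1e7)) {
  if (inherits(series, "sensorgram")) series <- list(series)
  stopifnot(length(series) >= 1L)
  for (s in series) {
    stopifnot(inherits(s, "sensorgram"))
    if (is.null(s$phases$association) || is.null(s$phases$dissociation))
      stop("every sensorgram needs association and dissociation phases",
           call. = FALSE)
    if (is.na(s$analyte_conc) || s$analyte_conc <= 0)
      stop("every sensorgram needs a declared positive analyte ",
           "concentration", call. = FALSE)
  }
  y <- unlist(lapply(series, function(s)
    c(s$phases$association$responses, s$phases$dissociation$responses)))
  if (length(series) == 1L) {
    d <- series[[1L]]$phases$dissociation$responses
    if (abs(d[length(d)] - d[1L]) < 1e-6 * max(abs(d), 1e-12))
      stop("single concentration with no dissociation signal: ka and kd ",
           "are not jointly identifiable", call. = FALSE)
  }
  ka_grid <- exp(seq(log(ka_bounds[1L]), log(ka_bounds[2L]), length.out = 7))
  kd_grid <- exp(seq(log(control$kd_bounds[1L]), log(control$kd_bounds[2L]),
                     length.out = 7))
  grid <- expand.grid(ka = ka_grid, kd = kd_grid)
  screened <- apply(grid, 1L, function(g) {
    u <- .series_unit_curve(g[["ka"]], g[["kd"]], series)
    rmax <- max(sum(u * y) / sum(u * u), 0)
    sum((rmax * u - y)^2)
  })
  lb <- c(log(ka_bounds[1L]), log(control$kd_bounds[1L]), log(1e-8))
  ub <- c(log(ka_bounds[2L]), log(control$kd_bounds[2L]), log(1e6))
  resid_fn <- function(par) {
    u <- .series_unit_curve(exp(par[1L]), exp(par[2L]), series)
    exp(par[3L]) * u - y
  }
  best <- NULL
  for (i in order(screened)[seq_len(min(6L, nrow(grid)))]) {
    u <- .series_unit_curve(grid$ka[i], grid$kd[i], series)
    rmax0 <- max(sum(u * y) / sum(u * u), 1e-6)
    p0 <- pmin(pmax(c(log(grid$ka[i]), log(grid$kd[i]), log(rmax0)), lb), ub)
    fit <- tryCatch(
      suppressWarnings(
        minpack.lm::nls.lm(par = p0, lower = lb, upper = ub, fn = resid_fn,
                           control = minpack.lm::nls.lm.control(
                             ftol = control$tol, ptol = 1e-12,
                             maxiter = 300))),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(resid_fn(fit$par)^2)
    if (is.null(best) || rss < best$rss * (1 - 1e-12))
      best <- list(par = fit$par, rss = rss)
  }
  if (is.null(best)) stop("global 1:1 fit failed to converge", call. = FALSE)
  par <- best$par
  ka <- exp(par[1L]); kd <- exp(par[2L]); rmax <- exp(par[3L])
  J <- .num_jacobian(resid_fn, par)
  sigma2 <- best$rss / max(length(y) - 3L, 1L)
  se_log <- tryCatch(sqrt(pmax(diag(solve(crossprod(J)) * sigma2), 0)),
                     error = function(e) rep(NA_real_, 3L))
  res <- resid_fn(par)
  lens <- vapply(series, function(s)
    length(s$phases$association$times) + length(s$phases$dissociation$times),
    integer(1L))
  structure(list(ka = ka, kd = kd, rmax = rmax, KD = binding_KD(ka, kd),
                 se_ka = ka * se_log[1L], se_kd = kd * se_log[2L],
                 se_rmax = rmax * se_log[3L], rss = best$rss,
                 residuals = split(res, rep(seq_along(series), lens)),
                 n_curves = length(series)),
            class = "langmuir_global_fit")
}

#' @export
print.langmuir_global_fit <- function(x, ...) {
  cat(sprintf("Global 1:1 Langmuir fit over %d curve(s)\n", x$n_curves))
  cat(sprintf("  ka = %.4g 1/(M s) (se %.2g)\n", x$ka, x$se_ka))
  cat(sprintf("  kd = %.4g 1/s (se %.2g)\n", x$kd, x$se_kd))
  cat(sprintf("  rmax = %.4g, K_D = %.4g M (%.3g nM)\n",
              x$rmax, x$KD, x$KD * 1e9))
  cat(sprintf("  rss = %.4g\n", x$rss))
  invisible(x)
}

# Unit-capacity competing-model curve over the sensorgram's grids; linear
# in rmax (the whole solution scales with the forcing).
.competing_unit_curve <- function(ka, kd, conc, mw, t_assoc, t_dissoc) {
  sys <- competing_system(ka = ka, kd = kd, conc = conc, mw = mw, rmax = 1)
  m <- .competing_matrices(sys)
  comp_a <- .solve_linear_binding(m$A, m$b, numeric(length(ka)), t_assoc)
  r_end <- comp_a[nrow(comp_a), ]
  comp_d <- exp(-outer(t_dissoc, kd)) * rep(r_end, each = length(t_dissoc))
  list(total = c(rowSums(comp_a), rowSums(comp_d)),
       comp_a = comp_a, comp_d = comp_d)
}

#' Heterogeneous-analyte (competing reactions) fit of a mixture sensorgram
#'
#' Simultaneously fits the association and dissociation phases of a
#' two-analyte mixture at known molar concentrations to the competing
#' reactions mass-action model, estimating (ka, kd) per analyte plus a
#' shared rmax, and returning the dissected per-analyte component
#' time-courses. This is the reference analysis the dissociation-only
#' avidity binning is validated against: it requires known concentrations,
#' which polyclonal samples do not have.
#'
#' The dissociation phase is first avidity-binned ([paart()]) to seed the
#' two kd values; ka seeds come from a log-spaced grid, and the best
#' screening combinations are refined by Levenberg-Marquardt with rmax
#' profiled linearly.
#'
#' @param s A [sensorgram] with association and dissociation phases.
#' @param conc Length-2 vector of molar analyte concentrations. If one is
#'   zero the fit degenerates to a single-analyte 1:1 fit.
#' @param control A [paart_control()].
#' @param ka_bounds Association rate bounds for seeding and fitting.
#' @param labels Analyte labels.
#' @param mw Optional molecular weights (response-scale coupling; default
#'   equal).
#' @param kinetics_init Optional data.frame with columns `ka`, `kd`: one
#'   row of approximate known kinetics per analyte (e.g. from fitting each
#'   mAb alone). With equal molecular weights the total curve depends on
#'   the analytes only through the exchangeable pairs (ka x conc, kd), so
#'   which fitted pair belongs to which named analyte cannot be decided
#'   from the mixture data; `kinetics_init` resolves the labeling by
#'   nearest log-kd. Without it, the slower-dissociating pair is assigned
#'   to the first analyte.
#' @return An object of class `"competing_fit"`: `analytes` data.frame
#'   (`label, ka, kd, se_ka, se_kd, conc`), `rmax`, `rss`, component
#'   curves (`assoc_components`, `dissoc_components`), `fitted`,
#'   `residuals` and the end-of-association occupancy `shares`.
#' @export
fit_competing <- function(s, conc, control = paart_control(),
                          ka_bounds = c(1e3, 1e7), labels = NULL,
                          mw = NULL, kinetics_init = NULL) {
  stopifnot(inherits(s, "sensorgram"))
  if (length(conc) != 2L)
    stop("exactly two analyte concentrations required", call. = FALSE)
  if (any(is.na(conc)))
    stop("analyte concentrations unknown: the competing-reactions model ",
         "needs them; use paart() on the dissociation phase instead",
         call. = FALSE)
  if (is.null(s$phases$association) || is.null(s$phases$dissociation))
    stop("association and dissociation phases required", call. = FALSE)
  if (is.null(labels)) labels <- paste0("analyte", 1:2)
  if (is.null(mw)) mw <- c(1, 1)
  t_a <- s$phases$association$times - s$phases$association$times[1L]
  t_d <- s$phases$dissociation$times - s$phases$dissociation$times[1L]
  y <- c(s$phases$association$responses, s$phases$dissociation$responses)

  if (any(conc == 0)) {
    j <- which(conc > 0)
    if (!length(j)) stop("both concentrations are zero", call. = FALSE)
    s1 <- s; s1$analyte_conc <- conc[j]
    g <- fit_global_langmuir(list(s1), control, ka_bounds)
    ka <- kd <- se_ka <- se_kd <- rep(NA_real_, 2L)
    ka[j] <- g$ka; kd[j] <- g$kd; se_ka[j] <- g$se_ka; se_kd[j] <- g$se_kd
    uc <- .competing_unit_curve(c(g$ka, g$ka)[1:2], c(g$kd, g$kd)[1:2],
                                ifelse(conc > 0, conc, 0), mw, t_a, t_d)
    fitted <- g$rmax * uc$total
    return(structure(list(
      analytes = data.frame(label = labels, ka = ka, kd = kd,
                            se_ka = se_ka, se_kd = se_kd, conc = conc,
                            stringsAsFactors = FALSE),
      rmax = g$rmax, rss = g$rss,
      assoc_times = t_a, dissoc_times = t_d,
      assoc_components = g$rmax * uc$comp_a,
      dissoc_components = g$rmax * uc$comp_d,
      fitted = fitted, residuals = y - fitted,
      shares = stats::setNames(as.numeric(conc > 0), labels),
      degenerate = TRUE), class = "competing_fit"))
  }

  # kd seeds from dissociation-only avidity binning
  seed_ctrl <- control
  seed_ctrl$max_components <- 2L
  ph <- dissociation_window(s, t_start = 0, t_end = NULL)
  kd_seed <- tryCatch(paart(ph, seed_ctrl)$components$kd,
                      error = function(e) NULL)
  if (is.null(kd_seed) || length(kd_seed) < 2L)
    kd_seed <- exp(seq(log(control$kd_bounds[1L] * 10),
                       log(control$kd_bounds[2L] / 10), length.out = 2L))
  ka_grid <- exp(seq(log(ka_bounds[1L]), log(ka_bounds[2L]), length.out = 5))
  starts <- expand.grid(ka1 = ka_grid, ka2 = ka_grid, flip = c(FALSE, TRUE))
  screen <- vapply(seq_len(nrow(starts)), function(i) {
    kds <- if (starts$flip[i]) rev(kd_seed) else kd_seed
    u <- .competing_unit_curve(c(starts$ka1[i], starts$ka2[i]), kds, conc,
                               mw, t_a, t_d)$total
    rmax <- max(sum(u * y) / sum(u * u), 0)
    sum((rmax * u - y)^2)
  }, numeric(1L))
  lb <- c(rep(log(ka_bounds[1L]), 2L), rep(log(control$kd_bounds[1L]), 2L))
  ub <- c(rep(log(ka_bounds[2L]), 2L), rep(log(control$kd_bounds[2L]), 2L))
  resid_fn <- function(par) { # rmax profiled
    u <- .competing_unit_curve(exp(par[1:2]), exp(par[3:4]), conc, mw,
                               t_a, t_d)$total
    rmax <- max(sum(u * y) / sum(u * u), 0)
    rmax * u - y
  }
  best <- NULL
  for (i in order(screen)[seq_len(min(8L, nrow(starts)))]) {
    kds <- if (starts$flip[i]) rev(kd_seed) else kd_seed
    p0 <- pmin(pmax(log(c(starts$ka1[i], starts$ka2[i], kds)), lb), ub)
    fit <- tryCatch(
      suppressWarnings(
        minpack.lm::nls.lm(par = p0, lower = lb, upper = ub, fn = resid_fn,
                           control = minpack.lm::nls.lm.control(
                             ftol = control$tol, ptol = 1e-12,
                             maxiter = 300))),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(resid_fn(fit$par)^2)
    if (is.null(best) || rss < best$rss * (1 - 1e-12))
      best <- list(par = fit$par, rss = rss)
  }
  if (is.null(best))
    stop("competing-reactions fit failed to converge", call. = FALSE)
  par <- best$par
  ka <- exp(par[1:2]); kd <- exp(par[3:4])
  # With equal response weights the model depends on the analytes only
  # through the exchangeable pairs (ka * conc, kd): the swapped labeling
  # (with ka rescaled to keep ka * conc fixed) fits identically. Resolve
  # the labeling by supplied prior kinetics, else slow-kd analyte first.
  if (abs(mw[1L] - mw[2L]) < 1e-12 * mw[1L]) {
    a_pair <- ka * conc
    swap <- c(2L, 1L)
    pick_swap <- if (!is.null(kinetics_init)) {
      stopifnot(is.data.frame(kinetics_init), nrow(kinetics_init) == 2L,
                all(c("ka", "kd") %in% names(kinetics_init)))
      d_keep <- sum((log(kd) - log(kinetics_init$kd))^2)
      d_swap <- sum((log(kd[swap]) - log(kinetics_init$kd))^2)
      d_swap < d_keep
    } else kd[1L] > kd[2L]
    if (pick_swap) {
      kd <- kd[swap]
      ka <- a_pair[swap] / conc
      par <- c(log(ka), log(kd))
    }
  }
  u <- .competing_unit_curve(ka, kd, conc, mw, t_a, t_d)
  rmax <- max(sum(u$total * y) / sum(u$total * u$total), 0)
  # SEs over the full parameter set (log ka, log kd, rmax)
  full_resid <- function(p) {
    uu <- .competing_unit_curve(exp(p[1:2]), exp(p[3:4]), conc, mw,
                                t_a, t_d)$total
    p[5L] * uu - y
  }
  J <- .num_jacobian(full_resid, c(par, rmax))
  sigma2 <- best$rss / max(length(y) - 5L, 1L)
  se <- tryCatch(sqrt(pmax(diag(solve(crossprod(J)) * sigma2), 0)),
                 error = function(e) rep(NA_real_, 5L))
  fitted <- rmax * u$total
  r_end <- rmax * u$comp_a[nrow(u$comp_a), ]
  structure(list(
    analytes = data.frame(label = labels, ka = ka, kd = kd,
                          se_ka = ka * se[1:2], se_kd = kd * se[3:4],
                          conc = conc, stringsAsFactors = FALSE),
    rmax = rmax, se_rmax = se[5L], rss = best$rss,
    assoc_times = t_a, dissoc_times = t_d,
    assoc_components = rmax * u$comp_a,
    dissoc_components = rmax * u$comp_d,
    fitted = fitted, residuals = y - fitted,
    shares = stats::setNames(r_end / sum(r_end), labels),
    degenerate = FALSE), class = "competing_fit")
}

#' @export
print.competing_fit <- function(x, ...) {
  cat("Heterogeneous-analyte (competing reactions) fit\n")
  a <- x$analytes
  for (i in seq_len(nrow(a)))
    cat(sprintf(
      "  %-10s ka %.4g 1/(M s) (se %.2g), kd %.4g 1/s (se %.2g), conc %.3g M\n",
      a$label[i], a$ka[i], a$se_ka[i], a$kd[i], a$se_kd[i], a$conc[i]))
  cat(sprintf("  rmax = %.4g, rss = %.4g\n", x$rmax, x$rss))
  cat(sprintf("  end-of-association shares: %s\n",
              paste(sprintf("%s %.3f", names(x$shares), x$shares),
                    collapse = ", ")))
  invisible(x)
}
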