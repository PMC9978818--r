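# Batch analysis and machine-readable reporting.

#' Avidity-bin every sample in a tidy CSV or sensorgram list
#'
#' Runs [paart()] on the dissociation phase of each (sample, replicate)
#' independently — replicates are never averaged or auto-selected — and
#' collects the results. Per-sample failures are recorded rather than
#' aborting the batch.
#'
#' @param input Path to a tidy CSV (see [read_sensorgrams()]) or a list of
#'   [sensorgram]s.
#' @param t_start,t_end Dissociation analysis window in seconds.
#' @param control A [paart_control()].
#' @return An object of class `"paart_batch"`: a list of records with
#'   `sample_id`, `replicate`, `fit` (a `"paart"` object or `NULL`) and
#'   `error` (message or `NA`).
#' @export
paart_batch <- function(input, t_start = 5, t_end = NULL,
                        control = paart_control()) {
  sgs <- if (is.character(input)) read_sensorgrams(input) else input
  if (inherits(sgs, "sensorgram")) sgs <- list(sgs)
  records <- lapply(sgs, function(s) {
    fit <- tryCatch(paart(s, control = control, t_start = t_start,
                          t_end = t_end),
                    error = function(e) e)
    if (inherits(fit, "error"))
      list(sample_id = s$sample_id, replicate = s$replicate, fit = NULL,
           error = conditionMessage(fit))
    else
      list(sample_id = s$sample_id, replicate = s$replicate, fit = fit,
           error = NA_character_)
  })
  structure(list(records = records, control = control,
                 window = c(t_start, if (is.null(t_end)) NA_real_ else t_end)),
            class = "paart_batch")
}

#' @export
print.paart_batch <- function(x, ...) {
  ok <- vapply(x$records, function(r) is.null(r$fit), logical(1L))
  cat(sprintf("<batch> %d record(s), %d failed\n", length(x$records),
              sum(ok)))
  for (r in x$records) {
    if (is.null(r$fit))
      cat(sprintf("  %s/%d: FAILED (%s)\n", r$sample_id, r$replicate,
                  r$error))
    else
      cat(sprintf("  %s/%d: %d component(s), chi^2 %.3g\n", r$sample_id,
                  r$replicate, r$fit$selected_n, r$fit$chi2))
  }
  invisible(x)
}

#' Write a batch report as JSON
#'
#' The JSON report is the canonical machine-readable output: one record per
#' (sample, replicate) with the selected order, per-component estimates and
#' standard errors, fit diagnostics, the AIC trace, the analysis window,
#' accumulated warnings, and the configuration (echoed verbatim with a
#' short hash) for reproducibility.
#'
#' @param batch A `"paart_batch"`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_paart_report <- function(batch, path) {
  stopifnot(inherits(batch, "paart_batch"))
  cfg <- unclass(batch$control)
  recs <- lapply(batch$records, function(r) {
    base <- list(sample_id = r$sample_id, replicate = r$replicate)
    if (is.null(r$fit)) return(c(base, list(error = r$error)))
    f <- r$fit
    c(base, list(
      selected_n = f$selected_n,
      components = f$components,
      r_inf = if (f$control$include_r_inf) f$r_inf else NULL,
      chi2 = f$chi2,
      aic_trace = f$aic_trace,
      window = f$window,
      warnings = as.list(f$warnings)))
  })
  jsonlite::write_json(list(
    software = paste0("paart ",
                      as.character(utils::packageVersion("paart"))),
    config = cfg, config_hash = .config_hash(batch$control),
    records = recs), path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' One-row-per-component summary table of a batch
#'
#' @param batch A `"paart_batch"`.
#' @return A data.frame with columns `sample_id, replicate, component, kd,
#'   se_kd, alpha, fraction, chi2, selected_n`.
#' @export
paart_summary_table <- function(batch) {
  stopifnot(inherits(batch, "paart_batch"))
  rows <- lapply(batch$records, function(r) {
    if (is.null(r$fit)) return(NULL)
    f <- r$fit
    data.frame(sample_id = r$sample_id, replicate = r$replicate,
               component = seq_len(f$selected_n), kd = f$components$kd,
               se_kd = f$components$se_kd, alpha = f$components$alpha,
               fraction = f$components$fraction, chi2 = f$chi2,
               selected_n = f$selected_n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no successful fits in batch", call. = FALSE)
  out
}

#' Group-level summary of component counts
#'
#' Tabulates, per group, the proportion of records showing each number of
#' avidity components at or above a reporting fraction (e.g. the share of
#' vaccinees with >= 5% of 2 or 3 components).
#'
#' @param batch A `"paart_batch"`.
#' @param min_fraction Minimum fraction for a component to count.
#' @param groups Optional named character vector mapping `sample_id` to a
#'   group label; default puts everything in one group.
#' @return A data.frame with columns `group, n_components, count,
#'   proportion`; within each group the proportions sum to 1 and the
#'   counts to the number of fitted records.
#' @export
summarize_components <- function(batch, min_fraction = 0.05,
                                 groups = NULL) {
  stopifnot(inherits(batch, "paart_batch"))
  ok <- Filter(function(r) !is.null(r$fit), batch$records)
  if (!length(ok)) stop("no successful fits to summarize", call. = FALSE)
  ids <- vapply(ok, `[[`, character(1L), "sample_id")
  grp <- if (is.null(groups)) rep("all", length(ok))
         else unname(groups[ids])
  ncomp <- vapply(ok, function(r)
    count_components(r$fit, min_fraction), integer(1L))
  out <- do.call(rbind, lapply(split(seq_along(ok), grp), function(idx) {
    tab <- table(ncomp[idx])
    data.frame(group = grp[idx[1L]], n_components = as.integer(names(tab)),
               count = as.integer(tab),
               proportion = as.integer(tab) / length(idx),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
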