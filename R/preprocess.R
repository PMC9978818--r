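#' Reference subtraction
#'
#' Removes non-specific signal by subtracting a control-sensor trace
#' (recorded in parallel, e.g. on a scrambled-peptide surface) from a sample
#' trace, pointwise on the sample's time grid. When the two grids differ the
#' reference is linearly interpolated; the sample grid is never touched, so
#' the fitted signal keeps its original sampling.
#'
#' @param sample A [timecourse].
#' @param reference A [timecourse] whose time range covers the sample's.
#' @return A [timecourse] on the sample grid with the reference subtracted.
#' @export
reference_subtract <- function(sample, reference) {
  stopifnot(inherits(sample, "timecourse"), inherits(reference, "timecourse"))
  if (min(reference$times) > min(sample$times) + 1e-9 ||
      max(reference$times) < max(sample$times) - 1e-9)
    stop("reference time range [", min(reference$times), ", ",
         max(reference$times), "] does not cover the sample range",
         call. = FALSE)
  ref <- stats::approx(reference$times, reference$responses,
                       xout = sample$times, rule = 2)$y
  timecourse(sample$times, sample$responses - ref, sample$unit)
}

#' Inter-step correction at the association/dissociation boundary
#'
#' Dipping sensors back into the baseline buffer at the start of dissociation
#' commonly introduces a constant offset. This aligns the dissociation phase
#' by shifting it so its first point equals the last association response;
#' the applied offset is recorded in the sensorgram's notes.
#'
#' @param s A [sensorgram] with both association and dissociation phases.
#' @return The corrected [sensorgram].
#' @export
align_intersteps <- function(s) {
  stopifnot(inherits(s, "sensorgram"))
  if (is.null(s$phases$association) || is.null(s$phases$dissociation))
    stop("inter-step alignment needs both association and dissociation phases",
         call. = FALSE)
  a_end <- s$phases$association$responses[length(s$phases$association$times)]
  d_start <- s$phases$dissociation$responses[1L]
  if (!is.finite(a_end) || !is.finite(d_start))
    stop("non-finite response at the step boundary", call. = FALSE)
  offset <- d_start - a_end
  s$phases$dissociation$responses <- s$phases$dissociation$responses - offset
  s$notes <- c(s$notes, sprintf("inter-step offset %.6g removed", offset))
  s
}

#' Extract the analysis window of a dissociation phase
#'
#' Cuts the dissociation phase to `[t_start, t_end]` (in dissociation-step
#' time) and rebases the clock so the first retained point is t = 0. Signal
#' distortion in the first few seconds after the step transition, and
#' residual non-specific binding late in the phase, are excluded this way;
#' the default drops the first 5 s and keeps the rest.
#'
#' The fractional contributions reported by [paart()] are shares of the
#' bound response at the *window start*, so the window is part of the
#' analysis definition and is carried in the result.
#'
#' @param s A [sensorgram] with a dissociation phase, or a [timecourse]
#'   holding a dissociation trace.
#' @param t_start,t_end Window bounds in seconds of dissociation-step time;
#'   `t_end = NULL` means the full duration.
#' @param min_points Minimum number of points that must remain.
#' @return A [dissociation_phase].
#' @export
dissociation_window <- function(s, t_start = 5, t_end = NULL,
                                min_points = 10L) {
  if (inherits(s, "sensorgram")) {
    tc <- s$phases$dissociation
    if (is.null(tc)) stop("sensorgram has no dissociation phase", call. = FALSE)
    src <- sprintf("%s/%d", s$sample_id, s$replicate)
  } else if (inherits(s, "timecourse")) {
    tc <- s
    src <- ""
  } else stop("'s' must be a sensorgram or timecourse", call. = FALSE)
  dur <- max(tc$times) - tc$times[1L]
  if (is.null(t_end)) t_end <- dur
  if (t_start < 0 || t_start >= t_end || t_end > dur + 1e-9)
    stop("need 0 <= t_start < t_end <= ", dur, " s", call. = FALSE)
  rel <- tc$times - tc$times[1L]
  keep <- rel >= t_start - 1e-9 & rel <= t_end + 1e-9
  if (sum(keep) < min_points)
    stop(sum(keep), " points in window [", t_start, ", ", t_end,
         "] s; widen the window (>= ", min_points, " needed)", call. = FALSE)
  dissociation_phase(rel[keep] - rel[keep][1L], tc$responses[keep],
                     window = c(t_start, t_end), source = src,
                     unit = tc$unit)
}
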