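#' Biosensor time-course
#'
#' A `timecourse` holds one sampled response trace: time in seconds and
#' instrument response in the platform's native units (nm for biolayer
#' interferometry, RU for surface plasmon resonance). The kinetics math is
#' unit-agnostic, so responses are never rescaled; the label travels with the
#' object for reporting only.
#'
#' @param times Numeric vector of times in seconds, strictly increasing.
#' @param responses Numeric vector of responses, same length as `times`.
#' @param unit Response unit label, e.g. `"nm"` or `"RU"`.
#' @return An object of class `"timecourse"`: a list with elements `times`,
#'   `responses` and `unit`.
#' @examples
#' tc <- timecourse(0:10, exp(-0.1 * (0:10)))
#' tc
#' @export
timecourse <- function(times, responses, unit = "nm") {
  times <- as.numeric(times)
  responses <- as.numeric(responses)
  if (length(times) < 2L)
    stop("a timecourse needs at least 2 points", call. = FALSE)
  if (length(times) != length(responses))
    stop("'times' and 'responses' must have the same length", call. = FALSE)
  if (!all(is.finite(times)) || !all(is.finite(responses)))
    stop("times and responses must all be finite", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  structure(list(times = times, responses = responses,
                 unit = as.character(unit)[1L]),
            class = "timecourse")
}

#' @export
print.timecourse <- function(x, ...) {
  cat(sprintf("<timecourse> %d points, t = [%g, %g] s, response [%g, %g] %s\n",
              length(x$times), min(x$times), max(x$times),
              min(x$responses), max(x$responses), x$unit))
  invisible(x)
}

#' @export
length.timecourse <- function(x) length(x$times)

#' Sensorgram: phased biosensor record for one sample
#'
#' A `sensorgram` groups the baseline, association and dissociation
#' time-courses of one (sample, replicate) pair. Phase time ranges must be
#' non-overlapping and in assay order; each phase's clock starts at 0 at the
#' phase start. At least a dissociation phase is required for avidity-binning
#' analysis.
#'
#' @param phases Named list of [timecourse] objects; allowed names are
#'   `"baseline"`, `"association"`, `"dissociation"`.
#' @param sample_id Sample identifier.
#' @param replicate Replicate number (integer >= 1).
#' @param analyte_conc Optional molar analyte concentration (`NA` when
#'   unknown, as for polyclonal sera).
#' @param notes Character vector of free-text processing notes.
#' @return An object of class `"sensorgram"`.
#' @examples
#' d <- timecourse(seq(0, 60, 2), 0.8 * exp(-0.01 * seq(0, 60, 2)))
#' sensorgram(list(dissociation = d), sample_id = "S1")
#' @export
sensorgram <- function(phases, sample_id, replicate = 1L,
                       analyte_conc = NA_real_, notes = character()) {
  if (!is.list(phases) || is.null(names(phases)) || any(names(phases) == ""))
    stop("'phases' must be a named list of timecourses", call. = FALSE)
  allowed <- c("baseline", "association", "dissociation")
  bad <- setdiff(names(phases), allowed)
  if (length(bad))
    stop("unknown phase label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(names(phases)))
    stop("duplicated phase labels", call. = FALSE)
  for (nm in names(phases))
    if (!inherits(phases[[nm]], "timecourse"))
      stop("phase '", nm, "' is not a timecourse", call. = FALSE)
  # canonical assay order
  phases <- phases[intersect(allowed, names(phases))]
  replicate <- as.integer(replicate)
  if (is.na(replicate) || replicate < 1L)
    stop("'replicate' must be an integer >= 1", call. = FALSE)
  structure(list(phases = phases,
                 sample_id = as.character(sample_id)[1L],
                 replicate = replicate,
                 analyte_conc = as.numeric(analyte_conc)[1L],
                 notes = as.character(notes)),
            class = "sensorgram")
}

#' @export
print.sensorgram <- function(x, ...) {
  cat(sprintf("<sensorgram> sample '%s' replicate %d\n",
              x$sample_id, x$replicate))
  for (nm in names(x$phases)) {
    tc <- x$phases[[nm]]
    cat(sprintf("  %-12s %4d points, %g s\n", nm, length(tc$times),
                max(tc$times) - min(tc$times)))
  }
  if (!is.na(x$analyte_conc))
    cat(sprintf("  analyte conc %.3g M\n", x$analyte_conc))
  if (length(x$notes)) cat("  notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' Windowed dissociation phase ready for fitting
#'
#' Internal constructor for the fit-ready dissociation record: times rebased
#' so the first retained point is t = 0, together with the window (in
#' instrument dissociation-step time) it was cut from and its provenance.
#'
#' @param times,responses Numeric vectors (times rebased to start at 0).
#' @param window Length-2 numeric `(t_start, t_end)` in dissociation-step time.
#' @param source Character tag, typically `"sample_id/replicate"`.
#' @param unit Response unit label.
#' @return An object of class `"dissociation_phase"`.
#' @keywords internal
#' @export
dissociation_phase <- function(times, responses, window = c(0, max(times)),
                               source = "", unit = "nm") {
  tc <- timecourse(times, responses, unit)
  if (abs(tc$times[1L]) > 1e-9)
    stop("dissociation phase times must be rebased to start at 0",
         call. = FALSE)
  structure(list(times = tc$times, responses = tc$responses,
                 window = as.numeric(window), source = as.character(source)[1L],
                 unit = tc$unit),
            class = c("dissociation_phase", "timecourse"))
}

#' @export
print.dissociation_phase <- function(x, ...) {
  cat(sprintf(
    "<dissociation phase> %d points over %g s (window %g-%g s)%s\n",
    length(x$times), max(x$times), x$window[1L], x$window[2L],
    if (nzchar(x$source)) paste0(" from ", x$source) else ""))
  invisible(x)
}
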