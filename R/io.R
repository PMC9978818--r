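#' Read sensorgrams from CSV
#'
#' Reads biosensor time-courses from disk into a list of [sensorgram]
#' objects. Two dialects are supported:
#'
#' * `"tidy"` (canonical, also the only write format): one row per sampled
#'   point with header columns `sample_id, replicate, phase, time_s,
#'   response` and optional `conc_molar`, `unit`. `phase` must be one of
#'   `baseline`, `association`, `dissociation`; times must be strictly
#'   increasing within each phase.
#' * `"wide"` (import only): first column `time_s`, one column per sensor,
#'   all traces sharing the time grid and belonging to a single phase given
#'   by `phase`.
#'
#' @param path Path to a CSV file.
#' @param dialect `"tidy"` or `"wide"`.
#' @param phase Phase label for every trace of a wide file.
#' @return A list of [sensorgram] objects, one per (sample_id, replicate).
#' @seealso [write_sensorgrams()]
#' @export
read_sensorgrams <- function(path, dialect = c("tidy", "wide"),
                             phase = "dissociation") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (dialect == "wide") return(.sensorgrams_from_wide(df, phase, path))
  .sensorgrams_from_tidy(df, path)
}

.sensorgrams_from_tidy <- function(df, path = "<data>") {
  required <- c("sample_id", "replicate", "phase", "time_s", "response")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("missing required column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  allowed <- c("baseline", "association", "dissociation")
  bad <- which(!df$phase %in% allowed)
  if (length(bad))
    stop("unknown phase label '", df$phase[bad[1L]], "' at row ",
         bad[1L] + 1L, " of ", path, call. = FALSE)
  has_conc <- "conc_molar" %in% names(df)
  unit <- if ("unit" %in% names(df)) as.character(df$unit[1L]) else "nm"
  df$.row <- seq_len(nrow(df))
  key <- interaction(df$sample_id, df$replicate, drop = TRUE, lex.order = TRUE)
  out <- lapply(split(df, key), function(g) {
    phases <- list()
    for (ph in intersect(allowed, unique(g$phase))) {
      gp <- g[g$phase == ph, , drop = FALSE]
      dt <- diff(gp$time_s)
      if (any(dt <= 0)) {
        i <- which(dt <= 0)[1L]
        stop("time not strictly increasing within phase '", ph,
             "' of sample '", g$sample_id[1L], "' at row ",
             gp$.row[i + 1L] + 1L, # file line, counting the header
             " of ", path, call. = FALSE)
      }
      phases[[ph]] <- timecourse(gp$time_s, gp$response, unit)
    }
    conc <- if (has_conc) g$conc_molar[1L] else NA_real_
    sensorgram(phases, sample_id = g$sample_id[1L],
               replicate = g$replicate[1L], analyte_conc = conc)
  })
  unname(out)
}

.sensorgrams_from_wide <- function(df, phase, path) {
  if (names(df)[1L] != "time_s")
    stop("wide files must have 'time_s' as first column (", path, ")",
         call. = FALSE)
  if (ncol(df) < 2L)
    stop("wide file has no sensor columns: ", path, call. = FALSE)
  if (any(diff(df$time_s) <= 0)) {
    i <- which(diff(df$time_s) <= 0)[1L]
    stop("time not strictly increasing at row ", i + 1L, " of ", path,
         call. = FALSE)
  }
  lapply(names(df)[-1L], function(id) {
    ph <- stats::setNames(list(timecourse(df$time_s, df[[id]])), phase)
    sensorgram(ph, sample_id = id)
  })
}

#' Write sensorgrams to tidy CSV
#'
#' Serializes sensorgrams in the canonical tidy dialect (the only on-disk
#' writer, so read/write round trips are lossless). Columns: `sample_id,
#' replicate, phase, time_s, response, conc_molar, unit`.
#'
#' @param sgs A [sensorgram] or list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sensorgrams <- function(sgs, path) {
  if (inherits(sgs, "sensorgram")) sgs <- list(sgs)
  rows <- lapply(sgs, function(s) {
    do.call(rbind, lapply(names(s$phases), function(ph) {
      tc <- s$phases[[ph]]
      data.frame(sample_id = s$sample_id, replicate = s$replicate,
                 phase = ph, time_s = tc$times, response = tc$responses,
                 conc_molar = s$analyte_conc, unit = tc$unit,
                 stringsAsFactors = FALSE)
    }))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
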