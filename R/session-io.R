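#' Save a session to a directory
#'
#' Writes the on-disk session layout: \code{metadata.json} (rate,
#' electrode count, identifiers, event timeline), \code{lfp.f32}
#' (electrode-major little-endian float32 samples in uV),
#' \code{trials.csv} (one row per trial, lick times semicolon-joined)
#' and, when a lick trace is present, \code{licks.f32}. Output bytes are
#' deterministic for a fixed input.
#'
#' Note that samples are stored as 32-bit floats: the first save of a
#' double-precision session rounds them; load/save cycles thereafter are
#' byte-identical.
#'
#' @param session an [LfpSession-class].
#' @param trialTable a [TrialTable-class].
#' @param path session directory (created if needed).
#' @return \code{path}, invisibly.
#' @seealso [loadSession()]
#' @export
saveSession <- function(session, trialTable, path) {
  validObject(session)
  validObject(trialTable)
  ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path))
    stop("cannot create session directory '", path, "'")
  meta <- list(session_id = session@sessionId,
               subject_id = session@subjectId,
               rate = session@rate,
               electrode_count = nrow(session@samples),
               n_samples = ncol(session@samples),
               duration_s = ncol(session@samples) / session@rate,
               odorant_labels = c("S+", "S-"),
               has_licks = length(session@lickTrace) > 0,
               events = session@events)
  jsonlite::write_json(meta, file.path(path, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  con <- file(file.path(path, "lfp.f32"), "wb")
  writeBin(as.numeric(t(session@samples)), con, size = 4,
           endian = "little")
  close(con)
  if (length(session@lickTrace)) {
    con <- file(file.path(path, "licks.f32"), "wb")
    writeBin(as.numeric(session@lickTrace), con, size = 4,
             endian = "little")
    close(con)
  }
  tr <- trialTable@trials
  df <- data.frame(trial_start_s = tr$trial_start_s,
                   odor_on_s = tr$odor_on_s, odorant = tr$odorant,
                   outcome = tr$outcome, reinforced = tr$reinforced,
                   lick_times_s = vapply(tr$lick_times, function(lt)
                     paste(formatC(lt, format = "g", digits = 17),
                           collapse = ";"), character(1)))
  utils::write.csv(df, file.path(path, "trials.csv"), row.names = FALSE)
  invisible(path)
}

#' Load a session from a directory
#'
#' Reads the layout written by [saveSession()] and returns validated
#' objects. If the trial table lacks an \code{outcome} column, outcomes
#' are recomputed from the lick times with [classifyOutcome()] and the
#' result is flagged with \code{attr(, "derived_outcomes")}.
#'
#' @param path session directory.
#' @param config an [AnalysisConfig-class] (response-window geometry for
#'   derived outcomes).
#' @return list with \code{session} ([LfpSession-class]) and
#'   \code{trials} ([TrialTable-class]).
#' @export
loadSession <- function(path, config = analysisConfig()) {
  need <- c("metadata.json", "lfp.f32", "trials.csv")
  for (f in need) {
    if (!file.exists(file.path(path, f)))
      stop("missing session file '", f, "' in '", path, "'")
  }
  meta <- jsonlite::fromJSON(file.path(path, "metadata.json"))
  nEl <- meta$electrode_count
  nS <- meta$n_samples
  fsize <- file.info(file.path(path, "lfp.f32"))$size
  if (fsize != 4 * nEl * nS)
    stop("format error: metadata declares ", nEl, " x ", nS,
         " samples (", 4 * nEl * nS, " bytes) but lfp.f32 has ", fsize,
         " bytes")
  con <- file(file.path(path, "lfp.f32"), "rb")
  raw <- readBin(con, numeric(), n = nEl * nS, size = 4, endian = "little")
  close(con)
  samples <- t(matrix(raw, nrow = nS, ncol = nEl))
  lick <- numeric(0)
  if (isTRUE(meta$has_licks) && file.exists(file.path(path, "licks.f32"))) {
    con <- file(file.path(path, "licks.f32"), "rb")
    lick <- readBin(con, numeric(), n = nS, size = 4, endian = "little")
    close(con)
  }
  events <- if (!is.null(meta$events) && length(meta$events))
    as.data.frame(meta$events)
  else data.frame(label = character(), time_s = numeric())
  session <- lfpSession(samples, rate = meta$rate, events = events,
                        lickTrace = lick,
                        sessionId = as.character(meta$session_id),
                        subjectId = as.character(meta$subject_id))
  df <- utils::read.csv(file.path(path, "trials.csv"),
                        stringsAsFactors = FALSE)
  if (!all(df$odorant %in% c("S+", "S-")))
    stop("unknown odorant label(s): ",
         paste(setdiff(unique(df$odorant), c("S+", "S-")), collapse = ", "))
  df$lick_times <- lapply(df$lick_times_s, function(s) {
    if (is.na(s) || !nzchar(s)) numeric(0)
    else as.numeric(strsplit(s, ";", fixed = TRUE)[[1]])
  })
  df$lick_times_s <- NULL
  list(session = session, trials = trialTable(df, config = config))
}
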