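#' Construct a validated BMCA session record
#'
#' A session holds the raw multi-channel sEMG of one visit together with the
#' trial event table. Events carry 0-based half-open sample windows
#' `[start, end)` — the on-disk convention — one row per
#' (movement, trial, condition).
#'
#' @param emg numeric matrix, channels x samples; rownames must match the
#'   layout channel names (any order; stored canonically ordered).
#' @param fs sampling rate in Hz.
#' @param events data.frame with columns `movement`, `trial`, `condition`,
#'   `start`, `end`.
#' @param participant_id character scalar.
#' @param session_index integer >= 1 (follow-up visit number).
#' @param group `"SCI"` or `"control"`.
#' @param layout a [channel_layout()].
#' @return object of class `session_record`.
#' @seealso [write_session()], [read_session()], [synthesize_session()]
#' @export
session_record <- function(emg, fs = 600, events, participant_id = "P1",
                           session_index = 1L, group = c("SCI", "control"),
                           layout = channel_layout()) {
  group <- match.arg(group)
  if (!is.matrix(emg) || !is.numeric(emg))
    stop("emg must be a numeric matrix (channels x samples)")
  if (is.null(rownames(emg)))
    stop("emg must have channel names as rownames")
  missing <- setdiff(layout$names, rownames(emg))
  if (length(missing))
    stop("missing channel: ", paste(missing, collapse = ", "))
  extra <- setdiff(rownames(emg), layout$names)
  if (length(extra))
    stop("unknown channel: ", paste(extra, collapse = ", "))
  emg <- emg[layout$names, , drop = FALSE]

  events <- as.data.frame(events, stringsAsFactors = FALSE)
  req <- c("movement", "trial", "condition", "start", "end")
  if (!all(req %in% names(events)))
    stop("events must have columns: ", paste(req, collapse = ", "))
  events <- events[, req]
  events$start <- as.integer(events$start)
  events$end <- as.integer(events$end)
  events$trial <- as.integer(events$trial)
  bad_cond <- setdiff(unique(events$condition),
                      c("stim", "no_stim", "control"))
  if (length(bad_cond))
    stop("unknown condition label: ", paste(bad_cond, collapse = ", "))
  if (any(events$start < 0L) || any(events$start >= events$end))
    stop("events: start must satisfy 0 <= start < end")
  if (any(events$end > ncol(emg)))
    stop("events: end exceeds the number of samples")
  for (cond in unique(events$condition)) {
    ev <- events[events$condition == cond, ]
    ev <- ev[order(ev$start), ]
    if (nrow(ev) > 1L && any(ev$start[-1L] < ev$end[-nrow(ev)]))
      stop("overlapping events within condition '", cond, "'")
  }
  if (length(session_index) != 1L || session_index < 1L)
    stop("session_index must be a single integer >= 1")

  structure(list(emg = emg, fs = as.numeric(fs), events = events,
                 participant_id = as.character(participant_id),
                 session_index = as.integer(session_index),
                 group = group, layout = layout),
            class = "session_record")
}

#' @export
print.session_record <- function(x, ...) {
  cat("BMCA session record\n")
  cat(sprintf("  participant %s, session %d, group %s\n",
              x$participant_id, x$session_index, x$group))
  cat(sprintf("  %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$emg), ncol(x$emg), x$fs, ncol(x$emg) / x$fs))
  cat(sprintf("  %d events, conditions: %s\n", nrow(x$events),
              paste(unique(x$events$condition), collapse = ", ")))
  invisible(x)
}

# numbers are written with %.17g so doubles round-trip bit-exactly
fmt_num <- function(x) sprintf("%.17g", x)

#' Write a session to the open text container
#'
#' The container is a directory holding `emg.tsv` (samples x channels, full
#' 64-bit precision), `events.tsv` and `meta.json`. Writes are deterministic:
#' two writes of the same record produce byte-identical files (no
#' timestamps).
#'
#' @param record a [session_record()].
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_session <- function(record, path) {
  if (!inherits(record, "session_record"))
    stop("record must be a session_record")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stop("cannot create session directory: ", path)

  meta <- list(format = "synergykit-session", version = 1L,
               fs = record$fs, participant_id = record$participant_id,
               session_index = record$session_index, group = record$group,
               channels = record$layout$names,
               artifact_channels = record$layout$artifact_channels,
               n_samples = ncol(record$emg))
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA),
             file.path(path, "meta.json"))

  ev <- record$events
  con <- file(file.path(path, "events.tsv"), "wb")
  writeLines(paste(c("movement", "trial", "condition", "start", "end"),
                   collapse = "\t"), con)
  writeLines(paste(ev$movement, ev$trial, ev$condition, ev$start, ev$end,
                   sep = "\t"), con)
  close(con)

  m <- t(record$emg)  # samples x channels
  con <- file(file.path(path, "emg.tsv"), "wb")
  writeLines(paste(colnames(m), collapse = "\t"), con)
  body <- do.call(paste, c(lapply(seq_len(ncol(m)),
                                  function(j) fmt_num(m[, j])),
                           sep = "\t"))
  writeLines(body, con)
  close(con)
  invisible(path)
}

#' Read a session from the open text container
#'
#' Channel order is canonicalized to the layout order regardless of the
#' column order on disk. Validation failures name the offending field.
#'
#' @param path session directory written by [write_session()].
#' @param layout expected [channel_layout()].
#' @return a validated [session_record()].
#' @export
read_session <- function(path, layout = channel_layout()) {
  if (!dir.exists(path)) stop("session directory not found: ", path)
  meta <- jsonlite::fromJSON(file.path(path, "meta.json"))
  events <- utils::read.delim(file.path(path, "events.tsv"),
                              stringsAsFactors = FALSE)
  emg_t <- as.matrix(utils::read.delim(file.path(path, "emg.tsv"),
                                       check.names = FALSE,
                                       colClasses = "numeric"))
  emg <- t(emg_t)
  session_record(emg = emg, fs = meta$fs, events = events,
                 participant_id = meta$participant_id,
                 session_index = meta$session_index,
                 group = meta$group, layout = layout)
}
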