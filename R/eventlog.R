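# JSONL event logs: one record per event
# {participant_id, day, event_kind, payload}, one JSON object per line.
# The event log is the unit of replay and of all analytics.

#' Build an event log
#'
#' An event log is an ordered list of records, each
#' `list(participant_id, day, event_kind, payload)`. Event kinds comprise
#' every engine action kind plus driver-level events: `enrolled`,
#' `text_reply`, `web_submit`, and `video_library_link` (the only content
#' event in the enhanced-usual-care arm).
#'
#' @param records List of event records.
#' @return The list with class `event_log`.
#' @export
event_log <- function(records = list()) {
  structure(records, class = "event_log")
}

#' @export
print.event_log <- function(x, ...) {
  cat(sprintf("<event_log: %d events, %d participant(s)>\n", length(x),
              length(unique(vapply(x, `[[`, "", "participant_id")))))
  invisible(x)
}

#' @export
as.data.frame.event_log <- function(x, ...) {
  if (length(x) == 0L) {
    return(data.frame(participant_id = character(), day = integer(),
                      event_kind = character(), stringsAsFactors = FALSE))
  }
  data.frame(
    participant_id = vapply(x, `[[`, "", "participant_id"),
    day = vapply(x, function(e) as.integer(e$day), 0L),
    event_kind = vapply(x, `[[`, "", "event_kind"),
    stringsAsFactors = FALSE
  )
}

# Drop NULL payload entries so serialization is canonical.
.clean_payload <- function(p) {
  if (is.null(p)) return(NULL)
  p <- p[!vapply(p, is.null, TRUE)]
  if (length(p) == 0L) NULL else p
}

#' Write / read an event log as JSONL
#'
#' One JSON object per line. `write_event_log()` accepts a single log or a
#' list of per-participant logs (concatenated in order); `read_event_log()`
#' returns one flat `event_log`. Re-serializing a read log reproduces the
#' file byte for byte.
#'
#' @param log An `event_log`, or a list of them.
#' @param path File path.
#' @return `read_event_log()` returns an `event_log`;
#'   `write_event_log()` returns `path` invisibly.
#' @export
write_event_log <- function(log, path) {
  if (!inherits(log, "event_log")) {
    log <- event_log(do.call(c, lapply(log, unclass)))
  }
  lines <- vapply(log, function(e) {
    rec <- list(participant_id = e$participant_id, day = as.integer(e$day),
                event_kind = e$event_kind)
    pay <- .clean_payload(e$payload)
    if (!is.null(pay)) rec$payload <- pay
    as.character(jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null",
                                  na = "null", digits = NA))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_event_log
#' @export
read_event_log <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  event_log(lapply(lines, function(l) {
    e <- jsonlite::fromJSON(l, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
    e$day <- as.integer(e$day)
    e
  }))
}

#' Split a flat event log by participant
#'
#' @param log An `event_log`.
#' @return A named list of per-participant `event_log`s, in order of first
#'   appearance.
#' @export
split_event_log <- function(log) {
  ids <- vapply(log, `[[`, "", "participant_id")
  out <- lapply(unique(ids), function(id) event_log(log[ids == id]))
  names(out) <- unique(ids)
  out
}

#' Replay recorded participant inputs through the engine
#'
#' Deterministically re-runs a recorded event stream: `enrolled` events
#' start the program, `text_reply` and `web_submit` events are fed to
#' [process_text_reply()] and [process_web_checkin()] in order, with the
#' clock advanced as recorded. The emitted actions (with the welcome
#' sequence, prompts, reprompts and missed-markings) are returned as a new
#' event log — the engine's half of the conversation reconstructed from the
#' participant's half.
#'
#' @param log An `event_log` holding `enrolled` / `text_reply` /
#'   `web_submit` records for one or more participants.
#' @param config Engine configuration.
#' @return An `event_log` of emitted actions.
#' @export
replay_event_log <- function(log, config = default_config()) {
  out <- list()
  emit <- function(id, acts) {
    for (a in acts) {
      out[[length(out) + 1L]] <<- list(
        participant_id = id, day = a$day, event_kind = a$kind,
        payload = c(a$payload,
                    list(scheduled_day =
                           if (is.na(a$scheduled_day)) NULL
                           else a$scheduled_day))
      )
    }
  }
  states <- list()
  horizon_end <- function(id) {
    # flush remaining scheduled events inside the horizon
    st <- states[[id]]
    if (is.null(st)) return()
    last <- config$horizon_days - 1L
    if (st$state$day < last) {
      repeat {
        nd <- next_event_day(st$state)
        if (is.na(nd) || nd > last) break
        res <- advance_clock(st$state, nd)
        states[[id]]$state <<- res$state
        st <- states[[id]]
        emit(id, res$actions)
      }
    }
  }
  for (e in log) {
    id <- e$participant_id
    kind <- e$event_kind
    if (kind == "enrolled") {
      res <- start_program(id, e$day, config,
                           existing = states[[id]]$state)
      states[[id]] <- list(state = res$state)
      emit(id, res$actions)
    } else if (kind == "text_reply") {
      st <- states[[id]]
      if (is.null(st)) .err("mosth_protocol_error",
                            sprintf("reply before enrollment for '%s'", id))
      res <- process_text_reply(st$state, e$day, e$payload$raw)
      states[[id]]$state <- res$state
      emit(id, res$actions)
    } else if (kind == "web_submit") {
      st <- states[[id]]
      if (is.null(st)) .err("mosth_protocol_error",
                            sprintf("submission before enrollment for '%s'",
                                    id))
      p <- e$payload
      wc <- web_checkin(e$day,
                        stressors = as.character(unlist(p$stressors)),
                        negative_effects =
                          as.character(unlist(p$negative_effects)),
                        self_efficacy =
                          if (is.null(p$self_efficacy)) NA_character_
                          else p$self_efficacy,
                        completed = !isFALSE(p$completed))
      res <- process_web_checkin(st$state, wc)
      states[[id]]$state <- res$state
      emit(id, res$actions)
    }
    # engine-action kinds in the input are ignored: replay regenerates them
  }
  for (id in names(states)) horizon_end(id)
  event_log(out)
}
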