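# Engine configuration: cadence, reprompt windows, escalation rule variant,
# vocabularies, URLs, and the message library. All timings are whole days;
# day 0 is the enrollment day.

#' Default engine configuration
#'
#' @details
#' Parameters (all durations in whole days):
#' \describe{
#'   \item{monthly_interval}{Step-down interval after a POSITIVE rating or a
#'     HIGH self-efficacy report (default 30).}
#'   \item{weekly_interval}{Step-up interval after a LOW self-efficacy
#'     report (default 7).}
#'   \item{reprompt_delay}{Days from an unanswered prompt to its single
#'     reprompt (default 1).}
#'   \item{missing_delay}{Days from the reprompt until the check-in is
#'     marked missed (default 2).}
#'   \item{missing_reschedule}{Days from the original prompt day to the next
#'     check-in after a missed one (default 7; missingness is treated
#'     conservatively as potential need).}
#'   \item{horizon_days}{Program length (default 90).}
#'   \item{escalation_window}{Maximum day gap for two qualifying check-ins
#'     to count as "in a row" (default 14).}
#'   \item{escalation_rating}{Which ratings qualify for the safety rule:
#'     `"suboptimal"` (fair or poor, the default, matching the web check-in
#'     trigger partition) or `"poor"` (strictly poor).}
#'   \item{consent_decline_reschedules}{Whether declining the "ok to check
#'     in next week?" ask alters scheduling (default `FALSE`: the reply is
#'     logged only).}
#'   \item{carry_over}{Simulator: probability a stressor/effect endorsement
#'     state is copied from the previous check-in rather than redrawn
#'     (default 0.5).}
#'   \item{video_url, web_url, resources_url}{Opaque link tokens standing in
#'     for the psychoeducational video library, the web check-in page, and
#'     care-seeking resources.}
#'   \item{stressors, effects}{The canonical checklist vocabularies.}
#'   \item{messages}{Message template data.frame, see
#'     [default_message_library()].}
#' }
#'
#' @return A named list of class `mosth_config`.
#' @export
default_config <- function() {
  cfg <- list(
    monthly_interval = 30L,
    weekly_interval = 7L,
    reprompt_delay = 1L,
    missing_delay = 2L,
    missing_reschedule = 7L,
    horizon_days = 90L,
    escalation_window = 14L,
    escalation_rating = "suboptimal",
    consent_decline_reschedules = FALSE,
    carry_over = 0.5,
    video_url = "https://videos.example.org/college-mh",
    web_url = "https://checkin.example.org/web",
    resources_url = "https://resources.example.org/care",
    stressors = .STRESSOR_VOCAB,
    effects = .EFFECT_VOCAB,
    messages = default_message_library()
  )
  class(cfg) <- "mosth_config"
  cfg
}

#' Read a configuration file
#'
#' A declarative YAML file whose top-level keys override the defaults of
#' [default_config()]. The message library may be given inline as a list of
#' `{id, kind, text}` records under `messages`, or as a path to a CSV or
#' JSONL file under `messages_file`.
#'
#' @param path Path to a YAML config file.
#' @return A `mosth_config` list.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- default_config()
  if (!is.null(raw$messages_file)) {
    raw$messages <- read_message_library(raw$messages_file)
    raw$messages_file <- NULL
  } else if (!is.null(raw$messages)) {
    raw$messages <- do.call(rbind, lapply(raw$messages, function(m) {
      data.frame(id = m$id, kind = m$kind, text = m$text,
                 stringsAsFactors = FALSE)
    }))
  }
  known <- names(cfg)
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  cfg[names(raw)] <- raw
  validate_config(cfg)
}

#' @rdname read_config
#' @param cfg A config list to validate.
#' @export
validate_config <- function(cfg) {
  for (key in c("monthly_interval", "weekly_interval", "reprompt_delay",
                "missing_delay", "missing_reschedule", "horizon_days",
                "escalation_window")) {
    if (!is.numeric(cfg[[key]]) || cfg[[key]] < 0) {
      stop(sprintf("config '%s' must be a non-negative number", key))
    }
    cfg[[key]] <- as.integer(cfg[[key]])
  }
  if (!cfg$escalation_rating %in% c("suboptimal", "poor")) {
    stop("config 'escalation_rating' must be 'suboptimal' or 'poor'")
  }
  stopifnot(is.data.frame(cfg$messages),
            all(c("id", "kind", "text") %in% names(cfg$messages)))
  class(cfg) <- "mosth_config"
  cfg
}

#' Read / write a message library file
#'
#' CSV (columns `id`, `kind`, `text`) or JSONL (one `{id, kind, text}`
#' object per line), selected by file extension.
#'
#' @param path File path; `.csv` or anything else treated as JSONL.
#' @return A message template data.frame.
#' @export
read_message_library <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    lib <- utils::read.csv(path, stringsAsFactors = FALSE)
  } else {
    rows <- lapply(readLines(path, warn = FALSE), jsonlite::fromJSON)
    lib <- do.call(rbind, lapply(rows, function(m) {
      data.frame(id = m$id, kind = m$kind, text = m$text,
                 stringsAsFactors = FALSE)
    }))
  }
  stopifnot(all(c("id", "kind", "text") %in% names(lib)))
  lib
}
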