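# Descriptive engagement, endorsement, retention, and care-use analytics
# over event logs and instrument scores. All percentages are integers,
# rounded half-up to match the reporting style of trial tables.

#' Half-up rounding and integer percentages
#'
#' `round_half_up()` rounds halves away from zero-wards-up (2.5 -> 3),
#' unlike base R's round-half-even. `percent_of()` is the integer
#' percentage `round(100 * count / total)` under that rule.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @param count,total Non-negative counts, `count <= total`, `total > 0`.
#' @return Numeric / integer vector.
#' @examples
#' percent_of(43, 55)  # 78
#' percent_of(45, 52)  # 87
#' @export
round_half_up <- function(x, digits = 0L) {
  f <- 10^digits
  floor(x * f + 0.5) / f
}

#' @rdname round_half_up
#' @export
percent_of <- function(count, total) {
  if (any(total <= 0)) {
    .err("mosth_validation_error", "total must be positive")
  }
  if (any(count < 0 | count > total)) {
    .err("mosth_validation_error", "count must lie in [0, total]")
  }
  as.integer(round_half_up(100 * count / total))
}

.kinds <- function(log) vapply(log, `[[`, "", "event_kind")

# Per-participant prompt/completion counts from a flat or per-participant
# log list. A reprompt belongs to the same check-in and is never counted
# as a separate prompt. A text check-in counts as completed when a reply
# carrying one of the five rating levels was recorded for it.
.participant_counts <- function(plog) {
  kinds <- .kinds(plog)
  text_completed <- sum(vapply(plog, function(e) {
    e$event_kind == "text_reply" && !is.null(e$payload$rating) &&
      !is.na(e$payload$rating) && e$payload$rating %in% .RATING_LEVELS
  }, TRUE))
  web_completed <- sum(vapply(plog, function(e) {
    e$event_kind == "web_submit" && !isFALSE(e$payload$completed)
  }, TRUE))
  data.frame(
    text_prompted = sum(kinds == "send_text_checkin"),
    text_completed = text_completed,
    web_prompted = sum(kinds == "send_web_link"),
    web_completed = web_completed,
    stringsAsFactors = FALSE
  )
}

.as_log_list <- function(logs) {
  if (inherits(logs, "event_log")) return(split_event_log(logs))
  if (length(logs) == 0L) return(list())
  split_event_log(event_log(do.call(c, lapply(logs, unclass))))
}

#' Cohort engagement summary
#'
#' Per-participant counts of text and web check-in prompts and
#' completions, cohort medians and ranges of those counts (over
#' participants with at least one prompt of the given modality), and
#' integer completion percentages. Reprompts are part of the same check-in
#' and are excluded from the prompt denominators.
#'
#' @param logs An [event_log()] or a list of per-participant logs.
#' @return A list of class `engagement_summary`: `per_participant`
#'   (data.frame), total prompt/completion counts, `text_completion_pct`,
#'   `web_completion_pct`, and `text_median`/`text_range` /
#'   `web_median`/`web_range`.
#' @export
engagement_summary <- function(logs) {
  per <- .as_log_list(logs)
  if (length(per) == 0L) {
    out <- list(per_participant = data.frame(participant_id = character(),
                                             text_prompted = integer(),
                                             text_completed = integer(),
                                             web_prompted = integer(),
                                             web_completed = integer()),
                text_prompted = 0L, text_completed = 0L,
                web_prompted = 0L, web_completed = 0L,
                text_completion_pct = NA_integer_,
                web_completion_pct = NA_integer_,
                text_median = NA_real_, text_range = c(NA_real_, NA_real_),
                web_median = NA_real_, web_range = c(NA_real_, NA_real_))
    class(out) <- "engagement_summary"
    return(out)
  }
  rows <- do.call(rbind, lapply(per, .participant_counts))
  rows <- cbind(data.frame(participant_id = names(per),
                           stringsAsFactors = FALSE),
                rows, row.names = NULL)
  if (any(rows$text_completed > rows$text_prompted) ||
      any(rows$web_completed > rows$web_prompted)) {
    .err("mosth_validation_error",
         "completions exceed prompts: log is not protocol-valid")
  }
  tp <- sum(rows$text_prompted); tc <- sum(rows$text_completed)
  wp <- sum(rows$web_prompted); wc <- sum(rows$web_completed)
  tn <- rows$text_prompted[rows$text_prompted > 0L]
  wn <- rows$web_prompted[rows$web_prompted > 0L]
  out <- list(
    per_participant = rows,
    text_prompted = tp, text_completed = tc,
    web_prompted = wp, web_completed = wc,
    text_completion_pct = if (tp > 0L) percent_of(tc, tp) else NA_integer_,
    web_completion_pct = if (wp > 0L) percent_of(wc, wp) else NA_integer_,
    text_median = if (length(tn)) stats::median(tn) else NA_real_,
    text_range = if (length(tn)) range(tn) else c(NA_real_, NA_real_),
    web_median = if (length(wn)) stats::median(wn) else NA_real_,
    web_range = if (length(wn)) range(wn) else c(NA_real_, NA_real_)
  )
  class(out) <- "engagement_summary"
  out
}

#' @export
print.engagement_summary <- function(x, ...) {
  cat(sprintf(
    paste0("Engagement over %d participant(s)\n",
           "  text check-ins: %d prompted, %d completed (%s%%); ",
           "median %s (range %s-%s)\n",
           "  web check-ins:  %d prompted, %d completed (%s%%); ",
           "median %s (range %s-%s)\n"),
    nrow(x$per_participant),
    x$text_prompted, x$text_completed, x$text_completion_pct,
    x$text_median, x$text_range[1], x$text_range[2],
    x$web_prompted, x$web_completed, x$web_completion_pct,
    x$web_median, x$web_range[1], x$web_range[2]))
  invisible(x)
}

#' Stressor and negative-effect endorsement frequencies
#'
#' Per-item endorsement counts over completed web check-ins, with integer
#' percentages of the completed-check-in denominator, plus per-check-in
#' medians and ranges of the number of stressors and of negative effects
#' reported.
#'
#' @param logs An [event_log()] or a list of per-participant logs.
#' @return A list of class `frequency_table`: `table` (data.frame with
#'   `item`, `category`, `count`, `pct`), `n_completed`,
#'   `stressor_median`, `stressor_range`, `effect_median`, `effect_range`.
#' @export
endorsement_frequencies <- function(logs) {
  per <- .as_log_list(logs)
  flat <- if (length(per)) do.call(c, lapply(per, unclass)) else list()
  subs <- Filter(function(e) e$event_kind == "web_submit" &&
                   !isFALSE(e$payload$completed), flat)
  n <- length(subs)
  if (n == 0L) {
    out <- list(table = data.frame(item = character(),
                                   category = character(),
                                   count = integer(), pct = integer(),
                                   stringsAsFactors = FALSE),
                n_completed = 0L,
                stressor_median = NA_real_,
                stressor_range = c(NA_real_, NA_real_),
                effect_median = NA_real_,
                effect_range = c(NA_real_, NA_real_))
    class(out) <- "frequency_table"
    return(out)
  }
  get_set <- function(e, field) as.character(unlist(e$payload[[field]]))
  s_sets <- lapply(subs, get_set, "stressors")
  e_sets <- lapply(subs, get_set, "negative_effects")
  count_items <- function(sets, vocab, category) {
    counts <- vapply(vocab, function(v) {
      sum(vapply(sets, function(s) v %in% s, TRUE))
    }, 0L)
    data.frame(item = vocab, category = category, count = as.integer(counts),
               pct = percent_of(as.integer(counts), n),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  tab <- rbind(count_items(s_sets, .STRESSOR_VOCAB, "stressor"),
               count_items(e_sets, .EFFECT_VOCAB, "negative_effect"))
  s_n <- vapply(s_sets, length, 0L)
  e_n <- vapply(e_sets, length, 0L)
  out <- list(table = tab, n_completed = n,
              stressor_median = stats::median(s_n),
              stressor_range = range(s_n),
              effect_median = stats::median(e_n),
              effect_range = range(e_n))
  class(out) <- "frequency_table"
  out
}

#' Retention percentage at a follow-up wave
#'
#' @param enrolled Number enrolled (> 0).
#' @param completed_at_wave Number completing the wave's assessment
#'   battery (`<= enrolled`).
#' @return Integer percentage.
#' @examples
#' retention_rate(52, 45)  # 87
#' @export
retention_rate <- function(enrolled, completed_at_wave) {
  if (enrolled <= 0) {
    .err("mosth_validation_error", "enrolled must be > 0")
  }
  if (completed_at_wave > enrolled || completed_at_wave < 0) {
    .err("mosth_validation_error",
         "completed_at_wave must lie in [0, enrolled]")
  }
  percent_of(completed_at_wave, enrolled)
}

.CARE_TYPES <- c("any", "inpatient", "outpatient", "primary_care")

#' Care-use counts and percentages by arm and wave
#'
#' Tabulates per-participant monthly care indicators into counts and
#' integer percentages per arm, wave, and care type; denominators are the
#' wave-specific per-arm sample sizes (distinct participants with any
#' indicator at that arm and wave).
#'
#' @param records A long data.frame with columns `participant_id`, `arm`,
#'   `wave`, `care_type` (one of any / inpatient / outpatient /
#'   primary_care), and logical `received`.
#' @return A data.frame with `arm`, `wave`, `care_type`, `n`, `count`,
#'   `pct`.
#' @export
care_use_table <- function(records) {
  needed <- c("participant_id", "arm", "wave", "care_type", "received")
  if (!all(needed %in% names(records))) {
    .err("mosth_validation_error",
         paste("records needs columns:", paste(needed, collapse = ", ")))
  }
  if (nrow(records) == 0L) {
    return(data.frame(arm = character(), wave = character(),
                      care_type = character(), n = integer(),
                      count = integer(), pct = integer(),
                      stringsAsFactors = FALSE))
  }
  bad <- setdiff(unique(records$care_type), .CARE_TYPES)
  if (length(bad) > 0L) {
    .err("mosth_validation_error",
         paste("unknown care type(s):", paste(bad, collapse = ", ")))
  }
  cells <- unique(records[c("arm", "wave")])
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sub <- records[records$arm == cells$arm[i] &
                   records$wave == cells$wave[i], ]
    denom <- length(unique(sub$participant_id))
    do.call(rbind, lapply(.CARE_TYPES, function(ct) {
      cnt <- length(unique(sub$participant_id[sub$care_type == ct &
                                              sub$received]))
      data.frame(arm = cells$arm[i], wave = cells$wave[i], care_type = ct,
                 n = denom, count = cnt, pct = percent_of(cnt, denom),
                 stringsAsFactors = FALSE)
    }))
  }))
  row.names(out) <- NULL
  out
}

#' Longitudinal instrument-score means
#'
#' Cell means and sample standard deviations (n - 1 denominator) of
#' instrument scores grouped by arm and assessment wave (and optionally by
#' subscale), the layout used for symptom tables. A cell with one value
#' has an `NA` SD; an empty cell is absent from the output.
#'
#' @param scores A data.frame with columns `arm`, `wave`, `score`, and
#'   optionally `subscale`.
#' @return A data.frame with the grouping columns plus `n`, `mean`, `sd`.
#' @export
longitudinal_means <- function(scores) {
  needed <- c("arm", "wave", "score")
  if (!all(needed %in% names(scores))) {
    .err("mosth_validation_error",
         paste("scores needs columns:", paste(needed, collapse = ", ")))
  }
  by_cols <- intersect(c("arm", "wave", "subscale"), names(scores))
  scores <- scores[!is.na(scores$score), , drop = FALSE]
  if (nrow(scores) == 0L) {
    return(cbind(scores[by_cols],
                 data.frame(n = integer(), mean = numeric(),
                            sd = numeric())))
  }
  agg <- aggregate(scores["score"], by = scores[by_cols], FUN = length)
  names(agg)[names(agg) == "score"] <- "n"
  agg$mean <- aggregate(scores["score"], by = scores[by_cols],
                        FUN = mean)$score
  agg$sd <- aggregate(scores["score"], by = scores[by_cols], FUN = function(v) {
    if (length(v) < 2L) NA_real_ else stats::sd(v)
  })$score
  agg[order(agg[[1L]], agg[[2L]]), , drop = FALSE]
}
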