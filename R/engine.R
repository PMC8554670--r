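# The per-participant state machine.
#
# The engine is a pure function of (state, input, clock): every operation
# takes a state and returns list(state = <new state>, actions = <ordered
# list of actions>). Replaying the same event stream therefore yields an
# identical action stream. Time is a whole-day clock with day 0 = the
# enrollment day.
#
# Protocol in brief: a text check-in asks for a weekly emotional-health
# rating. POSITIVE ratings (excellent / very good / good) get positive
# feedback plus the video-library link and the next check-in steps down to
# monthly. SUBOPTIMAL ratings (fair / poor) trigger a web check-in
# collecting stressors, negative effects, and a self-efficacy gate; HIGH
# self-efficacy ("completely") steps down to monthly, LOW steps up to
# weekly with a skill message, the video link, and an "ok to check in next
# week?" ask. A repeat LOW report adds a care-seeking prompt, and two
# qualifying check-ins (suboptimal + low self-efficacy) at most 14 days
# apart trigger the safety escalation. Unanswered prompts are reprompted
# exactly once, then marked missed and rescheduled a week out. Texting
# "Quit" is absorbing: no action is ever emitted afterwards.

.err <- function(class, msg) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1L))))
}

.action <- function(kind, day, template = NULL, data = list(),
                    comparison = NULL, scheduled_day = NA_integer_) {
  list(kind = kind, day = as.integer(day),
       payload = list(template = template, data = data,
                      comparison = comparison),
       scheduled_day = as.integer(scheduled_day))
}

#' Single check-in records
#'
#' `text_checkin()` records one text-message check-in: its prompt day, the
#' observed rating (or `NA` when the check-in was missed), and whether a
#' reprompt was needed. `web_checkin()` records one web check-in: the
#' endorsed stressors and negative effects and the self-efficacy answer; an
#' incomplete (`completed = FALSE`) record carries no content.
#'
#' @param day Days since enrollment (day 0 = enrollment), non-negative.
#' @param rating One of [rating_levels()] or `NA`.
#' @param reprompted Whether the single allowed reprompt was sent.
#' @param stressors Subset of [stressor_vocabulary()].
#' @param negative_effects Subset of [effect_vocabulary()].
#' @param self_efficacy One of [self_efficacy_levels()] or `NA`.
#' @param completed Whether the web check-in was completed.
#' @return A list of class `text_checkin` / `web_checkin`.
#' @export
text_checkin <- function(day, rating = NA_character_, reprompted = FALSE) {
  day <- as.integer(day)
  if (is.na(day) || day < 0L) {
    .err("mosth_validation_error", "check-in day must be >= 0")
  }
  if (!is.na(rating) && !rating %in% .RATING_LEVELS) {
    .err("mosth_validation_error",
         sprintf("unknown rating '%s'", rating))
  }
  structure(list(day = day, rating = rating,
                 reprompted = isTRUE(reprompted)),
            class = "text_checkin")
}

#' @rdname text_checkin
#' @export
web_checkin <- function(day, stressors = character(),
                        negative_effects = character(),
                        self_efficacy = NA_character_, completed = TRUE) {
  day <- as.integer(day)
  if (is.na(day) || day < 0L) {
    .err("mosth_validation_error", "check-in day must be >= 0")
  }
  if (!completed) {
    stressors <- character()
    negative_effects <- character()
    self_efficacy <- NA_character_
  } else {
    bad_s <- setdiff(stressors, .STRESSOR_VOCAB)
    if (length(bad_s) > 0L) {
      .err("mosth_validation_error",
           paste("unknown stressor token(s):", paste(bad_s, collapse = ", ")))
    }
    bad_e <- setdiff(negative_effects, .EFFECT_VOCAB)
    if (length(bad_e) > 0L) {
      .err("mosth_validation_error",
           paste("unknown negative-effect token(s):",
                 paste(bad_e, collapse = ", ")))
    }
    if (is.na(self_efficacy) || !self_efficacy %in% .SE_LEVELS) {
      .err("mosth_validation_error",
           "completed web check-in requires a self-efficacy level")
    }
  }
  structure(list(day = day, stressors = unique(stressors),
                 negative_effects = unique(negative_effects),
                 self_efficacy = self_efficacy, completed = isTRUE(completed)),
            class = "web_checkin")
}

#' Enroll a participant and start the program
#'
#' Emits the welcome message sequence (what to expect, privacy advice, and
#' how to quit) and schedules the first text check-in on the enrollment day
#' itself; the check-in prompt fires when the clock is advanced to that day
#' with [advance_clock()].
#'
#' @param participant_id Opaque participant token.
#' @param enrolled_day Enrollment day (the participant's day 0 reference).
#' @param config Engine configuration, see [default_config()].
#' @param existing An existing state for the same participant, if any;
#'   passing one raises an already-enrolled error.
#' @return `list(state, actions)`.
#' @examples
#' res <- start_program("p1", 0)
#' res$state$next_checkin_day
#' sapply(res$actions, `[[`, "kind")
#' @export
start_program <- function(participant_id, enrolled_day = 0L,
                          config = default_config(), existing = NULL) {
  if (!is.null(existing) &&
      identical(existing$participant_id, participant_id)) {
    .err("mosth_already_enrolled",
         sprintf("participant '%s' is already enrolled", participant_id))
  }
  enrolled_day <- as.integer(enrolled_day)
  if (is.na(enrolled_day) || enrolled_day < 0L) {
    .err("mosth_validation_error", "enrolled_day must be >= 0")
  }
  state <- structure(list(
    participant_id = participant_id,
    enrolled_day = enrolled_day,
    day = enrolled_day,
    next_checkin_day = enrolled_day,
    active = TRUE,
    quit = FALSE,
    pending_text = NULL,
    pending_web = NULL,
    history = list(),
    consecutive_flag_count = 0L,
    skill_cursor = 0L,
    last_web = NULL,
    safety_prompts = 0L,
    config = config
  ), class = "participant_state")

  welcome <- config$messages[config$messages$kind == "send_welcome", ,
                             drop = FALSE]
  actions <- lapply(welcome$id, function(id) {
    .action("send_welcome", enrolled_day, template = id)
  })
  list(state = state, actions = actions)
}

# The next internal deadline for a state: the pending reprompt or
# missed-marking, else the scheduled check-in. NULL when nothing is due.
.next_event <- function(state) {
  if (!state$active) return(NULL)
  cfg <- state$config
  pend <- function(p, what) {
    if (!p$reprompted) {
      list(day = p$prompt_day + cfg$reprompt_delay,
           type = paste0(what, "_reprompt"))
    } else {
      list(day = p$reprompt_day + cfg$missing_delay,
           type = paste0(what, "_missed"))
    }
  }
  if (!is.null(state$pending_text)) return(pend(state$pending_text, "text"))
  if (!is.null(state$pending_web)) return(pend(state$pending_web, "web"))
  if (!is.na(state$next_checkin_day)) {
    return(list(day = state$next_checkin_day, type = "checkin"))
  }
  NULL
}

#' Day of the next scheduled engine event
#'
#' The day on which [advance_clock()] would next emit something (a check-in
#' prompt, a reprompt, or a missed-marking), or `NA` when the participant
#' has quit or nothing is scheduled. Drivers use this to jump the clock
#' from event to event instead of stepping day by day.
#'
#' @param state A participant state.
#' @return Integer day or `NA`.
#' @export
next_event_day <- function(state) {
  ev <- .next_event(state)
  if (is.null(ev)) NA_integer_ else as.integer(ev$day)
}

# Mark the pending text check-in missed: record a rating-less check-in,
# reschedule a week from the original prompt day.
.mark_text_missed <- function(state, day) {
  p <- state$pending_text
  entry <- list(text = text_checkin(p$prompt_day, NA_character_,
                                    reprompted = p$reprompted),
                web = NULL)
  state$history[[length(state$history) + 1L]] <- entry
  state$pending_text <- NULL
  state$next_checkin_day <- p$prompt_day + state$config$missing_reschedule
  list(state = state,
       action = .action("none", day, data = list(note = "text_checkin_missed")))
}

# Mark the pending web check-in missed: the open history entry gets an
# incomplete web record; the escalation counter is left untouched.
.mark_web_missed <- function(state, day) {
  p <- state$pending_web
  n <- length(state$history)
  state$history[[n]]$web <- web_checkin(p$prompt_day, completed = FALSE)
  state$pending_web <- NULL
  state$next_checkin_day <- p$prompt_day + state$config$missing_reschedule
  list(state = state,
       action = .action("none", day, data = list(note = "web_checkin_missed")))
}

#' Advance the participant clock
#'
#' Moves the clock forward to `to_day`, firing every deadline passed on the
#' way: scheduled check-in prompts, the single reprompt of an unanswered
#' prompt (sent `reprompt_delay` days after it), and missed-markings
#' (`missing_delay` days after the reprompt, rescheduling the next check-in
#' `missing_reschedule` days after the original prompt). A participant who
#' has quit never receives another action.
#'
#' @param state A participant state.
#' @param to_day Target day; must not precede the current clock.
#' @param config Ignored; kept on the state.
#' @return `list(state, actions)`.
#' @export
advance_clock <- function(state, to_day, config = NULL) {
  to_day <- as.integer(to_day)
  if (to_day < state$day) {
    .err("mosth_time_error",
         sprintf("cannot move clock backwards from day %d to day %d",
                 state$day, to_day))
  }
  actions <- list()
  repeat {
    ev <- .next_event(state)
    if (is.null(ev) || ev$day > to_day) break
    d <- ev$day
    state$day <- max(state$day, d)
    if (ev$type == "checkin") {
      actions[[length(actions) + 1L]] <-
        .action("send_text_checkin", d, template = "text_checkin")
      state$pending_text <- list(prompt_day = d, reprompted = FALSE,
                                 reprompt_day = NA_integer_)
      state$next_checkin_day <- NA_integer_
    } else if (ev$type == "text_reprompt") {
      actions[[length(actions) + 1L]] <-
        .action("reprompt", d, template = "text_checkin")
      state$pending_text$reprompted <- TRUE
      state$pending_text$reprompt_day <- d
    } else if (ev$type == "text_missed") {
      res <- .mark_text_missed(state, d)
      state <- res$state
      actions[[length(actions) + 1L]] <- res$action
    } else if (ev$type == "web_reprompt") {
      actions[[length(actions) + 1L]] <-
        .action("reprompt", d, template = "web_link",
                data = list(web_url = state$config$web_url))
      state$pending_web$reprompted <- TRUE
      state$pending_web$reprompt_day <- d
    } else if (ev$type == "web_missed") {
      res <- .mark_web_missed(state, d)
      state <- res$state
      actions[[length(actions) + 1L]] <- res$action
    }
  }
  state$day <- to_day
  list(state = state, actions = actions)
}

#' Schedule the next check-in
#'
#' The adaptive cadence rule: POSITIVE rating, or SUBOPTIMAL rating with
#' HIGH self-efficacy, steps down to `current_day + 30` (monthly);
#' SUBOPTIMAL with LOW self-efficacy steps up to `current_day + 7`
#' (weekly). Inactive participants get `NA`.
#'
#' @param rating One of [rating_levels()].
#' @param self_efficacy One of [self_efficacy_levels()], or `NULL`/`NA` for
#'   a POSITIVE rating (no web check-in occurred).
#' @param current_day Day the outcome was observed.
#' @param config Engine configuration.
#' @param active Whether the participant is still active.
#' @return Integer day, or `NA` for an inactive participant.
#' @examples
#' decide_next_checkin("good", NULL, 10)        # 40
#' decide_next_checkin("poor", "not_at_all", 10) # 17
#' @export
decide_next_checkin <- function(rating, self_efficacy = NULL, current_day,
                                config = default_config(), active = TRUE) {
  if (!active) return(NA_integer_)
  current_day <- as.integer(current_day)
  if (is_positive_rating(rating)) {
    return(current_day + config$monthly_interval)
  }
  if (!is_suboptimal_rating(rating)) {
    .err("mosth_validation_error", sprintf("unknown rating '%s'", rating))
  }
  if (is.null(self_efficacy) || is.na(self_efficacy)) {
    .err("mosth_validation_error",
         "suboptimal rating needs a self-efficacy level to schedule from")
  }
  if (is_low_self_efficacy(self_efficacy)) {
    current_day + config$weekly_interval
  } else {
    current_day + config$monthly_interval
  }
}

#' Process a raw text reply to a pending check-in
#'
#' The clock is first advanced to `day` (firing any deadlines on the way).
#' A parseable rating resolves the pending check-in: POSITIVE ratings get
#' positive feedback with the video link and a monthly reschedule;
#' SUBOPTIMAL ratings get the web check-in link and the engine awaits the
#' web outcome. "Quit" (case-insensitive) is absorbing. An unparseable
#' reply is reprompted once; a second unparseable reply marks the check-in
#' missed under the missing-response policy.
#'
#' @param state A participant state with a pending text check-in.
#' @param day Reply day (>= the prompt day).
#' @param reply Raw reply text.
#' @return `list(state, actions)`.
#' @export
process_text_reply <- function(state, day, reply) {
  if (state$quit || !state$active) {
    .err("mosth_protocol_error", "participant is no longer active")
  }
  adv <- advance_clock(state, day)
  state <- adv$state
  actions <- adv$actions
  if (is.null(state$pending_text)) {
    .err("mosth_protocol_error", "no text check-in is pending")
  }
  cfg <- state$config
  p <- state$pending_text
  parsed <- parse_reply(reply)

  if (identical(parsed, "quit")) {
    state$quit <- TRUE
    state$active <- FALSE
    state$pending_text <- NULL
    state$pending_web <- NULL
    state$next_checkin_day <- NA_integer_
    return(list(state = state, actions = actions))
  }

  if (is.na(parsed)) {
    if (!p$reprompted) {
      state$pending_text$reprompted <- TRUE
      state$pending_text$reprompt_day <- as.integer(day)
      actions[[length(actions) + 1L]] <-
        .action("reprompt", day, template = "text_checkin")
    } else {
      res <- .mark_text_missed(state, day)
      state <- res$state
      actions[[length(actions) + 1L]] <- res$action
    }
    return(list(state = state, actions = actions))
  }

  checkin <- text_checkin(p$prompt_day, parsed, reprompted = p$reprompted)
  state$pending_text <- NULL

  if (is_positive_rating(parsed)) {
    state$history[[length(state$history) + 1L]] <-
      list(text = checkin, web = NULL)
    state$consecutive_flag_count <- 0L
    state$next_checkin_day <-
      decide_next_checkin(parsed, NULL, day, cfg)
    actions[[length(actions) + 1L]] <-
      .action("send_positive_feedback_with_video", day,
              template = "positive_feedback",
              data = list(video_url = cfg$video_url),
              scheduled_day = state$next_checkin_day)
  } else {
    # suboptimal: open a web check-in and wait for it
    state$history[[length(state$history) + 1L]] <-
      list(text = checkin, web = NULL)
    state$pending_web <- list(prompt_day = as.integer(day),
                              reprompted = FALSE,
                              reprompt_day = NA_integer_)
    state$next_checkin_day <- NA_integer_
    actions[[length(actions) + 1L]] <-
      .action("send_web_link", day, template = "web_link",
              data = list(web_url = cfg$web_url))
  }
  list(state = state, actions = actions)
}

#' Compare two completed web check-ins
#'
#' Partitions each of the stressor and negative-effect sets into items
#' resolved since the prior check-in (`prior \ current`), persisting items
#' (`prior` intersect `current`), and newly reported items
#' (`current \ prior`). The three sets are pairwise disjoint;
#' resolved + persisting recover the prior set and new + persisting the
#' current one.
#'
#' @param prior,current Completed [web_checkin()] records.
#' @return `list(stressors = list(resolved, persisting, new),
#'   negative_effects = list(resolved, persisting, new))`.
#' @examples
#' a <- web_checkin(0, stressors = c("school", "finances"),
#'                  self_efficacy = "a_little")
#' b <- web_checkin(7, stressors = "school", self_efficacy = "somewhat")
#' compare_checkins(a, b)$stressors$resolved
#' @export
compare_checkins <- function(prior, current) {
  if (!isTRUE(prior$completed) || !isTRUE(current$completed)) {
    .err("mosth_validation_error",
         "both check-ins must be completed to compare them")
  }
  part <- function(a, b) {
    list(resolved = setdiff(a, b), persisting = intersect(a, b),
         new = setdiff(b, a))
  }
  list(stressors = part(prior$stressors, current$stressors),
       negative_effects = part(prior$negative_effects,
                               current$negative_effects))
}

# Does a history entry qualify for the safety rule? Requires an observed
# suboptimal (or strictly poor, per config) rating together with a
# completed web check-in reporting low self-efficacy.
.qualifies <- function(entry, config) {
  r <- entry$text$rating
  rating_ok <- if (identical(config$escalation_rating, "poor")) {
    !is.na(r) && r == "poor"
  } else {
    is_suboptimal_rating(r)
  }
  rating_ok && !is.null(entry$web) && isTRUE(entry$web$completed) &&
    is_low_self_efficacy(entry$web$self_efficacy)
}

#' Safety escalation rule
#'
#' `TRUE` iff the two most recent check-ins in the history both carry a
#' suboptimal rating with a low self-efficacy report and their prompt days
#' are at most 14 days apart (consecutive weekly cadence) — the "poor
#' mental health and low self-efficacy 2 weeks in a row" rule. Evaluated
#' once after each completed web check-in, so each qualifying pair fires at
#' most once.
#'
#' @param state A participant state.
#' @return Logical.
#' @export
check_safety_escalation <- function(state) {
  h <- state$history
  n <- length(h)
  if (n < 2L) return(FALSE)
  cfg <- state$config
  a <- h[[n - 1L]]
  b <- h[[n]]
  .qualifies(a, cfg) && .qualifies(b, cfg) &&
    (b$text$day - a$text$day) <= cfg$escalation_window
}

#' Process a completed (or abandoned) web check-in
#'
#' Resolves the outstanding web link. HIGH self-efficacy ("completely")
#' earns positive feedback with the video link and a monthly reschedule;
#' LOW self-efficacy earns a skill message (round-robin from the skills
#' library, with the video link), the "ok to check in next week?" ask, and
#' a weekly reschedule. When a prior completed web check-in exists the
#' feedback payload carries the [compare_checkins()] record so rendered
#' feedback reflects improvement and unresolved items. A repeat check-in
#' with still-low self-efficacy additionally emits the care-seeking prompt,
#' and the safety rule ([check_safety_escalation()]) is evaluated last. An
#' incomplete record is treated as missed web data: rescheduled a week from
#' the link day, escalation counter untouched.
#'
#' @param state A participant state with an outstanding web link.
#' @param checkin A [web_checkin()] record (`checkin$day` >= link day).
#' @return `list(state, actions)`.
#' @export
process_web_checkin <- function(state, checkin) {
  if (state$quit || !state$active) {
    .err("mosth_protocol_error", "participant is no longer active")
  }
  if (is.null(state$pending_web)) {
    .err("mosth_protocol_error", "no web check-in link is outstanding")
  }
  if (!inherits(checkin, "web_checkin")) {
    checkin <- do.call(web_checkin, checkin)
  }
  adv <- advance_clock(state, max(state$day, checkin$day))
  state <- adv$state
  actions <- adv$actions
  if (is.null(state$pending_web)) {
    .err("mosth_protocol_error",
         "web check-in window already closed as missed")
  }
  cfg <- state$config
  day <- checkin$day

  if (!checkin$completed) {
    res <- .mark_web_missed(state, day)
    state <- res$state
    actions[[length(actions) + 1L]] <- res$action
    return(list(state = state, actions = actions))
  }

  n <- length(state$history)
  state$history[[n]]$web <- checkin
  state$pending_web <- NULL

  cmp <- if (!is.null(state$last_web)) compare_checkins(state$last_web, checkin)
  state$last_web <- checkin

  low <- is_low_self_efficacy(checkin$self_efficacy)
  if (low) {
    state$consecutive_flag_count <- state$consecutive_flag_count + 1L
  } else {
    state$consecutive_flag_count <- 0L
  }

  if (!low) {
    state$next_checkin_day <-
      decide_next_checkin(state$history[[n]]$text$rating,
                          checkin$self_efficacy, day, cfg)
    actions[[length(actions) + 1L]] <-
      .action("send_positive_feedback_with_video", day,
              template = if (is.null(cmp)) "positive_feedback"
                         else "positive_feedback_progress",
              data = list(video_url = cfg$video_url),
              comparison = cmp,
              scheduled_day = state$next_checkin_day)
  } else {
    skill <- next_skill_message(state, cfg$messages)
    state <- skill$state
    state$next_checkin_day <-
      decide_next_checkin(state$history[[n]]$text$rating,
                          checkin$self_efficacy, day, cfg)
    if (is.null(cmp)) {
      actions[[length(actions) + 1L]] <-
        .action("send_skill_message", day,
                template = skill$template$id,
                data = list(video_url = cfg$video_url),
                scheduled_day = state$next_checkin_day)
    } else {
      skill_text <- render_message(
        list(kind = "send_skill_message",
             payload = list(template = skill$template$id,
                            data = list(video_url = cfg$video_url))),
        library = cfg$messages
      )
      actions[[length(actions) + 1L]] <-
        .action("send_skill_message", day,
                template = "skill_feedback_progress",
                data = list(skill_text = skill_text,
                            video_url = cfg$video_url),
                comparison = cmp,
                scheduled_day = state$next_checkin_day)
    }
    actions[[length(actions) + 1L]] <-
      .action("send_weekly_consent_ask", day,
              template = "weekly_consent_ask")
    if (state$consecutive_flag_count >= 2L) {
      actions[[length(actions) + 1L]] <-
        .action("send_care_prompt", day, template = "care_prompt",
                data = list(resources_url = cfg$resources_url))
    }
  }

  if (check_safety_escalation(state)) {
    state$safety_prompts <- state$safety_prompts + 1L
    actions[[length(actions) + 1L]] <-
      .action("send_safety_care_prompt", day,
              template = "safety_care_prompt",
              data = list(resources_url = cfg$resources_url))
  }
  list(state = state, actions = actions)
}
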