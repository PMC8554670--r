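# Shared helpers: a scripted engine driver and small state builders.

# Drive one participant through a scripted reply stream. `script` is a list
# of steps; each step answers the next text prompt with `reply` (NULL =
# ignore prompt and reprompt) and, when a web link follows, submits `web`
# (a list(stressors, effects, self_efficacy); NULL = ignore the link).
# Returns list(state, actions, prompts).
drive_script <- function(script, horizon = 90L, config = default_config(),
                         id = "s1") {
  state <- start_program(id, 0L, config)$state
  actions <- list()
  step_i <- 0L
  repeat {
    nd <- next_event_day(state)
    if (is.na(nd) || nd > horizon - 1L || !state$active) break
    out <- advance_clock(state, nd)
    state <- out$state
    actions <- c(actions, out$actions)
    for (a in out$actions) {
      if (a$kind == "send_text_checkin") {
        step_i <- step_i + 1L
        step <- if (step_i <= length(script)) script[[step_i]] else NULL
        if (!is.null(step) && !is.null(step$reply)) {
          res <- process_text_reply(state, a$day, step$reply)
          state <- res$state
          actions <- c(actions, res$actions)
          if (!is.null(state$pending_web) && !is.null(step$web)) {
            wc <- web_checkin(
              a$day,
              stressors = step$web$stressors %||% character(),
              negative_effects = step$web$effects %||% character(),
              self_efficacy = step$web$self_efficacy
            )
            res <- process_web_checkin(state, wc)
            state <- res$state
            actions <- c(actions, res$actions)
          }
        }
      }
    }
  }
  list(state = state, actions = actions,
       prompts = sum(vapply(actions, function(a)
         a$kind == "send_text_checkin", TRUE)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

action_kinds <- function(actions) vapply(actions, `[[`, "", "kind")

event_kinds <- function(log) vapply(log, `[[`, "", "event_kind")

# Build a participant state with an injected check-in history. Each history
# element: list(day, rating, low_se) with low_se NA meaning no (or
# incomplete) web check-in.
state_with_history <- function(entries, config = default_config()) {
  state <- start_program("h1", 0L, config)$state
  state$history <- lapply(entries, function(e) {
    web <- if (is.na(e$low_se)) {
      NULL
    } else {
      web_checkin(e$day,
                  self_efficacy = if (e$low_se) "a_little" else "completely")
    }
    list(text = text_checkin(e$day, e$rating), web = web)
  })
  state
}

# Degenerate profiles used across tests.
always_good_profile <- function() {
  behavior_profile(p_rating = c(0, 0, 1, 0, 0), p_stressor = rep(0, 6),
                   p_effect = rep(0, 9), p_low_se = 0)
}

always_poor_low_profile <- function() {
  behavior_profile(p_rating = c(0, 0, 0, 0, 1), p_stressor = rep(0.5, 6),
                   p_effect = rep(0.5, 9), p_low_se = 1)
}
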