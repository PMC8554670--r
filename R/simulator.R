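# Seeded stochastic cohort simulator: samples participant behavior from a
# BehaviorProfile and drives the engine in closed loop, producing protocol-
# valid event logs whose engagement statistics match the calibration
# constants (text completion 100%, web completion 78%, low self-efficacy
# 91%, Table-2-style endorsement frequencies).

#' Behavior profile of one simulated participant
#'
#' The stochastic model of one participant's check-in behavior.
#'
#' @param p_rating Probability vector over the five rating levels (in
#'   [rating_levels()] order, or named); must sum to 1.
#' @param p_stressor Per-item endorsement probabilities over the six
#'   stressors (in [stressor_vocabulary()] order, or named).
#' @param p_effect Per-item endorsement probabilities over the nine
#'   negative effects (in [effect_vocabulary()] order, or named).
#' @param p_low_se Probability of a LOW self-efficacy answer on a completed
#'   web check-in (the LOW level is then drawn uniformly from "somewhat",
#'   "a_little", "not_at_all").
#' @param p_text_nonresponse,p_web_nonresponse Probability a prompt ends
#'   unanswered, i.e. that both the original prompt and its single reprompt
#'   are ignored. The two ignores are independent draws, each with
#'   probability `sqrt(p)`, so the overall nonresponse rate equals `p`.
#' @param p_quit Per-reply probability of texting Quit (default 0; no
#'   participant quit in the trial this simulator is calibrated to).
#' @param carry_over Probability that a stressor/effect endorsement state
#'   is copied from the participant's previous web check-in rather than
#'   redrawn (default 0.5). Copying leaves the marginal endorsement rate at
#'   the profile probability while inducing the within-person persistence
#'   that exercises resolved / persisting / new feedback.
#' @return A list of class `behavior_profile`.
#' @export
behavior_profile <- function(p_rating, p_stressor, p_effect, p_low_se,
                             p_text_nonresponse = 0, p_web_nonresponse = 0,
                             p_quit = 0, carry_over = 0.5) {
  align <- function(p, vocab, what) {
    if (length(p) != length(vocab)) {
      .err("mosth_validation_error",
           sprintf("%s must have length %d", what, length(vocab)))
    }
    if (!is.null(names(p))) {
      if (!setequal(names(p), vocab)) {
        .err("mosth_validation_error",
             sprintf("%s names must match the canonical vocabulary", what))
      }
      p <- p[vocab]
    } else {
      names(p) <- vocab
    }
    if (any(p < 0 | p > 1)) {
      .err("mosth_validation_error",
           sprintf("%s entries must be probabilities in [0,1]", what))
    }
    p
  }
  p_rating <- align(p_rating, .RATING_LEVELS, "p_rating")
  if (abs(sum(p_rating) - 1) > 1e-8) {
    .err("mosth_validation_error", "p_rating must sum to 1")
  }
  p_stressor <- align(p_stressor, .STRESSOR_VOCAB, "p_stressor")
  p_effect <- align(p_effect, .EFFECT_VOCAB, "p_effect")
  for (p in list(p_low_se, p_text_nonresponse, p_web_nonresponse, p_quit,
                 carry_over)) {
    if (!is.numeric(p) || length(p) != 1L || p < 0 || p > 1) {
      .err("mosth_validation_error",
           "scalar profile probabilities must lie in [0,1]")
    }
  }
  structure(list(p_rating = p_rating, p_stressor = p_stressor,
                 p_effect = p_effect, p_low_se = p_low_se,
                 p_text_nonresponse = p_text_nonresponse,
                 p_web_nonresponse = p_web_nonresponse,
                 p_quit = p_quit, carry_over = carry_over),
            class = "behavior_profile")
}

#' Default behavior-profile mixture
#'
#' A two-component mixture calibrated to the trial's printed engagement
#' behavior: an *at-risk* profile whose stressor and negative-effect
#' endorsement probabilities equal the printed per-check-in percentages
#' divided by 100 (school 0.51 ... feeling worn out 0.65 ...), whose
#' probability of a low self-efficacy report is 0.91 (low 91\%, 39/43),
#' whose text nonresponse is 0 (100\% of text check-ins were completed) and
#' web nonresponse 0.22 (78\% of web check-ins completed); and a
#' *mostly-well* profile that only ever gives POSITIVE ratings and so never
#' reaches the web check-in. The at-risk weight of 0.75 and its rating
#' distribution (45\% of ratings suboptimal) are calibrated so that about
#' 21 of 34 intervention participants report at least one suboptimal
#' rating over 90 days, with a per-participant web check-in median near 2
#' (range up to ~8) and a text check-in median in the 3-10 band.
#'
#' @return A list of `list(profile, weight)` components; weights sum to 1.
#' @examples
#' mix <- default_profiles()
#' mix[[which(sapply(mix, function(m) m$name) == "at_risk")]]$profile$p_low_se
#' @export
default_profiles <- function() {
  stressor_rates <- c(
    school = 0.51, finances = 0.37, friends_roommates = 0.28,
    family = 0.26, romantic = 0.21, other = 0.07
  )
  effect_rates <- c(
    feeling_worn_out = 0.65, low_motivation = 0.56, trouble_focusing = 0.51,
    poor_sleep = 0.47, unhealthy_eating = 0.42, overreacting = 0.33,
    no_one_to_talk_to = 0.30, alcohol_drugs_to_cope = 0.12, other = 0.02
  )
  at_risk <- behavior_profile(
    p_rating = c(excellent = 0.05, very_good = 0.20, good = 0.30,
                 fair = 0.30, poor = 0.15),
    p_stressor = stressor_rates,
    p_effect = effect_rates,
    p_low_se = 0.91,
    p_text_nonresponse = 0,
    p_web_nonresponse = 0.22
  )
  mostly_well <- behavior_profile(
    p_rating = c(excellent = 0.30, very_good = 0.40, good = 0.30,
                 fair = 0, poor = 0),
    p_stressor = stressor_rates,
    p_effect = effect_rates,
    p_low_se = 0.91,
    p_text_nonresponse = 0,
    p_web_nonresponse = 0.22
  )
  list(list(name = "at_risk", profile = at_risk, weight = 0.75),
       list(name = "mostly_well", profile = mostly_well, weight = 0.25))
}

# Raw reply text for a sampled rating token ("very_good" -> "very good").
.rating_to_raw <- function(token) gsub("_", " ", token)

#' Sample one web check-in submission from a profile
#'
#' Endorsements are drawn independently per item; when a previous
#' submission is given, each item's endorsement state is copied from it
#' with probability `carry_over` and redrawn otherwise, which preserves
#' the marginal endorsement probabilities while modelling within-person
#' persistence. Self-efficacy is LOW with probability `p_low_se`.
#'
#' @param profile A [behavior_profile()].
#' @param day Day stamp for the record.
#' @param prev The participant's previous [web_checkin()], or `NULL`.
#' @return A completed [web_checkin()].
#' @export
sample_web_submission <- function(profile, day = 0L, prev = NULL) {
  draw_set <- function(p, vocab, prev_set) {
    fresh <- runif(length(vocab)) < p
    if (is.null(prev_set)) {
      endorsed <- fresh
    } else {
      keep <- runif(length(vocab)) < profile$carry_over
      endorsed <- ifelse(keep, vocab %in% prev_set, fresh)
    }
    vocab[endorsed]
  }
  stressors <- draw_set(profile$p_stressor, .STRESSOR_VOCAB,
                        if (is.null(prev)) NULL else prev$stressors)
  effects <- draw_set(profile$p_effect, .EFFECT_VOCAB,
                      if (is.null(prev)) NULL else prev$negative_effects)
  se <- if (runif(1) < profile$p_low_se) {
    sample(.LOW_SE, 1L)
  } else {
    .HIGH_SE
  }
  web_checkin(day, stressors = stressors, negative_effects = effects,
              self_efficacy = se, completed = TRUE)
}

# Growable event recorder (environment-backed to avoid quadratic copying).
.new_recorder <- function(participant_id) {
  rec <- new.env(parent = emptyenv())
  rec$events <- vector("list", 64L)
  rec$n <- 0L
  rec$id <- participant_id
  rec
}

.record <- function(rec, day, kind, payload = NULL) {
  rec$n <- rec$n + 1L
  if (rec$n > length(rec$events)) {
    rec$events <- c(rec$events, vector("list", length(rec$events)))
  }
  rec$events[[rec$n]] <- list(participant_id = rec$id,
                              day = as.integer(day), event_kind = kind,
                              payload = payload)
  invisible(rec)
}

.record_actions <- function(rec, actions) {
  for (a in actions) {
    pay <- a$payload
    if (!is.na(a$scheduled_day)) pay$scheduled_day <- a$scheduled_day
    .record(rec, a$day, a$kind, pay)
  }
  invisible(rec)
}

#' Simulate one participant's full event log
#'
#' Drives the engine in closed loop over the program horizon: the clock
#' jumps from engine event to engine event; each prompt (and reprompt) is
#' answered or ignored according to the profile's nonresponse model;
#' ratings, web submissions, and self-efficacy answers are sampled from the
#' profile. The resulting log records the engine's actions and the
#' participant's replies in order and is protocol-valid by construction.
#' An identical seed yields a byte-identical log.
#'
#' @param profile A [behavior_profile()].
#' @param horizon_days Program length in days (prompts fire on days
#'   `0 .. horizon_days - 1`).
#' @param seed Integer seed for this participant.
#' @param participant_id Participant token.
#' @param config Engine configuration.
#' @param arm `"MoST-MH"` (full engine loop) or `"eUC"` (enhanced usual
#'   care: enrollment and the video-library link only, no check-ins).
#' @return An [event_log()].
#' @examples
#' always_good <- behavior_profile(
#'   p_rating = c(0, 0, 1, 0, 0),
#'   p_stressor = rep(0, 6), p_effect = rep(0, 9), p_low_se = 0)
#' log <- simulate_participant(always_good, 90, seed = 1)
#' sum(sapply(log, `[[`, "event_kind") == "send_text_checkin")  # 3
#' @export
simulate_participant <- function(profile, horizon_days = 90L, seed = 1L,
                                 participant_id = "p1",
                                 config = default_config(),
                                 arm = c("MoST-MH", "eUC")) {
  arm <- match.arg(arm)
  if (horizon_days < 1L) {
    .err("mosth_validation_error", "horizon_days must be >= 1")
  }
  if (!inherits(profile, "behavior_profile")) {
    .err("mosth_validation_error", "profile must be a behavior_profile")
  }
  withr::with_seed(seed, {
    rec <- .new_recorder(participant_id)
    .record(rec, 0L, "enrolled", list(arm = arm))
    if (arm == "eUC") {
      .record(rec, 0L, "video_library_link",
              list(video_url = config$video_url))
      return(event_log(rec$events[seq_len(rec$n)]))
    }

    q_text <- sqrt(profile$p_text_nonresponse)
    q_web <- sqrt(profile$p_web_nonresponse)
    last_day <- as.integer(horizon_days) - 1L

    res <- start_program(participant_id, 0L, config)
    state <- res$state
    .record_actions(rec, res$actions)
    prev_web <- NULL

    react <- function(a) {
      # returns newly emitted actions (to react to in turn), updates state
      if (a$kind == "send_text_checkin" ||
          (a$kind == "reprompt" &&
           identical(a$payload$template, "text_checkin"))) {
        if (runif(1) < q_text) return(list())
        raw <- if (profile$p_quit > 0 && runif(1) < profile$p_quit) {
          "Quit"
        } else {
          .rating_to_raw(sample(.RATING_LEVELS, 1L,
                                prob = profile$p_rating))
        }
        .record(rec, a$day, "text_reply",
                list(raw = raw, rating = parse_reply(raw)))
        out <- process_text_reply(state, a$day, raw)
        state <<- out$state
        .record_actions(rec, out$actions)
        return(out$actions)
      }
      if (a$kind == "send_web_link" ||
          (a$kind == "reprompt" &&
           identical(a$payload$template, "web_link"))) {
        if (runif(1) < q_web) return(list())
        sub <- sample_web_submission(profile, day = a$day, prev = prev_web)
        prev_web <<- sub
        .record(rec, a$day, "web_submit",
                list(completed = TRUE, stressors = sub$stressors,
                     negative_effects = sub$negative_effects,
                     self_efficacy = sub$self_efficacy))
        out <- process_web_checkin(state, sub)
        state <<- out$state
        .record_actions(rec, out$actions)
        return(out$actions)
      }
      list()
    }

    repeat {
      if (!state$active) break
      nd <- next_event_day(state)
      if (is.na(nd) || nd > last_day) break
      out <- advance_clock(state, nd)
      state <- out$state
      .record_actions(rec, out$actions)
      queue <- out$actions
      while (length(queue) > 0L) {
        a <- queue[[1L]]
        queue <- queue[-1L]
        queue <- c(queue, react(a))
      }
    }
    event_log(rec$events[seq_len(rec$n)])
  })
}

#' Cohort specification
#'
#' @param n_mosth Number of intervention-arm participants (default 34, the
#'   trial's 2:1 allocation of 52).
#' @param n_euc Number of enhanced-usual-care participants (default 18).
#' @param horizon_days Program horizon (default 90).
#' @param profile_mixture Mixture of `list(profile, weight)` components for
#'   the intervention arm, see [default_profiles()].
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_mosth = 34L, n_euc = 18L, horizon_days = 90L,
                        profile_mixture = default_profiles()) {
  w <- vapply(profile_mixture, `[[`, 0, "weight")
  if (abs(sum(w) - 1) > 1e-8) {
    .err("mosth_validation_error", "mixture weights must sum to 1")
  }
  structure(list(n_mosth = as.integer(n_mosth), n_euc = as.integer(n_euc),
                 horizon_days = as.integer(horizon_days),
                 profile_mixture = profile_mixture),
            class = "cohort_spec")
}

#' Simulate a full cohort
#'
#' Per-participant seeds and mixture assignments are drawn deterministically
#' from the master seed, so a fixed seed reproduces the cohort exactly.
#' Enhanced-usual-care logs contain only the enrollment and video-library
#' events.
#'
#' @param spec A [cohort_spec()].
#' @param seed Master integer seed.
#' @param config Engine configuration.
#' @return A named list of per-participant [event_log()]s (intervention arm
#'   first).
#' @export
simulate_cohort <- function(spec = cohort_spec(), seed = 1L,
                            config = default_config()) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_mosth + spec$n_euc
  if (n == 0L) return(list())
  plan <- withr::with_seed(seed, {
    w <- vapply(spec$profile_mixture, `[[`, 0, "weight")
    list(seeds = sample.int(.Machine$integer.max - 1L, n),
         comp = if (spec$n_mosth > 0L) {
           sample.int(length(spec$profile_mixture), spec$n_mosth,
                      replace = TRUE, prob = w)
         } else integer())
  })
  logs <- vector("list", n)
  ids <- character(n)
  for (i in seq_len(n)) {
    if (i <= spec$n_mosth) {
      id <- sprintf("mh%02d", i)
      logs[[i]] <- simulate_participant(
        spec$profile_mixture[[plan$comp[i]]]$profile,
        spec$horizon_days, plan$seeds[i], id, config, arm = "MoST-MH")
    } else {
      id <- sprintf("uc%02d", i - spec$n_mosth)
      logs[[i]] <- simulate_participant(
        spec$profile_mixture[[1L]]$profile,
        spec$horizon_days, plan$seeds[i], id, config, arm = "eUC")
    }
    ids[i] <- id
  }
  names(logs) <- ids
  logs
}
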