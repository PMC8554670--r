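test_that("enrollment schedules the first check-in on the enrollment day", {
  res <- start_program("p1", 0)
  expect_equal(res$state$next_checkin_day, 0L)
  expect_true(res$state$active)
  expect_equal(action_kinds(res$actions)[1], "send_welcome")

  # enrollment-relative clock
  expect_equal(start_program("p2", 5)$state$next_checkin_day, 5L)

  # duplicate enrollment is rejected
  expect_error(start_program("p1", 0, existing = res$state),
               class = "mosth_already_enrolled")
})

test_that("text replies branch on the rating partition", {
  cfg <- default_config()
  st <- start_program("p1", 0)$state
  st <- advance_clock(st, 0)$state

  pos <- process_text_reply(st, 0, "good")
  expect_equal(action_kinds(pos$actions), "send_positive_feedback_with_video")
  expect_equal(pos$state$next_checkin_day, 30L)
  expect_equal(pos$state$consecutive_flag_count, 0L)

  # the two-word rating form and case-insensitivity parse too
  vg <- process_text_reply(st, 0, "Very Good")
  expect_equal(vg$state$next_checkin_day, 30L)

  sub <- process_text_reply(st, 0, "fair")
  expect_equal(action_kinds(sub$actions), "send_web_link")
  expect_true(is.na(sub$state$next_checkin_day))
  expect_false(is.null(sub$state$pending_web))

  # replying without a pending check-in is a protocol-order error
  expect_error(process_text_reply(pos$state, 1, "good"),
               class = "mosth_protocol_error")
})

test_that("texting Quit is absorbing: no action is ever emitted again", {
  st <- start_program("p1", 0)$state
  st <- advance_clock(st, 0)$state
  q <- process_text_reply(st, 0, "Quit")
  expect_true(q$state$quit)
  expect_false(q$state$active)
  expect_length(q$actions, 0)
  for (d in c(1, 30, 89)) {
    expect_length(advance_clock(q$state, d)$actions, 0)
  }
  expect_true(is.na(next_event_day(q$state)))
})

test_that("unparseable replies are reprompted exactly once, then missed", {
  st <- start_program("p1", 0)$state
  st <- advance_clock(st, 0)$state
  r1 <- process_text_reply(st, 0, "meh")
  expect_equal(action_kinds(r1$actions), "reprompt")
  r2 <- process_text_reply(r1$state, 0, "still meh")
  expect_equal(action_kinds(r2$actions), "none")
  # missed check-in recorded with no rating, rescheduled +7 from prompt day
  h <- r2$state$history
  expect_length(h, 1)
  expect_true(is.na(h[[1]]$text$rating))
  expect_true(h[[1]]$text$reprompted)
  expect_equal(r2$state$next_checkin_day, 7L)
})

test_that("an unanswered prompt gets one timed reprompt then a missed mark", {
  st <- start_program("p1", 0)$state
  out <- advance_clock(st, 5)
  kinds <- action_kinds(out$actions)
  expect_equal(kinds, c("send_text_checkin", "reprompt", "none"))
  days <- vapply(out$actions, `[[`, 0L, "day")
  expect_equal(days, c(0L, 1L, 3L))  # prompt, +1 reprompt, +2 missed
  expect_equal(out$state$next_checkin_day, 7L)
  expect_error(advance_clock(out$state, 2), class = "mosth_time_error")
})

test_that("adaptive cadence: monthly after positive or high SE, weekly after low SE", {
  expect_equal(decide_next_checkin("good", NULL, 10), 40L)
  expect_equal(decide_next_checkin("poor", "not_at_all", 10), 17L)
  expect_equal(decide_next_checkin("fair", "completely", 0), 30L)
  expect_true(is.na(decide_next_checkin("good", NULL, 10, active = FALSE)))
  expect_error(decide_next_checkin("fair", NULL, 0),
               class = "mosth_validation_error")
})

test_that("web check-in outcome drives scheduling, skills, and care prompts", {
  st <- start_program("p1", 0)$state
  st <- advance_clock(st, 0)$state
  st <- process_text_reply(st, 0, "fair")$state

  # first web check-in, high self-efficacy: monthly step-down
  hi <- process_web_checkin(st, web_checkin(0, stressors = "school",
                                            self_efficacy = "completely"))
  expect_equal(action_kinds(hi$actions), "send_positive_feedback_with_video")
  expect_equal(hi$state$next_checkin_day, 30L)
  expect_equal(hi$state$consecutive_flag_count, 0L)

  # first web check-in, low self-efficacy: skill + consent ask, weekly
  lo <- process_web_checkin(st, web_checkin(0, stressors = "school",
                                            self_efficacy = "a_little"))
  expect_equal(action_kinds(lo$actions),
               c("send_skill_message", "send_weekly_consent_ask"))
  expect_equal(lo$state$next_checkin_day, 7L)
  expect_equal(lo$state$consecutive_flag_count, 1L)

  # second consecutive low: care prompt and safety escalation join in
  st2 <- advance_clock(lo$state, 7)$state
  st2 <- process_text_reply(st2, 7, "poor")$state
  lo2 <- process_web_checkin(st2, web_checkin(7, stressors = "finances",
                                              self_efficacy = "somewhat"))
  kinds <- action_kinds(lo2$actions)
  expect_true("send_care_prompt" %in% kinds)
  expect_true("send_safety_care_prompt" %in% kinds)
  expect_equal(lo2$state$consecutive_flag_count, 2L)
  # feedback payload carries the comparison with the prior check-in
  skill <- lo2$actions[[which(kinds == "send_skill_message")]]
  expect_equal(skill$payload$comparison$stressors$resolved, "school")
  expect_equal(skill$payload$comparison$stressors$new, "finances")

  # submitting with no outstanding link is a protocol-order error
  expect_error(
    process_web_checkin(hi$state,
                        web_checkin(1, self_efficacy = "completely")),
    class = "mosth_protocol_error"
  )
  # unknown checklist tokens are rejected
  expect_error(web_checkin(0, stressors = "exams",
                           self_efficacy = "completely"),
               class = "mosth_validation_error")
})

test_that("a high self-efficacy report resets the consecutive-flag counter", {
  st <- start_program("p1", 0)$state
  st <- advance_clock(st, 0)$state
  st <- process_text_reply(st, 0, "poor")$state
  st <- process_web_checkin(st, web_checkin(0, self_efficacy = "a_little"))$state
  expect_equal(st$consecutive_flag_count, 1L)
  st <- advance_clock(st, 7)$state
  st <- process_text_reply(st, 7, "poor")$state
  st <- process_web_checkin(st, web_checkin(7, self_efficacy = "completely"))$state
  expect_equal(st$consecutive_flag_count, 0L)
  # a positive rating also resets it
  st2 <- start_program("p2", 0)$state
  st2 <- advance_clock(st2, 0)$state
  st2 <- process_text_reply(st2, 0, "poor")$state
  st2 <- process_web_checkin(st2,
                             web_checkin(0, self_efficacy = "somewhat"))$state
  st2 <- advance_clock(st2, 7)$state
  st2 <- process_text_reply(st2, 7, "good")$state
  expect_equal(st2$consecutive_flag_count, 0L)
})

test_that("an abandoned web link counts as missing and leaves the counter alone", {
  st <- start_program("p1", 0)$state
  st <- advance_clock(st, 0)$state
  st <- process_text_reply(st, 0, "poor")$state
  st <- process_web_checkin(st, web_checkin(0, self_efficacy = "a_little"))$state
  expect_equal(st$consecutive_flag_count, 1L)
  st <- advance_clock(st, 7)$state
  st <- process_text_reply(st, 7, "poor")$state
  # web link never answered: reprompt at day 8, missed at day 10
  out <- advance_clock(st, 10)
  expect_equal(action_kinds(out$actions), c("reprompt", "none"))
  st <- out$state
  expect_equal(st$consecutive_flag_count, 1L)
  expect_equal(st$next_checkin_day, 14L)  # +7 from the link day
  h <- st$history
  expect_false(h[[length(h)]]$web$completed)
})

test_that("safety escalation requires two qualifying check-ins at most 14 days apart", {
  q <- function(day) list(day = day, rating = "poor", low_se = TRUE)
  expect_true(check_safety_escalation(
    state_with_history(list(q(0), q(7)))))
  expect_false(check_safety_escalation(state_with_history(list(q(0)))))
  expect_false(check_safety_escalation(
    state_with_history(list(q(0), q(30)))))

  # brute-force oracle over all two-element histories: rating in
  # {poor, fair, good, missing} x web in {low, high, none} x gap 1..20
  ratings <- list(
    list(rating = "poor", low_se = TRUE, qual = TRUE),
    list(rating = "fair", low_se = TRUE, qual = TRUE),
    list(rating = "poor", low_se = FALSE, qual = FALSE),
    list(rating = "good", low_se = NA, qual = FALSE),
    list(rating = "poor", low_se = NA, qual = FALSE)
  )
  for (a in ratings) for (b in ratings) for (gap in c(1, 7, 14, 15, 20)) {
    st <- state_with_history(list(
      list(day = 0, rating = a$rating, low_se = a$low_se),
      list(day = gap, rating = b$rating, low_se = b$low_se)
    ))
    expect_identical(check_safety_escalation(st),
                     a$qual && b$qual && gap <= 14,
                     info = sprintf("a=%s b=%s gap=%d", a$rating, b$rating,
                                    gap))
  }

  # strictly-poor variant: fair no longer qualifies
  cfg <- default_config()
  cfg$escalation_rating <- "poor"
  st <- state_with_history(list(list(day = 0, rating = "fair", low_se = TRUE),
                                list(day = 7, rating = "fair", low_se = TRUE)),
                           config = cfg)
  expect_false(check_safety_escalation(st))
})

test_that("comparison of consecutive check-ins obeys the set algebra", {
  a <- web_checkin(0, stressors = c("school", "finances"),
                   self_efficacy = "a_little")
  b <- web_checkin(7, stressors = "school", self_efficacy = "somewhat")
  cmp <- compare_checkins(a, b)
  expect_equal(cmp$stressors$resolved, "finances")
  expect_equal(cmp$stressors$persisting, "school")
  expect_length(cmp$stressors$new, 0)

  same <- compare_checkins(a, web_checkin(7, stressors = a$stressors,
                                          self_efficacy = "somewhat"))
  expect_length(same$stressors$resolved, 0)
  expect_length(same$stressors$new, 0)

  empty_prior <- compare_checkins(
    web_checkin(0, self_efficacy = "a_little"),
    web_checkin(7, negative_effects = "poor_sleep",
                self_efficacy = "somewhat"))
  expect_equal(empty_prior$negative_effects$new, "poor_sleep")

  expect_error(compare_checkins(a, web_checkin(7, completed = FALSE)),
               class = "mosth_validation_error")
})

test_that("every suboptimal rating yields one web link; every positive one feedback", {
  set.seed(42)
  ratings <- rating_levels()
  for (rep in 1:25) {
    n_steps <- sample(3:6, 1)
    script <- lapply(seq_len(n_steps), function(i) {
      r <- sample(ratings, 1)
      list(reply = r,
           web = if (is_suboptimal_rating(r)) {
             list(self_efficacy = sample(self_efficacy_levels(), 1))
           })
    })
    res <- drive_script(script)
    kinds <- action_kinds(res$actions)
    used <- script[seq_len(min(res$prompts, length(script)))]
    n_sub <- sum(kinds == "send_web_link")
    n_replied_sub <- sum(vapply(used, function(s)
      is_suboptimal_rating(s$reply), TRUE))
    expect_equal(n_sub, n_replied_sub)
    # positive feedback count = positive replies + high-SE web outcomes
    n_pos_replies <- sum(vapply(used, function(s)
      is_positive_rating(s$reply), TRUE))
    n_high_se <- sum(vapply(used, function(s)
      !is.null(s$web) && !is_low_self_efficacy(s$web$self_efficacy), TRUE))
    expect_equal(sum(kinds == "send_positive_feedback_with_video"),
                 n_pos_replies + n_high_se)
  }
})

test_that("the engine is pure: replaying a stream gives an identical action stream", {
  script <- list(
    list(reply = "fair", web = list(stressors = "school",
                                    self_efficacy = "a_little")),
    list(reply = "poor", web = list(stressors = c("school", "finances"),
                                    self_efficacy = "somewhat")),
    list(reply = "good"),
    list(reply = NULL),
    list(reply = "excellent")
  )
  r1 <- drive_script(script)
  r2 <- drive_script(script)
  expect_identical(r1$actions, r2$actions)
  expect_identical(r1$state, r2$state)
})
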