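test_that("percentages round half-up to integers like the trial tables", {
  expect_equal(percent_of(43, 55), 78L)
  expect_equal(percent_of(45, 52), 87L)
  expect_equal(percent_of(1, 8), 13L)     # 12.5 rounds up, not to even
  expect_equal(round_half_up(2.5), 3)
  expect_equal(round_half_up(86.5), 87)
  expect_error(percent_of(5, 0), class = "mosth_validation_error")
  expect_error(percent_of(6, 5), class = "mosth_validation_error")
})

test_that("engagement summaries count prompts excluding reprompts", {
  mk <- function(id, text_days, reply_days, web_days, submit_days,
                 reprompts = 0L) {
    ev <- list()
    add <- function(day, kind, payload = NULL) {
      ev[[length(ev) + 1L]] <<- list(participant_id = id, day = day,
                                     event_kind = kind, payload = payload)
    }
    for (d in text_days) add(d, "send_text_checkin")
    for (d in seq_len(reprompts)) add(d, "reprompt")
    for (d in reply_days) add(d, "text_reply",
                              list(raw = "good", rating = "good"))
    for (d in web_days) add(d, "send_web_link")
    for (d in submit_days) add(d, "web_submit",
                               list(completed = TRUE,
                                    stressors = list("school"),
                                    negative_effects = list()))
    event_log(ev)
  }
  logs <- list(mk("a", 0:4, 0:4, 0:2, 0:2, reprompts = 3L),
               mk("b", 0:2, 0:2, integer(), integer()),
               mk("c", 0:9, 0:9, 0:7, 0:5))
  es <- engagement_summary(logs)
  expect_equal(es$per_participant$text_prompted, c(5L, 3L, 10L))
  expect_equal(es$text_median, 5)
  expect_equal(es$text_range, c(3L, 10L))
  expect_equal(es$text_completion_pct, 100L)
  expect_equal(es$web_prompted, 11L)
  expect_equal(es$web_completed, 9L)
  expect_equal(es$web_completion_pct, percent_of(9, 11))
  # web medians are over participants with at least one web prompt
  expect_equal(es$web_median, median(c(3L, 8L)))

  empty <- engagement_summary(list())
  expect_equal(nrow(empty$per_participant), 0L)
  expect_true(is.na(empty$text_median))
})

test_that("endorsement frequencies use completed web check-ins as denominator", {
  ev <- list()
  for (i in 1:43) {
    ev[[length(ev) + 1L]] <- list(
      participant_id = "p", day = i, event_kind = "web_submit",
      payload = list(completed = TRUE,
                     stressors = if (i <= 22) list("school") else list(),
                     negative_effects = if (i <= 28) list("feeling_worn_out")
                                        else list()))
  }
  # an incomplete submission must not enter the denominator
  ev[[length(ev) + 1L]] <- list(participant_id = "p", day = 99,
                                event_kind = "web_submit",
                                payload = list(completed = FALSE))
  ft <- endorsement_frequencies(event_log(ev))
  expect_equal(ft$n_completed, 43L)
  tab <- ft$table
  expect_equal(tab$pct[tab$item == "feeling_worn_out"], 65L)
  expect_equal(tab$pct[tab$item == "school"], 51L)
  expect_true(all(tab$count <= ft$n_completed))
  expect_true(all(tab$pct >= 0L & tab$pct <= 100L))

  none <- endorsement_frequencies(list())
  expect_equal(none$n_completed, 0L)
  expect_equal(nrow(none$table), 0L)
})

test_that("retention percentages match the printed follow-up rates", {
  expect_equal(retention_rate(52, 45), 87L)
  expect_equal(retention_rate(52, 49), 94L)
  expect_equal(retention_rate(52, 52), 100L)
  expect_error(retention_rate(0, 0), class = "mosth_validation_error")
  expect_error(retention_rate(52, 53), class = "mosth_validation_error")
})

test_that("care-use tables tally counts per arm and wave", {
  recs <- expand.grid(participant_id = paste0("u", 1:18), wave = "BL",
                      care_type = "any", stringsAsFactors = FALSE)
  recs$arm <- "eUC"
  recs$received <- recs$participant_id %in% paste0("u", 1:12)
  inp <- recs
  inp$care_type <- "inpatient"
  inp$received <- recs$participant_id %in% paste0("u", 1:2)
  tab <- care_use_table(rbind(recs, inp))
  any_row <- tab[tab$care_type == "any", ]
  expect_equal(any_row$count, 12L)
  expect_equal(any_row$n, 18L)
  expect_equal(any_row$pct, 67L)
  expect_equal(tab$pct[tab$care_type == "inpatient"], 11L)

  bad <- recs
  bad$care_type <- "chiropractor"
  expect_error(care_use_table(bad), class = "mosth_validation_error")
  expect_equal(nrow(care_use_table(recs[0, ])), 0L)
})

test_that("longitudinal cell means and SDs match a brute-force oracle", {
  set.seed(31)
  df <- expand.grid(arm = c("eUC", "MoST-MH"), wave = c("BL", "M1", "M3"),
                    rep = 1:6, stringsAsFactors = FALSE)
  df$score <- round(runif(nrow(df), 0, 4), 2)
  df$rep <- NULL
  out <- longitudinal_means(df)
  for (i in seq_len(nrow(out))) {
    v <- df$score[df$arm == out$arm[i] & df$wave == out$wave[i]]
    expect_equal(out$n[i], length(v))
    expect_equal(out$mean[i], sum(v) / length(v))
    m <- sum(v) / length(v)
    expect_equal(out$sd[i], sqrt(sum((v - m)^2) / (length(v) - 1)))
  }
  # single-value cells have undefined sample SD; constant cells SD 0
  one <- data.frame(arm = "eUC", wave = "BL", score = 2)
  expect_true(is.na(longitudinal_means(one)$sd))
  const <- data.frame(arm = "eUC", wave = "BL", score = rep(2, 5))
  expect_equal(longitudinal_means(const)$sd, 0)
})

test_that("the simulate-then-summarise pipeline shows the trial's engagement profile", {
  logs <- simulate_cohort(cohort_spec(34, 0), seed = 2024)
  es <- engagement_summary(logs)
  expect_equal(es$text_completion_pct, 100L)
  expect_gt(es$web_completion_pct, 63)
  expect_lt(es$web_completion_pct, 93)
  expect_gte(es$text_median, 3)
  expect_lte(es$text_median, 10)
  ft <- endorsement_frequencies(logs)
  expect_lte(ft$stressor_median, ft$effect_median)
  expect_true(all(ft$table$pct >= 0L & ft$table$pct <= 100L))
  expect_true(all(ft$table$count <= ft$n_completed))
})
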