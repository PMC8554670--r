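# Message template library and tailored-feedback rendering.
#
# Templates are data, not logic: a data.frame of {id, kind, text} with
# {placeholder} slots. The engine attaches a template id and data values to
# each action; render_message() substitutes placeholders (including the
# resolved / persisting / new lists from a check-in comparison) and fails
# loudly on any unresolved slot.

#' Default message template library
#'
#' One or more templates per engine action kind. The check-in question, the
#' welcome message, and the care-seeking prompt carry the program's fixed
#' wording; the skill messages are a small illustrative library drawing on
#' positive psychology, cognitive behavioral therapy, and dialectical
#' behavioral therapy (message content is configuration, not code, and can
#' be replaced wholesale via the config file).
#'
#' Placeholder grammar: `{name}` slots are filled from the action payload
#' and, for tailored feedback, from a check-in comparison record
#' (`{resolved_list}`, `{persisting_list}`, `{new_list}`).
#'
#' @return A data.frame with columns `id`, `kind`, `text`.
#' @export
default_message_library <- function() {
  tpl <- function(id, kind, text) data.frame(
    id = id, kind = kind, text = text, stringsAsFactors = FALSE
  )
  rbind(
    tpl("welcome_privacy", "send_welcome",
        paste("Welcome to MoST-MH. Over the next 3 months we'll be checking",
              "in by text message. Set up a password on your phone and erase",
              "messages you do not want anyone to see after reading them.")),
    tpl("welcome_quit", "send_welcome",
        "You can drop out of the program at any time by texting Quit."),
    tpl("text_checkin", "send_text_checkin",
        "How would you rate your emotional health this past week?"),
    tpl("generic_reprompt", "reprompt",
        paste("Just a reminder -- we'd still like to hear from you when you",
              "have a moment.")),
    tpl("positive_feedback", "send_positive_feedback_with_video",
        paste("Glad to hear it! Keep doing what works for you. Videos on",
              "staying mentally well at college: {video_url}")),
    tpl("positive_feedback_progress", "send_positive_feedback_with_video",
        paste("Great progress -- improved since last time: {resolved_list}.",
              "Still on your plate: {persisting_list}. New this time:",
              "{new_list}. Videos: {video_url}")),
    tpl("web_link", "send_web_link",
        paste("Sorry things have been tough. Tap here to tell us a bit more",
              "so we can point you to the right support: {web_url}")),
    tpl("self_efficacy_question", "send_web_link",
        paste("To what extent do you feel you can manage your stressors and",
              "negative effects with supports and skills you have?")),
    tpl("skill_positive_psych", "send_skill_message",
        paste("Tonight, write down three things that went well today and why",
              "they went well. Videos: {video_url}")),
    tpl("skill_cbt", "send_skill_message",
        paste("When a stressful thought shows up, ask yourself: what is the",
              "evidence for it, and what is the evidence against it?",
              "Videos: {video_url}")),
    tpl("skill_dbt", "send_skill_message",
        paste("When emotions run high, try paced breathing: exhale longer",
              "than you inhale, for two minutes. Videos: {video_url}")),
    tpl("skill_feedback_progress", "send_skill_message",
        paste("Since last time -- improved: {resolved_list}. Still",
              "unresolved: {persisting_list}. New: {new_list}. One skill to",
              "try this week: {skill_text}")),
    tpl("weekly_consent_ask", "send_weekly_consent_ask",
        "Is it ok if we check in with you again next week?"),
    tpl("care_prompt", "send_care_prompt",
        paste("Your doctor or another health professional can help. Would",
              "you be willing to reach out to them to set up an",
              "appointment?")),
    tpl("safety_care_prompt", "send_safety_care_prompt",
        paste("You've reported a rough couple of weeks in a row. Your doctor",
              "or another health professional can help. Would you be willing",
              "to reach out to them to set up an appointment? Resources:",
              "{resources_url}"))
  )
}

# Comma-join a token set into readable prose; empty set reads "none".
.format_item_list <- function(items) {
  if (length(items) == 0L) return("none")
  paste(gsub("_", " ", items), collapse = ", ")
}

# Flatten a compare_checkins() record into placeholder values. Stressors and
# negative effects are pooled: feedback talks about both in one breath.
.comparison_placeholders <- function(context) {
  pool <- function(field) c(context$stressors[[field]],
                            context$negative_effects[[field]])
  list(
    resolved_list = .format_item_list(pool("resolved")),
    persisting_list = .format_item_list(pool("persisting")),
    new_list = .format_item_list(pool("new"))
  )
}

#' Render an engine action into message text
#'
#' Looks up the template named in the action payload (falling back to the
#' first template for the action's kind), substitutes `{placeholder}` slots
#' from the payload data and, when supplied, the comparison record from
#' [compare_checkins()]. Resolved items are phrased as improvement and
#' persisting items as unresolved by the feedback templates.
#'
#' @param action An engine action (an element of the `actions` list returned
#'   by the engine operations).
#' @param context A comparison record from [compare_checkins()], or `NULL`.
#' @param library Template data.frame, by default [default_message_library()].
#' @return The rendered message text, with no unresolved placeholders.
#' @examples
#' act <- list(kind = "send_care_prompt",
#'             payload = list(template = "care_prompt", data = list()))
#' render_message(act)
#' @export
render_message <- function(action, context = NULL,
                           library = default_message_library()) {
  stopifnot(is.list(action), !is.null(action$kind))
  id <- action$payload$template
  row <- if (!is.null(id)) library[library$id == id, , drop = FALSE]
         else library[0, , drop = FALSE]
  if (nrow(row) == 0L) row <- library[library$kind == action$kind, ,
                                      drop = FALSE]
  if (nrow(row) == 0L) {
    stop(sprintf("no message template for action kind '%s'", action$kind))
  }
  text <- row$text[1L]

  if (is.null(context)) context <- action$payload$comparison
  values <- action$payload$data
  if (!is.null(context)) {
    values <- utils::modifyList(as.list(values), .comparison_placeholders(context))
  }
  slots <- regmatches(text, gregexpr("\\{[a-z_]+\\}", text))[[1L]]
  for (slot in unique(slots)) {
    name <- substr(slot, 2L, nchar(slot) - 1L)
    if (is.null(values[[name]])) {
      stop(sprintf("unresolved placeholder '%s' in template '%s'",
                   name, row$id[1L]))
    }
    text <- gsub(slot, values[[name]], text, fixed = TRUE)
  }
  text
}

#' Next skill message, round-robin
#'
#' Deterministic rotation through the skill-message library: messages are
#' delivered in library order without repetition until the library is
#' exhausted, then the cycle restarts. The participant state carries the
#' rotation cursor, so the choice is a pure function of history.
#'
#' @param state A participant state.
#' @param library Template data.frame; only rows with kind
#'   `send_skill_message` are used.
#' @return `list(template = <one-row data.frame>, state = <updated state>)`.
#' @export
next_skill_message <- function(state, library = default_message_library()) {
  skills <- library[library$kind == "send_skill_message" &
                    !grepl("feedback", library$id), , drop = FALSE]
  if (nrow(skills) == 0L) {
    stop("configuration error: skill-message library is empty")
  }
  idx <- (state$skill_cursor %% nrow(skills)) + 1L
  state$skill_cursor <- state$skill_cursor + 1L
  list(template = skills[idx, , drop = FALSE], state = state)
}
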