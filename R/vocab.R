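# Controlled vocabularies for ratings, self-efficacy, stressors and
# negative effects, plus the text-reply parser.

.RATING_LEVELS <- c("excellent", "very_good", "good", "fair", "poor")
.POSITIVE_RATINGS <- c("excellent", "very_good", "good")
.SUBOPTIMAL_RATINGS <- c("fair", "poor")

.SE_LEVELS <- c("completely", "somewhat", "a_little", "not_at_all")
.HIGH_SE <- "completely"
.LOW_SE <- c("somewhat", "a_little", "not_at_all")

.STRESSOR_VOCAB <- c(
  "school", "finances", "friends_roommates", "family", "romantic", "other"
)

.EFFECT_VOCAB <- c(
  "feeling_worn_out", "low_motivation", "trouble_focusing", "poor_sleep",
  "unhealthy_eating", "overreacting", "no_one_to_talk_to",
  "alcohol_drugs_to_cope", "other"
)

#' Controlled vocabularies
#'
#' The five emotional-health rating levels, the four self-efficacy levels,
#' and the canonical checklists of six common stressors and nine negative
#' effects used on the web check-in.
#'
#' Ratings partition into POSITIVE (`excellent`, `very_good`, `good`) and
#' SUBOPTIMAL (`fair`, `poor`); self-efficacy into HIGH (`completely`) and
#' LOW (`somewhat`, `a_little`, `not_at_all`).
#'
#' @return A character vector of tokens.
#' @examples
#' rating_levels()
#' stressor_vocabulary()
#' @export
rating_levels <- function() .RATING_LEVELS

#' @rdname rating_levels
#' @export
self_efficacy_levels <- function() .SE_LEVELS

#' @rdname rating_levels
#' @export
stressor_vocabulary <- function() .STRESSOR_VOCAB

#' @rdname rating_levels
#' @export
effect_vocabulary <- function() .EFFECT_VOCAB

#' Rating and self-efficacy partitions
#'
#' `is_positive_rating()` is `TRUE` for excellent / very good / good;
#' `is_suboptimal_rating()` for fair / poor (the web check-in trigger);
#' `is_low_self_efficacy()` for any answer other than "completely".
#'
#' @param rating,level A rating or self-efficacy token (may be `NA`).
#' @return Logical; `NA` input gives `FALSE`.
#' @export
is_positive_rating <- function(rating) {
  !is.na(rating) & rating %in% .POSITIVE_RATINGS
}

#' @rdname is_positive_rating
#' @export
is_suboptimal_rating <- function(rating) {
  !is.na(rating) & rating %in% .SUBOPTIMAL_RATINGS
}

#' @rdname is_positive_rating
#' @export
is_low_self_efficacy <- function(level) {
  !is.na(level) & level %in% .LOW_SE
}

#' Parse a raw text reply
#'
#' Case-insensitive exact match on the five rating words (accepting the
#' two-word form "very good") and the program exit word "quit". Anything
#' else is unparseable.
#'
#' @param text Raw reply text.
#' @return One of the five rating tokens, `"quit"`, or `NA_character_` when
#'   unparseable.
#' @examples
#' parse_reply("Very Good")
#' parse_reply("  poor ")
#' parse_reply("meh")
#' @export
parse_reply <- function(text) {
  if (length(text) != 1L || is.na(text)) return(NA_character_)
  word <- tolower(trimws(text))
  word <- gsub("[[:space:]]+", "_", word)
  if (word == "quit") return("quit")
  if (word %in% .RATING_LEVELS) return(word)
  NA_character_
}
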