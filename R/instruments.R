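# Item-level scoring for the three self-report instruments: CCAPS-62
# (symptom severity, 8 subscales, items 0-4), MHSES (mental-health
# self-efficacy, 6 items, 1-10), and PSSUQ (usability, 19 items, 1-7,
# overall plus 3 subscales). Scores are unweighted means of answered
# items; a (sub)scale is scored only when at least 2/3 of its items were
# answered, otherwise it is NA.

.INSTRUMENT_SPECS <- list(
  CCAPS = list(n_items = 62L, lo = 0L, hi = 4L),
  MHSES = list(n_items = 6L, lo = 1L, hi = 10L),
  PSSUQ = list(n_items = 19L, lo = 1L, hi = 7L)
)

#' CCAPS-62 subscale map
#'
#' Structural map of the 62 items onto the 8 symptom subscales with the
#' instrument's published subscale sizes (depression 13, generalized
#' anxiety 9, social anxiety 7, academic distress 5, eating concerns 9,
#' family distress 6, hostility 7, substance use 6). Item *content* and
#' ordering are not modelled: indices are assigned block-sequentially
#' (a synthetic ordering), so the map is exchangeable with the real keying
#' up to a permutation of items. Indices are 1-based. Subscale index sets
#' are disjoint and cover all 62 items.
#'
#' @return Named list of integer index vectors.
#' @export
ccaps_subscale_map <- function() {
  sizes <- c(depression = 13L, generalized_anxiety = 9L,
             social_anxiety = 7L, academic_distress = 5L,
             eating_concerns = 9L, family_distress = 6L,
             hostility = 7L, substance_use = 6L)
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  stats::setNames(
    lapply(seq_along(sizes), function(i) seq.int(starts[i], ends[i])),
    names(sizes)
  )
}

#' PSSUQ subscale map
#'
#' The standard published 19-item keying: system usefulness items 1-8,
#' information quality 9-15, interface quality 16-18, and overall over all
#' 19 items.
#'
#' @return Named list of integer index vectors.
#' @export
pssuq_subscale_map <- function() {
  list(system_usefulness = 1:8, information_quality = 9:15,
       interface_quality = 16:18, overall = 1:19)
}

.validate_items <- function(items, instrument) {
  spec <- .INSTRUMENT_SPECS[[instrument]]
  if (length(items) != spec$n_items) {
    .err("mosth_validation_error",
         sprintf("%s requires %d items, got %d", instrument, spec$n_items,
                 length(items)))
  }
  items <- as.numeric(items)
  bad <- which(!is.na(items) &
               (items < spec$lo | items > spec$hi | items != round(items)))
  if (length(bad) > 0L) {
    .err("mosth_validation_error",
         sprintf("%s item %d out of range [%d,%d]: %s", instrument, bad[1L],
                 spec$lo, spec$hi, items[bad[1L]]))
  }
  items
}

# Mean of answered items, provided at least `tol` of them were answered.
.scale_mean <- function(items, idx, tol = 2 / 3) {
  x <- items[idx]
  answered <- sum(!is.na(x))
  if (answered < tol * length(x)) return(NA_real_)
  mean(x, na.rm = TRUE)
}

#' Score a CCAPS-62 response
#'
#' Each subscale score is the unweighted mean of its answered items, on the
#' 0-4 item scale; higher means greater symptom severity. A subscale with
#' fewer than 2/3 of its items answered is `NA`.
#'
#' @param items Integer vector of 62 item ratings in 0-4 (`NA` = missing).
#' @return Named numeric vector of the 8 subscale scores.
#' @examples
#' score_ccaps(rep(2, 62))["depression"]
#' @export
score_ccaps <- function(items) {
  items <- .validate_items(items, "CCAPS")
  map <- ccaps_subscale_map()
  vapply(map, function(idx) .scale_mean(items, idx), 0)
}

#' Score an MHSES response
#'
#' The unweighted mean of the answered items on the 1-10 scale; higher
#' means higher mental-health self-efficacy. `NA` when fewer than 2/3 of
#' the 6 items were answered.
#'
#' @param items Integer vector of 6 item ratings in 1-10 (`NA` = missing).
#' @return A single numeric score.
#' @examples
#' score_mhses(c(2, 4, 6, 8, 10, 6))  # 6
#' @export
score_mhses <- function(items) {
  items <- .validate_items(items, "MHSES")
  .scale_mean(items, seq_along(items))
}

#' Score a PSSUQ response
#'
#' Overall and subscale scores are unweighted means of answered items on
#' the 1-7 scale; *lower* means higher perceived usability (to a limit of
#' one). A (sub)scale with fewer than 2/3 of its items answered is `NA`.
#'
#' @param items Integer vector of 19 item ratings in 1-7 (`NA` = missing).
#' @return Named numeric vector: `overall`, `system_usefulness`,
#'   `information_quality`, `interface_quality`.
#' @export
score_pssuq <- function(items) {
  items <- .validate_items(items, "PSSUQ")
  map <- pssuq_subscale_map()
  out <- vapply(map, function(idx) .scale_mean(items, idx), 0)
  out[c("overall", "system_usefulness", "information_quality",
        "interface_quality")]
}

#' Score a wide item-response table
#'
#' One row per respondent-occasion; item columns named `item_1 ..
#' item_<k>` (any other columns — ids, arm, wave — are carried through).
#'
#' @param df A data.frame of item responses.
#' @param instrument `"CCAPS"`, `"MHSES"`, or `"PSSUQ"`.
#' @return A data.frame of the carried-through columns plus one column per
#'   score.
#' @export
score_responses <- function(df, instrument = c("CCAPS", "MHSES", "PSSUQ")) {
  instrument <- match.arg(instrument)
  n_items <- .INSTRUMENT_SPECS[[instrument]]$n_items
  item_cols <- paste0("item_", seq_len(n_items))
  missing_cols <- setdiff(item_cols, names(df))
  if (length(missing_cols) > 0L) {
    .err("mosth_validation_error",
         paste("missing item columns:",
               paste(utils::head(missing_cols, 3L), collapse = ", ")))
  }
  scorer <- switch(instrument, CCAPS = score_ccaps, MHSES = score_mhses,
                   PSSUQ = score_pssuq)
  mat <- as.matrix(df[item_cols])
  scores <- do.call(rbind, lapply(seq_len(nrow(mat)), function(i) {
    s <- scorer(mat[i, ])
    if (is.null(names(s))) names(s) <- "score"
    as.data.frame(as.list(s), stringsAsFactors = FALSE)
  }))
  cbind(df[setdiff(names(df), item_cols)], scores, row.names = NULL)
}
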