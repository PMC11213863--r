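#' Exclude low-accuracy participants
#'
#' Removes every trial of any participant whose overall proportion of
#' correct responses falls below the criterion, with timeouts counted as
#' incorrect. Accuracy is computed pooled across all sensory conditions by
#' default; with `per_condition = TRUE` a participant is excluded when any
#' single condition falls below the criterion. Participants exactly at the
#' criterion are retained. Surviving rows and their order are untouched.
#'
#' @param trials trial table (columns `participant_id`, `condition`,
#'   `correct`, `timeout`).
#' @param criterion minimum proportion correct (default 0.5).
#' @param per_condition apply the criterion within each condition instead of
#'   pooled.
#' @return list with `trials` (filtered) and `report` (counts and excluded
#'   ids).
#' @export
exclude_participants <- function(trials, criterion = 0.5,
                                 per_condition = FALSE) {
  if (nrow(trials) == 0) {
    return(list(trials = trials,
                report = list(participants_in = 0L, participants_out = 0L,
                              excluded_participant_ids = character(),
                              trials_in = 0L, trials_out = 0L)))
  }
  ok <- trials$correct & !is.na(trials$correct) & !trials$timeout
  acc_of <- function(sel) sum(ok[sel]) / sum(sel)
  ids <- unique(trials$participant_id)
  excl <- vapply(ids, function(id) {
    sel <- trials$participant_id == id
    if (per_condition) {
      any(vapply(unique(trials$condition[sel]), function(cc)
        acc_of(sel & trials$condition == cc) < criterion, logical(1)))
    } else {
      acc_of(sel) < criterion
    }
  }, logical(1))
  keep <- !(trials$participant_id %in% ids[excl])
  list(trials = trials[keep, , drop = FALSE],
       report = list(participants_in = length(ids),
                     participants_out = sum(!excl),
                     excluded_participant_ids = as.character(ids[excl]),
                     trials_in = nrow(trials), trials_out = sum(keep)))
}

#' Robust reaction-time filtering
#'
#' Per participant, removes timeouts and any trial whose RT lies outside
#' `median +/- k * MAD`, where the median and MAD are computed over that
#' participant's non-timeout RTs (pooled across conditions by default). The
#' MAD is the raw median absolute deviation, without the normal-consistency
#' constant. Filtering is pure selection: surviving rows are unaltered and
#' keep their order.
#'
#' @param trials trial table with `participant_id`, `rt` (ms), `timeout`.
#' @param k MAD multiplier (default 2.5).
#' @param per_condition compute the bounds within each condition rather than
#'   pooled over a participant's trials.
#' @return list with `trials` (filtered) and `removed`, a data frame of
#'   per-participant removal counts by rule (`timeout`, `mad_outlier`).
#' @export
mad_filter_rts <- function(trials, k = 2.5, per_condition = FALSE) {
  if (nrow(trials) == 0) {
    return(list(trials = trials,
                removed = data.frame(participant_id = character(),
                                     timeout = integer(),
                                     mad_outlier = integer(),
                                     stringsAsFactors = FALSE)))
  }
  keep <- rep(TRUE, nrow(trials))
  ids <- unique(trials$participant_id)
  removed <- data.frame(participant_id = as.character(ids),
                        timeout = 0L, mad_outlier = 0L,
                        stringsAsFactors = FALSE)
  for (j in seq_along(ids)) {
    sel <- which(trials$participant_id == ids[j])
    to <- trials$timeout[sel] | is.na(trials$rt[sel])
    removed$timeout[j] <- sum(to)
    keep[sel[to]] <- FALSE
    groups <- if (per_condition) split(sel[!to], trials$condition[sel[!to]])
              else list(sel[!to])
    for (g in groups) {
      if (!length(g)) next
      rts <- trials$rt[g]
      med <- median(rts)
      mad_raw <- median(abs(rts - med))
      out <- rts < med - k * mad_raw | rts > med + k * mad_raw
      removed$mad_outlier[j] <- removed$mad_outlier[j] + sum(out)
      keep[g[out]] <- FALSE
    }
  }
  list(trials = trials[keep, , drop = FALSE], removed = removed)
}

#' Full preprocessing pass
#'
#' Applies the participant-level accuracy criterion first, then the
#' per-participant timeout and MAD reaction-time filters, and assembles an
#' exclusion report reconciling all counts.
#'
#' @inheritParams exclude_participants
#' @inheritParams mad_filter_rts
#' @return list with `trials` (cleaned table) and `report` (class
#'   `exclusion_report`).
#' @export
preprocess <- function(trials, criterion = 0.5, k = 2.5,
                       per_condition_accuracy = FALSE,
                       per_condition_mad = FALSE) {
  step1 <- exclude_participants(trials, criterion, per_condition_accuracy)
  step2 <- mad_filter_rts(step1$trials, k, per_condition_mad)
  report <- list(
    participants_in = step1$report$participants_in,
    participants_out = step1$report$participants_out,
    excluded_participant_ids = step1$report$excluded_participant_ids,
    trials_in = nrow(trials),
    trials_out = nrow(step2$trials),
    removed_by_accuracy_criterion = nrow(trials) - nrow(step1$trials),
    removed_by_rule = step2$removed)
  class(report) <- "exclusion_report"
  list(trials = step2$trials, report = report)
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat("Exclusion report\n")
  cat("  participants:", x$participants_in, "->", x$participants_out, "\n")
  cat("  trials:      ", x$trials_in, "->", x$trials_out, "\n")
  cat("  removed: accuracy criterion", x$removed_by_accuracy_criterion,
      "| timeouts", sum(x$removed_by_rule$timeout),
      "| MAD outliers", sum(x$removed_by_rule$mad_outlier), "\n")
  invisible(x)
}
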