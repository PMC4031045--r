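#' Bundle one subject's trial log, choices and trait score
#'
#' @param schedule A `"trial_schedule"` whose decision rows carry a `choice`
#'   column (`"fractal"` or `"square"`); observation rows have `NA`.
#' @param subject_id Identifier.
#' @param trait_score Integer trait-optimism score on the 0-24 questionnaire
#'   scale (`NA` allowed for model-only use).
#' @param true_params Optional named list/vector of the generating parameters
#'   (kept for parameter-recovery scoring of synthetic subjects).
#' @return A list of class `"subject_data"` with elements `subject_id`,
#'   `trait_score`, `true_params`, `events`, `fractal_probs`, `valence`,
#'   `design`.
#' @export
subject_data <- function(schedule, subject_id = 1L, trait_score = NA_integer_,
                         true_params = NULL) {
  stopifnot(inherits(schedule, "trial_schedule"))
  events <- schedule$events
  if (!"choice" %in% names(events)) events$choice <- NA_character_
  dec <- events$event_type == "dec"
  if (any(is.na(events$choice[dec]))) {
    stop("every decision event needs a recorded choice", call. = FALSE)
  }
  if (!all(events$choice[dec] %in% c("fractal", "square"))) {
    stop('choices must be "fractal" or "square"', call. = FALSE)
  }
  structure(
    list(
      subject_id = subject_id,
      trait_score = trait_score,
      true_params = true_params,
      events = events,
      fractal_probs = schedule$fractal_probs,
      valence = schedule$valence,
      design = schedule$config$design %||% NA_character_
    ),
    class = "subject_data"
  )
}

#' Evidence available at each decision screen
#'
#' For every decision event, counts the observations of that fractal that
#' precede the decision in the trial log: `n_shown` presentations and
#' `n_rewards` positive outcomes among them. Only observation screens
#' contribute evidence; decisions are unrewarded and carry no feedback. A
#' decision about a never-observed fractal is legal and yields
#' `n_shown = 0` (the observer falls back on its prior).
#'
#' @param x A `"subject_data"`, `"trial_schedule"`, or an events tibble.
#' @return A tibble with one row per decision: `event_index`, `fractal_id`,
#'   `n_rewards`, `n_shown`, `square_prob`, `choice` (NA if unsimulated).
#' @export
decision_evidence <- function(x) {
  events <- if (inherits(x, "subject_data") || inherits(x, "trial_schedule")) {
    x$events
  } else {
    x
  }
  events <- events[order(events$event_index), ]
  if (!"choice" %in% names(events)) events$choice <- NA_character_
  obs <- events[events$event_type == "obs", ]
  dec <- events[events$event_type == "dec", ]
  n_shown <- integer(nrow(dec))
  n_rewards <- integer(nrow(dec))
  for (i in seq_len(nrow(dec))) {
    sel <- obs$fractal_id == dec$fractal_id[i] & obs$event_index < dec$event_index[i]
    n_shown[i] <- sum(sel)
    n_rewards[i] <- sum(obs$outcome[sel])
  }
  tibble::tibble(
    event_index = dec$event_index,
    fractal_id = dec$fractal_id,
    n_rewards = n_rewards,
    n_shown = n_shown,
    square_prob = dec$square_prob,
    choice = dec$choice
  )
}

#' Ordered outcome histories per fractal
#'
#' For sequential (temporal-difference) observers the order of outcomes
#' matters, not just their counts. Returns, for each fractal, the outcomes of
#' its observation screens in presentation order.
#'
#' @param x A `"subject_data"`, `"trial_schedule"`, or events tibble.
#' @return Named list (by fractal id) of integer outcome vectors.
#' @keywords internal
outcome_histories <- function(x) {
  events <- if (inherits(x, "subject_data") || inherits(x, "trial_schedule")) {
    x$events
  } else {
    x
  }
  events <- events[order(events$event_index), ]
  obs <- events[events$event_type == "obs", ]
  split(obs$outcome, obs$fractal_id)
}

#' @export
print.subject_data <- function(x, ...) {
  cat("<subject_data> id ", x$subject_id, ", trait score ", x$trait_score,
      ", ", sum(x$events$event_type == "dec"), " decisions (", x$valence,
      ")\n", sep = "")
  invisible(x)
}
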