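#' Task configuration for a conditioning session
#'
#' Describes one session of the Pavlovian conditioning task: a set of fractal
#' conditioned stimuli (CS), each paired with a binary outcome at a fixed but
#' unknown probability, observed a random number of times and then pitted
#' against a reference square whose outcome probability is cued explicitly.
#'
#' Three named designs are provided:
#' \describe{
#'   \item{exp1}{60 fractals, mean 4 presentations each, interleaved in
#'     groups of 5, reward valence. The high-uncertainty main design.}
#'   \item{exp2}{as exp1 but mean 10 presentations and blocked presentation;
#'     the low-uncertainty control design.}
#'   \item{exp3}{as exp1 but outcomes are punishments that the subject must
#'     avoid.}
#' }
#'
#' @param design One of `"exp1"`, `"exp2"`, `"exp3"`, or `"custom"`.
#' @param n_fractals Number of fractal stimuli (default 60).
#' @param mean_presentations Mean of the Poisson presentation-count
#'   distribution before truncation (4 for exp1/exp3, 10 for exp2).
#' @param presentation_min Counts are truncated to be strictly greater than
#'   this value (default 2, so every fractal is observed at least 3 times).
#' @param interleaving `"interleaved_groups_of_5"` or `"blocked"`.
#' @param valence `"reward"` or `"punishment"`.
#' @param group_size Number of fractals per interleaving group (default 5);
#'   must divide `n_fractals` in interleaved mode.
#' @param square_prob_step Grid step for the square's cued probability
#'   (default 0.1, giving the 11-point grid 0, 0.1, ..., 1).
#' @param seed Optional integer seed making schedule generation reproducible.
#' @return A list of class `"task_config"`.
#' @examples
#' cfg <- task_config("exp1", seed = 1)
#' sched <- build_schedule(cfg)
#' @export
task_config <- function(design = c("exp1", "exp2", "exp3", "custom"),
                        n_fractals = 60L,
                        mean_presentations = NULL,
                        presentation_min = 2L,
                        interleaving = NULL,
                        valence = NULL,
                        group_size = 5L,
                        square_prob_step = 0.1,
                        seed = NULL) {
  design <- match.arg(design)
  preset <- switch(design,
    exp1 = list(mean = 4, inter = "interleaved_groups_of_5", val = "reward"),
    exp2 = list(mean = 10, inter = "blocked", val = "reward"),
    exp3 = list(mean = 4, inter = "interleaved_groups_of_5", val = "punishment"),
    custom = list(mean = 4, inter = "interleaved_groups_of_5", val = "reward")
  )
  mean_presentations <- mean_presentations %||% preset$mean
  interleaving <- interleaving %||% preset$inter
  valence <- valence %||% preset$val
  interleaving <- match.arg(interleaving, c("interleaved_groups_of_5", "blocked"))
  valence <- match.arg(valence, c("reward", "punishment"))

  stopifnot(
    n_fractals > 0,
    mean_presentations > 0,
    presentation_min >= 0,
    square_prob_step > 0, square_prob_step <= 1
  )
  if (interleaving == "interleaved_groups_of_5" && n_fractals %% group_size != 0) {
    stop("`group_size` (", group_size, ") must divide `n_fractals` (",
         n_fractals, ") in interleaved mode", call. = FALSE)
  }
  structure(
    list(
      design = design,
      n_fractals = as.integer(n_fractals),
      mean_presentations = mean_presentations,
      presentation_min = as.integer(presentation_min),
      interleaving = interleaving,
      valence = valence,
      group_size = as.integer(group_size),
      square_prob_step = square_prob_step,
      seed = seed
    ),
    class = "task_config"
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Draw the per-fractal outcome probabilities
#'
#' Each fractal's outcome probability is drawn independently and uniformly on
#' \[0, 1\] at the start of a session, and stays fixed throughout.
#'
#' @param config A [task_config()].
#' @return Named numeric vector of length `n_fractals` (names are fractal ids).
#' @export
sample_fractal_probs <- function(config) {
  stopifnot(inherits(config, "task_config"))
  probs <- stats::runif(config$n_fractals)
  names(probs) <- seq_len(config$n_fractals)
  probs
}

#' Draw the per-fractal presentation counts
#'
#' Counts follow a Poisson distribution with mean `mean_presentations`,
#' truncated to values strictly greater than `presentation_min` (sampling by
#' rejection, which is exact on the truncated support).
#'
#' @param config A [task_config()].
#' @return Named integer vector of presentation counts, all
#'   `> presentation_min`.
#' @export
sample_presentation_counts <- function(config) {
  stopifnot(inherits(config, "task_config"))
  n <- config$n_fractals
  counts <- integer(n)
  todo <- rep(TRUE, n)
  while (any(todo)) {
    draw <- stats::rpois(sum(todo), config$mean_presentations)
    ok <- draw > config$presentation_min
    counts[which(todo)[ok]] <- draw[ok]
    todo[which(todo)[ok]] <- FALSE
  }
  names(counts) <- seq_len(n)
  counts
}

#' Mean of a truncated Poisson distribution
#'
#' Mean of `Poisson(lambda)` conditioned on values strictly greater than
#' `min`. Used as the analytic reference for [sample_presentation_counts()].
#'
#' @param lambda Poisson mean before truncation.
#' @param min Truncation point (values must exceed it).
#' @return The truncated mean.
#' @export
truncated_poisson_mean <- function(lambda, min = 2L) {
  p_le <- stats::ppois(min, lambda)
  # E[X; X > min] = lambda * P(X >= min) by the Poisson identity E[X 1{X>k}] =
  # lambda P(X > k - 1)
  lambda * (1 - stats::ppois(min - 1L, lambda)) / (1 - p_le)
}

#' Build a full trial schedule
#'
#' Lays out the ordered sequence of observation and decision events for one
#' session. In interleaved mode the fractals are partitioned into consecutive
#' groups of `group_size`; within a group the observation events are shuffled
#' and each fractal's single decision event is placed immediately after its
#' last observation, so observations of different fractals and decision
#' screens intermix. In blocked mode each fractal's observations are
#' contiguous and immediately followed by its decision event.
#'
#' Outcomes are sampled as independent Bernoulli draws at the fractal's
#' probability; the square's cued probability on each decision screen is drawn
#' uniformly from the step-0.1 grid; the side of the screen on which the
#' fractal appears is randomized and recorded (it plays no role in any model).
#'
#' @param config A [task_config()]. If `config$seed` is non-`NULL` the whole
#'   schedule (probabilities, counts, ordering, outcomes) is generated under
#'   that seed without disturbing the global RNG.
#' @param probs Optional pre-drawn fractal probabilities
#'   (default: [sample_fractal_probs()]).
#' @param counts Optional pre-drawn presentation counts
#'   (default: [sample_presentation_counts()]).
#' @return A list of class `"trial_schedule"` with elements `events` (a tibble
#'   with one row per event: `event_index`, `event_type` (`"obs"`/`"dec"`),
#'   `fractal_id`, `outcome`, `square_prob`, `side`), `fractal_probs`,
#'   `valence`, and `config`.
#' @export
build_schedule <- function(config, probs = NULL, counts = NULL) {
  stopifnot(inherits(config, "task_config"))
  gen <- function() {
    p <- probs %||% sample_fractal_probs(config)
    k <- counts %||% sample_presentation_counts(config)
    if (!identical(sort(names(p)), sort(names(k)))) {
      stop("`probs` and `counts` must cover the same fractal ids", call. = FALSE)
    }
    ids <- as.integer(names(p))
    stopifnot(all(k >= 1))

    groups <- if (config$interleaving == "interleaved_groups_of_5") {
      split(ids, ceiling(seq_along(ids) / config$group_size))
    } else {
      as.list(ids)
    }

    ev_type <- character(0); ev_id <- integer(0)
    for (g in groups) {
      if (config$interleaving == "blocked") {
        for (id in g) {
          ev_type <- c(ev_type, rep("obs", k[[as.character(id)]]), "dec")
          ev_id <- c(ev_id, rep(id, k[[as.character(id)]]), id)
        }
      } else {
        obs <- rep(g, k[as.character(g)])
        obs <- sample(obs)
        # decision goes right after the fractal's final observation
        last <- vapply(g, function(id) max(which(obs == id)), integer(1))
        ord <- order(last)
        type <- rep("obs", length(obs))
        id_seq <- obs
        for (j in ord) {
          pos <- which(id_seq == g[j] & type == "obs")
          pos <- max(pos)
          type <- append(type, "dec", after = pos)
          id_seq <- append(id_seq, g[j], after = pos)
        }
        ev_type <- c(ev_type, type)
        ev_id <- c(ev_id, id_seq)
      }
    }

    is_obs <- ev_type == "obs"
    outcome <- rep(NA_integer_, length(ev_type))
    outcome[is_obs] <- stats::rbinom(sum(is_obs), 1L, p[as.character(ev_id[is_obs])])
    grid <- seq(0, 1, by = config$square_prob_step)
    square_prob <- rep(NA_real_, length(ev_type))
    square_prob[!is_obs] <- sample(grid, sum(!is_obs), replace = TRUE)
    side <- rep(NA_character_, length(ev_type))
    side[!is_obs] <- sample(c("left", "right"), sum(!is_obs), replace = TRUE)

    events <- tibble::tibble(
      event_index = seq_along(ev_type),
      event_type = ev_type,
      fractal_id = ev_id,
      outcome = outcome,
      square_prob = square_prob,
      side = side
    )
    structure(
      list(events = events, fractal_probs = p, valence = config$valence,
           config = config),
      class = "trial_schedule"
    )
  }
  if (!is.null(config$seed)) withr::with_seed(config$seed, gen()) else gen()
}

#' Reinterpret a reward schedule as a punishment schedule (and back)
#'
#' Flips the valence tag of a schedule: outcomes and cued square probabilities
#' are reinterpreted as punishment probabilities. The event structure is
#' untouched; only the decision rule applied by observers changes (they avoid,
#' rather than seek, the option with the higher estimated probability).
#'
#' @param schedule A `"trial_schedule"`.
#' @return The same schedule with the opposite `valence` tag.
#' @export
flip_valence <- function(schedule) {
  stopifnot(inherits(schedule, "trial_schedule"))
  schedule$valence <- if (schedule$valence == "reward") "punishment" else "reward"
  schedule
}

#' @export
print.trial_schedule <- function(x, ...) {
  n_obs <- sum(x$events$event_type == "obs")
  n_dec <- sum(x$events$event_type == "dec")
  cat("<trial_schedule> ", length(x$fractal_probs), " fractals, ",
      n_obs, " observation and ", n_dec, " decision events (",
      x$valence, ", ", x$config$interleaving, ")\n", sep = "")
  invisible(x)
}
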