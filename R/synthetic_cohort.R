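#' Configuration of a synthetic cohort
#'
#' A synthetic cohort stands in for the human participants: each subject gets
#' a trait-optimism score (0-24 questionnaire scale) and generating model
#' parameters, with a planted correlation between the trait score and the
#' prior mean. The defaults reproduce the main experiment's group moments —
#' 51 subjects, trait mean 14.7 (sd 4.42), prior mean 0.42 (sd 0.23), softmax
#' gamma 7.88 (sd 3.93), and a trait-to-prior-mean correlation of 0.44.
#'
#' @param n_subjects Number of subjects (default 51).
#' @param trait_mean,trait_sd Moments of the trait score before integer
#'   rounding and clipping to \[0, 24\].
#' @param prior_mean_mean,prior_mean_sd Moments of each subject's prior mean
#'   `alpha/(alpha+beta)` before clipping to (0.01, 0.99).
#' @param trait_prior_corr Planted correlation between trait score and prior
#'   mean (pre-clipping); set to 0 for a null cohort.
#' @param concentration Prior concentration `alpha + beta` (default 2, a
#'   weakly informative prior whose influence a handful of observations can
#'   override); `alpha = prior_mean * concentration`.
#' @param gamma_mean,gamma_sd Moments of the softmax parameter, truncated to
#'   be positive.
#' @param agent_type `"bayes"` (posterior-mean chooser) or `"rl"` (TD learner
#'   with `v0` set to the drawn prior mean, learning rate 0.1, and `tau` set
#'   to the drawn softmax value).
#' @param design Task design, one of `"exp1"`, `"exp2"`, `"exp3"`.
#' @param seed Optional integer seed for full reproducibility.
#' @return A list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_subjects = 51L,
                          trait_mean = 14.7, trait_sd = 4.42,
                          prior_mean_mean = 0.42, prior_mean_sd = 0.23,
                          trait_prior_corr = 0.44,
                          concentration = 2,
                          gamma_mean = 7.88, gamma_sd = 3.93,
                          agent_type = c("bayes", "rl"),
                          design = c("exp1", "exp2", "exp3"),
                          seed = NULL) {
  agent_type <- match.arg(agent_type)
  design <- match.arg(design)
  stopifnot(
    n_subjects >= 1,
    trait_sd > 0, prior_mean_sd > 0, gamma_sd > 0,
    abs(trait_prior_corr) < 1,
    concentration > 0
  )
  structure(
    list(n_subjects = as.integer(n_subjects),
         trait_mean = trait_mean, trait_sd = trait_sd,
         prior_mean_mean = prior_mean_mean, prior_mean_sd = prior_mean_sd,
         trait_prior_corr = trait_prior_corr,
         concentration = concentration,
         gamma_mean = gamma_mean, gamma_sd = gamma_sd,
         agent_type = agent_type, design = design, seed = seed),
    class = "cohort_config"
  )
}

#' Draw per-subject generating parameters
#'
#' Trait score and prior mean come from a bivariate Gaussian with the
#' configured moments and correlation; the trait score is then rounded to an
#' integer and clipped to \[0, 24\], the prior mean clipped to (0.01, 0.99)
#' (the planted correlation refers to the pre-clipping values, reported in the
#' `trait_raw` / `prior_mean_raw` columns). Beta shapes follow from the fixed
#' concentration; gamma is truncated-normal positive (sampled by rejection).
#'
#' @param config A [cohort_config()]. Uses the current RNG state (seeding is
#'   handled by [generate_cohort()]).
#' @return A tibble with one row per subject: `subject_id`, `trait_raw`,
#'   `trait_score`, `prior_mean_raw`, `prior_mean`, `alpha`, `beta`, `gamma`.
#' @export
draw_subject_params <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_subjects
  Sigma <- matrix(c(
    config$trait_sd^2,
    config$trait_prior_corr * config$trait_sd * config$prior_mean_sd,
    config$trait_prior_corr * config$trait_sd * config$prior_mean_sd,
    config$prior_mean_sd^2
  ), 2, 2)
  xy <- MASS::mvrnorm(n, mu = c(config$trait_mean, config$prior_mean_mean),
                      Sigma = Sigma)
  xy <- matrix(xy, ncol = 2)  # mvrnorm drops to a vector when n = 1
  trait_raw <- xy[, 1]
  pm_raw <- xy[, 2]
  trait <- as.integer(pmin(24, pmax(0, round(trait_raw))))
  pm <- pmin(0.99, pmax(0.01, pm_raw))
  gamma <- numeric(n)
  todo <- rep(TRUE, n)
  while (any(todo)) {
    g <- stats::rnorm(sum(todo), config$gamma_mean, config$gamma_sd)
    ok <- g > 0
    gamma[which(todo)[ok]] <- g[ok]
    todo[which(todo)[ok]] <- FALSE
  }
  tibble::tibble(
    subject_id = seq_len(n),
    trait_raw = trait_raw,
    trait_score = trait,
    prior_mean_raw = pm_raw,
    prior_mean = pm,
    alpha = pm * config$concentration,
    beta = (1 - pm) * config$concentration,
    gamma = gamma
  )
}

#' Simulate one subject's choices on a schedule
#'
#' Walks the schedule in order; at each decision screen the agent's choice is
#' sampled from its current choice probability — the Bayesian agent's softmax
#' of the posterior mean given the observations seen so far, or the TD agent's
#' softmax of the learned value. Punishment-valence schedules use the
#' avoidance (sign-flipped) rule.
#'
#' @param params For a Bayesian agent, anything with `alpha`, `beta`, `gamma`
#'   (e.g. [bayes_params()] or a row of [draw_subject_params()]); for a TD
#'   agent, an [rl_params()] or a list with `eps_pos`, `eps_neg`, `v0`, `tau`.
#' @param schedule A `"trial_schedule"`.
#' @param agent_type `"bayes"` or `"rl"`.
#' @param subject_id,trait_score Metadata stored on the result.
#' @return A `"subject_data"` with choices filled in and `true_params`
#'   recording the generating parameters.
#' @export
simulate_subject <- function(params, schedule, agent_type = c("bayes", "rl"),
                             subject_id = 1L, trait_score = NA_integer_) {
  agent_type <- match.arg(agent_type)
  stopifnot(inherits(schedule, "trial_schedule"))
  events <- schedule$events[order(schedule$events$event_index), ]
  s <- if (identical(schedule$valence, "punishment")) -1 else 1
  ids <- as.character(unique(events$fractal_id))
  choice <- rep(NA_character_, nrow(events))

  if (agent_type == "bayes") {
    n_rew <- stats::setNames(numeric(length(ids)), ids)
    n_show <- n_rew
    for (i in seq_len(nrow(events))) {
      id <- as.character(events$fractal_id[i])
      if (events$event_type[i] == "obs") {
        n_show[id] <- n_show[id] + 1
        n_rew[id] <- n_rew[id] + events$outcome[i]
      } else {
        c_hat <- posterior_mean(params$alpha, params$beta, n_rew[id], n_show[id])
        p <- stats::plogis(s * params$gamma * (c_hat - events$square_prob[i]))
        choice[i] <- if (stats::runif(1) < p) "fractal" else "square"
      }
    }
    true_params <- list(agent_type = "bayes", alpha = params$alpha,
                        beta = params$beta, gamma = params$gamma,
                        prior_mean = params$alpha / (params$alpha + params$beta))
  } else {
    v <- stats::setNames(rep(params$v0, length(ids)), ids)
    for (i in seq_len(nrow(events))) {
      id <- as.character(events$fractal_id[i])
      if (events$event_type[i] == "obs") {
        v[id] <- td_update(v[id], events$outcome[i], params$eps_pos,
                           params$eps_neg)
      } else {
        p <- stats::plogis(s * params$tau * (v[id] - events$square_prob[i]))
        choice[i] <- if (stats::runif(1) < p) "fractal" else "square"
      }
    }
    true_params <- list(agent_type = "rl", eps_pos = params$eps_pos,
                        eps_neg = params$eps_neg, v0 = params$v0,
                        tau = params$tau)
  }

  schedule$events$choice <- choice[order(order(schedule$events$event_index))]
  subject_data(schedule, subject_id = subject_id, trait_score = trait_score,
               true_params = true_params)
}

#' Generate a full synthetic cohort
#'
#' Draws per-subject parameters, builds a fresh task schedule for every
#' subject (as in the experiment, where each participant got their own
#' randomization), and simulates their choices.
#'
#' @param config A [cohort_config()]. If `config$seed` is non-`NULL`,
#'   generation is fully reproducible and leaves the global RNG untouched.
#' @return A list of class `"cohort"` with `subjects` (list of
#'   `"subject_data"`), `params` (the [draw_subject_params()] tibble), and
#'   `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  gen <- function() {
    params <- draw_subject_params(config)
    task_cfg <- task_config(config$design)
    subjects <- lapply(seq_len(config$n_subjects), function(i) {
      sched <- build_schedule(task_cfg)
      row <- params[i, ]
      agent_params <- if (config$agent_type == "bayes") {
        row
      } else {
        list(eps_pos = 0.1, eps_neg = 0.1, v0 = row$prior_mean, tau = row$gamma)
      }
      simulate_subject(agent_params, sched, agent_type = config$agent_type,
                       subject_id = row$subject_id,
                       trait_score = row$trait_score)
    })
    structure(list(subjects = subjects, params = params, config = config),
              class = "cohort")
  }
  if (!is.null(config$seed)) withr::with_seed(config$seed, gen()) else gen()
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort> ", length(x$subjects), " subjects, design ", x$config$design,
      ", agent ", x$config$agent_type, ", planted trait-prior correlation ",
      x$config$trait_prior_corr, "\n", sep = "")
  invisible(x)
}
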