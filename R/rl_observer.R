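#' Parameters of the temporal-difference observers
#'
#' Four nested variants of a simple TD value learner over the observation
#' screens, each paired with a softmax choice rule with parameter `tau`:
#' \describe{
#'   \item{RL_eps}{one free learning rate (`eps_pos = eps_neg`),
#'     initial value fixed at 0.5.}
#'   \item{RL_2}{two free learning rates for better- and worse-than-expected
#'     outcomes, initial value fixed at 0.5.}
#'   \item{RL_2b}{two free learning rates and a free initial value.}
#'   \item{RL_b}{free initial value only, learning rate fixed at 0.1.}
#' }
#' The free initial value `v0` plays the role the prior mean plays in the
#' Bayesian observer; the asymmetric rates allow selective learning from good
#' versus bad news.
#'
#' @param variant One of `"RL_eps"`, `"RL_2"`, `"RL_2b"`, `"RL_b"`.
#' @param eps_pos,eps_neg Learning rates in \[0, 1\] for positive / negative
#'   prediction errors.
#' @param v0 Initial value in \[0, 1\], shared by every fractal.
#' @param tau Non-negative softmax parameter.
#' @return A list of class `"rl_params"`.
#' @export
rl_params <- function(variant = c("RL_eps", "RL_2", "RL_2b", "RL_b"),
                      eps_pos = 0.1, eps_neg = eps_pos, v0 = 0.5, tau = 1) {
  variant <- match.arg(variant)
  if (variant == "RL_eps") {
    if (eps_pos != eps_neg) stop("RL_eps has a single learning rate", call. = FALSE)
    v0 <- 0.5
  } else if (variant == "RL_2") {
    v0 <- 0.5
  } else if (variant == "RL_b") {
    eps_pos <- eps_neg <- 0.1
  }
  stopifnot(
    eps_pos >= 0, eps_pos <= 1, eps_neg >= 0, eps_neg <= 1,
    v0 >= 0, v0 <= 1, tau >= 0
  )
  structure(
    list(variant = variant, eps_pos = eps_pos, eps_neg = eps_neg,
         v0 = v0, tau = tau),
    class = "rl_params"
  )
}

#' One temporal-difference value update
#'
#' Computes the prediction error `delta = r - v` and returns
#' `v + eps(delta) * delta`, where the learning rate is `eps_pos` for
#' better-than-expected outcomes (`delta > 0`) and `eps_neg` for
#' worse-than-expected ones. A zero prediction error leaves the value
#' unchanged (the rate applied to it is immaterial; the positive branch is
#' used for determinism).
#'
#' @param v Current value (vectorized).
#' @param r Binary outcome, 0 or 1 (vectorized).
#' @param eps_pos,eps_neg Learning rates in \[0, 1\].
#' @return Updated value(s); stays in \[0, 1\] whenever `v` starts there.
#' @export
td_update <- function(v, r, eps_pos, eps_neg) {
  stopifnot(all(r %in% c(0, 1)))
  delta <- r - v
  eps <- ifelse(delta > 0, eps_pos, ifelse(delta < 0, eps_neg, eps_pos))
  v + eps * delta
}

#' Softmax probability of choosing the fractal for a TD observer
#'
#' Identical logistic form to the Bayesian observer's [choice_prob()], with
#' the learned value in place of the posterior mean:
#' `p = 1 / (1 + exp(-tau * (v - b)))`, sign-flipped under punishment valence.
#'
#' @param v Learned value of the fractal (vectorized).
#' @param b Square's cued probability.
#' @param tau Softmax parameter, `>= 0`.
#' @param valence `"reward"` (default) or `"punishment"`.
#' @return Probability of choosing the fractal.
#' @export
rl_choice_prob <- function(v, b, tau, valence = "reward") {
  choice_prob(v, b, tau, valence)
}

#' Log-likelihood of a subject's choices under a TD observer
#'
#' Every fractal's value starts at `v0` and is updated by [td_update()] after
#' each of its observation screens, in trial-log order; each decision screen
#' is scored with [rl_choice_prob()] at the fractal's value current at that
#' decision. Decision screens give no feedback and therefore trigger no
#' update. Unlike the Bayesian observer, the likelihood depends on the order
#' of outcomes within a fractal whenever `eps_pos != eps_neg`.
#'
#' @param params An [rl_params()].
#' @param data A `"subject_data"`.
#' @return The log-likelihood.
#' @export
rl_log_lik <- function(params, data) {
  stopifnot(inherits(data, "subject_data"))
  events <- data$events[order(data$events$event_index), ]
  dec <- events$event_type == "dec"
  stopifnot(any(dec), !any(is.na(events$choice[dec])))
  s <- if (identical(data$valence, "punishment")) -1 else 1
  ids <- unique(events$fractal_id)
  v <- rep(params$v0, length(ids))
  names(v) <- as.character(ids)
  ll <- 0
  for (i in seq_len(nrow(events))) {
    id <- as.character(events$fractal_id[i])
    if (events$event_type[i] == "obs") {
      v[id] <- td_update(v[id], events$outcome[i], params$eps_pos, params$eps_neg)
    } else {
      x <- s * params$tau * (v[id] - events$square_prob[i])
      ll <- ll + stats::plogis(if (events$choice[i] == "fractal") x else -x,
                               log.p = TRUE)
    }
  }
  unname(ll)
}
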