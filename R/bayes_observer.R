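#' Parameters of the Bayesian observer
#'
#' The Bayesian observer carries a Beta(`alpha`, `beta`) prior over every
#' fractal's outcome probability — the same prior for all fractals — and
#' converts the posterior-mean estimate into a choice through a logistic
#' softmax with steepness `gamma`. The prior mean `alpha / (alpha + beta)` is
#' the model's measure of optimism: above 0.5 the observer expects reward
#' before seeing anything.
#'
#' @param alpha,beta Positive Beta shape parameters.
#' @param gamma Non-negative softmax steepness (0 = random choice).
#' @return A list of class `"bayes_params"` with an extra `prior_mean` field.
#' @export
bayes_params <- function(alpha, beta, gamma) {
  stopifnot(alpha > 0, beta > 0, gamma >= 0)
  structure(
    list(alpha = alpha, beta = beta, gamma = gamma,
         prior_mean = alpha / (alpha + beta)),
    class = "bayes_params"
  )
}

#' Prior density over an outcome probability
#'
#' The Beta(`alpha`, `beta`) density, the conjugate prior for Bernoulli
#' evidence, evaluated at `c`.
#'
#' @param c Probability value(s) in (0, 1).
#' @param alpha,beta Positive shape parameters.
#' @return Density value(s).
#' @export
prior_density <- function(c, alpha, beta) {
  stopifnot(alpha > 0, beta > 0)
  stats::dbeta(c, alpha, beta)
}

#' Posterior-mean estimate of a fractal's outcome probability
#'
#' With a Beta(`alpha`, `beta`) prior and `n_rewards` positive outcomes in
#' `n_shown` presentations, the posterior is Beta(`alpha + n_rewards`,
#' `beta + n_shown - n_rewards`) and its mean is
#' `(alpha + n_rewards) / (alpha + beta + n_shown)`. The prior's weight
#' `(alpha + beta) / (alpha + beta + n_shown)` shrinks as evidence
#' accumulates, which is what makes a prior-like optimism bias fade with
#' experience.
#'
#' @param alpha,beta Positive shape parameters.
#' @param n_rewards,n_shown Evidence counts, `0 <= n_rewards <= n_shown`
#'   (vectorized).
#' @return Posterior mean(s) in (0, 1).
#' @export
posterior_mean <- function(alpha, beta, n_rewards, n_shown) {
  stopifnot(alpha > 0, beta > 0, all(n_rewards >= 0), all(n_rewards <= n_shown))
  (alpha + n_rewards) / (alpha + beta + n_shown)
}

#' Softmax probability of choosing the fractal
#'
#' Logistic comparison of the observer's estimate `c_hat` with the square's
#' cued probability `b`:
#' `p = 1 / (1 + exp(-gamma * (c_hat - b)))` under reward valence. Under
#' punishment valence the sign is flipped — the observer avoids the option
#' with the higher estimated punishment probability.
#'
#' @param c_hat Estimated fractal outcome probability (vectorized).
#' @param b Square's cued probability (vectorized).
#' @param gamma Softmax steepness, `>= 0`.
#' @param valence `"reward"` (default) or `"punishment"`.
#' @return Probability of choosing the fractal.
#' @export
choice_prob <- function(c_hat, b, gamma, valence = "reward") {
  stopifnot(gamma >= 0, all(b >= 0 & b <= 1))
  s <- if (valence == "punishment") -1 else 1
  stats::plogis(s * gamma * (c_hat - b))
}

#' Log-likelihood of a subject's choices under the Bayesian observer
#'
#' Sums, over decision screens, the log-probability of the recorded choice:
#' the fractal-choice probability is the softmax of the posterior-mean
#' estimate against the cued square probability, and the square-choice
#' probability is its complement. Evidence for each decision uses all and only
#' the observation screens that precede it in the log; decisions with no prior
#' observations are scored from the prior mean alone.
#'
#' @param params A [bayes_params()] (or list with `alpha`, `beta`, `gamma`).
#' @param data A `"subject_data"`.
#' @param evidence Optional precomputed [decision_evidence()] table (an
#'   optimization for repeated evaluation; must match `data`).
#' @return The log-likelihood (finite for finite `gamma`).
#' @export
bayes_log_lik <- function(params, data, evidence = NULL) {
  ev <- evidence %||% decision_evidence(data)
  stopifnot(nrow(ev) >= 1, !any(is.na(ev$choice)))
  valence <- if (inherits(data, "subject_data")) data$valence else data
  c_hat <- posterior_mean(params$alpha, params$beta, ev$n_rewards, ev$n_shown)
  s <- if (identical(valence, "punishment")) -1 else 1
  x <- s * params$gamma * (c_hat - ev$square_prob)
  # log p(choice): plogis(x, log=TRUE) for fractal, plogis(-x, log=TRUE) for square
  sum(stats::plogis(ifelse(ev$choice == "fractal", x, -x), log.p = TRUE))
}
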