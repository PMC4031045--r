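test_that("prior density is the Beta density with the right special values", {
  # uniform prior
  cs <- seq(0.05, 0.95, by = 0.05)
  expect_equal(prior_density(cs, 1, 1), rep(1, length(cs)))
  # Jeffreys prior at its midpoint: 2/pi
  expect_equal(prior_density(0.5, 0.5, 0.5), 2 / pi, tolerance = 1e-12)
  # normalization by quadrature for random shapes
  set.seed(5)
  for (i in 1:5) {
    a <- stats::runif(1, 0.2, 8)
    b <- stats::runif(1, 0.2, 8)
    int <- stats::integrate(prior_density, 0, 1, alpha = a, beta = b)
    expect_equal(int$value, 1, tolerance = 1e-6)
  }
  expect_error(bayes_params(-1, 1, 1))
})

test_that("posterior mean matches the quadrature oracle on random instances", {
  # oracle: mean of prior x likelihood by adaptive quadrature, no conjugacy
  quad_mean <- function(a, b, n, N) {
    num <- stats::integrate(function(c) c * stats::dbeta(c, a, b) *
                              c^n * (1 - c)^(N - n), 0, 1, rel.tol = 1e-10)$value
    den <- stats::integrate(function(c) stats::dbeta(c, a, b) *
                              c^n * (1 - c)^(N - n), 0, 1, rel.tol = 1e-10)$value
    num / den
  }
  set.seed(101)
  for (i in 1:50) {
    a <- stats::runif(1, 0.1, 10)
    b <- stats::runif(1, 0.1, 10)
    N <- sample(0:30, 1)
    n <- if (N > 0) sample(0:N, 1) else 0L
    expect_equal(posterior_mean(a, b, n, N), quad_mean(a, b, n, N),
                 tolerance = 1e-6)
  }
  # symmetric special cases
  expect_equal(posterior_mean(0.5, 0.5, 0, 0), 0.5)
  expect_equal(posterior_mean(0.5, 0.5, 2, 4), 0.5)
})

test_that("prior influence vanishes with accumulating evidence", {
  a <- 3; b <- 1  # optimistic prior, mean 0.75
  f <- 0.2        # empirical rate
  Ns <- c(10, 100, 1000, 10000)
  pm <- posterior_mean(a, b, f * Ns, Ns)
  expect_true(all(diff(abs(pm - f)) < 0))
  expect_lt(abs(pm[length(Ns)] - f), 0.001)
  # prior weight (a+b)/(a+b+N) goes to zero
  expect_lt((a + b) / (a + b + max(Ns)), 0.001)
})

test_that("softmax choice rule has the right symmetries and limits", {
  expect_equal(choice_prob(0.3, 0.3, 5), 0.5)
  expect_equal(choice_prob(0.9, 0.1, 0), 0.5)
  expect_gt(choice_prob(0.8, 0.2, 50), 1 - 1e-10)
  # complementarity: swapping the two options' values flips the probability
  set.seed(3)
  ch <- stats::runif(20); b <- stats::runif(20); g <- stats::runif(20, 0, 20)
  expect_equal(choice_prob(ch, b, g[1]) + choice_prob(b, ch, g[1]),
               rep(1, 20), tolerance = 1e-12)
  # punishment valence flips the comparison
  expect_equal(choice_prob(0.8, 0.2, 5, valence = "punishment"),
               choice_prob(0.2, 0.8, 5), tolerance = 1e-12)
})

test_that("log-likelihood sums per-decision softmax log-probabilities", {
  subj <- tiny_subject(choices = c("fractal", "square"))
  # gamma = 0: every choice has probability 1/2
  expect_equal(bayes_log_lik(bayes_params(2, 3, 0), subj), 2 * log(0.5))
  # hand-computed: alpha=beta=0.5 -> c_hat1 = 1.5/3 = 0.5 vs b=0.5 -> p=0.5;
  # c_hat2 = 2.5/3 vs b=0.3, gamma=10 -> p(square) = 1 - plogis(10*(2.5/3-0.3))
  ll <- log(0.5) + stats::plogis(-10 * (2.5 / 3 - 0.3), log.p = TRUE)
  expect_equal(bayes_log_lik(bayes_params(0.5, 0.5, 10), subj), ll,
               tolerance = 1e-12)
  # single-decision closed form: c_hat 0.7 vs b 0.5 at gamma 10
  expect_equal(stats::plogis(10 * (0.7 - 0.5), log.p = TRUE),
               log(1 / (1 + exp(-2))), tolerance = 1e-12)
})

test_that("only evidence counts matter, not observation order", {
  subj <- tiny_subject()
  ev <- subj$events
  # swap fractal 1's two observation outcomes (1,0) -> (0,1)
  ev$outcome[1:2] <- ev$outcome[2:1]
  sched <- structure(list(events = ev, fractal_probs = subj$fractal_probs,
                          valence = subj$valence,
                          config = task_config("custom", n_fractals = 2,
                                               interleaving = "blocked")),
                     class = "trial_schedule")
  subj2 <- subject_data(sched, trait_score = subj$trait_score)
  p <- bayes_params(1.3, 0.6, 4)
  expect_equal(bayes_log_lik(p, subj), bayes_log_lik(p, subj2))
})

test_that("a decision about a never-observed fractal is scored from the prior", {
  sched <- tiny_schedule()
  ev <- tibble::add_row(sched$events,
                        event_index = 7L, event_type = "dec", fractal_id = 3L,
                        outcome = NA_integer_, square_prob = 0.5,
                        side = "left")
  sched$events <- ev
  sched$fractal_probs <- c(sched$fractal_probs, `3` = 0.5)
  sched$events$choice <- NA_character_
  sched$events$choice[sched$events$event_type == "dec"] <-
    c("fractal", "square", "fractal")
  subj <- subject_data(sched)
  evd <- decision_evidence(subj)
  expect_equal(evd$n_shown[evd$fractal_id == 3], 0L)
  p <- bayes_params(3, 1, 2)  # prior mean 0.75
  expect_true(is.finite(bayes_log_lik(p, subj)))
  # the prior-only decision contributes plogis(2 * (0.75 - 0.5))
  base <- tiny_subject(choices = c("fractal", "square"))
  expect_equal(bayes_log_lik(p, subj) - bayes_log_lik(p, base),
               stats::plogis(2 * 0.25, log.p = TRUE), tolerance = 1e-12)
})

test_that("log-likelihood is continuous in the parameters", {
  subj <- tiny_subject()
  base <- bayes_log_lik(bayes_params(2, 2, 5), subj)
  for (eps in c(1e-4, 1e-6)) {
    expect_lt(abs(bayes_log_lik(bayes_params(2 + eps, 2, 5), subj) - base), 1e-2)
    expect_lt(abs(bayes_log_lik(bayes_params(2, 2, 5 + eps), subj) - base), 1e-2)
  }
})
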