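#' Models available for fitting
#'
#' `bayes_full` is the three-parameter Bayesian observer (alpha, beta, gamma);
#' `bayes_jeffreys` fixes the prior at the non-informative Jeffreys Beta(0.5,
#' 0.5) and fits gamma only — the reference model against which a flexible
#' prior must justify its extra parameters. The four `RL_*` variants are the
#' temporal-difference observers of [rl_params()].
#'
#' @keywords internal
model_registry <- function() {
  list(
    bayes_full     = list(kind = "bayes", k = 3L),
    bayes_jeffreys = list(kind = "bayes", k = 1L),
    RL_eps         = list(kind = "rl", k = 2L),
    RL_2           = list(kind = "rl", k = 3L),
    RL_2b          = list(kind = "rl", k = 4L),
    RL_b           = list(kind = "rl", k = 2L)
  )
}

#' Bayesian Information Criterion
#'
#' `BIC = k * log(n) - 2 * log_lik`; lower is better. The sample size `n` is
#' the number of decision events, since only decisions enter the likelihood.
#'
#' @param log_lik Maximized log-likelihood.
#' @param k Number of free parameters.
#' @param n_decisions Number of decision events.
#' @return The BIC value.
#' @export
compute_bic <- function(log_lik, k, n_decisions) {
  stopifnot(n_decisions >= 1, k >= 0)
  k * log(n_decisions) - 2 * log_lik
}

# fast negative log-likelihood factories -----------------------------------

bayes_negll_factory <- function(data) {
  ev <- decision_evidence(data)
  s <- if (identical(data$valence, "punishment")) -1 else 1
  n <- ev$n_rewards; N <- ev$n_shown; b <- ev$square_prob
  sgn <- ifelse(ev$choice == "fractal", 1, -1)
  function(alpha, beta, gamma) {
    c_hat <- (alpha + n) / (alpha + beta + N)
    -sum(stats::plogis(sgn * s * gamma * (c_hat - b), log.p = TRUE))
  }
}

rl_negll_factory <- function(data) {
  events <- data$events[order(data$events$event_index), ]
  s <- if (identical(data$valence, "punishment")) -1 else 1
  dec <- events[events$event_type == "dec", ]
  obs <- events[events$event_type == "obs", ]
  hist <- lapply(seq_len(nrow(dec)), function(i) {
    sel <- obs$fractal_id == dec$fractal_id[i] & obs$event_index < dec$event_index[i]
    obs$outcome[sel]
  })
  b <- dec$square_prob
  sgn <- ifelse(dec$choice == "fractal", 1, -1)
  function(eps_pos, eps_neg, v0, tau) {
    v <- vapply(hist, function(r) {
      x <- v0
      for (ri in r) {
        d <- ri - x
        x <- x + (if (d > 0) eps_pos else if (d < 0) eps_neg else 0) * d
      }
      x
    }, numeric(1))
    -sum(stats::plogis(sgn * s * tau * (v - b), log.p = TRUE))
  }
}

# parameter-space descriptions: transform to/from the optimizer's box
model_space <- function(model) {
  switch(model,
    bayes_full = list(
      names = c("alpha", "beta", "gamma"),
      lower = log(c(0.05, 0.05, 0.01)),
      upper = log(c(20, 20, 100)),
      to_natural = exp
    ),
    bayes_jeffreys = list(
      names = "gamma",
      lower = log(0.01), upper = log(100),
      to_natural = exp
    ),
    RL_eps = list(
      names = c("eps", "tau"),
      lower = c(0, 0), upper = c(1, 100),
      to_natural = identity
    ),
    RL_2 = list(
      names = c("eps_pos", "eps_neg", "tau"),
      lower = c(0, 0, 0), upper = c(1, 1, 100),
      to_natural = identity
    ),
    RL_2b = list(
      names = c("eps_pos", "eps_neg", "v0", "tau"),
      lower = c(0, 0, 0, 0), upper = c(1, 1, 1, 100),
      to_natural = identity
    ),
    RL_b = list(
      names = c("v0", "tau"),
      lower = c(0, 0), upper = c(1, 100),
      to_natural = identity
    ),
    stop("unknown model: ", model, call. = FALSE)
  )
}

# map the optimizer's natural-space vector to the negll arguments
model_objective <- function(model, data) {
  if (model %in% c("bayes_full", "bayes_jeffreys")) {
    negll <- bayes_negll_factory(data)
    switch(model,
      bayes_full = function(p) negll(p[1], p[2], p[3]),
      bayes_jeffreys = function(p) negll(0.5, 0.5, p[1])
    )
  } else {
    negll <- rl_negll_factory(data)
    switch(model,
      RL_eps = function(p) negll(p[1], p[1], 0.5, p[2]),
      RL_2   = function(p) negll(p[1], p[2], 0.5, p[3]),
      RL_2b  = function(p) negll(p[1], p[2], p[3], p[4]),
      RL_b   = function(p) negll(0.1, 0.1, p[1], p[2])
    )
  }
}

# full natural-space parameter vector, fixed values filled in
full_params <- function(model, est) {
  switch(model,
    bayes_full = c(alpha = unname(est["alpha"]), beta = unname(est["beta"]),
                   gamma = unname(est["gamma"]),
                   prior_mean = unname(est["alpha"] / (est["alpha"] + est["beta"]))),
    bayes_jeffreys = c(alpha = 0.5, beta = 0.5, gamma = unname(est["gamma"]),
                       prior_mean = 0.5),
    RL_eps = c(eps_pos = unname(est["eps"]), eps_neg = unname(est["eps"]),
               v0 = 0.5, tau = unname(est["tau"])),
    RL_2 = c(eps_pos = unname(est["eps_pos"]), eps_neg = unname(est["eps_neg"]),
             v0 = 0.5, tau = unname(est["tau"])),
    RL_2b = c(eps_pos = unname(est["eps_pos"]), eps_neg = unname(est["eps_neg"]),
              v0 = unname(est["v0"]), tau = unname(est["tau"])),
    RL_b = c(eps_pos = 0.1, eps_neg = 0.1, v0 = unname(est["v0"]),
             tau = unname(est["tau"]))
  )
}

#' Fit one model to one subject by maximum likelihood
#'
#' Bounded multi-start local optimization of the model's log-likelihood. The
#' Bayesian observers are optimized on the log scale of their parameters to
#' respect positivity (alpha, beta in \[0.05, 20\], gamma in \[0.01, 100\]);
#' the TD observers are optimized in natural space (rates and `v0` in
#' \[0, 1\], tau in \[0, 100\]). Starts are a Latin-hypercube sample of the
#' box; the best start is reported. The one-dimensional `bayes_jeffreys`
#' profile is solved by golden-section search instead, which needs no
#' restarts.
#'
#' @param model One of `"bayes_full"`, `"bayes_jeffreys"`, `"RL_eps"`,
#'   `"RL_2"`, `"RL_2b"`, `"RL_b"`.
#' @param data A `"subject_data"` with at least one decision.
#' @param n_starts Number of optimizer starts (default 20).
#' @param seed Optional seed for the start sample (deterministic refits).
#' @return A list of class `"fit_result"`: `model`, `params` (full
#'   natural-space named vector, fixed values filled in; Bayesian fits also
#'   carry `prior_mean`), `log_lik`, `n_free_params`, `bic`, `n_starts`,
#'   `converged`, `n_decisions`, `start_objectives`.
#' @export
fit_subject <- function(model, data, n_starts = 20L, seed = NULL) {
  stopifnot(inherits(data, "subject_data"))
  reg <- model_registry()
  if (!model %in% names(reg)) stop("unknown model: ", model, call. = FALSE)
  n_dec <- sum(data$events$event_type == "dec")
  stopifnot(n_dec >= 1)

  space <- model_space(model)
  objective <- model_objective(model, data)
  d <- length(space$names)

  if (model == "bayes_jeffreys") {
    opt <- stats::optimize(function(lg) objective(exp(lg)),
                           lower = space$lower, upper = space$upper,
                           tol = 1e-10)
    # compare interior optimum with the boundary values
    cand <- rbind(c(opt$minimum, opt$objective),
                  c(space$lower, objective(exp(space$lower))),
                  c(space$upper, objective(exp(space$upper))))
    best <- cand[which.min(cand[, 2]), ]
    est <- stats::setNames(exp(best[1]), "gamma")
    result_ll <- -best[2]
    start_obj <- -best[2]
    converged <- TRUE
    n_starts_used <- 1L
  } else {
    run <- function() {
      u <- lhs::randomLHS(n_starts, d)
      starts <- sweep(sweep(u, 2, space$upper - space$lower, "*"),
                      2, space$lower, "+")
      if (model == "bayes_full") {
        # warm start at the nested Jeffreys solution; since local descent never
        # worsens the objective, the full model's fit is guaranteed to be at
        # least as good as the one-parameter reference fit
        jg <- stats::optimize(function(lg) objective(c(0.5, 0.5, exp(lg))),
                              lower = log(0.01), upper = log(100),
                              tol = 1e-10)$minimum
        starts <- rbind(starts, c(log(0.5), log(0.5), jg))
      }
      obj_in_box <- if (identical(space$to_natural, exp)) {
        function(p) objective(exp(p))
      } else {
        objective
      }
      fits <- lapply(seq_len(nrow(starts)), function(i) {
        tryCatch(
          stats::optim(starts[i, ], obj_in_box, method = "L-BFGS-B",
                       lower = space$lower, upper = space$upper,
                       control = list(maxit = 500)),
          error = function(e) NULL
        )
      })
      fits
    }
    fits <- if (is.null(seed)) run() else withr::with_seed(seed, run())
    fits <- Filter(Negate(is.null), fits)
    if (length(fits) == 0) {
      return(structure(
        list(model = model, params = NULL, log_lik = NA_real_,
             n_free_params = reg[[model]]$k, bic = NA_real_,
             n_starts = as.integer(n_starts), converged = FALSE,
             n_decisions = n_dec, start_objectives = numeric(0)),
        class = "fit_result"
      ))
    }
    start_obj <- -vapply(fits, `[[`, numeric(1), "value")
    best_fit <- fits[[which.max(start_obj)]]
    est <- stats::setNames(space$to_natural(best_fit$par), space$names)
    result_ll <- -best_fit$value
    converged <- any(vapply(fits, function(f) f$convergence == 0, logical(1)))
    n_starts_used <- as.integer(n_starts)
  }

  k <- reg[[model]]$k
  structure(
    list(
      model = model,
      params = full_params(model, est),
      log_lik = result_ll,
      n_free_params = k,
      bic = compute_bic(result_ll, k, n_dec),
      n_starts = n_starts_used,
      converged = converged,
      n_decisions = n_dec,
      start_objectives = start_obj
    ),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> ", x$model, ": logLik ", format(x$log_lik, digits = 6),
      ", BIC ", format(x$bic, digits = 6), ", k = ", x$n_free_params, "\n",
      sep = "")
  if (!is.null(x$params)) {
    print(round(x$params, 4))
  }
  invisible(x)
}

#' Fit one or several models to every subject of a cohort
#'
#' @param cohort A `"cohort"` (see [generate_cohort()]) or plain list of
#'   `"subject_data"`.
#' @param models Character vector of model names (see [fit_subject()]).
#' @param n_starts Starts per fit.
#' @param seed Optional base seed; each (subject, model) fit gets a distinct
#'   derived seed so the whole table is reproducible.
#' @return A tibble with one row per subject-model pair: `subject_id`,
#'   `trait_score`, `model`, `log_lik`, `n_free_params`, `bic`, `converged`,
#'   `prior_mean` (the fitted `alpha/(alpha+beta)` for Bayesian models, `v0`
#'   for TD models), and a `params` list-column of full parameter vectors.
#' @export
fit_cohort <- function(cohort, models = "bayes_full", n_starts = 20L,
                       seed = NULL) {
  subjects <- if (inherits(cohort, "cohort")) cohort$subjects else cohort
  rows <- list()
  for (i in seq_along(subjects)) {
    s <- subjects[[i]]
    for (j in seq_along(models)) {
      fit_seed <- if (is.null(seed)) NULL else
        (seed + 7907L * i + 104729L * j) %% .Machine$integer.max
      fit <- fit_subject(models[j], s, n_starts = n_starts, seed = fit_seed)
      pm <- if (is.null(fit$params)) NA_real_ else if ("prior_mean" %in% names(fit$params)) {
        fit$params[["prior_mean"]]
      } else {
        fit$params[["v0"]]
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        subject_id = s$subject_id,
        trait_score = s$trait_score,
        model = models[j],
        log_lik = fit$log_lik,
        n_free_params = fit$n_free_params,
        bic = fit$bic,
        converged = fit$converged,
        prior_mean = pm,
        params = list(fit$params)
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Compare fitted models across subjects by BIC
#'
#' For each subject the winning model is the one with the lowest BIC; exact
#' ties are broken toward the model with fewer free parameters and flagged.
#'
#' @param fits A tibble from [fit_cohort()] with at least two models per
#'   subject.
#' @return A list with `per_subject` (subject_id, best_model, best_bic, tie)
#'   and `summary` (model, mean_bic, n_best, frac_best).
#' @export
compare_models <- function(fits) {
  stopifnot(all(c("subject_id", "model", "bic", "n_free_params") %in% names(fits)))
  per_subject <- fits |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::group_modify(function(df, key) {
      stopifnot(nrow(df) >= 2)
      best_bic <- min(df$bic)
      cand <- df[df$bic == best_bic, ]
      tie <- nrow(cand) > 1
      cand <- cand[order(cand$n_free_params), ]
      tibble::tibble(best_model = cand$model[1], best_bic = best_bic, tie = tie)
    }) |>
    dplyr::ungroup()
  summary <- fits |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(mean_bic = mean(.data$bic), .groups = "drop") |>
    dplyr::left_join(
      per_subject |>
        dplyr::count(.data$best_model, name = "n_best") |>
        dplyr::rename(model = "best_model"),
      by = "model"
    ) |>
    dplyr::mutate(
      n_best = ifelse(is.na(.data$n_best), 0L, .data$n_best),
      frac_best = .data$n_best / nrow(per_subject)
    )
  list(per_subject = per_subject, summary = summary)
}
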