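#' Per-decision performance table for one subject
#'
#' For every decision screen, tabulates the empirically observed outcome rate
#' of the fractal (`n_rewards / n_shown`), the square's cued probability, the
#' difference `delta = rate - square_prob`, the recorded choice, and whether
#' the choice was "empirically correct" — picking the option with the higher
#' observed rate (lower, under punishment valence). Decisions where the two
#' rates tie, or where the fractal was never observed, have `correct = NA`.
#'
#' @param subject A `"subject_data"`.
#' @return A tibble with one row per decision.
#' @export
subject_performance <- function(subject) {
  stopifnot(inherits(subject, "subject_data"))
  ev <- decision_evidence(subject)
  rate <- ifelse(ev$n_shown > 0, ev$n_rewards / ev$n_shown, NA_real_)
  delta <- rate - ev$square_prob
  # under punishment the lower probability is the better option
  sgn <- if (identical(subject$valence, "punishment")) -1 else 1
  better <- sign(sgn * (rate - ev$square_prob))
  correct <- ifelse(
    is.na(better) | better == 0, NA,
    (better > 0) == (ev$choice == "fractal")
  )
  tibble::tibble(
    subject_id = subject$subject_id,
    event_index = ev$event_index,
    fractal_id = ev$fractal_id,
    n_rewards = ev$n_rewards,
    n_shown = ev$n_shown,
    observed_rate = rate,
    square_prob = ev$square_prob,
    delta = delta,
    choice = ev$choice,
    chose_fractal = ev$choice == "fractal",
    correct = correct
  )
}

#' Drop subjects who do not beat chance
#'
#' A subject's performance is the fraction of empirically correct decisions
#' (see [subject_performance()]; tied and never-observed decisions are
#' excluded from the denominator). Subjects at or below 50% are removed, as in
#' the study's post-hoc exclusion rule. A subject whose decisions are all ties
#' is retained and flagged.
#'
#' @param cohort A `"cohort"` or list of `"subject_data"`.
#' @return The cohort with low performers removed; the attribute `"exclusions"`
#'   carries a tibble of every subject's performance with `excluded` and
#'   `all_ties` flags.
#' @export
exclude_low_performers <- function(cohort) {
  subjects <- if (inherits(cohort, "cohort")) cohort$subjects else cohort
  perf <- vapply(subjects, function(s) {
    ok <- subject_performance(s)$correct
    ok <- ok[!is.na(ok)]
    if (length(ok) == 0) NA_real_ else mean(ok)
  }, numeric(1))
  all_ties <- is.na(perf)
  excluded <- !all_ties & perf <= 0.5
  info <- tibble::tibble(
    subject_id = vapply(subjects, function(s) s$subject_id, numeric(1)),
    performance = perf,
    all_ties = all_ties,
    excluded = excluded
  )
  keep <- !excluded
  out <- if (inherits(cohort, "cohort")) {
    cohort$subjects <- subjects[keep]
    if (!is.null(cohort$params)) {
      cohort$params <- cohort$params[cohort$params$subject_id %in%
                                       info$subject_id[keep], ]
    }
    cohort
  } else {
    subjects[keep]
  }
  attr(out, "exclusions") <- info
  out
}

#' Split trait scores into optimists and pessimists
#'
#' Scores strictly above the group mean are optimists; scores at or below it
#' (including exact ties with the mean) are pessimists.
#'
#' @param trait_scores Numeric vector.
#' @return Factor with levels `"pessimist"`, `"optimist"`.
#' @export
trait_split <- function(trait_scores) {
  factor(ifelse(trait_scores > mean(trait_scores), "optimist", "pessimist"),
         levels = c("pessimist", "optimist"))
}

#' Group performance curves
#'
#' The fraction of decisions on which the fractal was chosen, binned by
#' `delta = observed rate - square probability` over \[-1, 1\]. An optimist
#' whose prior inflates the estimate chooses the fractal more often than a
#' pessimist at the same `delta`, most visibly for `delta < 0`. Decisions
#' about never-observed fractals have no observed rate and are dropped (their
#' count is reported in the `"n_dropped"` attribute); empty bins get `NA`
#' proportions.
#'
#' @param cohort A `"cohort"` or list of `"subject_data"` (run
#'   [exclude_low_performers()] first if desired).
#' @param bin_width Bin width on the `delta` axis (default 0.2).
#' @param split If `TRUE` (default), also return separate optimist and
#'   pessimist curves based on [trait_split()] of the subjects' trait scores.
#' @return A tibble with columns `group`, `bin_lo`, `bin_hi`, `bin_mid`, `n`,
#'   `prop_fractal`.
#' @export
performance_curve <- function(cohort, bin_width = 0.2, split = TRUE) {
  subjects <- if (inherits(cohort, "cohort")) cohort$subjects else cohort
  tab <- dplyr::bind_rows(lapply(subjects, subject_performance))
  n_dropped <- sum(is.na(tab$observed_rate))
  tab <- tab[!is.na(tab$observed_rate), ]
  if (split) {
    traits <- stats::setNames(
      vapply(subjects, function(s) as.numeric(s$trait_score), numeric(1)),
      vapply(subjects, function(s) as.character(s$subject_id), character(1))
    )
    grp <- trait_split(traits)
    tab$group <- as.character(grp[match(as.character(tab$subject_id),
                                        names(traits))])
    tab <- dplyr::bind_rows(tab, dplyr::mutate(tab, group = "all"))
  } else {
    tab$group <- "all"
  }
  edges <- seq(-1, 1, by = bin_width)
  tab$bin <- cut(tab$delta, breaks = edges, include.lowest = TRUE)
  grid <- expand.grid(group = unique(tab$group), bin = levels(tab$bin),
                      stringsAsFactors = FALSE)
  out <- tab |>
    dplyr::group_by(.data$group, .data$bin) |>
    dplyr::summarise(n = dplyr::n(),
                     prop_fractal = mean(.data$chose_fractal),
                     .groups = "drop")
  out <- dplyr::left_join(tibble::as_tibble(grid), out,
                          by = c("group", "bin"))
  out$n[is.na(out$n)] <- 0L
  idx <- match(out$bin, levels(tab$bin))
  out$bin_lo <- edges[idx]
  out$bin_hi <- edges[idx + 1]
  out$bin_mid <- (out$bin_lo + out$bin_hi) / 2
  out <- out[order(out$group, out$bin_mid),
             c("group", "bin_lo", "bin_hi", "bin_mid", "n", "prop_fractal")]
  attr(out, "n_dropped") <- n_dropped
  tibble::as_tibble(out)
}

#' Correlate trait scores with fitted prior means
#'
#' Pearson correlation with the exact two-sided p-value from the t transform
#' on `n - 2` degrees of freedom, plus the Bonferroni-adjusted p-value for the
#' study's family of `m` comparisons (default 42: every questionnaire subscale
#' against every fitted parameter).
#'
#' @param trait_scores,fitted_prior_means Paired per-subject vectors, `n >= 4`.
#' @param m Bonferroni multiplier (default 42).
#' @return A list: `r`, `p`, `p_adjusted`, `n`, `df`, `m`.
#' @export
correlate_trait_prior <- function(trait_scores, fitted_prior_means, m = 42) {
  stopifnot(length(trait_scores) == length(fitted_prior_means),
            length(trait_scores) >= 4)
  if (stats::sd(trait_scores) == 0 || stats::sd(fitted_prior_means) == 0) {
    stop("zero variance in one of the vectors; correlation undefined",
         call. = FALSE)
  }
  ct <- stats::cor.test(trait_scores, fitted_prior_means, method = "pearson")
  list(
    r = unname(ct$estimate),
    p = ct$p.value,
    p_adjusted = min(1, m * ct$p.value),
    n = length(trait_scores),
    df = unname(ct$parameter),
    m = m
  )
}

#' Fisher r-to-z comparison of two independent correlations
#'
#' `Z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`, referred to the
#' standard normal, two-sided.
#'
#' @param r1,r2 Correlations with `|r| < 1`.
#' @param n1,n2 Sample sizes, both `> 3`.
#' @return A list: `z`, `p`.
#' @export
fisher_z_compare <- function(r1, n1, r2, n2) {
  stopifnot(abs(r1) < 1, abs(r2) < 1, n1 > 3, n2 > 3)
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Optimist-versus-pessimist comparisons of fitted parameters
#'
#' Splits the fitted subjects at the cohort-mean trait score (ties go to the
#' pessimists) and runs a Welch two-sample t-test on every fitted parameter,
#' producing the per-group means and standard deviations of the study's
#' group-summary tables. Parameters held fixed by the model (zero variance in
#' both groups) get `NA` test statistics.
#'
#' @param fits A tibble from [fit_cohort()] for a single model (or filter one
#'   model out of a multi-model table first).
#' @return A list with `groups` (per-group n and trait summary) and `tests`
#'   (one row per parameter: group means/sds, `t`, `df`, `p`).
#' @export
split_group_tests <- function(fits) {
  stopifnot(all(c("trait_score", "params") %in% names(fits)))
  if (length(unique(fits$model)) != 1) {
    stop("`fits` must contain a single model; filter first", call. = FALSE)
  }
  grp <- trait_split(fits$trait_score)
  if (min(table(grp)) < 2) stop("a group has fewer than 2 members", call. = FALSE)

  long <- dplyr::bind_rows(lapply(seq_len(nrow(fits)), function(i) {
    p <- fits$params[[i]]
    tibble::tibble(subject_id = fits$subject_id[i], group = as.character(grp[i]),
                   param = names(p), value = unname(p))
  }))
  tests <- long |>
    dplyr::group_by(.data$param) |>
    dplyr::group_modify(function(df, key) {
      x <- df$value[df$group == "optimist"]
      y <- df$value[df$group == "pessimist"]
      tt <- tryCatch(stats::t.test(x, y), error = function(e) NULL)
      tibble::tibble(
        mean_optimist = mean(x), sd_optimist = stats::sd(x),
        mean_pessimist = mean(y), sd_pessimist = stats::sd(y),
        t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
        df = if (is.null(tt)) NA_real_ else unname(tt$parameter),
        p = if (is.null(tt)) NA_real_ else tt$p.value
      )
    }) |>
    dplyr::ungroup()
  groups <- tibble::tibble(
    group = c("optimist", "pessimist"),
    n = c(sum(grp == "optimist"), sum(grp == "pessimist")),
    trait_mean = c(mean(fits$trait_score[grp == "optimist"]),
                   mean(fits$trait_score[grp == "pessimist"])),
    trait_sd = c(stats::sd(fits$trait_score[grp == "optimist"]),
                 stats::sd(fits$trait_score[grp == "pessimist"]))
  )
  list(groups = groups, tests = tests)
}

#' Under- versus over-observed stratified analysis
#'
#' Within each subject, splits decisions by how often the fractal had been
#' observed: fewer than `threshold` times ("under-observed") versus more than
#' `threshold` times ("over-observed"); decisions at exactly `threshold` fall
#' in neither stratum. The per-subject bias in each stratum is the fraction of
#' those decisions on which the fractal was chosen. If the prior drives the
#' optimist-pessimist difference, the difference should be strongest where
#' evidence is thinnest. Three tests are run: Welch two-sample t-tests of
#' optimists versus pessimists within each stratum, and a one-tailed
#' two-sample t-test that the per-subject (under minus over) bias difference
#' is greater for optimists.
#'
#' @param cohort A `"cohort"` or list of `"subject_data"`.
#' @param threshold Stratum boundary on the presentation count (default 4).
#' @return A list: `per_subject` (subject_id, group, bias_under, bias_over,
#'   diff), `under_test`, `over_test`, `interaction_test` (each a list with
#'   `t`, `df`, `p`, and group means), `n_dropped_under`, `n_dropped_over`.
#' @export
under_over_observed_analysis <- function(cohort, threshold = 4L) {
  subjects <- if (inherits(cohort, "cohort")) cohort$subjects else cohort
  per <- dplyr::bind_rows(lapply(subjects, function(s) {
    perf <- subject_performance(s)
    under <- perf$chose_fractal[perf$n_shown < threshold]
    over <- perf$chose_fractal[perf$n_shown > threshold]
    tibble::tibble(
      subject_id = s$subject_id,
      trait_score = as.numeric(s$trait_score),
      bias_under = if (length(under)) mean(under) else NA_real_,
      bias_over = if (length(over)) mean(over) else NA_real_
    )
  }))
  per$group <- as.character(trait_split(per$trait_score))
  per$diff <- per$bias_under - per$bias_over

  welch <- function(x, y, alternative = "two.sided") {
    tt <- stats::t.test(x, y, alternative = alternative)
    list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
         mean_optimist = mean(x), mean_pessimist = mean(y))
  }
  opt <- per$group == "optimist"
  u_ok <- !is.na(per$bias_under)
  o_ok <- !is.na(per$bias_over)
  d_ok <- u_ok & o_ok
  list(
    per_subject = per,
    under_test = welch(per$bias_under[opt & u_ok], per$bias_under[!opt & u_ok]),
    over_test = welch(per$bias_over[opt & o_ok], per$bias_over[!opt & o_ok]),
    interaction_test = welch(per$diff[opt & d_ok], per$diff[!opt & d_ok],
                             alternative = "greater"),
    n_dropped_under = sum(!u_ok),
    n_dropped_over = sum(!o_ok)
  )
}
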