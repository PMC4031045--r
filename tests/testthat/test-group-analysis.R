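test_that("maximizing agents are never excluded; random agents often are", {
  set.seed(91)
  maximizers <- lapply(1:4, function(i) {
    simulate_subject(bayes_params(1, 1, 1000), build_schedule(task_config("exp1")),
                     "bayes", subject_id = i, trait_score = 10L + i)
  })
  kept <- exclude_low_performers(maximizers)
  expect_length(kept, 4)
  info <- attr(kept, "exclusions")
  # a posterior-mean maximizer can disagree with the raw-rate criterion on
  # near-ties (prior shrinkage), but stays far above the 50% exclusion bar
  expect_true(all(info$performance > 0.75))
  expect_false(any(info$excluded))

  # gamma = 0 agents sit at binomial(n_informative, 0.5): excluded about half
  # the time
  set.seed(93)
  randoms <- lapply(1:40, function(i) {
    simulate_subject(bayes_params(1, 1, 0), build_schedule(task_config("exp1")),
                     "bayes", subject_id = i, trait_score = 12L)
  })
  kept_r <- exclude_low_performers(randoms)
  frac_excluded <- 1 - length(kept_r) / 40
  expect_gt(frac_excluded, 0.2)
  expect_lt(frac_excluded, 0.8)
})

test_that("exclusion handles cohorts and keeps params in sync", {
  co <- small_cohort(n = 6, seed = 97)
  # force one subject to always pick the empirically worse option
  s <- co$subjects[[2]]
  perf <- subject_performance(s)
  anti <- ifelse(!is.na(perf$observed_rate) & perf$observed_rate > perf$square_prob,
                 "square", "fractal")
  co$subjects[[2]]$events$choice[co$subjects[[2]]$events$event_type == "dec"] <- anti
  kept <- exclude_low_performers(co)
  info <- attr(kept, "exclusions")
  expect_true(info$excluded[2])
  expect_equal(length(kept$subjects), 5)
  expect_equal(nrow(kept$params), 5)
  expect_false(2 %in% kept$params$subject_id)
})

test_that("performance curves separate optimists from pessimists at negative delta", {
  set.seed(103)
  # two planted groups: optimistic prior mean 0.8 vs pessimistic 0.2
  mk <- function(pm, id, trait) {
    simulate_subject(bayes_params(2 * pm, 2 * (1 - pm), 10),
                     build_schedule(task_config("exp1")), "bayes",
                     subject_id = id, trait_score = trait)
  }
  subs <- c(lapply(1:8, function(i) mk(0.8, i, 20L)),
            lapply(9:16, function(i) mk(0.2, i, 5L)))
  curve <- performance_curve(subs, bin_width = 0.2)
  expect_true(all(curve$prop_fractal >= 0 & curve$prop_fractal <= 1, na.rm = TRUE))
  neg <- curve$bin_mid < 0 & curve$n > 5
  opt <- curve[curve$group == "optimist" & neg, ]
  pes <- curve[curve$group == "pessimist" & neg, ]
  shared <- intersect(opt$bin_mid, pes$bin_mid)
  expect_gt(mean(opt$prop_fractal[match(shared, opt$bin_mid)]),
            mean(pes$prop_fractal[match(shared, pes$bin_mid)]))

  # near-deterministic unbiased observers produce a sigmoid step around 0
  set.seed(105)
  steps <- lapply(1:6, function(i) {
    simulate_subject(bayes_params(0.5, 0.5, 1000),
                     build_schedule(task_config("exp2")), "bayes",
                     subject_id = i, trait_score = 12L)
  })
  sc <- performance_curve(steps, split = FALSE)
  lo <- sc$prop_fractal[sc$bin_mid < -0.3 & sc$n > 0]
  hi <- sc$prop_fractal[sc$bin_mid > 0.3 & sc$n > 0]
  expect_lt(max(lo), 0.2)
  expect_gt(min(hi), 0.8)
})

test_that("subjects who always choose the fractal give a flat curve at 1", {
  co <- small_cohort(n = 3, seed = 107)
  for (i in 1:3) {
    dec <- co$subjects[[i]]$events$event_type == "dec"
    co$subjects[[i]]$events$choice[dec] <- "fractal"
  }
  curve <- performance_curve(co, split = FALSE)
  expect_true(all(curve$prop_fractal[curve$n > 0] == 1))
})

test_that("trait-prior correlation reports r, exact p and Bonferroni adjustment", {
  x <- 1:10
  y <- 2 * x + 3
  res <- correlate_trait_prior(x, y)
  expect_equal(res$r, 1)
  # the paper's printed adjustment: raw p = 0.001 -> adjusted 0.042
  expect_equal(min(1, 42 * 0.001), 0.042)
  # p agrees with the brute-force t transform
  set.seed(109)
  for (i in 1:10) {
    a <- stats::rnorm(20); b <- 0.4 * a + stats::rnorm(20)
    res <- correlate_trait_prior(a, b)
    tstat <- res$r * sqrt((res$n - 2) / (1 - res$r^2))
    p_oracle <- 2 * stats::pt(-abs(tstat), df = res$n - 2)
    expect_equal(res$p, p_oracle, tolerance = 1e-10)
    expect_equal(res$p_adjusted, min(1, 42 * p_oracle))
  }
  expect_error(correlate_trait_prior(rep(1, 5), 1:5), "variance")
})

test_that("fisher z comparison matches the closed form and its symmetries", {
  # equal correlations: no difference
  same <- fisher_z_compare(0.3, 30, 0.3, 50)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)
  # antisymmetry
  a <- fisher_z_compare(0.6, 40, 0.2, 35)
  b <- fisher_z_compare(0.2, 35, 0.6, 40)
  expect_equal(a$z, -b$z)
  expect_equal(a$p, b$p)
  # the published cross-experiment comparison
  z <- fisher_z_compare(0.438, 51, 0.009, 51)
  expect_lt(abs(z$z - 2.26), 0.01)
  expect_lt(abs(z$p - 0.02), 0.005)
  expect_error(fisher_z_compare(1, 10, 0.2, 10))
})

test_that("optimist/pessimist split tests find a planted prior-mean difference", {
  co <- generate_cohort(cohort_config(n_subjects = 40, trait_prior_corr = 0.9,
                                      seed = 113))
  fits <- fit_cohort(co, "bayes_full", n_starts = 10, seed = 113)
  res <- split_group_tests(fits)
  expect_equal(sum(res$groups$n), 40)
  pm <- res$tests[res$tests$param == "prior_mean", ]
  expect_gt(pm$mean_optimist, pm$mean_pessimist)
  expect_lt(pm$p, 0.05)
  # ties at the mean go to pessimists
  expect_equal(as.character(trait_split(c(10, 10, 10, 14))),
               c("pessimist", "pessimist", "pessimist", "optimist"))
})

test_that("identical groups give near-zero t statistics", {
  co <- small_cohort(n = 6, seed = 127)
  fits <- fit_cohort(co, "bayes_jeffreys")
  # force alternating trait scores so groups see identical fitted params
  fits$trait_score <- rep(c(5L, 20L), 3)
  fits$params <- rep(list(c(alpha = 0.5, beta = 0.5, gamma = 2, prior_mean = 0.5)), 6)
  res <- split_group_tests(fits)
  g <- res$tests[res$tests$param == "gamma", ]
  expect_true(is.na(g$t) || abs(g$t) < 1e-8)
})

test_that("under/over stratification respects strict inequalities and drops", {
  co <- small_cohort(n = 10, seed = 131)
  res <- under_over_observed_analysis(co, threshold = 4)
  expect_equal(nrow(res$per_subject), 10)
  # recompute one subject by hand
  s <- co$subjects[[1]]
  perf <- subject_performance(s)
  expect_equal(res$per_subject$bias_under[1],
               mean(perf$chose_fractal[perf$n_shown < 4]))
  expect_equal(res$per_subject$bias_over[1],
               mean(perf$chose_fractal[perf$n_shown > 4]))
  # decisions at exactly the threshold belong to neither stratum
  n4 <- sum(perf$n_shown == 4)
  n_used <- sum(perf$n_shown < 4) + sum(perf$n_shown > 4)
  expect_equal(n_used + n4, nrow(perf))
})

test_that("a null cohort shows no stratified group differences", {
  pu <- pint <- numeric(8)
  for (i in 1:8) {
    co <- generate_cohort(cohort_config(trait_prior_corr = 0, seed = 5200 + i))
    a <- under_over_observed_analysis(co)
    pu[i] <- a$under_test$p
    pint[i] <- a$interaction_test$p
  }
  # under the null, p-values should not pile up near zero
  expect_gt(mean(pu > 0.05), 0.5)
  expect_gt(mean(pint > 0.05), 0.5)
})

test_that("type-I error of the pipeline correlation is calibrated", {
  # null cohorts: |r| exceeds the 5% critical value about 5% of the time.
  # measured on the generator's true prior means (no fitting) to keep the
  # calibration check cheap and focused on the statistics
  set.seed(137)
  crit <- stats::qt(0.975, 49)
  hits <- replicate(200, {
    p <- draw_subject_params(cohort_config(trait_prior_corr = 0))
    r <- stats::cor(p$trait_score, p$prior_mean)
    abs(r * sqrt(49 / (1 - r^2))) > crit
  })
  expect_lt(abs(mean(hits) - 0.05), 0.04)
})
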