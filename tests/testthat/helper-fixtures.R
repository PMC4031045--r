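# small in-code fixtures shared across test files

# a tiny schedule with known structure: 2 fractals, hand-set outcomes
tiny_schedule <- function(valence = "reward") {
  events <- tibble::tibble(
    event_index = 1:6,
    event_type = c("obs", "obs", "obs", "dec", "obs", "dec"),
    fractal_id = c(1L, 1L, 2L, 1L, 2L, 2L),
    outcome = c(1L, 0L, 1L, NA, 1L, NA),
    square_prob = c(NA, NA, NA, 0.5, NA, 0.3),
    side = c(NA, NA, NA, "left", NA, "right")
  )
  cfg <- task_config("custom", n_fractals = 2, valence = valence,
                     interleaving = "blocked")
  structure(
    list(events = events, fractal_probs = c(`1` = 0.6, `2` = 0.9),
         valence = valence, config = cfg),
    class = "trial_schedule"
  )
}

tiny_subject <- function(choices = c("fractal", "square"), valence = "reward",
                         trait_score = 12L) {
  sched <- tiny_schedule(valence)
  sched$events$choice <- NA_character_
  sched$events$choice[sched$events$event_type == "dec"] <- choices
  subject_data(sched, subject_id = 1L, trait_score = trait_score)
}

# small simulated cohort for pipeline tests (kept tiny for speed)
small_cohort <- function(n = 8, seed = 42, ...) {
  generate_cohort(cohort_config(n_subjects = n, seed = seed, ...))
}
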