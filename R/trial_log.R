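#' Write a subject's trial log to CSV
#'
#' One row per event with columns `subject_id`, `event_index`, `event_type`
#' (`obs`/`dec`), `fractal_id`, `outcome` (0/1, empty for decisions),
#' `square_prob` (grid value, empty for observations), `side`, `choice`
#' (`fractal`/`square`, empty for observations). A JSON sidecar
#' (`<path>.json`) stores the metadata needed to rebuild the subject: trait
#' score, valence, design, true fractal probabilities, and the generating
#' parameters when known.
#'
#' @param subject A `"subject_data"`.
#' @param path CSV file path; the sidecar is written to `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_trial_log <- function(subject, path) {
  stopifnot(inherits(subject, "subject_data"))
  df <- subject$events
  df <- cbind(subject_id = subject$subject_id, df)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  meta <- list(
    subject_id = subject$subject_id,
    trait_score = subject$trait_score,
    valence = subject$valence,
    design = subject$design,
    fractal_probs = as.list(subject$fractal_probs),
    true_params = subject$true_params
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a subject's trial log from CSV
#'
#' Inverse of [write_trial_log()]. If the JSON sidecar is missing, the subject
#' is reconstructed from the CSV alone with unknown fractal probabilities and
#' the valence given by the `valence` argument.
#'
#' @param path CSV file path.
#' @param valence Fallback valence when no sidecar exists.
#' @return A `"subject_data"`.
#' @export
read_trial_log <- function(path, valence = "reward") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(side = "character", choice = "character"))
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else NULL
  events <- tibble::tibble(
    event_index = as.integer(df$event_index),
    event_type = df$event_type,
    fractal_id = as.integer(df$fractal_id),
    outcome = as.integer(df$outcome),
    square_prob = as.numeric(df$square_prob),
    side = ifelse(df$side == "" | is.na(df$side), NA_character_, df$side),
    choice = ifelse(df$choice == "" | is.na(df$choice), NA_character_, df$choice)
  )
  probs <- if (!is.null(meta$fractal_probs)) {
    unlist(meta$fractal_probs)
  } else {
    ids <- sort(unique(events$fractal_id))
    stats::setNames(rep(NA_real_, length(ids)), ids)
  }
  val <- meta$valence %||% valence
  design <- meta$design %||% NA_character_
  cfg <- structure(list(design = design, valence = val), class = "task_config")
  sched <- structure(
    list(events = events, fractal_probs = probs, valence = val, config = cfg),
    class = "trial_schedule"
  )
  subject_data(
    sched,
    subject_id = meta$subject_id %||% df$subject_id[1],
    trait_score = if (is.null(meta$trait_score)) NA_integer_ else
      as.integer(meta$trait_score),
    true_params = meta$true_params
  )
}

#' Write a cohort as one trial log per subject plus a manifest
#'
#' @param cohort A `"cohort"`.
#' @param dir Output directory (created if needed). Each subject goes to
#'   `subject_<id>.csv` (+ sidecar); the true generating parameters and the
#'   cohort configuration go to `manifest.json` for recovery scoring.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in cohort$subjects) {
    write_trial_log(s, file.path(dir, sprintf("subject_%03d.csv", s$subject_id)))
  }
  manifest <- list(
    config = unclass(cohort$config),
    params = cohort$params
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `subject_*.csv` files and `manifest.json`.
#' @return A `"cohort"`.
#' @export
read_cohort <- function(dir) {
  files <- sort(list.files(dir, pattern = "^subject_\\d+\\.csv$",
                           full.names = TRUE))
  stopifnot(length(files) >= 1)
  subjects <- lapply(files, read_trial_log)
  manifest_path <- file.path(dir, "manifest.json")
  manifest <- if (file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  } else {
    NULL
  }
  config <- if (!is.null(manifest$config)) {
    do.call(cohort_config, manifest$config[
      setdiff(names(manifest$config), character(0))
    ])
  } else {
    NULL
  }
  structure(
    list(subjects = subjects,
         params = if (!is.null(manifest$params))
           tibble::as_tibble(manifest$params) else NULL,
         config = config),
    class = "cohort"
  )
}
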