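#' Cohort configuration for the paired-sample simulator
#'
#' Describes the subjects of a simulated paired mucosa/feces study. The
#' defaults reproduce the structure of a 20-adult colorectal-polyp cohort:
#' 12 males and 8 females, ages 44-68 years, BMI 19.7-27 kg/m2, and polyp
#' pathology groups of 3 (hyperplastic, low risk), 12 (tubular adenomas,
#' moderate risk) and 5 (tubulovillous adenomas, high risk) subjects.
#'
#' @param n_subjects number of subjects; each contributes one mucosa and one
#'   feces sample.
#' @param age_range `[min, max]` age in whole years (sampled uniformly).
#' @param gender_ratio fraction of male subjects; the realized count is
#'   `round(gender_ratio * n_subjects)`, assigned to random subjects.
#' @param bmi_range `[min, max]` BMI in kg/m2 (sampled uniformly, 1 decimal).
#' @param polyp_group_sizes integer vector of subjects per polyp risk group
#'   (low, moderate, high); must sum to `n_subjects`.
#' @return a validated `cohort_config` list.
#' @export
cohort_config <- function(n_subjects = 20L,
                          age_range = c(44, 68),
                          gender_ratio = 0.6,
                          bmi_range = c(19.7, 27),
                          polyp_group_sizes = c(3L, 12L, 5L)) {
  if (!is_count(n_subjects, min = 2L)) stop_config("n_subjects", "must be an integer >= 2")
  check_range(age_range, "age_range")
  check_range(bmi_range, "bmi_range")
  if (!is.numeric(gender_ratio) || length(gender_ratio) != 1L ||
      is.na(gender_ratio) || gender_ratio < 0 || gender_ratio > 1) {
    stop_config("gender_ratio", "must be a fraction in [0, 1]")
  }
  if (!is.numeric(polyp_group_sizes) || length(polyp_group_sizes) != 3L ||
      any(polyp_group_sizes < 0) || any(polyp_group_sizes != round(polyp_group_sizes))) {
    stop_config("polyp_group_sizes", "must be three non-negative integer counts (low/moderate/high)")
  }
  if (sum(polyp_group_sizes) != n_subjects) {
    stop_config("polyp_group_sizes", sprintf("must sum to n_subjects (%d), got %d",
                                             n_subjects, sum(polyp_group_sizes)))
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 age_range = age_range,
                 gender_ratio = gender_ratio,
                 bmi_range = bmi_range,
                 polyp_group_sizes = as.integer(polyp_group_sizes)),
            class = "cohort_config")
}

#' Generate paired sample metadata for a synthetic cohort
#'
#' Draws subject phenotypes under a [cohort_config()] and expands each
#' subject into two samples (one per site). Ages are uniform integers over
#' the configured range, BMI uniform to one decimal, the male count is fixed
#' at `round(gender_ratio * n_subjects)`, and polyp risk groups are assigned
#' with exactly the configured sizes, all in randomized subject order.
#'
#' @param config a [cohort_config()].
#' @param seed integer global seed; the cohort uses its own derived stream,
#'   see [stream_seed()].
#' @return data.frame with one row per sample and columns `sample_id`,
#'   `subject_id`, `site`, `age`, `gender`, `bmi`, `polyp_group`.
#' @examples
#' md <- generate_cohort(cohort_config(), seed = 1)
#' table(md$site)
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1L) {
  if (!inherits(config, "cohort_config")) config <- do.call(cohort_config, config)
  n <- config$n_subjects
  with_seed(stream_seed(seed, 1L), {
    subject_id <- sprintf("S%02d", seq_len(n))
    n_male <- as.integer(round(config$gender_ratio * n))
    gender <- sample(c(rep("male", n_male), rep("female", n - n_male)))
    age <- sample(seq(ceiling(config$age_range[1]), floor(config$age_range[2])),
                  n, replace = TRUE)
    bmi <- round(stats::runif(n, config$bmi_range[1], config$bmi_range[2]), 1)
    polyp_group <- sample(rep.int(1:3, config$polyp_group_sizes))
    metadata <- data.frame(
      sample_id = paste(rep(subject_id, each = 2L), rep(c("mucosa", "feces"), n), sep = "_"),
      subject_id = rep(subject_id, each = 2L),
      site = rep(c("mucosa", "feces"), n),
      age = rep(age, each = 2L),
      gender = rep(gender, each = 2L),
      bmi = rep(bmi, each = 2L),
      polyp_group = rep(polyp_group, each = 2L),
      stringsAsFactors = FALSE
    )
    validate_metadata(metadata, require_paired = TRUE)
    metadata
  })
}
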