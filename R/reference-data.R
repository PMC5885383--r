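# Published course-level reference tables from the source SOF training studies.
# Stored as plain CSV under inst/extdata and parsed on demand.

ref_file <- function(file) {
  system.file("extdata", file, package = "opsfuel", mustWork = TRUE)
}

#' Published course-level anthropometry of SOF training cohorts
#'
#' Mean and 95% confidence interval of body mass, fat-free mass and fat mass
#' (kg) for eleven SOF training courses, plus the pooled row, as published by
#' the source study. Small Unit Ranger Training appears once here (its
#' classroom and field phases share one anthropometry row); the energy table
#' from [sof_training_energy()] splits it into two phases.
#'
#' @param include_overall keep the pooled "Overall" row (default `FALSE`).
#' @return A data.frame with columns `course`, `n`, and `{bm,ffm,fm}_mean`,
#'   `{bm,ffm,fm}_ci_low`, `{bm,ffm,fm}_ci_high`.
#' @seealso [sof_training_energy()], [training_course_specs()]
#' @export
#' @examples
#' a <- sof_training_anthropometry()
#' sum(a$n)  # 133 participants
sof_training_anthropometry <- function(include_overall = FALSE) {
  x <- utils::read.csv(ref_file("sof_training_anthropometry.csv"),
                       stringsAsFactors = FALSE)
  if (!include_overall) x <- x[x$course != "Overall", , drop = FALSE]
  rownames(x) <- NULL
  x
}

#' Published course-level energy expenditure, intake and balance
#'
#' Course means of measured daily energy expenditure (`tdee`, kcal/d with its
#' 95% CI), resting metabolic rate (`rmr`), diet-induced energy expenditure
#' (`dit`), activity-induced energy expenditure (`aiee`), physical activity
#' level (`pal`), energy intake and balance (kcal/d), body-mass change
#' (`delta_bm`, kg), the physical activity factor (`paf`, 0-3) under the
#' published quartile scheme, and the published Model A / Model B predicted
#' course means. Twelve rows: Small Unit Ranger Training is split into
#' classroom and field phases; `anthropometry_course` maps each row back to
#' [sof_training_anthropometry()]. The per-phase participant counts were not
#' published; the packaged split (6 classroom / 7 field) is an assumption
#' documented in the methods vignette.
#'
#' @param include_overall keep the pooled "Overall" row (default `FALSE`).
#' @return A data.frame, one row per training course (phase).
#' @export
#' @examples
#' e <- sof_training_energy()
#' e[e$course == "Urban Combat", c("tdee", "pal", "paf")]
sof_training_energy <- function(include_overall = FALSE) {
  x <- utils::read.csv(ref_file("sof_training_energy.csv"),
                       stringsAsFactors = FALSE)
  if (!include_overall) x <- x[x$course != "Overall", , drop = FALSE]
  rownames(x) <- NULL
  x
}

#' Reconstruct a standard deviation from a 95% confidence interval
#'
#' Inverts the normal-theory interval: `sd = half_width * sqrt(n) / 1.96`.
#' Used to parameterize the synthetic generator from published tables that
#' report means with 95% CIs only.
#'
#' @param ci_low,ci_high interval bounds.
#' @param n sample size the interval was computed from.
#' @return standard deviation (same units as the bounds).
#' @export
#' @examples
#' sd_from_ci(76.9, 86.2, 11)
sd_from_ci <- function(ci_low, ci_high, n) {
  if (any(ci_high < ci_low)) stop("ci_high must be >= ci_low")
  if (any(n < 2)) stop("n must be >= 2")
  (ci_high - ci_low) / 2 * sqrt(n) / 1.96
}

#' Course specifications parameterized from the published tables
#'
#' Builds [course_spec()] objects for the twelve published training-course
#' phases, with means taken from the published tables and standard deviations
#' reconstructed from the printed 95% CIs via [sd_from_ci()]. Anthropometry
#' sds for the two Small Unit Ranger Training phases use the pooled n = 13
#' interval.
#'
#' @param duration_days nominal course duration used for default isotope
#'   sampling schedules (days).
#' @return A named list of `course_spec` objects (12 courses, total n = 133).
#' @export
training_course_specs <- function(duration_days = 7) {
  an <- sof_training_anthropometry()
  en <- sof_training_energy()
  i <- match(en$anthropometry_course, an$course)
  stopifnot(!anyNA(i))
  specs <- lapply(seq_len(nrow(en)), function(r) {
    a <- an[i[r], ]
    course_spec(
      name      = en$course[r],
      n         = en$n[r],
      bm_mean   = a$bm_mean,
      bm_sd     = sd_from_ci(a$bm_ci_low, a$bm_ci_high, a$n),
      ffm_mean  = a$ffm_mean,
      ffm_sd    = sd_from_ci(a$ffm_ci_low, a$ffm_ci_high, a$n),
      tdee_mean = en$tdee[r],
      tdee_sd   = sd_from_ci(en$tdee_ci_low[r], en$tdee_ci_high[r], en$n[r]),
      intake_mean = if (is.na(en$intake[r])) NULL else en$intake[r],
      intake_sd   = if (is.na(en$intake[r])) NULL else
        sd_from_ci(en$intake_ci_low[r], en$intake_ci_high[r], en$n[r]),
      duration_days = duration_days,
      paf       = en$paf[r]
    )
  })
  names(specs) <- en$course
  specs
}
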