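# Body composition and energy-budget accounting.

HYDRATION_FFM <- 0.73   # water fraction of fat-free tissue
RMR_INTERCEPT <- 370    # kcal/d (Cunningham-type FFM equation)
RMR_SLOPE <- 21.6       # kcal/d per kg FFM
DIT_FRACTION <- 0.10    # diet-induced thermogenesis as fraction of TDEE

#' Fat-free mass from total body water
#'
#' Assumes 73% hydration of fat-free tissue: `FFM = TBW / 0.73`.
#'
#' @param tbw_kg total body water, kg (>= 0). Vectorized.
#' @return fat-free mass, kg.
#' @export
#' @examples
#' ffm_from_tbw(46.574)  # ~63.8 kg
ffm_from_tbw <- function(tbw_kg) {
  if (any(tbw_kg < 0)) stop("tbw_kg must be >= 0")
  tbw_kg / HYDRATION_FFM
}

#' Fat mass from body mass and fat-free mass
#'
#' @param bm body mass, kg.
#' @param ffm fat-free mass, kg; must not exceed `bm`.
#' @return fat mass `bm - ffm`, kg.
#' @export
#' @examples
#' fm_from_bm_ffm(81.6, 63.8)  # 17.8
fm_from_bm_ffm <- function(bm, ffm) {
  if (any(ffm > bm)) stop("ffm must not exceed bm")
  bm - ffm
}

#' Resting metabolic rate from fat-free mass
#'
#' `RMR (kcal/d) = 370 + 21.6 x FFM (kg)`.
#'
#' @param ffm fat-free mass, kg (>= 0). Vectorized.
#' @return kcal/day.
#' @export
#' @examples
#' rmr_from_ffm(63.8)  # ~1748
rmr_from_ffm <- function(ffm) {
  if (any(ffm < 0)) stop("ffm must be >= 0")
  RMR_INTERCEPT + RMR_SLOPE * ffm
}

#' Energy balance
#'
#' `intake - expenditure`: negative values are deficits. (Published course
#' tables print balance on this sign convention.)
#'
#' @param intake daily energy intake, kcal/d (>= 0).
#' @param tdee daily energy expenditure, kcal/d (>= 0).
#' @return kcal/day, positive = surplus.
#' @export
#' @examples
#' energy_balance(2503, 5215)  # -2712 (Urban Combat deficit)
energy_balance <- function(intake, tdee) {
  if (any(intake < 0, na.rm = TRUE) || any(tdee < 0, na.rm = TRUE))
    stop("intake and tdee must be >= 0")
  intake - tdee
}

#' Energy-budget profile from expenditure and fat-free mass
#'
#' Decomposes measured total daily energy expenditure into resting metabolic
#' rate (`rmr_from_ffm`), diet-induced thermogenesis (10% of TDEE) and
#' activity-induced expenditure (`tdee - rmr - dit`), and derives the
#' physical activity level `pal = tdee / rmr`, the activity share
#' `pct_aiee = 100 x aiee / tdee`, and the energy balance when intake is
#' supplied. The decomposition is exact: `rmr + dit + aiee == tdee`.
#'
#' @param tdee measured daily energy expenditure, kcal/d (> 0). Vectorized.
#' @param ffm fat-free mass, kg (> 0).
#' @param intake optional daily energy intake, kcal/d.
#' @return A data.frame with columns `tdee`, `rmr`, `dit`, `aiee`, `pal`,
#'   `pct_aiee` and, when `intake` is given, `balance`.
#' @export
#' @examples
#' energy_profile(tdee = 4264, ffm = 63.1, intake = 2957)
energy_profile <- function(tdee, ffm, intake = NULL) {
  if (any(tdee <= 0)) stop("tdee must be positive")
  if (any(ffm <= 0)) stop("ffm must be positive")
  rmr <- rmr_from_ffm(ffm)
  dit <- DIT_FRACTION * tdee
  aiee <- tdee - rmr - dit
  out <- data.frame(tdee = tdee, rmr = rmr, dit = dit, aiee = aiee,
                    pal = tdee / rmr, pct_aiee = 100 * aiee / tdee)
  if (!is.null(intake)) out$balance <- energy_balance(intake, tdee)
  out
}

#' Per-participant energy profiles
#'
#' Applies [energy_profile()] to a participant table (as produced by
#' [generate_cohort()] or [read_participants()]), keeping ids and courses.
#'
#' @param participants data.frame with `id`, `course`, `ffm_kg`,
#'   `tdee_kcal_d` and optionally `intake_kcal_d`.
#' @return A data.frame `id`, `course` plus the [energy_profile()] columns.
#' @export
participant_profiles <- function(participants) {
  need <- c("id", "course", "ffm_kg", "tdee_kcal_d")
  miss <- setdiff(need, names(participants))
  if (length(miss))
    stop("participants table lacks column(s): ", paste(miss, collapse = ", "))
  intake <- if ("intake_kcal_d" %in% names(participants))
    participants$intake_kcal_d else NULL
  prof <- energy_profile(participants$tdee_kcal_d, participants$ffm_kg,
                         intake)
  cbind(participants[, c("id", "course")], prof)
}

# mean with t-based 95% CI; n = 1 gives NA bounds
mean_ci <- function(x, conf = 0.95) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0) return(c(n = 0, mean = NA_real_, ci_low = NA, ci_high = NA))
  m <- mean(x)
  if (n == 1) return(c(n = 1, mean = m, ci_low = NA, ci_high = NA))
  half <- stats::qt(1 - (1 - conf) / 2, n - 1) * stats::sd(x) / sqrt(n)
  c(n = n, mean = m, ci_low = m - half, ci_high = m + half)
}

#' Course-level summaries: mean and 95% confidence interval
#'
#' t-based mean and 95% CI of each requested quantity, per course and
#' overall. Courses with a single participant report the mean with `NA`
#' interval bounds (flagged by `ci_absent`).
#'
#' @param data data.frame with a `course` column and the quantities.
#' @param vars character vector of column names to summarize (default: all
#'   numeric columns).
#' @param conf confidence level (default 0.95).
#' @return A long-format data.frame `course`, `variable`, `n`, `mean`,
#'   `ci_low`, `ci_high`, `ci_absent`; includes an `"Overall"` row per
#'   variable.
#' @export
#' @examples
#' cohort <- generate_cohort(sim_config(training_course_specs(), seed = 2))
#' head(course_summary(cohort, vars = c("body_mass_kg", "ffm_kg")))
course_summary <- function(data, vars = NULL, conf = 0.95) {
  if (!"course" %in% names(data)) stop("data must have a 'course' column")
  if (is.null(vars))
    vars <- names(data)[vapply(data, is.numeric, TRUE) &
                          names(data) != "course"]
  groups <- c(split(data, data$course), list(Overall = data))
  rows <- lapply(names(groups), function(g) {
    d <- groups[[g]]
    do.call(rbind, lapply(vars, function(v) {
      s <- mean_ci(d[[v]], conf)
      data.frame(course = g, variable = v, n = as.integer(s["n"]),
                 mean = s["mean"], ci_low = s["ci_low"],
                 ci_high = s["ci_high"],
                 ci_absent = is.na(s["ci_low"]),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Round an energy profile for reporting
#'
#' kcal quantities to the nearest integer, PAL to 2 decimals, percentages to
#' 1 decimal; computation elsewhere stays at full precision.
#'
#' @param profiles data.frame from [participant_profiles()] or
#'   [energy_profile()].
#' @return The rounded data.frame.
#' @export
round_profile <- function(profiles) {
  kcal <- intersect(c("tdee", "rmr", "dit", "aiee", "balance"),
                    names(profiles))
  for (v in kcal) profiles[[v]] <- round(profiles[[v]])
  if ("pal" %in% names(profiles)) profiles$pal <- round(profiles$pal, 2)
  if ("pct_aiee" %in% names(profiles))
    profiles$pct_aiee <- round(profiles$pct_aiee, 1)
  profiles
}
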