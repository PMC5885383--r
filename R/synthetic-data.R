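# Synthetic cohort and isotope-series generation.

#' Specify one training course for simulation
#'
#' A course is described by its sample size, the mean and sd of body mass and
#' fat-free mass (kg), of measured daily energy expenditure (kcal/d) and,
#' optionally, of daily energy intake (kcal/d), plus a nominal duration. An
#' optional physical activity factor (`paf`, integer 0-3) is carried so that
#' cohorts can be simulated from a known prediction model
#' (see [generate_cohort()]).
#'
#' @param name course name.
#' @param n number of participants (>= 1).
#' @param bm_mean,bm_sd body mass mean and sd, kg.
#' @param ffm_mean,ffm_sd fat-free mass mean and sd, kg; `ffm_mean` must not
#'   exceed `bm_mean`.
#' @param tdee_mean,tdee_sd measured daily energy expenditure mean and sd,
#'   kcal/d; `tdee_mean` must be positive.
#' @param intake_mean,intake_sd optional daily energy intake mean and sd,
#'   kcal/d.
#' @param duration_days nominal course duration, days.
#' @param paf optional physical activity factor (0-3) for model-based
#'   simulation.
#' @return An object of class `course_spec`.
#' @export
#' @examples
#' course_spec("Combat Dive School", n = 11, bm_mean = 81.6, bm_sd = 7.9,
#'             ffm_mean = 63.8, ffm_sd = 6.0, tdee_mean = 4567, tdee_sd = 398)
course_spec <- function(name, n, bm_mean, bm_sd, ffm_mean, ffm_sd,
                        tdee_mean, tdee_sd,
                        intake_mean = NULL, intake_sd = NULL,
                        duration_days = 7, paf = NULL) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("name must be a non-empty string")
  if (length(n) != 1L || is.na(n) || n < 1 || n != round(n))
    stop("n must be a positive integer (course '", name, "')")
  for (f in c("bm_sd", "ffm_sd", "tdee_sd")) {
    v <- get(f)
    if (length(v) != 1L || is.na(v) || v < 0)
      stop("field '", f, "' must be a non-negative number (course '",
           name, "')")
  }
  if (ffm_mean > bm_mean)
    stop("field 'ffm_mean' must not exceed 'bm_mean' (course '", name, "')")
  if (tdee_mean <= 0)
    stop("field 'tdee_mean' must be positive (course '", name, "')")
  if (!is.null(intake_sd) && intake_sd < 0)
    stop("field 'intake_sd' must be non-negative (course '", name, "')")
  if (!is.null(paf) && (is.na(paf) || paf < 0 || paf > 3 || paf != round(paf)))
    stop("field 'paf' must be an integer in 0..3 (course '", name, "')")
  if (duration_days <= 0)
    stop("field 'duration_days' must be positive (course '", name, "')")
  structure(
    list(name = name, n = as.integer(n),
         bm_mean = bm_mean, bm_sd = bm_sd,
         ffm_mean = ffm_mean, ffm_sd = ffm_sd,
         tdee_mean = tdee_mean, tdee_sd = tdee_sd,
         intake_mean = intake_mean, intake_sd = intake_sd,
         duration_days = duration_days,
         paf = if (is.null(paf)) NULL else as.integer(paf)),
    class = "course_spec")
}

#' Simulation configuration
#'
#' Bundles the course specifications with the random seed and the isotope
#' forward-model settings. With a fixed seed the generators are fully
#' deterministic: identical configs yield identical output, byte for byte.
#'
#' @param courses a `course_spec` or list of them (see [course_spec()],
#'   [training_course_specs()]).
#' @param seed integer seed controlling all randomness.
#' @param isotope_noise_cv coefficient of variation of the assay noise applied
#'   to isotope enrichments (dimensionless fraction, >= 0).
#' @param sampling_times urine sampling times in days, strictly increasing,
#'   first >= 0. Default `NULL` uses `0:duration_days` of each course.
#' @param model_truth optional [prediction_model()]; when supplied, simulated
#'   expenditure is the model applied to each participant plus
#'   `Normal(0, residual_sd)` noise (courses then need a `paf`).
#' @param residual_sd residual sd (kcal/d) around `model_truth`.
#' @param ko_kh_ratio ratio kO/kH used to pin the one free degree of freedom
#'   of the isotope forward model; must exceed 1.04/1.01.
#' @param noise `"relative"` (multiplicative, scales with enrichment excess;
#'   default) or `"additive"` (constant sd `isotope_noise_cv * e0_excess`).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(courses, seed = 1L, isotope_noise_cv = 0,
                       sampling_times = NULL, model_truth = NULL,
                       residual_sd = 0, ko_kh_ratio = 1.25,
                       noise = c("relative", "additive")) {
  noise <- match.arg(noise)
  if (inherits(courses, "course_spec")) courses <- list(courses)
  if (length(courses) && !all(vapply(courses, inherits, TRUE, "course_spec")))
    stop("courses must be course_spec objects")
  if (length(seed) != 1L || is.na(seed)) stop("seed must be a single integer")
  if (isotope_noise_cv < 0) stop("isotope_noise_cv must be >= 0")
  if (!is.null(sampling_times)) {
    if (!length(sampling_times) || sampling_times[1] < 0 ||
        is.unsorted(sampling_times, strictly = TRUE))
      stop("sampling_times must be strictly increasing with first >= 0")
  }
  if (!is.null(model_truth) && !inherits(model_truth, "prediction_model"))
    stop("model_truth must be a prediction_model")
  if (residual_sd < 0) stop("residual_sd must be >= 0")
  if (ko_kh_ratio <= 1.04 / 1.01)
    stop("ko_kh_ratio must exceed 1.04/1.01 for positive CO2 production")
  structure(
    list(courses = courses, seed = as.integer(seed),
         isotope_noise_cv = isotope_noise_cv,
         sampling_times = sampling_times, model_truth = model_truth,
         residual_sd = residual_sd, ko_kh_ratio = ko_kh_ratio,
         noise = noise),
    class = "sim_config")
}

# draw body mass / fat-free mass pairs, rejecting ffm > bm
draw_masses <- function(n, sp) {
  bm <- stats::rnorm(n, sp$bm_mean, sp$bm_sd)
  ffm <- stats::rnorm(n, sp$ffm_mean, sp$ffm_sd)
  for (iter in 1:1000) {
    bad <- which(ffm > bm)
    if (!length(bad)) break
    bm[bad] <- stats::rnorm(length(bad), sp$bm_mean, sp$bm_sd)
    ffm[bad] <- stats::rnorm(length(bad), sp$ffm_mean, sp$ffm_sd)
  }
  ffm <- pmin(ffm, bm)
  list(bm = bm, ffm = ffm)
}

#' Generate a synthetic cohort
#'
#' Draws `n` participants per course with body mass and fat-free mass from
#' truncated normals (pairs with FFM > BM are redrawn), measured expenditure
#' either `Normal(tdee_mean, tdee_sd)` or, when the config carries a
#' `model_truth`, the model prediction plus residual noise, and intake when
#' intake parameters are present. Deterministic given the config seed.
#'
#' @param config a [sim_config()].
#' @return A data.frame with columns `id`, `course`, `body_mass_kg`,
#'   `ffm_kg`, `tdee_kcal_d` and (when any course specifies intake)
#'   `intake_kcal_d`; plus `paf` when courses carry one.
#' @export
#' @examples
#' cfg <- sim_config(training_course_specs(), seed = 7)
#' head(generate_cohort(cfg))
generate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) stop("config must be a sim_config")
  if (!length(config$courses)) stop("config has no courses to generate")
  set.seed(config$seed)
  any_intake <- any(vapply(config$courses,
                           function(s) !is.null(s$intake_mean), TRUE))
  any_paf <- any(vapply(config$courses, function(s) !is.null(s$paf), TRUE))
  if (!is.null(config$model_truth)) {
    missing_paf <- vapply(config$courses, function(s) is.null(s$paf), TRUE)
    if (any(missing_paf))
      stop("model_truth simulation requires a paf for every course; missing ",
           "for: ", paste(vapply(config$courses[missing_paf], `[[`, "", "name"),
                          collapse = ", "))
  }
  out <- lapply(config$courses, function(sp) {
    m <- draw_masses(sp$n, sp)
    if (is.null(config$model_truth)) {
      tdee <- stats::rnorm(sp$n, sp$tdee_mean, sp$tdee_sd)
      for (iter in 1:1000) {
        bad <- which(tdee <= 0)
        if (!length(bad)) break
        tdee[bad] <- stats::rnorm(length(bad), sp$tdee_mean, sp$tdee_sd)
      }
    } else {
      mt <- config$model_truth
      mass <- if (mt$mass_kind == "body_mass") m$bm else m$ffm
      tdee <- predict_energy(mt, mass, rep(sp$paf, sp$n)) +
        stats::rnorm(sp$n, 0, config$residual_sd)
    }
    df <- data.frame(course = sp$name, body_mass_kg = m$bm, ffm_kg = m$ffm,
                     tdee_kcal_d = tdee, stringsAsFactors = FALSE)
    if (any_intake) {
      df$intake_kcal_d <- if (is.null(sp$intake_mean)) NA_real_ else
        stats::rnorm(sp$n, sp$intake_mean, sp$intake_sd)
    }
    if (any_paf) df$paf <- if (is.null(sp$paf)) NA_integer_ else sp$paf
    df
  })
  out <- do.call(rbind, out)
  out <- cbind(id = sprintf("S%03d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# mol of water per kg: 1000 / 18.02
WATER_MOL_PER_KG <- 1000 / 18.02
# net Schoeller coefficient: 1/2.078 - 0.0246 * 1.05 (see compute_rco2)
SCHOELLER_NET <- 1 / 2.078 - 0.0246 * 1.05

#' Generate a pair of synthetic urine isotope series
#'
#' Forward model inverted from the analysis chain: given total body water and
#' a target CO2 production rate, elimination rates (kO, kH) are chosen so the
#' Schoeller equation returns exactly `rco2_mol_d`; the equation constrains
#' only `1.01 kO - 1.04 kH`, so the remaining degree of freedom is pinned by
#' the config's `ko_kh_ratio` (default 1.25, a typical DLW ratio). When
#' `rco2_mol_d` is zero the ratio constraint degenerates and the generator
#' instead keeps a baseline water turnover (`kh = 0.10`/d) with
#' `1.01 kO = 1.04 kH`, giving a flat net signal. Initial enrichments are set
#' by inverting the isotope-dilution total-body-water equation for the given
#' doses, so a noiseless series run through [compute_ee_dlw()] returns the
#' configured truth.
#'
#' @param tbw_kg total body water, kg (> 0).
#' @param rco2_mol_d CO2 production, mol/day (>= 0).
#' @param config a [sim_config()]; supplies sampling times, noise and seed.
#' @param dose_o18,dose_2h [isotope_dose()] objects (defaults:
#'   [default_dose()]).
#' @param baseline pre-dose enrichment added to both series.
#' @param participant_id id stored on the series.
#' @return A list with elements `o18` and `h2`, each a [urine_series()], plus
#'   attributes `ko`, `kh` (the true rates).
#' @export
#' @examples
#' cfg <- sim_config(list(), seed = 1, sampling_times = 0:7)
#' s <- generate_isotope_series(40, 30, cfg)
#' res <- compute_ee_dlw(s$o18, s$h2)
#' res$rco2  # 30, recovered
generate_isotope_series <- function(tbw_kg, rco2_mol_d, config,
                                    dose_o18 = default_dose("18O"),
                                    dose_2h = default_dose("2H"),
                                    baseline = 0, participant_id = "sim") {
  if (tbw_kg <= 0) stop("tbw_kg must be positive")
  if (rco2_mol_d < 0) stop("rco2_mol_d must be >= 0")
  times <- config$sampling_times
  if (is.null(times) || !length(times)) stop("sampling_times must be set")
  set.seed(config$seed)

  n_mol <- tbw_kg * WATER_MOL_PER_KG
  flux <- rco2_mol_d / (n_mol * SCHOELLER_NET)  # = 1.01 kO - 1.04 kH
  if (flux > 0) {
    kh <- flux / (1.01 * config$ko_kh_ratio - 1.04)
    ko <- config$ko_kh_ratio * kh
  } else {
    kh <- 0.10                      # baseline water turnover, /day
    ko <- 1.04 / 1.01 * kh          # flat net signal, rCO2 = 0
  }

  make_series <- function(dose, k) {
    # invert the TBW equation: excess at t = 0 given dose and body water
    e0 <- dose_moles_excess(dose) * 18.02 /
      (dose$r_standard * 1.01 * n_mol)
    decay <- e0 * exp(-k * times)
    cv <- config$isotope_noise_cv
    if (cv > 0) {
      eps <- stats::rnorm(length(times), 0, cv)
      decay <- if (config$noise == "relative") decay * (1 + eps)
               else decay + eps * e0
    }
    urine_series(participant_id, dose$isotope, times, baseline + decay,
                 baseline = baseline)
  }

  out <- list(o18 = make_series(dose_o18, ko), h2 = make_series(dose_2h, kh))
  attr(out, "ko") <- ko
  attr(out, "kh") <- kh
  out
}

#' Read a simulation configuration from a YAML file
#'
#' Keys mirror the arguments of [sim_config()] and [course_spec()]: top level
#' `seed`, `isotope_noise_cv`, `sampling_times`, `residual_sd`,
#' `ko_kh_ratio`, `noise`, and a `courses` list whose entries carry the
#' course_spec fields (`name`, `n`, `bm_mean`, `bm_sd`, `ffm_mean`,
#' `ffm_sd`, `tdee_mean`, `tdee_sd`, optional `intake_mean`, `intake_sd`,
#' `duration_days`, `paf`).
#'
#' @param path YAML file path.
#' @return A [sim_config()].
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$courses)) stop("config file has no 'courses' key")
  courses <- lapply(y$courses, function(cs) {
    # YAML 1.1 resolves a bare `n` key to a boolean; map it back
    names(cs)[names(cs) %in% c("FALSE", "F")] <- "n"
    do.call(course_spec, cs)
  })
  args <- y[setdiff(names(y), "courses")]
  do.call(sim_config, c(list(courses = courses), args))
}

#' Write a synthetic cohort to CSV
#'
#' @param cohort data.frame from [generate_cohort()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
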