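# Reading, writing and the end-to-end pipeline.

#' Read a participant table
#'
#' Expects a comma-separated, header-bearing file with columns `id`,
#' `course`, `body_mass_kg`, and `ffm_kg` and/or `tbw_kg` (fat-free mass is
#' computed as TBW/0.73 where absent); `tdee_kcal_d`, `intake_kcal_d` and
#' `paf` are carried through when present. Row-level problems (non-numeric
#' fields, FFM exceeding body mass) are collected and reported together with
#' their row numbers rather than silently dropped.
#'
#' @param path CSV file path.
#' @return A validated participant data.frame.
#' @export
read_participants <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("id", "course", "body_mass_kg")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  if (!any(c("ffm_kg", "tbw_kg") %in% names(raw)))
    stop("missing required column(s): ffm_kg (or tbw_kg)")

  numcols <- intersect(c("body_mass_kg", "ffm_kg", "tbw_kg", "tdee_kcal_d",
                         "intake_kcal_d", "paf", "delta_bm_kg"),
                       names(raw))
  errors <- character(0)
  out <- raw
  for (v in numcols) {
    x <- suppressWarnings(as.numeric(raw[[v]]))
    bad <- which(is.na(x) & !(is.na(raw[[v]]) | raw[[v]] %in% c("", "NA")))
    if (length(bad))
      errors <- c(errors, sprintf("row %d: non-numeric %s ('%s')",
                                  bad, v, raw[[v]][bad]))
    out[[v]] <- x
  }
  if (!"ffm_kg" %in% names(out)) out$ffm_kg <- NA_real_
  fill <- which(is.na(out$ffm_kg) & !is.na(out$tbw_kg %||% NA))
  if (length(fill)) out$ffm_kg[fill] <- ffm_from_tbw(out$tbw_kg[fill])
  bad_ffm <- which(!is.na(out$ffm_kg) & !is.na(out$body_mass_kg) &
                     out$ffm_kg > out$body_mass_kg)
  if (length(bad_ffm))
    errors <- c(errors,
                sprintf("row %d: ffm_kg (%.2f) exceeds body_mass_kg (%.2f)",
                        bad_ffm, out$ffm_kg[bad_ffm],
                        out$body_mass_kg[bad_ffm]))
  if (length(errors))
    stop("invalid participant file '", path, "':\n  ",
         paste(errors, collapse = "\n  "))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a participant table
#'
#' @param participants participant data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_participants <- function(participants, path) {
  utils::write.csv(participants, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read urine isotope series from CSV
#'
#' Columns `id,isotope,time_d,enrichment`; rows with `time_d < 0` (or an
#' optional logical `baseline` column) define the pre-dose baseline per
#' participant and isotope.
#'
#' @param path CSV file path.
#' @return A nested list: `series[[id]][[isotope]]` is a [urine_series()].
#' @export
read_urine_series <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "isotope", "time_d", "enrichment")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  is_base <- if ("baseline" %in% names(raw)) as.logical(raw$baseline)
             else raw$time_d < 0
  out <- list()
  for (id in unique(raw$id)) {
    out[[id]] <- list()
    for (iso in unique(raw$isotope[raw$id == id])) {
      i <- raw$id == id & raw$isotope == iso
      base <- raw$enrichment[i & is_base]
      base <- if (length(base)) mean(base) else 0
      post <- raw[i & !is_base, , drop = FALSE]
      post <- post[order(post$time_d), , drop = FALSE]
      out[[id]][[iso]] <- urine_series(id, iso, post$time_d,
                                       post$enrichment, baseline = base)
    }
  }
  out
}

#' Write / read prediction-model coefficients
#'
#' Small JSON files with keys `intercept`, `beta_mass`, `beta_paf`,
#' `mass_kind` (and `see`, `r`, `n` when available).
#'
#' @param model a [prediction_model()].
#' @param path file path.
#' @return `write_model`: `path`, invisibly. `read_model`: a
#'   [prediction_model()].
#' @export
write_model <- function(model, path) {
  if (!inherits(model, "prediction_model"))
    stop("model must be a prediction_model")
  jsonlite::write_json(model[!vapply(model, is.null, TRUE)], path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  prediction_model(x$intercept, x$beta_mass, x$beta_paf, x$mass_kind,
                   see = x$see, r = x$r, n = x$n)
}

#' Configure a pipeline run
#'
#' @param participants participant CSV path or data.frame.
#' @param scheme `"default"` (published cutpoints) or `"derived"`
#'   (re-derived from course-mean PAL quartiles).
#' @param model `"A"`, `"B"` (published) or `"fit"` (refit on the input
#'   cohort).
#' @param out_dir output directory (created if needed).
#' @param seed integer seed recorded with the run.
#' @param verbose print stage messages.
#' @return An object of class `run_config`.
#' @export
run_config <- function(participants, scheme = c("default", "derived"),
                       model = c("A", "B", "fit"), out_dir = tempdir(),
                       seed = 1L, verbose = FALSE) {
  scheme <- match.arg(scheme)
  model <- match.arg(model)
  if (is.character(participants) && !file.exists(participants))
    stop("participants file does not exist: ", participants)
  structure(list(participants = participants, scheme = scheme,
                 model = model, out_dir = out_dir,
                 seed = as.integer(seed), verbose = verbose),
            class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage ", name, ": ", conditionMessage(e), call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Reads (or accepts) a participant table, derives per-participant energy
#' profiles and course summaries, assigns physical activity factors from
#' course-mean PALs, predicts expenditure with the selected model, evaluates
#' measured vs predicted, and writes every table plus a log of all constants
#' used (so each emitted number is re-derivable from inputs and log).
#' Deterministic: the same config and seed produce byte-identical outputs.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with `profiles`, `course_summary`,
#'   `paf_assignments`, `predictions`, `evaluation`, `model`, `scheme`,
#'   `constants` and the output `files`.
#' @export
#' @examples
#' cohort <- generate_cohort(sim_config(training_course_specs(), seed = 1))
#' res <- run_pipeline(run_config(cohort, out_dir = tempfile()))
#' res$evaluation
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) stop("config must be a run_config")
  set.seed(config$seed)
  say <- function(...) if (config$verbose) message(...)

  participants <- stage("read", {
    if (is.character(config$participants)) read_participants(config$participants)
    else config$participants
  })
  has_intake <- "intake_kcal_d" %in% names(participants) &&
    any(!is.na(participants$intake_kcal_d))
  if (!has_intake)
    warning("no usable intake column: balance columns omitted")

  say("profiles")
  profiles <- stage("profiles", participant_profiles(participants))
  summary_tab <- stage("summary", course_summary(profiles))

  say("paf")
  paf_tab <- stage("paf", {
    course_pal <- summary_tab[summary_tab$variable == "pal" &
                                summary_tab$course != "Overall", ]
    scheme <- if (config$scheme == "default") default_paf_scheme()
              else derive_paf_scheme(course_pal$mean)
    data.frame(course = course_pal$course, pal = course_pal$mean,
               paf = assign_paf(course_pal$mean, scheme),
               stringsAsFactors = FALSE)
  })
  scheme <- if (config$scheme == "default") default_paf_scheme()
            else derive_paf_scheme(paf_tab$pal)
  paf_by_course <- stats::setNames(paf_tab$paf, paf_tab$course)
  participants$paf <- unname(paf_by_course[participants$course])

  say("model")
  model <- stage("model", switch(config$model,
    A = published_model("A"),
    B = published_model("B"),
    fit = fit_prediction_model(participants, "body_mass")))

  say("predict")
  predictions <- stage("predict", {
    mcol <- if (model$mass_kind == "body_mass") "body_mass_kg" else "ffm_kg"
    data.frame(id = participants$id, course = participants$course,
               paf = participants$paf,
               measured_kcal_d = participants$tdee_kcal_d,
               predicted_kcal_d = predict_energy(
                 model, participants[[mcol]], participants$paf),
               stringsAsFactors = FALSE)
  })
  evaluation <- stage("evaluate",
                      evaluate_model(participants, model))

  constants <- list(
    seed = config$seed,
    rq = 0.86,
    energy_equivalent_kcal_per_mol_co2 = co2_energy_equivalent(0.86),
    hydration_ffm = HYDRATION_FFM,
    rmr_intercept = RMR_INTERCEPT, rmr_slope = RMR_SLOPE,
    dit_fraction = DIT_FRACTION,
    quantile_method = "linear interpolation (type 7)",
    scheme_source = config$scheme,
    paf_cutpoints = scheme$cutpoints,
    model_source = config$model,
    model = list(intercept = model$intercept, beta_mass = model$beta_mass,
                 beta_paf = model$beta_paf, mass_kind = model$mass_kind))

  say("write")
  files <- stage("write", {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(config$out_dir, f)
    if (!has_intake) profiles$balance <- NULL
    utils::write.csv(profiles, p("profiles.csv"), row.names = FALSE,
                     quote = FALSE)
    utils::write.csv(summary_tab, p("course_summary.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(paf_tab, p("paf_assignments.csv"), row.names = FALSE,
                     quote = FALSE)
    utils::write.csv(predictions, p("predictions.csv"), row.names = FALSE,
                     quote = FALSE)
    utils::write.csv(evaluation$by_course, p("evaluation_by_course.csv"),
                     row.names = FALSE, quote = FALSE)
    jsonlite::write_json(constants, p("constants.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    vapply(c("profiles.csv", "course_summary.csv", "paf_assignments.csv",
             "predictions.csv", "evaluation_by_course.csv",
             "constants.json"), p, "")
  })

  invisible(list(profiles = profiles, course_summary = summary_tab,
                 paf_assignments = paf_tab, predictions = predictions,
                 evaluation = evaluation, model = model, scheme = scheme,
                 constants = constants, files = files))
}
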