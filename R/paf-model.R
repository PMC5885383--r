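# Physical activity factors and the linear energy-requirement models.

#' Physical activity factor scheme
#'
#' Three ascending physical-activity-level (PAL) cutpoints partition courses
#' into four factors 0-3. Bands are upper-inclusive: a PAL exactly at a
#' cutpoint falls in the lower band, which reproduces every published course
#' assignment under the default scheme.
#'
#' @param cutpoints three strictly increasing PAL thresholds. Defaults to
#'   the published scheme (2.10, 2.40, 2.75).
#' @param labels four descriptive names for factors 0-3.
#' @return An object of class `paf_scheme`.
#' @export
#' @examples
#' paf_scheme()
paf_scheme <- function(cutpoints = c(2.10, 2.40, 2.75),
                       labels = c("low (mission prep)",
                                  "low-moderate (common warrior tasks)",
                                  "moderate-high (battle drills)",
                                  "high (specialized intense activity)")) {
  if (length(cutpoints) != 3 || is.unsorted(cutpoints, strictly = TRUE))
    stop("cutpoints must be three strictly increasing values")
  if (length(labels) != 4) stop("exactly 4 category labels are required")
  structure(list(cutpoints = as.numeric(cutpoints),
                 labels = as.character(labels)),
            class = "paf_scheme")
}

#' The published PAF scheme
#'
#' Cutpoints 2.10 / 2.40 / 2.75, frozen from the source study so downstream
#' results never depend on the quantile estimator used to re-derive them.
#'
#' @return A [paf_scheme()].
#' @export
default_paf_scheme <- function() paf_scheme()

#' @export
print.paf_scheme <- function(x, ...) {
  cat("PAF scheme (PAL cutpoints):\n")
  bounds <- c("-Inf", format(x$cutpoints), "Inf")
  for (i in 1:4)
    cat(sprintf("  %d  %-38s (%s, %s]\n", i - 1, x$labels[i],
                bounds[i], bounds[i + 1]))
  invisible(x)
}

#' Derive a PAF scheme from observed PALs
#'
#' Cutpoints are the 25th/50th/75th percentiles of the supplied PAL values
#' (linear-interpolation quantiles, `stats::quantile` type 7).
#'
#' @param pals numeric PAL values, at least 4 distinct.
#' @param labels passed to [paf_scheme()].
#' @return A [paf_scheme()].
#' @export
#' @examples
#' derive_paf_scheme(c(1, 2, 3, 4))$cutpoints  # 1.75 2.50 3.25
derive_paf_scheme <- function(pals, labels = paf_scheme()$labels) {
  pals <- pals[!is.na(pals)]
  if (length(unique(pals)) < 4)
    stop("degenerate scheme: need at least 4 distinct PAL values")
  q <- unname(stats::quantile(pals, c(0.25, 0.50, 0.75), type = 7))
  if (any(diff(q) <= 0))
    stop("degenerate scheme: quartile cutpoints are not strictly increasing")
  paf_scheme(q, labels)
}

#' Assign physical activity factors
#'
#' @param pal PAL value(s), > 0.
#' @param scheme a [paf_scheme()] (default: the published scheme).
#' @return integer factor(s) 0-3; `pal <= c1` gives 0, `c1 < pal <= c2`
#'   gives 1, `c2 < pal <= c3` gives 2, else 3.
#' @export
#' @examples
#' assign_paf(c(1.97, 2.31, 2.61, 3.05))  # 0 1 2 3
assign_paf <- function(pal, scheme = default_paf_scheme()) {
  if (!inherits(scheme, "paf_scheme")) stop("scheme must be a paf_scheme")
  if (any(pal <= 0, na.rm = TRUE)) stop("pal must be positive")
  vapply(pal, function(p) {
    if (is.na(p)) NA_integer_ else sum(p > scheme$cutpoints)
  }, integer(1))
}

#' Linear energy-requirement prediction model
#'
#' `tdee = intercept + beta_mass x mass + beta_paf x PAF`, where mass is
#' either total body mass or fat-free mass depending on `mass_kind`.
#'
#' @param intercept kcal/d.
#' @param beta_mass kcal/d per kg.
#' @param beta_paf kcal/d per PAF unit.
#' @param mass_kind `"body_mass"` or `"ffm"`.
#' @param see optional standard error of the estimate, kcal/d.
#' @param r optional Pearson correlation of predicted vs measured.
#' @param n optional fitting sample size.
#' @return An object of class `prediction_model`.
#' @export
prediction_model <- function(intercept, beta_mass, beta_paf,
                             mass_kind = c("body_mass", "ffm"),
                             see = NULL, r = NULL, n = NULL) {
  mass_kind <- match.arg(mass_kind)
  for (v in c("intercept", "beta_mass", "beta_paf"))
    if (!is.numeric(get(v)) || length(get(v)) != 1L || !is.finite(get(v)))
      stop("'", v, "' must be a single finite number")
  structure(list(intercept = intercept, beta_mass = beta_mass,
                 beta_paf = beta_paf, mass_kind = mass_kind,
                 see = see, r = r, n = n),
            class = "prediction_model")
}

#' @export
print.prediction_model <- function(x, ...) {
  mass <- if (x$mass_kind == "body_mass") "BM" else "FFM"
  cat(sprintf("tdee (kcal/d) = %.2f + %.2f x %s (kg) + %.2f x PAF\n",
              x$intercept, x$beta_mass, mass, x$beta_paf))
  if (!is.null(x$see)) cat(sprintf("  SEE %.0f kcal/d", x$see))
  if (!is.null(x$r)) cat(sprintf("  r %.2f", x$r))
  if (!is.null(x$see) || !is.null(x$r)) cat("\n")
  invisible(x)
}

#' Published prediction models
#'
#' Model A: `47.97 x BM + 706.33 x PAF - 467.22` (SEE 642 kcal/d, r 0.74).
#' Model B: `61.99 x FFM + 716.49 x PAF - 721.30` (SEE 626 kcal/d, r 0.76).
#' Both fitted on n = 133 participants across 12 SOF training courses.
#'
#' @param which `"A"` (body mass) or `"B"` (fat-free mass).
#' @return A [prediction_model()].
#' @export
#' @examples
#' published_model("A")
published_model <- function(which = c("A", "B")) {
  which <- match.arg(which)
  if (which == "A")
    prediction_model(-467.22, 47.97, 706.33, "body_mass",
                     see = 642, r = 0.74, n = 133)
  else
    prediction_model(-721.30, 61.99, 716.49, "ffm",
                     see = 626, r = 0.76, n = 133)
}

#' Predict daily energy expenditure
#'
#' @param model a [prediction_model()].
#' @param mass body mass or fat-free mass (kg, matching `model$mass_kind`),
#'   > 0. Vectorized with `paf`.
#' @param paf physical activity factor; values outside 0-3 warn but are
#'   still computed.
#' @return kcal/day at full precision (round for reports).
#' @export
#' @examples
#' predict_energy(published_model("A"), 80.8, 3)  # ~5528
predict_energy <- function(model, mass, paf) {
  if (!inherits(model, "prediction_model"))
    stop("model must be a prediction_model")
  if (any(mass <= 0, na.rm = TRUE)) stop("mass must be positive")
  if (any(paf < 0 | paf > 3, na.rm = TRUE))
    warning("paf outside 0..3; prediction computed anyway")
  model$intercept + model$beta_mass * mass + model$beta_paf * paf
}

#' @rdname predict_energy
#' @param bm body mass, kg.
#' @export
predict_model_a <- function(bm, paf) predict_energy(published_model("A"), bm, paf)

#' @rdname predict_energy
#' @param ffm fat-free mass, kg.
#' @export
predict_model_b <- function(ffm, paf) predict_energy(published_model("B"), ffm, paf)

mass_column <- function(mass_kind) {
  if (mass_kind == "body_mass") "body_mass_kg" else "ffm_kg"
}

#' Fit an energy-requirement model on a cohort
#'
#' Ordinary least squares of measured expenditure on mass (body mass or
#' fat-free mass) and the numeric PAF covariate. The standard error of the
#' estimate is `sqrt(RSS / (n - 3))` and `r` the Pearson correlation between
#' fitted and measured expenditure.
#'
#' @param participants data.frame with `tdee_kcal_d` and the mass column
#'   (`body_mass_kg` or `ffm_kg`).
#' @param mass_kind `"body_mass"` or `"ffm"`.
#' @param paf numeric PAF per participant; defaults to a `paf` column of
#'   `participants`.
#' @return A [prediction_model()] with `see`, `r` and `n` filled in.
#' @export
#' @examples
#' cfg <- sim_config(training_course_specs(), seed = 3,
#'                   model_truth = published_model("A"), residual_sd = 640)
#' fit_prediction_model(generate_cohort(cfg), "body_mass")
fit_prediction_model <- function(participants,
                                 mass_kind = c("body_mass", "ffm"),
                                 paf = participants$paf) {
  mass_kind <- match.arg(mass_kind)
  mcol <- mass_column(mass_kind)
  if (!all(c("tdee_kcal_d", mcol) %in% names(participants)))
    stop("participants must have columns tdee_kcal_d and ", mcol)
  if (is.null(paf)) stop("paf values are required (column or argument)")
  y <- participants$tdee_kcal_d
  mass <- participants[[mcol]]
  n <- length(y)
  if (n < 4) stop("need at least 4 participants to fit")
  if (length(unique(mass)) < 2 || length(unique(paf)) < 2)
    stop("singular design: both predictors must vary")
  fit <- stats::lm(y ~ mass + paf)
  if (fit$rank < 3 || anyNA(stats::coef(fit)))
    stop("singular design: collinear predictors")
  b <- stats::coef(fit)
  see <- sqrt(sum(stats::resid(fit)^2) / (n - 3))
  prediction_model(unname(b[1]), unname(b["mass"]), unname(b["paf"]),
                   mass_kind, see = see,
                   r = stats::cor(stats::fitted(fit), y), n = n)
}

#' Compare measured and model-predicted expenditure
#'
#' Per-participant predictions from a [prediction_model()] are compared with
#' measured expenditure: overall and per-course means with 95% CIs, a
#' two-sided one-sample t-test of the within-course prediction error
#' (predicted - measured) with Bonferroni adjustment over the courses
#' tested, an omnibus F-test of error differences across courses, Pearson
#' r and r-squared, and the standard error of the estimate
#' `sqrt(RSS / (n - 3))`. Courses with a single participant are excluded
#' from testing with a warning. The per-course construction is a pragmatic
#' reading of a measured-vs-predicted ANOVA and is flagged approximate.
#'
#' @param participants data.frame with `course`, `tdee_kcal_d` and the mass
#'   column required by the model.
#' @param model a [prediction_model()].
#' @param paf numeric PAF per participant (default: `paf` column).
#' @return A list of class `model_evaluation`: `by_course` (n, measured and
#'   predicted means with CIs, mean difference, p, p_bonferroni), `overall`,
#'   `r`, `r_squared`, `see`, `omnibus_p`, `m_tests`.
#' @export
evaluate_model <- function(participants, model, paf = participants$paf) {
  mcol <- mass_column(model$mass_kind)
  if (!all(c("course", "tdee_kcal_d", mcol) %in% names(participants)))
    stop("participants must have columns course, tdee_kcal_d and ", mcol)
  if (is.null(paf)) stop("paf values are required (column or argument)")
  measured <- participants$tdee_kcal_d
  predicted <- predict_energy(model, participants[[mcol]], paf)
  err <- predicted - measured
  n <- length(measured)

  counts <- table(participants$course)
  singletons <- names(counts)[counts < 2]
  if (length(singletons))
    warning("course(s) with n = 1 excluded from testing: ",
            paste(singletons, collapse = ", "))
  testable <- names(counts)[counts >= 2]
  m <- length(testable)

  by_course <- do.call(rbind, lapply(names(counts), function(g) {
    i <- participants$course == g
    meas <- mean_ci(measured[i])
    pred <- mean_ci(predicted[i])
    p <- if (g %in% testable && stats::sd(err[i]) > 0)
      stats::t.test(err[i])$p.value
    else if (g %in% testable && mean(err[i]) == 0) 1 else NA_real_
    data.frame(course = g, n = as.integer(sum(i)),
               measured = meas["mean"], measured_ci_low = meas["ci_low"],
               measured_ci_high = meas["ci_high"],
               predicted = pred["mean"], predicted_ci_low = pred["ci_low"],
               predicted_ci_high = pred["ci_high"],
               mean_diff = mean(err[i]), p = p,
               p_bonferroni = if (is.na(p)) NA_real_ else min(1, m * p),
               stringsAsFactors = FALSE)
  }))
  rownames(by_course) <- NULL

  omnibus_p <- if (m >= 2) {
    sub <- participants$course %in% testable
    stats::anova(stats::lm(err[sub] ~ factor(participants$course[sub])))[[
      "Pr(>F)"]][1]
  } else NA_real_

  meas_all <- mean_ci(measured)
  pred_all <- mean_ci(predicted)
  overall <- data.frame(
    measured = meas_all["mean"], measured_ci_low = meas_all["ci_low"],
    measured_ci_high = meas_all["ci_high"],
    predicted = pred_all["mean"], predicted_ci_low = pred_all["ci_low"],
    predicted_ci_high = pred_all["ci_high"],
    mean_diff = mean(err))
  rownames(overall) <- NULL

  r <- if (stats::sd(predicted) == 0 || stats::sd(measured) == 0) {
    if (all(err == 0)) 1 else NA_real_
  } else stats::cor(predicted, measured)
  structure(
    list(by_course = by_course, overall = overall,
         r = r, r_squared = r^2,
         see = sqrt(sum(err^2) / (n - 3)),
         omnibus_p = omnibus_p, m_tests = m),
    class = "model_evaluation")
}

#' @export
print.model_evaluation <- function(x, ...) {
  cat(sprintf(
    "Model evaluation: r = %.3f (r2 = %.3f), SEE = %.0f kcal/d\n",
    x$r, x$r_squared, x$see))
  cat(sprintf("Overall measured %.0f vs predicted %.0f kcal/d\n",
              x$overall$measured, x$overall$predicted))
  flagged <- x$by_course$course[!is.na(x$by_course$p_bonferroni) &
                                  x$by_course$p_bonferroni < 0.05]
  if (length(flagged))
    cat("Courses with measured != predicted (Bonferroni p < 0.05):",
        paste(flagged, collapse = ", "), "\n")
  else cat("No course differs after Bonferroni correction.\n")
  invisible(x)
}
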