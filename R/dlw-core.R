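# Doubly-labeled-water computations: isotope dilution, elimination kinetics,
# CO2 production, energy expenditure.

# heavy/light isotope ratios of Vienna Standard Mean Ocean Water
R_VSMOW <- c("18O" = 2005.20e-6, "2H" = 155.76e-6)

#' Describe an isotope dose
#'
#' @param grams dose mass `A`, grams (> 0).
#' @param mw_dose molecular weight of the dose water, g/mol (18-22).
#' @param ape_percent atom percent excess of the dose water, % (0-100].
#' @param isotope `"18O"` or `"2H"`.
#' @param r_standard heavy/light isotope ratio of the standard
#'   (default: VSMOW ratio for the isotope). Enrichments passed to
#'   [compute_tbw()] must be on a scale consistent with this ratio; the
#'   package is agnostic to the particular delta convention.
#' @return An object of class `isotope_dose`.
#' @export
#' @examples
#' isotope_dose(150, 18.22, 10, "18O")
isotope_dose <- function(grams, mw_dose, ape_percent,
                         isotope = c("18O", "2H"), r_standard = NULL) {
  isotope <- match.arg(isotope)
  if (grams <= 0) stop("dose grams must be positive")
  if (mw_dose < 18 || mw_dose > 22)
    stop("mw_dose must lie in [18, 22] g/mol")
  if (ape_percent <= 0 || ape_percent > 100)
    stop("ape_percent must lie in (0, 100]")
  if (is.null(r_standard)) r_standard <- unname(R_VSMOW[isotope])
  if (r_standard <= 0) stop("r_standard must be positive")
  structure(list(grams = grams, mw_dose = mw_dose,
                 ape_percent = ape_percent, isotope = isotope,
                 r_standard = r_standard),
            class = "isotope_dose")
}

#' Default isotope doses used by the synthetic generator
#'
#' 150 g of 10 atom-percent-excess H2(18)O (MW 18.22 g/mol) and 12 g of
#' 99.9% D2O (MW 20.03 g/mol), referenced to VSMOW.
#'
#' @param isotope `"18O"` or `"2H"`.
#' @return An [isotope_dose()].
#' @export
default_dose <- function(isotope = c("18O", "2H")) {
  isotope <- match.arg(isotope)
  if (isotope == "18O") isotope_dose(150, 18.22, 10, "18O")
  else isotope_dose(12, 20.03, 99.9, "2H")
}

# moles of excess heavy-isotope label delivered by the dose
dose_moles_excess <- function(dose) {
  dose$grams / dose$mw_dose * dose$ape_percent / 100
}

#' Time-stamped urine enrichment series for one isotope
#'
#' @param participant_id id string.
#' @param isotope `"18O"` or `"2H"`.
#' @param time_d sampling times, days, strictly increasing.
#' @param enrichment enrichments at `time_d`, same (arbitrary but internally
#'   consistent) units as the pre-dose `baseline`; must be finite.
#' @param baseline pre-dose enrichment.
#' @return An object of class `urine_series`.
#' @export
urine_series <- function(participant_id, isotope = c("18O", "2H"),
                         time_d, enrichment, baseline = 0) {
  isotope <- match.arg(isotope)
  if (length(time_d) != length(enrichment))
    stop("time_d and enrichment must have the same length")
  if (is.unsorted(time_d, strictly = TRUE))
    stop("time_d must be strictly increasing")
  if (!all(is.finite(enrichment)))
    stop("enrichments must be finite")
  if (!is.finite(baseline)) stop("baseline must be finite")
  structure(list(participant_id = participant_id, isotope = isotope,
                 time_d = as.numeric(time_d),
                 enrichment = as.numeric(enrichment),
                 baseline = baseline),
            class = "urine_series")
}

#' Total body water by isotope dilution
#'
#' Implements the two-sample dilution equation
#' `TBW = (A/MW_d)(APE_d/100) x 18.02 x [1/(R_std (E_s - E_p))] x (1/corr)`,
#' where `A` is the dose in grams, `MW_d` and `APE_d` the molecular weight
#' and atom percent excess of the dose water, `R_std` the heavy/light ratio
#' of the standard, and `E_s`, `E_p` the post- and pre-dose enrichments. The
#' divisor `corr` is the dilution-space correction: 1.01 by default (the
#' (18)O dilution space); `deuterium_space = TRUE` uses 1.04 for a (2)H dose.
#' The result is returned in moles with an explicit kg conversion
#' (x 18.02/1000).
#'
#' @param dose an [isotope_dose()].
#' @param e_final post-dose enrichment `E_s` (typically the value at the
#'   dilution plateau or the back-extrapolated zero-time intercept).
#' @param e_predose pre-dose enrichment `E_p`, same units.
#' @param deuterium_space use the 1.04 deuterium dilution-space correction
#'   when `dose$isotope == "2H"` (default `FALSE`: the 1.01 divisor of the
#'   printed equation is applied for either isotope).
#' @return A list with `tbw_mol` and `tbw_kg`.
#' @export
#' @examples
#' d <- default_dose("18O")
#' compute_tbw(d, e_final = 1.5e-3, e_predose = 2e-4)
compute_tbw <- function(dose, e_final, e_predose, deuterium_space = FALSE) {
  if (!inherits(dose, "isotope_dose")) stop("dose must be an isotope_dose")
  grad <- e_final - e_predose
  if (grad == 0)
    stop("dilution undefined: post-dose enrichment equals pre-dose baseline")
  corr <- if (deuterium_space && dose$isotope == "2H") 1.04 else 1.01
  tbw_mol <- dose_moles_excess(dose) * 18.02 /
    (dose$r_standard * grad) / corr
  if (tbw_mol <= 0)
    stop("inconsistent enrichments: computed body water is not positive ",
         "(post-dose enrichment below baseline?)")
  list(tbw_mol = tbw_mol, tbw_kg = tbw_mol * 18.02 / 1000)
}

#' Fit an isotope elimination rate
#'
#' Least-squares fit of `ln(enrichment - baseline)` against time; the
#' elimination rate `k` is the negative slope. Samples at or below the
#' baseline carry no usable excess and are dropped with a warning; at least
#' two usable samples are required.
#'
#' @param series a [urine_series()].
#' @return A list with `k` (per day), `e0_excess` (back-extrapolated excess
#'   enrichment at t = 0, i.e. `exp(intercept)`), `n_used`, and `dropped`
#'   (indices of excluded samples).
#' @export
#' @examples
#' s <- urine_series("p1", "18O", 0:10, 100 * exp(-0.1 * 0:10))
#' fit_elimination_rate(s)$k  # 0.1
fit_elimination_rate <- function(series) {
  if (!inherits(series, "urine_series")) stop("series must be a urine_series")
  excess <- series$enrichment - series$baseline
  usable <- which(excess > 0)
  dropped <- setdiff(seq_along(excess), usable)
  if (length(dropped))
    warning("dropped ", length(dropped),
            " sample(s) at or below baseline for participant ",
            series$participant_id, " (", series$isotope, ")")
  if (length(usable) < 2)
    stop("fewer than 2 usable post-dose samples for participant ",
         series$participant_id, " (", series$isotope, ")")
  t <- series$time_d[usable]
  y <- log(excess[usable])
  fit <- stats::lm(y ~ t)
  b <- stats::coef(fit)
  list(k = -unname(b[2]), e0_excess = exp(unname(b[1])),
       n_used = length(usable), dropped = dropped)
}

#' CO2 production from body water and elimination rates
#'
#' Schoeller two-pool equation:
#' `rCO2 = (N/2.078)(1.01 kO - 1.04 kH) - 0.0246 rH2Of`, with fractionated
#' evaporative water loss `rH2Of = 1.05 N (1.01 kO - 1.04 kH)`. `N` is total
#' body water in moles; rates are per day. A negative production (when
#' `1.01 kO < 1.04 kH`) is returned as-is and flagged, never clipped.
#'
#' @param n_mol total body water, moles (> 0).
#' @param ko,kh (18)O and (2)H elimination rates, per day (>= 0).
#' @return A list with `rco2_mol_d`, `rh2of_mol_d` and logical `negative`.
#' @export
#' @examples
#' compute_rco2(2220, 0.12, 0.09)$rco2_mol_d  # ~27.9 mol/day
compute_rco2 <- function(n_mol, ko, kh) {
  if (any(n_mol <= 0)) stop("n_mol must be positive")
  if (any(ko < 0) || any(kh < 0)) stop("elimination rates must be >= 0")
  flux <- 1.01 * ko - 1.04 * kh
  rh2of <- 1.05 * n_mol * flux
  rco2 <- n_mol / 2.078 * flux - 0.0246 * rh2of
  neg <- rco2 < 0
  if (any(neg))
    warning("negative CO2 production (1.01 kO < 1.04 kH); flagged, not clipped")
  list(rco2_mol_d = rco2, rh2of_mol_d = rh2of, negative = neg)
}

#' Energy equivalent of CO2 at a given respiratory quotient
#'
#' Weir-derived constant: `(1.106 + 3.941/RQ)` kcal per liter of CO2 times
#' the molar volume of an ideal gas (22.414 L/mol), giving kcal per mole of
#' CO2 produced. At the food quotient 0.86 this is ~127.5 kcal/mol.
#'
#' @param rq respiratory quotient, within the physiologic range (0.7-1.0).
#' @param molar_volume L/mol (default 22.414).
#' @return kcal per mole CO2.
#' @export
co2_energy_equivalent <- function(rq = 0.86, molar_volume = 22.414) {
  if (any(rq < 0.7 | rq > 1.0))
    stop("rq must lie in the physiologic range [0.7, 1.0]")
  molar_volume * (1.106 + 3.941 / rq)
}

#' Energy expenditure from CO2 production
#'
#' @param rco2 CO2 production, mol/day (>= 0).
#' @param rq respiratory quotient (default 0.86, the average food quotient).
#' @param molar_volume L/mol (default 22.414).
#' @return kcal/day.
#' @export
#' @examples
#' energy_from_rco2(35)  # 35 mol/d at RQ 0.86
energy_from_rco2 <- function(rco2, rq = 0.86, molar_volume = 22.414) {
  if (any(rco2 < 0)) stop("rco2 must be >= 0")
  rco2 * co2_energy_equivalent(rq, molar_volume)
}

#' Full DLW computation for one participant
#'
#' Chains the components: elimination rates for both isotopes by log-linear
#' regression, total body water from the (18)O dilution using the
#' back-extrapolated zero-time enrichment (or the first post-dose sample),
#' CO2 production by the Schoeller equation, and energy expenditure at the
#' given respiratory quotient. All intermediates are retained.
#'
#' @param series_o18,series_2h [urine_series()] for (18)O and (2)H.
#' @param dose_o18,dose_2h matching [isotope_dose()] objects.
#' @param rq respiratory quotient (default 0.86).
#' @param tbw_from isotope used for body water: `"18O"` (default) or `"2H"`.
#' @param post_dose `"intercept"` (default; zero-time intercept of the
#'   log-linear fit) or `"first"` (first post-dose sample) as the dilution
#'   enrichment `E_s`.
#' @return An object of class `dlw_result`: `participant_id`, `tbw_mol`,
#'   `tbw_kg`, `ko`, `kh`, `rh2of`, `rco2`, `rq`, `tdee` (kcal/d; `NA` with a
#'   warning when production is negative), and a `provenance` list of fit
#'   details.
#' @export
compute_ee_dlw <- function(series_o18, series_2h,
                           dose_o18 = default_dose("18O"),
                           dose_2h = default_dose("2H"),
                           rq = 0.86, tbw_from = c("18O", "2H"),
                           post_dose = c("intercept", "first")) {
  tbw_from <- match.arg(tbw_from)
  post_dose <- match.arg(post_dose)
  if (!inherits(series_o18, "urine_series") ||
      series_o18$isotope != "18O")
    stop("missing or mislabeled 18O series")
  if (!inherits(series_2h, "urine_series") ||
      series_2h$isotope != "2H")
    stop("missing or mislabeled 2H series")

  fit_o <- fit_elimination_rate(series_o18)
  fit_h <- fit_elimination_rate(series_2h)

  dil <- if (tbw_from == "18O") list(s = series_o18, f = fit_o, d = dose_o18)
         else list(s = series_2h, f = fit_h, d = dose_2h)
  e_s <- if (post_dose == "intercept") dil$s$baseline + dil$f$e0_excess
         else dil$s$enrichment[1]
  tbw <- compute_tbw(dil$d, e_s, dil$s$baseline)

  prod <- suppressWarnings(compute_rco2(tbw$tbw_mol, fit_o$k, fit_h$k))
  tdee <- if (prod$negative) {
    warning("negative CO2 production for participant ",
            series_o18$participant_id, "; tdee set to NA")
    NA_real_
  } else energy_from_rco2(prod$rco2_mol_d, rq)

  structure(
    list(participant_id = series_o18$participant_id,
         tbw_mol = tbw$tbw_mol, tbw_kg = tbw$tbw_kg,
         ko = fit_o$k, kh = fit_h$k,
         rh2of = prod$rh2of_mol_d, rco2 = prod$rco2_mol_d,
         rq = rq, tdee = tdee,
         provenance = list(fit_o18 = fit_o, fit_2h = fit_h,
                           e_s = e_s, tbw_from = tbw_from,
                           post_dose = post_dose,
                           energy_equivalent = co2_energy_equivalent(rq))),
    class = "dlw_result")
}

#' @export
print.dlw_result <- function(x, ...) {
  cat("DLW result for", x$participant_id, "\n")
  cat(sprintf("  TBW  : %.1f mol (%.2f kg)\n", x$tbw_mol, x$tbw_kg))
  cat(sprintf("  kO   : %.4f /d   kH: %.4f /d\n", x$ko, x$kh))
  cat(sprintf("  rCO2 : %.2f mol/d (rH2Of %.1f mol/d)\n", x$rco2, x$rh2of))
  cat(sprintf("  TDEE : %.0f kcal/d at RQ %.2f\n", x$tdee, x$rq))
  invisible(x)
}
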