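#' Henderson-Hasselbalch pH of a bicarbonate/CO2-buffered medium
#'
#' Predicts the equilibrium pH of an open bicarbonate buffer system from the
#' bicarbonate concentration and the CO2 gas fraction,
#' `pH = pKa + log10(HCO3- / (s * pCO2))`, with dissolved CO2 computed from
#' Henry's law at the stated barometric pressure after subtracting water
#' vapour. Default physical constants are 37 degC values: pKa 6.1, CO2
#' solubility 0.0307 mM/mmHg, barometric pressure 760 mmHg, vapour pressure
#' 47 mmHg.
#'
#' @param hco3_mM Bicarbonate concentration (mM), > 0. Vectorised.
#' @param co2_pct CO2 gas fraction (percent), > 0.
#' @param pka Apparent pKa of the CO2/HCO3- system.
#' @param solubility CO2 solubility (mM per mmHg).
#' @param barometric Barometric pressure (mmHg).
#' @param vapor Water vapour pressure (mmHg).
#' @return Predicted pH (numeric, same length as `hco3_mM`).
#' @examples
#' hh_ph(22, 5)    # standard medium equilibrated at 5% CO2 -> 7.40
#' hh_ph(c(2.75, 5.5, 11, 22, 33, 44), 5)
#' @export
hh_ph <- function(hco3_mM, co2_pct, pka = 6.1, solubility = 0.0307,
                  barometric = 760, vapor = 47) {
  if (any(hco3_mM <= 0)) abort("`hco3_mM` must be positive.")
  if (any(co2_pct <= 0)) abort("`co2_pct` must be positive.")
  dco2 <- solubility * co2_pct / 100 * (barometric - vapor)
  pka + log10(hco3_mM / dco2)
}

#' Bicarbonate concentration required for a target pH
#'
#' Exact algebraic inverse of [hh_ph()]: the bicarbonate concentration (mM)
#' that equilibrates to `target_ph` at the stated CO2 fraction, so that
#' `hh_ph(hh_hco3(p, co2), co2) == p` to machine precision.
#'
#' @param target_ph Target medium pH, in `[5.5, 8.5]`.
#' @inheritParams hh_ph
#' @return Bicarbonate concentration in mM.
#' @examples
#' hh_hco3(7.4, 5)  # ~22 mM
#' @export
hh_hco3 <- function(target_ph, co2_pct, pka = 6.1, solubility = 0.0307,
                    barometric = 760, vapor = 47) {
  if (any(target_ph < 5.5 | target_ph > 8.5)) {
    abort("`target_ph` must lie in [5.5, 8.5].")
  }
  dco2 <- solubility * co2_pct / 100 * (barometric - vapor)
  dco2 * 10^(target_ph - pka)
}

#' Iso-osmolar bicarbonate/NaCl media series
#'
#' Designs an iso-osmolar series of media in which pH is set by replacing
#' NaHCO3 with NaCl at a fixed total of 44 mM monovalent sodium salt
#' (the mixing strategy behind a 2.75-44 mM bicarbonate titration at 5% CO2).
#' Each medium gets the Henderson-Hasselbalch predicted pH and, optionally,
#' a user-supplied empirical pH correction (e.g. the offset measured by
#' phenol-red photometry in serum-containing medium); the ideal prediction is
#' always reported alongside.
#'
#' @param hco3_mM Vector of bicarbonate concentrations (mM), each in (0, 44].
#' @param co2_pct CO2 gas fraction (percent).
#' @param hepes_mM,mes_mM Supplementary buffer concentrations (mM) used for
#'   the reported buffering capacity.
#' @param empirical_offset Optional additive correction (pH units) applied to
#'   the ideal prediction to give `ph_empirical`; scalar or one per medium.
#' @inheritParams hh_ph
#' @return A tibble with columns `hco3_mM`, `nacl_mM`, `co2_pct`,
#'   `ph_predicted`, `ph_empirical`, `buffering_mM_per_pH`.
#' @examples
#' bicarb_series(c(2.75, 5.5, 11, 22, 33, 44))
#' @export
bicarb_series <- function(hco3_mM, co2_pct = 5, hepes_mM = 0, mes_mM = 0,
                          empirical_offset = 0, pka = 6.1, solubility = 0.0307,
                          barometric = 760, vapor = 47) {
  if (any(hco3_mM <= 0)) {
    abort("`hco3_mM` must be positive: pH is undefined without bicarbonate in the open CO2 system.")
  }
  if (any(hco3_mM > 44)) abort("`hco3_mM` must not exceed 44 mM (iso-osmolar ceiling).")
  ph <- hh_ph(hco3_mM, co2_pct, pka, solubility, barometric, vapor)
  tibble::tibble(
    hco3_mM = hco3_mM,
    nacl_mM = 44 - hco3_mM,
    co2_pct = co2_pct,
    ph_predicted = ph,
    ph_empirical = ph + empirical_offset,
    buffering_mM_per_pH = buffering_capacity(hepes_mM, mes_mM, hco3_mM, ph)
  )
}

#' Buffering capacity of a HEPES/MES/bicarbonate medium
#'
#' Buffering capacity beta (mM of strong acid per pH unit) as the sum of the
#' closed-system terms for each Good's buffer,
#' `2.303 * C * Ka * h / (Ka + h)^2` (HEPES pKa 7.5, MES pKa 6.1), plus the
#' open-CO2-system bicarbonate term `2.303 * [HCO3-]` (pCO2 clamped by the
#' incubator, so beta_bicarb is proportional to the bicarbonate itself).
#'
#' @param hepes_mM,mes_mM,hco3_mM Concentrations in mM, >= 0. Vectorised.
#' @param ph pH at which beta is evaluated.
#' @param pka_hepes,pka_mes Buffer pKa values.
#' @return beta in mM per pH unit.
#' @examples
#' buffering_capacity(10, 10, 0, 6.8)
#' buffering_capacity(10, 0, 0, 7.5)  # = 2.303 * 10 / 4 at pH == pKa
#' @export
buffering_capacity <- function(hepes_mM = 0, mes_mM = 0, hco3_mM = 0, ph,
                               pka_hepes = 7.5, pka_mes = 6.1) {
  if (any(hepes_mM < 0) || any(mes_mM < 0) || any(hco3_mM < 0)) {
    abort("Buffer concentrations must be non-negative.")
  }
  h <- 10^(-ph)
  bell <- function(conc, pka) {
    ka <- 10^(-pka)
    2.303 * conc * ka * h / (ka + h)^2
  }
  bell(hepes_mM, pka_hepes) + bell(mes_mM, pka_mes) + 2.303 * hco3_mM
}

#' Ratiometric dye calibration curve
#'
#' Constructor for the three-parameter sigmoid relating a fluorescence or
#' absorbance ratio to pH: `R(pH) = (R_acid + R_base * 10^(pH - pKa)) /
#' (1 + 10^(pH - pKa))`. Covers phenol red (A430/A560), cSNARF1 (F590/F640)
#' and HPTS (F450/F416) with appropriate plateau values; dyes whose ratio
#' falls with pH simply have `r_acid > r_base`.
#'
#' @param r_acid Ratio plateau at low pH.
#' @param r_base Ratio plateau at high pH.
#' @param pka_app Apparent pKa of the dye, in `[5, 9]`.
#' @return An object of class `calibration_curve`.
#' @export
calibration_curve <- function(r_acid, r_base, pka_app) {
  if (r_acid == r_base) abort("`r_acid` and `r_base` must differ.")
  if (pka_app < 5 || pka_app > 9) abort("`pka_app` must lie in [5, 9].")
  structure(list(r_acid = r_acid, r_base = r_base, pka_app = pka_app),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> r_acid = %.4g, r_base = %.4g, pKa_app = %.3f\n",
              x$r_acid, x$r_base, x$pka_app))
  invisible(x)
}

#' Forward ratio model: predicted dye ratio at a given pH
#'
#' @param ph pH values.
#' @param calib A [calibration_curve()].
#' @return Predicted ratio.
#' @export
ratio_model <- function(ph, calib) {
  stopifnot(inherits(calib, "calibration_curve"))
  t <- 10^(ph - calib$pka_app)
  (calib$r_acid + calib$r_base * t) / (1 + t)
}

#' Convert measured dye ratios to pH
#'
#' Inverts the ratiometric sigmoid: `pH = pKa_app + log10((R - R_acid) /
#' (R_base - R))`. The same expression serves dyes whose ratio rises or falls
#' with pH (the calibration stores the plateaus in either order). Ratios at or
#' beyond the calibrated plateaus cannot be inverted and are returned as `NA`
#' with `censored = TRUE`.
#'
#' @param r Measured ratios.
#' @param calib A [calibration_curve()].
#' @return A tibble with columns `r`, `ph`, `censored`.
#' @examples
#' cal <- calibration_curve(0.4, 2.0, 7.1)
#' ratiometric_ph(ratio_model(c(6.8, 7.4), cal), cal)
#' @export
ratiometric_ph <- function(r, calib) {
  stopifnot(inherits(calib, "calibration_curve"))
  lo <- min(calib$r_acid, calib$r_base)
  hi <- max(calib$r_acid, calib$r_base)
  ok <- r > lo & r < hi
  ph <- rep(NA_real_, length(r))
  ph[ok] <- calib$pka_app +
    log10((r[ok] - calib$r_acid) / (calib$r_base - r[ok]))
  if (any(!ok)) {
    warn(sprintf("%d ratio(s) outside the calibrated range (%.4g, %.4g); returned as censored.",
                 sum(!ok), lo, hi))
  }
  tibble::tibble(r = r, ph = ph, censored = !ok)
}

#' Fit a ratiometric calibration curve to known-pH standards
#'
#' Least-squares fit of the three-parameter ratio sigmoid to calibration
#' points, e.g. nigericin-clamped wells at known pH. Requires at least four
#' points and coverage of the transition: a fit whose apparent pKa falls
#' outside the measured pH range is rejected as unidentifiable (all points on
#' one plateau).
#'
#' @param data A data frame with columns `ph` and `r` (measured ratio).
#' @return A `calibration_fit` object: the `calibration_curve` plus residual
#'   diagnostics. Use [tidy()] / [glance()] to extract, and `$calib` for the
#'   curve itself.
#' @export
fit_calibration <- function(data) {
  stopifnot(is.data.frame(data), all(c("ph", "r") %in% names(data)))
  data <- dplyr::filter(data, is.finite(.data$ph), is.finite(.data$r))
  if (nrow(data) < 4) abort("At least 4 calibration points are required.")
  # orientation-free starts from the observed extremes
  o <- order(data$ph)
  start <- list(r_acid = data$r[o][1], r_base = data$r[o][nrow(data)],
                pka_app = median(data$ph))
  fit <- minpack.lm::nlsLM(
    r ~ (r_acid + r_base * 10^(ph - pka_app)) / (1 + 10^(ph - pka_app)),
    data = data, start = start,
    lower = c(r_acid = -Inf, r_base = -Inf, pka_app = 4),
    upper = c(r_acid = Inf, r_base = Inf, pka_app = 10),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  est <- coef(fit)
  if (est[["pka_app"]] < min(data$ph) || est[["pka_app"]] > max(data$ph)) {
    abort("Calibration unidentifiable: fitted pKa lies outside the measured pH range (points on one plateau?).")
  }
  structure(list(
    calib = calibration_curve(est[["r_acid"]], est[["r_base"]], est[["pka_app"]]),
    residuals = resid(fit), rss = sum(resid(fit)^2), n = nrow(data),
    data = tibble::as_tibble(data)
  ), class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  print(x$calib)
  cat(sprintf("  n = %d points, RSS = %.4g\n", x$n, x$rss))
  invisible(x)
}

#' @rdname fit_calibration
#' @param x A `calibration_fit`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.calibration_fit <- function(x, ...) {
  tibble::tibble(
    term = c("r_acid", "r_base", "pka_app"),
    estimate = c(x$calib$r_acid, x$calib$r_base, x$calib$pka_app)
  )
}

#' @rdname fit_calibration
#' @exportS3Method generics::glance
glance.calibration_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, n = x$n)
}

#' Stern-Volmer oxygen concentration from collisional quenching
#'
#' Converts a quenched fluorescence reading of an O2-sensitive dye (e.g.
#' RuBPY) to oxygen concentration via `F0/F = 1 + Ksv * [O2]`, i.e.
#' `[O2] = (F0/F - 1) / Ksv`.
#'
#' @param f0 Unquenched intensity (at zero O2), > 0.
#' @param f Measured intensity, `0 < f <= f0`.
#' @param ksv Stern-Volmer constant (per unit O2 concentration).
#' @return O2 concentration in the reciprocal units of `ksv`.
#' @examples
#' stern_volmer_o2(1000, 500, ksv = 5)  # = 1/5
#' @export
stern_volmer_o2 <- function(f0, f, ksv) {
  if (any(f <= 0)) abort("`f` must be positive.")
  if (any(f > f0)) abort("`f` exceeds `f0`: negative quenching is not physical.")
  if (any(ksv <= 0)) abort("`ksv` must be positive.")
  (f0 / f - 1) / ksv
}

#' Cell-number-normalised ROS index
#'
#' Reactive-oxygen-species readout as the ratio of oxidised-DCF fluorescence
#' to Hoechst-33342 fluorescence; dividing by the DNA stain removes variation
#' in cell number, so the index is invariant to scaling both channels.
#'
#' @param f_dcf H2DCFDA-derived fluorescence, >= 0.
#' @param f_hoechst Hoechst-33342 fluorescence, > 0.
#' @return Numeric ratio.
#' @export
ros_index <- function(f_dcf, f_hoechst) {
  if (any(f_hoechst <= 0)) abort("`f_hoechst` must be positive.")
  if (any(f_dcf < 0)) abort("`f_dcf` must be non-negative.")
  f_dcf / f_hoechst
}

#' Metabolic flux rates from endpoint glucose/lactate assays
#'
#' Per-biomass production and consumption rates from initial and final medium
#' concentrations, `rate = delta_conc * volume / (duration * biomass)`, plus
#' the lactate:glucose stoichiometric ratio. Pure glycolysis yields at most
#' two lactate per glucose; a ratio above 2 is flagged (it implies another
#' lactate source or assay error).
#'
#' @param glucose_initial_mM,glucose_final_mM Medium glucose (mM).
#' @param lactate_initial_mM,lactate_final_mM Medium lactate (mM).
#' @param duration_h Assay duration (hours), > 0.
#' @param volume_mL Medium volume (mL).
#' @param biomass Biomass proxy (e.g. SRB absorbance or cell count), > 0.
#' @return One-row tibble: `glucose_consumption`, `lactate_production`
#'   (umol per hour per biomass unit), `lactate_glucose_ratio`,
#'   `exceeds_glycolytic_stoichiometry`.
#' @export
flux_rates <- function(glucose_initial_mM, glucose_final_mM,
                       lactate_initial_mM, lactate_final_mM,
                       duration_h, volume_mL = 1, biomass = 1) {
  if (any(duration_h <= 0)) abort("`duration_h` must be positive.")
  if (any(biomass <= 0)) abort("`biomass` must be positive.")
  glc <- (glucose_initial_mM - glucose_final_mM) * volume_mL / (duration_h * biomass)
  lac <- (lactate_final_mM - lactate_initial_mM) * volume_mL / (duration_h * biomass)
  ratio <- dplyr::if_else(glc > 0, lac / glc, NA_real_)
  tibble::tibble(
    glucose_consumption = glc,
    lactate_production = lac,
    lactate_glucose_ratio = ratio,
    exceeds_glycolytic_stoichiometry = !is.na(ratio) & ratio > 2
  )
}
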