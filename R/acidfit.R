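#' Biphasic Hill model parameters
#'
#' Parameter set for the five-parameter biphasic Hill model of cell growth as
#' a function of extracellular pH: a maximal growth `g_max`, an activatory
#' proton binding constant `K` with cooperativity `n_act` (protons are
#' required for growth, so growth rolls off on the alkaline side as
#' `[H+]` falls below `K`), and an inhibitory binding constant `Q` with
#' cooperativity `n_inh` (excess protons inhibit, producing the acid limb).
#' An interior growth optimum requires `K < Q` in concentration terms,
#' i.e. the activatory half-point is more alkaline than the inhibitory one.
#'
#' @param g_max Maximal growth (assay units, e.g. SRB absorbance), > 0.
#' @param K Activatory binding constant, mol/L of H+.
#' @param n_act Activatory Hill cooperativity, > 0.
#' @param Q Inhibitory binding constant, mol/L of H+; must exceed `K`.
#' @param n_inh Inhibitory Hill cooperativity, > 0.
#' @return An object of class `biphasic_params`.
#' @examples
#' biphasic_params(g_max = 1, K = 10^-7.8, Q = 10^-6.6)
#' @export
biphasic_params <- function(g_max, K, n_act = 1, Q, n_inh = 1) {
  if (g_max <= 0 || K <= 0 || Q <= 0 || n_act <= 0 || n_inh <= 0) {
    abort("All biphasic parameters must be positive.")
  }
  if (K >= Q) abort("`K` must be smaller than `Q` for an interior growth optimum.")
  structure(list(g_max = g_max, K = K, n_act = n_act, Q = Q, n_inh = n_inh),
            class = "biphasic_params")
}

#' @export
print.biphasic_params <- function(x, ...) {
  cat(sprintf(
    "<biphasic_params> g_max = %.4g | pK = %.3f (n_act = %.2f) | pQ = %.3f (n_inh = %.2f)\n",
    x$g_max, -log10(x$K), x$n_act, -log10(x$Q), x$n_inh))
  invisible(x)
}

# logistic form of the two Hill factors in pH space; numerically stable for
# extreme pH because it never forms h^n explicitly
.biphasic_g <- function(ph, g_max, pk_act, n_act, pk_inh, n_inh) {
  act <- 1 / (1 + 10^(n_act * (ph - pk_act)))   # h^n/(h^n + K^n)
  inh <- 1 / (1 + 10^(n_inh * (pk_inh - ph)))   # Q^n/(h^n + Q^n)
  g_max * act * inh
}

#' Predicted growth from the biphasic Hill model
#'
#' Evaluates `G(pH) = G_max * h^n_act/(h^n_act + K^n_act) *
#' Q^n_inh/(h^n_inh + Q^n_inh)` with `h = 10^-pH`. The product of an
#' activatory and an inhibitory Hill term gives a unimodal curve bounded by
#' `[0, G_max]` whenever `K < Q`; for unit cooperativities the optimum sits
#' exactly midway between the two pK values.
#'
#' @param ph pH values (vectorised).
#' @param params A [biphasic_params()] object.
#' @return Predicted growth, same length as `ph`.
#' @export
biphasic_growth <- function(ph, params) {
  stopifnot(inherits(params, "biphasic_params"))
  .biphasic_g(ph, params$g_max, -log10(params$K), params$n_act,
              -log10(params$Q), params$n_inh)
}

#' pH of maximal predicted growth
#'
#' @param params A [biphasic_params()] object.
#' @param interval pH search interval.
#' @return The pH at which the model predicts maximal growth.
#' @export
ph_optimum <- function(params, interval = c(4, 10)) {
  stopifnot(inherits(params, "biphasic_params"))
  opt <- optimize(function(p) biphasic_growth(p, params),
                  interval = interval, maximum = TRUE, tol = 1e-10)
  opt$maximum
}

#' Acid-side half-growth pH (pH50)
#'
#' The pH50 is the extracellular pH on the acidic side of the growth optimum
#' at which predicted growth falls to half its value at the optimum: higher
#' pH50 means the line is more acid-sensitive. The root is bracketed on
#' `[floor, pH_opt]` and found by bisection; when the curve never falls to
#' half-maximum above the extrapolation floor the result is censored at the
#' floor (fits to data truncated at the most acidic pH tested extrapolate
#' below the data, and the floor bounds that extrapolation).
#'
#' @param params A [biphasic_params()] object (or a `biphasic_fit`).
#' @param floor Extrapolation floor in pH units (default 5.0).
#' @return A list with `ph50`, `censored`, `ph_opt`, `g_opt`.
#' @export
compute_ph50 <- function(params, floor = 5.0) {
  if (inherits(params, "biphasic_fit")) params <- params$params
  stopifnot(inherits(params, "biphasic_params"))
  ph_opt <- ph_optimum(params)
  g_opt <- biphasic_growth(ph_opt, params)
  f <- function(p) biphasic_growth(p, params) - 0.5 * g_opt
  if (floor >= ph_opt || f(floor) > 0) {
    return(list(ph50 = floor, censored = TRUE, ph_opt = ph_opt, g_opt = g_opt))
  }
  root <- uniroot(f, lower = floor, upper = ph_opt, tol = 1e-10)
  list(ph50 = root$root, censored = FALSE, ph_opt = ph_opt, g_opt = g_opt)
}

# deterministic multi-start grid over (pK_act, pK_inh) pairs; cooperativities
# start at 1 and g_max at the observed maximum. The fit is parameterised as
# pk_act = pk_inh + gap with gap > 0, which confines the optimiser to the
# physical K < Q ordering (for unequal cooperativities a mirrored K > Q
# solution can otherwise shadow the physical one under noise).
.biphasic_starts <- function(g0) {
  grid <- expand.grid(pk_inh = c(5.4, 6.1, 6.8), pk_act = c(7.2, 7.9, 8.6))
  purrr::pmap(grid, function(pk_inh, pk_act) {
    list(g_max = g0, gap = pk_act - pk_inh, n_act = 1, pk_inh = pk_inh,
         n_inh = 1)
  })
}

#' Fit the biphasic Hill model to one group's growth-vs-pHe data
#'
#' Nonlinear least squares of absorbance on pHe for a single group (cell
#' line / genotype / treatment), on the raw absorbance scale. The fit is
#' parameterised in pK units, bounded (pK in `[5, 9]`, cooperativities in
#' `[0.3, 8]`) and multi-started from a deterministic 3x3 grid of
#' (pK_inh, pK_act) pairs spanning the physiological range; the converged
#' start with the lowest residual sum of squares wins, so the result is
#' independent of well order.
#'
#' @param data Data frame with columns `phe` and `absorbance` (one group's
#'   wells; replicate wells are simply additional rows).
#' @param ph50_floor Extrapolation floor passed to [compute_ph50()].
#' @return A `biphasic_fit`: fitted [biphasic_params()], `rss`, `ph_opt`,
#'   `ph50`, `censored`, `n_points`, number of converged starts, and the data.
#'   Methods: [tidy()], [glance()], [augment()], [ggplot2::autoplot()].
#' @examples
#' p <- biphasic_params(1, K = 10^-7.8, Q = 10^-6.6)
#' plate <- simulate_growth_plate(list(wt = p), ph_levels = seq(6.3, 7.9, 0.3),
#'                                n_reps = 3, noise_cv = 0, seed = 1)
#' fit_biphasic(plate)
#' @export
fit_biphasic <- function(data, ph50_floor = 5.0) {
  stopifnot(is.data.frame(data), all(c("phe", "absorbance") %in% names(data)))
  data <- dplyr::filter(data, is.finite(.data$phe), is.finite(.data$absorbance))
  if (nrow(data) < 5) {
    abort("At least 5 wells are required to fit 5 free parameters.")
  }
  if (dplyr::n_distinct(data$phe) < 5) {
    abort("At least 5 distinct pHe levels are required (5 free parameters).")
  }
  if (all(data$absorbance == 0)) abort("All absorbances are zero; nothing to fit.")
  # canonical row order so the fit is invariant to input well order
  data <- dplyr::arrange(data, .data$phe, .data$absorbance)
  g0 <- max(data$absorbance)
  lower <- c(g_max = g0 * 1e-6, gap = 0.05, n_act = 0.3, pk_inh = 5, n_inh = 0.3)
  upper <- c(g_max = g0 * 100, gap = 4, n_act = 8, pk_inh = 9, n_inh = 8)

  fits <- purrr::map(.biphasic_starts(g0), function(st) {
    tryCatch({
      fit <- minpack.lm::nlsLM(
        absorbance ~ .biphasic_g(phe, g_max, pk_inh + gap, n_act, pk_inh, n_inh),
        data = data, start = st, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12,
                                             ptol = 1e-12)
      )
      est <- coef(fit)
      # the activatory pK must stay within the physiological bound
      if (est[["pk_inh"]] + est[["gap"]] > 9 + 1e-6) NULL
      else list(fit = fit, rss = sum(resid(fit)^2))
    }, error = function(e) NULL)
  })
  fits <- purrr::compact(fits)
  if (length(fits) == 0) {
    abort("No start converged to a valid biphasic optimum; check that the data span both limbs of the growth curve.")
  }
  best <- fits[[which.min(purrr::map_dbl(fits, "rss"))]]
  est <- coef(best$fit)
  params <- biphasic_params(
    g_max = est[["g_max"]],
    K = 10^(-(est[["pk_inh"]] + est[["gap"]])), n_act = est[["n_act"]],
    Q = 10^(-est[["pk_inh"]]), n_inh = est[["n_inh"]]
  )
  p50 <- compute_ph50(params, floor = ph50_floor)
  structure(list(
    params = params, rss = best$rss,
    ph_opt = p50$ph_opt, ph50 = p50$ph50, censored = p50$censored,
    g_opt = p50$g_opt, n_points = nrow(data), n_converged = length(fits),
    data = tibble::as_tibble(data)
  ), class = "biphasic_fit")
}

#' @export
print.biphasic_fit <- function(x, ...) {
  print(x$params)
  cat(sprintf("  pH_opt = %.3f | pH50 = %.3f%s | RSS = %.4g (n = %d wells)\n",
              x$ph_opt, x$ph50, if (x$censored) " (censored)" else "",
              x$rss, x$n_points))
  invisible(x)
}

#' @rdname fit_biphasic
#' @param x A `biphasic_fit`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.biphasic_fit <- function(x, ...) {
  p <- x$params
  tibble::tibble(
    term = c("g_max", "pk_act", "n_act", "pk_inh", "n_inh"),
    estimate = c(p$g_max, -log10(p$K), p$n_act, -log10(p$Q), p$n_inh)
  )
}

#' @rdname fit_biphasic
#' @exportS3Method generics::glance
glance.biphasic_fit <- function(x, ...) {
  tibble::tibble(ph_opt = x$ph_opt, ph50 = x$ph50, censored = x$censored,
                 rss = x$rss, n_points = x$n_points,
                 n_converged = x$n_converged)
}

#' @rdname fit_biphasic
#' @exportS3Method generics::augment
augment.biphasic_fit <- function(x, ...) {
  dplyr::mutate(x$data,
                .fitted = biphasic_growth(.data$phe, x$params),
                .resid = .data$absorbance - .fitted)
}

#' Normalise plate growth to the fitted optimum
#'
#' Divides each well's absorbance by the model-predicted growth at the fitted
#' optimum pHe, giving relative growth on a 0-1 scale ("relative cell growth
#' normalised to optimum pHe"). Scale-invariant: multiplying all absorbances
#' by a constant rescales `G_max` identically and leaves the result unchanged.
#'
#' @param data Data frame of wells with columns `phe`, `absorbance`.
#' @param fit A `biphasic_fit` for the same group.
#' @return The input tibble with a `relative_growth` column.
#' @export
normalize_to_optimum <- function(data, fit) {
  stopifnot(inherits(fit, "biphasic_fit"))
  dplyr::mutate(tibble::as_tibble(data),
                relative_growth = .data$absorbance / fit$g_opt)
}

#' Compare pH50 between two groups with a case-resampling bootstrap
#'
#' Estimates the pH50 difference (alt minus ref; positive = the alternative
#' group is more acid-sensitive) with a percentile bootstrap CI. Wells are
#' resampled with replacement within each pHe level of each group (stratified
#' case resampling keeps all pHe levels represented, without which the
#' five-parameter fit can lose identifiability), the model is refitted to
#' each resample, and pH50 recomputed. If censored pH50 estimates occur in
#' more than 20% of resamples the CI is flagged unreliable.
#'
#' @param wells_ref,wells_alt Data frames of wells (`phe`, `absorbance`) for
#'   the reference and alternative groups.
#' @param n_boot Number of bootstrap resamples.
#' @param seed RNG seed.
#' @param conf Confidence level for the percentile interval.
#' @param ph50_floor Extrapolation floor.
#' @return One-row tibble: `ph50_ref`, `ph50_alt`, `delta_ph50`, `ci_lo`,
#'   `ci_hi`, `n_boot_ok`, `censored_fraction`, `unreliable`.
#' @export
compare_ph50 <- function(wells_ref, wells_alt, n_boot = 1000, seed = 1,
                         conf = 0.95, ph50_floor = 5.0) {
  fit_ref <- fit_biphasic(wells_ref, ph50_floor = ph50_floor)
  fit_alt <- fit_biphasic(wells_alt, ph50_floor = ph50_floor)
  resample <- function(wells) {
    wells |>
      dplyr::group_by(.data$phe) |>
      dplyr::slice_sample(prop = 1, replace = TRUE) |>
      dplyr::ungroup()
  }
  boot_one <- function(wells) {
    tryCatch(fit_biphasic(resample(wells), ph50_floor = ph50_floor),
             error = function(e) NULL)
  }
  set.seed(seed)
  deltas <- numeric(0)
  n_cens <- 0L
  n_ok <- 0L
  for (b in seq_len(n_boot)) {
    fr <- boot_one(tibble::as_tibble(wells_ref))
    fa <- boot_one(tibble::as_tibble(wells_alt))
    if (is.null(fr) || is.null(fa)) next
    n_ok <- n_ok + 1L
    if (fr$censored || fa$censored) n_cens <- n_cens + 1L
    deltas <- c(deltas, fa$ph50 - fr$ph50)
  }
  if (n_ok == 0) abort("Every bootstrap refit failed.")
  alpha <- (1 - conf) / 2
  ci <- unname(quantile(deltas, c(alpha, 1 - alpha), type = 7))
  cens_frac <- n_cens / n_ok
  tibble::tibble(
    ph50_ref = fit_ref$ph50, ph50_alt = fit_alt$ph50,
    delta_ph50 = fit_alt$ph50 - fit_ref$ph50,
    ci_lo = ci[1], ci_hi = ci[2],
    n_boot_ok = n_ok, censored_fraction = cens_frac,
    unreliable = cens_frac > 0.2
  )
}
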