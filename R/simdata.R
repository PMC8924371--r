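#' Configuration for a synthetic pooled CRISPR screen
#'
#' Assembles and validates the generative parameters for [simulate_screen()].
#' Defaults mirror a genome-scale knockout-library viability screen run at
#' three extracellular pH conditions: a 4-guides-per-gene library infected at
#' MOI 0.3 with a representation of 675 cells per guide, treated for 11 days
#' with a passaging bottleneck at day 5 reseeding 3e6 cells, harvested in two
#' independent replicates per condition, and sequenced to a mean depth per
#' guide with negative-binomial overdispersion. Gene classes encode the
#' selection logic of interest: `neutral` knockouts grow like wild type
#' everywhere, `core_essential` ones are impaired at every pHe,
#' `acid_essential` ones are impaired only under acidic conditions and
#' `acid_dispensable` ones gain fitness there.
#'
#' @param n_genes Number of genes.
#' @param guides_per_gene Guides per gene (default 4).
#' @param class_fractions Named proportions over
#'   `neutral`, `core_essential`, `acid_essential`, `acid_dispensable`;
#'   must sum to 1.
#' @param fitness_effect Data frame with columns `class`, `phe`, `multiplier`:
#'   the per-class growth-rate multiplier at each pHe condition (unitless,
#'   applied per day). Defaults plant a 0.7x acid-only defect for
#'   `acid_essential` (0.85x at the mild condition), a uniform 0.5x for
#'   `core_essential` and a 1.3x acid advantage for `acid_dispensable`.
#' @param base_growth_rate Named per-condition wild-type growth rate
#'   (per day); names are the pHe conditions.
#' @param representation Cells per guide at T0 (default 675).
#' @param moi Infection multiplicity (default 0.3; recorded, not simulated).
#' @param days Treatment duration in days (default 11).
#' @param passage_day Day of the passaging bottleneck (default 5).
#' @param reseed_cells Cells reseeded at each passage (default 3e6).
#' @param depth Mean sequencing reads per guide.
#' @param dispersion Negative-binomial overdispersion of counts
#'   (`Var = mu + dispersion * mu^2`); 0 gives Poisson counts.
#' @param library_skew_sd Log-scale SD of T0 guide abundance (plasmid-library
#'   skew); 0 gives a perfectly even library.
#' @param guide_efficacy_range Interval for the per-guide knockout efficiency
#'   (uniform draw), within `[0, 1]`; lentiviral pools are mixed populations
#'   of edited and unedited cells, so efficacy is rarely 1.
#' @param n_replicates Independent screen replicates (default 2).
#' @param seed RNG seed.
#' @return A validated list of class `screen_sim_config`.
#' @export
screen_sim_config <- function(
    n_genes = 2000,
    guides_per_gene = 4,
    class_fractions = c(neutral = 0.85, core_essential = 0.05,
                        acid_essential = 0.05, acid_dispensable = 0.05),
    fitness_effect = NULL,
    base_growth_rate = c("7.4" = 0.69, "6.9" = 0.55, "6.63" = 0.35),
    representation = 675,
    moi = 0.3,
    days = 11,
    passage_day = 5,
    reseed_cells = 3e6,
    depth = 500,
    dispersion = 0.1,
    library_skew_sd = 0.5,
    guide_efficacy_range = c(0.6, 1),
    n_replicates = 2,
    seed = 1) {
  classes <- c("neutral", "core_essential", "acid_essential", "acid_dispensable")
  if (!setequal(names(class_fractions), classes)) {
    abort("`class_fractions` must be named over the four gene classes.")
  }
  if (abs(sum(class_fractions) - 1) > 1e-8) abort("`class_fractions` must sum to 1.")
  if (n_genes < 1 || guides_per_gene < 1) abort("Gene and guide counts must be positive.")
  if (depth <= 0) abort("`depth` must be positive.")
  if (representation <= 0 || reseed_cells <= 0) abort("Cell numbers must be positive.")
  if (dispersion < 0 || library_skew_sd < 0) abort("Noise parameters must be non-negative.")
  if (passage_day < 0 || passage_day > days) abort("`passage_day` must lie within the treatment window.")
  if (any(guide_efficacy_range < 0) || any(guide_efficacy_range > 1) ||
      guide_efficacy_range[1] > guide_efficacy_range[2]) {
    abort("`guide_efficacy_range` must be an interval within [0, 1].")
  }
  conditions <- names(base_growth_rate)
  if (is.null(fitness_effect)) {
    fitness_effect <- default_fitness_effect(conditions)
  }
  fitness_effect <- tibble::as_tibble(fitness_effect)
  stopifnot(all(c("class", "phe", "multiplier") %in% names(fitness_effect)))
  neutral <- dplyr::filter(fitness_effect, .data$class == "neutral")
  if (any(neutral$multiplier != 1)) {
    abort("Neutral genes must have multiplier 1 in every condition.")
  }
  structure(list(
    n_genes = as.integer(n_genes), guides_per_gene = as.integer(guides_per_gene),
    class_fractions = class_fractions[classes],
    fitness_effect = fitness_effect,
    base_growth_rate = base_growth_rate, conditions = conditions,
    representation = representation, moi = moi,
    days = days, passage_day = passage_day, reseed_cells = reseed_cells,
    depth = depth, dispersion = dispersion,
    library_skew_sd = library_skew_sd,
    guide_efficacy_range = guide_efficacy_range,
    n_replicates = as.integer(n_replicates), seed = as.integer(seed)
  ), class = "screen_sim_config")
}

#' Default per-class, per-condition fitness multipliers
#'
#' @param conditions Character vector of pHe conditions (most alkaline first).
#' @return Tibble with columns `class`, `phe`, `multiplier`.
#' @export
default_fitness_effect <- function(conditions = c("7.4", "6.9", "6.63")) {
  tidyr::expand_grid(
    class = c("neutral", "core_essential", "acid_essential", "acid_dispensable"),
    phe = conditions
  ) |>
    dplyr::mutate(multiplier = dplyr::case_when(
      class == "neutral" ~ 1,
      class == "core_essential" ~ 0.5,
      class == "acid_essential" & phe == "6.63" ~ 0.7,
      class == "acid_essential" & phe == "6.9" ~ 0.85,
      class == "acid_essential" ~ 1,
      class == "acid_dispensable" & phe == "6.63" ~ 1.3,
      class == "acid_dispensable" & phe == "6.9" ~ 1.15,
      TRUE ~ 1
    ))
}

# deterministic class assignment honouring the fractions as closely as
# possible at finite n (largest-remainder rounding)
.assign_classes <- function(n_genes, fractions) {
  raw <- fractions * n_genes
  base <- floor(raw)
  short <- n_genes - sum(base)
  extra <- order(raw - base, decreasing = TRUE)[seq_len(short)]
  base[extra] <- base[extra] + 1
  rep(names(fractions), times = base)
}

#' Simulate a pooled CRISPR viability screen across pHe conditions
#'
#' Generates sgRNA count matrices for T0 and T11 samples under a mechanistic
#' growth model. T0 guide abundance is log-normally skewed around the
#' representation; each guide then grows deterministically and exponentially
#' at rate `base_rate(condition) * multiplier(class, condition)^efficacy`
#' per day, where the per-guide knockout efficacy tempers the planted effect
#' (unedited cells grow at wild-type rate). At `passage_day` the population
#' passes through a multinomial bottleneck reseeding `reseed_cells` cells,
#' then grows to day `days`. Sequencing counts are negative binomial with
#' mean proportional to abundance times depth. Replicates share the T0
#' library but have independent bottlenecks and sequencing noise. All
#' randomness flows from `config$seed`, so outputs are bit-reproducible.
#'
#' @param config A [screen_sim_config()].
#' @return A list of class `screen_sim` with elements
#'   \describe{
#'     \item{counts}{tibble `guide_id`, `gene_id`, one integer column per sample}
#'     \item{samples}{tibble `sample`, `timepoint`, `phe`, `replicate`}
#'     \item{truth}{tibble `gene_id`, `class`, plus `effect_<phe>` multipliers}
#'     \item{config}{the input configuration}
#'   }
#' @examples
#' sim <- simulate_screen(screen_sim_config(n_genes = 50, depth = 100, seed = 7))
#' head(sim$counts)
#' @export
simulate_screen <- function(config) {
  stopifnot(inherits(config, "screen_sim_config"))
  set.seed(config$seed)
  n_guides <- config$n_genes * config$guides_per_gene
  gene_id <- sprintf("gene_%05d", seq_len(config$n_genes))
  class <- .assign_classes(config$n_genes, config$class_fractions)
  guides <- tibble::tibble(
    gene_id = rep(gene_id, each = config$guides_per_gene),
    guide_id = sprintf("%s_g%d", gene_id,
                       rep(seq_len(config$guides_per_gene), config$n_genes)),
    class = rep(class, each = config$guides_per_gene)
  )

  # T0 library skew (plasmid pool unevenness), mean-preserving on the raw scale
  skew <- config$library_skew_sd
  x0 <- config$representation *
    rlnorm(n_guides, meanlog = -skew^2 / 2, sdlog = skew)
  efficacy <- runif(n_guides, config$guide_efficacy_range[1],
                    config$guide_efficacy_range[2])

  eff_wide <- config$fitness_effect |>
    tidyr::pivot_wider(names_from = "phe", values_from = "multiplier")
  mult <- as.matrix(eff_wide[match(guides$class, eff_wide$class),
                             config$conditions, drop = FALSE])

  draw_counts <- function(abundance) {
    mu <- abundance / sum(abundance) * config$depth * n_guides
    x <- if (config$dispersion <= 0) rpois(n_guides, mu)
         else rnbinom(n_guides, mu = mu, size = 1 / config$dispersion)
    as.integer(x)
  }

  counts <- list()
  samples <- list()
  for (r in seq_len(config$n_replicates)) {
    nm0 <- sprintf("T0_R%d", r)
    counts[[nm0]] <- draw_counts(x0)
    samples[[nm0]] <- tibble::tibble(sample = nm0, timepoint = "T0",
                                     phe = NA_character_, replicate = r)
    for (cond in config$conditions) {
      rate <- config$base_growth_rate[[cond]] * mult[, cond]^efficacy
      n_pass <- x0 * exp(rate * config$passage_day)
      reseed <- as.numeric(rmultinom(1, size = config$reseed_cells,
                                     prob = n_pass))
      n_final <- reseed * exp(rate * (config$days - config$passage_day))
      nm <- sprintf("T%d_ph%s_R%d", config$days, cond, r)
      counts[[nm]] <- draw_counts(n_final)
      samples[[nm]] <- tibble::tibble(sample = nm, timepoint = sprintf("T%d", config$days),
                                      phe = cond, replicate = r)
    }
  }

  truth <- tibble::tibble(gene_id = gene_id, class = class) |>
    dplyr::left_join(
      config$fitness_effect |>
        tidyr::pivot_wider(names_from = "phe", values_from = "multiplier",
                           names_prefix = "effect_"),
      by = "class"
    )

  structure(list(
    counts = dplyr::bind_cols(guides[c("guide_id", "gene_id")],
                              tibble::as_tibble(counts)),
    samples = dplyr::bind_rows(samples),
    truth = truth,
    config = config
  ), class = "screen_sim")
}

#' @export
print.screen_sim <- function(x, ...) {
  cat(sprintf("<screen_sim> %d genes x %d guides, %d samples (seed %d)\n",
              x$config$n_genes, x$config$guides_per_gene,
              nrow(x$samples), x$config$seed))
  print(x$samples)
  invisible(x)
}

#' Simulate an SRB growth plate from known biphasic parameters
#'
#' Generates well-level absorbances for one or more groups from the biphasic
#' Hill model with multiplicative noise:
#' `absorbance = G(pHe) * (1 + e)`, `e ~ N(0, noise_cv)`, truncated at zero.
#' Used both as a fixture generator for fitting tests and to emulate the
#' 6-bicarbonate-level, 3-technical-replicate SRB plate design.
#'
#' @param params_by_group Named list of [biphasic_params()], one per group.
#' @param ph_levels Vector of pHe levels (>= 2).
#' @param n_reps Technical replicates per pHe level.
#' @param noise_cv Coefficient of variation of multiplicative noise (>= 0).
#' @param seed RNG seed.
#' @param batch Batch label recorded on every well.
#' @return Tibble with columns `well`, `group`, `phe`, `absorbance`,
#'   `replicate`, `batch`.
#' @export
simulate_growth_plate <- function(params_by_group, ph_levels, n_reps = 3,
                                  noise_cv = 0.05, seed = 1, batch = 1L) {
  if (length(ph_levels) < 2) abort("At least 2 pHe levels are required.")
  if (noise_cv < 0) abort("`noise_cv` must be non-negative.")
  stopifnot(is.list(params_by_group), !is.null(names(params_by_group)))
  set.seed(seed)
  purrr::imap(params_by_group, function(params, group) {
    grid <- tidyr::expand_grid(phe = ph_levels, replicate = seq_len(n_reps))
    g <- biphasic_growth(grid$phe, params)
    noise <- if (noise_cv > 0) rnorm(nrow(grid), 0, noise_cv) else 0
    tibble::tibble(
      group = group, phe = grid$phe,
      absorbance = pmax(g * (1 + noise), 0),
      replicate = grid$replicate, batch = batch
    )
  }) |>
    dplyr::bind_rows() |>
    dplyr::mutate(well = sprintf("W%03d", dplyr::row_number()),
                  .before = 1)
}

#' Configuration for a medium pH / O2 photometry time-course simulation
#'
#' @param ocr O2 consumption rate (mM/h), >= 0.
#' @param max_glycolytic_flux Maximal glycolytic H+ production rate (mM/h).
#' @param glycolysis_pk pH at which glycolytic acid production is
#'   half-inhibited (acid inhibits glycolysis, so flux falls as pH drops).
#' @param glycolysis_n Hill steepness of that inhibition.
#' @param hepes_mM,mes_mM Buffer concentrations (mM).
#' @param o2_init Initial dissolved O2 (mM); ~0.2 mM at air saturation, 37 degC.
#' @param duration_h Time span (hours, default 17).
#' @param dt Euler step (hours), > 0.
#' @param seed RNG seed (used only when channel noise is requested).
#' @return A list of class `phot_sim_config`.
#' @export
phot_sim_config <- function(ocr = 0.04, max_glycolytic_flux = 0.3,
                            glycolysis_pk = 6.9, glycolysis_n = 2,
                            hepes_mM = 10, mes_mM = 10, o2_init = 0.2,
                            duration_h = 17, dt = 0.01, seed = 1) {
  if (ocr < 0 || max_glycolytic_flux < 0) abort("Rates must be non-negative.")
  if (dt <= 0) abort("`dt` must be positive.")
  if (duration_h <= 0) abort("`duration_h` must be positive.")
  structure(list(ocr = ocr, max_glycolytic_flux = max_glycolytic_flux,
                 glycolysis_pk = glycolysis_pk, glycolysis_n = glycolysis_n,
                 hepes_mM = hepes_mM, mes_mM = mes_mM, o2_init = o2_init,
                 duration_h = duration_h, dt = dt, seed = as.integer(seed)),
            class = "phot_sim_config")
}

#' Glycolytic acid flux as a function of medium pH
#'
#' Hill-type product inhibition: flux approaches the maximum at alkaline pH
#' and is suppressed as the medium acidifies below the half-inhibition pK.
#'
#' @param ph Medium pH.
#' @param config A [phot_sim_config()].
#' @return H+ production rate in mM/h.
#' @export
glycolytic_flux <- function(ph, config) {
  config$max_glycolytic_flux /
    (1 + 10^(config$glycolysis_n * (config$glycolysis_pk - ph)))
}

#' Simulate a sealed-well medium pH and O2 photometry time course
#'
#' Forward-Euler integration of `dpH/dt = -J_H(pH) / beta(pH)` and
#' `dO2/dt = -OCR` (floored at zero), where `J_H` is the pH-inhibited
#' glycolytic acid flux of [glycolytic_flux()] and `beta` the HEPES/MES
#' buffering capacity from [buffering_capacity()] (no bicarbonate: sealed
#' wells are closed to CO2). Synthetic dye channels are derived from the
#' state: an HPTS-like excitation ratio pair via the forward ratio model and
#' a RuBPY-like intensity via Stern-Volmer quenching.
#'
#' @param config A [phot_sim_config()].
#' @param start_ph Starting medium pH, in `[5.5, 8.5]`.
#' @param hpts_calib Optional [calibration_curve()] for the synthetic HPTS
#'   channels (default pKa 7.3 curve).
#' @param ksv Stern-Volmer constant for the O2 channel (per mM).
#' @return Tibble of class `photometry_trace`: `time_h`, `ph`, `o2_mM`,
#'   `i_450`, `i_416`, `i_rubpy`.
#' @export
simulate_phot_timecourse <- function(config, start_ph,
                                     hpts_calib = calibration_curve(0.3, 3.0, 7.3),
                                     ksv = 10) {
  stopifnot(inherits(config, "phot_sim_config"))
  if (start_ph < 5.5 || start_ph > 8.5) abort("`start_ph` must lie in [5.5, 8.5].")
  times <- seq(0, config$duration_h, by = config$dt)
  n <- length(times)
  ph <- numeric(n)
  ph[1] <- start_ph
  for (i in seq_len(n - 1)) {
    beta <- buffering_capacity(config$hepes_mM, config$mes_mM, 0, ph[i])
    dph <- -glycolytic_flux(ph[i], config) / beta
    ph[i + 1] <- ph[i] + dph * config$dt
  }
  o2 <- pmax(config$o2_init - config$ocr * times, 0)
  f0 <- 1000
  r_hpts <- ratio_model(ph, hpts_calib)
  out <- tibble::tibble(
    time_h = times, ph = ph, o2_mM = o2,
    i_416 = f0,
    i_450 = f0 * r_hpts,
    i_rubpy = f0 / (1 + ksv * o2)
  )
  class(out) <- c("photometry_trace", class(out))
  out
}
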