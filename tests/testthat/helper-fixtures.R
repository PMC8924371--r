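# shared fixtures, built in code

# canonical wild-type-like biphasic parameter set used across fitting tests
wt_params <- function() {
  biphasic_params(g_max = 1.2, K = 10^-7.8, n_act = 1.5, Q = 10^-6.5, n_inh = 2)
}

# the six-level bicarbonate pHe series (2.75-44 mM at 5% CO2)
plate_ph_levels <- function() hh_ph(c(2.75, 5.5, 11, 22, 33, 44), 5)

# all-neutral null screen configuration at the screen's stated scale
null_screen_config <- function(n_genes = 2000, seed = 1, ...) {
  screen_sim_config(
    n_genes = n_genes,
    class_fractions = c(neutral = 1, core_essential = 0,
                        acid_essential = 0, acid_dispensable = 0),
    depth = 500, seed = seed, ...
  )
}

# 5% acid-essential genes with multiplier 0.7 at pHe 6.63 only
planted_screen_config <- function(n_genes = 2000, seed = 1, ...) {
  eff <- default_fitness_effect() |>
    dplyr::mutate(multiplier = dplyr::case_when(
      class == "acid_essential" & phe == "6.63" ~ 0.7,
      class == "acid_essential" ~ 1,
      class == "neutral" ~ 1,
      TRUE ~ multiplier
    ))
  screen_sim_config(
    n_genes = n_genes,
    class_fractions = c(neutral = 0.95, core_essential = 0,
                        acid_essential = 0.05, acid_dispensable = 0),
    fitness_effect = eff, depth = 500, seed = seed, ...
  )
}

# brute-force one-sided hypergeometric tail used as the Fisher oracle
hyper_tail_oracle <- function(overlap, set_size, hits, universe) {
  ks <- overlap:min(set_size, hits)
  sum(choose(set_size, ks) * choose(universe - set_size, hits - ks)) /
    choose(universe, hits)
}
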