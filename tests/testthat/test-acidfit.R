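test_that("biphasic growth respects its limits and bounds", {
  p <- wt_params()
  expect_lt(biphasic_growth(12, p), 1e-4)   # h -> 0: activation lost
  expect_lt(biphasic_growth(2, p), 1e-4)    # h -> Inf: inhibition total
  grid <- seq(3, 10, by = 0.01)
  g <- biphasic_growth(grid, p)
  expect_true(all(g >= 0 & g <= p$g_max))
  # unimodal for K < Q: one sign change of the finite difference
  expect_equal(sum(diff(sign(diff(g))) != 0), 1)
})

test_that("unit cooperativities place the optimum midway between the pKs (calculus)", {
  p <- biphasic_params(1, K = 10^-7.8, Q = 10^-6.6)
  expect_equal(ph_optimum(p), (7.8 + 6.6) / 2, tolerance = 1e-6)
  # grid-search oracle for the optimum value
  grid <- seq(5, 9, length.out = 1e5)
  gmax_grid <- max(biphasic_growth(grid, p))
  expect_equal(biphasic_growth(ph_optimum(p), p), gmax_grid, tolerance = 1e-6)
})

test_that("pH50 agrees with a fine-grid bisection oracle and censors correctly", {
  p <- biphasic_params(1, K = 10^-7.8, Q = 10^-6.6)
  res <- compute_ph50(p)
  # oracle: nearest half-growth crossing on a 1e5-point acidic-side grid
  grid <- seq(5, res$ph_opt, length.out = 1e5)
  half <- 0.5 * biphasic_growth(res$ph_opt, p)
  oracle <- grid[which.min(abs(biphasic_growth(grid, p) - half))]
  expect_false(res$censored)
  expect_equal(res$ph50, oracle, tolerance = 1e-3)
  expect_lt(res$ph50, res$ph_opt)
  expect_equal(biphasic_growth(res$ph50, p),
               0.5 * biphasic_growth(res$ph_opt, p), tolerance = 1e-8)
  # negligible inhibition in range: curve never halves above the floor
  p_flat <- biphasic_params(1, K = 10^-7.8, Q = 10^-2)
  res_flat <- compute_ph50(p_flat)
  expect_true(res_flat$censored)
  expect_equal(res_flat$ph50, 5.0)
})

test_that("pH50 responds monotonically to the acid-limb parameters", {
  # steeper acid limb (larger n_inh) pulls pH50 toward the optimum
  ph50s <- sapply(c(0.5, 1, 2, 4), function(n) {
    compute_ph50(biphasic_params(1, K = 10^-7.9, n_act = 1.5,
                                 Q = 10^-6.5, n_inh = n))$ph50
  })
  expect_true(all(diff(ph50s) > 0))
  # raising Q (more alkaline inhibition midpoint) raises pH50
  ph50q <- sapply(c(6.8, 6.5, 6.2, 5.9), function(pk) {
    compute_ph50(biphasic_params(1, K = 10^-7.9, n_act = 1.5,
                                 Q = 10^(-pk), n_inh = 2))$ph50
  })
  expect_true(all(diff(ph50q) < 0))
})

test_that("noiseless plates recover all five parameters almost exactly", {
  p <- wt_params()
  plate <- simulate_growth_plate(list(wt = p), plate_ph_levels(),
                                 n_reps = 3, noise_cv = 0, seed = 1)
  fit <- fit_biphasic(plate)
  truth <- c(1.2, 7.8, 1.5, 6.5, 2)
  expect_lt(max(abs(tidy(fit)$estimate - truth) / truth), 0.01)
  expect_lt(fit$rss, 1e-12)
  # normalized curve peaks at exactly 1 on noiseless data
  rel <- normalize_to_optimum(plate, fit)
  expect_equal(max(rel$relative_growth),
               max(plate$absorbance) / fit$g_opt, tolerance = 1e-12)
  expect_lte(max(rel$relative_growth), 1 + 1e-9)
})

test_that("the fit is invariant to well order and absorbance units", {
  p <- wt_params()
  plate <- simulate_growth_plate(list(wt = p), plate_ph_levels(),
                                 n_reps = 3, noise_cv = 0.05, seed = 3)
  fit1 <- fit_biphasic(plate)
  set.seed(99)
  fit2 <- fit_biphasic(plate[sample(nrow(plate)), ])
  expect_equal(tidy(fit1)$estimate, tidy(fit2)$estimate, tolerance = 1e-9)
  # unit change scales g_max only; pH50 and normalized values unchanged
  plate_scaled <- dplyr::mutate(plate, absorbance = absorbance * 37)
  fit3 <- fit_biphasic(plate_scaled)
  expect_equal(fit3$params$g_max, fit1$params$g_max * 37, tolerance = 1e-6)
  expect_equal(fit3$ph50, fit1$ph50, tolerance = 1e-6)
  expect_equal(normalize_to_optimum(plate_scaled, fit3)$relative_growth,
               normalize_to_optimum(plate, fit1)$relative_growth,
               tolerance = 1e-6)
})

test_that("degenerate fitting inputs are rejected", {
  p <- wt_params()
  plate <- simulate_growth_plate(list(wt = p), plate_ph_levels(),
                                 n_reps = 1, noise_cv = 0, seed = 1)
  expect_error(fit_biphasic(plate[1:4, ]), "5")
  flat <- dplyr::mutate(plate, absorbance = 0)
  expect_error(fit_biphasic(flat), "zero")
})

test_that("normalize_to_optimum matches hand computation on a toy plate", {
  p <- biphasic_params(2, K = 10^-7.8, Q = 10^-6.6)
  toy <- tibble::tibble(phe = c(6.5, 6.8, 7.1, 7.4, 7.7, 8.0))
  toy$absorbance <- biphasic_growth(toy$phe, p)
  fit <- fit_biphasic(toy)
  g_opt <- biphasic_growth(ph_optimum(p), p)
  expect_equal(normalize_to_optimum(toy, fit)$relative_growth,
               toy$absorbance / g_opt, tolerance = 1e-4)
})

test_that("pH50 recovery on the plate design is tight over seeded simulations", {
  p <- wt_params()
  true50 <- compute_ph50(p)$ph50
  est <- sapply(1:40, function(s) {
    plate <- simulate_growth_plate(list(wt = p), plate_ph_levels(),
                                   n_reps = 3, noise_cv = 0.05, seed = s)
    fit_biphasic(plate)$ph50
  })
  expect_lt(abs(mean(est) - true50), 0.02)        # bias
  expect_lt(sqrt(mean((est - true50)^2)), 0.05)   # RMSE
})

test_that("bootstrap pH50 comparison behaves on identical and shifted groups", {
  p <- wt_params()
  plate <- simulate_growth_plate(list(wt = p), plate_ph_levels(),
                                 n_reps = 3, noise_cv = 0.05, seed = 7)
  # identical groups: delta ~ 0 with CI spanning 0
  same <- compare_ph50(plate, plate, n_boot = 40, seed = 11)
  expect_equal(same$delta_ph50, 0, tolerance = 1e-9)
  expect_lt(same$ci_lo, 0)
  expect_gt(same$ci_hi, 0)
  expect_false(same$unreliable)
  # n_boot = 1 with a fixed seed is reproducible
  one_a <- compare_ph50(plate, plate, n_boot = 1, seed = 5)
  one_b <- compare_ph50(plate, plate, n_boot = 1, seed = 5)
  expect_identical(one_a, one_b)
})

test_that("a planted acid-limb shift is recovered within the bootstrap CI", {
  p <- wt_params()
  shift <- 0.3
  # acid limb moved +0.3 pH units alkaline-ward: more acid-sensitive
  ko <- biphasic_params(p$g_max, K = p$K, n_act = p$n_act,
                        Q = p$Q * 10^-shift, n_inh = p$n_inh)
  true_delta <- compute_ph50(ko)$ph50 - compute_ph50(p)$ph50
  hits <- sapply(1:10, function(s) {
    ref <- simulate_growth_plate(list(g = p), plate_ph_levels(), 3, 0.05,
                                 seed = 100 + s)
    alt <- simulate_growth_plate(list(g = ko), plate_ph_levels(), 3, 0.05,
                                 seed = 200 + s)
    cmp <- compare_ph50(ref, alt, n_boot = 40, seed = s)
    cmp$ci_lo <= true_delta && true_delta <= cmp$ci_hi
  })
  expect_gte(mean(hits), 0.9)
})

test_that("fit accessors expose tidy, glance, augment and autoplot", {
  plate <- simulate_growth_plate(list(wt = wt_params()), plate_ph_levels(),
                                 n_reps = 3, noise_cv = 0.03, seed = 2)
  fit <- fit_biphasic(plate)
  expect_named(tidy(fit), c("term", "estimate"))
  gl <- glance(fit)
  expect_true(gl$ph50 < gl$ph_opt)
  aug <- augment(fit)
  expect_equal(aug$.resid, aug$absorbance - aug$.fitted)
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
})
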